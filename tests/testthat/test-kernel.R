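mi_kb <- load_kb(system.file("extdata", "mi.yaml", package = "dominoagent"))

fresh_c <- function() build_agents(mi_kb)$C

test_that("belief maintenance chains chest pain to the specific possibility of an infarction", {
  ag <- fresh_c()
  s1_maintain_beliefs(ag, list(atom("chest_pain", "present"),
                               atom("patient", "elderly")))
  keys <- wm_belief_keys(ag$wm)
  expect_true("possible=heart_attack" %in% keys)
  expect_true("possible=myocardial_infarction" %in% keys)
})

test_that("belief maintenance is idempotent and a no-op without applicable rules", {
  ag <- fresh_c()
  s1_maintain_beliefs(ag, list(atom("chest_pain", "present")))
  snap <- sort(wm_belief_keys(ag$wm))
  n_items <- length(ag$wm$items)
  produced <- s1_maintain_beliefs(ag, list())
  expect_length(produced, 0)
  expect_identical(sort(wm_belief_keys(ag$wm)), snap)
  expect_identical(length(ag$wm$items), n_items)
})

test_that("the s1 fixpoint equals naive repeat-until-no-change iteration on random rule bases", {
  for (i in 1:200) {
    fx <- generate_random_fixture(i + 500, n_concepts = 2L, n_rules = 5L,
                                  n_beliefs = 4L)
    ag <- agent_new("t", fx$onto)
    s1_maintain_beliefs(ag, fx$beliefs)
    expect_identical(sort(unique(wm_belief_keys(ag$wm))),
                     fixpoint_oracle(fx$onto$rules, fx$beliefs))
  }
})

test_that("a cyclic rule base terminates by duplicate suppression", {
  onto <- ontology(rules = list(
    rule("r1", "belief", when = atom("a", "1"), then = list(atom("b", "1"))),
    rule("r2", "belief", when = atom("b", "1"), then = list(atom("a", "1")))))
  ag <- agent_new("t", onto)
  s1_maintain_beliefs(ag, list(atom("a", "1")))
  expect_setequal(unique(wm_belief_keys(ag$wm)), c("a=1", "b=1"))
})

test_that("the chronic-pain presentation raises the two decision goals", {
  ag <- build_agents(mi_kb)$S   # shared rule, any decision agent
  s1_maintain_beliefs(ag, list(atom("pain", "severe"),
                               atom("pain", "chronic")))
  ids <- s2_raise_goals(ag)
  tmpls <- vapply(ids, function(i) ag$wm$items[[as.character(i)]]$content$template,
                  character(1))
  expect_setequal(tmpls, c("decide_cause", "decide_preferred_treatment"))
  # duplicates suppressed on the next pass
  expect_length(s2_raise_goals(ag), 0)
})

test_that("the manage goal raises the clotting and pain sub-goals under it", {
  ag <- fresh_c()
  s1_maintain_beliefs(ag, list(atom("chest_pain", "present"),
                               atom("patient", "elderly")))
  s2_raise_goals(ag)  # manage_mi
  ids <- s2_raise_goals(ag)  # its sub-goals
  items <- lapply(ids, function(i) ag$wm$items[[as.character(i)]])
  tmpls <- vapply(items, function(it) it$content$template, character(1))
  expect_true(all(c("prevent_clotting", "prevent_pain",
                    "treatment_decision") %in% tmpls))
  parent <- goal_item_for_test(ag, "manage_mi")
  for (it in items) expect_identical(it$content$parent, parent)
  expect_length(s2_raise_goals(agent_new("empty", ontology())), 0)
})

test_that("candidate retrieval finds the two drugs; a goal with no indexed solutions records an impasse", {
  ag <- fresh_c()
  s1_maintain_beliefs(ag, list(atom("chest_pain", "present"),
                               atom("patient", "elderly")))
  s2_raise_goals(ag); s2_raise_goals(ag)
  git <- ag$wm$items[[as.character(goal_item_for_test(ag,
                                                      "treatment_decision"))]]
  cands <- s3_generate_candidates(ag, git)
  expect_setequal(vapply(cands, `[[`, character(1), "payload"),
                  c("clopidogrel", "aspirin"))
  # an accept-mode goal with no candidate source suspends with an impasse
  s1_maintain_beliefs(ag, list(atom("pain", "severe"),
                               atom("pain", "chronic")))
  s2_raise_goals(ag)
  git2 <- ag$wm$items[[as.character(goal_item_for_test(ag, "decide_cause"))]]
  expect_length(s3_generate_candidates(ag, git2), 0)
  expect_true(any(vapply(ag$impasses, function(im) {
    identical(im$goal, "decide_cause")
  }, logical(1))))
})

test_that("a single candidate on a routine goal commits firm; unresolved ties impasse when tie-breaking is off", {
  onto <- ontology(
    goals = list(goal_template("pick", atom("picked", "yes"),
                               mode = "adopt")),
    rules = list(rule("c1", "candidate", then = "only_option",
                      when_goal = "pick")))
  ag <- agent_new("t", onto)
  wm_assert(ag$wm, "goal",
            list(template = "pick", condition = atom("picked", "yes"),
                 parent = NULL, priority = 1L, stakes = "routine",
                 mode = "adopt", accept_attr = NULL, consult = NULL,
                 status = "active"),
            justification("assumption"))
  git <- wm_active(ag$wm, "goal")[[1]]
  cid <- decide(ag, git)
  expect_false(is.na(cid))
  expect_equal(ag$wm$items[[as.character(cid)]]$content$firmness, "firm")
  # the firm commitment settles the goal's condition
  expect_true("picked=yes" %in% wm_belief_keys(ag$wm))

  onto2 <- ontology(
    goals = list(goal_template("pick2", atom("p2", "yes"), mode = "adopt")),
    rules = list(rule("c2", "candidate", then = c("x", "y"),
                      when_goal = "pick2")))
  ag2 <- agent_new("t2", onto2, tie_break = "none")
  wm_assert(ag2$wm, "goal",
            list(template = "pick2", condition = atom("p2", "yes"),
                 parent = NULL, priority = 1L, stakes = "routine",
                 mode = "adopt", accept_attr = NULL, consult = NULL,
                 status = "active"),
            justification("assumption"))
  cid2 <- decide(ag2, wm_active(ag2$wm, "goal")[[1]])
  expect_true(is.na(cid2))
  expect_true(any(vapply(ag2$impasses, function(im) {
    identical(im$reason, "unresolved tie")
  }, logical(1))))
})

test_that("an accepted hypothesis becomes a belief independent of the goal", {
  onto <- ontology(
    goals = list(goal_template("diagnose", atom("diagnosis", "decided"),
                               mode = "accept", accept_attr = "diagnosis")),
    rules = list(rule("c1", "candidate", then = "gastric_ulcer",
                      when_goal = "diagnose")))
  ag <- agent_new("t", onto)
  wm_assert(ag$wm, "goal",
            list(template = "diagnose",
                 condition = atom("diagnosis", "decided"), parent = NULL,
                 priority = 1L, stakes = "routine", mode = "accept",
                 accept_attr = "diagnosis", consult = NULL,
                 status = "active"),
            justification("assumption"))
  decide(ag, wm_active(ag$wm, "goal")[[1]])
  expect_true("diagnosis=gastric_ulcer" %in% wm_belief_keys(ag$wm))
})

soap_plan_item <- function(ag) {
  pt <- plan_template("soap", list(
    list(id = "subjective", type = "enquiry"),
    list(id = "objective", type = "enquiry"),
    list(id = "assess", type = "decision",
         after = c("subjective", "objective")),
    list(id = "plan", type = "action", after = "assess")))
  status <- stats::setNames(rep("pending", 4), names(pt$tasks))
  id <- wm_assert(ag$wm, "plan",
                  list(template = "soap", tasks = pt$tasks,
                       status = status, goal = NULL),
                  justification("assumption"))
  ag$wm$items[[as.character(id)]]
}

test_that("the assessment decision is not enabled until both enquiries are done", {
  ag <- agent_new("t", ontology())
  pit <- soap_plan_item(ag)
  expect_setequal(s7_enact(ag, pit), c("subjective", "objective"))
  plan_mark_done(ag, pit, "subjective")
  pit <- ag$wm$items[[as.character(pit$id)]]
  expect_identical(s7_enact(ag, pit), "objective")
  plan_mark_done(ag, pit, "objective")
  pit <- ag$wm$items[[as.character(pit$id)]]
  expect_identical(s7_enact(ag, pit), "assess")
  # an empty plan enables nothing
  id <- wm_assert(ag$wm, "plan",
                  list(template = "empty", tasks = list(),
                       status = stats::setNames(character(0), character(0)),
                       goal = NULL),
                  justification("assumption"))
  expect_length(s7_enact(ag, ag$wm$items[[as.character(id)]]), 0)
})

test_that("enabled tasks equal the brute-force predecessor check on random acyclic networks", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    tasks <- lapply(seq_len(n), function(k) {
      after <- if (k > 1L) {
        pool <- paste0("t", seq_len(k - 1L))
        pool[stats::runif(k - 1L) < 0.4]
      } else character(0)
      list(id = paste0("t", k), type = "action", after = after)
    })
    pt <- plan_template(paste0("p", i), tasks)
    status <- stats::setNames(sample(c("pending", "done"), n,
                                     replace = TRUE),
                              names(pt$tasks))
    ag <- agent_new("t", ontology())
    id <- wm_assert(ag$wm, "plan",
                    list(template = pt$id, tasks = pt$tasks,
                         status = status, goal = NULL),
                    justification("assumption"))
    got <- s7_enact(ag, ag$wm$items[[as.character(id)]])
    want <- names(pt$tasks)[vapply(pt$tasks, function(t) {
      status[t$id] == "pending" &&
        all(vapply(t$after, function(d) status[d] == "done", logical(1)))
    }, logical(1))]
    expect_setequal(c(got, ""), c(want, ""))
  }
})

test_that("an action with an unsatisfied precondition is postponed, then discarded after retries", {
  ag <- agent_new("t", ontology())
  pt <- plan_template("p", list(list(id = "act", type = "action",
                                     precondition = atom("ready", "yes"))))
  id <- wm_assert(ag$wm, "plan",
                  list(template = "p", tasks = pt$tasks,
                       status = c(act = "pending"), goal = NULL),
                  justification("assumption"))
  pit <- ag$wm$items[[as.character(id)]]
  for (k in 1:3) {
    expect_length(s8_execute(ag, pit, pit$content$tasks$act,
                             max_retries = 3L), 0)
    pit <- ag$wm$items[[as.character(id)]]
    expect_equal(pit$content$status[["act"]], "pending")
  }
  s8_execute(ag, pit, pit$content$tasks$act, max_retries = 3L)
  pit <- ag$wm$items[[as.character(id)]]
  expect_equal(pit$content$status[["act"]], "discarded")
})

test_that("a violated expectation asserts a violation belief justified by both sides", {
  ag <- agent_new("t", ontology())
  eid <- wm_assert(ag$wm, "expectation",
                   list(predicted = atom("feedback", "positive"),
                        origin = NULL, window = NULL),
                   justification("assumption"))
  obs <- atom("feedback", "negative")
  s1_maintain_beliefs(ag, list(obs))
  v <- s9_monitor(ag, list(obs))
  expect_length(v, 1)
  it <- ag$wm$items[[as.character(v)]]
  expect_equal(it$content$attr, "expectation_violation")
  expect_true(eid %in% it$justifications[[1]]$supports)
  # the matched case closes the expectation without a violation
  ag2 <- agent_new("t2", ontology())
  eid2 <- wm_assert(ag2$wm, "expectation",
                    list(predicted = atom("feedback", "positive"),
                         origin = NULL, window = NULL),
                    justification("assumption"))
  ok <- atom("feedback", "positive")
  s1_maintain_beliefs(ag2, list(ok))
  expect_length(s9_monitor(ag2, list(ok)), 0)
  expect_equal(ag2$wm$items[[as.character(eid2)]]$status, "retracted")
  # with no active expectations the observation is handled by s1 alone
  ag3 <- agent_new("t3", ontology())
  s1_maintain_beliefs(ag3, list(ok))
  expect_length(s9_monitor(ag3, list(ok)), 0)
})

test_that("running the same decision twice increments the context-decision counter to two", {
  for (k in 1:2) {
    run <- run_mi_scenario(seed = 1,
                           path = system.file("extdata", "mi.yaml",
                                              package = "dominoagent"))
    if (k == 1L) {
      cnt <- run$agents$C$counters
      expect_equal(unname(cnt[["treatment_decision|clopidogrel"]]), 1)
      expect_length(run$agents$C$episodes, 1)
      epi <- run$agents$C$episodes[[1]]
      expect_identical(epi$episode$goal, "treatment_decision")
      expect_identical(epi$episode$decision, "clopidogrel")
      expect_true("possible=myocardial_infarction" %in%
                    epi$episode$beliefs)
      expect_identical(epi$provenance, "learned")
    }
  }
  # same agent deciding the same goal twice: counter reaches two
  onto <- ontology(
    goals = list(goal_template("pick", atom("picked", "yes"),
                               mode = "adopt")),
    rules = list(rule("c1", "candidate", then = "opt", when_goal = "pick")))
  ag <- agent_new("t", onto)
  for (k in 1:2) {
    gid <- wm_assert(ag$wm, "goal",
                     list(template = "pick",
                          condition = atom("picked", "yes"), parent = NULL,
                          priority = 1L, stakes = "routine",
                          mode = "adopt", accept_attr = NULL,
                          consult = NULL, status = "active"),
                     justification("assumption"))
    git <- ag$wm$items[[as.character(gid)]]
    decide(ag, git)
    s10_learn(ag, git)
    # reset for the second pass
    wm_retract(ag$wm, gid, cascade = TRUE)
    bel <- wm_query(ag$wm, "belief", atom("picked", "yes"))
    if (length(bel)) wm_retract(ag$wm, bel[[1]]$item$id, cascade = TRUE)
  }
  expect_equal(unname(ag$counters[["pick|opt"]]), 2)
})

test_that("learned frequency counters can weight a later tie", {
  onto <- ontology(
    goals = list(goal_template("pick", atom("picked", "yes"),
                               mode = "adopt")),
    rules = list(rule("c1", "candidate", then = c("left", "right"),
                      when_goal = "pick")))
  ag <- agent_new("t", onto, use_frequency = TRUE,
                  tie_break = "lexicographic")
  ag$counters[["pick|right"]] <- 3
  gid <- wm_assert(ag$wm, "goal",
                   list(template = "pick", condition = atom("picked", "yes"),
                        parent = NULL, priority = 1L, stakes = "routine",
                        mode = "adopt", accept_attr = NULL, consult = NULL,
                        status = "active"),
                   justification("assumption"))
  decide(ag, ag$wm$items[[as.character(gid)]])
  dec <- ag$decisions[[as.character(gid)]]
  expect_identical(dec$preference[1], "right")
  expect_gt(dec$merits[["right"]], dec$merits[["left"]])
})

test_that("an empty agent in an empty environment quiesces after one cycle", {
  ag <- agent_new("t", ontology())
  tr <- run_cycle(ag, environment = NULL, max_cycles = 10)
  expect_true(attr(tr, "complete"))
  expect_equal(ag$wm$clock, 1L)
})

test_that("retracting a goal retracts the plan adopted under it", {
  onto <- ontology(
    goals = list(goal_template("pick", atom("picked", "yes"),
                               mode = "adopt")),
    rules = list(rule("c1", "candidate", then = "opt", when_goal = "pick")))
  ag <- agent_new("t", onto)
  gid <- wm_assert(ag$wm, "goal",
                   list(template = "pick", condition = atom("picked", "yes"),
                        parent = NULL, priority = 1L, stakes = "routine",
                        mode = "adopt", accept_attr = NULL, consult = NULL,
                        status = "active"),
                   justification("assumption"))
  git <- ag$wm$items[[as.character(gid)]]
  decide(ag, git)
  expect_length(wm_active(ag$wm, "plan"), 1)
  expect_length(wm_active(ag$wm, "commitment"), 1)
  drop_goal(ag, git)
  expect_length(wm_active(ag$wm, "plan"), 0)
  expect_length(wm_active(ag$wm, "commitment"), 0)
})

test_that("every trace record names the canon that produced it and its items", {
  run <- run_mi_scenario(seed = 2)
  for (rec in run$trace) {
    expect_true(rec$canon %in% c(paste0("s", 1:10), "trial"))
    expect_true(is.integer(rec$consumed))
    expect_true(is.integer(rec$produced))
    expect_true(nzchar(rec$agent))
  }
  # produced ids are unique across each agent's trace
  for (ag in run$agents) {
    prod <- unlist(lapply(ag$trace, `[[`, "produced"))
    expect_false(anyDuplicated(prod) > 0)
  }
})

test_that("executing a communication act enqueues a message; effects assert expectations", {
  sb <- switchboard_new()
  ag <- agent_new("A", ontology())
  register_agent(sb, ag)
  register_agent(sb, agent_new("B", ontology(), roles = "records"))
  pt <- plan_template("talk", list(
    list(id = "ask", type = "action", performative = "query",
         receiver = "B", content = list(type = "case_query"),
         dialog = "d1")))
  id <- wm_assert(ag$wm, "plan",
                  list(template = "talk", tasks = pt$tasks,
                       status = c(ask = "pending"), goal = NULL),
                  justification("assumption"))
  pit <- ag$wm$items[[as.character(id)]]
  s8_execute(ag, pit, pit$content$tasks$ask, switchboard = sb)
  expect_equal(sb$sent, 1L)
  expect_equal(sb$queue[[1]]$performative, "query")

  # an environment act applies the transition and asserts its expectation
  env <- list(observe = function(id, cyc) list(),
              apply = function(action) list(atom("door", "open")))
  ag2 <- agent_new("C", ontology())
  pt2 <- plan_template("open", list(
    list(id = "push", type = "action",
         effect = list(atom = list("door", "open")))))
  id2 <- wm_assert(ag2$wm, "plan",
                   list(template = "open", tasks = pt2$tasks,
                        status = c(push = "pending"), goal = NULL),
                   justification("assumption"))
  pit2 <- ag2$wm$items[[as.character(id2)]]
  obs <- s8_execute(ag2, pit2, pit2$content$tasks$push, environment = env)
  expect_length(obs, 1)
  expect_length(wm_active(ag2$wm, "expectation"), 1)
  expect_equal(ag2$wm$items[[as.character(id2)]]$content$status[["push"]],
               "done")
})
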