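#' Construct a plan template (task network)
#'
#' A plan is a network of tasks -- enquiries, decisions, actions, and
#' sub-plans -- whose scheduling constraints are completion dependencies
#' (a task may not start until the tasks it is `after` have been done) and
#' whose preconditions are descriptions over the current beliefs. The
#' clinical SOAP pattern (two enquiries that may run in either order,
#' followed by an assessment decision, followed by a plan) is the canonical
#' example.
#'
#' @param id plan template identifier
#' @param tasks list of task nodes: each `list(id, type, after =
#'   character(), precondition = NULL, ...)` with `type` one of
#'   `"enquiry"`, `"decision"`, `"action"`, `"subplan"`; action nodes may
#'   carry `performative`/`content` fields (communication acts) or an
#'   `effect` description (expected observation)
#' @return a `plan_template` object
#' @export
plan_template <- function(id, tasks) {
  tids <- vapply(tasks, `[[`, character(1), "id")
  if (anyDuplicated(tids)) stop("plan '", id, "': duplicate task ids")
  tasks <- lapply(tasks, function(t) {
    t$after <- as.character(t$after %||% character(0))
    bad <- setdiff(t$after, tids)
    if (length(bad)) {
      stop("plan '", id, "': task '", t$id, "' depends on unknown task(s) ",
           paste(bad, collapse = ", "))
    }
    if (!is.null(t$precondition)) t$precondition <- parse_desc(t$precondition)
    t
  })
  names(tasks) <- tids
  # dependency graph must be acyclic: Kahn's algorithm
  indeg <- vapply(tasks, function(t) length(t$after), integer(1))
  done <- character(0)
  repeat {
    ready <- names(indeg)[indeg == 0L & !names(indeg) %in% done]
    if (!length(ready)) break
    done <- c(done, ready)
    for (t in tasks) {
      if (any(t$after %in% ready)) {
        indeg[t$id] <- length(setdiff(t$after, done))
      }
    }
  }
  if (length(done) != length(tasks)) {
    stop("plan '", id, "': task dependency graph is cyclic")
  }
  structure(list(id = id, tasks = tasks), class = "plan_template")
}

#' Create an agent
#'
#' An agent bundles an ontology (shared knowledge merged with any
#' specialist partition), a working memory, a trace, an episodic store and
#' decision-frequency counters, and configuration (aggregator, tie-break
#' policy, registered candidate-generation strategies).
#'
#' @param id agent identifier
#' @param onto the agent's [ontology()] (already merged with its
#'   specialist partition, or use `partition`)
#' @param partition optional specialist ontology merged into `onto`
#' @param roles character vector of role tags (e.g. `"lead"`,
#'   `"specialist"`, `"records"`)
#' @param aggregator merit aggregator name
#' @param tie_break preference tie-break policy (`"none"` records an
#'   impasse on an unresolved tie)
#' @param use_frequency add the learned-frequency bonus during aggregation
#' @param case named list of case facts served by a records-role agent
#'   (attribute -> value)
#' @return an `agent` environment
#' @export
agent_new <- function(id, onto, partition = NULL, roles = "decision",
                      aggregator = "bentham",
                      tie_break = c("random", "lexicographic", "priority",
                                    "none"),
                      use_frequency = FALSE, case = NULL) {
  tie_break <- match.arg(tie_break)
  if (!is.null(partition)) onto <- merge_ontology(onto, partition)
  ag <- new.env(parent = emptyenv())
  ag$id <- id
  ag$onto <- onto
  ag$roles <- roles
  ag$wm <- wm_new(id)
  ag$trace <- list()
  ag$episodes <- list()
  ag$counters <- numeric(0)
  ag$decisions <- list()
  ag$history <- list()
  ag$impasses <- list()
  ag$consulted <- character(0)
  ag$dialogs <- list()
  ag$pending <- list()
  ag$config <- list(aggregator = aggregator, tie_break = tie_break,
                    use_frequency = use_frequency, frequency_weight = 1,
                    max_derivation_depth = 100L, strategies = list())
  ag$case <- case
  class(ag) <- "agent"
  ag
}

#' @export
print.agent <- function(x, ...) {
  cat("<agent", x$id, "> roles:", paste(x$roles, collapse = ", "), "\n")
  print(x$wm)
  invisible(x)
}

trace_add <- function(agent, canon, consumed = integer(0),
                      produced = integer(0), info = list()) {
  agent$trace[[length(agent$trace) + 1L]] <-
    list(cycle = agent$wm$clock, agent = agent$id, canon = canon,
         consumed = as.integer(consumed), produced = as.integer(produced),
         info = info)
  invisible(NULL)
}

active_goal_items <- function(agent) {
  Filter(function(it) it$content$status %in% c("raised", "active"),
         wm_active(agent$wm, "goal"))
}

active_goal_templates <- function(agent) {
  vapply(active_goal_items(agent), function(it) it$content$template,
         character(1))
}

goal_item_for <- function(agent, template) {
  for (it in wm_active(agent$wm, "goal")) {
    if (identical(it$content$template, template)) return(it)
  }
  NULL
}

# --- S1: belief maintenance ------------------------------------------------

#' S1 -- maintain beliefs
#'
#' Ingests the cycle's observations (each becomes an observation item plus
#' a belief justified by it) and then propagates beliefs forward through
#' the belief rules of the ontology to the derivation fixpoint. Consistency
#' is restored on each assertion by the working-memory policy. Terminates
#' on cyclic rule bases because re-assertion of an already-active duplicate
#' is a no-op; a derivation-depth guard catches genuinely productive
#' cycles.
#'
#' @param agent an [agent_new()] agent
#' @param observations list of ground atoms (optionally with a `source`
#'   attribute, `"environment"` or `"message"`)
#' @return integer vector of item ids produced
#' @export
s1_maintain_beliefs <- function(agent, observations = list()) {
  wm <- agent$wm
  first_new <- wm$next_id
  produced <- integer(0)
  for (obs in observations) {
    src <- attr(obs, "source") %||% "environment"
    jkind <- if (identical(src, "message")) "communication" else "observation"
    oid <- wm_assert(wm, "observation", obs, justification(jkind))
    if (is.na(oid)) next
    bid <- wm_assert(wm, "belief", obs,
                     justification("inference", supports = oid))
    produced <- c(produced, oid, bid)
  }
  depth <- 0L
  repeat {
    depth <- depth + 1L
    if (depth > agent$config$max_derivation_depth) {
      stop("s1: derivation depth guard exceeded (",
           agent$config$max_derivation_depth,
           "); check the belief rules for a productive cycle")
    }
    atoms <- wm_belief_atoms(wm)
    keys <- vapply(atoms, atom_key, character(1))
    grew <- FALSE
    for (kind in c("belief", "expectation")) {
      recs <- applicable_rules(atoms, kind, agent$onto,
                               active_goals = active_goal_templates(agent))
      for (rec in recs) {
        for (cq in rec$consequents) {
          if (cq$type == "atom" && atom_key(cq) %in% keys) next
          just <- justification("inference",
                                supports = unique(rec$support),
                                rule = rec$rule)
          id <- if (kind == "belief") {
            wm_assert(wm, "belief", cq, just)
          } else {
            wm_assert(wm, "expectation",
                      list(predicted = cq, origin = rec$rule, window = NULL),
                      just)
          }
          if (!is.na(id) && !id %in% produced &&
              !(kind == "belief" && atom_key(cq) %in% keys)) {
            produced <- c(produced, id)
            grew <- TRUE
          }
        }
      }
    }
    if (!grew) break
  }
  produced <- unique(produced[produced >= first_new])
  trace_add(agent, "s1", produced = produced,
            info = list(n_observations = length(observations)))
  produced
}

# --- S2: raise goals -------------------------------------------------------

#' S2 -- raise goals and sub-goals
#'
#' Fires the goal rules: belief-triggered rules raise top-level goals,
#' goal-guarded rules (`when_goal`) raise sub-goals under the active parent
#' goal. A goal is raised only if its condition does not already hold and
#' no goal for the same template exists (duplicate suppression). Each new
#' goal is justified by the triggering beliefs or parent goal.
#'
#' @param agent an agent
#' @return integer vector of new goal item ids
#' @export
s2_raise_goals <- function(agent) {
  wm <- agent$wm
  first_new <- wm$next_id
  atoms <- wm_belief_atoms(wm)
  keys <- vapply(atoms, atom_key, character(1))
  produced <- integer(0)
  existing <- vapply(wm_active(wm, "goal"), function(it) it$content$template,
                     character(1))
  recs <- applicable_rules(atoms, "goal", agent$onto,
                           active_goals = active_goal_templates(agent))
  for (rec in recs) {
    parent <- NULL
    if (!is.null(agent$onto$rules[[rec$rule]]$when_goal)) {
      pit <- goal_item_for(agent, agent$onto$rules[[rec$rule]]$when_goal)
      if (!is.null(pit)) parent <- pit
    }
    for (gid in rec$consequents) {
      if (gid %in% existing) next
      tmpl <- agent$onto$goals[[gid]]
      if (is.null(tmpl)) stop("rule '", rec$rule,
                              "' raises unknown goal template '", gid, "'")
      if (holds(tmpl$condition, keys, closed_world = TRUE) == "true") next
      content <- list(template = gid, condition = tmpl$condition,
                      parent = if (is.null(parent)) NULL else parent$id,
                      priority = tmpl$priority, stakes = tmpl$stakes,
                      mode = tmpl$mode, accept_attr = tmpl$accept_attr,
                      consult = tmpl$consult, status = "active")
      sup <- unique(c(rec$support,
                      if (!is.null(parent)) parent$id))
      id <- wm_assert(wm, "goal", content,
                      justification("inference", supports = sup,
                                    rule = rec$rule,
                                    goal = if (!is.null(parent))
                                      parent$content$template))
      produced <- c(produced, id)
      existing <- c(existing, gid)
    }
  }
  produced <- produced[produced >= first_new]
  trace_add(agent, "s2", produced = produced)
  produced
}

# --- S3: generate candidates ----------------------------------------------

#' S3 -- generate decision candidates
#'
#' The default strategy is retrieval: candidate rules guarded by the goal
#' supply payload (concept or plan-template) ids from the knowledge base.
#' Scenario modules may register constructive strategies per goal template
#' (`agent$config$strategies[[template]]`, a function of the agent and the
#' goal item returning payload ids). An empty candidate set logs an
#' impasse and suspends the goal.
#'
#' @param agent an agent
#' @param goal_item an active goal working-memory item
#' @return list of candidate records `list(id, payload, item_id, goal)`
#' @export
s3_generate_candidates <- function(agent, goal_item) {
  wm <- agent$wm
  first_new <- wm$next_id
  tmpl <- goal_item$content$template
  payloads <- character(0)
  via <- list()
  recs <- applicable_rules(wm_belief_atoms(wm), "candidate", agent$onto,
                           active_goals = tmpl)
  for (rec in recs) {
    r <- agent$onto$rules[[rec$rule]]
    if (!identical(r$when_goal, tmpl)) next
    for (p in rec$consequents) {
      if (!p %in% payloads) {
        payloads <- c(payloads, p)
        via[[p]] <- list(rule = rec$rule, support = rec$support)
      }
    }
  }
  strat <- agent$config$strategies[[tmpl]]
  if (!is.null(strat)) {
    for (p in strat(agent, goal_item)) {
      if (!p %in% payloads) {
        payloads <- c(payloads, p)
        via[[p]] <- list(rule = NULL, support = integer(0))
      }
    }
  }
  if (!length(payloads)) {
    agent$impasses[[length(agent$impasses) + 1L]] <-
      list(goal = tmpl, cycle = wm$clock, reason = "no candidates")
    goal_item$content$status <- "raised"   # suspended pending new knowledge
    trace_add(agent, "s3", consumed = goal_item$id,
              info = list(impasse = "no candidates", goal = tmpl))
    return(list())
  }
  kind <- if (identical(goal_item$content$mode, "accept")) "hypothesis"
          else "action_option"
  cands <- list()
  for (p in payloads) {
    content <- list(goal = goal_item$id, payload = p, kind = kind,
                    origin = if (is.null(via[[p]]$rule)) "constructed"
                             else "retrieved")
    id <- wm_assert(wm, "candidate", content,
                    justification("inference",
                                  supports = unique(c(goal_item$id,
                                                      via[[p]]$support)),
                                  rule = via[[p]]$rule,
                                  goal = tmpl))
    cands[[length(cands) + 1L]] <- list(id = p, payload = p, item_id = id,
                                        goal = tmpl)
  }
  new_ids <- vapply(cands, `[[`, integer(1), "item_id")
  trace_add(agent, "s3", consumed = goal_item$id,
            produced = new_ids[new_ids >= first_new],
            info = list(goal = tmpl, n = length(cands)))
  cands
}

# --- S4: construct reasons -------------------------------------------------

#' S4 -- construct reasons
#'
#' Delegates to [construct_arguments()] over the ontology's schemas, then
#' merges in any communicated arguments already present in working memory
#' for this decision (arguments received through explanation dialogs).
#' Every constructed argument is asserted as a working-memory item
#' justified by its grounds.
#'
#' @param agent an agent
#' @param goal_item the decision goal item
#' @param candidates candidate records from [s3_generate_candidates()]
#' @return list of `argument` objects
#' @export
s4_construct_reasons <- function(agent, goal_item, candidates) {
  wm <- agent$wm
  first_new <- wm$next_id
  args <- construct_arguments(candidates, goal_item$content, wm, agent$onto)
  produced <- integer(0)
  for (i in seq_along(args)) {
    a <- args[[i]]
    sup <- unique(c(as.integer(a$grounds$support),
                    candidate_item_id(candidates, a$candidate)))
    id <- wm_assert(wm, "argument",
                    list(goal = goal_item$content$template,
                         candidate = a$candidate, polarity = a$polarity,
                         schema = a$schema, strength = a$strength,
                         grounds = a$grounds),
                    justification("inference", supports = sup[!is.na(sup)],
                                  schema = a$schema,
                                  goal = goal_item$content$template))
    args[[i]]$item_id <- id
    produced <- c(produced, id)
  }
  # communicated arguments held in working memory for this decision; a
  # communicated argument that duplicates a locally constructed one (same
  # candidate, schema, and polarity) is the same line of reasoning heard
  # twice and is not counted again
  comm <- communicated_arguments(agent, goal_item$content$template,
                                 vapply(candidates, `[[`, character(1),
                                        "id"))
  if (length(comm)) {
    have <- vapply(args, function(a) {
      paste(a$candidate, a$schema, a$polarity)
    }, character(1))
    n <- length(args)
    for (a in comm) {
      if (paste(a$candidate, a$schema, a$polarity) %in% have) next
      n <- n + 1L
      a$id <- paste0("a", n)
      args[[n]] <- a
    }
  }
  produced <- produced[produced >= first_new]
  trace_add(agent, "s4", consumed = goal_item$id, produced = produced,
            info = list(n_constructed = length(args) - length(comm),
                        n_communicated = length(comm)))
  args
}

candidate_item_id <- function(candidates, id) {
  for (cd in candidates) if (identical(cd$id, id)) return(cd$item_id)
  NA_integer_
}

communicated_arguments <- function(agent, template, candidate_ids) {
  out <- list()
  for (it in wm_active(agent$wm, "argument")) {
    jkinds <- vapply(it$justifications, `[[`, character(1), "kind")
    if (!"communication" %in% jkinds) next
    ct <- it$content
    if (!identical(ct$goal, template)) next
    if (!ct$candidate %in% candidate_ids) next
    a <- new_argument("a0", ct$candidate, ct$polarity, ct$schema,
                      ct$strength, grounds = ct$grounds)
    a$item_id <- it$id
    out[[length(out) + 1L]] <- a
  }
  out
}

# --- S5: aggregate ---------------------------------------------------------

#' S5 -- aggregate reasons into merits and a preference order
#'
#' Resolves defeat (grounded labelling of the undercut graph), aggregates
#' the undefeated arguments into one merit per candidate with the
#' configured aggregator, and returns the total preference order. Merits
#' are asserted as working-memory items.
#'
#' @param agent an agent
#' @param goal_item the decision goal item
#' @param candidates candidate records
#' @param args arguments from [s4_construct_reasons()]
#' @return `list(arguments, merits, preference)`
#' @export
s5_aggregate <- function(agent, goal_item, candidates, args) {
  first_new <- agent$wm$next_id
  args <- resolve_defeat(args)
  counts <- NULL
  if (isTRUE(agent$config$use_frequency)) {
    counts <- decision_counts(agent, goal_item$content$template)
  }
  merits <- aggregate_merits(candidates, args,
                             aggregator = agent$config$aggregator,
                             counts = counts,
                             count_weight = agent$config$frequency_weight)
  tb <- agent$config$tie_break
  pref <- prefer(candidates, merits,
                 tie_break = if (tb == "none") "lexicographic" else tb)
  produced <- integer(0)
  for (cd in candidates) {
    id <- wm_assert(agent$wm, "merit",
                    list(goal = goal_item$content$template,
                         candidate = cd$id,
                         value = unname(merits[cd$id]),
                         aggregator = agent$config$aggregator),
                    justification("inference",
                                  supports = cd$item_id,
                                  goal = goal_item$content$template))
    produced <- c(produced, id)
  }
  produced <- produced[produced >= first_new]
  trace_add(agent, "s5", consumed = goal_item$id, produced = produced,
            info = list(merits = as.list(merits), preference = pref))
  list(arguments = args, merits = merits, preference = pref)
}

decision_counts <- function(agent, template) {
  pre <- paste0(template, "|")
  keys <- names(agent$counters)
  hit <- startsWith(keys, pre)
  if (!any(hit)) return(NULL)
  stats::setNames(agent$counters[hit], substring(keys[hit], nchar(pre) + 1L))
}

# --- S6: commitment --------------------------------------------------------

#' S6 -- commit to the preferred candidate
#'
#' Commits to the top-ranked candidate. The commitment is *firm* when the
#' top merit strictly exceeds the runner-up, the goal's stakes are routine,
#' and no declared consultation source remains unexploited; otherwise it is
#' *provisional*, and if a consultation source is declared a consultation
#' goal is raised so further information can be sought before acting.
#' Accept-mode commitments (hypothesis choice) assert the accepted belief
#' -- acceptability of a belief is independent of the agent's goals, so the
#' belief stands on the commitment, not on the goal. Adopt-mode commitments
#' retain the goal and instantiate the serving plan template (or a
#' singleton enactment plan when none is declared); they last only as long
#' as the goal is extant.
#'
#' An unresolved tie at the top with the `"none"` tie-break policy records
#' an impasse and makes no commitment.
#'
#' @param agent an agent
#' @param goal_item the decision goal item
#' @param candidates candidate records
#' @param decision result of [s5_aggregate()]
#' @return the commitment item id, or `NA_integer_` on impasse
#' @export
s6_commit <- function(agent, goal_item, candidates, decision) {
  wm <- agent$wm
  first_new <- wm$next_id
  pref <- decision$preference
  if (!length(pref)) stop("s6: empty preference order")
  merits <- decision$merits
  top <- pref[1]
  tied <- length(pref) > 1L && merits[pref[2]] == merits[top]
  if (tied && agent$config$tie_break == "none") {
    agent$impasses[[length(agent$impasses) + 1L]] <-
      list(goal = goal_item$content$template, cycle = wm$clock,
           reason = "unresolved tie")
    trace_add(agent, "s6", consumed = goal_item$id,
              info = list(impasse = "unresolved tie"))
    return(NA_integer_)
  }
  g <- goal_item$content
  strict <- length(pref) == 1L || merits[top] > merits[pref[2]]
  consult <- g$consult
  if (identical(consult, agent$id)) consult <- NULL
  consult_pending <- !is.null(consult) &&
    !g$template %in% agent$consulted
  # firm only when no further information could change the preference:
  # strict winner, and either routine stakes or the declared consultation
  # for a high-stakes goal has been carried out
  firmness <- if (strict && !consult_pending &&
                  (identical(g$stakes, "routine") ||
                   g$template %in% agent$consulted)) "firm"
              else "provisional"

  # replace any earlier commitment on this goal (re-decision)
  old <- agent$decisions[[as.character(goal_item$id)]]
  if (!is.null(old) && !is.na(old$commitment_id)) {
    oldit <- wm$items[[as.character(old$commitment_id)]]
    if (!is.null(oldit) && oldit$status == "active" &&
        oldit$content$firmness == "provisional") {
      wm_retract(wm, old$commitment_id, cascade = FALSE)
    }
  }

  mode <- g$mode %||% "adopt"
  cid <- wm_assert(wm, "commitment",
                   list(mode = mode, candidate = top,
                        goal = goal_item$id, firmness = firmness),
                   justification("commitment",
                                 supports = c(goal_item$id,
                                              candidate_item_id(candidates,
                                                                top)),
                                 goal = g$template))
  produced <- cid
  if (firmness == "firm") {
    if (mode == "accept") {
      bid <- wm_assert(wm, "belief",
                       atom(g$accept_attr %||% "accepted", top),
                       justification("commitment", supports = cid,
                                     goal = g$template))
      produced <- c(produced, bid)
    }
    if (mode == "adopt") {
      pid <- instantiate_plan(agent, goal_item, top, cid)
      produced <- c(produced, pid)
    }
    # a firm commitment settles the decision goal's condition
    if (g$condition$type == "atom" && !g$condition$neg) {
      did <- wm_assert(wm, "belief", g$condition,
                       justification("commitment", supports = cid,
                                     goal = g$template))
      produced <- c(produced, did)
    }
  }
  if (firmness == "provisional" && consult_pending) {
    cg <- consultation_goal(agent, goal_item, consult)
    produced <- c(produced, cg)
  }
  rec <- list(goal = g$template, candidates = candidates,
              arguments = decision$arguments, merits = merits,
              preference = pref, commitment_id = cid, firmness = firmness,
              cycle = wm$clock)
  agent$decisions[[as.character(goal_item$id)]] <- rec
  agent$history[[length(agent$history) + 1L]] <- rec
  trace_add(agent, "s6", consumed = goal_item$id,
            produced = produced[produced >= first_new],
            info = list(candidate = top, firmness = firmness, mode = mode))
  cid
}

instantiate_plan <- function(agent, goal_item, payload, commitment_id) {
  tmpl <- goal_item$content$template
  plan_id <- NULL
  for (tm in agent$onto$tasks) {
    if (identical(tm$serves, tmpl)) plan_id <- tm$plan
  }
  if (!is.null(plan_id) && payload %in% names(agent$onto$plans)) {
    plan_id <- payload
  }
  pt <- if (!is.null(plan_id)) agent$onto$plans[[plan_id]] else
    if (payload %in% names(agent$onto$plans)) agent$onto$plans[[payload]] else
    plan_template(paste0("enact_", payload),
                  list(list(id = paste0("do_", payload), type = "action",
                            concept = payload)))
  status <- stats::setNames(rep("pending", length(pt$tasks)),
                            names(pt$tasks))
  wm_assert(agent$wm, "plan",
            list(template = pt$id, tasks = pt$tasks, status = status,
                 goal = goal_item$id),
            justification("commitment", supports = commitment_id,
                          goal = tmpl))
}

consultation_goal <- function(agent, goal_item, consult) {
  tmpl <- goal_item$content$template
  ctmpl <- paste0("consult:", tmpl)
  if (!is.null(goal_item_for(agent, ctmpl))) return(integer(0))
  content <- list(template = ctmpl,
                  condition = atom("consulted", tmpl),
                  parent = goal_item$id, priority = 0L, stakes = "routine",
                  mode = NULL, accept_attr = NULL, consult = NULL,
                  status = "active", consult_target = consult,
                  about = tmpl)
  wm_assert(agent$wm, "goal", content,
            justification("inference", supports = goal_item$id,
                          goal = tmpl))
}

# --- S7: plan enactment ----------------------------------------------------

#' S7 -- enact a plan
#'
#' Returns the plan's enabled tasks: pending tasks whose completion
#' dependencies are all done and whose preconditions hold under the current
#' beliefs. Completed sub-plans fold back (a subplan task is done when its
#' instantiated plan's tasks are all done). Tasks whose preconditions fail
#' are left pending (the repair hook postpones by default).
#'
#' @param agent an agent
#' @param plan_item a plan working-memory item
#' @return character vector of enabled task ids
#' @export
s7_enact <- function(agent, plan_item) {
  p <- plan_item$content
  keys <- wm_belief_keys(agent$wm)
  enabled <- character(0)
  for (t in p$tasks) {
    if (p$status[t$id] != "pending") next
    if (!all(p$status[t$after] == "done")) next
    if (!is.null(t$precondition) &&
        holds(t$precondition, keys, closed_world = TRUE) != "true") next
    enabled <- c(enabled, t$id)
  }
  trace_add(agent, "s7", consumed = plan_item$id,
            info = list(enabled = enabled))
  enabled
}

#' Mark a plan task complete
#' @param agent an agent
#' @param plan_item plan item
#' @param task_id task to mark done
#' @return invisibly, the plan item id
#' @export
plan_mark_done <- function(agent, plan_item, task_id) {
  it <- wm_get(agent$wm, plan_item$id)
  it$content$status[task_id] <- "done"
  wm_put(agent$wm, it)
  invisible(it$id)
}

# --- S8: action ------------------------------------------------------------

#' S8 -- execute an action
#'
#' An action is a plan step that cannot be decomposed further. If its
#' logical preconditions hold it is executed: an environment act is applied
#' through the environment interface and its effect expectations asserted;
#' a communication act is enqueued on the switchboard. On unsatisfied
#' preconditions the action is postponed (requeued) and a postponement
#' record traced; after `max_retries` postponements it is discarded.
#'
#' @param agent an agent
#' @param plan_item the plan item the action belongs to
#' @param task the action task node
#' @param environment environment interface
#'   (`list(observe = function(agent_id, cycle), apply = function(action))`)
#'   or `NULL`
#' @param switchboard a [switchboard_new()] or `NULL`
#' @param max_retries postponements before the action is discarded
#' @return list of effect observations (ground atoms), possibly empty
#' @export
s8_execute <- function(agent, plan_item, task, environment = NULL,
                       switchboard = NULL, max_retries = 3L) {
  wm <- agent$wm
  keys <- wm_belief_keys(wm)
  if (!is.null(task$precondition) &&
      holds(task$precondition, keys, closed_world = TRUE) != "true") {
    it <- wm_get(wm, plan_item$id)
    retries <- (task$retries %||% 0L) + 1L
    it$content$tasks[[task$id]]$retries <- retries
    if (retries > max_retries) {
      it$content$status[task$id] <- "discarded"
      trace_add(agent, "s8", consumed = plan_item$id,
                info = list(task = task$id, outcome = "discarded"))
    } else {
      trace_add(agent, "s8", consumed = plan_item$id,
                info = list(task = task$id, outcome = "postponed",
                            retries = retries))
    }
    wm_put(wm, it)
    return(list())
  }
  obs <- list()
  if (!is.null(task$performative)) {
    if (is.null(switchboard)) stop("communication act without a switchboard")
    msg <- message_new(sender = agent$id, receiver = task$receiver,
                       performative = task$performative,
                       content = task$content, dialog = task$dialog)
    send(switchboard, msg)
  } else if (!is.null(environment)) {
    obs <- environment$apply(list(agent = agent$id, task = task))
  }
  produced <- integer(0)
  if (!is.null(task$effect)) {
    eff <- parse_desc(task$effect)
    eid <- wm_assert(wm, "expectation",
                     list(predicted = eff, origin = plan_item$id,
                          window = c(wm$clock, wm$clock + 2L)),
                     justification("inference", supports = plan_item$id))
    produced <- c(produced, eid)
  }
  plan_mark_done(agent, plan_item, task$id)
  trace_add(agent, "s8", consumed = plan_item$id, produced = produced,
            info = list(task = task$id, outcome = "executed"))
  obs
}

# --- S9: monitoring --------------------------------------------------------

#' S9 -- monitor observations against expectations
#'
#' Each incoming observation is matched against the active expectations. A
#' matched expectation closes (it is retracted as fulfilled). A mismatch --
#' an observation on the same attribute as a predicted atom but with a
#' different value -- asserts an expectation-violation belief justified by
#' both the expectation and the observation; downstream rules or scenario
#' code interpret the violation (e.g. "the sorting rule applied on this
#' trial is incorrect").
#'
#' @param agent an agent
#' @param observations list of ground atoms just ingested
#' @return integer vector of violation belief item ids
#' @export
s9_monitor <- function(agent, observations = list()) {
  wm <- agent$wm
  first_new <- wm$next_id
  violations <- integer(0)
  for (obs in observations) {
    if (obs$type != "atom") next
    for (exp_it in wm_active(wm, "expectation")) {
      pred <- exp_it$content$predicted
      if (pred$type != "atom" || pred$attr != obs$attr) next
      obs_items <- wm_query(wm, pattern = obs)
      obs_id <- if (length(obs_items)) obs_items[[1]]$item$id else integer(0)
      if (pred$value == obs$value && pred$neg == obs$neg) {
        wm_retract(wm, exp_it$id, cascade = FALSE)
      } else {
        vid <- wm_assert(wm, "belief",
                         atom("expectation_violation",
                              as.character(exp_it$id)),
                         justification("inference",
                                       supports = c(exp_it$id, obs_id)))
        violations <- c(violations, vid)
        wm_retract(wm, exp_it$id, cascade = FALSE)
      }
    }
  }
  violations <- unique(violations[violations >= first_new])
  trace_add(agent, "s9", produced = violations,
            info = list(n_observations = length(observations)))
  violations
}

# --- S10: learning ---------------------------------------------------------

#' S10 -- learn from a terminated decision process
#'
#' Two mechanisms, applied when a decision has been committed firmly: (1)
#' an episodic scenario model recording the goal that was active and the
#' beliefs that held at commitment is appended to the agent's ontology;
#' (2) a (context, decision) frequency counter is incremented, which the
#' aggregation step can use to weight options in future decisions.
#'
#' @param agent an agent
#' @param goal_item the terminated decision goal item
#' @return the episode id
#' @export
s10_learn <- function(agent, goal_item) {
  dec <- agent$decisions[[as.character(goal_item$id)]]
  if (is.null(dec)) stop("s10: no decision recorded for goal item ",
                         goal_item$id)
  n <- length(agent$episodes) + 1L
  beliefs <- wm_belief_keys(agent$wm)
  epi_id <- paste0("episode_", agent$id, "_", n)
  epi <- scenario_model(epi_id,
                        label = paste("episode:", dec$goal),
                        situation = d_and(),
                        goals = dec$goal, provenance = "learned",
                        episode = list(goal = dec$goal,
                                       decision = dec$preference[1],
                                       beliefs = beliefs,
                                       cycle = agent$wm$clock))
  agent$episodes[[n]] <- epi
  agent$onto$scenarios[[epi_id]] <- epi
  key <- paste0(dec$goal, "|", dec$preference[1])
  agent$counters[key] <- (agent$counters[key] %||% 0) + 1
  if (is.na(agent$counters[key])) agent$counters[key] <- 1
  trace_add(agent, "s10",
            consumed = goal_item$id,
            info = list(episode = epi_id, counter = key,
                        count = unname(agent$counters[key])))
  epi_id
}

# --- the decision pipeline and cycle ---------------------------------------

#' Run the decision pipeline (S3--S6) on one goal
#'
#' @param agent an agent
#' @param goal_item an active decision goal item
#' @return the commitment id, or `NA_integer_` (impasse / no candidates)
#' @export
decide <- function(agent, goal_item) {
  cands <- s3_generate_candidates(agent, goal_item)
  if (!length(cands)) return(NA_integer_)
  args <- s4_construct_reasons(agent, goal_item, cands)
  dec <- s5_aggregate(agent, goal_item, cands, args)
  s6_commit(agent, goal_item, cands, dec)
}

pending_decision_goals <- function(agent) {
  out <- list()
  for (it in active_goal_items(agent)) {
    g <- it$content
    if (is.null(g$mode)) next
    dec <- agent$decisions[[as.character(it$id)]]
    if (!is.null(dec) && identical(dec$firmness, "firm")) next
    if (!is.null(dec) && identical(dec$firmness, "provisional") &&
        !isTRUE(attr_reconsider(agent, it))) next
    out[[length(out) + 1L]] <- it
  }
  # highest priority first, FIFO (item id) among equals
  if (length(out) > 1L) {
    pr <- vapply(out, function(it) it$content$priority, integer(1))
    ids <- vapply(out, `[[`, integer(1), "id")
    out <- out[order(pr, ids)]
  }
  out
}

# a provisionally decided goal is reconsidered when its consultation has
# completed or new communicated arguments arrived since the decision
attr_reconsider <- function(agent, goal_item) {
  g <- goal_item$content
  if (g$template %in% agent$consulted) return(TRUE)
  dec <- agent$decisions[[as.character(goal_item$id)]]
  for (it in wm_active(agent$wm, "argument")) {
    jkinds <- vapply(it$justifications, `[[`, character(1), "kind")
    if ("communication" %in% jkinds &&
        identical(it$content$goal, g$template) &&
        it$asserted_at >= dec$cycle) {
      return(TRUE)
    }
  }
  FALSE
}

#' Run the decision cycle of a single agent
#'
#' Sequences the canonical operations per cycle: ingest observations, S1
#' to quiescence, S9, S2, the decision pipeline (S3--S6) on the
#' highest-priority pending decision goal, S7/S8 over the active plans,
#' goal-termination check, and S10 on each decision that terminated. The
#' run halts at quiescence (a cycle that ingested nothing and produced
#' nothing) or after `max_cycles` (the trace is then flagged incomplete).
#' With a fixed knowledge base, scenario, and seed the trace is identical
#' across runs.
#'
#' @param agent an agent
#' @param environment environment interface (`observe`/`apply`), or `NULL`
#' @param max_cycles cycle budget
#' @param seed optional integer seed for the kernel's random choices
#' @param switchboard optional switchboard for communication acts
#' @return the agent's trace (list of records), with attribute
#'   `complete` = `FALSE` when `max_cycles` was exhausted
#' @export
run_cycle <- function(agent, environment = NULL, max_cycles = 20L,
                      seed = NULL, switchboard = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  complete <- TRUE
  for (cyc in seq_len(max_cycles)) {
    agent$wm$clock <- agent$wm$clock + 1L
    before <- agent$wm$next_id
    obs <- if (!is.null(environment)) {
      environment$observe(agent$id, agent$wm$clock)
    } else list()
    worked <- agent_step(agent, obs, environment, switchboard)
    produced_any <- agent$wm$next_id > before
    if (!length(obs) && !produced_any && !worked) break
    if (cyc == max_cycles) complete <- FALSE
  }
  structure(agent$trace, complete = complete)
}

# One full pass of the canon ordering; returns TRUE if any plan/decision
# work was performed (used for the quiescence test).
agent_step <- function(agent, obs, environment = NULL, switchboard = NULL) {
  s1_maintain_beliefs(agent, obs)
  s9_monitor(agent, obs)
  s2_raise_goals(agent)
  worked <- FALSE
  goals <- pending_decision_goals(agent)
  if (length(goals)) {
    cid <- decide(agent, goals[[1]])
    worked <- worked || !is.na(cid)
  }
  for (plan_it in wm_active(agent$wm, "plan")) {
    gid <- plan_it$content$goal
    git <- agent$wm$items[[as.character(gid)]]
    if (!is.null(git) &&
        (git$status != "active" ||
         !git$content$status %in% c("raised", "active"))) next
    enabled <- s7_enact(agent, plan_it)
    for (tid in enabled) {
      task <- plan_it$content$tasks[[tid]]
      if (task$type %in% c("action", "enquiry")) {
        effects <- s8_execute(agent, plan_it, task, environment, switchboard)
        if (length(effects)) {
          s1_maintain_beliefs(agent, effects)
          s9_monitor(agent, effects)
        }
        worked <- TRUE
      }
      plan_it <- wm_get(agent$wm, plan_it$id)
    }
  }
  achieved <- check_goal_termination(agent$wm, agent$onto)
  for (gid in achieved) {
    git <- wm_get(agent$wm, gid)
    dec <- agent$decisions[[as.character(gid)]]
    if (!is.null(dec) && !isTRUE(dec$learned)) {
      s10_learn(agent, git)
      agent$decisions[[as.character(gid)]]$learned <- TRUE
    }
  }
  # firm commitments on still-open goals also terminate their decision
  for (key in names(agent$decisions)) {
    dec <- agent$decisions[[key]]
    if (identical(dec$firmness, "firm") && !isTRUE(dec$learned)) {
      git <- agent$wm$items[[key]]
      if (!is.null(git)) {
        s10_learn(agent, git)
        agent$decisions[[key]]$learned <- TRUE
      }
    }
  }
  worked
}

#' Retract a goal and every structure that depends on it
#'
#' An adopt commitment never outlives its goal: retracting the goal
#' cascades through the commitment and its plan instance.
#'
#' @param agent an agent
#' @param goal_item the goal item to drop
#' @return integer vector of retracted item ids
#' @export
drop_goal <- function(agent, goal_item) {
  wm_retract(agent$wm, goal_item$id, cascade = TRUE)
}
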