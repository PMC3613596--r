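obs_just <- function() justification("observation")

test_that("asserting an identical belief twice yields one item with merged justifications", {
  wm <- wm_new()
  o1 <- wm_assert(wm, "observation", atom("chest_pain", "present"),
                  obs_just())
  b1 <- wm_assert(wm, "belief", atom("possible", "mi"),
                  justification("inference", supports = o1, rule = "r1"))
  b2 <- wm_assert(wm, "belief", atom("possible", "mi"),
                  justification("inference", supports = o1, rule = "r2"))
  expect_identical(b1, b2)
  it <- wm$items[[as.character(b1)]]
  expect_length(it$justifications, 2)
  # asserting with an identical justification does not duplicate it
  wm_assert(wm, "belief", atom("possible", "mi"),
            justification("inference", supports = o1, rule = "r1"))
  expect_length(wm$items[[as.character(b1)]]$justifications, 2)
})

test_that("observations outrank inferences and newer observations outrank older", {
  wm2 <- wm_new()
  oo <- wm_assert(wm2, "observation", atom("lamp", "on"), obs_just())
  bb <- wm_assert(wm2, "belief", atom("lamp", "on"),
                  justification("inference", supports = oo))
  # inferred negation loses against the active observation-backed atom
  res <- wm_assert(wm2, "belief", atom("lamp", "on", neg = TRUE),
                   justification("inference", supports = oo))
  expect_true(is.na(res))
  expect_equal(wm2$items[[as.character(bb)]]$status, "active")
  # a newer observation replaces an older conflicting one
  o3 <- wm_assert(wm2, "observation", atom("lamp", "on", neg = TRUE),
                  obs_just())
  expect_false(is.na(o3))
  expect_equal(wm2$items[[as.character(oo)]]$status, "retracted")
  # the belief derived from the retracted observation cascaded away
  expect_equal(wm2$items[[as.character(bb)]]$status, "retracted")
})

test_that("retracting a leaf removes exactly that item; cascades follow justification chains", {
  wm <- wm_new()
  o <- wm_assert(wm, "observation", atom("a", "1"), obs_just())
  leaf <- wm_assert(wm, "belief", atom("b", "1"),
                    justification("inference", supports = o))
  gone <- wm_retract(wm, leaf)
  expect_identical(gone, leaf)
  expect_equal(wm$items[[as.character(o)]]$status, "active")
})

test_that("retracting the chest-pain observation retracts the derived possibility chain", {
  kb <- load_kb(system.file("extdata", "mi.yaml", package = "dominoagent"))
  ag <- build_agents(kb)$C
  pain <- atom("chest_pain", "present")
  eld <- atom("patient", "elderly")
  s1_maintain_beliefs(ag, list(pain, eld))
  keys <- wm_belief_keys(ag$wm)
  expect_true("possible=heart_attack" %in% keys)
  expect_true("possible=myocardial_infarction" %in% keys)
  obs <- wm_query(ag$wm, "observation", pain)
  gone <- wm_retract(ag$wm, obs[[1]]$item$id, cascade = TRUE)
  keys <- wm_belief_keys(ag$wm)
  expect_false("possible=heart_attack" %in% keys)
  expect_false("possible=myocardial_infarction" %in% keys)
  expect_true("patient=elderly" %in% keys)
  expect_gte(length(gone), 3)
})

test_that("cascaded retraction equals the diff against from-scratch recomputation", {
  set.seed(21)
  for (i in 1:40) {
    wm <- wm_new()
    roots <- vapply(1:4, function(k) {
      wm_assert(wm, "observation", atom(paste0("r", k), "1"), obs_just())
    }, integer(1))
    derived <- integer(0)
    for (k in 1:10) {
      pool <- c(roots, derived)
      sup <- sample(pool, min(length(pool), sample(1:2, 1)))
      id <- wm_assert(wm, "belief", atom(paste0("d", k), "1"),
                      justification("inference", supports = sup))
      derived <- c(derived, id)
    }
    victim <- sample(roots, 1)
    gone <- wm_retract(wm, victim, cascade = TRUE)
    active_now <- vapply(wm_active(wm), `[[`, integer(1), "id")
    expect_setequal(active_now, wm_wellfounded(wm))
    expect_true(all(!gone %in% active_now))
  }
})

test_that("re-asserting a cascade-retracted root restores the derivable set", {
  wm <- wm_new()
  o <- wm_assert(wm, "observation", atom("x", "1"), obs_just())
  b <- wm_assert(wm, "belief", atom("y", "1"),
                 justification("inference", supports = o, rule = "r"))
  before <- sort(wm_belief_keys(wm))
  wm_retract(wm, o, cascade = TRUE)
  expect_length(wm_belief_keys(wm), 0)
  o2 <- wm_assert(wm, "observation", atom("x", "1"), obs_just())
  b2 <- wm_assert(wm, "belief", atom("y", "1"),
                  justification("inference", supports = o2, rule = "r"))
  expect_identical(sort(wm_belief_keys(wm)), before)
})

test_that("query returns all and only matching active items, with bindings", {
  wm <- wm_new()
  ids <- c(wm_assert(wm, "belief", atom("sym", "pain"),
                     justification("assumption")),
           wm_assert(wm, "belief", atom("sym", "nausea"),
                     justification("assumption")),
           wm_assert(wm, "belief", atom("age", "old"),
                     justification("assumption")))
  hits <- wm_query(wm, "belief", atom("sym", "?v"))
  expect_length(hits, 2)
  expect_setequal(vapply(hits, function(h) h$bindings[["?v"]],
                         character(1)),
                  c("pain", "nausea"))
  expect_length(wm_query(wm_new(), "belief"), 0)
  # match count equals an exhaustive scan on random memories
  set.seed(3)
  for (i in 1:30) {
    wm <- wm_new()
    n <- sample(3:10, 1)
    for (k in seq_len(n)) {
      wm_assert(wm, "belief",
                atom(sample(c("p", "q"), 1), sample(c("1", "2"), 1)),
                justification("assumption"))
    }
    pat <- atom("p", "?v")
    scan <- sum(vapply(wm_active(wm, "belief"), function(it) {
      it$content$attr == "p"
    }, logical(1)))
    expect_length(wm_query(wm, "belief", pat), scan)
  }
})

test_that("goals whose condition becomes true are marked achieved, exactly per holds()", {
  wm <- wm_new()
  g <- wm_assert(wm, "goal",
                 list(template = "diagnose", status = "active",
                      condition = atom("diagnosis", "decided"),
                      priority = 1L, stakes = "routine"),
                 justification("assumption"))
  expect_length(check_goal_termination(wm), 0)
  wm_assert(wm, "belief", atom("diagnosis", "decided"),
            justification("assumption"))
  expect_identical(check_goal_termination(wm), g)
  expect_equal(wm$items[[as.character(g)]]$content$status, "achieved")
  # no beliefs changed: nothing further terminates
  expect_length(check_goal_termination(wm), 0)
})

test_that("no active item both asserts and negates the same ground atom after any assertion sequence", {
  set.seed(9)
  for (i in 1:30) {
    wm <- wm_new()
    for (k in 1:15) {
      a <- atom(sample(c("p", "q"), 1), "1", neg = stats::runif(1) < 0.5)
      kind <- sample(c("observation", "belief"), 1)
      j <- if (kind == "observation") obs_just() else
        justification("assumption")
      wm_assert(wm, kind, a, j)
    }
    keys <- wm_belief_keys(wm)
    pos <- keys[!startsWith(keys, "!")]
    neg <- substring(keys[startsWith(keys, "!")], 2)
    expect_length(intersect(pos, neg), 0)
  }
})
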