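test_that("feedback is positive iff the criterion features match, over all cards, targets and criteria", {
  deck <- wcst_deck(64, shuffle = FALSE)
  targets <- wcst_targets()
  for (card in deck) {
    for (placement in 1:4) {
      for (crit in c("color", "form", "number")) {
        st <- wcst_state_new(crit, switch_after = 100L)
        fb <- wcst_feedback(placement, card, st)
        feat <- switch(crit, color = card$color, form = card$shape,
                       number = card$number)
        tfeat <- switch(crit, color = targets[[placement]]$color,
                        form = targets[[placement]]$shape,
                        number = targets[[placement]]$number)
        expect_identical(as.character(fb),
                         if (identical(feat, tfeat)) "positive"
                         else "negative")
      }
    }
  }
  expect_error(wcst_feedback(5, deck[[1]], wcst_state_new()), "range")
})

test_that("a card identical to the chosen target is positive under every criterion", {
  targets <- wcst_targets()
  for (k in 1:4) {
    for (crit in c("color", "form", "number")) {
      st <- wcst_state_new(crit, 100L)
      expect_identical(as.character(wcst_feedback(k, targets[[k]], st)),
                       "positive")
    }
  }
})

test_that("the criterion switches exactly on reaching the consecutive-correct threshold", {
  st <- wcst_state_new("color", switch_after = 6L)
  green_card <- wcst_card(1, "triangle", "green")   # target 2 is green
  for (k in 1:5) {
    fb <- wcst_feedback(2, green_card, st)
    expect_false(attr(fb, "switched"))
  }
  fb <- wcst_feedback(2, green_card, st)
  expect_true(attr(fb, "switched"))
  expect_identical(st$criterion, "form")
  expect_identical(st$prev_criterion, "color")
  expect_equal(st$counter, 0L)
  # an error resets the counter
  st2 <- wcst_state_new("color", 6L)
  wcst_feedback(2, green_card, st2)
  wcst_feedback(1, green_card, st2)   # red target: wrong
  expect_equal(st2$counter, 0L)
})

test_that("the worked single-trial example yields 4 options, 3 reasons, merits 2 vs 1, preferring target 1", {
  we <- wcst_worked_example()
  expect_length(we$candidates, 4)
  expect_length(we$arguments, 3)
  expect_equal(unname(we$merits[c("target1", "target2", "target3",
                                  "target4")]),
               c(2, 1, 0, 0))
  expect_identical(we$preference[1], "target1")
  schemas <- vapply(we$arguments, `[[`, character(1), "schema")
  expect_setequal(schemas, c("match_form", "match_number", "match_color"))
  tgts <- vapply(we$arguments, `[[`, character(1), "candidate")
  expect_equal(sum(tgts == "target1"), 2)
  expect_equal(sum(tgts == "target2"), 1)
})

test_that("the rule strategy starts from exactly three candidate sorting rules", {
  tr <- run_wcst(lesion_config(strategy = "rule"), n_trials = 5, seed = 2)
  expect_equal(tr$trials$n_live_before[1], 3L)
  expect_true(all(tr$trials$rule %in% c("color", "form", "number")))
})

test_that("once the rule is identified, positive feedback is expected each trial", {
  tr <- run_wcst(lesion_config(), n_trials = 64, switch_after = 6, seed = 5)
  identified <- tr$trials$n_live_before == 1L
  expect_true(any(identified))
  expect_true(all(tr$trials$expected_positive[identified]))
  expect_true(all(!tr$trials$expected_positive[!identified]))
})

test_that("a zero-trial run yields an empty trace", {
  tr <- run_wcst(n_trials = 0L, seed = 1)
  expect_equal(nrow(tr$trials), 0L)
  counts <- classify_errors(tr)
  expect_equal(counts, list(perseverative = 0L, set_loss = 0L, other = 0L))
})

test_that("identical seeds reproduce identical traces", {
  a <- run_wcst(lesion_config(retention_failure = 0.1), n_trials = 64,
                seed = 9)
  b <- run_wcst(lesion_config(retention_failure = 0.1), n_trials = 64,
                seed = 9)
  expect_identical(a$trials, b$trials)
  fa <- generate_random_fixture(0)
  fb <- generate_random_fixture(0)
  expect_identical(fa, fb)
})

hand_trace <- function(rows, n_switches) {
  structure(list(trials = rows, n_switches = n_switches,
                 config = list()),
            class = "wcst_trace")
}

test_that("a hand-built trace with one post-switch old-rule error classifies as one perseverative error", {
  # six corrects under color (switch on trial 6), then an error sorted by
  # the old color rule, then three corrects
  mk <- function(trial, color, placement, feedback, prev, switched) {
    data.frame(trial = trial, number = 1L, shape = "triangle",
               color = color, criterion = if (trial <= 6) "color" else "form",
               prev_criterion = prev, rule = NA_character_,
               placement = placement, expected_positive = FALSE,
               feedback = feedback, violation = FALSE, forgot = FALSE,
               switched = switched, n_live_before = 3L,
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(
    lapply(1:6, function(t) mk(t, "green", 2L, "positive",
                               NA_character_, t == 6L)),
    list(mk(7L, "green", 2L, "negative", "color", FALSE)),  # old rule
    lapply(8:10, function(t) mk(t, "red", 1L, "positive", "color", FALSE))))
  counts <- classify_errors(hand_trace(rows, 1L))
  expect_equal(counts$perseverative, 1L)
  expect_equal(counts$set_loss, 0L)
  expect_equal(counts$other, 0L)
})

test_that("an error after a clean run of three correct with no switch classifies as set loss", {
  mk <- function(trial, feedback) {
    data.frame(trial = trial, number = 2L, shape = "star", color = "green",
               criterion = "color", prev_criterion = NA_character_,
               rule = "color", placement = if (feedback == "positive") 2L
                                           else 3L,
               expected_positive = FALSE, feedback = feedback,
               violation = FALSE, forgot = FALSE, switched = FALSE,
               n_live_before = 1L, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(lapply(1:4, function(t) mk(t, "positive")),
                           list(mk(5L, "negative"))))
  counts <- classify_errors(hand_trace(rows, 0L))
  expect_equal(counts$set_loss, 1L)
  expect_equal(counts$perseverative, 0L)
})

test_that("error counts are invariant under relabeling of non-criterion features", {
  tr <- run_wcst(lesion_config(retention_failure = 0.05), n_trials = 128,
                 switch_after = 6, seed = 13)
  base <- classify_errors(tr)
  # relabel colors by a bijection applied to cards and targets alike
  perm <- c(red = "blue", green = "yellow", yellow = "green", blue = "red")
  tr2 <- tr
  tr2$trials$color <- unname(perm[tr2$trials$color])
  targets2 <- lapply(wcst_targets(), function(tc) {
    wcst_card(tc$number, tc$shape, unname(perm[tc$color]))
  })
  expect_identical(classify_errors(tr2, targets = targets2), base)
})

test_that("with no retention failure there are no set-loss errors", {
  for (seed in 1:5) {
    tr <- run_wcst(lesion_config(), n_trials = 128, switch_after = 6,
                   seed = seed)
    expect_equal(classify_errors(tr)$set_loss, 0L)
  }
})

test_that("the location strategy sorts without cross-trial learning and errs at a roughly constant rate", {
  tr <- run_wcst(lesion_config(strategy = "location"), n_trials = 64,
                 seed = 3)
  expect_true(all(is.na(tr$trials$rule)))
  expect_false(any(tr$trials$expected_positive))
  err <- tr$trials$feedback == "negative"
  # chance-level behavior: errors in both halves of the run
  expect_gt(sum(err[1:32]), 0)
  expect_gt(sum(err[33:64]), 0)
})

test_that("the consultation fixture validates and its pieces answer as the walkthrough states", {
  fx <- build_mi_fixture()
  expect_length(validate_ontology(fx$kb$onto), 0)
  expect_setequal(vapply(fx$agents, `[[`, character(1), "id"),
                  c("records", "C", "S"))
  expect_identical(fx$agents$records$case$gastritis, "present")
})

test_that("random fixtures are deterministic per seed and always valid", {
  for (seed in c(0, 1, 42)) {
    a <- generate_random_fixture(seed)
    b <- generate_random_fixture(seed)
    expect_identical(a, b)
    expect_length(validate_ontology(a$onto), 0)
  }
})
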