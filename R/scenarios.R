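#' Construct a sorting-test card
#'
#' Cards show one to four shapes (triangles, stars, crosses, or circles)
#' printed in red, green, yellow, or blue. `diamond` is admitted solely for
#' the worked single-trial example, which reasons about a one-green-diamond
#' card.
#'
#' @param number integer 1--4
#' @param shape one of triangle, star, cross, circle, diamond
#' @param color one of red, green, yellow, blue
#' @return a `wcst_card`
#' @export
wcst_card <- function(number, shape, color) {
  stopifnot(number %in% 1:4,
            shape %in% c("triangle", "star", "cross", "circle", "diamond"),
            color %in% c("red", "green", "yellow", "blue"))
  structure(list(number = as.integer(number), shape = shape, color = color),
            class = "wcst_card")
}

card_feature <- function(card, criterion) {
  switch(criterion, color = card$color, form = card$shape,
         number = card$number, stop("unknown criterion: ", criterion))
}

WCST_CRITERIA <- c("color", "form", "number")

#' Standard target cards
#'
#' One red triangle, two green stars, three yellow crosses, four blue
#' circles: every pair of targets differs on every criterion, so each
#' sorting rule picks out exactly one target for any card.
#'
#' @return list of four [wcst_card()]s
#' @export
wcst_targets <- function() {
  list(wcst_card(1, "triangle", "red"), wcst_card(2, "star", "green"),
       wcst_card(3, "cross", "yellow"), wcst_card(4, "circle", "blue"))
}

#' Build a response deck
#'
#' The standard 64-card deck contains every combination of number (1--4),
#' shape (four standard shapes) and color (four colors) once; `n` greater
#' than 64 cycles through further shuffled copies.
#'
#' @param n number of cards
#' @param shuffle shuffle each 64-card block (uses the current RNG state)
#' @return list of [wcst_card()]s
#' @export
wcst_deck <- function(n = 64L, shuffle = TRUE) {
  combos <- expand.grid(number = 1:4,
                        shape = c("triangle", "star", "cross", "circle"),
                        color = c("red", "green", "yellow", "blue"),
                        stringsAsFactors = FALSE)
  deck <- list()
  while (length(deck) < n) {
    idx <- if (shuffle) sample.int(nrow(combos)) else seq_len(nrow(combos))
    block <- lapply(idx, function(i) {
      wcst_card(combos$number[i], combos$shape[i], combos$color[i])
    })
    deck <- c(deck, block)
  }
  deck[seq_len(n)]
}

#' Experimenter state for the sorting test
#'
#' Tracks the hidden sorting criterion, the consecutive-correct counter,
#' and the criterion switches. After `switch_after` consecutive correct
#' placements the criterion changes -- without warning -- to the next in
#' the rotation color, form, number.
#'
#' @param criterion initial criterion
#' @param switch_after consecutive correct placements before a switch
#' @param targets target cards
#' @return a `wcst_state` environment
#' @export
wcst_state_new <- function(criterion = "color", switch_after = 6L,
                           targets = wcst_targets()) {
  st <- new.env(parent = emptyenv())
  st$criterion <- match.arg(criterion, WCST_CRITERIA)
  st$switch_after <- as.integer(switch_after)
  st$targets <- targets
  st$counter <- 0L
  st$n_switches <- 0L
  st$prev_criterion <- NA_character_
  class(st) <- "wcst_state"
  st
}

#' Experimenter feedback for a placement
#'
#' Positive iff the card's feature on the current criterion equals the
#' chosen target's feature on that criterion. Applies the
#' consecutive-correct bookkeeping: the counter resets on error, and on
#' reaching `switch_after` the criterion switches and the counter resets.
#'
#' @param placement target index 1--4
#' @param card the sorted [wcst_card()]
#' @param state a [wcst_state_new()] state (mutated)
#' @return `"positive"` or `"negative"`; the attribute `switched` is
#'   `TRUE` when this trial triggered a criterion switch
#' @export
wcst_feedback <- function(placement, card, state) {
  if (!placement %in% 1:4) stop("placement out of range: ", placement)
  crit <- state$criterion
  ok <- identical(card_feature(card, crit),
                  card_feature(state$targets[[placement]], crit))
  switched <- FALSE
  if (ok) {
    state$counter <- state$counter + 1L
    if (state$counter >= state$switch_after) {
      state$prev_criterion <- state$criterion
      i <- match(state$criterion, WCST_CRITERIA)
      state$criterion <- WCST_CRITERIA[i %% length(WCST_CRITERIA) + 1L]
      state$counter <- 0L
      state$n_switches <- state$n_switches + 1L
      switched <- TRUE
    }
  } else {
    state$counter <- 0L
  }
  structure(if (ok) "positive" else "negative", switched = switched)
}

#' Lesion configuration for the sorting simulation
#'
#' Two toggles dissociate the classic error types: disabling monitoring
#' removes the expectation-violation pathway, so a maintained sorting rule
#' is never dislodged by negative feedback (perseveration); a positive
#' retention-failure probability makes the maintained rule belief
#' spontaneously forgotten on a trial (set loss).
#'
#' @param monitoring expectation monitoring enabled
#' @param retention_failure per-trial probability of losing the maintained
#'   rule belief
#' @param strategy `"rule"` (sorting rules as decision options, with
#'   feedback learning) or `"location"` (the simplistic strategy: the four
#'   placements as options, no cross-trial learning)
#' @param aspiration `"general"` (seek the rule) or `"specific"` (solve
#'   this trial); recorded for reference, the strategy field governs
#' @return a `lesion_config` list
#' @export
lesion_config <- function(monitoring = TRUE, retention_failure = 0,
                          strategy = c("rule", "location"),
                          aspiration = c("general", "specific")) {
  stopifnot(retention_failure >= 0, retention_failure <= 1)
  structure(list(monitoring = isTRUE(monitoring),
                 retention_failure = retention_failure,
                 strategy = match.arg(strategy),
                 aspiration = match.arg(aspiration)),
            class = "lesion_config")
}

# one pro argument per live sorting rule, strength = accumulated support
rule_arguments <- function(live, strengths) {
  args <- list()
  for (i in seq_along(live)) {
    r <- live[i]
    args[[i]] <- new_argument(paste0("a", i), r, "pro",
                              paste0("rule_support_", r),
                              strengths[[r]])
  }
  args
}

# placement chosen by applying a sorting rule to a card
rule_placement <- function(rule, card, targets) {
  for (k in seq_along(targets)) {
    if (identical(card_feature(card, rule),
                  card_feature(targets[[k]], rule))) return(k)
  }
  stop("no target matches card on criterion ", rule)
}

#' Run the card-sorting simulation
#'
#' Per trial: candidate generation according to the strategy, argument
#' construction, aggregation (Bentham), commitment (seeded-random
#' tie-break), placement, experimenter feedback, expectation monitoring,
#' and argument-weight update. Under the rule strategy the three sorting
#' rules are the decision options; positive feedback strengthens the rules
#' that matched the chosen target (+1) and removes the arguments of rules
#' that did not, so feedback cycles eliminate all but one rule. Once a
#' single rule is maintained, placement is routine and an expectation of
#' positive feedback is asserted each trial; an expectation violation
#' (negative feedback, monitoring intact) removes the violated rule's
#' supporting argument, reopening the decision. With monitoring disabled
#' the violation is never registered and the agent keeps sorting by the
#' previously appropriate rule. Retention failure (seeded, drawn before
#' the deck so toggling lesions does not change the card sequence) deletes
#' the maintained rule belief before the trial.
#'
#' @param lesion a [lesion_config()]
#' @param n_trials number of trials
#' @param switch_after consecutive correct placements before a criterion
#'   switch
#' @param seed integer seed governing retention draws, deck shuffle, and
#'   tie-breaks
#' @param deck optional deck (default: shuffled standard deck of
#'   `n_trials` cards)
#' @param initial_criterion experimenter's first criterion
#' @return a `wcst_trace`: list with `trials` (data frame), `config`,
#'   `n_switches`
#' @export
run_wcst <- function(lesion = lesion_config(), n_trials = 64L,
                     switch_after = 6L, seed = 1L, deck = NULL,
                     initial_criterion = "color") {
  set.seed(as.integer(seed))
  forget_draws <- stats::runif(n_trials)
  if (is.null(deck)) deck <- wcst_deck(n_trials)
  state <- wcst_state_new(initial_criterion, switch_after)
  targets <- state$targets

  strengths <- stats::setNames(rep(1, 3), WCST_CRITERIA)
  live <- WCST_CRITERIA

  empty_log <- data.frame(trial = integer(0), number = integer(0),
                          shape = character(0), color = character(0),
                          criterion = character(0),
                          prev_criterion = character(0), rule = character(0),
                          placement = integer(0),
                          expected_positive = logical(0),
                          feedback = character(0), violation = logical(0),
                          forgot = logical(0), switched = logical(0),
                          n_live_before = integer(0),
                          stringsAsFactors = FALSE)
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    card <- deck[[t]]
    forgot <- FALSE
    if (lesion$strategy == "rule" &&
        forget_draws[t] < lesion$retention_failure) {
      live <- WCST_CRITERIA
      strengths[] <- 1
      forgot <- TRUE
    }
    crit_before <- state$criterion
    prev_crit <- state$prev_criterion
    n_live_before <- length(live)

    if (lesion$strategy == "rule") {
      cands <- lapply(live, function(r) list(id = r, payload = r))
      args <- resolve_defeat(rule_arguments(live, strengths))
      merits <- aggregate_merits(cands, args)
      pref <- prefer(cands, merits, tie_break = "random")
      committed <- pref[1]
      placement <- rule_placement(committed, card, targets)
      expected <- length(live) == 1L
    } else {
      cands <- lapply(1:4, function(k) {
        list(id = paste0("target", k), payload = k)
      })
      args <- list()
      n <- 0L
      for (k in 1:4) {
        for (r in WCST_CRITERIA) {
          if (identical(card_feature(card, r),
                        card_feature(targets[[k]], r))) {
            n <- n + 1L
            args[[n]] <- new_argument(paste0("a", n), paste0("target", k),
                                      "pro", paste0("match_", r), 1)
          }
        }
      }
      args <- resolve_defeat(args)
      merits <- aggregate_merits(cands, args)
      pref <- prefer(cands, merits, tie_break = "random")
      committed <- NA_character_
      placement <- as.integer(sub("target", "", pref[1]))
      expected <- FALSE
    }

    fb <- wcst_feedback(placement, card, state)
    switched <- attr(fb, "switched")
    violation <- expected && fb == "negative"

    if (lesion$strategy == "rule") {
      if (fb == "positive") {
        if (length(live) > 1L) {
          matched <- live[vapply(live, function(r) {
            identical(card_feature(card, r),
                      card_feature(targets[[placement]], r))
          }, logical(1))]
          strengths[matched] <- strengths[matched] + 1
          strengths[setdiff(live, matched)] <- 1
          live <- matched
        } else {
          strengths[live] <- strengths[live] + 1
        }
      } else {
        if (length(live) > 1L) {
          # feedback assimilation while still testing rules: the rules
          # consistent with the (wrong) placement are disconfirmed
          wrong <- live[vapply(live, function(r) {
            identical(card_feature(card, r),
                      card_feature(targets[[placement]], r))
          }, logical(1))]
          remaining <- setdiff(live, wrong)
          strengths[wrong] <- 1
          live <- if (length(remaining)) remaining
                  else setdiff(WCST_CRITERIA, committed)
        } else if (violation && lesion$monitoring) {
          # expectation violation: the maintained rule is incorrect
          strengths[] <- 1
          live <- setdiff(WCST_CRITERIA, committed)
        }
        # monitoring disabled: the violation goes unregistered and the
        # maintained rule persists (perseveration)
      }
    }

    rows[[t]] <- data.frame(
      trial = t, number = card$number, shape = card$shape,
      color = card$color, criterion = crit_before,
      prev_criterion = if (is.na(prev_crit)) NA_character_ else prev_crit,
      rule = committed, placement = placement,
      expected_positive = expected, feedback = as.character(fb),
      violation = violation, forgot = forgot, switched = switched,
      n_live_before = n_live_before, stringsAsFactors = FALSE)
  }

  structure(list(trials = if (n_trials == 0L) empty_log
                          else do.call(rbind, rows),
                 config = list(lesion = unclass(lesion),
                               n_trials = n_trials,
                               switch_after = switch_after, seed = seed,
                               initial_criterion = initial_criterion),
                 n_switches = state$n_switches),
            class = "wcst_trace")
}

#' @export
print.wcst_trace <- function(x, ...) {
  summarize_trace(x)
  invisible(x)
}

#' Classify sorting errors
#'
#' *Perseverative*: an error, occurring after at least one criterion
#' switch, whose placement matches the immediately previous criterion
#' (sorting by the previously appropriate rule). *Set loss*: an error
#' following at least `set_loss_run` consecutive correct placements, with
#' no intervening switch, made while a single sorting rule was being
#' maintained -- the run of correct sorts evidences that the rule had been
#' inferred, and the error that it was then spontaneously lost. A run of
#' coincidentally correct placements during rule *search* (several live
#' rules) does not qualify: losing a set requires having acquired one.
#' The categories are disjoint; perseverative takes precedence.
#'
#' @param trace a `wcst_trace` from [run_wcst()]
#' @param set_loss_run consecutive-correct run length that qualifies an
#'   error as set loss (3, common scoring practice)
#' @param targets the target cards the trace was sorted against
#' @return list `(perseverative, set_loss, other)`
#' @export
classify_errors <- function(trace, set_loss_run = 3L,
                            targets = wcst_targets()) {
  tr <- trace$trials
  pers <- 0L; setl <- 0L; other <- 0L
  run <- 0L          # consecutive correct since last error or switch
  run_set <- TRUE    # whole run sorted under a maintained single rule
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (row$feedback == "positive") {
      if (row$switched) {
        run <- 0L
        run_set <- TRUE
      } else {
        run <- run + 1L
        run_set <- run_set && identical(row$n_live_before, 1L)
      }
      next
    }
    card <- wcst_card(row$number, row$shape, row$color)
    is_pers <- !is.na(row$prev_criterion) &&
      identical(card_feature(card, row$prev_criterion),
                card_feature(targets[[row$placement]], row$prev_criterion))
    if (is_pers) {
      pers <- pers + 1L
    } else if (run >= set_loss_run && run_set) {
      setl <- setl + 1L
    } else {
      other <- other + 1L
    }
    run <- 0L
    run_set <- TRUE
  }
  list(perseverative = pers, set_loss = setl, other = other)
}

#' Did the agent reach criterion after every switch?
#'
#' A switch occurs exactly when the consecutive-correct criterion is
#' reached, so every inter-switch segment except the final one ends at
#' criterion by construction; this checks that the run does not get stuck:
#' the final segment either also ends at a switch or is shorter than
#' `tail_allowance` trials (too few left in the deck to demand
#' convergence).
#'
#' @param trace a `wcst_trace`
#' @param tail_allowance trials granted to the unfinished final segment
#' @return logical scalar
#' @export
wcst_reached_criterion <- function(trace, tail_allowance = 25L) {
  tr <- trace$trials
  if (trace$n_switches == 0L) {
    return(nrow(tr) < tail_allowance)
  }
  last_switch <- max(which(tr$switched))
  nrow(tr) - last_switch < tail_allowance
}

#' The worked single-trial example
#'
#' The to-be-sorted card shows one green diamond; target 1 shares its
#' shape and number, target 2 its color, targets 3 and 4 nothing. Under
#' the simplistic (location) strategy the four placements are the decision
#' options; feature matching yields three lines of reasoning (shape and
#' number for target 1, color for target 2); Bentham aggregation gives
#' merits 2 and 1, yielding a preference for target 1.
#'
#' @return list with `card`, `targets`, `candidates`, `arguments`,
#'   `merits`, `preference`
#' @export
wcst_worked_example <- function() {
  card <- wcst_card(1, "diamond", "green")
  targets <- list(wcst_card(1, "diamond", "red"),
                  wcst_card(2, "star", "green"),
                  wcst_card(3, "cross", "yellow"),
                  wcst_card(4, "circle", "blue"))
  candidates <- lapply(1:4, function(k) {
    list(id = paste0("target", k), payload = k, item_id = NA_integer_)
  })
  schemas <- lapply(WCST_CRITERIA, function(r) {
    argument_schema(paste0("match_", r), "pro", strength = 1,
                    condition = local({
                      feat <- r
                      function(candidate, goal, wm, onto) {
                        k <- candidate$payload
                        if (identical(card_feature(card, feat),
                                      card_feature(targets[[k]], feat))) {
                          list(list(feature = feat, target = k))
                        } else NULL
                      }
                    }))
  })
  onto <- ontology()
  wm <- wm_new("wcst")
  args <- construct_arguments(candidates, goal = NULL, wm = wm, onto = onto,
                              schemas = schemas)
  args <- resolve_defeat(args)
  merits <- aggregate_merits(candidates, args)
  pref <- prefer(candidates, merits, tie_break = "lexicographic")
  list(card = card, targets = targets, candidates = candidates,
       arguments = args, merits = merits, preference = pref)
}

#' Convert a sorting-test trial log to generic trace records
#'
#' @param trace a `wcst_trace`
#' @return list of records suitable for [write_trace()]
#' @export
wcst_trace_records <- function(trace) {
  tr <- trace$trials
  lapply(seq_len(nrow(tr)), function(i) {
    row <- as.list(tr[i, ])
    list(cycle = row$trial, agent = "subject", canon = "trial",
         consumed = integer(0), produced = integer(0),
         info = row[setdiff(names(row), "trial")])
  })
}

# --- the clinical consultation fixture ------------------------------------

#' Build the myocardial-infarction consultation fixture
#'
#' Loads the shipped knowledge base and constructs the three-agent
#' network: a patient-records agent serving the case table (elderly, chest
#' pain, gastritis), a lead cardiology agent whose knowledge retrieves two
#' candidate drugs and which consults before acting on a high-stakes
#' decision, and a drug-safety specialist that knows a third option
#' (proton-pump inhibitors) and that aspirin exacerbates gastritis.
#'
#' @param path knowledge-base path (default: the installed `mi.yaml`)
#' @param ... passed to [build_agents()]
#' @return list with `kb`, `agents` (records, lead, specialist, in
#'   registration order), `presentations`
#' @export
build_mi_fixture <- function(path = system.file("extdata", "mi.yaml",
                                                package = "dominoagent"),
                             ...) {
  kb <- load_kb(path)
  agents <- build_agents(kb, ...)
  list(kb = kb, agents = agents, presentations = kb$presentations)
}

#' Run the consultation scenario end to end
#'
#' @param seed integer seed
#' @param path knowledge-base path
#' @param max_rounds round budget
#' @return the [run_network()] result
#' @export
run_mi_scenario <- function(seed = 1L, path = system.file("extdata",
                                                          "mi.yaml",
                                                          package =
                                                            "dominoagent"),
                            max_rounds = 30L) {
  fx <- build_mi_fixture(path)
  run_network(fx$agents, fx$presentations, max_rounds = max_rounds,
              seed = seed)
}

# --- random fixtures for property tests -----------------------------------

#' Generate a random valid fixture
#'
#' Constructively valid random ontologies and belief sets for the property
#' suites: a random concept DAG (parents drawn among earlier concepts, so
#' acyclicity holds by construction), random properties, relation
#' assertions, belief rules over a small attribute/value alphabet, and a
#' random ground belief set. The same seed yields the same fixture.
#'
#' @param seed integer seed
#' @param n_concepts,n_relations,n_rules,n_beliefs size parameters
#' @param n_attrs,n_values alphabet sizes for rule/belief atoms
#' @param p_parent probability of each candidate parent link
#' @return list `(onto, beliefs)` where `beliefs` is a list of ground
#'   atoms
#' @export
generate_random_fixture <- function(seed, n_concepts = 12L,
                                    n_relations = 10L, n_rules = 6L,
                                    n_beliefs = 5L, n_attrs = 4L,
                                    n_values = 3L, p_parent = 0.3) {
  stopifnot(n_concepts > 0)
  set.seed(as.integer(seed))
  ids <- paste0("c", seq_len(n_concepts))
  concepts <- vector("list", n_concepts)
  prop_pool <- paste0("p", 1:5)
  for (i in seq_len(n_concepts)) {
    parents <- if (i > 1L) {
      cand <- ids[seq_len(i - 1L)]
      cand[stats::runif(length(cand)) < p_parent]
    } else character(0)
    nprop <- stats::rbinom(1, 2, 0.4)
    props <- if (nprop > 0) {
      nm <- sample(prop_pool, nprop)
      stats::setNames(as.list(paste0("v_", nm, "_", i)), nm)
    } else list()
    concepts[[i]] <- concept(ids[i], parents = parents, properties = props)
  }
  vocab <- c("causes", "exacerbates", "controls")
  relations <- if (n_relations > 0) {
    data.frame(subject = sample(ids, n_relations, replace = TRUE),
               relation = sample(vocab, n_relations, replace = TRUE),
               object = sample(ids, n_relations, replace = TRUE),
               stringsAsFactors = FALSE)
  } else empty_relations()
  attrs <- paste0("f", seq_len(n_attrs))
  vals <- paste0("u", seq_len(n_values))
  rand_atom <- function() atom(sample(attrs, 1), sample(vals, 1))
  rules <- lapply(seq_len(n_rules), function(i) {
    n_ante <- sample(1:2, 1)
    ante <- if (n_ante == 1L) rand_atom() else
      d_and(rand_atom(), rand_atom())
    rule(paste0("r", i), "belief", when = ante, then = list(rand_atom()))
  })
  beliefs <- lapply(seq_len(n_beliefs), function(i) rand_atom())
  list(onto = ontology(concepts = concepts, relations = relations,
                       relation_vocab = vocab, rules = rules),
       beliefs = beliefs)
}
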