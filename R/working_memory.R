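#' Create a working memory
#'
#' Working memory is the justification-tagged store of an agent's current
#' cognitive states: beliefs, goals, candidates, arguments, merits,
#' commitments, plans, expectations, and observations. Every item carries a
#' justification naming the grounds for holding it, so retracting a support
#' cascades to everything that depended on it (reason maintenance), and the
#' rationale for any decision can be read back from the store.
#'
#' Implemented as an environment so the kernel operations mutate it in
#' place; item ids are monotonically increasing integers and cycle stamps
#' come from the kernel clock, which makes traces replayable.
#'
#' @param agent_id owner label used in traces
#' @return a `working_memory` environment
#' @export
wm_new <- function(agent_id = "agent") {
  wm <- new.env(parent = emptyenv())
  wm$agent_id <- agent_id
  wm$items <- list()
  wm$next_id <- 1L
  wm$clock <- 0L
  class(wm) <- "working_memory"
  wm
}

#' Build a justification
#'
#' @param kind one of `"observation"`, `"inference"`, `"commitment"`,
#'   `"communication"`, `"assumption"`, `"axiom"`
#' @param supports integer vector of supporting item ids (must be non-empty
#'   for inference and communication justifications that derive from prior
#'   items; communication from another agent may stand on its own message)
#' @param rule,schema,goal optional identifiers recording which rule,
#'   argument schema, or goal produced the item
#' @return a `justification` object
#' @export
justification <- function(kind, supports = integer(0), rule = NULL,
                          schema = NULL, goal = NULL) {
  kind <- match.arg(kind, c("observation", "inference", "commitment",
                            "communication", "assumption", "axiom"))
  if (kind == "inference" && length(supports) == 0L) {
    stop("inference justifications require non-empty supports")
  }
  structure(list(kind = kind, supports = as.integer(supports), rule = rule,
                 schema = schema, goal = goal),
            class = "justification")
}

# kinds whose justifications are self-standing (chains bottom out here)
GROUND_JUST <- c("observation", "axiom", "assumption", "communication")

wm_get <- function(wm, id) {
  it <- wm$items[[as.character(id)]]
  if (is.null(it)) stop("unknown working-memory item id: ", id)
  it
}

wm_put <- function(wm, item) {
  wm$items[[as.character(item$id)]] <- item
  item$id
}

#' Active items of a working memory
#'
#' @param wm a working memory
#' @param kind optional content kind filter (`"belief"`, `"goal"`, ...)
#' @return list of items
#' @export
wm_active <- function(wm, kind = NULL) {
  Filter(function(it) {
    it$status == "active" && (is.null(kind) || it$kind == kind)
  }, wm$items)
}

#' Ground atoms currently believed
#'
#' Collects the atoms of all active belief and observation items. Each atom
#' carries an `item_id` attribute so rule matches can report which items
#' supported them.
#'
#' @param wm a working memory
#' @return list of ground atom descriptions
#' @export
wm_belief_atoms <- function(wm) {
  out <- list()
  for (it in wm$items) {
    if (it$status != "active" || !it$kind %in% c("belief", "observation")) next
    d <- it$content
    if (is_desc(d) && d$type == "atom") {
      attr(d, "item_id") <- it$id
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

#' Canonical keys of the believed atoms
#' @param wm a working memory
#' @return character vector suitable for [holds()]
#' @export
wm_belief_keys <- function(wm) {
  vapply(wm_belief_atoms(wm), atom_key, character(1))
}

content_signature <- function(kind, content) {
  paste(kind, paste(deparse(content, control = "all"), collapse = ""),
        sep = "\r")
}

#' Assert an item into working memory
#'
#' Exact duplicates (same kind and content among the active items) are
#' merged: the new justification is recorded on the existing item and its
#' id returned. Asserting a belief atom that contradicts an active belief
#' triggers the consistency policy: observation-supported items outrank
#' inference-supported ones, and between two observations the most recent
#' wins; the loser is retracted with cascade (or, if the incoming item
#' loses, it is not asserted and `NA` is returned).
#'
#' @param wm a working memory
#' @param kind content kind: `"belief"`, `"goal"`, `"candidate"`,
#'   `"argument"`, `"merit"`, `"commitment"`, `"plan"`, `"expectation"`,
#'   or `"observation"`
#' @param content the content object (a description for beliefs and
#'   observations; structured lists for the other kinds)
#' @param just a [justification()]
#' @return the item id, or `NA_integer_` when the consistency policy
#'   rejected the assertion
#' @export
wm_assert <- function(wm, kind, content, just) {
  kind <- match.arg(kind, c("belief", "goal", "candidate", "argument",
                            "merit", "commitment", "plan", "expectation",
                            "observation"))
  stopifnot(inherits(just, "justification"))
  for (s in just$supports) {
    sup <- wm_get(wm, s)
    if (sup$status != "active") {
      stop("justification support ", s, " is not active")
    }
  }

  sig <- content_signature(kind, content)
  for (it in wm$items) {
    if (it$status == "active" && it$sig == sig) {
      have <- vapply(it$justifications, function(j) {
        identical(unclass(j), unclass(just))
      }, logical(1))
      if (!any(have)) {
        it$justifications <- c(it$justifications, list(just))
        wm_put(wm, it)
      }
      return(it$id)
    }
  }

  if (kind %in% c("belief", "observation") && is_desc(content) &&
      content$type == "atom") {
    repeat {
      conflict <- wm_find_conflict(wm, content)
      if (is.null(conflict)) break
      if (!wm_conflict_keeps_new(conflict, just)) return(NA_integer_)
      wm_retract(wm, conflict$id, cascade = TRUE)
    }
  }

  id <- wm$next_id
  wm$next_id <- wm$next_id + 1L
  item <- list(id = id, kind = kind, content = content, sig = sig,
               justifications = list(just), status = "active",
               asserted_at = wm$clock, retracted_at = NA_integer_)
  wm_put(wm, item)
  id
}

# Find an active belief/observation atom asserting the negation of `d`.
wm_find_conflict <- function(wm, d) {
  negkey <- atom_key(atom(d$attr, d$value, !d$neg))
  for (it in wm$items) {
    if (it$status != "active" || !it$kind %in% c("belief", "observation")) next
    cd <- it$content
    if (is_desc(cd) && cd$type == "atom" && atom_key(cd) == negkey) return(it)
  }
  NULL
}

just_rank <- function(justs) {
  kinds <- vapply(justs, `[[`, character(1), "kind")
  if ("observation" %in% kinds) 2L else if ("axiom" %in% kinds) 2L else 1L
}

# Consistency policy: observations outrank inferences; between two
# observation-backed items the newer wins; between two inference-backed
# items the newer wins as well (reconsideration in the light of the latest
# derivation).
wm_conflict_keeps_new <- function(old_item, new_just) {
  new_rank <- if (new_just$kind %in% c("observation", "axiom")) 2L else 1L
  old_rank <- just_rank(old_item$justifications)
  new_rank >= old_rank
}

#' Retract an item, optionally cascading through justification chains
#'
#' With `cascade = TRUE` every active item whose justifications all lose
#' support is retracted too, repeatedly, until the store is well-founded
#' again: each surviving non-ground item keeps at least one justification
#' whose supports are all active.
#'
#' @param wm a working memory
#' @param id item id to retract
#' @param cascade follow dependent items
#' @return integer vector of all retracted item ids (the argument first)
#' @export
wm_retract <- function(wm, id, cascade = TRUE) {
  it <- wm_get(wm, id)
  if (it$status != "active") return(integer(0))
  it$status <- "retracted"
  it$retracted_at <- wm$clock
  wm_put(wm, it)
  gone <- id
  if (cascade) {
    repeat {
      dropped <- FALSE
      for (jt in wm$items) {
        if (jt$status != "active") next
        ok <- vapply(jt$justifications, function(j) {
          if (length(j$supports) == 0L) return(j$kind %in% GROUND_JUST)
          all(vapply(j$supports, function(s) {
            wm$items[[as.character(s)]]$status == "active"
          }, logical(1)))
        }, logical(1))
        if (!any(ok)) {
          jt$status <- "retracted"
          jt$retracted_at <- wm$clock
          wm_put(wm, jt)
          gone <- c(gone, jt$id)
          dropped <- TRUE
        }
      }
      if (!dropped) break
    }
  }
  as.integer(gone)
}

#' Query active items matching a pattern
#'
#' @param wm a working memory
#' @param kind optional content kind
#' @param pattern optional description pattern; items whose content is an
#'   atom unifying with it (or a ground description equal to it) match
#' @return list of `list(item, bindings)`
#' @export
wm_query <- function(wm, kind = NULL, pattern = NULL) {
  out <- list()
  for (it in wm_active(wm, kind)) {
    if (is.null(pattern)) {
      out[[length(out) + 1L]] <- list(item = it, bindings = character(0))
      next
    }
    cd <- it$content
    if (!is_desc(cd)) next
    if (cd$type == "atom" && pattern$type == "atom" &&
        pattern$neg == cd$neg) {
      b <- unify_atom(pattern, cd)
      if (!is.null(b)) {
        out[[length(out) + 1L]] <- list(item = it, bindings = b)
      }
    } else if (identical(unclass(cd), unclass(pattern))) {
      out[[length(out) + 1L]] <- list(item = it, bindings = character(0))
    }
  }
  out
}

#' Mark achieved goals
#'
#' Every active goal whose condition now evaluates true is marked
#' `achieved` (achieved goals are terminal). Provisional structures that
#' depended on the goal are left in place but flagged for review by the
#' kernel.
#'
#' @param wm a working memory
#' @param onto the agent's ontology (unused by the default evaluation but
#'   part of the operation's contract; rule-derived conditions already live
#'   in the goal)
#' @return integer vector of goal item ids newly marked achieved
#' @export
check_goal_termination <- function(wm, onto = NULL) {
  keys <- wm_belief_keys(wm)
  achieved <- integer(0)
  for (it in wm_active(wm, "goal")) {
    g <- it$content
    if (!g$status %in% c("raised", "active")) next
    if (holds(g$condition, keys, closed_world = TRUE) == "true") {
      g$status <- "achieved"
      it$content <- g
      it$sig <- content_signature("goal", g)
      wm_put(wm, it)
      achieved <- c(achieved, it$id)
    }
  }
  achieved
}

#' Recompute the active set from scratch
#'
#' Returns the item ids that are well-founded: reachable from ground
#' justifications (observations, axioms, assumptions, communications) by
#' repeatedly adding items one of whose justifications has all supports
#' already included. Used as the reference for the justification-closure
#' invariant: after any sequence of asserts and cascading retracts the
#' active set equals this fixpoint.
#'
#' @param wm a working memory
#' @return integer vector of well-founded active item ids
#' @export
wm_wellfounded <- function(wm) {
  active <- Filter(function(it) it$status == "active", wm$items)
  inset <- integer(0)
  repeat {
    grew <- FALSE
    for (it in active) {
      if (it$id %in% inset) next
      ok <- vapply(it$justifications, function(j) {
        if (length(j$supports) == 0L) return(j$kind %in% GROUND_JUST)
        all(j$supports %in% inset)
      }, logical(1))
      if (any(ok)) {
        inset <- c(inset, it$id)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(inset)
}

#' @export
print.working_memory <- function(x, ...) {
  act <- wm_active(x)
  kinds <- table(vapply(act, `[[`, character(1), "kind"))
  cat("<working memory of", x$agent_id, "> clock", x$clock, "-",
      length(act), "active items\n")
  if (length(kinds)) {
    cat(paste0("  ", names(kinds), ": ", as.integer(kinds), collapse = "\n"),
        "\n")
  }
  invisible(x)
}
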