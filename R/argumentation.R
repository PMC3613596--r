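#' Construct an argument schema
#'
#' Argument schemas are the reusable patterns from which concrete reasons
#' are instantiated: a *pro* or *con* schema yields arguments for or
#' against a decision candidate; an *undercut* schema yields arguments that
#' attack the veracity of another argument rather than the candidate
#' itself. The classic clinical example: "if a treatment is proposed and is
#' known to exacerbate a condition, and the patient has that condition,
#' this is an argument against the treatment".
#'
#' The applicability condition is either a declarative form evaluated
#' against the candidate, the beliefs, and the ontology relations:
#' \describe{
#'   \item{`list(property = p)`}{the candidate's payload concept has
#'     (inherited) property `p`}
#'   \item{`list(relation = r, object_state = s)`}{some concept `o` with
#'     `payload r o` asserted (including via is-a ancestors of the payload)
#'     is believed to be in state `s` (atom `o = s`); one argument per such
#'     `o`}
#'   \item{`list(belief = d)`}{the ground description `d` holds true}
#' }
#' or an R function `function(candidate, goal, wm, onto)` returning `NULL`
#' (not applicable) or a list of grounds (possibly empty) -- the hook
#' through which scenario modules register bespoke reasons such as the
#' card-sorting feature matches.
#'
#' @param id schema identifier
#' @param polarity `"pro"`, `"con"`, or `"undercut"`
#' @param strength positive number added (pro) or subtracted (con) by the
#'   sum-of-reasons aggregation; default 1
#' @param condition applicability condition (see above)
#' @param target `"candidate"` for pro/con, `"argument"` for undercuts
#' @param target_schema for undercut schemas, the id of the schema whose
#'   arguments are attacked
#' @return an `argument_schema` object
#' @export
argument_schema <- function(id, polarity = c("pro", "con", "undercut"),
                            strength = 1, condition = list(),
                            target = NULL, target_schema = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(target)) {
    target <- if (polarity == "undercut") "argument" else "candidate"
  }
  if (polarity == "undercut" && target != "argument") {
    stop("schema '", id, "': undercut schemas must target an argument")
  }
  if (polarity != "undercut" && target != "candidate") {
    stop("schema '", id, "': pro/con schemas must target a candidate")
  }
  stopifnot(is.numeric(strength), strength > 0)
  structure(list(id = id, polarity = polarity, strength = strength,
                 condition = condition, target = target,
                 target_schema = target_schema),
            class = "argument_schema")
}

#' Construct an argument directly
#'
#' Arguments are normally instantiated from schemas by
#' [construct_arguments()]; this low-level constructor builds one directly
#' -- scenario code and communicated (testimonial) arguments use it.
#'
#' @param id argument identifier (unique within one decision)
#' @param candidate candidate id the argument bears on
#' @param polarity `"pro"`, `"con"` or `"undercut"`
#' @param schema id of the schema or line of reasoning it instantiates
#' @param strength positive number
#' @param grounds list recording the instantiated condition and supporting
#'   belief item ids
#' @param target the candidate id (pro/con) or argument id (undercut)
#'   attacked
#' @param target_type `"candidate"` or `"argument"`
#' @return an `argument` object (undefeated)
#' @export
new_argument <- function(id, candidate, polarity, schema, strength,
                         grounds = list(), target = candidate,
                         target_type = "candidate") {
  structure(list(id = id, candidate = candidate, target = target,
                 target_type = target_type, polarity = polarity,
                 schema = schema, strength = strength, grounds = grounds,
                 defeated = FALSE, undecided = FALSE),
            class = "argument")
}

# Evaluate a schema condition against one candidate. Returns NULL when not
# applicable, else a list of grounds records (one argument per record).
schema_instances <- function(schema, candidate, goal, wm, onto) {
  cond <- schema$condition
  if (is.function(cond)) {
    res <- cond(candidate, goal, wm, onto)
    if (is.null(res)) return(NULL)
    if (length(res) == 0L) return(list(list()))
    return(res)
  }
  payload <- candidate$payload
  if (!is.null(cond$property)) {
    if (!payload %in% concept_ids(onto)) return(NULL)
    props <- inherited_properties(onto, payload)
    if (!cond$property %in% names(props)) return(NULL)
    p <- props[[cond$property]]
    if (identical(p, FALSE)) return(NULL)
    return(list(list(property = cond$property)))
  }
  if (!is.null(cond$relation)) {
    if (!payload %in% concept_ids(onto)) return(NULL)
    objs <- related(onto, payload, cond$relation, include_inherited = TRUE)
    if (!length(objs)) return(NULL)
    out <- list()
    keys <- wm_belief_keys(wm)
    for (o in objs) {
      a <- atom(o, cond$object_state %||% "present")
      if (holds(a, keys) == "true") {
        sup <- wm_query(wm, pattern = a)
        ids <- unlist(lapply(sup, function(s) s$item$id))
        out[[length(out) + 1L]] <-
          list(relation = cond$relation, object = o,
               support = as.integer(ids))
      }
    }
    if (!length(out)) return(NULL)
    return(out)
  }
  if (!is.null(cond$belief)) {
    d <- parse_desc(cond$belief)
    if (holds(d, wm_belief_keys(wm)) != "true") return(NULL)
    sup <- if (d$type == "atom") {
      unlist(lapply(wm_query(wm, pattern = d), function(s) s$item$id))
    } else integer(0)
    return(list(list(belief = format(d), support = as.integer(sup))))
  }
  # empty condition: applicable unconditionally
  list(list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct arguments for and against decision candidates
#'
#' Instantiates every satisfied pro/con schema against every candidate,
#' then every satisfied undercut schema against the arguments built from
#' its target schema. Each argument records its grounds (the instantiated
#' condition and the supporting belief item ids).
#'
#' @param candidates list of candidates, each `list(id, payload, goal)`
#' @param goal the goal the decision serves (a goal template or item
#'   content; passed through to functional schema conditions)
#' @param wm working memory supplying the current beliefs
#' @param onto the agent's ontology
#' @param schemas list of [argument_schema()]; defaults to `onto$schemas`
#' @return list of `argument` objects (pro/con first, undercuts after)
#' @export
construct_arguments <- function(candidates, goal, wm, onto,
                                schemas = onto$schemas) {
  if (length(candidates) == 0L) stop("construct_arguments: no candidates")
  args <- list()
  n <- 0L
  for (schema in schemas) {
    if (schema$polarity == "undercut") next
    for (cand in candidates) {
      inst <- schema_instances(schema, cand, goal, wm, onto)
      if (is.null(inst)) next
      for (g in inst) {
        n <- n + 1L
        args[[n]] <- new_argument(paste0("a", n), cand$id, schema$polarity,
                                  schema$id, schema$strength, grounds = g)
      }
    }
  }
  for (schema in schemas) {
    if (schema$polarity != "undercut") next
    targets <- Filter(function(a) identical(a$schema, schema$target_schema),
                      args)
    for (tgt in targets) {
      cand <- NULL
      for (cd in candidates) if (identical(cd$id, tgt$candidate)) cand <- cd
      inst <- schema_instances(schema, cand, goal, wm, onto)
      if (is.null(inst)) next
      for (g in inst) {
        n <- n + 1L
        args[[n]] <- new_argument(paste0("a", n), tgt$candidate, "undercut",
                                  schema$id, schema$strength, grounds = g,
                                  target = tgt$id, target_type = "argument")
      }
    }
  }
  args
}

#' Resolve defeat among arguments (grounded labelling)
#'
#' Computes the grounded (skeptical) labelling of the undercut graph: an
#' argument is labelled defeated (out) iff it is attacked by an undefeated
#' (in) undercutter; an argument is in iff all its attackers are out.
#' Labels are propagated iteratively to fixpoint. Members of undercut
#' cycles that the grounded semantics leaves undecided are flagged
#' `undecided` and are *not* treated as defeated.
#'
#' @param arguments list of `argument` objects
#' @return the list with `defeated` and `undecided` flags set
#' @export
resolve_defeat <- function(arguments) {
  if (!length(arguments)) return(arguments)
  ids <- vapply(arguments, `[[`, character(1), "id")
  attackers <- lapply(arguments, function(a) {
    which(vapply(arguments, function(b) {
      b$target_type == "argument" && identical(b$target, a$id)
    }, logical(1)))
  })
  lab <- rep("undec", length(arguments))
  repeat {
    changed <- FALSE
    for (i in seq_along(arguments)) {
      if (lab[i] != "undec") next
      att <- attackers[[i]]
      if (all(lab[att] == "out")) {
        lab[i] <- "in"; changed <- TRUE
      } else if (any(lab[att] == "in")) {
        lab[i] <- "out"; changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (i in seq_along(arguments)) {
    arguments[[i]]$defeated <- lab[i] == "out"
    arguments[[i]]$undecided <- lab[i] == "undec"
  }
  arguments
}

# --- aggregators -----------------------------------------------------------

aggregator_registry <- new.env(parent = emptyenv())

#' Register a merit aggregator
#'
#' Aggregation is pluggable: an aggregator maps the undefeated arguments
#' bearing on each candidate to a merit. The built-ins are `"bentham"`
#' (sum the strengths of the undefeated pros, subtract the undefeated
#' cons) and `"ordinal"` (count undefeated pros minus undefeated cons,
#' ignoring strengths -- the purely logical variant in which defeat alone
#' can decide the preference).
#'
#' @param id aggregator name
#' @param fn `function(candidate_id, arguments, ...)` returning a numeric
#'   merit; it receives only the undefeated candidate-targeting arguments
#'   for that candidate
#' @return invisibly, the id
#' @export
register_aggregator <- function(id, fn) {
  assign(id, fn, envir = aggregator_registry)
  invisible(id)
}

local({
  register_aggregator("bentham", function(candidate_id, arguments, ...) {
    s <- 0
    for (a in arguments) {
      s <- s + if (a$polarity == "pro") a$strength else -a$strength
    }
    s
  })
  register_aggregator("ordinal", function(candidate_id, arguments, ...) {
    sum(vapply(arguments, function(a) {
      if (a$polarity == "pro") 1 else -1
    }, numeric(1)))
  })
})

#' Aggregate arguments into candidate merits
#'
#' Applies the selected aggregation rule to the *undefeated* arguments for
#' and against each candidate (defeat must have been resolved first;
#' defeated arguments contribute nothing). The default is the Bentham
#' sum-of-reasons rule: merit = sum of pro strengths minus sum of con
#' strengths. A learned-frequency bonus can be mixed in: when `counts` is
#' supplied, each candidate's merit gains `count_weight` times the recorded
#' frequency with which its payload was chosen in this context.
#'
#' @param candidates list of candidates (`list(id, payload, ...)`)
#' @param arguments list of arguments with defeat resolved
#' @param aggregator aggregator name (see [register_aggregator()])
#' @param counts optional named numeric vector of decision frequencies by
#'   payload id (from the learning operation)
#' @param count_weight weight of the frequency bonus, default 0
#' @return named numeric vector of merits by candidate id
#' @export
aggregate_merits <- function(candidates, arguments, aggregator = "bentham",
                             counts = NULL, count_weight = 0) {
  fn <- get0(aggregator, envir = aggregator_registry)
  if (is.null(fn)) stop("unknown aggregator id: '", aggregator, "'")
  ids <- vapply(candidates, `[[`, character(1), "id")
  merits <- stats::setNames(numeric(length(ids)), ids)
  for (cid in ids) {
    rel <- Filter(function(a) {
      a$target_type == "candidate" && identical(a$candidate, cid) &&
        !a$defeated && a$polarity %in% c("pro", "con")
    }, arguments)
    merits[cid] <- fn(cid, rel)
  }
  if (!is.null(counts) && count_weight != 0) {
    for (i in seq_along(candidates)) {
      p <- candidates[[i]]$payload
      if (!is.null(p) && p %in% names(counts)) {
        merits[ids[i]] <- merits[ids[i]] + count_weight * counts[[p]]
      }
    }
  }
  merits
}

#' Total preference order over candidates
#'
#' Orders candidates by descending merit. Ties are broken by the selected
#' policy: `"random"` (a seeded draw -- with no discriminating arguments
#' the adoption of one option over another is arbitrary), `"lexicographic"`
#' (candidate id), or `"priority"` (caller-declared ranks). The result is
#' always a total order consistent with the merits.
#'
#' @param candidates list of candidates or character vector of ids
#' @param merits named numeric vector by candidate id
#' @param tie_break tie-break policy
#' @param priorities named numeric vector (smaller = earlier) for the
#'   `"priority"` policy
#' @return character vector of candidate ids, most preferred first
#' @export
prefer <- function(candidates, merits,
                   tie_break = c("random", "lexicographic", "priority"),
                   priorities = NULL) {
  tie_break <- match.arg(tie_break)
  ids <- if (is.character(candidates)) candidates else
    vapply(candidates, `[[`, character(1), "id")
  m <- merits[ids]
  key <- switch(tie_break,
    random = stats::runif(length(ids)),
    lexicographic = order(ids),
    priority = {
      if (is.null(priorities)) stop("priority tie-break needs priorities")
      priorities[ids]
    })
  ids[order(-m, key)]
}

#' @export
format.argument <- function(x, ...) {
  paste0("[", x$id, "] ", x$polarity, " ",
         if (x$target_type == "argument") paste0("-> ", x$target)
         else x$candidate,
         " (schema ", x$schema, ", strength ", x$strength,
         if (x$defeated) ", DEFEATED" else "", ")")
}

#' @export
print.argument <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
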