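#' Descriptions: ground atoms and logical combinations
#'
#' A *description* is the basic unit of situation knowledge: either an atom
#' pairing an attribute term with a value term (e.g. `indigestion` is
#' `present`), or an and/or/not combination of child descriptions. Atoms may
#' be negated, and attribute or value positions may hold variables (strings
#' beginning with `?`) when the description is used as a rule pattern.
#'
#' Evaluation is three-valued (true / false / unknown) with strong Kleene
#' semantics for the connectives. Under the default open-world assumption an
#' atom absent from the belief set evaluates `unknown`; with
#' `closed_world = TRUE` absence counts as `false` (negation as failure),
#' which goal conditions need ("a situation that does not currently hold").
#'
#' @param attr attribute term (character scalar, or a `?var`)
#' @param value value term (character scalar, or a `?var`)
#' @param neg logical; `TRUE` for a negated atom
#' @return an object of class `ddesc`
#' @examples
#' d <- d_and(atom("indigestion", "present"), atom("patient", "elderly"))
#' holds(d, c("indigestion=present", "patient=elderly"))
#' @export
atom <- function(attr, value, neg = FALSE) {
  stopifnot(is.character(attr), length(attr) == 1L,
            is.character(value), length(value) == 1L)
  structure(list(type = "atom", attr = attr, value = value, neg = isTRUE(neg)),
            class = "ddesc")
}

#' @rdname atom
#' @param ... child descriptions
#' @export
d_and <- function(...) structure(list(type = "and", args = list(...)), class = "ddesc")

#' @rdname atom
#' @export
d_or <- function(...) structure(list(type = "or", args = list(...)), class = "ddesc")

#' @rdname atom
#' @param d a description
#' @export
d_not <- function(d) structure(list(type = "not", args = list(d)), class = "ddesc")

is_desc <- function(x) inherits(x, "ddesc")

is_var <- function(x) is.character(x) && length(x) == 1L && startsWith(x, "?")

#' Is a description ground (free of variables)?
#' @param d a description
#' @return logical scalar
#' @export
desc_is_ground <- function(d) {
  if (d$type == "atom") return(!is_var(d$attr) && !is_var(d$value))
  all(vapply(d$args, desc_is_ground, logical(1)))
}

#' Canonical key of a ground (possibly negated) atom
#' @param d an atom description
#' @return character scalar like `"attr=value"` or `"!attr=value"`
#' @export
atom_key <- function(d) {
  stopifnot(d$type == "atom")
  paste0(if (d$neg) "!" else "", d$attr, "=", d$value)
}

#' Variables occurring in a description
#' @param d a description
#' @return character vector of `?var` names
#' @export
desc_vars <- function(d) {
  if (d$type == "atom") {
    v <- character(0)
    if (is_var(d$attr)) v <- c(v, d$attr)
    if (is_var(d$value)) v <- c(v, d$value)
    return(v)
  }
  unique(unlist(lapply(d$args, desc_vars), use.names = FALSE))
}

#' Substitute variable bindings into a description
#' @param d a description
#' @param bindings named character vector mapping `?var` to terms
#' @return the instantiated description
#' @export
desc_subst <- function(d, bindings) {
  if (d$type == "atom") {
    a <- d$attr; v <- d$value
    if (is_var(a) && a %in% names(bindings)) a <- unname(bindings[[a]])
    if (is_var(v) && v %in% names(bindings)) v <- unname(bindings[[v]])
    return(atom(a, v, d$neg))
  }
  d$args <- lapply(d$args, desc_subst, bindings = bindings)
  d
}

# Three-valued truth arithmetic: false = 0, unknown = 1, true = 2.
tv_num <- c(false = 0, unknown = 1, true = 2)
tv_name <- c("false", "unknown", "true")

#' Three-valued evaluation of a ground description
#'
#' @param d a ground description
#' @param beliefs character vector of canonical keys of believed ground
#'   atoms (`"attr=value"` for atoms believed true, `"!attr=value"` for
#'   atoms believed false), as produced by [atom_key()] or
#'   [wm_belief_keys()]
#' @param closed_world if `TRUE`, an atom absent from `beliefs` evaluates
#'   `"false"` rather than `"unknown"`
#' @return `"true"`, `"false"` or `"unknown"`
#' @export
holds <- function(d, beliefs, closed_world = FALSE) {
  if (!desc_is_ground(d)) {
    stop("holds() requires a ground description; found variables: ",
         paste(desc_vars(d), collapse = ", "))
  }
  tv_name[holds_num(d, beliefs, closed_world) + 1L]
}

holds_num <- function(d, beliefs, closed_world) {
  switch(d$type,
    atom = {
      pos <- paste0(d$attr, "=", d$value)
      val <- if (pos %in% beliefs) 2L
             else if (paste0("!", pos) %in% beliefs) 0L
             else if (closed_world) 0L
             else 1L
      if (d$neg) 2L - val else val
    },
    and = {
      if (length(d$args) == 0L) return(2L)  # vacuous truth
      min(vapply(d$args, holds_num, integer(1),
                 beliefs = beliefs, closed_world = closed_world))
    },
    or = {
      if (length(d$args) == 0L) return(0L)
      max(vapply(d$args, holds_num, integer(1),
                 beliefs = beliefs, closed_world = closed_world))
    },
    not = 2L - holds_num(d$args[[1]], beliefs, closed_world),
    stop("unknown description type: ", d$type)
  )
}

# Flatten a conjunction into its literal list, or NULL if the description is
# not a conjunction of (possibly negated) atoms. Used by the rule matcher;
# arbitrary ground formulas still evaluate through holds().
conj_literals <- function(d) {
  if (d$type == "atom") return(list(d))
  if (d$type == "not" && d$args[[1]]$type == "atom") {
    a <- d$args[[1]]
    return(list(atom(a$attr, a$value, !a$neg)))
  }
  if (d$type != "and") return(NULL)
  out <- list()
  for (a in d$args) {
    lits <- conj_literals(a)
    if (is.null(lits)) return(NULL)
    out <- c(out, lits)
  }
  out
}

#' Match a description pattern against ground belief atoms
#'
#' Performs conjunctive pattern matching: positive atom literals are unified
#' against the belief atoms (plain matching over ground terms -- no
#' occurs-check is needed since beliefs are ground), then the fully bound
#' antecedent is re-evaluated with [holds()] so that negated literals and
#' non-conjunctive structure are honoured.
#'
#' @param pattern a description, possibly containing `?variables`
#' @param belief_atoms list of ground atom descriptions; may carry an `id`
#'   attribute per atom (working-memory item id) used to report support
#' @param closed_world passed to [holds()] for the final check
#' @return list of matches, each `list(bindings = <named chr>, support =
#'   <integer item ids>)`; one entry with empty bindings when a
#'   variable-free pattern holds
#' @export
match_pattern <- function(pattern, belief_atoms, closed_world = FALSE) {
  keys <- vapply(belief_atoms, atom_key, character(1))
  ids <- vapply(belief_atoms, function(a) {
    id <- attr(a, "item_id")
    if (is.null(id)) NA_integer_ else as.integer(id)
  }, integer(1))

  lits <- conj_literals(pattern)
  if (is.null(lits)) {
    if (!desc_is_ground(pattern)) {
      stop("rule antecedents with variables must be conjunctions of literals")
    }
    ok <- holds(pattern, keys, closed_world) == "true"
    return(if (ok) list(list(bindings = character(0), support = integer(0)))
           else list())
  }
  pos <- Filter(function(l) !l$neg, lits)

  results <- list()
  recurse <- function(i, bindings, support) {
    if (i > length(pos)) {
      inst <- desc_subst(pattern, bindings)
      if (!desc_is_ground(inst)) return(invisible(NULL))
      if (holds(inst, keys, closed_world) == "true") {
        results[[length(results) + 1L]] <<-
          list(bindings = bindings, support = support[!is.na(support)])
      }
      return(invisible(NULL))
    }
    lit <- desc_subst(pos[[i]], bindings)
    for (j in seq_along(belief_atoms)) {
      b <- belief_atoms[[j]]
      if (b$neg) next
      nb <- unify_atom(lit, b)
      if (is.null(nb)) next
      recurse(i + 1L, c(bindings, nb), c(support, ids[[j]]))
    }
  }
  recurse(1L, stats::setNames(character(0), character(0)), integer(0))
  results
}

# Unify a (partially bound) positive atom pattern with a ground atom.
# Returns the new bindings added, or NULL on mismatch.
unify_atom <- function(pat, ground) {
  add <- character(0)
  for (slot in c("attr", "value")) {
    p <- pat[[slot]]; g <- ground[[slot]]
    if (is_var(p)) {
      add[p] <- g
      pat <- desc_subst(pat, stats::setNames(g, p))
    } else if (p != g) {
      return(NULL)
    }
  }
  add
}

# Parse the YAML/list form of a description.
parse_desc <- function(x) {
  if (is_desc(x)) return(x)
  stopifnot(is.list(x))
  if (!is.null(x$atom)) {
    return(atom(as.character(x$atom[[1]]), as.character(x$atom[[2]]),
                isTRUE(x$neg)))
  }
  if (!is.null(x$and)) return(do.call(d_and, lapply(x$and, parse_desc)))
  if (!is.null(x$or)) return(do.call(d_or, lapply(x$or, parse_desc)))
  if (!is.null(x$not)) return(d_not(parse_desc(x$not)))
  stop("cannot parse description: ", paste(deparse(x), collapse = " "))
}

# Serialize a description back to the YAML/list form (round-trip inverse of
# parse_desc).
unparse_desc <- function(d) {
  switch(d$type,
    atom = {
      out <- list(atom = list(d$attr, d$value))
      if (d$neg) out$neg <- TRUE
      out
    },
    and = list(and = lapply(d$args, unparse_desc)),
    or = list(or = lapply(d$args, unparse_desc)),
    not = list(not = unparse_desc(d$args[[1]]))
  )
}

#' @export
format.ddesc <- function(x, ...) {
  switch(x$type,
    atom = paste0(if (x$neg) "not " else "", x$attr, " = ", x$value),
    and = paste0("(", paste(vapply(x$args, format, character(1)),
                            collapse = " and "), ")"),
    or = paste0("(", paste(vapply(x$args, format, character(1)),
                           collapse = " or "), ")"),
    not = paste0("not ", format(x$args[[1]]))
  )
}

#' @export
print.ddesc <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
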