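# Independent brute-force oracles used by the property suites. These share
# no code with the implementation paths they check.

# exhaustive reachability in the is-a graph by path enumeration
reach_oracle <- function(onto, a, b) {
  if (identical(a, b)) return(TRUE)
  stack <- list(a)
  visited <- character(0)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur %in% visited) next
    visited <- c(visited, cur)
    for (p in onto$concepts[[cur]]$parents) {
      if (identical(p, b)) return(TRUE)
      stack[[length(stack) + 1L]] <- p
    }
  }
  FALSE
}

# ancestor set by independent recursive traversal
ancestor_oracle <- function(onto, a) {
  out <- a
  for (p in onto$concepts[[a]]$parents) {
    out <- union(out, ancestor_oracle(onto, p))
  }
  out
}

# three-valued evaluation via explicit lookup tables (0 false, 1 unknown,
# 2 true)
tt_oracle <- function(d, assignment, closed_world) {
  AND <- outer(0:2, 0:2, pmin)
  OR <- outer(0:2, 0:2, pmax)
  ev <- function(d) {
    if (d$type == "atom") {
      key <- paste0(d$attr, "=", d$value)
      v <- if (key %in% names(assignment)) assignment[[key]]
           else if (closed_world) 0L else 1L
      return(if (d$neg) 2L - v else v)
    }
    if (d$type == "not") return(2L - ev(d$args[[1]]))
    vals <- vapply(d$args, ev, integer(1))
    if (d$type == "and") {
      acc <- 2L
      for (v in vals) acc <- AND[acc + 1L, v + 1L]
      return(acc)
    }
    acc <- 0L
    for (v in vals) acc <- OR[acc + 1L, v + 1L]
    acc
  }
  c("false", "unknown", "true")[ev(d) + 1L]
}

# random description over a fixed alphabet of 4 atoms
random_desc <- function(depth = 3L) {
  attrs <- c("w", "x", "y", "z")
  vals <- c("1", "2")
  if (depth == 0L || stats::runif(1) < 0.4) {
    return(atom(sample(attrs, 1), sample(vals, 1),
                neg = stats::runif(1) < 0.3))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") return(d_not(random_desc(depth - 1L)))
  k <- sample(0:3, 1)
  kids <- replicate(k, random_desc(depth - 1L), simplify = FALSE)
  if (op == "and") do.call(d_and, kids) else do.call(d_or, kids)
}

# enumerate-and-test rule instantiation: substitute every combination of
# constants for the variables and keep the ground instances whose
# antecedent holds true
enumerate_rule_oracle <- function(r, belief_atoms, constants) {
  keys <- vapply(belief_atoms, atom_key, character(1))
  vars <- if (is.null(r$when)) character(0) else desc_vars(r$when)
  if (!length(vars)) {
    ok <- is.null(r$when) || holds(r$when, keys, r$closed_world) == "true"
    return(if (ok) list(stats::setNames(character(0), character(0)))
           else list())
  }
  grids <- rep(list(constants), length(vars))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    b <- stats::setNames(as.character(combos[i, ]), vars)
    inst <- desc_subst(r$when, b)
    if (desc_is_ground(inst) &&
        holds(inst, keys, r$closed_world) == "true") {
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

# naive repeat-until-no-change forward chaining over ground-key sets,
# using the enumeration oracle for matching
fixpoint_oracle <- function(rules, initial_atoms) {
  keys <- unique(vapply(initial_atoms, atom_key, character(1)))
  constants <- unique(unlist(lapply(initial_atoms, function(a) {
    c(a$attr, a$value)
  })))
  atoms <- initial_atoms
  repeat {
    grew <- FALSE
    for (r in rules) {
      if (r$kind != "belief") next
      for (b in enumerate_rule_oracle(r, atoms, constants)) {
        for (cq in r$then) {
          inst <- desc_subst(cq, b)
          k <- atom_key(inst)
          if (!k %in% keys) {
            keys <- c(keys, k)
            atoms <- c(atoms, list(inst))
            grew <- TRUE
          }
        }
      }
    }
    if (!grew) break
  }
  sort(keys)
}

# grounded extension by exhaustive subset enumeration: the grounded
# extension is the unique subset-minimal complete extension
grounded_oracle <- function(n, attacks) {
  # attacks: 2-column matrix (attacker, target) of indices
  attackers_of <- lapply(seq_len(n), function(i) {
    attacks[attacks[, 2] == i, 1]
  })
  conflict_free <- function(S) {
    !any(attacks[, 1] %in% S & attacks[, 2] %in% S)
  }
  defends <- function(S, i) {
    all(vapply(attackers_of[[i]], function(a) {
      any(attackers_of[[a]] %in% S)
    }, logical(1)))
  }
  complete_exts <- list()
  for (bits in 0:(2^n - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0)
    if (!conflict_free(S)) next
    defended <- vapply(seq_len(n), function(i) defends(S, i), logical(1))
    if (setequal(which(defended), S)) {
      complete_exts[[length(complete_exts) + 1L]] <- S
    }
  }
  sizes <- vapply(complete_exts, length, integer(1))
  complete_exts[[which.min(sizes)]]
}

# direct tally of undefeated pro/con strengths
tally_oracle <- function(arguments, candidate_id) {
  total <- 0
  for (a in arguments) {
    if (a$target_type != "candidate") next
    if (!identical(a$candidate, candidate_id)) next
    if (a$defeated) next
    total <- total + switch(a$polarity, pro = a$strength,
                            con = -a$strength, 0)
  }
  total
}

# random argument set: each node is either a pro/con argument on a
# candidate or an undercutter attacking one other node (undercutters may
# themselves be undercut, giving chains; with acyclic = FALSE targets may
# point forward, allowing cycles)
random_argument_set <- function(n, p_undercut = 0.5, acyclic = TRUE) {
  cands <- c("A", "B", "C")
  args <- vector("list", n)
  attacks <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    pool <- if (acyclic) seq_len(i - 1L) else setdiff(seq_len(n), i)
    if (length(pool) && stats::runif(1) < p_undercut) {
      j <- if (length(pool) == 1L) pool else sample(pool, 1)
      args[[i]] <- new_argument(paste0("a", i), "A", "undercut",
                                paste0("u", i), 1,
                                target = paste0("a", j),
                                target_type = "argument")
      attacks <- rbind(attacks, c(i, j))
    } else {
      args[[i]] <- new_argument(paste0("a", i), sample(cands, 1),
                                sample(c("pro", "con"), 1),
                                paste0("s", i), sample(1:3, 1))
    }
  }
  list(args = args, attacks = attacks)
}

# goal item id for a template on an agent (test convenience)
goal_item_for_test <- function(ag, tmpl) {
  for (it in wm_active(ag$wm, "goal")) {
    if (identical(it$content$template, tmpl)) return(it$id)
  }
  NULL
}
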