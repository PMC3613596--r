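#' Construct a concept
#'
#' Concepts are nodes of the knowledge-level hierarchy. Each concept may
#' have several parents (the is-a-kind-of graph is a DAG, not a tree) and a
#' set of property assertions that descendants inherit.
#'
#' @param id concept identifier (unique within an ontology)
#' @param label human-readable term; defaults to the id
#' @param parents character vector of parent concept ids
#' @param properties named list of property assertions (name -> value;
#'   use `TRUE` for flag properties)
#' @return a `concept` object
#' @export
concept <- function(id, label = id, parents = character(0),
                    properties = list()) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, label = label,
                 parents = as.character(parents),
                 properties = properties),
            class = "concept")
}

#' Construct an ontology
#'
#' The ontology is the agent's background knowledge: a concept network with
#' is-a inheritance, inter-concept relations drawn from a declared
#' vocabulary, rules (belief, goal, candidate, expectation), goal templates,
#' argument schemas, plan templates, and scenario/task models.
#'
#' @param concepts list of [concept()] objects
#' @param relations data frame with columns `subject`, `relation`, `object`
#' @param relation_vocab character vector of admissible relation names
#' @param rules list of rules (see [rule()])
#' @param goals list of goal templates (see [goal_template()])
#' @param schemas list of argument schemas (see [argument_schema()])
#' @param plans named list of plan templates (see [plan_template()])
#' @param scenarios list of scenario models
#' @param tasks list of task models
#' @return an `ontology` object
#' @export
ontology <- function(concepts = list(), relations = empty_relations(),
                     relation_vocab = character(0), rules = list(),
                     goals = list(), schemas = list(), plans = list(),
                     scenarios = list(), tasks = list()) {
  names(concepts) <- vapply(concepts, `[[`, character(1), "id")
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  names(goals) <- vapply(goals, `[[`, character(1), "id")
  names(schemas) <- vapply(schemas, `[[`, character(1), "id")
  if (length(plans)) names(plans) <- vapply(plans, `[[`, character(1), "id")
  if (length(scenarios))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "id")
  if (length(tasks)) names(tasks) <- vapply(tasks, `[[`, character(1), "id")
  structure(list(concepts = concepts, relations = relations,
                 relation_vocab = as.character(relation_vocab),
                 rules = rules, goals = goals, schemas = schemas,
                 plans = plans, scenarios = scenarios, tasks = tasks),
            class = "ontology")
}

empty_relations <- function() {
  data.frame(subject = character(0), relation = character(0),
             object = character(0), stringsAsFactors = FALSE)
}

#' Construct a rule
#'
#' Rules connect descriptions: when the antecedent holds under the current
#' beliefs, the consequents are derivable. The `kind` states what the rule
#' produces: new beliefs, raised goals, decision candidates, or
#' expectations. Variables (`?x`) in consequents must be bound by the
#' antecedent.
#'
#' @param id rule identifier
#' @param kind one of `"belief"`, `"goal"`, `"candidate"`, `"expectation"`
#' @param when antecedent description pattern (may contain variables), or
#'   `NULL` for rules triggered purely by a goal (`when_goal`)
#' @param then for belief/expectation rules, a list of consequent
#'   description patterns; for goal rules, a character vector of goal
#'   template ids; for candidate rules, a character vector of payload
#'   (concept or plan-template) ids
#' @param when_goal optional goal-template id; the rule fires only while
#'   that goal is active (used for sub-goal raising and candidate retrieval)
#' @param closed_world evaluate this rule's antecedent with negation as
#'   failure
#' @param provenance `"authored"` or `"learned"`
#' @return a `rule` object
#' @export
rule <- function(id, kind, when = NULL, then, when_goal = NULL,
                 closed_world = FALSE, provenance = "authored") {
  kind <- match.arg(kind, c("belief", "goal", "candidate", "expectation"))
  if (!is.null(when)) when <- parse_desc(when)
  if (kind %in% c("belief", "expectation")) {
    then <- lapply(then, parse_desc)
    av <- if (is.null(when)) character(0) else desc_vars(when)
    for (cq in then) {
      unbound <- setdiff(desc_vars(cq), av)
      if (length(unbound)) {
        stop("rule '", id, "': consequent variable(s) ",
             paste(unbound, collapse = ", "), " not bound in antecedent")
      }
    }
  } else {
    then <- as.character(then)
  }
  structure(list(id = id, kind = kind, when = when, then = then,
                 when_goal = when_goal, closed_world = isTRUE(closed_world),
                 provenance = provenance),
            class = "rule")
}

#' Construct a goal template
#'
#' A goal template names a condition that, when raised as a goal, does not
#' currently hold; the goal is achieved when the condition becomes true.
#' Decision goals additionally carry the commitment mode: `accept` commits
#' to a belief (hypothesis choice), `adopt` commits to a plan of action.
#'
#' @param id template identifier
#' @param condition description to bring about
#' @param priority smaller numbers are processed first
#' @param stakes `"routine"` or `"high"`; high-stakes decisions are
#'   committed provisionally while a consultation source remains unexploited
#' @param mode `NULL` for plain goals, `"accept"` or `"adopt"` for decision
#'   goals
#' @param accept_attr for accept-mode goals, the attribute the accepted
#'   belief asserts (value = committed candidate payload)
#' @param consult optional id of an agent that can be consulted before a
#'   firm commitment is made on this goal
#' @return a `goal_template` object
#' @export
goal_template <- function(id, condition, priority = 1L,
                          stakes = c("routine", "high"), mode = NULL,
                          accept_attr = NULL, consult = NULL) {
  stakes <- match.arg(stakes)
  if (!is.null(mode)) mode <- match.arg(mode, c("accept", "adopt"))
  structure(list(id = id, condition = parse_desc(condition),
                 priority = as.integer(priority), stakes = stakes,
                 mode = mode, accept_attr = accept_attr, consult = consult),
            class = "goal_template")
}

#' Construct a scenario model
#'
#' Scenario models condense descriptions into reusable situation patterns
#' with associated goals; the learning operation appends episodic scenario
#' models recording what was decided and under which beliefs.
#'
#' @param id,label identifier and term
#' @param situation situation description pattern
#' @param goals character vector of associated goal template ids
#' @param provenance `"authored"` or `"learned"`
#' @param episode optional episodic payload (goal, commitment, beliefs)
#' @return a `scenario_model` object
#' @export
scenario_model <- function(id, label = id, situation = d_and(),
                           goals = character(0), provenance = "authored",
                           episode = NULL) {
  structure(list(id = id, label = label, situation = parse_desc(situation),
                 goals = as.character(goals), provenance = provenance,
                 episode = episode),
            class = "scenario_model")
}

#' Construct a task model
#'
#' @param id,label identifier and term
#' @param serves goal template id this task achieves
#' @param plan plan template id
#' @return a `task_model` object
#' @export
task_model <- function(id, label = id, serves, plan) {
  structure(list(id = id, label = label, serves = serves, plan = plan),
            class = "task_model")
}

concept_ids <- function(onto) names(onto$concepts)

resolve_concept <- function(onto, id) {
  c <- onto$concepts[[id]]
  if (is.null(c)) stop("unknown concept id: '", id, "'")
  c
}

#' Is-a (reflexive-transitive) test
#'
#' `is_a(onto, a, b)` is `TRUE` iff `b` lies in the reflexive-transitive
#' closure of the is-a-kind-of links starting from `a` — e.g. a gastric
#' ulcer is a kind of peptic ulcer, and of disease, and of itself.
#'
#' @param onto an [ontology()]
#' @param a,b concept ids
#' @return logical scalar
#' @export
is_a <- function(onto, a, b) {
  resolve_concept(onto, a); resolve_concept(onto, b)
  b %in% ancestors(onto, a)
}

#' Ancestors of a concept (reflexive closure, breadth-first order)
#'
#' @param onto an [ontology()]
#' @param a concept id
#' @return character vector of concept ids, starting with `a` itself,
#'   ordered by increasing is-a distance (ties in declaration order),
#'   deduplicated
#' @export
ancestors <- function(onto, a) {
  resolve_concept(onto, a)
  seen <- character(0)
  frontier <- a
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, function(id) {
      cpt <- onto$concepts[[id]]
      if (is.null(cpt)) character(0) else cpt$parents
    }), use.names = FALSE)
  }
  seen
}

#' Properties of a concept including inherited ones
#'
#' Returns the union of the concept's own property assertions and those of
#' all its ancestors. A property declared on a descendant shadows a
#' same-named property on an ancestor (specific-over-general); among
#' equally specific ancestors the first in breadth-first order wins.
#'
#' @param onto an [ontology()]
#' @param a concept id
#' @return named list of property values
#' @export
inherited_properties <- function(onto, a) {
  out <- list()
  for (id in ancestors(onto, a)) {
    props <- onto$concepts[[id]]$properties
    for (nm in names(props)) {
      if (!nm %in% names(out)) out[[nm]] <- props[[nm]]
    }
  }
  out
}

#' Concepts related to a concept through a named relation
#'
#' @param onto an [ontology()]
#' @param a subject concept id
#' @param relation relation name from the declared vocabulary
#' @param include_inherited also collect assertions whose subject is an
#'   ancestor of `a` (e.g. symptoms caused by more general kinds of ulcer)
#' @return character vector of object concept ids (deduplicated, in
#'   assertion order)
#' @export
related <- function(onto, a, relation, include_inherited = FALSE) {
  resolve_concept(onto, a)
  if (!relation %in% onto$relation_vocab) {
    stop("undeclared relation name: '", relation, "'")
  }
  subjects <- if (include_inherited) ancestors(onto, a) else a
  hit <- onto$relations$relation == relation &
    onto$relations$subject %in% subjects
  unique(onto$relations$object[hit])
}

#' Instantiated rule consequents applicable under the current beliefs
#'
#' For every rule of the requested kind whose antecedent holds true under
#' the beliefs (in every variable binding that makes it true), returns the
#' instantiated consequents together with the bindings and the supporting
#' belief atoms.
#'
#' @param belief_atoms list of ground atom descriptions (optionally
#'   carrying `item_id` attributes); see [wm_belief_atoms()]
#' @param kind rule kind to consider
#' @param onto an [ontology()]
#' @param active_goals character vector of goal template ids currently
#'   active; rules with a `when_goal` guard fire only when it is listed
#' @return list of records `list(rule, bindings, support, consequents)`;
#'   for belief/expectation rules `consequents` is a list of ground
#'   descriptions, for goal/candidate rules a character vector of ids
#' @export
applicable_rules <- function(belief_atoms, kind, onto,
                             active_goals = character(0)) {
  out <- list()
  for (r in onto$rules) {
    if (r$kind != kind) next
    if (!is.null(r$when_goal) && !r$when_goal %in% active_goals) next
    if (is.null(r$when)) {
      matches <- list(list(bindings = character(0), support = integer(0)))
    } else {
      matches <- match_pattern(r$when, belief_atoms,
                               closed_world = r$closed_world)
    }
    for (m in matches) {
      cons <- if (kind %in% c("belief", "expectation")) {
        lapply(r$then, desc_subst, bindings = m$bindings)
      } else {
        r$then
      }
      out[[length(out) + 1L]] <- list(rule = r$id, bindings = m$bindings,
                                      support = m$support,
                                      consequents = cons)
    }
  }
  out
}

#' Check an ontology's referential and structural integrity
#'
#' @param onto an [ontology()]
#' @return character vector of violations, empty when the ontology is
#'   valid; each entry names the offending element
#' @export
validate_ontology <- function(onto) {
  v <- character(0)
  ids <- concept_ids(onto)
  if (anyDuplicated(ids)) {
    v <- c(v, paste0("duplicate concept id: '",
                     unique(ids[duplicated(ids)]), "'"))
  }
  for (cpt in onto$concepts) {
    missing <- setdiff(cpt$parents, ids)
    for (m in missing) {
      v <- c(v, paste0("concept '", cpt$id, "': unresolved parent '", m, "'"))
    }
  }
  cyc <- find_isa_cycle(onto)
  if (!is.null(cyc)) {
    v <- c(v, paste0("is-a cycle: ", paste(cyc, collapse = " -> ")))
  }
  if (nrow(onto$relations)) {
    for (i in seq_len(nrow(onto$relations))) {
      row <- onto$relations[i, ]
      if (!row$relation %in% onto$relation_vocab) {
        v <- c(v, paste0("relation assertion ", i, ": undeclared relation '",
                         row$relation, "'"))
      }
      for (side in c("subject", "object")) {
        if (!row[[side]] %in% ids) {
          v <- c(v, paste0("relation assertion ", i, ": unresolved ", side,
                           " '", row[[side]], "'"))
        }
      }
    }
  }
  for (r in onto$rules) {
    if (r$kind == "goal") {
      for (g in r$then) {
        if (!g %in% names(onto$goals)) {
          v <- c(v, paste0("rule '", r$id, "': unknown goal template '",
                           g, "'"))
        }
      }
    }
    if (!is.null(r$when_goal) && !r$when_goal %in% names(onto$goals)) {
      v <- c(v, paste0("rule '", r$id, "': unknown when_goal '",
                       r$when_goal, "'"))
    }
  }
  for (s in onto$schemas) {
    rel <- s$condition$relation
    if (!is.null(rel) && !rel %in% onto$relation_vocab) {
      v <- c(v, paste0("schema '", s$id, "': undeclared relation '",
                       rel, "'"))
    }
    if (identical(s$target, "argument") && is.null(s$target_schema)) {
      v <- c(v, paste0("schema '", s$id,
                       "': undercut schema lacks target_schema"))
    }
  }
  for (tm in onto$tasks) {
    if (!tm$plan %in% names(onto$plans)) {
      v <- c(v, paste0("task model '", tm$id, "': unknown plan template '",
                       tm$plan, "'"))
    }
    if (!tm$serves %in% names(onto$goals)) {
      v <- c(v, paste0("task model '", tm$id, "': unknown goal template '",
                       tm$serves, "'"))
    }
  }
  for (sc in onto$scenarios) {
    missing <- setdiff(sc$goals, names(onto$goals))
    for (m in missing) {
      v <- c(v, paste0("scenario '", sc$id, "': unknown goal template '",
                       m, "'"))
    }
  }
  v
}

# Depth-first search for a cycle in the is-a graph; returns the cycle as a
# character vector of ids, or NULL.
find_isa_cycle <- function(onto) {
  colour <- stats::setNames(rep("white", length(onto$concepts)),
                            concept_ids(onto))
  path <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return(invisible(NULL))
    colour[id] <<- "grey"
    path <<- c(path, id)
    for (p in onto$concepts[[id]]$parents) {
      if (!p %in% names(colour)) next
      if (colour[p] == "grey") {
        found <<- c(path[which(path == p)[1]:length(path)], p)
        return(invisible(NULL))
      }
      if (colour[p] == "white") visit(p)
    }
    colour[id] <<- "black"
    path <<- path[-length(path)]
  }
  for (id in names(colour)) {
    if (colour[id] == "white") visit(id)
    if (!is.null(found)) break
  }
  found
}

#' Merge two ontologies (shared knowledge plus a specialist partition)
#'
#' Used to give each agent its own view: the shared knowledge base plus the
#' agent's specialist partition. Element ids in the partition must not
#' collide with shared ids.
#'
#' @param base,extra ontologies
#' @return merged ontology
#' @export
merge_ontology <- function(base, extra) {
  for (section in c("concepts", "rules", "goals", "schemas", "plans",
                    "scenarios", "tasks")) {
    clash <- intersect(names(base[[section]]), names(extra[[section]]))
    if (length(clash)) {
      stop("specialist partition redefines shared ", section, ": ",
           paste(clash, collapse = ", "))
    }
    base[[section]] <- c(base[[section]], extra[[section]])
  }
  base$relations <- rbind(base$relations, extra$relations)
  base$relation_vocab <- union(base$relation_vocab, extra$relation_vocab)
  base
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology>", length(x$concepts), "concepts,",
      nrow(x$relations), "relation assertions,",
      length(x$rules), "rules,",
      length(x$goals), "goal templates,",
      length(x$schemas), "schemas,",
      length(x$plans), "plan templates\n")
  invisible(x)
}
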