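#' Load a knowledge-base file
#'
#' Knowledge bases are YAML documents with top-level sections `concepts`,
#' `relations` (vocabulary + assertions), `rules`, `goals`, `schemas`,
#' `plans`, `scenarios`, `tasks`, `agents`, and `presentations`. The loader
#' validates the document against the expected structure and the ontology
#' integrity rules; errors are reported with the file and, where the
#' offending element can be located, the line. Loading is atomic: any
#' violation aborts with no partial state.
#'
#' @param path path to a YAML knowledge base
#' @return a `knowledge_base` list: `onto` (the shared [ontology()]),
#'   `agents` (list of agent specs: `id`, `roles`, `partition`, `case`,
#'   `aggregator`), `presentations`, `format_version`
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("knowledge base not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  anchor <- function(id) {
    hit <- grep(paste0("\\bid:\\s*", id, "\\b"), readLines(path, warn = FALSE))
    if (length(hit)) paste0(path, ":", hit[1]) else path
  }
  onto <- parse_kb_ontology(doc, anchor)
  v <- validate_ontology(onto)
  agents <- lapply(doc$agents %||% list(), function(a) {
    part <- if (is.null(a$partition)) NULL else
      parse_kb_ontology(a$partition, anchor)
    if (!is.null(part)) {
      merged <- tryCatch(merge_ontology(onto, part), error = function(e) {
        v <<- c(v, paste0("agent '", a$id, "': ", conditionMessage(e)))
        NULL
      })
      if (!is.null(merged)) {
        pv <- setdiff(validate_ontology(merged), v)
        if (length(pv)) v <<- c(v, paste0("agent '", a$id, "': ", pv))
      }
    }
    list(id = a$id, roles = as.character(a$roles %||% "decision"),
         partition = part, case = a$case,
         aggregator = a$aggregator %||% "bentham")
  })
  if (length(v)) {
    stop("invalid knowledge base ", path, ":\n  ",
         paste(vapply(v, function(m) paste0(anchor_guess(m, anchor), m),
                      character(1)),
               collapse = "\n  "))
  }
  structure(list(onto = onto, agents = agents,
                 presentations = doc$presentations %||% list(),
                 format_version = doc$format_version %||% 1L),
            class = "knowledge_base")
}

anchor_guess <- function(msg, anchor) {
  id <- regmatches(msg, regexpr("'[^']+'", msg))
  if (length(id)) {
    a <- anchor(gsub("'", "", id[1]))
    paste0(a, ": ")
  } else ""
}

parse_kb_ontology <- function(doc, anchor = identity) {
  concepts <- lapply(doc$concepts %||% list(), function(cc) {
    concept(cc$id, label = cc$label %||% cc$id,
            parents = as.character(cc$parents %||% character(0)),
            properties = cc$properties %||% list())
  })
  rel <- doc$relations %||% list()
  asserts <- rel$assertions %||% list()
  relations <- if (length(asserts)) {
    data.frame(subject = vapply(asserts, function(x) as.character(x[[1]]),
                                character(1)),
               relation = vapply(asserts, function(x) as.character(x[[2]]),
                                 character(1)),
               object = vapply(asserts, function(x) as.character(x[[3]]),
                               character(1)),
               stringsAsFactors = FALSE)
  } else empty_relations()
  rules <- lapply(doc$rules %||% list(), function(r) {
    rule(r$id, r$kind, when = r[["when"]], then = r$then,
         when_goal = r[["when_goal"]], closed_world = isTRUE(r$closed_world),
         provenance = r$provenance %||% "authored")
  })
  goals <- lapply(doc$goals %||% list(), function(g) {
    goal_template(g$id, condition = g$condition,
                  priority = g$priority %||% 1L,
                  stakes = g$stakes %||% "routine", mode = g$mode,
                  accept_attr = g$accept_attr, consult = g$consult)
  })
  schemas <- lapply(doc$schemas %||% list(), function(s) {
    argument_schema(s$id, polarity = s$polarity,
                    strength = s$strength %||% 1,
                    condition = s$condition %||% list(),
                    target_schema = s$target_schema)
  })
  plans <- lapply(doc$plans %||% list(), function(p) {
    plan_template(p$id, lapply(p$tasks, function(t) {
      t$after <- as.character(t$after %||% character(0))
      t
    }))
  })
  scenarios <- lapply(doc$scenarios %||% list(), function(s) {
    scenario_model(s$id, label = s$label %||% s$id,
                   situation = s$situation %||% list(and = list()),
                   goals = as.character(s$goals %||% character(0)),
                   provenance = s$provenance %||% "authored")
  })
  tasks <- lapply(doc$tasks %||% list(), function(t) {
    task_model(t$id, label = t$label %||% t$id, serves = t$serves,
               plan = t$plan)
  })
  ontology(concepts = concepts, relations = relations,
           relation_vocab = as.character(rel$vocabulary %||% character(0)),
           rules = rules, goals = goals, schemas = schemas, plans = plans,
           scenarios = scenarios, tasks = tasks)
}

#' Serialize a knowledge base back to YAML
#'
#' Inverse of [load_kb()] up to formatting: `load_kb(write_kb(kb, f))`
#' yields an identical object graph.
#'
#' @param kb a `knowledge_base`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_kb <- function(kb, path) {
  doc <- c(list(format_version = kb$format_version),
           unparse_kb_ontology(kb$onto))
  if (length(kb$agents)) {
    doc$agents <- lapply(kb$agents, function(a) {
      out <- list(id = a$id, roles = as.list(a$roles))
      if (!is.null(a$partition)) {
        out$partition <- unparse_kb_ontology(a$partition)
      }
      if (!is.null(a$case)) out$case <- a$case
      if (!identical(a$aggregator, "bentham")) out$aggregator <- a$aggregator
      out
    })
  }
  if (length(kb$presentations)) doc$presentations <- kb$presentations
  yaml::write_yaml(doc, path)
  invisible(path)
}

unparse_kb_ontology <- function(onto) {
  doc <- list()
  if (length(onto$concepts)) {
    doc$concepts <- unname(lapply(onto$concepts, function(cc) {
      out <- list(id = cc$id)
      if (!identical(cc$label, cc$id)) out$label <- cc$label
      if (length(cc$parents)) out$parents <- as.list(cc$parents)
      if (length(cc$properties)) out$properties <- cc$properties
      out
    }))
  }
  if (length(onto$relation_vocab) || nrow(onto$relations)) {
    doc$relations <- list(vocabulary = as.list(onto$relation_vocab))
    if (nrow(onto$relations)) {
      doc$relations$assertions <- lapply(seq_len(nrow(onto$relations)),
        function(i) as.list(unname(unlist(onto$relations[i, ]))))
    }
  }
  if (length(onto$rules)) {
    doc$rules <- unname(lapply(onto$rules, function(r) {
      out <- list(id = r$id, kind = r$kind)
      if (!is.null(r$when)) out$when <- unparse_desc(r$when)
      out$then <- if (r$kind %in% c("belief", "expectation")) {
        lapply(r$then, unparse_desc)
      } else as.list(r$then)
      if (!is.null(r$when_goal)) out$when_goal <- r$when_goal
      if (r$closed_world) out$closed_world <- TRUE
      if (!identical(r$provenance, "authored")) out$provenance <- r$provenance
      out
    }))
  }
  if (length(onto$goals)) {
    doc$goals <- unname(lapply(onto$goals, function(g) {
      out <- list(id = g$id, condition = unparse_desc(g$condition))
      if (g$priority != 1L) out$priority <- g$priority
      if (!identical(g$stakes, "routine")) out$stakes <- g$stakes
      if (!is.null(g$mode)) out$mode <- g$mode
      if (!is.null(g$accept_attr)) out$accept_attr <- g$accept_attr
      if (!is.null(g$consult)) out$consult <- g$consult
      out
    }))
  }
  if (length(onto$schemas)) {
    doc$schemas <- unname(lapply(onto$schemas, function(s) {
      out <- list(id = s$id, polarity = s$polarity)
      if (s$strength != 1) out$strength <- s$strength
      if (length(s$condition)) out$condition <- s$condition
      if (!is.null(s$target_schema)) out$target_schema <- s$target_schema
      out
    }))
  }
  if (length(onto$plans)) {
    doc$plans <- unname(lapply(onto$plans, function(p) {
      list(id = p$id, tasks = unname(lapply(p$tasks, function(t) {
        out <- list(id = t$id, type = t$type)
        if (length(t$after)) out$after <- as.list(t$after)
        if (!is.null(t$precondition)) {
          out$precondition <- unparse_desc(t$precondition)
        }
        for (f in c("performative", "receiver", "content", "effect",
                    "concept")) {
          if (!is.null(t[[f]])) out[[f]] <- t[[f]]
        }
        out
      })))
    }))
  }
  if (length(onto$scenarios)) {
    doc$scenarios <- unname(lapply(onto$scenarios, function(s) {
      out <- list(id = s$id)
      if (!identical(s$label, s$id)) out$label <- s$label
      out$situation <- unparse_desc(s$situation)
      if (length(s$goals)) out$goals <- as.list(s$goals)
      if (!identical(s$provenance, "authored")) out$provenance <- s$provenance
      out
    }))
  }
  if (length(onto$tasks)) {
    doc$tasks <- unname(lapply(onto$tasks, function(t) {
      list(id = t$id, serves = t$serves, plan = t$plan)
    }))
  }
  doc
}

#' Build agents from a loaded knowledge base
#'
#' @param kb a `knowledge_base` from [load_kb()]
#' @param ... additional arguments passed to [agent_new()] (e.g.
#'   `tie_break`)
#' @return named list of agents in declaration (registration) order
#' @export
build_agents <- function(kb, ...) {
  agents <- lapply(kb$agents, function(sp) {
    agent_new(sp$id, kb$onto, partition = sp$partition, roles = sp$roles,
              aggregator = sp$aggregator, case = sp$case, ...)
  })
  stats::setNames(agents, vapply(agents, `[[`, character(1), "id"))
}

# --- traces ---------------------------------------------------------------

canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

#' Write a trace to a JSONL file
#'
#' One JSON object per line; the first line is a meta record (`type:
#' "meta"`) holding the scenario name, seed and parameters needed for
#' replay, each subsequent line one trace record.
#'
#' @param trace list of trace records (from [run_cycle()],
#'   [run_network()]`$trace`, or a WCST trial log converted by
#'   [wcst_trace_records()])
#' @param path output path
#' @param meta named list stored in the meta record (must include
#'   `scenario` and `seed` for [replay()] to work)
#' @return invisibly, `path`
#' @export
write_trace <- function(trace, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(canonical_json(c(list(type = "meta", format_version = 1L),
                              meta)), con)
  for (rec in trace) writeLines(canonical_json(rec), con)
  invisible(path)
}

#' Read a JSONL trace
#' @param path trace path
#' @return list with `meta` and `records`
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  if (!length(objs) || !identical(objs[[1]]$type, "meta")) {
    stop("trace ", path, " has no meta record")
  }
  list(meta = objs[[1]], records = objs[-1])
}

#' Replay a stored trace and verify it against a fresh run
#'
#' Re-runs the scenario named in the trace's meta record (from the same
#' knowledge base and seed) and compares the stored records with the fresh
#' ones, record by record, on their canonical JSON form. A divergence
#' aborts with a report naming the first differing record; a truncated
#' trace is flagged incomplete without error.
#'
#' @param path trace path
#' @param kb_path knowledge-base path for scenario `"mi"`; ignored for
#'   `"wcst"`
#' @return list `(ok, n_compared, incomplete, scenario)`
#' @export
replay <- function(path, kb_path = NULL) {
  tr <- read_trace(path)
  meta <- tr$meta
  fresh <- switch(meta$scenario,
    mi = {
      fx <- build_mi_fixture(kb_path %||%
                               system.file("extdata", "mi.yaml",
                                           package = "dominoagent"))
      run <- run_network(fx$agents, fx$presentations, seed = meta$seed)
      run$trace
    },
    wcst = {
      lg <- run_wcst(lesion = do.call(lesion_config,
                                      as.list(meta$lesion)),
                     n_trials = meta$n_trials,
                     switch_after = meta$switch_after, seed = meta$seed)
      wcst_trace_records(lg)
    },
    stop("replay: unknown scenario '", meta$scenario, "'")
  )
  # normalise both sides through a JSON round-trip so list/vector
  # representation differences do not mask true divergence
  norm <- function(r) {
    canonical_json(jsonlite::fromJSON(canonical_json(r),
                                      simplifyVector = TRUE))
  }
  stored <- vapply(tr$records, norm, character(1))
  fresh_js <- vapply(fresh, norm, character(1))
  n <- min(length(stored), length(fresh_js))
  for (i in seq_len(n)) {
    if (!identical(stored[i], fresh_js[i])) {
      stop("replay divergence at record ", i, ":\n  stored: ", stored[i],
           "\n  fresh:  ", fresh_js[i])
    }
  }
  incomplete <- length(stored) < length(fresh_js)
  list(ok = TRUE, n_compared = n, incomplete = incomplete,
       scenario = meta$scenario)
}

#' Summarize a trace
#'
#' Prints decision endpoints (final commitments), argument counts, and --
#' for card-sorting traces -- the error-category counts.
#'
#' @param x a trace path, a `network_run`, or a `wcst_trace`
#' @return invisibly, a list of summary figures
#' @export
summarize_trace <- function(x) {
  if (is.character(x)) {
    tr <- read_trace(x)
    recs <- tr$records
    if (identical(tr$meta$scenario, "wcst")) {
      rows <- lapply(recs, function(r) {
        info <- r$info
        data.frame(trial = r$cycle, number = as.integer(info$number),
                   shape = info$shape, color = info$color,
                   criterion = info$criterion,
                   prev_criterion = info$prev_criterion %||% NA_character_,
                   rule = info$rule %||% NA_character_,
                   placement = as.integer(info$placement),
                   expected_positive = isTRUE(info$expected_positive),
                   feedback = info$feedback,
                   violation = isTRUE(info$violation),
                   forgot = isTRUE(info$forgot),
                   switched = isTRUE(info$switched),
                   n_live_before = as.integer(info$n_live_before),
                   stringsAsFactors = FALSE)
      })
      lg <- structure(list(trials = do.call(rbind, rows),
                           n_switches = sum(vapply(rows, function(r) {
                             r$switched
                           }, logical(1))),
                           config = list()),
                      class = "wcst_trace")
      return(summarize_trace(lg))
    }
    canons <- vapply(recs, function(r) r$canon %||% "", character(1))
    commits <- Filter(function(r) identical(r$canon, "s6"), recs)
    for (cm in commits) {
      cat("commitment:", cm$agent, "->", cm$info$candidate,
          paste0("(", cm$info$firmness, ")"), "\n")
    }
    cat("records:", length(recs), "| s4 firings:", sum(canons == "s4"), "\n")
    return(invisible(list(records = length(recs),
                          commitments = length(commits))))
  }
  if (inherits(x, "wcst_trace")) {
    counts <- classify_errors(x)
    cat("wcst:", nrow(x$trials), "trials,", x$n_switches, "switches;",
        "errors:", sum(x$trials$feedback == "negative"),
        "(perseverative", counts$perseverative,
        ", set-loss", counts$set_loss, ", other", counts$other, ")\n")
    return(invisible(counts))
  }
  if (inherits(x, "network_run")) {
    out <- list()
    for (ag in x$agents) {
      for (dec in ag$decisions) {
        cat(ag$id, "decided", dec$goal, "->", dec$preference[1],
            paste0("(", dec$firmness, ")"), "\n")
        out[[length(out) + 1L]] <- list(agent = ag$id, goal = dec$goal,
                                        choice = dec$preference[1],
                                        firmness = dec$firmness)
      }
    }
    cat("messages:", length(x$messages), "| rounds:", x$rounds, "\n")
    return(invisible(out))
  }
  stop("summarize_trace: unsupported input")
}
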