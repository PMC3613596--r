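#' Construct an inter-agent message
#'
#' Messages are performative-typed communication acts in the tradition of
#' speech-act based agent communication languages. Sequence numbers are
#' assigned per dialog by the switchboard at send time and are strictly
#' increasing.
#'
#' @param sender,receiver agent ids (must differ)
#' @param performative one of `"inform"`, `"request"`, `"query"`,
#'   `"explain"`, `"instruct"`, `"challenge"`, `"accept"`, `"reject"`
#' @param content message payload (a list with a `type` field)
#' @param dialog dialog id (`"<initiator>:<counter>"`); one dialog per
#'   consultation goal
#' @return a `message` object
#' @export
message_new <- function(sender, receiver, performative, content = list(),
                        dialog = NULL) {
  performative <- match.arg(performative,
                            c("inform", "request", "query", "explain",
                              "instruct", "challenge", "accept", "reject"))
  if (identical(sender, receiver)) {
    stop("message rejected: sender and receiver are the same agent ('",
         sender, "')")
  }
  structure(list(sender = sender, receiver = receiver,
                 performative = performative, content = content,
                 dialog = dialog %||% "adhoc", seq = NA_integer_),
            class = "message")
}

#' Create a switchboard
#'
#' The switchboard routes messages between registered agents: sends append
#' to a first-in-first-out pending queue, and [dispatch()] delivers every
#' queued message exactly once, in send order, recording each delivery in
#' the log.
#'
#' @return a `switchboard` environment
#' @export
switchboard_new <- function() {
  sb <- new.env(parent = emptyenv())
  sb$agents <- list()
  sb$queue <- list()
  sb$log <- list()
  sb$seqs <- list()
  sb$sent <- 0L
  sb$delivered <- 0L
  class(sb) <- "switchboard"
  sb
}

#' Register an agent with a switchboard
#' @param sb a switchboard
#' @param agent an agent
#' @return invisibly, the agent id
#' @export
register_agent <- function(sb, agent) {
  sb$agents[[agent$id]] <- agent
  invisible(agent$id)
}

#' Queue a message for delivery
#'
#' @param sb a switchboard
#' @param msg a [message_new()] message; the receiver must be registered
#' @return invisibly, the message with its dialog sequence number assigned
#' @export
send <- function(sb, msg) {
  stopifnot(inherits(msg, "message"))
  if (is.null(sb$agents[[msg$receiver]])) {
    stop("send: receiver '", msg$receiver, "' is not registered")
  }
  seq <- (sb$seqs[[msg$dialog]] %||% 0L) + 1L
  sb$seqs[[msg$dialog]] <- seq
  msg$seq <- seq
  sb$queue[[length(sb$queue) + 1L]] <- msg
  sb$sent <- sb$sent + 1L
  invisible(msg)
}

#' Deliver all queued messages (FIFO)
#'
#' Each delivery is logged and handed to the receiver through
#' [handle_message()], which asserts a communication-justified observation
#' of the message in the receiver's memory and produces any protocol
#' responses (which are queued for the *next* dispatch round).
#'
#' @param sb a switchboard
#' @param round round number recorded in the log
#' @return number of messages delivered this round
#' @export
dispatch <- function(sb, round = NA_integer_) {
  batch <- sb$queue
  sb$queue <- list()
  for (msg in batch) {
    sb$delivered <- sb$delivered + 1L
    sb$log[[length(sb$log) + 1L]] <-
      list(round = round, sender = msg$sender, receiver = msg$receiver,
           performative = msg$performative,
           content_type = msg$content$type %||% "",
           dialog = msg$dialog, seq = msg$seq)
    handle_message(sb$agents[[msg$receiver]], msg, sb)
  }
  length(batch)
}

ser_argument <- function(a) {
  list(candidate = a$candidate, polarity = a$polarity, schema = a$schema,
       strength = a$strength,
       grounds = a$grounds[setdiff(names(a$grounds), "support")])
}

#' Handle a delivered message
#'
#' Implements the inform/challenge/explain consultation protocol plus the
#' records-agent case service:
#' \itemize{
#'   \item `request(open_dialog)` is answered with `accept`;
#'   \item `request(confirm)` triggers the receiver's full decision
#'     pipeline on the referenced goal (querying the records agent for case
#'     facts first if it has a case source and has not yet asked), after
#'     which it `inform`s the requester of its own preference;
#'   \item `challenge` is answered with `explain`, carrying the receiver's
#'     undefeated argument set for its preference;
#'   \item `explain` feeds [incorporate_explanation()];
#'   \item `inform(case_facts)` asserts the facts with communication
#'     justification; `inform(preference)` is compared with the receiver's
#'     own preference -- conflicting advice is challenged, concurring
#'     advice closes the consultation;
#'   \item `query`/`request(case_query)` on a records-role agent is
#'     answered from its case table.
#' }
#' Unknown performative content is answered with `reject`.
#'
#' @param agent the receiving agent
#' @param msg the delivered message
#' @param sb the switchboard (for responses)
#' @return invisibly, `NULL`
#' @export
handle_message <- function(agent, msg, sb) {
  perf <- msg$performative
  ctype <- msg$content$type %||% ""
  if ("records" %in% agent$roles) {
    if (perf %in% c("query", "request") && ctype %in% c("case_query", "")) {
      facts <- case_facts(agent, msg$content$attrs)
      send(sb, message_new(agent$id, msg$sender, "inform",
                           list(type = "case_facts", facts = facts),
                           dialog = msg$dialog))
    }
    return(invisible(NULL))
  }
  switch(paste(perf, ctype, sep = "/"),
    "request/open_dialog" = {
      agent$dialogs[[msg$dialog]] <-
        list(state = "open", peer = msg$sender, role = "responder")
      send(sb, message_new(agent$id, msg$sender, "accept",
                           list(type = "open_dialog"), dialog = msg$dialog))
    },
    "accept/open_dialog" = {
      dlg <- agent$dialogs[[msg$dialog]]
      if (!is.null(dlg) && dlg$state == "opening") {
        dlg$state <- "open"
        agent$dialogs[[msg$dialog]] <- dlg
        dialog_send_confirm(agent, msg$dialog, sb)
      }
    },
    "request/confirm" = respond_to_confirm(agent, msg, sb),
    "inform/case_facts" = {
      atoms <- lapply(msg$content$facts, function(f) {
        a <- atom(f$attr %||% f[[1]], f$value %||% f[[2]])
        attr(a, "source") <- "message"
        a
      })
      s1_maintain_beliefs(agent, atoms)
      s9_monitor(agent, atoms)
      resume_pending_confirm(agent, sb)
    },
    "inform/preference" = receive_advice(agent, msg, sb),
    "challenge/" = ,
    "challenge/preference" = respond_to_challenge(agent, msg, sb),
    "explain/arguments" = {
      incorporate_explanation(agent, msg$content$arguments,
                              msg$content$goal, sb)
      dlg <- agent$dialogs[[msg$dialog]]
      if (!is.null(dlg)) {
        dlg$state <- "closed"
        agent$dialogs[[msg$dialog]] <- dlg
      }
    },
    "reject/" = NULL,
    {
      send(sb, message_new(agent$id, msg$sender, "reject",
                           list(type = "unknown_performative",
                                received = perf),
                           dialog = msg$dialog))
    }
  )
  invisible(NULL)
}

case_facts <- function(agent, attrs = NULL) {
  facts <- agent$case %||% list()
  out <- list()
  for (attr in names(facts)) {
    if (!is.null(attrs) && !attr %in% attrs) next
    out[[length(out) + 1L]] <- list(attr = attr,
                                    value = as.character(facts[[attr]]))
  }
  out
}

# S receives request(confirm, goal, candidate): raise the goal, gather case
# facts if a records source exists, run the decision pipeline, reply.
respond_to_confirm <- function(agent, msg, sb) {
  tmpl <- msg$content$goal
  agent$pending$confirm <- list(dialog = msg$dialog, peer = msg$sender,
                                goal = tmpl,
                                proposed = msg$content$candidate)
  if (is.null(goal_item_for(agent, tmpl))) {
    g <- agent$onto$goals[[tmpl]]
    if (is.null(g)) {
      send(sb, message_new(agent$id, msg$sender, "reject",
                           list(type = "unknown_goal", goal = tmpl),
                           dialog = msg$dialog))
      agent$pending$confirm <- NULL
      return(invisible(NULL))
    }
    wm_assert(agent$wm, "goal",
              list(template = tmpl, condition = g$condition, parent = NULL,
                   priority = g$priority, stakes = g$stakes, mode = g$mode,
                   accept_attr = g$accept_attr, consult = NULL,
                   status = "active"),
              justification("communication", goal = tmpl))
  }
  rec_src <- records_source(sb, agent)
  if (!is.null(rec_src) && !isTRUE(agent$pending$case_requested)) {
    agent$pending$case_requested <- TRUE
    send(sb, message_new(agent$id, rec_src, "request",
                         list(type = "case_query"), dialog = msg$dialog))
    return(invisible(NULL))
  }
  finish_confirm(agent, sb)
}

records_source <- function(sb, agent) {
  for (other in sb$agents) {
    if ("records" %in% other$roles && other$id != agent$id) return(other$id)
  }
  NULL
}

resume_pending_confirm <- function(agent, sb) {
  if (!is.null(agent$pending$confirm)) finish_confirm(agent, sb)
}

finish_confirm <- function(agent, sb) {
  pc <- agent$pending$confirm
  agent$pending$confirm <- NULL
  git <- goal_item_for(agent, pc$goal)
  decide(agent, git)
  dec <- agent$decisions[[as.character(git$id)]]
  send(sb, message_new(agent$id, pc$peer, "inform",
                       list(type = "preference", goal = pc$goal,
                            candidate = dec$preference[1],
                            proposed = pc$proposed),
                       dialog = pc$dialog))
}

# C receives advice: challenge on conflict with its own preference,
# otherwise close the consultation.
receive_advice <- function(agent, msg, sb) {
  tmpl <- msg$content$goal
  advice <- msg$content$candidate
  own <- own_preference(agent, tmpl)
  if (!is.null(own) && !identical(own, advice)) {
    send(sb, message_new(agent$id, msg$sender, "challenge",
                         list(type = "preference", goal = tmpl,
                              candidate = advice),
                         dialog = msg$dialog))
  } else {
    close_consultation(agent, tmpl)
  }
}

own_preference <- function(agent, tmpl) {
  for (dec in agent$decisions) {
    if (identical(dec$goal, tmpl)) return(dec$preference[1])
  }
  NULL
}

respond_to_challenge <- function(agent, msg, sb) {
  tmpl <- msg$content$goal
  dec <- NULL
  for (d in agent$decisions) if (identical(d$goal, tmpl)) dec <- d
  if (is.null(dec)) {
    send(sb, message_new(agent$id, msg$sender, "reject",
                         list(type = "no_rationale", goal = tmpl),
                         dialog = msg$dialog))
    return(invisible(NULL))
  }
  undefeated <- Filter(function(a) {
    !a$defeated && a$target_type == "candidate"
  }, dec$arguments)
  send(sb, message_new(agent$id, msg$sender, "explain",
                       list(type = "arguments", goal = tmpl,
                            arguments = lapply(undefeated, ser_argument)),
                       dialog = msg$dialog))
}

#' Incorporate a communicated explanation into an open decision
#'
#' Asserts the received arguments (those referencing candidates of the
#' receiver's open decision; others are held pending) with communication
#' justification, closes the consultation, and re-runs defeat resolution
#' and aggregation over the merged argument set -- possibly changing the
#' preference, exactly as if the arguments had been constructed locally.
#'
#' @param agent the receiving agent
#' @param arguments list of serialized arguments (`candidate`, `polarity`,
#'   `schema`, `strength`, `grounds`)
#' @param template the goal template of the decision they bear on
#' @param sb switchboard (unused; present for handler symmetry)
#' @return the updated decision record (invisibly `NULL` when no open
#'   decision matches)
#' @export
incorporate_explanation <- function(agent, arguments, template, sb = NULL) {
  git <- goal_item_for(agent, template)
  if (is.null(git)) return(invisible(NULL))
  dec <- agent$decisions[[as.character(git$id)]]
  known <- if (is.null(dec)) character(0) else
    vapply(dec$candidates, `[[`, character(1), "id")
  for (a in arguments) {
    if (!a$candidate %in% known) {
      agent$pending$held_args <- c(agent$pending$held_args, list(a))
      next
    }
    wm_assert(agent$wm, "argument",
              list(goal = template, candidate = a$candidate,
                   polarity = a$polarity, schema = a$schema,
                   strength = a$strength, grounds = a$grounds),
              justification("communication", schema = a$schema,
                            goal = template))
  }
  close_consultation(agent, template)
  if (is.null(dec)) return(invisible(NULL))
  decide(agent, git)
  agent$decisions[[as.character(git$id)]]
}

close_consultation <- function(agent, template) {
  agent$consulted <- union(agent$consulted, template)
  a <- atom("consulted", template)
  attr(a, "source") <- "message"
  s1_maintain_beliefs(agent, list(a))
  cg <- goal_item_for(agent, paste0("consult:", template))
  if (!is.null(cg)) {
    check_goal_termination(agent$wm, agent$onto)
  }
  invisible(NULL)
}

# Initiate consultations for active consultation goals without a dialog.
progress_dialogs <- function(agent, sb) {
  for (it in active_goal_items(agent)) {
    g <- it$content
    if (is.null(g$consult_target)) next
    if (identical(g$consult_target, agent$id)) next
    open <- any(vapply(agent$dialogs, function(d) {
      identical(d$about, g$about)
    }, logical(1)))
    if (open) next
    did <- paste0(agent$id, ":", length(agent$dialogs) + 1L)
    agent$dialogs[[did]] <- list(state = "opening", peer = g$consult_target,
                                 role = "initiator", about = g$about)
    send(sb, message_new(agent$id, g$consult_target, "request",
                         list(type = "open_dialog", goal = g$about),
                         dialog = did))
  }
  invisible(NULL)
}

dialog_send_confirm <- function(agent, dialog_id, sb) {
  dlg <- agent$dialogs[[dialog_id]]
  own <- own_preference(agent, dlg$about)
  send(sb, message_new(agent$id, dlg$peer, "request",
                       list(type = "confirm", goal = dlg$about,
                            candidate = own),
                       dialog = dialog_id))
  dlg$state <- "confirm_sent"
  agent$dialogs[[dialog_id]] <- dlg
}

#' Run a multi-agent network to quiescence
#'
#' Rounds of (each agent, in registration order: one decision cycle step,
#' then dialog progression) followed by message dispatch, until a round
#' does nothing (no items produced, no messages delivered) or `max_rounds`
#' is exhausted. Registration order serializes the concurrent polling of a
#' production-system implementation without changing the outcome at
#' quiescence; with a fixed knowledge base, case, and seed the combined
#' trace is identical across runs.
#'
#' @param agents list of agents; the first is registered first
#' @param presentations list of initial messages, each
#'   `list(from, to, facts = list(list(attr, value), ...))` -- the case
#'   presentation a records agent pushes to the lead agent in round 1
#' @param max_rounds round budget
#' @param seed integer seed for all random choices in the run
#' @return a `network_run` list: `agents`, `switchboard`, `trace` (merged
#'   agent traces), `messages` (delivery log), `rounds`, `complete`
#' @export
run_network <- function(agents, presentations = list(), max_rounds = 30L,
                        seed = 1L) {
  set.seed(as.integer(seed))
  sb <- switchboard_new()
  for (ag in agents) register_agent(sb, ag)
  for (p in presentations) {
    send(sb, message_new(p$from, p$to, "inform",
                         list(type = "case_facts", facts = p$facts),
                         dialog = paste0(p$from, ":case")))
  }
  rounds <- 0L
  complete <- TRUE
  repeat {
    rounds <- rounds + 1L
    before_ids <- vapply(agents, function(a) a$wm$next_id, integer(1))
    for (ag in agents) {
      if ("records" %in% ag$roles) next
      ag$wm$clock <- ag$wm$clock + 1L
      agent_step(ag, list(), environment = NULL, switchboard = sb)
      progress_dialogs(ag, sb)
    }
    delivered <- dispatch(sb, round = rounds)
    produced <- any(vapply(agents, function(a) a$wm$next_id, integer(1)) >
                      before_ids)
    if (!delivered && !produced && length(sb$queue) == 0L) break
    if (rounds >= max_rounds) {
      complete <- length(sb$queue) == 0L
      break
    }
  }
  trace <- list()
  for (ag in agents) trace <- c(trace, ag$trace)
  structure(list(agents = stats::setNames(agents,
                                          vapply(agents, `[[`, character(1),
                                                 "id")),
                 switchboard = sb, trace = trace, messages = sb$log,
                 rounds = rounds, complete = complete),
            class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  cat("<network run>", length(x$agents), "agents,", x$rounds, "rounds,",
      length(x$messages), "messages",
      if (!x$complete) "(incomplete)" else "", "\n")
  invisible(x)
}
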