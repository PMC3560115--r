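## The process-event provenance taxonomy.
##
## A process is an ordered hierarchical container of sub-processes and
## events; an event is an atomic leaf operation (an acquisition, an analysis
## step, an administrative action) carrying data instances. Processes and
## events form a forest; children order is the sequential order of the
## activity. The standard clinical-experiment hierarchy maps onto it: visits
## and studies are processes (father-son), episodes and acquisitions collapse
## into events, while project and subject are context, not tree nodes.

#' Register a process or event type
#'
#' Custom process-event types and their permitted nesting describe the
#' taxonomy fitting the application.
#'
#' @param store a store handle.
#' @param type_name unique type name.
#' @param description free text.
#' @param allowed_children for process types: character vector of child type
#'   names permitted under this type; empty means any.
#' @return the type name, invisibly.
#' @export
register_process_type <- function(store, type_name, description = "",
                                  allowed_children = character()) {
  invisible(store_txn(store, function(tabs) {
    if (tolower(type_name) %in% tolower(tabs$process_types$type_name)) {
      xr_abort(paste0("process type '", type_name, "' already registered"),
               "xr_conflict_error")
    }
    tabs$process_types <- bind_rows(tabs$process_types, tibble(
      type_name = type_name, description = description,
      allowed_children = paste(allowed_children, collapse = ",")
    ))
    list(tables = tabs, value = invisible(type_name))
  }))
}

#' @rdname register_process_type
#' @export
register_event_type <- function(store, type_name, description = "") {
  invisible(store_txn(store, function(tabs) {
    if (tolower(type_name) %in% tolower(tabs$event_types$type_name)) {
      xr_abort(paste0("event type '", type_name, "' already registered"),
               "xr_conflict_error")
    }
    tabs$event_types <- bind_rows(tabs$event_types, tibble(
      type_name = type_name, description = description
    ))
    list(tables = tabs, value = invisible(type_name))
  }))
}

allowed_children_of <- function(tabs, type_name) {
  row <- tabs$process_types[
    tolower(tabs$process_types$type_name) == tolower(type_name), , drop = FALSE
  ]
  if (!nrow(row)) {
    return(NULL)
  }
  ac <- row$allowed_children[1]
  if (!nzchar(ac)) character() else strsplit(ac, ",", fixed = TRUE)[[1]]
}

next_child_seq <- function(tabs, parent_id) {
  pid <- if (is.na(parent_id[1])) NA_character_ else parent_id
  same <- function(col) if (is.na(pid)) is.na(col) else (!is.na(col) & col == pid)
  max(0L,
      tabs$processes$seq[same(tabs$processes$parent_id)],
      tabs$events$seq[same(tabs$events$process_id)]) + 1L
}

#' Create a process
#'
#' Appends a process under `parent` (or as a new root). The parent's type may
#' restrict permitted child types; an empty restriction list means any.
#'
#' @param store a store handle.
#' @param type_name a registered process type.
#' @param label display label.
#' @param parent optional parent process id.
#' @param subject_id optional owning subject.
#' @param started_at,ended_at optional ISO-8601 timestamps.
#' @return the new process id.
#' @export
create_process <- function(store, type_name, label, parent = NULL,
                           subject_id = NA, started_at = NA, ended_at = NA) {
  store_txn(store, function(tabs) {
    if (is.null(allowed_children_of(tabs, type_name))) {
      xr_abort(paste0("unknown process type '", type_name, "'"), "xr_taxonomy_error")
    }
    parent_id <- NA_character_
    if (!is.null(parent)) {
      prow <- tabs$processes[tabs$processes$process_id == parent, , drop = FALSE]
      if (!nrow(prow)) {
        xr_abort(paste0("unknown parent process '", parent, "'"), "xr_not_found_error")
      }
      allowed <- allowed_children_of(tabs, prow$type[1])
      if (length(allowed) && !tolower(type_name) %in% tolower(allowed)) {
        xr_abort(
          paste0("type '", type_name, "' is not an allowed child of '",
                 prow$type[1], "'"),
          "xr_taxonomy_error"
        )
      }
      parent_id <- parent
    }
    pid <- next_id(store, "process", "P")
    tabs$processes <- bind_rows(tabs$processes, tibble(
      process_id = pid, type = type_name, label = label,
      subject_id = if (is.na(subject_id[1])) NA_character_ else subject_id,
      parent_id = parent_id, seq = next_child_seq(tabs, parent_id),
      started_at = if (is.na(started_at[1])) NA_character_ else started_at,
      ended_at = if (is.na(ended_at[1])) NA_character_ else ended_at
    ))
    list(tables = tabs, value = pid)
  })
}

#' Add an event to a process
#'
#' Events are appended in sequence order; each event belongs to exactly one
#' process. An empty data list is valid (administrative events).
#'
#' @param store a store handle.
#' @param process_id the owning process.
#' @param type_name a registered event type.
#' @param occurred_at ISO-8601 timestamp.
#' @param data character vector of instance ids the event carries.
#' @param note optional free text.
#' @return the new event id.
#' @export
add_event <- function(store, process_id, type_name, occurred_at = NA,
                      data = character(), note = NA) {
  store_txn(store, function(tabs) {
    if (!process_id %in% tabs$processes$process_id) {
      xr_abort(paste0("unknown process '", process_id, "'"), "xr_not_found_error")
    }
    if (!tolower(type_name) %in% tolower(tabs$event_types$type_name)) {
      xr_abort(paste0("unknown event type '", type_name, "'"), "xr_taxonomy_error")
    }
    dangling <- setdiff(data, tabs$instances$instance_id)
    if (length(dangling)) {
      xr_abort(paste0("dangling data reference(s): ",
                      paste(dangling, collapse = ", ")), "xr_integrity_error")
    }
    eid <- next_id(store, "event", "E")
    tabs$events <- bind_rows(tabs$events, tibble(
      event_id = eid, type = type_name, process_id = process_id,
      seq = next_child_seq(tabs, process_id),
      occurred_at = if (is.na(occurred_at[1])) NA_character_ else occurred_at,
      note = if (is.na(note[1])) NA_character_ else note
    ))
    if (length(data)) {
      tabs$event_data <- bind_rows(tabs$event_data, tibble(
        event_id = eid, instance_id = data
      ))
      # back-link instances to their event, in both representations: the
      # table column and the canonical XML document must stay in agreement
      for (iid in data) {
        idx <- which(tabs$instances$instance_id == iid)
        tabs$instances$event_id[idx] <- eid
        doc <- xml2::read_xml(tabs$instances$xml[idx])
        xml2::xml_set_attr(doc, "event", eid)
        tabs$instances$xml[idx] <- as.character(doc)
      }
    }
    list(tables = tabs, value = eid)
  })
}

#' Timeline of a process
#'
#' Depth-first, sequence-order traversal of the process subtree collecting
#' every descendant event: within a process, children (sub-processes and
#' events interleaved) are visited in insertion order. This is the structural
#' order of performed operations; `occurred_at` is reported alongside for
#' callers who prefer chronological sorting.
#'
#' @param store a store handle.
#' @param process_id the root of the subtree.
#' @return a tibble `event_id`, `type`, `process_id`, `occurred_at`, `note`,
#'   `depth`, in timeline order.
#' @export
timeline <- function(store, process_id) {
  tabs <- store$tables
  if (!process_id %in% tabs$processes$process_id) {
    xr_abort(paste0("unknown process '", process_id, "'"), "xr_not_found_error")
  }
  out <- list()
  walk <- function(pid, depth) {
    kids <- bind_rows(
      tabs$processes[!is.na(tabs$processes$parent_id) &
        tabs$processes$parent_id == pid,
        c("process_id", "seq"), drop = FALSE
      ] |> mutate(kind = "process"),
      tabs$events[tabs$events$process_id == pid, c("event_id", "seq"),
                  drop = FALSE] |> mutate(kind = "event")
    )
    kids <- kids[order(kids$seq), , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      if (kids$kind[i] == "event") {
        ev <- tabs$events[tabs$events$event_id == kids$event_id[i], , drop = FALSE]
        out[[length(out) + 1L]] <<- tibble(
          event_id = ev$event_id, type = ev$type, process_id = ev$process_id,
          occurred_at = ev$occurred_at, note = ev$note, depth = depth
        )
      } else {
        walk(kids$process_id[i], depth + 1L)
      }
    }
  }
  walk(process_id, 1L)
  if (length(out)) {
    bind_rows(out)
  } else {
    tibble(event_id = character(), type = character(), process_id = character(),
           occurred_at = character(), note = character(), depth = integer())
  }
}

#' Map a clinical-experiment hierarchy level to a taxonomy node kind
#'
#' The standard experiment-exchange hierarchy (project, subject, visit,
#' study, episode, acquisition) maps onto the process-event model: visits and
#' studies become processes (study under visit), episodes and acquisitions
#' collapse into events, and project/subject are contextual, not tree nodes.
#'
#' @param level one of `"project"`, `"subject"`, `"visit"`, `"study"`,
#'   `"episode"`, `"acquisition"`.
#' @return `"process"`, `"event"` or `"context"`.
#' @export
xcede_level_kind <- function(level) {
  mapping <- c(
    project = "context", subject = "context", visit = "process",
    study = "process", episode = "event", acquisition = "event"
  )
  if (!is.character(level) || length(level) != 1L || !level %in% names(mapping)) {
    xr_abort(paste0("unknown hierarchy level '", level, "'"), "xr_usage_error")
  }
  unname(mapping[[level]])
}

#' Render a process subtree as an indented text outline
#'
#' @param store a store handle.
#' @param process_id root process.
#' @return character vector of outline lines.
#' @export
process_outline <- function(store, process_id) {
  tabs <- store$tables
  lines <- character()
  walk <- function(pid, indent) {
    p <- tabs$processes[tabs$processes$process_id == pid, , drop = FALSE]
    lines <<- c(lines, paste0(strrep("  ", indent), "+ [", p$type, "] ", p$label,
                              " (", pid, ")"))
    kids <- bind_rows(
      tabs$processes[!is.na(tabs$processes$parent_id) &
        tabs$processes$parent_id == pid, c("process_id", "seq")] |>
        mutate(kind = "process"),
      tabs$events[tabs$events$process_id == pid, c("event_id", "seq")] |>
        mutate(kind = "event")
    )
    kids <- kids[order(kids$seq), , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      if (kids$kind[i] == "event") {
        ev <- tabs$events[tabs$events$event_id == kids$event_id[i], , drop = FALSE]
        lines <<- c(lines, paste0(strrep("  ", indent + 1L), "- [", ev$type, "] ",
                                  ev$event_id,
                                  if (!is.na(ev$occurred_at)) paste0(" @ ", ev$occurred_at) else ""))
      } else {
        walk(kids$process_id[i], indent + 1L)
      }
    }
  }
  walk(process_id, 0L)
  lines
}
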