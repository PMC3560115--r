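## Biosample freezer inventory.
##
## A freezer bench (-80C or -45C) holds racks; each rack holds numbered
## slots; each slot holds one sample box with an x-y grid. A sample is
## located at one (freezer, rack, slot, x, y) coordinate, occupied by at most
## one sample at a time, and carries an append-only history: registration,
## placements, moves and courier shipments. Shipment clears the location (in
## transit) and records the courier mailing number, matching a
## multi-centre workflow with independent freezers at each site.

TEMPERATURE_CLASSES <- c("-80C", "-45C")
SAMPLE_MATERIALS <- c("blood", "DNA", "RNA", "other")

#' Describe a freezer layout
#'
#' @param freezer_id unique freezer identifier.
#' @param temperature_class `"-80C"` or `"-45C"`.
#' @param racks named integer vector: rack id -> slot count (each >= 1).
#' @param box_grid `c(columns, rows)` of the sample box in every slot.
#' @return an `xr_freezer_layout`.
#' @export
freezer_layout <- function(freezer_id, temperature_class, racks, box_grid) {
  if (!temperature_class %in% TEMPERATURE_CLASSES) {
    xr_abort(paste0("temperature_class must be one of: ",
                    paste(TEMPERATURE_CLASSES, collapse = ", ")),
             "xr_structural_error")
  }
  racks <- setNames(as.integer(racks), names(racks))
  if (length(racks) < 1L || is.null(names(racks)) || any(!nzchar(names(racks)))) {
    xr_abort("racks must be a named vector of slot counts", "xr_structural_error")
  }
  if (any(racks < 1L)) {
    xr_abort("every rack needs at least one slot", "xr_structural_error")
  }
  box_grid <- as.integer(box_grid)
  if (length(box_grid) != 2L || any(box_grid < 1L)) {
    xr_abort("box_grid must be c(columns, rows), both >= 1", "xr_structural_error")
  }
  structure(
    list(freezer_id = freezer_id, temperature_class = temperature_class,
         racks = racks, box_grid = box_grid),
    class = "xr_freezer_layout"
  )
}

#' Capacity of a freezer layout
#'
#' Total sample positions: sum over racks of slots x columns x rows.
#'
#' @param layout an `xr_freezer_layout`.
#' @return an integer.
#' @export
freezer_capacity <- function(layout) {
  as.integer(sum(layout$racks) * layout$box_grid[1] * layout$box_grid[2])
}

layout_to_json <- function(layout) {
  jsonlite::toJSON(
    list(racks = as.list(layout$racks), box_grid = layout$box_grid),
    auto_unbox = TRUE
  )
}

layout_from_row <- function(row) {
  spec <- jsonlite::fromJSON(row$layout[1])
  freezer_layout(row$freezer_id[1], row$temperature_class[1],
                 unlist(spec$racks), spec$box_grid)
}

#' Read a freezer layout from a YAML or JSON config file
#'
#' Expected keys: `freezer_id`, `temperature_class`, `racks` (mapping
#' rack id -> slots), `box_grid` (two integers).
#'
#' @param path config file path; format chosen by extension
#'   (`.yml`/`.yaml` vs `.json`).
#' @return an `xr_freezer_layout`.
#' @export
read_freezer_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  freezer_layout(cfg$freezer_id, cfg$temperature_class, unlist(cfg$racks),
                 unlist(cfg$box_grid))
}

#' Configure a freezer
#'
#' Reconfiguration (`replace = TRUE`) is rejected when any located sample
#' would fall outside the new bounds.
#'
#' @param store a store handle.
#' @param layout an [freezer_layout()].
#' @param replace allow replacing an existing configuration.
#' @return the freezer id, invisibly.
#' @export
configure_freezer <- function(store, layout, replace = FALSE) {
  stopifnot(inherits(layout, "xr_freezer_layout"))
  invisible(store_txn(store, function(tabs) {
    exists <- layout$freezer_id %in% tabs$freezers$freezer_id
    if (exists && !replace) {
      xr_abort(paste0("freezer '", layout$freezer_id, "' already configured"),
               "xr_conflict_error")
    }
    if (exists) {
      located <- tabs$samples[tabs$samples$status == "located" &
        tabs$samples$freezer_id == layout$freezer_id, , drop = FALSE]
      for (i in seq_len(nrow(located))) {
        if (!coordinate_in_bounds(layout, located$rack_id[i], located$slot[i],
                                  located$x[i], located$y[i])) {
          xr_abort(
            paste0("reconfiguration rejected: sample '", located$sample_id[i],
                   "' at ", located$rack_id[i], "/", located$slot[i], "/",
                   located$x[i], "x", located$y[i], " would fall out of bounds"),
            "xr_bounds_error"
          )
        }
      }
      tabs$freezers <- tabs$freezers[
        tabs$freezers$freezer_id != layout$freezer_id, , drop = FALSE
      ]
    }
    tabs$freezers <- bind_rows(tabs$freezers, tibble(
      freezer_id = layout$freezer_id,
      temperature_class = layout$temperature_class,
      layout = as.character(layout_to_json(layout))
    ))
    tabs <- log_op(tabs, store, "freezer.configure", layout$freezer_id)
    list(tables = tabs, value = invisible(layout$freezer_id))
  }))
}

coordinate_in_bounds <- function(layout, rack_id, slot, x, y) {
  if (!rack_id %in% names(layout$racks)) {
    return(FALSE)
  }
  slot >= 1L && slot <= layout$racks[[rack_id]] &&
    x >= 1L && x <= layout$box_grid[1] && y >= 1L && y <= layout$box_grid[2]
}

now_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

#' Register a sample
#'
#' The sample starts unplaced, with a registration history entry.
#'
#' @param store a store handle.
#' @param sample_id unique sample identifier.
#' @param material `"blood"`, `"DNA"`, `"RNA"` or `"other"`.
#' @param subject_id the subject the specimen was drawn from.
#' @param timestamp ISO-8601; defaults to now.
#' @return the sample id, invisibly.
#' @export
register_sample <- function(store, sample_id, material, subject_id,
                            timestamp = NULL) {
  if (!material %in% SAMPLE_MATERIALS) {
    xr_abort(paste0("material must be one of: ",
                    paste(SAMPLE_MATERIALS, collapse = ", ")),
             "xr_structural_error")
  }
  ts <- timestamp %||% now_iso()
  invisible(store_txn(store, function(tabs) {
    if (sample_id %in% tabs$samples$sample_id) {
      xr_abort(paste0("sample '", sample_id, "' already registered"),
               "xr_conflict_error")
    }
    if (!subject_id %in% tabs$subjects$subject_id) {
      xr_abort(paste0("no subject '", subject_id, "'"), "xr_integrity_error")
    }
    tabs$samples <- bind_rows(tabs$samples, tibble(
      sample_id = sample_id, material = material, subject_id = subject_id,
      freezer_id = NA_character_, rack_id = NA_character_, slot = NA_integer_,
      x = NA_integer_, y = NA_integer_, courier_number = NA_character_,
      status = "unplaced"
    ))
    tabs <- append_history(tabs, store, sample_id, ts, "registered")
    list(tables = tabs, value = invisible(sample_id))
  }))
}

append_history <- function(tabs, store, sample_id, ts, action,
                           freezer_id = NA, rack_id = NA, slot = NA,
                           x = NA, y = NA) {
  prev <- tabs$sample_history[tabs$sample_history$sample_id == sample_id, ,
                              drop = FALSE]
  seq <- if (nrow(prev)) max(prev$seq) + 1L else 1L
  if (nrow(prev) && any(prev$timestamp > ts)) {
    xr_abort("history timestamps must be non-decreasing", "xr_usage_error")
  }
  tabs$sample_history <- bind_rows(tabs$sample_history, tibble(
    sample_id = sample_id, seq = seq, timestamp = ts, action = action,
    freezer_id = as.character(freezer_id), rack_id = as.character(rack_id),
    slot = as.integer(slot), x = as.integer(x), y = as.integer(y)
  ))
  tabs
}

slot_occupied <- function(tabs, freezer_id, rack_id, slot, x, y) {
  any(
    tabs$samples$status == "located" &
      tabs$samples$freezer_id == freezer_id &
      tabs$samples$rack_id == rack_id &
      tabs$samples$slot == slot & tabs$samples$x == x & tabs$samples$y == y,
    na.rm = TRUE
  )
}

place_or_move <- function(store, sample_id, freezer_id, rack_id, slot, x, y,
                          action, timestamp) {
  ts <- timestamp %||% now_iso()
  invisible(store_txn(store, function(tabs) {
    srow <- tabs$samples[tabs$samples$sample_id == sample_id, , drop = FALSE]
    if (!nrow(srow)) {
      xr_abort(paste0("no sample '", sample_id, "'"), "xr_not_found_error")
    }
    frow <- tabs$freezers[tabs$freezers$freezer_id == freezer_id, , drop = FALSE]
    if (!nrow(frow)) {
      xr_abort(paste0("no freezer '", freezer_id, "'"), "xr_not_found_error")
    }
    layout <- layout_from_row(frow)
    if (!coordinate_in_bounds(layout, rack_id, as.integer(slot),
                              as.integer(x), as.integer(y))) {
      xr_abort(
        sprintf("coordinate %s/%s/%dx%d is outside freezer '%s' bounds",
                rack_id, as.character(slot), as.integer(x), as.integer(y),
                freezer_id),
        "xr_bounds_error"
      )
    }
    if (slot_occupied(tabs, freezer_id, rack_id, as.integer(slot),
                      as.integer(x), as.integer(y))) {
      xr_abort(
        sprintf("coordinate %s/%s/%s/%dx%d is already occupied",
                freezer_id, rack_id, as.character(slot), as.integer(x),
                as.integer(y)),
        "xr_occupancy_error"
      )
    }
    idx <- which(tabs$samples$sample_id == sample_id)
    tabs$samples$freezer_id[idx] <- freezer_id
    tabs$samples$rack_id[idx] <- rack_id
    tabs$samples$slot[idx] <- as.integer(slot)
    tabs$samples$x[idx] <- as.integer(x)
    tabs$samples$y[idx] <- as.integer(y)
    tabs$samples$status[idx] <- "located"
    tabs <- append_history(tabs, store, sample_id, ts, action, freezer_id,
                           rack_id, slot, x, y)
    tabs <- log_op(tabs, store, paste0("sample.", action),
                   paste0(sample_id, " -> ", freezer_id, "/", rack_id, "/",
                          slot, "/", x, "x", y))
    list(tables = tabs, value = invisible(sample_id))
  }))
}

#' Place or move a sample
#'
#' The target coordinate must lie within the freezer's configured bounds and
#' be unoccupied; moving frees the previous coordinate.
#'
#' @param store a store handle.
#' @param sample_id the sample.
#' @param freezer_id,rack_id,slot,x,y target coordinate (1-based slot, column
#'   `x`, row `y`).
#' @param timestamp ISO-8601; defaults to now.
#' @return the sample id, invisibly.
#' @export
place_sample <- function(store, sample_id, freezer_id, rack_id, slot, x, y,
                         timestamp = NULL) {
  place_or_move(store, sample_id, freezer_id, rack_id, slot, x, y,
                "placed", timestamp)
}

#' @rdname place_sample
#' @export
move_sample <- function(store, sample_id, freezer_id, rack_id, slot, x, y,
                        timestamp = NULL) {
  place_or_move(store, sample_id, freezer_id, rack_id, slot, x, y,
                "moved", timestamp)
}

#' Ship a sample by courier
#'
#' Stores the courier mailing number and clears the location: the sample is
#' in transit until placed into a destination freezer.
#'
#' @param store a store handle.
#' @param sample_id the sample.
#' @param courier_number the courier tracking number.
#' @param timestamp ISO-8601; defaults to now.
#' @return the sample id, invisibly.
#' @export
register_shipment <- function(store, sample_id, courier_number,
                              timestamp = NULL) {
  ts <- timestamp %||% now_iso()
  invisible(store_txn(store, function(tabs) {
    idx <- which(tabs$samples$sample_id == sample_id)
    if (!length(idx)) {
      xr_abort(paste0("no sample '", sample_id, "'"), "xr_not_found_error")
    }
    tabs$samples$freezer_id[idx] <- NA_character_
    tabs$samples$rack_id[idx] <- NA_character_
    tabs$samples$slot[idx] <- NA_integer_
    tabs$samples$x[idx] <- NA_integer_
    tabs$samples$y[idx] <- NA_integer_
    tabs$samples$courier_number[idx] <- courier_number
    tabs$samples$status[idx] <- "shipped"
    tabs <- append_history(tabs, store, sample_id, ts, "shipped")
    tabs <- log_op(tabs, store, "sample.ship",
                   paste0(sample_id, " courier ", courier_number))
    list(tables = tabs, value = invisible(sample_id))
  }))
}

#' Locate a sample
#'
#' @param store a store handle.
#' @param sample_id the sample.
#' @return a list with `sample` (one-row tibble: current status, coordinate,
#'   courier number, subject) and `history` (tibble in timestamp order).
#' @export
locate_sample <- function(store, sample_id) {
  srow <- store$tables$samples[store$tables$samples$sample_id == sample_id, ,
                               drop = FALSE]
  if (!nrow(srow)) {
    xr_abort(paste0("no sample '", sample_id, "'"), "xr_not_found_error")
  }
  hist <- store$tables$sample_history[
    store$tables$sample_history$sample_id == sample_id, , drop = FALSE
  ]
  list(
    sample = as_tibble(srow),
    history = as_tibble(hist[order(hist$seq), , drop = FALSE])
  )
}

#' Format a coordinate in A1 style
#'
#' Numeric x-y coordinates rendered alphanumerically (row letter + column
#' number), e.g. x=3, y=2 -> `"B3"`.
#'
#' @param x 1-based column. @param y 1-based row.
#' @return character.
#' @export
format_coordinate_a1 <- function(x, y) {
  paste0(LETTERS[y], x)
}

#' Plot the occupancy map of one freezer box
#'
#' @param store a store handle.
#' @param freezer_id,rack_id,slot which box to draw.
#' @return a ggplot object: the box grid with occupied cells labelled by
#'   sample id.
#' @export
plot_freezer_map <- function(store, freezer_id, rack_id, slot) {
  frow <- store$tables$freezers[
    store$tables$freezers$freezer_id == freezer_id, , drop = FALSE
  ]
  if (!nrow(frow)) {
    xr_abort(paste0("no freezer '", freezer_id, "'"), "xr_not_found_error")
  }
  layout <- layout_from_row(frow)
  grid <- tidyr::expand_grid(
    x = seq_len(layout$box_grid[1]), y = seq_len(layout$box_grid[2])
  )
  occ <- store$tables$samples[
    store$tables$samples$status == "located" &
      store$tables$samples$freezer_id == freezer_id &
      store$tables$samples$rack_id == rack_id &
      store$tables$samples$slot == as.integer(slot),
    c("sample_id", "x", "y"),
    drop = FALSE
  ]
  grid <- left_join(grid, occ, by = c("x", "y"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = !is.na(.data$sample_id)),
                       colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id), size = 2.5,
                       na.rm = TRUE) +
    ggplot2::scale_y_reverse(breaks = seq_len(layout$box_grid[2]),
                             labels = LETTERS[seq_len(layout$box_grid[2])]) +
    ggplot2::scale_x_continuous(breaks = seq_len(layout$box_grid[1]),
                                position = "top") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "steelblue2")) +
    ggplot2::labs(
      title = sprintf("%s / %s / slot %s", freezer_id, rack_id, slot),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}
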