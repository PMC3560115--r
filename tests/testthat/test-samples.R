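sample_store <- function() {
  store <- store_open()
  save_schema(store, mri_schema())
  save_subject(store, subject("S1"))
  save_subject(store, subject("S2"))
  configure_freezer(store, freezer_layout("F1", "-80C", c(R1 = 2L), c(9L, 9L)))
  store
}

test_that("layout validation and capacity arithmetic", {
  layout <- freezer_layout("F1", "-80C", c(R1 = 2L), c(9L, 9L))
  expect_equal(freezer_capacity(layout), 162L)
  expect_equal(
    freezer_capacity(freezer_layout("F2", "-45C", c(A = 3L, B = 1L), c(10L, 8L))),
    4L * 80L
  )
  expect_error(freezer_layout("F", "-80C", c(R1 = 0L), c(9, 9)),
               class = "xr_structural_error")
  expect_error(freezer_layout("F", "-80C", c(R1 = 1L), c(0, 9)),
               class = "xr_structural_error")
  expect_error(freezer_layout("F", "-20C", c(R1 = 1L), c(9, 9)),
               class = "xr_structural_error")

  store <- sample_store()
  expect_error(
    configure_freezer(store, freezer_layout("F1", "-80C", c(R1 = 1L), c(9, 9))),
    class = "xr_conflict_error"
  )
})

test_that("placement honours bounds and occupancy; history accumulates", {
  store <- sample_store()
  register_sample(store, "B1", "blood", "S1",
                  timestamp = "2010-01-01T10:00:00.000Z")
  loc <- locate_sample(store, "B1")
  expect_equal(loc$sample$status, "unplaced")
  expect_equal(loc$history$action, "registered")

  place_sample(store, "B1", "F1", "R1", 1, 3, 4,
               timestamp = "2010-01-01T11:00:00.000Z")
  loc <- locate_sample(store, "B1")
  expect_equal(loc$sample[, c("slot", "x", "y")],
               tibble::tibble(slot = 1L, x = 3L, y = 4L))

  register_sample(store, "B2", "DNA", "S2",
                  timestamp = "2010-01-01T10:30:00.000Z")
  expect_error(place_sample(store, "B2", "F1", "R1", 1, 3, 4),
               class = "xr_occupancy_error")
  expect_error(place_sample(store, "B2", "F1", "R1", 3, 1, 1),
               class = "xr_bounds_error")
  expect_error(place_sample(store, "B2", "F1", "R9", 1, 1, 1),
               class = "xr_bounds_error")
  expect_error(place_sample(store, "B2", "F9", "R1", 1, 1, 1),
               class = "xr_not_found_error")
  expect_error(place_sample(store, "GHOST", "F1", "R1", 1, 1, 1),
               class = "xr_not_found_error")

  # move twice: place + 2 moves = 3 location entries, timestamps ordered
  move_sample(store, "B1", "F1", "R1", 1, 5, 5,
              timestamp = "2010-01-01T12:00:00.000Z")
  move_sample(store, "B1", "F1", "R1", 2, 1, 1,
              timestamp = "2010-01-01T13:00:00.000Z")
  hist <- locate_sample(store, "B1")$history
  expect_equal(hist$action, c("registered", "placed", "moved", "moved"))
  expect_true(!is.unsorted(hist$timestamp))
  # the first coordinate was freed by the move
  place_sample(store, "B2", "F1", "R1", 1, 3, 4)
  expect_equal(locate_sample(store, "B2")$sample$x, 3L)
})

test_that("shipment clears the slot and keeps the courier number", {
  store <- sample_store()
  register_sample(store, "B1", "blood", "S1",
                  timestamp = "2010-01-01T10:00:00.000Z")
  place_sample(store, "B1", "F1", "R1", 1, 1, 1,
               timestamp = "2010-01-01T11:00:00.000Z")
  register_shipment(store, "B1", "CN-00123",
                    timestamp = "2010-01-02T09:00:00.000Z")
  loc <- locate_sample(store, "B1")
  expect_equal(loc$sample$status, "shipped")
  expect_equal(loc$sample$courier_number, "CN-00123")
  expect_true(is.na(loc$sample$slot))

  # destination site places it again: place -> ship -> place
  configure_freezer(store, freezer_layout("F-TX", "-45C", c(R1 = 1L), c(9, 9)))
  place_sample(store, "B1", "F-TX", "R1", 1, 1, 1,
               timestamp = "2010-01-09T09:00:00.000Z")
  hist <- locate_sample(store, "B1")$history
  expect_equal(hist$action, c("registered", "placed", "shipped", "placed"))
  expect_error(register_shipment(store, "GHOST", "X"),
               class = "xr_not_found_error")
})

test_that("reconfiguration cannot strand located samples", {
  store <- sample_store()
  register_sample(store, "B1", "blood", "S1")
  place_sample(store, "B1", "F1", "R1", 2, 9, 9)
  expect_error(
    configure_freezer(store, freezer_layout("F1", "-80C", c(R1 = 1L), c(9, 9)),
                      replace = TRUE),
    class = "xr_bounds_error"
  )
  # shrinking the grid below an occupied coordinate is also rejected
  expect_error(
    configure_freezer(store, freezer_layout("F1", "-80C", c(R1 = 2L), c(8, 9)),
                      replace = TRUE),
    class = "xr_bounds_error"
  )
  # compatible reconfiguration is fine
  configure_freezer(store, freezer_layout("F1", "-80C", c(R1 = 3L), c(9, 9)),
                    replace = TRUE)
  expect_equal(locate_sample(store, "B1")$sample$slot, 2L)
})

test_that("random operation sequences keep occupancy injective and history monotone", {
  set.seed(616)
  store <- sample_store()
  n <- 40L
  for (i in seq_len(n)) {
    register_sample(store, sprintf("SMP-%02d", i),
                    sample(c("blood", "DNA", "RNA"), 1), "S1")
  }
  hist_len <- stats::setNames(rep(1L, n), sprintf("SMP-%02d", seq_len(n)))
  for (step in 1:300) {
    sid <- sprintf("SMP-%02d", sample(n, 1))
    op <- sample(c("place", "ship"), 1, prob = c(0.7, 0.3))
    if (op == "place") {
      coord <- list(slot = sample(2, 1), x = sample(9, 1), y = sample(9, 1))
      ok <- tryCatch(
        {
          place_sample(store, sid, "F1", "R1", coord$slot, coord$x, coord$y)
          TRUE
        },
        xr_occupancy_error = function(e) FALSE
      )
      if (ok) hist_len[sid] <- hist_len[sid] + 1L
    } else {
      register_shipment(store, sid, sprintf("CN-%03d", step))
      hist_len[sid] <- hist_len[sid] + 1L
    }
    located <- store$tables$samples[store$tables$samples$status == "located", ]
    coords <- paste(located$freezer_id, located$rack_id, located$slot,
                    located$x, located$y)
    expect_false(anyDuplicated(coords) > 0)
  }
  # conservation: every sample is located, shipped or unplaced
  expect_equal(sum(store$tables$samples$status %in%
    c("located", "shipped", "unplaced")), n)
  # history never shrank
  for (sid in names(hist_len)) {
    expect_equal(nrow(locate_sample(store, sid)$history),
                 unname(hist_len[sid]))
  }
})

test_that("coordinates format in A1 style and occupancy maps render", {
  expect_equal(format_coordinate_a1(3, 2), "B3")
  expect_equal(format_coordinate_a1(1, 1), "A1")
  store <- sample_store()
  register_sample(store, "B1", "blood", "S1")
  place_sample(store, "B1", "F1", "R1", 1, 3, 4)
  p <- plot_freezer_map(store, "F1", "R1", 1)
  expect_s3_class(p, "ggplot")
})

test_that("freezer configs load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "freezer_id: FRZ-YML",
    "temperature_class: \"-45C\"",
    "racks:",
    "  R1: 2",
    "  R2: 3",
    "box_grid: [9, 9]"
  ), path)
  layout <- read_freezer_config(path)
  expect_equal(layout$freezer_id, "FRZ-YML")
  expect_equal(freezer_capacity(layout), 5L * 81L)
})
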