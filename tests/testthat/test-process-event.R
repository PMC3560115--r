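pre_surgical_store <- function() {
  store <- store_open()
  register_process_type(store, "analysis")
  register_event_type(store, "acquisition")
  register_event_type(store, "processing")
  store
}

test_that("a pre-surgical hierarchy builds with ordered sub-processes", {
  store <- pre_surgical_store()
  root <- create_process(store, "analysis", "Pre-surgical Process")
  sps <- vapply(
    c("Data Acquisition", "Image Post-Processing", "Trajectories study",
      "Surgery Area Estimation"),
    function(l) create_process(store, "analysis", l, parent = root),
    character(1)
  )
  kids <- store$tables$processes[!is.na(store$tables$processes$parent_id), ]
  expect_equal(kids$process_id[order(kids$seq)], unname(sps))

  # events under SP1 precede events under SP2 in the timeline
  e2 <- add_event(store, sps[2], "processing", occurred_at = "2010-01-01T09:00:00Z")
  e1a <- add_event(store, sps[1], "acquisition", occurred_at = "2010-01-01T10:00:00Z")
  e1b <- add_event(store, sps[1], "acquisition", occurred_at = "2010-01-01T11:00:00Z")
  e4 <- add_event(store, sps[4], "processing")
  tl <- timeline(store, root)
  expect_equal(tl$event_id, c(e1a, e1b, e2, e4))
  # and the structural order matches the independent flat-scan oracle
  expect_equal(tl$event_id, oracle_timeline_ids(store, root))
  # empty subtree -> empty timeline
  expect_equal(nrow(timeline(store, sps[3])), 0L)
})

test_that("taxonomy restrictions and unknown types are enforced", {
  store <- store_open()
  register_process_type(store, "visit", allowed_children = "study")
  register_process_type(store, "study")
  register_process_type(store, "audit")
  register_event_type(store, "acquisition")

  v <- create_process(store, "visit", "Visit 1")
  s <- create_process(store, "study", "Study A", parent = v)
  expect_error(create_process(store, "audit", "nope", parent = v),
               class = "xr_taxonomy_error")
  expect_error(create_process(store, "ghost", "x"), class = "xr_taxonomy_error")
  expect_error(add_event(store, s, "ghost-event"), class = "xr_taxonomy_error")
  expect_error(add_event(store, "P-404", "acquisition"),
               class = "xr_not_found_error")
  expect_error(add_event(store, s, "acquisition", data = "D-404"),
               class = "xr_integrity_error")
  # events append in insertion order
  ea <- add_event(store, s, "acquisition")
  eb <- add_event(store, s, "acquisition")
  tl <- timeline(store, s)
  expect_equal(tl$event_id, c(ea, eb))
})

test_that("the hierarchy mapping sends visits/studies to processes and leaves to events", {
  expect_equal(xcede_level_kind("visit"), "process")
  expect_equal(xcede_level_kind("study"), "process")
  expect_equal(xcede_level_kind("episode"), "event")
  expect_equal(xcede_level_kind("acquisition"), "event")
  expect_equal(xcede_level_kind("project"), "context")
  expect_equal(xcede_level_kind("subject"), "context")
  expect_error(xcede_level_kind("orbit"), class = "xr_usage_error")
})

test_that("random operation sequences preserve the forest invariant", {
  set.seed(2024)
  store <- pre_surgical_store()
  roots <- c(create_process(store, "analysis", "root"))
  all_procs <- roots
  for (i in 1:200) {
    if (stats::runif(1) < 0.4) {
      parent <- if (stats::runif(1) < 0.8) sample(all_procs, 1) else NULL
      p <- create_process(store, "analysis", paste0("p", i), parent = parent)
      all_procs <- c(all_procs, p)
    } else {
      add_event(store, sample(all_procs, 1), "acquisition")
    }
  }
  procs <- store$tables$processes
  # no process is its own ancestor
  for (pid in procs$process_id) {
    seen <- character()
    cur <- pid
    while (!is.na(cur)) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- procs$parent_id[procs$process_id == cur]
    }
  }
  # every event belongs to exactly one existing process
  expect_true(all(store$tables$events$process_id %in% procs$process_id))
  # timeline length equals the subtree event count, per the flat-scan oracle
  for (r in procs$process_id[is.na(procs$parent_id)]) {
    expect_equal(timeline(store, r)$event_id, oracle_timeline_ids(store, r))
  }
})
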