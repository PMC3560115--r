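acl_store <- function() {
  store <- tiny_store()
  create_group(store, "clinicians", "clinical staff")
  create_group(store, "geneticists", "genetics lab")
  create_group(store, "admins")
  add_user(store, "alice", c("clinicians", "admins"))
  add_user(store, "bob", "geneticists")
  add_user(store, "nobody", character())
  store
}

test_that("access is default-deny and group-union", {
  store <- acl_store()
  # zero permissions: everything false
  expect_false(check_access(store, "alice", "datatype:MRI", "view"))
  expect_false(check_access(store, "nobody", "datatype:MRI", "view"))
  expect_false(check_access(store, "stranger", "function:query.run", "view"))

  grant(store, "clinicians", "datatype:MRI", "view")
  grant(store, "geneticists", "function:query.run", "view")
  expect_true(check_access(store, "alice", "datatype:MRI", "view"))
  expect_false(check_access(store, "alice", "datatype:MRI", "modify"))
  expect_false(check_access(store, "bob", "datatype:MRI", "view"))
  expect_true(check_access(store, "bob", "function:query.run", "view"))

  # idempotent grant
  grant(store, "clinicians", "datatype:MRI", "view")
  expect_equal(nrow(store$tables$permissions), 2L)
  # unknown resources rejected
  expect_error(grant(store, "clinicians", "datatype:ghost", "view"),
               class = "xr_not_found_error")
  expect_error(grant(store, "ghosts", "datatype:MRI", "view"),
               class = "xr_not_found_error")
  # revoke restores deny
  revoke(store, "clinicians", "datatype:MRI", "view")
  expect_false(check_access(store, "alice", "datatype:MRI", "view"))
})

test_that("a user's effective permissions equal the union over their groups", {
  set.seed(311)
  store <- acl_store()
  resources <- c("datatype:MRI", "datatype:Microarray Protocol",
                 "function:query.run", "subject_personal_data")
  groups <- c("clinicians", "geneticists", "admins")
  granted <- list()
  for (g in groups) {
    for (r in resources) {
      for (a in c("view", "insert", "modify")) {
        if (stats::runif(1) < 0.3) {
          grant(store, g, r, a)
          granted[[length(granted) + 1L]] <- c(g, r, a)
        }
      }
    }
  }
  membership <- list(alice = c("clinicians", "admins"), bob = "geneticists",
                     nobody = character())
  for (u in names(membership)) {
    for (r in resources) {
      for (a in c("view", "insert", "modify")) {
        oracle <- any(vapply(granted, function(p) {
          p[1] %in% membership[[u]] && p[2] == r && p[3] == a
        }, logical(1)))
        expect_identical(check_access(store, u, r, a), oracle,
                         label = paste(u, r, a))
      }
    }
  }
})

test_that("personal fields are masked for users without the permission", {
  store <- acl_store()
  grant(store, "clinicians", "subject_personal_data", "view")
  grant(store, "geneticists", "datatype:MRI", "view")
  grant(store, "geneticists", "datatype:Microarray Protocol", "view")

  # the geneticist sees clinical fields but not the birth date
  v <- masked_view(store, "bob", "S1")
  expect_equal(v$birth_date, "[masked]")
  expect_equal(v$diagnosis, "Control")
  expect_equal(v$subject_id, "S1")
  # the clinician sees everything
  expect_equal(masked_view(store, "alice", "S1")$birth_date, "1950-01-01")

  # masking survives every rendering of the overview
  ov <- subject_overview(store, "S1", user = "bob")
  rendered <- c(format_overview_text(ov), format_overview_html(ov))
  expect_false(any(grepl("1950-01-01", rendered, fixed = TRUE)))
  expect_true(any(grepl("[masked]", rendered, fixed = TRUE)))

  # configurable personal fields
  set_personal_fields(store, c("birth_date", "diagnosis"))
  v2 <- masked_view(store, "bob", "S1")
  expect_equal(v2$diagnosis, "[masked]")
})

test_that("overviews omit data types the user may not view", {
  store <- acl_store()
  grant(store, "geneticists", "datatype:Microarray Protocol", "view")
  save_instance(store, reagent_instance("S1"))
  ov <- subject_overview(store, "S1", user = "bob")
  expect_equal(names(ov$sections), "Microarray Protocol")
  # file URIs of invisible datatypes are not listed either
  expect_false(any(ov$files$instance_id %in%
    store$tables$instances$instance_id[store$tables$instances$datatype == "MRI"]))
})

test_that("ACL configurations survive export and import", {
  store <- acl_store()
  grant(store, "clinicians", "datatype:MRI", "view")
  path <- withr::local_tempfile(fileext = ".json")
  acl_export(store, path)
  store2 <- tiny_store()
  acl_import(store2, path)
  expect_true(check_access(store2, "alice", "datatype:MRI", "view"))
  # mutating calls leave an operation log trail
  expect_true(any(store$tables$oplog$op == "acl.grant"))
})
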