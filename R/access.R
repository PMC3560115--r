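## Access control: groups, per-resource permissions, personal-data masking.
##
## Resources are "datatype:<name>", "function:<name>" or the special
## "subject_personal_data". Checks are default-deny: a user holds a
## permission only through a group that has been granted it. Authentication
## is out of scope — the engine trusts the caller-supplied user identity.

ACTIONS <- c("view", "insert", "modify")
MASK_MARKER <- "[masked]"

#' Create a user group
#'
#' @param store a store handle.
#' @param group_name unique group name.
#' @param description free text.
#' @return the group name, invisibly.
#' @export
create_group <- function(store, group_name, description = "") {
  invisible(store_txn(store, function(tabs) {
    if (tolower(group_name) %in% tolower(tabs$groups$group_name)) {
      xr_abort(paste0("group '", group_name, "' already exists"), "xr_conflict_error")
    }
    tabs$groups <- bind_rows(tabs$groups, tibble(
      group_name = group_name, description = description
    ))
    tabs <- log_op(tabs, store, "acl.create_group", group_name)
    list(tables = tabs, value = invisible(group_name))
  }))
}

#' Add a user to groups
#'
#' Users are plain identifiers; membership rows are idempotent.
#'
#' @param store a store handle.
#' @param user_id the user.
#' @param groups character vector of existing group names.
#' @return the user id, invisibly.
#' @export
add_user <- function(store, user_id, groups = character()) {
  invisible(store_txn(store, function(tabs) {
    unknown <- setdiff(tolower(groups), tolower(tabs$groups$group_name))
    if (length(unknown)) {
      xr_abort(paste0("unknown group(s): ", paste(unknown, collapse = ", ")),
               "xr_not_found_error")
    }
    add <- tibble(user_id = user_id, group_name = groups)
    tabs$members <- distinct(bind_rows(tabs$members, add))
    tabs <- log_op(tabs, store, "acl.add_user",
                   paste0(user_id, " -> ", paste(groups, collapse = ",")))
    list(tables = tabs, value = invisible(user_id))
  }))
}

check_resource <- function(tabs, resource) {
  if (identical(resource, "subject_personal_data")) {
    return(invisible(TRUE))
  }
  if (startsWith(resource, "datatype:")) {
    name <- sub("^datatype:", "", resource)
    if (!tolower(name) %in% tolower(tabs$schemas$name)) {
      xr_abort(paste0("unknown data type resource '", name, "'"),
               "xr_not_found_error")
    }
    return(invisible(TRUE))
  }
  if (startsWith(resource, "function:")) {
    name <- sub("^function:", "", resource)
    if (!tolower(name) %in% tolower(tabs$functions$function_name)) {
      xr_abort(paste0("unknown function resource '", name, "'"),
               "xr_not_found_error")
    }
    return(invisible(TRUE))
  }
  xr_abort(paste0("malformed resource '", resource, "'"), "xr_usage_error")
}

#' Grant or revoke a permission
#'
#' Grants are idempotent: granting twice leaves a single permission row.
#'
#' @param store a store handle.
#' @param group an existing group name.
#' @param resource `"datatype:<name>"`, `"function:<name>"` or
#'   `"subject_personal_data"`.
#' @param action `"view"`, `"insert"` or `"modify"`.
#' @return the store handle, invisibly.
#' @export
grant <- function(store, group, resource, action) {
  stopifnot(action %in% ACTIONS)
  invisible(store_txn(store, function(tabs) {
    if (!tolower(group) %in% tolower(tabs$groups$group_name)) {
      xr_abort(paste0("unknown group '", group, "'"), "xr_not_found_error")
    }
    check_resource(tabs, resource)
    tabs$permissions <- distinct(bind_rows(tabs$permissions, tibble(
      group_name = group, resource = resource, action = action
    )))
    tabs <- log_op(tabs, store, "acl.grant",
                   paste(group, resource, action, sep = " "))
    list(tables = tabs, value = invisible(store))
  }))
}

#' @rdname grant
#' @export
revoke <- function(store, group, resource, action) {
  invisible(store_txn(store, function(tabs) {
    keep <- !(tolower(tabs$permissions$group_name) == tolower(group) &
      tabs$permissions$resource == resource &
      tabs$permissions$action == action)
    tabs$permissions <- tabs$permissions[keep, , drop = FALSE]
    tabs <- log_op(tabs, store, "acl.revoke",
                   paste(group, resource, action, sep = " "))
    list(tables = tabs, value = invisible(store))
  }))
}

#' Check whether a user may perform an action on a resource
#'
#' True iff some group the user belongs to holds the permission. Default
#' deny: users in no groups, or groups with no grants, can do nothing.
#'
#' @param store a store handle.
#' @param user user id.
#' @param resource resource string (see [grant()]).
#' @param action `"view"`, `"insert"` or `"modify"`.
#' @return `TRUE` or `FALSE`.
#' @export
check_access <- function(store, user, resource, action) {
  tabs <- store$tables
  groups <- tabs$members$group_name[tabs$members$user_id == user]
  if (!length(groups)) {
    return(FALSE)
  }
  any(
    tolower(tabs$permissions$group_name) %in% tolower(groups) &
      tabs$permissions$resource == resource &
      tabs$permissions$action == action
  )
}

personal_fields <- function(store) {
  row <- store$tables$meta[store$tables$meta$key == "personal_fields", ,
                           drop = FALSE]
  if (nrow(row)) strsplit(row$value[1], ",", fixed = TRUE)[[1]] else "birth_date"
}

#' Configure which subject fields count as personal data
#'
#' Defaults to `birth_date`; the anonymous subject id is never personal (it
#' is the anonymization device itself) and sex/diagnosis are clinical.
#'
#' @param store a store handle.
#' @param fields character vector among `sex`, `birth_date`, `diagnosis`.
#' @return the store, invisibly.
#' @export
set_personal_fields <- function(store, fields) {
  stopifnot(all(fields %in% c("sex", "birth_date", "diagnosis")))
  invisible(store_txn(store, function(tabs) {
    tabs$meta <- tabs$meta[tabs$meta$key != "personal_fields", , drop = FALSE]
    tabs$meta <- bind_rows(tabs$meta, tibble(
      key = "personal_fields", value = paste(fields, collapse = ",")
    ))
    list(tables = tabs, value = invisible(store))
  }))
}

#' View a subject through a user's permissions
#'
#' Without the `subject_personal_data` view permission, the configured
#' personal fields are replaced by the mask marker. The anonymous subject id
#' is always visible.
#'
#' @param store a store handle.
#' @param user user id.
#' @param subject_id the subject.
#' @return a one-row tibble `subject_id`, `sex`, `birth_date`, `diagnosis`.
#' @export
masked_view <- function(store, user, subject_id) {
  tabs <- store$tables
  row <- tabs$subjects[tabs$subjects$subject_id == subject_id, , drop = FALSE]
  if (!nrow(row)) {
    xr_abort(paste0("no subject '", subject_id, "'"), "xr_not_found_error")
  }
  row <- as_tibble(row)
  if (!check_access(store, user, "subject_personal_data", "view")) {
    for (f in personal_fields(store)) row[[f]] <- MASK_MARKER
  }
  row
}

#' Export / import the ACL configuration as JSON
#'
#' @param store a store handle.
#' @param path JSON file path.
#' @return `path` (export) or the store (import), invisibly.
#' @export
acl_export <- function(store, path) {
  jsonlite::write_json(
    list(
      groups = as.data.frame(store$tables$groups),
      members = as.data.frame(store$tables$members),
      permissions = as.data.frame(store$tables$permissions)
    ),
    path, auto_unbox = TRUE, na = "null", digits = NA
  )
  invisible(path)
}

#' @rdname acl_export
#' @export
acl_import <- function(store, path) {
  acl <- jsonlite::read_json(path, simplifyVector = TRUE)
  invisible(store_txn(store, function(tabs) {
    if (NROW(acl$groups)) tabs$groups <- as_tibble(acl$groups)
    if (NROW(acl$members)) tabs$members <- as_tibble(acl$members)
    if (NROW(acl$permissions)) tabs$permissions <- as_tibble(acl$permissions)
    tabs <- log_op(tabs, store, "acl.import", path)
    list(tables = tabs, value = invisible(store))
  }))
}
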