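## Simulation utilities: random schemas, conforming instances, targeted
## mutations and random query specifications, plus an independently
## implemented reference query evaluator. These drive the property-style
## verification of the engine (round-trips, validation correctness,
## query-oracle equivalence); they are exported because they are useful for
## benchmarking and for users stress-testing their own deployments.

WORD_POOL <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "theta", "kappa",
  "lambda", "sigma", "omega", "cortex", "signal", "marker", "assay", "probe",
  "score", "index", "phase", "grade", "level", "panel", "titer", "ratio",
  "volume", "region", "tracer", "domain", "factor", "batch", "onset", "stage"
)

sample_words <- function(n, suffix = TRUE) {
  base <- sample(WORD_POOL, n, replace = n > length(WORD_POOL))
  if (suffix) paste0(base, "_", sample(1000:9999, n, replace = TRUE)) else base
}

#' Generate a random valid data-type schema
#'
#' Uniformly exercises the meta model: 1-3 groups of 1-4 members, ~30%
#' loops (1-3 attributes each), all six value kinds, enumerations of 2-4
#' values, optional defaults and units. The result always satisfies
#' [define_datatype()]'s invariants. Randomness comes from the session RNG;
#' seed with `set.seed()` or [withr::with_seed()] for reproducibility.
#'
#' @param name optional data type name (random when omitted).
#' @param file_associated header flag.
#' @return an `xr_schema`.
#' @export
random_schema <- function(name = NULL, file_associated = FALSE) {
  name <- name %||% paste0("type_", paste(sample(letters, 8, TRUE), collapse = ""))
  n_groups <- sample(1:3, 1)
  gnames <- sample_words(n_groups)
  groups <- lapply(gnames, function(gn) {
    n_members <- sample(1:4, 1)
    mnames <- sample_words(n_members)
    members <- lapply(mnames, function(mn) {
      if (stats::runif(1) < 0.3) {
        n_la <- sample(1:3, 1)
        loop_def(mn, lapply(sample_words(n_la), random_attribute))
      } else {
        random_attribute(mn)
      }
    })
    metadata_group(gn, members)
  })
  define_datatype(
    schema_header(name, description = "generated", file_associated = file_associated,
                  created_by = "generator", created_at = "2010-01-01T00:00:00Z"),
    groups
  )
}

random_attribute <- function(name) {
  kind <- sample(VALUE_KINDS, 1)
  allowed <- if (kind == "enumeration") sample_words(sample(2:4, 1)) else NULL
  required <- stats::runif(1) < 0.4
  default <- if (stats::runif(1) < 0.2) random_value_of_kind(kind, allowed) else NULL
  attribute_def(
    name, kind, required = required, allowed_values = allowed,
    unit = if (kind %in% c("integer", "decimal") && stats::runif(1) < 0.3) "mm" else NULL,
    default = default
  )
}

random_value_of_kind <- function(kind, allowed = NULL) {
  switch(kind,
    text = paste(sample_words(1, suffix = FALSE), sample(100:999, 1)),
    integer = sample(-500:500, 1),
    decimal = sample(c(-1, 1), 1) * round(stats::runif(1, 0, 250), sample(0:3, 1)),
    date = as.Date("1990-01-01") + sample(0:12000, 1),
    boolean = sample(c(TRUE, FALSE), 1),
    enumeration = sample(allowed, 1)
  )
}

#' Generate a random instance conforming to a schema
#'
#' Every required attribute is supplied; optional attributes appear with
#' probability `p_optional`; loops get 0-3 iterations.
#'
#' @param schema an `xr_schema`.
#' @param subject_id owning subject id.
#' @param p_optional inclusion probability for optional attributes.
#' @return a valid `xr_instance`.
#' @export
random_instance <- function(schema, subject_id = "SUBJ-000",
                            p_optional = 0.8) {
  values <- list()
  loops <- list()
  for (g in schema$groups) {
    for (m in g$members) {
      if (inherits(m, "xr_attribute")) {
        if (m$required || stats::runif(1) < p_optional) {
          values[[length(values) + 1L]] <- attribute_value(
            g$name, m$name, random_value_of_kind(m$kind, m$allowed_values)
          )
        }
      } else {
        n_iter <- sample(0:3, 1)
        iterations <- lapply(seq_len(n_iter), function(i) {
          iter <- list()
          for (a in m$attributes) {
            if (a$required || stats::runif(1) < p_optional) {
              iter[[a$name]] <- random_value_of_kind(a$kind, a$allowed_values)
            }
          }
          iter
        })
        loops[[length(loops) + 1L]] <- loop_instance(g$name, m$name, iterations)
      }
    }
  }
  data_instance(
    datatype = schema$header$datatype_name, subject_id = subject_id,
    values = values, loops = loops, version = schema$header$version
  )
}

#' Apply one targeted corruption to a conforming instance
#'
#' Picks one feasible mutation — drop a required attribute, corrupt a value's
#' kind, or add an unknown path — and returns the mutated instance together
#' with the path a validator must report.
#'
#' @param instance a valid `xr_instance`.
#' @param schema its schema.
#' @return list with `instance`, `expected_path`, `mutation`; `NULL` when no
#'   mutation is feasible (e.g. an empty instance of an all-optional type).
#' @export
mutate_instance <- function(instance, schema) {
  candidates <- list()
  # droppable: supplied plain values that are required without default
  for (vi in seq_along(instance$values)) {
    v <- instance$values[[vi]]
    a <- schema_find_attribute(schema, v$group, v$attribute)
    if (!is.null(a) && a$required && is.null(a$default)) {
      candidates[[length(candidates) + 1L]] <-
        list(type = "drop_required", index = vi,
             path = paste(v$group, v$attribute, sep = "."))
    }
    if (!is.null(a) && !a$kind %in% c("text", "enumeration")) {
      candidates[[length(candidates) + 1L]] <-
        list(type = "corrupt_kind", index = vi,
             path = paste(v$group, v$attribute, sep = "."))
    }
    if (!is.null(a) && a$kind == "enumeration") {
      candidates[[length(candidates) + 1L]] <-
        list(type = "corrupt_enum", index = vi,
             path = paste(v$group, v$attribute, sep = "."))
    }
  }
  # always feasible: unknown path in the first group
  candidates[[length(candidates) + 1L]] <-
    list(type = "unknown_path",
         path = paste(schema$groups[[1]]$name, "phantom_zzz", sep = "."))
  pick <- candidates[[sample(length(candidates), 1)]]
  if (pick$type == "drop_required") {
    instance$values[[pick$index]] <- NULL
  } else if (pick$type == "corrupt_kind") {
    instance$values[[pick$index]]$value <- "not@a@value"
  } else if (pick$type == "corrupt_enum") {
    instance$values[[pick$index]]$value <- "zz_not_allowed_zz"
  } else {
    instance$values[[length(instance$values) + 1L]] <- attribute_value(
      schema$groups[[1]]$name, "phantom_zzz", "x"
    )
  }
  list(instance = instance, expected_path = pick$path, mutation = pick$type)
}

#' Generate a random valid query specification against a store
#'
#' Mixes 0-2 subject conditions with 0-3 data conditions (existence tests
#' and field conditions, including loop attributes), drawing comparison
#' values partly from values actually stored so that result sets are
#' non-trivial.
#'
#' @param store a store handle.
#' @return an `xr_query` composed (and therefore validated) against `store`.
#' @export
random_query_spec <- function(store) {
  tabs <- store$tables
  subj_conds <- list()
  for (k in seq_len(sample(0:2, 1))) {
    field <- sample(SUBJECT_FIELDS, 1)
    op <- sample(SUBJECT_OPERATORS[[field]], 1)
    value <- switch(field,
      sex = sample(SEX_LEVELS, 1),
      diagnosis = {
        pool <- unique(tabs$subjects$diagnosis)
        v <- if (length(pool)) sample(pool, 1) else "Control"
        if (op == "contains" && nchar(v) > 3) substr(v, 2, 8) else v
      },
      birth_date = {
        pool <- tabs$subjects$birth_date[!is.na(tabs$subjects$birth_date)]
        if (length(pool)) sample(pool, 1) else "1950-01-01"
      }
    )
    subj_conds[[length(subj_conds) + 1L]] <- subject_condition(field, op, value)
  }
  data_conds <- list()
  datatypes <- unique(tabs$schemas$name)
  if (length(datatypes)) {
    for (k in seq_len(sample(0:3, 1))) {
      dt <- sample(datatypes, 1)
      if (stats::runif(1) < 0.3) {
        data_conds[[length(data_conds) + 1L]] <- data_condition(dt)
        next
      }
      fields <- list_fields(store, dt)
      if (!nrow(fields)) next
      row <- fields[sample(nrow(fields), 1), ]
      op <- sample(setdiff(OPERATORS_BY_KIND[[row$kind]], "in"), 1)
      stored <- tabs$eav$value[
        tabs$eav$datatype == dt & tabs$eav$grp == row$group &
          tabs$eav$attribute == row$attribute &
          (is.na(tabs$eav$loop) == is.na(row$loop))
      ]
      value <- if (length(stored) && stats::runif(1) < 0.6) {
        sample(stored, 1)
      } else {
        schema <- load_schema(store, dt)
        a <- schema_find_attribute(schema, row$group, row$attribute, loop = row$loop)
        as.character(encode_value(random_value_of_kind(a$kind, a$allowed_values),
                                  a$kind))
      }
      if (op == "contains" && nchar(value) > 2) {
        value <- substr(value, 1, max(2, nchar(value) - 1))
      }
      data_conds[[length(data_conds) + 1L]] <- data_condition(
        dt, path = row$path, operator = op, value = value
      )
    }
  }
  compose_query(store, subj_conds, data_conds)
}

## ---- independent reference query evaluator ---------------------------------

#' Pre-parse a store's instances for repeated reference evaluation
#'
#' @param store a store handle.
#' @return an opaque context consumed by [query_reference()].
#' @export
query_reference_context <- function(store) {
  schemas <- new.env(parent = emptyenv())
  get_schema <- function(name, version) {
    key <- paste0(tolower(name), "@", version)
    if (is.null(schemas[[key]])) schemas[[key]] <- load_schema(store, name, version)
    schemas[[key]]
  }
  instances <- lapply(seq_len(nrow(store$tables$instances)), function(i) {
    row <- store$tables$instances[i, ]
    parse_instance(row$xml, get_schema(row$datatype, row$version))
  })
  list(get_schema = get_schema, instances = instances)
}

#' Reference query evaluation by exhaustive scan
#'
#' An independently implemented evaluator with the same semantics as
#' [execute_query()]: it ignores the EAV table entirely, loads every instance
#' from its canonical XML document and filters subjects by plain R loops over
#' the typed objects. Used to verify the EAV execution path; intentionally
#' slow and simple.
#'
#' @param store a store handle.
#' @param spec an `xr_query`.
#' @param context optional pre-built [query_reference_context()]; parsing
#'   every instance document once up front amortizes repeated evaluations.
#' @return sorted character vector of subject ids.
#' @export
query_reference <- function(store, spec, context = NULL) {
  context <- context %||% query_reference_context(store)
  tabs <- store$tables
  subjects <- tabs$subjects
  get_schema <- context$get_schema
  inst_objs <- context$instances
  inst_dt <- tolower(tabs$instances$datatype)
  inst_subj <- tabs$instances$subject_id

  text_eq <- function(a, b) tolower(as.character(a)) == tolower(as.character(b))
  cmp <- function(typed, op, target, kind) {
    if (kind %in% c("text", "enumeration")) {
      switch(op,
        eq = text_eq(typed, target),
        ne = !text_eq(typed, target),
        contains = grepl(tolower(target), tolower(as.character(typed)), fixed = TRUE),
        `in` = tolower(as.character(typed)) %in% tolower(target),
        FALSE
      )
    } else if (kind == "boolean") {
      tv <- isTRUE(typed)
      tgt <- identical(target, "true") || isTRUE(target)
      switch(op, eq = tv == tgt, ne = tv != tgt, FALSE)
    } else {
      a <- if (kind == "date") as.Date(typed) else as.numeric(typed)
      b <- if (kind == "date") as.Date(target) else as.numeric(target)
      switch(op,
        eq = a == b, ne = a != b, lt = a < b, le = a <= b, gt = a > b,
        ge = a >= b, `in` = a %in% b, FALSE
      )
    }
  }
  instance_matches <- function(obj, dc, schema) {
    if (is.na(dc$loop)) {
      for (v in obj$values) {
        if (text_eq(v$group, dc$group) && text_eq(v$attribute, dc$attribute)) {
          a <- schema_find_attribute(schema, dc$group, dc$attribute)
          target <- if (identical(dc$operator, "in")) dc$encoded else dc$encoded[1]
          if (isTRUE(cmp(v$value, dc$operator, target, a$kind))) {
            return(TRUE)
          }
        }
      }
      return(FALSE)
    }
    for (l in obj$loops) {
      if (!text_eq(l$group, dc$group) || !text_eq(l$loop, dc$loop)) next
      a <- schema_find_attribute(schema, dc$group, dc$attribute, loop = dc$loop)
      for (iter in l$iterations) {
        for (an in names(iter)) {
          if (text_eq(an, dc$attribute)) {
            target <- if (identical(dc$operator, "in")) dc$encoded else dc$encoded[1]
            if (isTRUE(cmp(iter[[an]], dc$operator, target, a$kind))) {
              return(TRUE)
            }
          }
        }
      }
    }
    FALSE
  }

  result <- character()
  for (si in seq_len(nrow(subjects))) {
    s <- subjects[si, ]
    ok <- TRUE
    for (sc in spec$subject_conditions) {
      val <- s[[sc$field]]
      kind <- if (sc$field == "birth_date") "date" else "text"
      if (is.na(val) || !isTRUE(cmp(val, sc$operator, sc$value, kind))) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    for (dc in spec$data_conditions) {
      mine <- which(inst_subj == s$subject_id & inst_dt == tolower(dc$datatype))
      hit <- if (dc$mode == "exists") {
        length(mine) > 0L
      } else {
        any(vapply(mine, function(i) {
          obj <- inst_objs[[i]]
          instance_matches(obj, dc, get_schema(obj$datatype, obj$version))
        }, logical(1)))
      }
      if (!hit) {
        ok <- FALSE
        break
      }
    }
    if (ok) result <- c(result, s$subject_id)
  }
  sort(result, method = "radix")
}
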