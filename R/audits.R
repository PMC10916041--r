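# Audit records: one rater pair's complete audit of one school, validated
# against a scoring schema; long-CSV and nested-JSON I/O; rating matrices.

#' Construct a unit audit
#'
#' One audited unit (a school access segment, another segment near the
#' school, or a crossing) with a complete set of item responses for its
#' section.
#'
#' @param unit_id Unit identifier, unique within a school and stable across
#'   rater pairs (rater pairs auditing the same physical unit must use the
#'   same `unit_id`).
#' @param unit_kind `"school_access_segment"`, `"other_segment"` or
#'   `"crossing"`.
#' @param responses Named numeric vector or list, `item_id -> value`,
#'   covering exactly the schema's items for the section.
#' @return A `unit_audit` object.
#' @export
unit_audit <- function(unit_id, unit_kind, responses) {
  stopifnot(is.character(unit_id), length(unit_id) == 1)
  if (!unit_kind %in% SECTIONS) {
    stop("unit ", unit_id, ": unknown unit_kind '", unit_kind, "'")
  }
  responses <- unlist(responses)
  structure(list(unit_id = unit_id, unit_kind = unit_kind,
                 responses = responses),
            class = "unit_audit")
}

#' Construct a school audit
#'
#' @param school_id School identifier.
#' @param rater_pair_id Identifier of the two-person field team (a rater
#'   pair is treated as a single rating source).
#' @param access_segments,other_segments,crossings Lists of [unit_audit()]
#'   objects of the matching kind. At least one school access segment is
#'   required (schools with several entrances can have more).
#' @param date Optional ISO-8601 date string.
#' @return A `maps_audit` object.
#' @export
school_audit <- function(school_id, rater_pair_id, access_segments,
                         other_segments = list(), crossings = list(),
                         date = NA_character_) {
  for (pair in list(list(access_segments, "school_access_segment"),
                    list(other_segments, "other_segment"),
                    list(crossings, "crossing"))) {
    kinds <- vapply(pair[[1]], `[[`, "", "unit_kind")
    if (any(kinds != pair[[2]])) {
      stop("school ", school_id, ": unit of kind ",
           paste(unique(kinds[kinds != pair[[2]]]), collapse = ", "),
           " in the ", pair[[2]], " list")
    }
  }
  if (length(access_segments) < 1) {
    stop("school ", school_id, ": at least one school access segment required")
  }
  structure(list(school_id = school_id, rater_pair_id = rater_pair_id,
                 date = as.character(date),
                 access_segments = access_segments,
                 other_segments = other_segments, crossings = crossings),
            class = "maps_audit")
}

audit_units <- function(audit, section = NULL) {
  u <- c(audit$access_segments, audit$other_segments, audit$crossings)
  if (is.null(section)) return(u)
  u[vapply(u, function(x) identical(x$unit_kind, section), TRUE)]
}

#' @export
print.maps_audit <- function(x, ...) {
  cat("MAPS-SRTS audit: school ", x$school_id, ", rater pair ",
      x$rater_pair_id, "\n  units: ", length(x$access_segments),
      " access segment(s), ", length(x$other_segments),
      " other segment(s), ", length(x$crossings), " crossing(s)\n",
      sep = "")
  invisible(x)
}

# Domain membership check for one response value.
response_in_domain <- function(item, value) {
  dom <- item$response_domain
  if (length(value) != 1 || is.na(value)) return(FALSE)
  switch(dom$type,
    binary = value %in% c(0, 1),
    ordinal = value %in% dom$levels,
    count = is.finite(value) && value >= 0 && value == round(value) &&
      (is.null(dom$max) || value <= dom$max),
    categorical = as.character(value) %in% as.character(dom$levels),
    FALSE)
}

#' Validate audits against a schema
#'
#' Checks every unit of every audit: known items only, no duplicates,
#' exactly the schema's item set for the unit's section, and every response
#' inside its item's declared domain. Validation is total: all problems are
#' collected and reported in one error; nothing is silently zero-filled.
#'
#' @param audits A `maps_audit` or list of them.
#' @param schema A `maps_schema`.
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validate_audits <- function(audits, schema) {
  if (inherits(audits, "maps_audit")) audits <- list(audits)
  section_items <- lapply(SECTIONS, function(sec) {
    names(schema$items)[vapply(schema$items, function(it)
      identical(it$section, sec), TRUE)]
  })
  names(section_items) <- SECTIONS
  errs <- character()
  for (a in audits) {
    at <- paste0("school ", a$school_id, "/", a$rater_pair_id)
    for (u in audit_units(a)) {
      here <- paste0(at, ", unit ", u$unit_id)
      ids <- names(u$responses)
      if (anyDuplicated(ids)) {
        errs <- c(errs, paste0(here, ": duplicated item responses: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", ")))
        next
      }
      want <- section_items[[u$unit_kind]]
      unknown <- setdiff(ids, names(schema$items))
      wrong_sec <- setdiff(intersect(ids, names(schema$items)), want)
      missing <- setdiff(want, ids)
      if (length(unknown)) {
        errs <- c(errs, paste0(here, ": unknown item_id: ",
                               paste(unknown, collapse = ", ")))
      }
      if (length(wrong_sec)) {
        errs <- c(errs, paste0(here, ": items from another section: ",
                               paste(wrong_sec, collapse = ", ")))
      }
      if (length(missing)) {
        errs <- c(errs, paste0(here, ": missing required items: ",
                               paste(missing, collapse = ", ")))
      }
      for (id in intersect(ids, want)) {
        if (!response_in_domain(schema$items[[id]], u$responses[[id]])) {
          errs <- c(errs, paste0(here, ", item ", id, ": response ",
                                 u$responses[[id]],
                                 " outside the declared domain"))
        }
      }
    }
  }
  if (length(errs)) {
    stop("audit validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical ordering so file row order never affects the loaded objects.
canonicalize_audits <- function(audits, schema) {
  item_order <- names(schema$items)
  audits <- lapply(audits, function(a) {
    fix <- function(units) {
      units <- units[order(vapply(units, `[[`, "", "unit_id"))]
      lapply(units, function(u) {
        u$responses <- u$responses[intersect(item_order, names(u$responses))]
        u
      })
    }
    a$access_segments <- fix(a$access_segments)
    a$other_segments <- fix(a$other_segments)
    a$crossings <- fix(a$crossings)
    a
  })
  key <- vapply(audits, function(a)
    paste(a$school_id, a$rater_pair_id, sep = "\r"), "")
  audits[order(key)]
}

# Long data frame <-> audit list conversion (shared by CSV I/O and the
# synthetic generator).
audits_from_long <- function(df, schema) {
  need <- c("school_id", "rater_pair_id", "unit_id", "unit_kind", "item_id",
            "value")
  if (!all(need %in% names(df))) {
    stop("long audit table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"date" %in% names(df)) df$date <- NA_character_
  df$date <- as.character(df$date)
  key <- paste(df$school_id, df$rater_pair_id, sep = "\r")
  audits <- lapply(split(df, key), function(g) {
    units <- lapply(split(g, g$unit_id), function(gu) {
      kind <- unique(gu$unit_kind)
      if (length(kind) != 1) {
        stop("unit ", gu$unit_id[[1]], " has inconsistent unit_kind")
      }
      resp <- as.numeric(gu$value)
      names(resp) <- gu$item_id
      unit_audit(gu$unit_id[[1]], kind, resp)
    })
    kinds <- vapply(units, `[[`, "", "unit_kind")
    school_audit(
      school_id = g$school_id[[1]], rater_pair_id = g$rater_pair_id[[1]],
      access_segments = unname(units[kinds == "school_access_segment"]),
      other_segments = unname(units[kinds == "other_segment"]),
      crossings = unname(units[kinds == "crossing"]),
      date = g$date[[1]]
    )
  })
  canonicalize_audits(unname(audits), schema)
}

audits_to_long <- function(audits, schema) {
  if (inherits(audits, "maps_audit")) audits <- list(audits)
  rows <- lapply(canonicalize_audits(audits, schema), function(a) {
    do.call(rbind, lapply(audit_units(a), function(u) {
      data.frame(school_id = a$school_id, rater_pair_id = a$rater_pair_id,
                 date = a$date %||% NA_character_, unit_id = u$unit_id,
                 unit_kind = u$unit_kind, item_id = names(u$responses),
                 value = as.numeric(u$responses),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Read audit records
#'
#' Reads field (or synthetic) audit records from long-format CSV (one row =
#' school, rater pair, unit, item, value) or nested JSON, validates them
#' against the schema, and returns canonical `maps_audit` objects. Row
#' order in the file never affects the result, and any malformed input
#' fails as a whole — no partially loaded dataset is returned.
#'
#' @param path Audit file (`.csv` or `.json`).
#' @param schema A `maps_schema`.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return List of validated `maps_audit` objects in canonical order.
#' @export
read_audits <- function(path, schema, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("audit file does not exist: ", path)
  audits <- if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("audit file is empty: ", path)
    audits_from_long(df, schema)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(doc) == 0) stop("audit file is empty: ", path)
    canonicalize_audits(lapply(doc, function(a) {
      mk <- function(us) lapply(us, function(u)
        unit_audit(u$unit_id, u$unit_kind,
                   unlist(lapply(u$responses, as.numeric))))
      school_audit(a$school_id, a$rater_pair_id,
                   access_segments = mk(a$access_segments),
                   other_segments = mk(a$other_segments),
                   crossings = mk(a$crossings),
                   date = a$date %||% NA_character_)
    }), schema)
  }
  validate_audits(audits, schema)
  audits
}

#' @param audits List of `maps_audit` objects to write.
#' @rdname read_audits
#' @export
write_audits <- function(audits, path, schema,
                         format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (inherits(audits, "maps_audit")) audits <- list(audits)
  if (format == "csv") {
    write.csv(audits_to_long(audits, schema), path, row.names = FALSE)
  } else {
    doc <- lapply(canonicalize_audits(audits, schema), function(a) {
      mk <- function(us) lapply(us, function(u)
        list(unit_id = u$unit_id, unit_kind = u$unit_kind,
             responses = as.list(u$responses)))
      list(school_id = a$school_id, rater_pair_id = a$rater_pair_id,
           date = a$date, access_segments = mk(a$access_segments),
           other_segments = mk(a$other_segments),
           crossings = mk(a$crossings))
    })
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Build a schools-by-raters rating matrix for a subscale
#'
#' Assembles the complete n x k table of subscale scores (subjects =
#' schools, columns = rater pairs) used by the reliability engine. The
#' design must be complete: every school audited by every rater pair.
#'
#' @param audits List of `maps_audit` objects.
#' @param subscale_id A subscale id of `schema` (the total node is allowed).
#' @param schema A `maps_schema`.
#' @param scorer Scoring function `f(audit, schema)` returning the scalar
#'   score for `subscale_id`; defaults to the package scorer.
#' @return A numeric matrix with school ids as rows and rater pair ids as
#'   columns, with attribute `subscale_id`.
#' @export
build_rating_matrix <- function(audits, subscale_id, schema, scorer = NULL) {
  if (inherits(audits, "maps_audit")) audits <- list(audits)
  if (!subscale_id %in% names(schema$subscales)) {
    stop("unknown subscale '", subscale_id, "'")
  }
  if (is.null(scorer)) {
    scorer <- function(audit, schema) {
      rep_ <- score_school(audit, schema)
      if (identical(subscale_id, schema$total_id)) rep_$total
      else rep_$subscale_scores[[subscale_id]]
    }
  }
  schools <- sort(unique(vapply(audits, `[[`, "", "school_id")))
  raters <- sort(unique(vapply(audits, `[[`, "", "rater_pair_id")))
  if (length(schools) < 2) stop("need at least 2 schools (subjects)")
  if (length(raters) < 2) stop("need at least 2 rater pairs")
  m <- matrix(NA_real_, length(schools), length(raters),
              dimnames = list(schools, raters))
  for (a in audits) {
    if (!is.na(m[a$school_id, a$rater_pair_id])) {
      stop("duplicate audit for school ", a$school_id, " by rater pair ",
           a$rater_pair_id)
    }
    m[a$school_id, a$rater_pair_id] <- scorer(a, schema)
  }
  if (anyNA(m)) {
    bad <- schools[apply(m, 1, anyNA)]
    stop("incomplete rating design; school(s) missing a rater pair: ",
         paste(bad, collapse = ", "))
  }
  attr(m, "subscale_id") <- subscale_id
  m
}
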