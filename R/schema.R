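# Schema registry: loading, materializing, validating and diffing the
# instrument definition.

SCHEMA_VERSIONS <- c("initial_v1", "final_v2")

#' Load a MAPS-SRTS scoring schema
#'
#' Reads a scoring dictionary or a previously serialized schema (JSON) and
#' materializes the requested instrument version. The shipped default
#' dictionary ([maps_dictionary_path()]) defines 90 items in three sections
#' (33 school access segment, 30 other segment, 27 crossing). The
#' `initial_v1` version has 30 non-total subscales (11/11/8 per section) and
#' trichotomizes the road-width lane sum; `final_v2` has 26 subscales
#' (9/9/8) — the positive buffer and positive shade subscales of both
#' segment-type sections are dropped (their items are kept as unscored) and
#' road width is recoded to a dichotomy (more than 4 total lanes).
#'
#' @param path Path to a dictionary or schema JSON file. Defaults to the
#'   shipped dictionary.
#' @param version Instrument version, `"final_v2"` (default) or
#'   `"initial_v1"`. Ignored (but checked for agreement if supplied) when
#'   `path` contains an already materialized schema.
#' @return A `maps_schema` object: list with `version`, `items` (named list
#'   of item definitions), `subscales` (named list of subscale definitions),
#'   and `total_id`.
#' @seealso [count_items()], [diff_versions()], [write_schema()]
#' @export
#' @examples
#' sch <- load_schema(version = "final_v2")
#' count_items(sch, "school_access_segment")
load_schema <- function(path = maps_dictionary_path(),
                        version = c("final_v2", "initial_v1")) {
  if (!file.exists(path)) stop("schema file does not exist: ", path)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed schema file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (identical(doc$type, "schema")) {
    sch <- schema_from_json(doc)
    if (!missing(version) && !identical(sch$version, match.arg(version))) {
      stop("file contains a materialized '", sch$version,
           "' schema, not '", match.arg(version), "'")
    }
    validate_schema(sch)
    return(sch)
  }
  if (!identical(doc$type, "dictionary")) {
    stop("malformed schema file '", path,
         "': top-level 'type' must be \"dictionary\" or \"schema\"")
  }
  version <- match.arg(version)
  dict <- dictionary_from_json(doc)
  sch <- materialize_schema(dict, version)
  validate_schema(sch)
  sch
}

# Normalize a parsed dictionary JSON back to the in-memory shape
# (read_json leaves everything as nested lists; fix vectors and names).
dictionary_from_json <- function(doc) {
  fix_item <- function(it) {
    dom <- it$response_domain
    if (!is.null(dom$levels)) dom$levels <- as.integer(unlist(dom$levels))
    if (!is.null(dom$max)) dom$max <- as.integer(dom$max)
    compact(list(
      item_id = it$item_id, section = it$section, prompt = it$prompt,
      response_domain = dom,
      score_map = if (is.null(it$score_map)) NULL else
        lapply(it$score_map, as.numeric),
      valence = it$valence, subscale_id = it$subscale_id))
  }
  fix_sub <- function(s) {
    compact(list(
      subscale_id = s$subscale_id, section = s$section,
      valence = s$valence, children = as.character(unlist(s$children)),
      children_kind = s$children_kind, aggregation = s$aggregation,
      status = s$status %||% "retained",
      counterpart_id = s$counterpart_id, recode = s$recode,
      recode_active = s$recode_active))
  }
  items <- lapply(doc$items, fix_item)
  subscales <- lapply(doc$subscales, fix_sub)
  names(items) <- vapply(items, `[[`, "", "item_id")
  names(subscales) <- vapply(subscales, `[[`, "", "subscale_id")
  list(type = "dictionary", name = doc$name,
       dictionary_version = doc$dictionary_version,
       items = items, subscales = subscales, total_id = doc$total_id)
}

schema_from_json <- function(doc) {
  dict <- dictionary_from_json(doc)
  structure(
    list(version = doc$version, items = dict$items,
         subscales = dict$subscales, total_id = dict$total_id),
    class = "maps_schema"
  )
}

# Materialize one instrument version from a dictionary: resolve statuses and
# the active road-width recode.
materialize_schema <- function(dict, version) {
  items <- dict$items
  subscales <- dict$subscales
  for (id in names(subscales)) {
    s <- subscales[[id]]
    if (!is.null(s$recode)) {
      s$recode_active <-
        if (version == "final_v2") s$recode$final else s$recode$initial
    }
    s$status <- if (version == "initial_v1") "retained" else s$status
    subscales[[id]] <- s
  }
  sch <- structure(
    list(version = version, items = items, subscales = subscales,
         total_id = dict$total_id),
    class = "maps_schema"
  )
  if (version == "final_v2") {
    removed <- names(subscales)[vapply(subscales, function(s)
      identical(s$status, "removed"), TRUE)]
    sch <- drop_subscales(sch, removed)
  }
  sch
}

# Remove subscales from a schema: their ids leave the tree, parents keep the
# remaining children, and their items revert to unscored. Parents left with
# no children are removed in turn.
drop_subscales <- function(schema, ids) {
  if (length(ids) == 0) return(schema)
  repeat {
    schema$subscales <- schema$subscales[
      setdiff(names(schema$subscales), ids)]
    for (id in names(schema$subscales)) {
      s <- schema$subscales[[id]]
      s$children <- setdiff(s$children, ids)
      schema$subscales[[id]] <- s
    }
    for (iid in names(schema$items)) {
      it <- schema$items[[iid]]
      if (!is.null(it$subscale_id) && it$subscale_id %in% ids) {
        it$subscale_id <- NULL
        it$valence <- "unscored"
        schema$items[[iid]] <- it
      }
    }
    empty <- names(schema$subscales)[vapply(schema$subscales, function(s)
      length(s$children) == 0, TRUE)]
    if (length(empty) == 0) break
    ids <- empty
  }
  schema
}

#' Serialize a schema or dictionary to JSON
#'
#' @param schema A `maps_schema` object (or a dictionary list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  doc <- if (inherits(schema, "maps_schema")) {
    list(type = "schema", version = schema$version,
         items = unname(schema$items),
         subscales = unname(schema$subscales),
         total_id = schema$total_id)
  } else {
    schema$items <- unname(schema$items)
    schema$subscales <- unname(schema$subscales)
    schema
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a scoring schema
#'
#' Checks all structural invariants: unique item ids, known sections and
#' valences, complete score maps, scored items carrying a subscale, children
#' homogeneity, resolvable references, and acyclicity/reachability of the
#' aggregation tree. All violations are collected and reported together.
#'
#' @param schema A `maps_schema` object.
#' @return `TRUE` invisibly; stops with a message listing every violation
#'   otherwise.
#' @export
validate_schema <- function(schema) {
  errs <- character()
  items <- schema$items
  subs <- schema$subscales
  iid <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(iid)) {
    errs <- c(errs, paste0("duplicated item_id: ",
                           paste(unique(iid[duplicated(iid)]), collapse = ", ")))
  }
  sid <- vapply(subs, `[[`, "", "subscale_id")
  if (anyDuplicated(sid)) {
    errs <- c(errs, paste0("duplicated subscale_id: ",
                           paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  for (it in items) {
    if (!it$section %in% SECTIONS) {
      errs <- c(errs, paste0("item ", it$item_id, ": unknown section '",
                             it$section, "'"))
    }
    if (!it$valence %in% VALENCES) {
      errs <- c(errs, paste0("item ", it$item_id, ": unknown valence '",
                             it$valence, "'"))
    }
    dom <- it$response_domain
    if (dom$type %in% c("binary", "ordinal", "categorical")) {
      levs <- switch(dom$type, binary = c(0, 1), dom$levels)
      missing_map <- setdiff(as.character(levs), names(it$score_map %||% list()))
      if (length(missing_map)) {
        errs <- c(errs, paste0("item ", it$item_id,
                               ": score_map missing responses ",
                               paste(missing_map, collapse = ", ")))
      }
    }
    if (!is.null(it$subscale_id)) {
      if (identical(it$valence, "unscored")) {
        errs <- c(errs, paste0("item ", it$item_id,
                               ": unscored items cannot carry a subscale_id"))
      }
      if (!it$subscale_id %in% sid) {
        errs <- c(errs, paste0("item ", it$item_id,
                               ": unknown subscale_id '", it$subscale_id, "'"))
      }
    }
  }
  for (s in subs) {
    if (!s$section %in% c(SECTIONS, "total")) {
      errs <- c(errs, paste0("subscale ", s$subscale_id,
                             ": unknown section '", s$section, "'"))
    }
    kind <- s$children_kind
    if (!kind %in% c("items", "subscales")) {
      errs <- c(errs, paste0("subscale ", s$subscale_id,
                             ": children_kind must be items or subscales"))
      next
    }
    pool <- if (kind == "items") iid else sid
    bad <- setdiff(s$children, pool)
    if (length(bad)) {
      errs <- c(errs, paste0("subscale ", s$subscale_id,
                             ": unresolved children ",
                             paste(bad, collapse = ", ")))
    }
    if (identical(s$valence, "composite") &&
        !s$aggregation %in% c("positive_minus_negative", "sum_sections")) {
      errs <- c(errs, paste0("subscale ", s$subscale_id,
                             ": composite valence requires an overall/total",
                             " aggregation"))
    }
    if (identical(s$aggregation, "positive_minus_negative")) {
      vals <- vapply(subs[intersect(s$children, sid)], `[[`, "", "valence")
      if (!(sum(vals == "positive") == 1 && sum(vals == "negative") == 1)) {
        errs <- c(errs, paste0("subscale ", s$subscale_id,
                               ": positive_minus_negative needs exactly one",
                               " positive and one negative child"))
      }
    }
  }
  if (!schema$total_id %in% sid) {
    errs <- c(errs, paste0("total_id '", schema$total_id,
                           "' is not a subscale"))
  } else {
    # acyclicity + reachability by iterative expansion from the total node
    reach <- character()
    frontier <- schema$total_id
    for (step in seq_len(length(subs) + 1)) {
      nxt <- unique(unlist(lapply(subs[intersect(frontier, sid)],
                                  function(s)
                                    if (s$children_kind == "subscales")
                                      s$children else character())))
      nxt <- setdiff(nxt, reach)
      reach <- c(reach, frontier)
      if (length(nxt) == 0) break
      frontier <- nxt
      if (step > length(subs)) {
        errs <- c(errs, "aggregation tree contains a cycle")
        break
      }
    }
    unreached <- setdiff(sid, reach)
    if (length(unreached)) {
      errs <- c(errs, paste0("subscales unreachable from total: ",
                             paste(unreached, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop("schema validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Count instrument items in a section
#'
#' @param schema A `maps_schema`.
#' @param section One of `"school_access_segment"`, `"other_segment"`,
#'   `"crossing"`.
#' @return Integer count of items collected in that section.
#' @export
#' @examples
#' count_items(load_schema(), "crossing")
count_items <- function(schema, section) {
  if (!section %in% SECTIONS) {
    stop("unknown section '", section, "'; expected one of: ",
         paste(SECTIONS, collapse = ", "))
  }
  sum(vapply(schema$items, function(it) identical(it$section, section), TRUE))
}

#' Summarize schema structure
#'
#' @param schema A `maps_schema`.
#' @return A list with total item count, items per section, and non-total
#'   subscale counts per section.
#' @export
schema_counts <- function(schema) {
  subs <- schema$subscales[setdiff(names(schema$subscales), schema$total_id)]
  ssec <- vapply(subs, `[[`, "", "section")
  list(
    n_items = length(schema$items),
    items_per_section = vapply(SECTIONS, count_items, 0L, schema = schema),
    n_subscales = length(subs),
    subscales_per_section = vapply(SECTIONS, function(s) sum(ssec == s), 0L)
  )
}

#' Diff two schema versions
#'
#' Lists the subscales added, removed, or revised going from `a` to `b`.
#' A subscale present in both counts as revised when its child set or active
#' recode differs.
#'
#' @param a,b `maps_schema` objects over the same section vocabulary.
#' @return A tibble with columns `subscale_id` and
#'   `change` (`added`/`removed`/`revised`).
#' @export
#' @examples
#' diff_versions(load_schema(version = "initial_v1"),
#'               load_schema(version = "final_v2"))
diff_versions <- function(a, b) {
  seca <- sort(unique(vapply(a$items, `[[`, "", "section")))
  secb <- sort(unique(vapply(b$items, `[[`, "", "section")))
  if (!identical(seca, secb)) {
    stop("schemas use different section vocabularies")
  }
  ida <- names(a$subscales)
  idb <- names(b$subscales)
  removed <- setdiff(ida, idb)
  added <- setdiff(idb, ida)
  # a parent whose only change is losing/gaining the added/removed
  # subscales themselves is a knock-on effect, not a revision
  revised <- Filter(function(id) {
    sa <- a$subscales[[id]]
    sb <- b$subscales[[id]]
    ca <- setdiff(sort(sa$children), c(removed, added))
    cb <- setdiff(sort(sb$children), c(removed, added))
    !identical(ca, cb) ||
      !identical(sa$recode_active %||% NA_character_,
                 sb$recode_active %||% NA_character_)
  }, intersect(ida, idb))
  tibble::tibble(
    subscale_id = c(removed, added, unlist(revised)),
    change = rep(c("removed", "added", "revised"),
                 c(length(removed), length(added), length(revised)))
  )
}

#' @export
print.maps_schema <- function(x, ...) {
  cnt <- schema_counts(x)
  cat("MAPS-SRTS scoring schema (", x$version, ")\n", sep = "")
  cat("  items: ", cnt$n_items, " (",
      paste(cnt$items_per_section, collapse = "/"), " per section)\n",
      sep = "")
  cat("  subscales (non-total): ", cnt$n_subscales, " (",
      paste(cnt$subscales_per_section, collapse = "/"), " per section)\n",
      sep = "")
  cat("  total node: ", x$total_id, "\n", sep = "")
  invisible(x)
}

# Items as a data frame (used by the CSV data-dictionary interchange).
item_table <- function(schema) {
  tibble::tibble(
    item_id = vapply(schema$items, `[[`, "", "item_id"),
    section = vapply(schema$items, `[[`, "", "section"),
    prompt = vapply(schema$items, `[[`, "", "prompt"),
    response_domain = vapply(schema$items, function(it) {
      dom <- it$response_domain
      switch(dom$type,
             binary = "binary",
             ordinal = paste0("ordinal:", paste(dom$levels, collapse = ",")),
             count = paste0("count:", dom$max %||% ""),
             categorical = paste0("categorical:",
                                  paste(dom$levels, collapse = ",")))
    }, ""),
    score_map = vapply(schema$items, function(it) {
      if (is.null(it$score_map)) return("")
      paste(names(it$score_map), unlist(it$score_map),
            sep = "=", collapse = ";")
    }, ""),
    valence = vapply(schema$items, `[[`, "", "valence"),
    subscale_id = vapply(schema$items, function(it)
      it$subscale_id %||% NA_character_, "")
  )
}

#' Export / import the item dictionary as CSV
#'
#' Writes (or reads) the item definitions in a flat CSV data-dictionary
#' layout with columns `item_id, section, prompt, response_domain,
#' score_map, valence, subscale_id` for interoperability with spreadsheet
#' tooling. Subscale structure stays in the JSON dictionary.
#'
#' @param schema A `maps_schema`.
#' @param path CSV file path.
#' @return For the writer, `path` invisibly; for the reader, a named list of
#'   item definitions.
#' @export
write_items_csv <- function(schema, path) {
  write.csv(item_table(schema), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_items_csv
#' @export
read_items_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = character())
  need <- c("item_id", "section", "prompt", "response_domain", "score_map",
            "valence", "subscale_id")
  if (!all(need %in% names(df))) {
    stop("item CSV must have columns: ", paste(need, collapse = ", "))
  }
  items <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    spec <- strsplit(row$response_domain, ":", fixed = TRUE)[[1]]
    dom <- switch(spec[[1]],
      binary = list(type = "binary"),
      ordinal = list(type = "ordinal",
                     levels = as.integer(strsplit(spec[[2]], ",")[[1]])),
      count = c(list(type = "count"),
                if (length(spec) > 1 && nzchar(spec[[2]]))
                  list(max = as.integer(spec[[2]]))),
      categorical = list(type = "categorical",
                         levels = strsplit(spec[[2]], ",")[[1]]),
      stop("item ", row$item_id, ": unknown response_domain '",
           row$response_domain, "'")
    )
    smap <- NULL
    if (nzchar(row$score_map)) {
      kv <- strsplit(strsplit(row$score_map, ";", fixed = TRUE)[[1]], "=",
                     fixed = TRUE)
      smap <- lapply(kv, function(p) as.numeric(p[[2]]))
      names(smap) <- vapply(kv, `[[`, "", 1L)
    }
    item_def(row$item_id, row$section, row$prompt, domain = dom,
             score_map = smap, valence = row$valence,
             subscale_id = if (nzchar(row$subscale_id)) row$subscale_id)
  })
  names(items) <- vapply(items, `[[`, "", "item_id")
  items
}
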