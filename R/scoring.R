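# Hierarchical scoring: item points -> leaf subscale sums (summed across
# audited units) -> overall positive/negative per section -> section overall
# (positive minus negative) -> total (sum of the three section overalls).

#' Score one item response
#'
#' Maps a response value to points through the item's score map. Binary
#' items default to 1 point when present; ordinal items score their level
#' index; count items score their value identically unless a score map is
#' declared.
#'
#' @param item An item definition from a `maps_schema` (`schema$items[[id]]`).
#' @param value A response value inside the item's declared domain.
#' @return Numeric points.
#' @export
score_item <- function(item, value) {
  if (!response_in_domain(item, value)) {
    stop("item ", item$item_id, ": response ", value,
         " outside the declared domain")
  }
  if (item$response_domain$type == "count" && is.null(item$score_map)) {
    return(as.numeric(value))
  }
  pts <- item$score_map[[as.character(value)]]
  if (is.null(pts)) {
    stop("item ", item$item_id, ": no score_map entry for response ", value)
  }
  as.numeric(pts)
}

#' Dichotomous road-width recode
#'
#' The revised road-width rule: one negative-valence point when the total
#' number of lanes (travel plus turn) exceeds 4, reflecting the higher
#' pedestrian crash risk of roads wider than 4 lanes; 0 otherwise.
#'
#' @param travel_lanes,turn_lanes Nonnegative integer lane counts
#'   (vectorized).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' dichotomize_road_width(3, 1) # 4 lanes -> 0
#' dichotomize_road_width(4, 1) # 5 lanes -> 1
dichotomize_road_width <- function(travel_lanes, turn_lanes) {
  lanes <- c(travel_lanes, turn_lanes)
  if (any(!is.finite(lanes)) || any(lanes < 0) || any(lanes != round(lanes))) {
    stop("lane counts must be nonnegative integers")
  }
  as.integer(travel_lanes + turn_lanes > 4)
}

# Original road-width coding: the lane sum trichotomized. The bands are a
# reconstruction (<= 2 lanes -> 0, 3-4 -> 1, > 4 -> 2); only the revised
# dichotomy is fully pinned down by the published rule.
trichotomize_road_width <- function(travel_lanes, turn_lanes) {
  lanes <- c(travel_lanes, turn_lanes)
  if (any(!is.finite(lanes)) || any(lanes < 0) || any(lanes != round(lanes))) {
    stop("lane counts must be nonnegative integers")
  }
  total <- travel_lanes + turn_lanes
  ifelse(total <= 2, 0L, ifelse(total <= 4, 1L, 2L))
}

# Per-unit score of a leaf subscale (children are items).
unit_subscale_points <- function(subscale, unit, schema) {
  if (!identical(unit$unit_kind, subscale$section)) {
    stop("unit ", unit$unit_id, " (", unit$unit_kind,
         ") does not belong to section ", subscale$section)
  }
  recode <- subscale$recode_active %||% ""
  if (recode %in% c("dichotomous_gt4", "trichotomous_sum")) {
    # recoded lane-width subscale: children are (travel lanes, turn lanes)
    lanes <- lapply(subscale$children[1:2], function(id) unit$responses[[id]])
    f <- if (recode == "dichotomous_gt4") dichotomize_road_width
         else trichotomize_road_width
    return(f(lanes[[1]], lanes[[2]]))
  }
  sum(vapply(subscale$children, function(id)
    score_item(schema$items[[id]], unit$responses[[id]]), 0))
}

#' Score a leaf subscale over audited units
#'
#' Sums the subscale's item points within each unit and then across units.
#' Scores are summed, not averaged, across units: a school with more
#' audited segments accumulates a larger section score, matching the
#' instrument's aggregate scoring.
#'
#' @param schema A `maps_schema`.
#' @param subscale_id Id of a leaf subscale (children are items).
#' @param units List of [unit_audit()] objects of the subscale's section.
#' @return Numeric score.
#' @export
score_subscale <- function(schema, subscale_id, units) {
  s <- schema$subscales[[subscale_id]]
  if (is.null(s)) stop("unknown subscale '", subscale_id, "'")
  if (!identical(s$children_kind, "items")) {
    stop("subscale '", subscale_id, "' is not a leaf (children are subscales)")
  }
  if (length(units) == 0) return(0)
  sum(vapply(units, unit_subscale_points, 0, subscale = s, schema = schema))
}

#' Score one school audit
#'
#' Computes every subscale score, the per-section overalls (overall =
#' overall positive minus overall negative) and the total (sum of the three
#' section overalls) for one rater pair's audit of one school. A higher
#' total indicates a micro-scale environment more supportive of walking and
#' bicycling to school.
#'
#' @param audit A `maps_audit`.
#' @param schema A `maps_schema`.
#' @param validate Validate the audit first (default `TRUE`).
#' @return A `maps_score_report`: list with `school_id`, `rater_pair_id`,
#'   `subscale_scores` (named, every non-total subscale), `section_overalls`
#'   (named by section) and `total`.
#' @export
score_school <- function(audit, schema, validate = TRUE) {
  if (validate) validate_audits(audit, schema)
  units_by_section <- lapply(SECTIONS, audit_units, audit = audit)
  names(units_by_section) <- SECTIONS
  scores <- new.env(parent = emptyenv())
  node_score <- function(id) {
    if (!is.null(scores[[id]])) return(scores[[id]])
    s <- schema$subscales[[id]]
    val <- if (identical(s$children_kind, "items")) {
      score_subscale(schema, id, units_by_section[[s$section]])
    } else if (identical(s$aggregation, "positive_minus_negative")) {
      vals <- vapply(s$children, function(c)
        schema$subscales[[c]]$valence, "")
      node_score(s$children[vals == "positive"]) -
        node_score(s$children[vals == "negative"])
    } else {
      sum(vapply(s$children, node_score, 0))
    }
    scores[[id]] <- val
    val
  }
  total <- node_score(schema$total_id)
  non_total <- setdiff(names(schema$subscales), schema$total_id)
  subscale_scores <- vapply(non_total, node_score, 0)
  section_nodes <- schema$subscales[[schema$total_id]]$children
  section_overalls <- vapply(section_nodes, node_score, 0)
  names(section_overalls) <- vapply(section_nodes, function(id)
    schema$subscales[[id]]$section, "")
  structure(
    list(school_id = audit$school_id, rater_pair_id = audit$rater_pair_id,
         subscale_scores = subscale_scores,
         section_overalls = section_overalls, total = total),
    class = "maps_score_report"
  )
}

#' @export
print.maps_score_report <- function(x, ...) {
  cat("MAPS-SRTS score report: school ", x$school_id, ", rater pair ",
      x$rater_pair_id, "\n", sep = "")
  for (sec in names(x$section_overalls)) {
    cat(sprintf("  %-22s overall %g\n", sec, x$section_overalls[[sec]]))
  }
  cat("  total:", x$total, "\n")
  invisible(x)
}

#' Score a set of audits into a wide table
#'
#' @param audits List of `maps_audit` objects.
#' @param schema A `maps_schema`.
#' @return A tibble: one row per (school, rater pair), one column per
#'   subscale, the three section overalls and the total.
#' @export
score_audits <- function(audits, schema) {
  if (inherits(audits, "maps_audit")) audits <- list(audits)
  validate_audits(audits, schema)
  rows <- lapply(audits, function(a) {
    r <- score_school(a, schema, validate = FALSE)
    c(list(school_id = r$school_id, rater_pair_id = r$rater_pair_id),
      as.list(r$subscale_scores),
      list(overall_school_access_segment =
             r$section_overalls[["school_access_segment"]],
           overall_other_segment = r$section_overalls[["other_segment"]],
           overall_crossing = r$section_overalls[["crossing"]],
           total = r$total))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
}
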