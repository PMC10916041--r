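# Inter-rater reliability: one-way random-effects single-measure ICC
# (Shrout-Fleiss ICC(1,1)) with the exact F-based confidence interval,
# acceptability classification, subscale retention decision rules, and
# stepwise item pruning.

#' One-way random-effects single-measure ICC
#'
#' Estimates ICC(1,1) from a complete subjects-by-raters matrix. With
#' subject means \eqn{\bar y_i} and grand mean \eqn{\bar y}:
#' \deqn{MSB = k \sum_i (\bar y_i - \bar y)^2 / (n - 1), \quad
#'       MSW = \sum_{ij} (y_{ij} - \bar y_i)^2 / (n (k - 1))}
#' \deqn{ICC = (MSB - MSW) / (MSB + (k - 1) MSW)}
#' The 95\% (or `1 - alpha`) confidence interval maps the F-quantiles of
#' \eqn{F = MSB/MSW} on \eqn{(n-1, n(k-1))} degrees of freedom through
#' \eqn{(F^* - 1)/(F^* + k - 1)}. When the matrix has no variability at all
#' the ICC is undefined and returned as such (mirroring "N/A" reliability
#' entries), never silently as 0. Perfect agreement with between-subject
#' spread gives an estimate of 1 with no finite interval.
#'
#' @param values Complete numeric n x k matrix (n subjects/schools in rows,
#'   k raters/rater pairs in columns), n >= 2, k >= 2; or the result of
#'   [build_rating_matrix()].
#' @param alpha Two-sided interval level is `1 - alpha` (default 0.05).
#' @return A `maps_icc` object: list with `estimate`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_raters`, `msb`, `msw`, `alpha`, `subscale_id` (if the
#'   matrix carried one) and `undefined_reason` (`NULL` or
#'   `"no_variability"`).
#' @references Shrout, P. E. & Fleiss, J. L. (1979). Intraclass
#'   correlations: uses in assessing rater reliability. Psychological
#'   Bulletin, 86(2), 420-428.
#' @export
#' @examples
#' m <- cbind(c(1, 3, 5, 7, 9), c(2, 3, 4, 8, 9))
#' icc_oneway(m)
icc_oneway <- function(values, alpha = 0.05) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (anyNA(values)) stop("rating matrix must be complete (no missing cells)")
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2) stop("need at least 2 subjects (n >= 2)")
  if (k < 2) stop("need at least 2 raters (k >= 2)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  row_means <- rowMeans(values)
  grand <- mean(values)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((values - row_means)^2) / (n * (k - 1))
  out <- list(subscale_id = attr(values, "subscale_id"),
              estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_subjects = n, k_raters = k, msb = msb, msw = msw,
              alpha = alpha, undefined_reason = NULL)
  if (msb == 0 && msw == 0) {
    out$undefined_reason <- "no_variability"
    return(structure(out, class = "maps_icc"))
  }
  out$estimate <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw > 0) {
    f0 <- msb / msw
    df1 <- n - 1
    df2 <- n * (k - 1)
    fl <- f0 / qf(1 - alpha / 2, df1, df2)
    fu <- f0 * qf(1 - alpha / 2, df2, df1)
    out$ci_low <- (fl - 1) / (fl + k - 1)
    out$ci_high <- (fu - 1) / (fu + k - 1)
  }
  structure(out, class = "maps_icc")
}

#' @export
print.maps_icc <- function(x, ...) {
  lab <- if (!is.null(x$subscale_id)) paste0(" [", x$subscale_id, "]") else ""
  if (!is.null(x$undefined_reason)) {
    cat("ICC(1)", lab, ": undefined (", x$undefined_reason, ")\n", sep = "")
  } else if (is.na(x$ci_low)) {
    cat(sprintf("ICC(1)%s = %.3f (CI N/A; no within-subject variability)\n",
                lab, x$estimate))
  } else {
    cat(sprintf("ICC(1)%s = %.3f (%d%% CI %.3f, %.3f)\n", lab, x$estimate,
                round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  }
  cat(sprintf("  n = %d subjects, k = %d raters; MSB = %.4g, MSW = %.4g\n",
              x$n_subjects, x$k_raters, x$msb, x$msw))
  invisible(x)
}

#' Classify a reliability estimate
#'
#' @param result A `maps_icc`.
#' @param threshold Acceptability threshold; the boundary is inclusive
#'   (an ICC of 0.60 or higher counts as acceptable under the default).
#' @return `"acceptable"`, `"below_threshold"` or `"undefined"`.
#' @export
classify_reliability <- function(result, threshold = 0.60) {
  if (!is.null(result$undefined_reason) || is.na(result$estimate)) {
    return("undefined")
  }
  if (result$estimate >= threshold) "acceptable" else "below_threshold"
}

#' ICC table over every subscale
#'
#' Builds the rating matrix and the ICC for each non-total subscale and the
#' total score.
#'
#' @param audits List of `maps_audit` objects covering a complete
#'   schools x rater-pairs design.
#' @param schema A `maps_schema`.
#' @param threshold Acceptability threshold (default 0.60).
#' @param alpha Interval level (default 0.05).
#' @return A tibble: `subscale_id`, `n`, `k`, `icc`, `ci_low`, `ci_high`,
#'   `classification`.
#' @export
icc_table <- function(audits, schema, threshold = 0.60, alpha = 0.05) {
  reports <- lapply(audits, score_school, schema = schema)
  scorer <- function(id) {
    function(audit, schema) {
      r <- reports[[which(vapply(audits, function(a)
        identical(a$school_id, audit$school_id) &&
          identical(a$rater_pair_id, audit$rater_pair_id), TRUE))[1]]]
      if (identical(id, schema$total_id)) r$total
      else r$subscale_scores[[id]]
    }
  }
  ids <- c(setdiff(names(schema$subscales), schema$total_id),
           schema$total_id)
  rows <- lapply(ids, function(id) {
    m <- build_rating_matrix(audits, id, schema, scorer = scorer(id))
    res <- icc_oneway(m, alpha = alpha)
    tibble::tibble(subscale_id = id, n = res$n_subjects, k = res$k_raters,
                   icc = res$estimate, ci_low = res$ci_low,
                   ci_high = res$ci_high,
                   classification = classify_reliability(res, threshold))
  })
  do.call(rbind, rows)
}

#' Apply the subscale retention decision rules
#'
#' Given the initial reliability classification of every non-total
#' subscale, decides which subscales stay in the instrument:
#' \itemize{
#'   \item acceptable reliability: retained;
#'   \item registered revision (a recode restoring reliability, e.g. the
#'     road-width dichotomy): revised and retained;
#'   \item unacceptable or undefined, but the counterpart subscale with the
#'     same item content in another section is acceptable: retained
#'     (`retain_by_counterpart`);
#'   \item otherwise: removed.
#' }
#' Removed subscales leave the aggregation tree; composite parents are
#' re-derived over their remaining children and the items of removed
#' subscales are kept as unscored (so existing audits re-score without data
#' loss).
#'
#' @param classifications Named character vector
#'   (`subscale_id -> "acceptable"/"below_threshold"/"undefined"`) covering
#'   every non-total subscale of `schema`.
#' @param schema The `maps_schema` the classifications refer to (typically
#'   the initial version).
#' @param revisions Character vector of subscale ids with a registered
#'   recode (revision) restoring reliability.
#' @return List with `schema` (the revised schema) and `decisions` (tibble:
#'   `subscale_id`, `action`, `rationale`).
#' @export
apply_retention_rules <- function(classifications, schema,
                                  revisions = character()) {
  non_total <- setdiff(names(schema$subscales), schema$total_id)
  missing <- setdiff(non_total, names(classifications))
  if (length(missing)) {
    stop("classification missing for subscale(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(classifications),
                 c("acceptable", "below_threshold", "undefined"))
  if (length(bad)) stop("unknown classification value(s): ",
                        paste(bad, collapse = ", "))
  decide <- function(id) {
    cls <- classifications[[id]]
    if (id %in% revisions) {
      return(c("revise", "recoded"))
    }
    if (cls == "acceptable") return(c("retain", "acceptable"))
    ctr <- schema$subscales[[id]]$counterpart_id
    if (!is.null(ctr) && !is.na(ctr) && ctr %in% names(classifications) &&
        classifications[[ctr]] == "acceptable") {
      return(c("retain_by_counterpart", "low_icc_counterpart_reliable"))
    }
    c("remove", "low_icc_no_counterpart")
  }
  dec <- vapply(non_total, decide, character(2))
  decisions <- tibble::tibble(subscale_id = non_total,
                              action = dec[1, ], rationale = dec[2, ])
  removed <- decisions$subscale_id[decisions$action == "remove"]
  revised <- drop_subscales(schema, removed)
  for (id in intersect(names(revised$subscales), removed)) {
    revised$subscales[[id]] <- NULL # defensive; drop_subscales removed them
  }
  for (id in intersect(decisions$subscale_id[decisions$action == "revise"],
                       names(revised$subscales))) {
    s <- revised$subscales[[id]]
    if (!is.null(s$recode) && !is.null(s$recode$final)) {
      s$recode_active <- s$recode$final
      s$status <- "revised"
      revised$subscales[[id]] <- s
    }
  }
  validate_schema(revised)
  list(schema = revised, decisions = decisions)
}

#' Stepwise pruning of an unreliable subscale
#'
#' Removes the least reliable child one at a time, recomputing the parent's
#' ICC after each removal, until the parent reaches acceptable reliability
#' or a single child remains. This mirrors the stepwise process used to
#' assess how removing low-reliability items affects the reliability of
#' their subscale.
#'
#' @param matrix_builder Function taking a character vector of child ids and
#'   returning the subjects x raters rating matrix for the subscale
#'   restricted to those children (called with a single id to obtain a
#'   child's own matrix).
#' @param child_ids Children of the subscale under scrutiny (length >= 2 for
#'   any pruning to be possible).
#' @param threshold Acceptability threshold (default 0.60).
#' @param alpha Interval level (default 0.05).
#' @return A tibble trace with one row per removal step: `step`,
#'   `removed_child`, `child_icc`, `parent_icc_after`, `classification`.
#'   Zero rows when the parent is already acceptable.
#' @export
stepwise_prune <- function(matrix_builder, child_ids, threshold = 0.60,
                           alpha = 0.05) {
  est <- function(ids) {
    res <- icc_oneway(matrix_builder(ids), alpha = alpha)
    list(res = res, cls = classify_reliability(res, threshold))
  }
  trace <- list()
  remaining <- child_ids
  parent <- est(remaining)
  step <- 0L
  while (parent$cls != "acceptable" && length(remaining) > 1) {
    child_est <- vapply(remaining, function(id) {
      e <- est(id)
      if (e$cls == "undefined") -Inf else e$res$estimate
    }, 0)
    worst <- remaining[which.min(child_est)]
    remaining <- setdiff(remaining, worst)
    parent <- est(remaining)
    step <- step + 1L
    trace[[step]] <- tibble::tibble(
      step = step, removed_child = worst,
      child_icc = ifelse(is.finite(child_est[worst]), child_est[worst],
                         NA_real_),
      parent_icc_after = parent$res$estimate,
      classification = parent$cls)
  }
  if (length(trace) == 0) {
    return(tibble::tibble(step = integer(), removed_child = character(),
                          child_icc = numeric(),
                          parent_icc_after = numeric(),
                          classification = character()))
  }
  do.call(rbind, trace)
}
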