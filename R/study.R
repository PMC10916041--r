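# End-to-end reliability study: score -> ICC per subscale -> classify ->
# retention decision rules -> revised schema + report bundle.

#' Run a full reliability study
#'
#' Reproduces the instrument-revision workflow on a set of paired-rater
#' audits: scores every audit under the supplied (typically initial)
#' schema, estimates the one-way single-measure ICC for every non-total
#' subscale and the total, classifies each against the acceptability
#' threshold, optionally revises subscales that have a registered recode
#' (the road-width dichotomy), applies the retention decision rules, and
#' returns — and optionally writes — the full report bundle.
#'
#' With `revisions = "auto"`, any failing leaf subscale that declares an
#' alternative recode is re-scored under that recode and its ICC
#' recomputed; it is recorded as revised when the recode is applied.
#' Explicit subscale ids can be supplied instead.
#'
#' @param audits List of `maps_audit` objects: at least 2 schools, each
#'   audited by the same >= 2 rater pairs.
#' @param schema A `maps_schema`, typically `load_schema(version =
#'   "initial_v1")`.
#' @param threshold ICC acceptability threshold (default 0.60; the boundary
#'   is inclusive).
#' @param alpha Confidence interval level is `1 - alpha` (default 0.05).
#' @param revisions `"auto"` (default) or a character vector of subscale
#'   ids to revise via their registered recode.
#' @param out_dir Optional output directory; when given, writes
#'   `scores.csv`, `icc.csv`, `decisions.csv`, `schema_revised.json` and
#'   `summary.txt`.
#' @return A `maps_study` object: list with `scores` (tibble), `icc`
#'   (tibble, including post-revision rows for revised subscales),
#'   `decisions` (tibble), `schema_initial`, `schema_revised`, `summary`
#'   (named counts and retention percentage).
#' @export
run_reliability_study <- function(audits, schema, threshold = 0.60,
                                  alpha = 0.05, revisions = "auto",
                                  out_dir = NULL) {
  if (length(audits) == 0) stop("no audits supplied")
  validate_audits(audits, schema)
  schools <- unique(vapply(audits, `[[`, "", "school_id"))
  raters <- unique(vapply(audits, `[[`, "", "rater_pair_id"))
  if (length(schools) < 2 || length(raters) < 2) {
    stop("reliability study needs >= 2 schools audited by >= 2 rater pairs")
  }
  scores <- score_audits(audits, schema)
  icc0 <- icc_table(audits, schema, threshold = threshold, alpha = alpha)
  icc0$stage <- "initial"
  non_total <- setdiff(names(schema$subscales), schema$total_id)
  cls <- icc0$classification[match(non_total, icc0$subscale_id)]
  names(cls) <- non_total

  # revisions: failing subscales with a registered alternative recode
  revisable <- names(schema$subscales)[vapply(schema$subscales, function(s)
    !is.null(s$recode) && !identical(s$recode_active %||% "",
                                     s$recode$final), TRUE)]
  rev_ids <- if (identical(revisions, "auto")) {
    intersect(revisable, non_total[cls != "acceptable"])
  } else {
    setdiff(intersect(revisions, revisable), character(0))
  }
  icc_rev <- NULL
  schema_rev_coding <- schema
  if (length(rev_ids)) {
    for (id in rev_ids) {
      s <- schema_rev_coding$subscales[[id]]
      s$recode_active <- s$recode$final
      s$status <- "revised"
      schema_rev_coding$subscales[[id]] <- s
    }
    rows <- lapply(rev_ids, function(id) {
      m <- build_rating_matrix(audits, id, schema_rev_coding)
      res <- icc_oneway(m, alpha = alpha)
      tibble::tibble(subscale_id = id, n = res$n_subjects,
                     k = res$k_raters, icc = res$estimate,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     classification = classify_reliability(res, threshold),
                     stage = "revised")
    })
    icc_rev <- do.call(rbind, rows)
  }
  retained <- apply_retention_rules(cls, schema_rev_coding,
                                    revisions = rev_ids)
  decisions <- retained$decisions
  icc <- rbind(icc0, icc_rev)
  n_by_action <- table(factor(decisions$action,
                              levels = c("retain", "retain_by_counterpart",
                                         "revise", "remove")))
  summary <- list(
    n_subscales_initial = length(non_total),
    n_initially_acceptable = sum(cls == "acceptable"),
    n_removed = unname(n_by_action[["remove"]]),
    n_revised = unname(n_by_action[["revise"]]),
    n_retained_by_counterpart = unname(n_by_action[["retain_by_counterpart"]]),
    n_retained = length(non_total) - unname(n_by_action[["remove"]]),
    retention_pct = 100 * (length(non_total) - n_by_action[["remove"]]) /
      length(non_total),
    threshold = threshold, alpha = alpha
  )
  bundle <- structure(
    list(scores = scores, icc = icc, decisions = decisions,
         schema_initial = schema, schema_revised = retained$schema,
         summary = summary),
    class = "maps_study"
  )
  if (!is.null(out_dir)) write_study(bundle, out_dir)
  bundle
}

#' @export
print.maps_study <- function(x, ...) {
  s <- x$summary
  cat("MAPS-SRTS reliability study\n")
  cat(sprintf("  subscales tested: %d; initially acceptable: %d\n",
              s$n_subscales_initial, s$n_initially_acceptable))
  cat(sprintf("  removed: %d; revised: %d; retained via counterpart: %d\n",
              s$n_removed, s$n_revised, s$n_retained_by_counterpart))
  cat(sprintf("  retained in final schema: %d (%.1f%%)\n", s$n_retained,
              s$retention_pct))
  invisible(x)
}

write_study <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$scores, file.path(out_dir, "scores.csv"),
            row.names = FALSE)
  write.csv(bundle$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  write.csv(bundle$decisions, file.path(out_dir, "decisions.csv"),
            row.names = FALSE)
  write_schema(bundle$schema_revised,
               file.path(out_dir, "schema_revised.json"))
  s <- bundle$summary
  writeLines(c(
    "MAPS-SRTS reliability study summary",
    sprintf("threshold: %.2f (inclusive); alpha: %.2f", s$threshold,
            s$alpha),
    sprintf("subscales tested: %d", s$n_subscales_initial),
    sprintf("initially acceptable: %d", s$n_initially_acceptable),
    sprintf("removed: %d", s$n_removed),
    sprintf("revised: %d", s$n_revised),
    sprintf("retained via counterpart: %d", s$n_retained_by_counterpart),
    sprintf("retained in final schema: %d (%.1f%%)", s$n_retained,
            s$retention_pct)
  ), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
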