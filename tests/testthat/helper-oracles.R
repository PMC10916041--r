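# Independent oracles and fixture builders shared across the test files.

# ICC(1,1) via R's linear-model ANOVA decomposition: an independent route
# to the mean squares (the package computes them in closed form).
oracle_icc <- function(values, alpha = 0.05) {
  n <- nrow(values)
  k <- ncol(values)
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)))
  ms <- anova(lm(y ~ subject, df))$`Mean Sq`
  msb <- ms[[1]]
  msw <- ms[[2]]
  est <- (msb - msw) / (msb + (k - 1) * msw)
  f0 <- msb / msw
  fl <- f0 / qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f0 * qf(1 - alpha / 2, n * (k - 1), n - 1)
  list(estimate = est, ci_low = (fl - 1) / (fl + k - 1),
       ci_high = (fu - 1) / (fu + k - 1), msb = msb, msw = msw)
}

# Naive leaf-first tree walk over the aggregation hierarchy, with direct
# score-map lookups and an explicit double loop over units and items.
oracle_score_school <- function(audit, schema) {
  units <- c(audit$access_segments, audit$other_segments, audit$crossings)
  vals <- list()
  for (s in schema$subscales) {
    if (!identical(s$children_kind, "items")) next
    total <- 0
    for (u in units) {
      if (!identical(u$unit_kind, s$section)) next
      rec <- s$recode_active
      if (!is.null(rec)) {
        lanes <- u$responses[[s$children[[1]]]] +
          u$responses[[s$children[[2]]]]
        total <- total + switch(rec,
          dichotomous_gt4 = if (lanes > 4) 1 else 0,
          trichotomous_sum = if (lanes <= 2) 0 else if (lanes <= 4) 1 else 2)
      } else {
        for (id in s$children) {
          it <- schema$items[[id]]
          v <- u$responses[[id]]
          total <- total +
            if (it$response_domain$type == "count" && is.null(it$score_map))
              v else it$score_map[[as.character(v)]]
        }
      }
    }
    vals[[s$subscale_id]] <- total
  }
  # resolve parents by repeated passes until the tree is exhausted
  repeat {
    progressed <- FALSE
    for (s in schema$subscales) {
      if (identical(s$children_kind, "items") ||
          !is.null(vals[[s$subscale_id]])) next
      if (!all(s$children %in% names(vals))) next
      kid <- unlist(vals[s$children])
      vals[[s$subscale_id]] <- if (identical(s$aggregation,
                                             "positive_minus_negative")) {
        vl <- vapply(s$children, function(c)
          schema$subscales[[c]]$valence, "")
        kid[[which(vl == "positive")]] - kid[[which(vl == "negative")]]
      } else {
        sum(kid)
      }
      progressed <- TRUE
    }
    if (!progressed) break
  }
  vals
}

# Uniform random (valid) audit for property tests: every item of every
# section drawn uniformly from its declared domain.
random_audit <- function(schema, school_id = "s1", rater_pair_id = "r1",
                         n_access = 1, n_other = 1, n_crossings = 1) {
  draw <- function(it) {
    dom <- it$response_domain
    switch(dom$type,
           binary = sample(0:1, 1),
           ordinal = sample(dom$levels, 1),
           count = sample(0:(dom$max %||% 6), 1),
           categorical = sample(dom$levels, 1))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  section_items <- function(sec) Filter(function(it)
    identical(it$section, sec), schema$items)
  mk_units <- function(sec, n, prefix) {
    its <- section_items(sec)
    lapply(seq_len(n), function(i) {
      resp <- vapply(its, draw, 0)
      names(resp) <- names(its)
      unit_audit(sprintf("%s%02d", prefix, i), sec, resp)
    })
  }
  school_audit(
    school_id, rater_pair_id,
    access_segments = mk_units("school_access_segment", n_access, "a"),
    other_segments = mk_units("other_segment", n_other, "o"),
    crossings = mk_units("crossing", n_crossings, "c")
  )
}

# Paired-rater audit set with engineered low agreement on the buffer and
# shade subscales of both segment-type sections (the revision scenario).
engineered_low_agreement_audits <- function(schema, n_schools = 36,
                                            seed = 42) {
  net <- generate_grid_network(3, 3)
  targets <- c(sas_positive_buffer = 0.05, sas_positive_shade = 0.05,
               seg_positive_buffer = 0.05, seg_positive_shade = 0.05,
               default = 0.95)
  generate_rater_audits(schema, net, agreement_spec(
    target_icc = targets, n_schools = n_schools, seed = seed))
}

# The worked-example initial reliability classifications: 8 of the 30
# initial subscales failed (buffer and shade in both segment-type sections,
# bicycle infrastructure on the access segment lacking variability, the
# overall positive and overall access-segment composites, and road width).
worked_example_classifications <- function(schema) {
  ids <- setdiff(names(schema$subscales), schema$total_id)
  cls <- stats::setNames(rep("acceptable", length(ids)), ids)
  cls[c("sas_positive_buffer", "sas_positive_shade",
        "seg_positive_buffer", "seg_positive_shade",
        "sas_overall_positive", "sas_overall", "cr_road_width")] <-
    "below_threshold"
  cls["sas_positive_bicycle_infrastructure"] <- "undefined"
  cls
}
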