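# Synthetic street networks and paired-rater audit data with calibrated
# agreement, so scoring, reliability and route selection are testable
# end-to-end without field data.

#' Generate a rectangular grid street network
#'
#' Builds a blocks_x by blocks_y city grid with 4-way interior
#' intersections, places the school mid-block on the south edge of the
#' chosen block (frontage declared via `access_edge_ids`), and annotates
#' the requested number of school driveways on the access segment. The
#' construction is fully deterministic; `seed` is accepted for interface
#' stability.
#'
#' @param blocks_x,blocks_y Number of blocks in each direction (>= 1).
#' @param school_block Integer pair `c(i, j)` (1-based block indices);
#'   defaults to a central block.
#' @param driveways Number of school entrance/exit driveways on the access
#'   segment.
#' @param seed Unused; the construction is deterministic.
#' @return A `street_network`.
#' @export
#' @examples
#' net <- generate_grid_network(3, 3)
#' count_route_units(select_route(net))
generate_grid_network <- function(blocks_x, blocks_y,
                                  school_block = ceiling(c(blocks_x,
                                                           blocks_y) / 2),
                                  driveways = 0, seed = NULL) {
  stopifnot(blocks_x >= 1, blocks_y >= 1)
  i <- school_block[[1]]
  j <- school_block[[2]]
  if (i < 1 || i > blocks_x || j < 1 || j > blocks_y) {
    stop("school_block (", i, ", ", j, ") outside the ", blocks_x, "x",
         blocks_y, " grid")
  }
  xs <- 0:blocks_x
  ys <- 0:blocks_y
  grid <- expand.grid(x = xs, y = ys)
  nodes <- data.frame(id = sprintf("n_%d_%d", grid$x, grid$y),
                      x = as.numeric(grid$x), y = as.numeric(grid$y),
                      kind = "intersection", on_edge = NA_character_,
                      stringsAsFactors = FALSE)
  h <- expand.grid(x = 0:(blocks_x - 1), y = ys)
  v <- expand.grid(x = xs, y = 0:(blocks_y - 1))
  edges <- rbind(
    data.frame(id = sprintf("h_%d_%d", h$x, h$y),
               node_a = sprintf("n_%d_%d", h$x, h$y),
               node_b = sprintf("n_%d_%d", h$x + 1, h$y),
               street_name = sprintf("EW street %d", h$y),
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("v_%d_%d", v$x, v$y),
               node_a = sprintf("n_%d_%d", v$x, v$y),
               node_b = sprintf("n_%d_%d", v$x, v$y + 1),
               street_name = sprintf("NS street %d", v$x),
               stringsAsFactors = FALSE)
  )
  access <- sprintf("h_%d_%d", i - 1, j - 1)
  if (driveways > 0) {
    frac <- seq_len(driveways) / (driveways + 1)
    nodes <- rbind(nodes, data.frame(
      id = sprintf("d_%d", seq_len(driveways)),
      x = (i - 1) + frac, y = j - 1, kind = "driveway",
      on_edge = access, stringsAsFactors = FALSE))
  }
  school <- list(entrance_point = c(i - 0.5, j - 1),
                 access_edge_ids = access,
                 driveway_ids = if (driveways > 0)
                   sprintf("d_%d", seq_len(driveways)) else character())
  street_network(nodes, edges, school)
}

#' Agreement specification for synthetic paired-rater audits
#'
#' Describes the simulated study design: how many schools, how many
#' independent rater pairs, the between-school spread of item propensities
#' and the target intraclass correlation per subscale. The rater-noise
#' level is derived from the target ICC, so the generated subscale scores
#' have (approximately) the requested population reliability.
#'
#' @param target_icc Target ICC in (0, 1]; either a single default for all
#'   scored subscales or a named vector keyed by leaf subscale id (unnamed
#'   element or `default` entry acts as the default). A target of 1 means
#'   zero rater noise.
#' @param n_schools Number of schools (subjects). The study this design
#'   emulates audited 36 schools with a 5-school reliability subsample.
#' @param k_rater_pairs Number of independent rater pairs (default 2).
#' @param between_school_sd Between-school standard deviation of the item
#'   propensity on the logit scale (default 1.5).
#' @param seed Integer seed driving all randomness.
#' @return An `agreement_spec` object.
#' @export
agreement_spec <- function(target_icc = 0.8, n_schools = 36,
                           k_rater_pairs = 2, between_school_sd = 1.5,
                           seed = 1L) {
  if (any(target_icc <= 0) || any(target_icc > 1)) {
    stop("target_icc must lie in (0, 1]")
  }
  if (between_school_sd <= 0) stop("between_school_sd must be positive")
  if (n_schools < 2 || k_rater_pairs < 2) {
    stop("need n_schools >= 2 and k_rater_pairs >= 2")
  }
  structure(list(target_icc = target_icc, n_schools = n_schools,
                 k_rater_pairs = k_rater_pairs,
                 between_school_sd = between_school_sd,
                 seed = as.integer(seed)),
            class = "agreement_spec")
}

target_for <- function(spec, subscale_id) {
  t <- spec$target_icc
  if (is.null(names(t))) return(t[[1]])
  if (subscale_id %in% names(t)) return(t[[subscale_id]])
  if ("default" %in% names(t)) return(t[["default"]])
  unnamed <- t[names(t) == ""]
  if (length(unnamed)) return(unnamed[[1]])
  max(t)
}

# Variance components of the per-school presence propensity p = plogis(eta),
# eta ~ N(0, sd^2), by quadrature on normal quantiles.
logit_normal_moments <- function(sd, grid = 2001) {
  z <- stats::qnorm(seq(0.5, grid - 0.5) / grid)
  p <- plogis(sd * z)
  list(var_p = var(p) * (grid - 1) / grid, e_pq = mean(p * (1 - p)))
}

# Solve the rater-noise probability eps so that the population ICC of a
# rater pair's subscale sum equals the target. Both raters share the school
# propensity p_s and the realized per-unit item truths; the noise model and
# its variance bookkeeping depend on the response domain:
#
#   binary (m items x u units, truth T ~ Binomial(mu, p_s), symmetric flips
#   w.p. e in [0, 0.5)): subject variance (1-2e)^2 Var(T), within variance
#   mu e(1-e), Var(T) = mu^2 Var(p) + mu E[p(1-p)].
#
#   ordinal (levels 0..L, one truth per unit ~ Binomial(L, p_s), uniform
#   resampling w.p. e in [0, 1]): subject variance (1-e)^2 Var(T_sum),
#   within variance u [e(1-e) Var(T_unit) + e Var(U)].
#
#   count (additive mean-zero +/-1 perturbation w.p. e in [0, 1]): the
#   conditional mean is unchanged, so the subject variance is Var(T_sum)
#   and the within variance m u e; reliability cannot drop below
#   Var(T_sum)/(Var(T_sum) + m u), and targets under that floor error out.
#
# Every model is continuous and monotone in e, so the target is found by
# uniroot; infeasible targets raise an error stating the attainable range.
calibrate_flip_rate <- function(target_icc, n_items, n_units,
                                between_school_sd, domain = "binary",
                                ordinal_levels = 0:3) {
  if (target_icc >= 1) return(0)
  mom <- logit_normal_moments(between_school_sd)
  m <- n_items
  u <- n_units
  if (domain == "binary") {
    mu <- m * u
    var_t <- mu^2 * mom$var_p + mu * mom$e_pq
    icc_of <- function(e) {
      vs <- (1 - 2 * e)^2 * var_t
      vs / (vs + mu * e * (1 - e))
    }
    hi <- 0.5 - 1e-9
  } else if (domain == "ordinal") {
    L <- max(ordinal_levels) - min(ordinal_levels)
    var_unit <- L^2 * mom$var_p + L * mom$e_pq
    var_sum <- u^2 * L^2 * mom$var_p + u * L * mom$e_pq
    var_u <- (length(ordinal_levels)^2 - 1) / 12
    icc_of <- function(e) {
      vs <- (1 - e)^2 * var_sum
      vs / (vs + u * (e * (1 - e) * var_unit + e * var_u))
    }
    hi <- 1
  } else if (domain == "count") {
    # truth variance of the lane sum: travel ~ 2 + Binom(3, p), turn ~
    # Binom(2, p) per unit, shared p_s across units
    var_sum <- u^2 * 25 * mom$var_p + u * 5 * mom$e_pq
    icc_of <- function(e) var_sum / (var_sum + m * u * e)
    hi <- 1
  } else {
    stop("unsupported domain '", domain, "' for agreement calibration")
  }
  if (icc_of(0) <= 0) {
    stop("no between-school variability at this design; target ICC of ",
         target_icc, " is infeasible (increase between_school_sd)")
  }
  floor_icc <- icc_of(hi)
  if (floor_icc >= target_icc) {
    stop(sprintf(paste0(
      "target ICC %.3g infeasible for a %s-response subscale at this ",
      "design: attainable range is (%.3g, 1]"), target_icc, domain,
      floor_icc))
  }
  uniroot(function(e) icc_of(e) - target_icc, c(1e-12, hi),
          tol = 1e-12)$root
}

#' Generate synthetic paired-rater audits
#'
#' For every school, draws a latent per-subscale propensity (the
#' between-school component, on the logit scale), realizes item truths per
#' audited unit from it, and lets each rater pair observe the truths with
#' independent symmetric error at a rate calibrated so the subscale-level
#' population ICC matches `spec$target_icc`. Binary items flip; ordinal
#' items are re-sampled uniformly from their levels; lane counts are
#' perturbed by one lane. Every generated dataset validates against the
#' schema, and identical spec + seed reproduce identical audits.
#'
#' @param schema A `maps_schema`.
#' @param network A `street_network`; its observation route fixes the
#'   audited units per school.
#' @param spec An [agreement_spec()].
#' @return List of `maps_audit` objects (`n_schools * k_rater_pairs`).
#' @export
#' @examples
#' sch <- load_schema(version = "initial_v1")
#' net <- generate_grid_network(3, 3)
#' audits <- generate_rater_audits(sch, net, agreement_spec(
#'   target_icc = 0.9, n_schools = 5, seed = 7))
#' length(audits)
generate_rater_audits <- function(schema, network, spec) {
  stopifnot(inherits(spec, "agreement_spec"))
  route <- select_route(network)
  unit_templates <- rbind(
    data.frame(unit_id = route$access_segments,
               unit_kind = "school_access_segment",
               stringsAsFactors = FALSE),
    data.frame(unit_id = route$other_segments$edge_id,
               unit_kind = "other_segment", stringsAsFactors = FALSE),
    data.frame(unit_id = route$crossings, unit_kind = "crossing",
               stringsAsFactors = FALSE)
  )
  n_units <- table(factor(unit_templates$unit_kind, levels = SECTIONS))
  schools <- sprintf("school_%03d", seq_len(spec$n_schools))
  raters <- sprintf("pair_%d", seq_len(spec$k_rater_pairs))
  leaf <- Filter(function(s) identical(s$children_kind, "items"),
                 schema$subscales)
  default_target <- if (is.null(names(spec$target_icc))) {
    spec$target_icc[[1]]
  } else if ("default" %in% names(spec$target_icc)) {
    spec$target_icc[["default"]]
  } else if (any(names(spec$target_icc) == "")) {
    spec$target_icc[[which(names(spec$target_icc) == "")[1]]]
  } else {
    max(spec$target_icc)
  }
  default_eps <- calibrate_flip_rate(default_target, 1, 1,
                                     spec$between_school_sd)
  set.seed(spec$seed)
  # one long response table per (school, rater, unit, item), filled leaf by
  # leaf so draws stay in a fixed order regardless of platform
  rows <- list()
  emit <- function(item_id, section, value_matrix) {
    # value_matrix: (n_schools * units_in_section) x k_rater_pairs
    units <- unit_templates$unit_id[unit_templates$unit_kind == section]
    for (r in seq_along(raters)) {
      rows[[length(rows) + 1]] <<- data.frame(
        school_id = rep(schools, each = length(units)),
        rater_pair_id = raters[[r]],
        unit_id = paste(rep(schools, each = length(units)),
                        rep(units, times = length(schools)), sep = "."),
        unit_kind = section, item_id = item_id,
        value = value_matrix[, r], stringsAsFactors = FALSE)
    }
  }
  for (sid in names(leaf)) {
    s <- leaf[[sid]]
    u <- as.integer(n_units[[s$section]])
    if (u == 0) next
    m <- length(s$children)
    target <- target_for(spec, sid)
    dom_types <- unique(vapply(s$children, function(id)
      schema$items[[id]]$response_domain$type, ""))
    cal_domain <- if (length(dom_types) == 1 &&
                        dom_types %in% c("binary", "ordinal", "count")) {
      dom_types
    } else {
      "binary" # mixed-domain subscale: binary flips as the approximation
    }
    lev <- if (cal_domain == "ordinal") {
      schema$items[[s$children[[1]]]]$response_domain$levels
    } else 0:3
    eps <- calibrate_flip_rate(target, m, u, spec$between_school_sd,
                               domain = cal_domain, ordinal_levels = lev)
    p_school <- plogis(rnorm(spec$n_schools, 0, spec$between_school_sd))
    p_rep <- rep(p_school, each = u)
    for (item_id in s$children) {
      it <- schema$items[[item_id]]
      dom <- it$response_domain
      n_slots <- spec$n_schools * u
      if (dom$type == "binary") {
        truth <- rbinom(n_slots, 1, p_rep)
        obs <- vapply(seq_along(raters), function(r) {
          flip <- rbinom(n_slots, 1, eps)
          ifelse(flip == 1, 1 - truth, truth)
        }, numeric(n_slots))
      } else if (dom$type == "ordinal") {
        kmax <- max(dom$levels)
        truth <- rbinom(n_slots, kmax, p_rep) + min(dom$levels)
        obs <- vapply(seq_along(raters), function(r) {
          redraw <- rbinom(n_slots, 1, eps)
          alt <- sample(dom$levels, n_slots, replace = TRUE)
          ifelse(redraw == 1, alt, truth)
        }, numeric(n_slots))
      } else if (dom$type == "count") {
        cap <- dom$max %||% 10L
        base <- if (grepl("travel", item_id)) 2L else 0L
        truth <- pmin(base + rbinom(n_slots, 3, p_rep), cap)
        obs <- vapply(seq_along(raters), function(r) {
          bump <- rbinom(n_slots, 1, eps) * sample(c(-1, 1), n_slots,
                                                   replace = TRUE)
          pmin(pmax(truth + bump, 0), cap)
        }, numeric(n_slots))
      } else {
        stop("unsupported response domain '", dom$type,
             "' in synthetic generation")
      }
      if (!is.matrix(obs)) obs <- matrix(obs, nrow = 1)
      emit(item_id, s$section, obs)
    }
  }
  # unscored items: shared truth, default-level disagreement
  unscored <- Filter(function(it) is.null(it$subscale_id), schema$items)
  for (it in unscored) {
    u <- as.integer(n_units[[it$section]])
    if (u == 0) next
    n_slots <- spec$n_schools * u
    truth <- rbinom(n_slots, 1, 0.5)
    obs <- vapply(seq_along(raters), function(r) {
      flip <- rbinom(n_slots, 1, default_eps)
      ifelse(flip == 1, 1 - truth, truth)
    }, numeric(n_slots))
    if (!is.matrix(obs)) obs <- matrix(obs, nrow = 1)
    emit(it$item_id, it$section, obs)
  }
  long <- do.call(rbind, rows)
  audits_from_long(long, schema)
}

#' Simulate a continuous latent rating matrix
#'
#' Draws from the one-way random-effects model
#' \eqn{y_{ij} = \mu + b_i + e_{ij}} with
#' \eqn{b_i \sim N(0, \sigma_b^2)} and
#' \eqn{e_{ij} \sim N(0, \sigma_b^2 (1 - \rho)/\rho)}, so the population
#' ICC of the generated matrix is exactly `icc`. This is the continuous
#' latent-score model underlying the audit generator's calibration and is
#' the reference design for reliability parameter-recovery checks.
#'
#' @param n Number of subjects (schools).
#' @param k Number of raters (rater pairs), default 2.
#' @param icc True intraclass correlation in (0, 1).
#' @param between_sd Between-subject standard deviation (default 1).
#' @param mu Grand mean (default 0).
#' @return An n x k numeric matrix.
#' @export
simulate_rating_matrix <- function(n, k = 2, icc, between_sd = 1, mu = 0) {
  if (icc <= 0 || icc >= 1) stop("icc must be in (0, 1)")
  if (between_sd <= 0) stop("between_sd must be positive")
  within_sd <- between_sd * sqrt((1 - icc) / icc)
  b <- rnorm(n, 0, between_sd)
  mu + matrix(b, n, k) + matrix(rnorm(n * k, 0, within_sd), n, k)
}
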