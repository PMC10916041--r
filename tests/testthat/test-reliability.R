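test_that("the ICC matches a from-scratch ANOVA oracle on a worked matrix", {
  m <- cbind(c(1, 3, 5, 7, 9), c(2, 3, 4, 8, 9))
  res <- icc_oneway(m)
  # frozen values computed with the independent lm/anova oracle
  expect_equal(res$msb, 19.35)
  expect_equal(res$msw, 0.3)
  expect_equal(res$estimate, 0.969465648855, tolerance = 1e-12)
  expect_equal(res$ci_low, 0.794460897714, tolerance = 1e-10)
  expect_equal(res$ci_high, 0.996694260597, tolerance = 1e-10)
  orc <- oracle_icc(m)
  expect_equal(res$estimate, orc$estimate, tolerance = 1e-12)
  expect_equal(res$ci_low, orc$ci_low, tolerance = 1e-12)
  expect_equal(res$ci_high, orc$ci_high, tolerance = 1e-12)
})

test_that("ICC estimates agree with the ANOVA oracle on random matrices", {
  set.seed(314)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = sample(c(0.5, 1, 10), 1)), n, k)
    res <- icc_oneway(m)
    orc <- oracle_icc(m)
    expect_equal(res$estimate, orc$estimate, tolerance = 1e-12)
    expect_equal(res$ci_low, orc$ci_low, tolerance = 1e-12)
    expect_equal(res$ci_high, orc$ci_high, tolerance = 1e-12)
    expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
    expect_gte(res$estimate, -1 / (k - 1))
  }
})

test_that("degenerate matrices are handled explicitly", {
  # two identical columns with between-school spread: perfect agreement
  perfect <- cbind(c(1, 4, 9), c(1, 4, 9))
  res <- icc_oneway(perfect)
  expect_equal(res$estimate, 1)
  expect_null(res$undefined_reason)
  # a constant matrix has no variability at all: undefined, never 0 or NaN
  res0 <- icc_oneway(matrix(3, 4, 2))
  expect_true(is.na(res0$estimate))
  expect_equal(res0$undefined_reason, "no_variability")
  expect_equal(classify_reliability(res0), "undefined")
  # no between-subject variance: the lower bound -1/(k-1)
  set.seed(5)
  m <- matrix(rnorm(8), 4, 2)
  m <- m - rowMeans(m) # forces MSB = 0
  expect_equal(icc_oneway(m)$estimate, -1, tolerance = 1e-12)
  # malformed inputs
  expect_error(icc_oneway(matrix(1:2, 1, 2)), "at least 2 subjects")
  expect_error(icc_oneway(matrix(1:5, 5, 1)), "at least 2 raters")
  mna <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(icc_oneway(mna), "complete")
})

test_that("the ICC is invariant to location and scale changes", {
  set.seed(99)
  m <- matrix(rnorm(20), 10, 2)
  base <- icc_oneway(m)
  shifted <- icc_oneway(m + 1000)
  scaled <- icc_oneway(m * 0.004)
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-9)
  expect_equal(scaled$estimate, base$estimate, tolerance = 1e-12)
  expect_equal(scaled$ci_low, base$ci_low, tolerance = 1e-12)
})

test_that("negative estimates are legal outputs", {
  # rater disagreement exceeding between-school spread drives the ICC
  # below zero (the instrument's buffer and shade subscales showed this)
  set.seed(7)
  m <- cbind(rnorm(6), rnorm(6))
  m[, 2] <- -m[, 1] + rnorm(6, sd = 0.1)
  expect_lt(icc_oneway(m)$estimate, 0)
  expect_gte(icc_oneway(m)$estimate, -1)
})

test_that("acceptability classification is boundary-inclusive at 0.60", {
  mk <- function(est) structure(list(estimate = est,
                                     undefined_reason = NULL),
                                class = "maps_icc")
  expect_equal(classify_reliability(mk(0.97)), "acceptable")
  expect_equal(classify_reliability(mk(0.60)), "acceptable")
  expect_equal(classify_reliability(mk(0.5999)), "below_threshold")
  expect_equal(classify_reliability(mk(0.57)), "below_threshold")
})

test_that("retention rules reproduce the instrument revision outcome", {
  v1 <- load_schema(version = "initial_v1")
  v2 <- load_schema(version = "final_v2")
  cls <- worked_example_classifications(v1)
  expect_equal(sum(cls == "acceptable"), 22L)
  out <- apply_retention_rules(cls, v1, revisions = "cr_road_width")
  tab <- table(out$decisions$action)
  expect_equal(unname(tab[["remove"]]), 4L)
  expect_equal(unname(tab[["retain"]]), 22L)
  expect_equal(unname(tab[["retain_by_counterpart"]]), 3L)
  expect_equal(unname(tab[["revise"]]), 1L)
  removed <- out$decisions$subscale_id[out$decisions$action == "remove"]
  expect_setequal(removed, c("sas_positive_buffer", "sas_positive_shade",
                             "seg_positive_buffer", "seg_positive_shade"))
  # the bicycle-infrastructure and overall access-segment subscales stay in
  # through their reliable counterparts in the other-segment section
  kept_by_ctr <- out$decisions$subscale_id[
    out$decisions$action == "retain_by_counterpart"]
  expect_setequal(kept_by_ctr,
                  c("sas_positive_bicycle_infrastructure",
                    "sas_overall_positive", "sas_overall"))
  # the revised schema has the final subscale structure
  expect_setequal(names(out$schema$subscales), names(v2$subscales))
  expect_equal(length(out$schema$subscales) - 1L, 26L)
  # composite parents were re-derived over the surviving children
  expect_setequal(out$schema$subscales[["sas_overall_positive"]]$children,
                  v2$subscales[["sas_overall_positive"]]$children)
})

test_that("retention rules handle the trivial and error cases", {
  v1 <- load_schema(version = "initial_v1")
  ids <- setdiff(names(v1$subscales), v1$total_id)
  all_ok <- stats::setNames(rep("acceptable", length(ids)), ids)
  out <- apply_retention_rules(all_ok, v1)
  expect_true(all(out$decisions$action == "retain"))
  expect_setequal(names(out$schema$subscales), names(v1$subscales))
  expect_error(apply_retention_rules(all_ok[-1], v1),
               "classification missing")
  bad <- all_ok
  bad[1] <- "wonderful"
  expect_error(apply_retention_rules(bad, v1), "unknown classification")
})

test_that("stepwise pruning removes the least reliable child first", {
  n <- 40
  mk_child <- function(icc, between_sd, seed) {
    set.seed(seed)
    simulate_rating_matrix(n, 2, icc = icc, between_sd = between_sd)
  }
  builder_from <- function(children) {
    function(ids) Reduce(`+`, children[ids])
  }
  # one noisy child drags the parent below threshold; removing it restores
  # acceptability in a single step
  children <- list(good1 = mk_child(0.98, 3, 1), good2 = mk_child(0.98, 3, 2),
                   bad = mk_child(0.02, 2, 3))
  builder <- builder_from(children)
  parent0 <- icc_oneway(builder(names(children)))
  expect_lt(parent0$estimate, 0.6)
  trace <- stepwise_prune(builder, names(children))
  expect_equal(nrow(trace), 1L)
  expect_equal(trace$removed_child, "bad")
  expect_equal(trace$classification, "acceptable")
  expect_gte(trace$parent_icc_after, 0.6)
  # already-acceptable parent: empty trace
  ok <- list(a = mk_child(0.95, 3, 4), b = mk_child(0.95, 3, 5))
  expect_equal(nrow(stepwise_prune(builder_from(ok), names(ok))), 0L)
  # all children equally unreliable: pruning runs down to a single child
  noisy <- list(a = mk_child(0.05, 1, 6), b = mk_child(0.05, 1, 7),
                c = mk_child(0.05, 1, 8))
  trace3 <- stepwise_prune(builder_from(noisy), names(noisy))
  expect_equal(nrow(trace3), 2L)
  expect_false(any(trace3$classification == "acceptable"))
})
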