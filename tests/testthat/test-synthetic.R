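schema <- load_schema(version = "initial_v1")
net <- generate_grid_network(3, 3)

test_that("generated audits always validate and mirror the study design", {
  spec <- agreement_spec(target_icc = 0.8, n_schools = 5, seed = 21)
  audits <- generate_rater_audits(schema, net, spec)
  expect_equal(length(audits), 10L) # 5 schools x 2 rater pairs
  expect_true(validate_audits(audits, schema))
  m <- build_rating_matrix(audits, "seg_positive_sidewalk", schema)
  expect_equal(dim(m), c(5L, 2L)) # the 5-school reliability subsample shape
  # unit composition follows the observation route of the network
  a <- audits[[1]]
  expect_equal(length(a$access_segments), 1L)
  expect_equal(length(a$other_segments), 6L)
  expect_equal(length(a$crossings), 2L)
})

test_that("identical spec and seed reproduce byte-identical datasets", {
  spec <- agreement_spec(target_icc = 0.7, n_schools = 4, seed = 1234)
  a1 <- generate_rater_audits(schema, net, spec)
  a2 <- generate_rater_audits(schema, net, spec)
  expect_identical(a1, a2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_audits(a1, f1, schema)
  write_audits(a2, f2, schema)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the data
  a3 <- generate_rater_audits(schema, net,
                              agreement_spec(target_icc = 0.7,
                                             n_schools = 4, seed = 4321))
  expect_false(identical(a1, a3))
})

test_that("a target ICC of one makes both rater pairs agree exactly", {
  spec <- agreement_spec(target_icc = 1, n_schools = 3, seed = 3)
  audits <- generate_rater_audits(schema, net, spec)
  by_school <- split(audits, vapply(audits, `[[`, "", "school_id"))
  for (pair in by_school) {
    expect_equal(length(pair), 2L)
    u1 <- pair[[1]]
    u2 <- pair[[2]]
    u1$rater_pair_id <- u2$rater_pair_id
    expect_equal(u1, u2)
  }
})

test_that("latent continuous scores recover the target ICC at large n", {
  set.seed(2718)
  est <- icc_oneway(simulate_rating_matrix(1000, 2, icc = 0.8))$estimate
  expect_lt(abs(est - 0.8), 0.02)
  est2 <- icc_oneway(simulate_rating_matrix(1000, 2, icc = 0.3,
                                            between_sd = 4,
                                            mu = 100))$estimate
  expect_lt(abs(est2 - 0.3), 0.05)
})

test_that("binary-subscale agreement calibration hits its target", {
  spec <- agreement_spec(target_icc = 0.8, n_schools = 200, seed = 55)
  audits <- generate_rater_audits(schema, net, spec)
  # score only the subscale under test to keep the check cheap
  scorer <- function(sub) function(audit, schema) {
    s <- schema$subscales[[sub]]
    units <- Filter(function(u) identical(u$unit_kind, s$section),
                    c(audit$access_segments, audit$other_segments,
                      audit$crossings))
    sum(vapply(units, function(u) sum(u$responses[s$children]), 0))
  }
  for (sub in c("seg_positive_streetscape", "sas_positive_streetscape")) {
    m <- build_rating_matrix(audits, sub, schema, scorer = scorer(sub))
    expect_lt(abs(icc_oneway(m)$estimate - 0.8), 0.05)
  }
})

test_that("infeasible agreement targets fail loudly with bounds", {
  # lane counts disagree by at most one lane, so a near-zero reliability
  # target cannot be generated for the road-width subscale
  expect_error(
    generate_rater_audits(schema, net, agreement_spec(
      target_icc = c(cr_road_width = 0.05, default = 0.9),
      n_schools = 3, seed = 1)),
    "infeasible.*attainable range")
  expect_error(agreement_spec(target_icc = 0), "target_icc")
  expect_error(agreement_spec(target_icc = 1.2), "target_icc")
  expect_error(agreement_spec(target_icc = 0.8, between_school_sd = 0),
               "between_school_sd")
  expect_error(agreement_spec(target_icc = 0.8, n_schools = 1),
               "n_schools")
})

test_that("grid networks are deterministic and honor their parameters", {
  g1 <- generate_grid_network(3, 2, school_block = c(2, 1), driveways = 1)
  g2 <- generate_grid_network(3, 2, school_block = c(2, 1), driveways = 1)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$nodes), 4 * 3 + 1) # grid points + driveway
  expect_equal(nrow(g1$edges), 3 * 3 + 4 * 2)
})
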