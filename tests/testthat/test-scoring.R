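schema <- load_schema(version = "final_v2")
schema_v1 <- load_schema(version = "initial_v1")

test_that("item scoring follows the score map", {
  bin <- schema$items[["sas_sidewalk_present"]]
  expect_equal(score_item(bin, 1), 1)
  expect_equal(score_item(bin, 0), 0)
  expect_error(score_item(bin, 7), "outside the declared domain")
  shade <- schema_v1$items[["sas_shade_coverage"]]
  expect_equal(score_item(shade, 2), 2) # ordinal items score their level
  lanes <- schema$items[["cr_travel_lanes"]]
  expect_equal(score_item(lanes, 4), 4) # counts score identically
})

test_that("road-width dichotomization matches the printed lane rule", {
  grid <- expand.grid(travel = 0:10, turn = 0:10)
  got <- mapply(dichotomize_road_width, grid$travel, grid$turn)
  expect_equal(got, as.integer(grid$travel + grid$turn > 4))
  expect_equal(dichotomize_road_width(3, 1), 0L)
  expect_equal(dichotomize_road_width(4, 1), 1L)
  expect_equal(dichotomize_road_width(0, 0), 0L)
  expect_error(dichotomize_road_width(-1, 0), "nonnegative")
})

test_that("leaf subscales sum item points within and across units", {
  items <- Filter(function(it) identical(it$section, "other_segment"),
                  schema$items)
  zero <- vapply(items, function(it)
    if (it$response_domain$type == "ordinal") min(it$response_domain$levels)
    else 0, 0)
  names(zero) <- names(items)
  unit0 <- unit_audit("u1", "other_segment", zero)
  expect_equal(score_subscale(schema, "seg_positive_streetscape",
                              list(unit0)), 0)
  # the 11-item positive streetscape subscale, everything present
  ones <- zero
  ones[schema$subscales[["seg_positive_streetscape"]]$children] <- 1
  unit1 <- unit_audit("u2", "other_segment", ones)
  expect_equal(score_subscale(schema, "seg_positive_streetscape",
                              list(unit1)), 11)
  # linearity: duplicating the unit list doubles the score
  expect_equal(score_subscale(schema, "seg_positive_streetscape",
                              list(unit1, unit1)), 22)
  # section mismatch is an error
  expect_error(score_subscale(schema, "cr_positive_curbs", list(unit1)),
               "does not belong to section")
})

test_that("school scores decompose by valence and section on random audits", {
  set.seed(202)
  for (rep in 1:60) {
    sch <- if (rep %% 2 == 0) schema else schema_v1
    a <- random_audit(sch, n_other = sample(0:2, 1),
                      n_crossings = sample(0:2, 1))
    r <- score_school(a, sch)
    for (sec_node in sch$subscales[[sch$total_id]]$children) {
      s <- sch$subscales[[sec_node]]
      kids <- vapply(s$children, function(c) sch$subscales[[c]]$valence, "")
      pos <- r$subscale_scores[[s$children[kids == "positive"]]]
      neg <- r$subscale_scores[[s$children[kids == "negative"]]]
      expect_equal(r$subscale_scores[[sec_node]], pos - neg)
    }
    expect_equal(r$total, sum(r$section_overalls))
    # independent naive tree-walk oracle
    oracle <- oracle_score_school(a, sch)
    for (id in names(oracle)) {
      if (id == sch$total_id) {
        expect_equal(r$total, oracle[[id]])
      } else {
        expect_equal(r$subscale_scores[[id]], oracle[[id]])
      }
    }
    # permutation invariance over units and items
    b <- a
    b$other_segments <- rev(b$other_segments)
    b$crossings <- rev(b$crossings)
    b$access_segments <- lapply(b$access_segments, function(u) {
      u$responses <- u$responses[sample(length(u$responses))]
      u
    })
    r2 <- score_school(b, sch)
    expect_equal(r2$total, r$total)
    expect_equal(r2$subscale_scores[sort(names(r2$subscale_scores))],
                 r$subscale_scores[sort(names(r$subscale_scores))])
  }
})

test_that("flipping an item moves every ancestor in its valence direction", {
  set.seed(77)
  a <- random_audit(schema, n_other = 2, n_crossings = 2)
  base <- score_school(a, schema)
  flip_item <- function(audit, item_id, unit_idx, slot, to) {
    audit[[slot]][[unit_idx]]$responses[[item_id]] <- to
    audit
  }
  cases <- list(
    list(id = "seg_transit_stop", slot = "other_segments",
         sub = "seg_positive_streetscape", dir = +1),
    list(id = "sas_sidewalk_present", slot = "access_segments",
         sub = "sas_positive_sidewalk", dir = +1),
    list(id = "seg_trip_hazards", slot = "other_segments",
         sub = "seg_negative_sidewalk", dir = -1),
    list(id = "cr_crossing_poor_condition", slot = "crossings",
         sub = "cr_negative_impediments", dir = -1)
  )
  for (cs in cases) {
    lo <- flip_item(a, cs$id, 1, cs$slot, 0)
    hi <- flip_item(a, cs$id, 1, cs$slot, 1)
    r_lo <- score_school(lo, schema)
    r_hi <- score_school(hi, schema)
    sec <- schema$subscales[[cs$sub]]$section
    # presence always adds a point to the item's own leaf subscale ...
    expect_gt(r_hi$subscale_scores[[cs$sub]],
              r_lo$subscale_scores[[cs$sub]])
    # ... and the valence decides which way the ancestors move
    expect_equal(cs$dir, sign(r_hi$section_overalls[[sec]] -
                                r_lo$section_overalls[[sec]]))
    expect_equal(cs$dir, sign(r_hi$total - r_lo$total))
  }
  expect_s3_class(base, "maps_score_report")
})

test_that("score tables carry one row per school-rater pair", {
  net <- generate_grid_network(2, 2, school_block = c(1, 1))
  audits <- generate_rater_audits(schema_v1, net, agreement_spec(
    target_icc = 0.9, n_schools = 3, seed = 9))
  tab <- score_audits(audits, schema_v1)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("total", "overall_crossing",
                    "sas_positive_streetscape") %in% names(tab)))
  expect_equal(tab$total,
               tab$overall_school_access_segment +
                 tab$overall_other_segment + tab$overall_crossing)
})
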