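# Construction of the default MAPS-SRTS scoring dictionary.
#
# The instrument collects 90 items in three sections (33 school access
# segment, 30 other segment, 27 crossing). Scored items roll up into leaf
# subscales; leaves roll up into per-section overall-positive and
# overall-negative nodes; each section overall is positive minus negative;
# the total is the sum of the three section overalls. The initial scoring
# schema has 30 non-total subscales (11/11/8 per section); the final one has
# 26 (9/9/8) after the positive buffer and positive shade subscales were
# dropped from both segment-type sections and the road-width subscale was
# recoded to a dichotomy.

item_def <- function(item_id, section, prompt,
                     domain = list(type = "binary"),
                     score_map = NULL, valence = "unscored",
                     subscale_id = NULL) {
  if (is.null(score_map) && domain$type == "binary") {
    score_map <- list(`0` = 0, `1` = 1)
  }
  if (is.null(score_map) && domain$type == "ordinal") {
    score_map <- as.list(domain$levels)
    names(score_map) <- as.character(domain$levels)
  }
  compact(list(item_id = item_id, section = section, prompt = prompt,
               response_domain = domain, score_map = score_map,
               valence = valence, subscale_id = subscale_id))
}

subscale_def <- function(subscale_id, section, valence, children,
                         children_kind, aggregation = "sum_children",
                         status = "retained", counterpart_id = NULL,
                         recode = NULL) {
  compact(list(subscale_id = subscale_id, section = section,
               valence = valence, children = children,
               children_kind = children_kind, aggregation = aggregation,
               status = status, counterpart_id = counterpart_id,
               recode = recode))
}

# Items shared by the two segment-type sections (school access segment and
# other segments near school). `pre` is the section prefix ("sas"/"seg"),
# `n_context` the number of collected-but-unscored contextual items needed to
# reach the section's printed item count.
segment_section_items <- function(pre, section, n_context) {
  ss <- function(stub, prompt, ...) {
    item_def(paste0(pre, "_", stub), section, prompt, ...)
  }
  sub <- function(stub) paste0(pre, "_", stub)
  items <- list(
    # positive streetscape: 11 items
    ss("transit_stop", "Public transit stop present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("posted_speed_limit", "Posted speed limit sign present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("speed_restriction_sign", "Speed restriction signage present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("traffic_calming", "Traffic calming feature (e.g. speed hump) present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("instructional_sign", "Instructional/wayfinding sign present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("streetlights", "Streetlights present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("street_amenities", "Street amenities (benches, trash bins) present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("school_zone_sign", "School zone signage present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("school_speed_zone_sign",
       "Special school speed-zone (drop-off/pick-up times) signage present",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("streetscape_other_1", "Additional positive streetscape feature (a)",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    ss("streetscape_other_2", "Additional positive streetscape feature (b)",
       valence = "positive", subscale_id = sub("positive_streetscape")),
    # positive sidewalk: 3 items
    ss("sidewalk_present", "Sidewalk present",
       valence = "positive", subscale_id = sub("positive_sidewalk")),
    ss("sidewalk_width_adequate", "Sidewalk width adequate (>= 4 ft)",
       valence = "positive", subscale_id = sub("positive_sidewalk")),
    ss("sidewalk_other_1", "Additional positive sidewalk feature",
       valence = "positive", subscale_id = sub("positive_sidewalk")),
    # positive bicycle infrastructure: 1 item
    ss("bike_lane_marked", "Marked bicycle lane and physical barrier present",
       valence = "positive",
       subscale_id = sub("positive_bicycle_infrastructure")),
    # positive buffer: 1 item (removed from final scoring)
    ss("buffer_present",
       "Sidewalk separated from roadway by a buffer (e.g. parking lane)",
       valence = "positive", subscale_id = sub("positive_buffer")),
    # positive shade: 1 ordinal item (removed from final scoring);
    # percentage of sidewalk length shaded: 0 none, 1 = 1-25%, 2 = 26-75%,
    # 3 = 76-100%
    ss("shade_coverage", "Share of sidewalk shaded by tree canopy or awnings",
       domain = list(type = "ordinal", levels = 0:3),
       valence = "positive", subscale_id = sub("positive_shade")),
    # negative streetscape: 2 items
    ss("high_speed_limit", "Posted speed limit 30 mph or higher",
       valence = "negative", subscale_id = sub("negative_streetscape")),
    ss("heavy_driveway_traffic", "Driveways with frequent driver presence",
       valence = "negative", subscale_id = sub("negative_streetscape")),
    # negative sidewalk: 2 items
    ss("sidewalk_discontinuous", "Sidewalk is non-continuous",
       valence = "negative", subscale_id = sub("negative_sidewalk")),
    ss("trip_hazards", "Major trip hazards on the sidewalk",
       valence = "negative", subscale_id = sub("negative_sidewalk")),
    # negative aesthetics: 1 item
    ss("signs_of_neglect",
       "Signs of neglect (graffiti, poorly maintained buildings)",
       valence = "negative", subscale_id = sub("negative_aesthetics"))
  )
  context <- lapply(seq_len(n_context), function(i) {
    ss(sprintf("context_%02d", i),
       sprintf("Contextual observation %d (collected, not aggregated)", i))
  })
  c(items, context)
}

crossing_section_items <- function() {
  cc <- function(stub, prompt, ...) {
    item_def(paste0("cr_", stub), "crossing", prompt, ...)
  }
  items <- list(
    # positive crosswalk amenities: 7 items
    cc("crossing_aid", "Crossing aid (e.g. crossing guard stand, flags)",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("marked_crosswalk", "Marked crosswalk present",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("high_visibility_striping", "High visibility crosswalk striping",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("stop_lines", "Stop lines or crosswalk warnings before crossing",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("raised_crosswalk", "Raised crosswalk or different material than road",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("refuge_island", "Protected pedestrian refuge island",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    cc("curb_extension", "Curb extension or bicycle box",
       valence = "positive", subscale_id = "cr_positive_crosswalk_amenities"),
    # curbs: 2 items
    cc("curb_ramp_present", "Curb ramp present",
       valence = "positive", subscale_id = "cr_positive_curbs"),
    cc("ramp_aligned", "Curb ramp lines up with the crossing",
       valence = "positive", subscale_id = "cr_positive_curbs"),
    # positive intersection control and signage: 8 items
    cc("yield_sign", "Yield sign present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("stop_sign", "Stop sign present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("traffic_signal", "Traffic signal present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("traffic_circle", "Traffic circle present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("turn_arrow_green", "Green arrows for turn lane",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("ped_walk_signal", "Pedestrian walk signal present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("push_button", "Pedestrian push button present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    cc("countdown_signal", "Countdown signal present",
       valence = "positive", subscale_id = "cr_positive_intersection_control"),
    # road width: 2 raw lane-count items; the subscale recodes their sum
    cc("travel_lanes", "Number of travel lanes",
       domain = list(type = "count", max = 10),
       valence = "negative", subscale_id = "cr_road_width"),
    cc("turn_lanes", "Number of turn lanes",
       domain = list(type = "count", max = 10),
       valence = "negative", subscale_id = "cr_road_width"),
    # negative crossing impediments: 4 items
    cc("no_ramp_pre", "No curb ramp before the crossing",
       valence = "negative", subscale_id = "cr_negative_impediments"),
    cc("no_ramp_post", "No curb ramp after the crossing",
       valence = "negative", subscale_id = "cr_negative_impediments"),
    cc("crossing_poor_condition", "Crossing in poor condition",
       valence = "negative", subscale_id = "cr_negative_impediments"),
    cc("crossing_obstruction", "Obstruction within the crossing",
       valence = "negative", subscale_id = "cr_negative_impediments")
  )
  context <- lapply(1:4, function(i) {
    cc(sprintf("context_%02d", i),
       sprintf("Contextual observation %d (collected, not aggregated)", i))
  })
  c(items, context)
}

segment_section_subscales <- function(pre, section, other_pre) {
  sub <- function(stub) paste0(pre, "_", stub)
  ctr <- function(stub) paste0(other_pre, "_", stub)
  leaf_items <- function(stubs) paste0(pre, "_", stubs)
  list(
    subscale_def(sub("positive_streetscape"), section, "positive",
      leaf_items(c("transit_stop", "posted_speed_limit",
                   "speed_restriction_sign", "traffic_calming",
                   "instructional_sign", "streetlights", "street_amenities",
                   "school_zone_sign", "school_speed_zone_sign",
                   "streetscape_other_1", "streetscape_other_2")),
      "items", counterpart_id = ctr("positive_streetscape")),
    subscale_def(sub("positive_sidewalk"), section, "positive",
      leaf_items(c("sidewalk_present", "sidewalk_width_adequate",
                   "sidewalk_other_1")),
      "items", counterpart_id = ctr("positive_sidewalk")),
    subscale_def(sub("positive_bicycle_infrastructure"), section, "positive",
      leaf_items("bike_lane_marked"), "items",
      counterpart_id = ctr("positive_bicycle_infrastructure")),
    subscale_def(sub("positive_buffer"), section, "positive",
      leaf_items("buffer_present"), "items", status = "removed",
      counterpart_id = ctr("positive_buffer")),
    subscale_def(sub("positive_shade"), section, "positive",
      leaf_items("shade_coverage"), "items", status = "removed",
      counterpart_id = ctr("positive_shade")),
    subscale_def(sub("negative_streetscape"), section, "negative",
      leaf_items(c("high_speed_limit", "heavy_driveway_traffic")), "items",
      counterpart_id = ctr("negative_streetscape")),
    subscale_def(sub("negative_sidewalk"), section, "negative",
      leaf_items(c("sidewalk_discontinuous", "trip_hazards")), "items",
      counterpart_id = ctr("negative_sidewalk")),
    subscale_def(sub("negative_aesthetics"), section, "negative",
      leaf_items("signs_of_neglect"), "items",
      counterpart_id = ctr("negative_aesthetics")),
    subscale_def(sub("overall_positive"), section, "positive",
      sub(c("positive_streetscape", "positive_sidewalk",
            "positive_bicycle_infrastructure", "positive_buffer",
            "positive_shade")),
      "subscales", counterpart_id = ctr("overall_positive")),
    subscale_def(sub("overall_negative"), section, "negative",
      sub(c("negative_streetscape", "negative_sidewalk",
            "negative_aesthetics")),
      "subscales", counterpart_id = ctr("overall_negative")),
    subscale_def(sub("overall"), section, "composite",
      sub(c("overall_positive", "overall_negative")), "subscales",
      aggregation = "positive_minus_negative",
      counterpart_id = ctr("overall"))
  )
}

crossing_section_subscales <- function() {
  list(
    subscale_def("cr_positive_crosswalk_amenities", "crossing", "positive",
      paste0("cr_", c("crossing_aid", "marked_crosswalk",
                      "high_visibility_striping", "stop_lines",
                      "raised_crosswalk", "refuge_island", "curb_extension")),
      "items"),
    subscale_def("cr_positive_curbs", "crossing", "positive",
      c("cr_curb_ramp_present", "cr_ramp_aligned"), "items"),
    subscale_def("cr_positive_intersection_control", "crossing", "positive",
      paste0("cr_", c("yield_sign", "stop_sign", "traffic_signal",
                      "traffic_circle", "turn_arrow_green", "ped_walk_signal",
                      "push_button", "countdown_signal")),
      "items"),
    subscale_def("cr_road_width", "crossing", "negative",
      c("cr_travel_lanes", "cr_turn_lanes"), "items", status = "revised",
      recode = list(initial = "trichotomous_sum", final = "dichotomous_gt4")),
    subscale_def("cr_negative_impediments", "crossing", "negative",
      paste0("cr_", c("no_ramp_pre", "no_ramp_post",
                      "crossing_poor_condition", "crossing_obstruction")),
      "items"),
    subscale_def("cr_overall_positive", "crossing", "positive",
      c("cr_positive_crosswalk_amenities", "cr_positive_curbs",
        "cr_positive_intersection_control"), "subscales"),
    subscale_def("cr_overall_negative", "crossing", "negative",
      c("cr_road_width", "cr_negative_impediments"), "subscales"),
    subscale_def("cr_overall", "crossing", "composite",
      c("cr_overall_positive", "cr_overall_negative"), "subscales",
      aggregation = "positive_minus_negative")
  )
}

# The complete default dictionary (both instrument versions derivable).
build_default_dictionary <- function() {
  items <- c(
    segment_section_items("sas", "school_access_segment", n_context = 11),
    segment_section_items("seg", "other_segment", n_context = 8),
    crossing_section_items()
  )
  subscales <- c(
    segment_section_subscales("sas", "school_access_segment", "seg"),
    segment_section_subscales("seg", "other_segment", "sas"),
    crossing_section_subscales(),
    list(subscale_def("total", "total", "composite",
                      c("sas_overall", "seg_overall", "cr_overall"),
                      "subscales", aggregation = "sum_sections"))
  )
  names(items) <- vapply(items, `[[`, "", "item_id")
  names(subscales) <- vapply(subscales, `[[`, "", "subscale_id")
  list(type = "dictionary", name = "MAPS-SRTS default scoring dictionary",
       dictionary_version = "1.0", items = items, subscales = subscales,
       total_id = "total")
}

#' Path to the shipped MAPS-SRTS scoring dictionary
#'
#' Returns the filesystem path of the default machine-readable data
#' dictionary (JSON) installed with the package, suitable for
#' [load_schema()].
#'
#' @return A file path (character scalar).
#' @export
#' @examples
#' maps_dictionary_path()
maps_dictionary_path <- function() {
  system.file("extdata", "maps_srts_dictionary.json", package = "mapsrts",
              mustWork = TRUE)
}
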