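# Street networks and the nearest-neighbor observation route: start from
# the school access segment(s), take every crossing touching them, then
# every segment (one side of the street) incident to those crossings.

#' Construct a street network
#'
#' Nodes are crossing candidates: street intersections, plus driveway nodes
#' that sit on an edge as point annotations (a school driveway counts as a
#' crossing but never splits its access segment into two). Edges are street
#' segments between intersections. Selection is purely topological, so
#' coordinates are planar and only used for description.
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `kind`
#'   (`"intersection"` or `"driveway"`) and, for driveway nodes, `on_edge`
#'   (the id of the edge they sit on).
#' @param edges Data frame with columns `id`, `node_a`, `node_b` and
#'   optionally `street_name`.
#' @param school List with `entrance_node` (intersection node id) and/or
#'   `entrance_point` (c(x, y)), optional `access_edge_ids` (the declared
#'   school frontage), and `driveway_ids` (driveway nodes that are school
#'   entrances or exits).
#' @return A `street_network` object.
#' @export
street_network <- function(nodes, edges, school) {
  need_n <- c("id", "x", "y", "kind")
  need_e <- c("id", "node_a", "node_b")
  if (!all(need_n %in% names(nodes))) {
    stop("nodes need columns: ", paste(need_n, collapse = ", "))
  }
  if (!all(need_e %in% names(edges))) {
    stop("edges need columns: ", paste(need_e, collapse = ", "))
  }
  if (!"on_edge" %in% names(nodes)) nodes$on_edge <- NA_character_
  if (!"street_name" %in% names(edges)) edges$street_name <- NA_character_
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$id), , drop = FALSE]
  errs <- character()
  if (anyDuplicated(nodes$id)) errs <- c(errs, "duplicated node ids")
  if (anyDuplicated(edges$id)) errs <- c(errs, "duplicated edge ids")
  inter <- nodes$id[nodes$kind == "intersection"]
  drive <- nodes$id[nodes$kind == "driveway"]
  bad_kind <- setdiff(nodes$kind, c("intersection", "driveway"))
  if (length(bad_kind)) {
    errs <- c(errs, paste0("unknown node kind: ",
                           paste(bad_kind, collapse = ", ")))
  }
  missing_ep <- setdiff(c(edges$node_a, edges$node_b), inter)
  if (length(missing_ep)) {
    errs <- c(errs, paste0(
      "edge endpoints that are not intersection nodes: ",
      paste(missing_ep, collapse = ", ")))
  }
  bad_drive <- drive[!nodes$on_edge[match(drive, nodes$id)] %in% edges$id]
  if (length(bad_drive)) {
    errs <- c(errs, paste0("driveway nodes without a valid on_edge: ",
                           paste(bad_drive, collapse = ", ")))
  }
  school$driveway_ids <- as.character(school$driveway_ids %||% character())
  bad_sd <- setdiff(school$driveway_ids, drive)
  if (length(bad_sd)) {
    errs <- c(errs, paste0("school driveway_ids that are not driveway ",
                           "nodes: ", paste(bad_sd, collapse = ", ")))
  }
  if (!is.null(school$entrance_node) &&
      !school$entrance_node %in% nodes$id) {
    errs <- c(errs, paste0("entrance_node '", school$entrance_node,
                           "' is not a node"))
  }
  if (!is.null(school$access_edge_ids)) {
    bad_ae <- setdiff(school$access_edge_ids, edges$id)
    if (length(bad_ae)) {
      errs <- c(errs, paste0("access_edge_ids not in edges: ",
                             paste(bad_ae, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop("street network validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  net <- structure(list(nodes = nodes, edges = edges, school = school),
                   class = "street_network")
  # the school's neighborhood must be connected for a route to exist
  acc <- tryCatch(identify_access_segments(net), error = function(e) NULL)
  if (!is.null(acc) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("node_a", "node_b")], directed = FALSE,
      vertices = data.frame(name = inter))
    comp <- igraph::components(g)$membership
    ep <- unique(unlist(edges[match(acc, edges$id), c("node_a", "node_b")]))
    if (length(unique(comp[ep])) > 1) {
      stop("street network is disconnected around the school access segment")
    }
  }
  net
}

#' @export
print.street_network <- function(x, ...) {
  cat("Street network: ", sum(x$nodes$kind == "intersection"),
      " intersections, ", sum(x$nodes$kind == "driveway"), " driveways, ",
      nrow(x$edges), " segments\n", sep = "")
  acc <- tryCatch(identify_access_segments(x), error = function(e) NULL)
  if (!is.null(acc)) {
    cat("  school access segment(s): ", paste(acc, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Identify the school access segment(s)
#'
#' The access segments are the street edges fronting the main school
#' entrance(s) — the anchor of the observation route. When the network
#' declares `access_edge_ids` (frontage is confirmed manually in the field
#' protocol) they are validated and returned; otherwise the edges incident
#' to the entrance node are used. Several access segments arise when an
#' intersection faces the entrance or entrances sit on different segments.
#'
#' @param network A `street_network`.
#' @return Sorted character vector of access edge ids.
#' @export
identify_access_segments <- function(network) {
  school <- network$school
  edges <- network$edges
  if (!is.null(school$access_edge_ids) &&
      length(school$access_edge_ids) > 0) {
    acc <- sort(unique(as.character(school$access_edge_ids)))
    if (!is.null(school$entrance_node)) {
      touching <- edges$id[edges$node_a == school$entrance_node |
                             edges$node_b == school$entrance_node]
      if (length(intersect(acc, touching)) == 0 &&
          length(touching) > 0) {
        stop("declared access segments are not adjacent to the entrance node")
      }
    }
    return(acc)
  }
  if (is.null(school$entrance_node)) {
    stop("school must declare access_edge_ids or an entrance_node")
  }
  acc <- edges$id[edges$node_a == school$entrance_node |
                    edges$node_b == school$entrance_node]
  if (length(acc) == 0) {
    stop("entrance node '", school$entrance_node,
         "' is not adjacent to any street segment")
  }
  sort(acc)
}

#' Select the observation route
#'
#' Applies nearest-neighbor spatial sampling: (1) the crossings of the
#' route are all intersection endpoints of the school access segment(s)
#' plus any school entrance/exit driveways on them; (2) the other segments
#' are, for each intersection crossing, every incident street segment other
#' than the access segments, audited on one side of the street only. The
#' default side is the one facing the school approach; it is recorded
#' explicitly so field teams can override it. Output lists are sorted by
#' id, so the route is deterministic and independent of node/edge insertion
#' order.
#'
#' @param network A `street_network`.
#' @param side Side label recorded for every audited segment (default
#'   `"toward_school"`).
#' @return An `observation_route`: list with `access_segments` (edge ids),
#'   `crossings` (node ids; intersections and school driveways) and
#'   `other_segments` (tibble: `edge_id`, `side`, `via_crossing`).
#' @export
select_route <- function(network, side = "toward_school") {
  edges <- network$edges
  nodes <- network$nodes
  acc <- identify_access_segments(network)
  acc_edges <- edges[match(acc, edges$id), , drop = FALSE]
  ints <- sort(unique(c(acc_edges$node_a, acc_edges$node_b)))
  drive <- nodes$id[nodes$kind == "driveway"]
  school_drive <- intersect(network$school$driveway_ids, drive)
  school_drive <- sort(school_drive[
    nodes$on_edge[match(school_drive, nodes$id)] %in% acc])
  crossings <- sort(unique(c(ints, school_drive)))
  incident <- edges[(edges$node_a %in% ints | edges$node_b %in% ints) &
                      !(edges$id %in% acc), , drop = FALSE]
  via <- vapply(seq_len(nrow(incident)), function(i) {
    ep <- intersect(c(incident$node_a[i], incident$node_b[i]), ints)
    min(ep)
  }, "")
  other <- tibble::tibble(edge_id = incident$id, side = side,
                          via_crossing = via)
  other <- other[order(other$edge_id), , drop = FALSE]
  structure(list(access_segments = acc, crossings = crossings,
                 other_segments = other),
            class = "observation_route")
}

#' @export
print.observation_route <- function(x, ...) {
  n <- count_route_units(x)
  cat("Observation route: ", n[["n_access"]], " access segment(s), ",
      n[["n_crossings"]], " crossing(s), ", n[["n_other_segments"]],
      " other segment(s)\n", sep = "")
  invisible(x)
}

#' Count the units of an observation route
#'
#' @param route An `observation_route`.
#' @return Named integer vector `n_access`, `n_crossings`,
#'   `n_other_segments`.
#' @export
count_route_units <- function(route) {
  c(n_access = length(route$access_segments),
    n_crossings = length(route$crossings),
    n_other_segments = nrow(route$other_segments))
}

#' Read / write a street network directory
#'
#' A network directory holds `nodes.csv` (`id,x,y,kind[,on_edge]`),
#' `edges.csv` (`id,node_a,node_b[,street_name]`) and `school.json`
#' (`entrance_node`, `entrance_point`, `access_edge_ids`, `driveway_ids`).
#'
#' @param dir Directory path.
#' @return A `street_network` (reader) or `dir` invisibly (writer).
#' @export
read_street_network <- function(dir) {
  nodes <- read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE,
                    colClasses = "character")
  nodes$x <- as.numeric(nodes$x)
  nodes$y <- as.numeric(nodes$y)
  edges <- read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE,
                    colClasses = "character")
  school <- jsonlite::read_json(file.path(dir, "school.json"),
                                simplifyVector = TRUE)
  if (!is.null(school$driveway_ids)) {
    school$driveway_ids <- as.character(school$driveway_ids)
  }
  street_network(nodes, edges, school)
}

#' @rdname read_street_network
#' @param network A `street_network`.
#' @export
write_street_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(network$nodes, file.path(dir, "nodes.csv"), row.names = FALSE,
            na = "")
  write.csv(network$edges, file.path(dir, "edges.csv"), row.names = FALSE,
            na = "")
  jsonlite::write_json(network$school, file.path(dir, "school.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
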