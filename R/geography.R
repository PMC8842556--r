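# Travel-time geography: weighted undirected municipality network, exact
# shortest-path travel times, isochrone catchment membership sets (not bound
# by district borders), and nearest-facility times.

#' Construct a travel network
#'
#' @param edges Data frame with columns \code{from_id}, \code{to_id},
#'   \code{minutes}; undirected, weights are car-travel minutes (> 0,
#'   finite, no self-loops).
#' @param municipality_ids Optional character vector of municipality ids
#'   that must all appear as nodes; isolated municipalities without edges
#'   are added as isolated nodes.
#' @return A \code{phc_network}.
#' @export
travel_network <- function(edges, municipality_ids = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from_id", "to_id", "minutes")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  edges$from_id <- as.character(edges$from_id)
  edges$to_id <- as.character(edges$to_id)
  edges$minutes <- as.numeric(edges$minutes)
  if (any(!is.finite(edges$minutes)) || any(edges$minutes <= 0))
    stop("edge weights must be finite minutes > 0")
  if (any(edges$from_id == edges$to_id))
    stop("self-loop edges are not allowed")
  nodes <- unique(c(edges$from_id, edges$to_id, municipality_ids))
  g <- igraph::graph_from_data_frame(
    edges[, c("from_id", "to_id")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::E(g)$minutes <- edges$minutes
  structure(list(edges = edges, graph = g, nodes = nodes),
            class = "phc_network")
}

#' @export
print.phc_network <- function(x, ...) {
  cat("Travel network:", length(x$nodes), "municipalities,",
      nrow(x$edges), "edges; median edge",
      round(stats::median(x$edges$minutes), 1), "min\n")
  invisible(x)
}

#' Read a travel network from an edge-list CSV or a GraphML file
#'
#' CSV needs columns \code{from_id,to_id,minutes}; GraphML needs a
#' \code{minutes} edge attribute.
#'
#' @param path File path (\code{.csv} or \code{.graphml}).
#' @param municipality_ids Optional ids that must appear as nodes.
#' @return A \code{phc_network}.
#' @export
read_network <- function(path, municipality_ids = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    ea <- igraph::edge_attr(g)
    if (is.null(ea$minutes)) stop("GraphML file lacks a 'minutes' edge attribute")
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(from_id = el[, 1], to_id = el[, 2],
                        minutes = as.numeric(ea$minutes),
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(from_id = "character",
                                            to_id = "character"))
  }
  travel_network(edges, municipality_ids)
}

stop_unknown_node <- function(net, id) {
  if (!id %in% net$nodes)
    stop("unknown municipality id: '", id, "'")
}

#' Shortest car-travel times from one municipality
#'
#' Exact shortest-path travel time (Dijkstra on the weighted graph) from
#' \code{origin} to every reachable municipality. The origin maps to 0;
#' unreachable municipalities are absent from the result.
#'
#' @param net A \code{phc_network}.
#' @param origin Municipality id.
#' @return Named numeric vector of minutes.
#' @export
shortest_travel_times <- function(net, origin) {
  stopifnot(inherits(net, "phc_network"))
  stop_unknown_node(net, origin)
  m <- igraph::distances(net$graph, v = origin,
                         weights = igraph::E(net$graph)$minutes)
  d <- m[1, ]
  names(d) <- colnames(m)
  d[is.finite(d)]
}

# All-origins travel-time matrix (origins x nodes), Inf where unreachable.
travel_time_matrix <- function(net, origins = NULL) {
  if (is.null(origins)) origins <- net$nodes
  igraph::distances(net$graph, v = origins,
                    weights = igraph::E(net$graph)$minutes)
}

#' Compute an isochrone catchment area
#'
#' The catchment of a location municipality is the set of municipalities
#' whose shortest car-travel time from the location is at most
#' \code{cutoff} minutes (closed boundary: a time exactly equal to the
#' cutoff is inside). Membership deliberately ignores district borders.
#'
#' @param net A \code{phc_network}.
#' @param location Municipality id anchoring the catchment.
#' @param cutoff Maximum car-travel time in minutes (> 0); typical report
#'   levels are 10, 15 and 20.
#' @return A \code{phc_catchment}: list with \code{location_id},
#'   \code{cutoff_minutes} and \code{members}, a named vector of travel
#'   times (location included at 0), sorted by time.
#' @export
compute_catchment <- function(net, location, cutoff) {
  stopifnot(inherits(net, "phc_network"))
  stop_unknown_node(net, location)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("cutoff must be a single positive number of minutes")
  d <- shortest_travel_times(net, location)
  members <- sort(d[d <= cutoff])
  structure(list(location_id = location, cutoff_minutes = cutoff,
                 members = members), class = "phc_catchment")
}

#' @export
print.phc_catchment <- function(x, ...) {
  cat(sprintf("Catchment of %s (<= %g min): %d municipalities\n",
              x$location_id, x$cutoff_minutes, length(x$members)))
  invisible(x)
}

#' Travel time to the nearest facility of a type
#'
#' Minimum car-travel time from the location municipality to any
#' municipality hosting a facility of \code{facility_type}; 0 when the
#' location itself hosts one; \code{NA} when no such facility is reachable
#' (reports render this as "n/a").
#'
#' @param net A \code{phc_network}.
#' @param location Municipality id.
#' @param facilities Facility table with columns \code{facility_id},
#'   \code{facility_type}, \code{municipality_id}.
#' @param facility_type One of \code{\link{phc_facility_types}}.
#' @return Minutes (numeric scalar), or \code{NA_real_}.
#' @export
nearest_facility_time <- function(net, location, facilities, facility_type) {
  stopifnot(inherits(net, "phc_network"))
  stop_unknown_node(net, location)
  check_facility_type(facility_type)
  hosts <- unique(facilities$municipality_id[
    facilities$facility_type == facility_type])
  hosts <- intersect(hosts, net$nodes)
  if (!length(hosts)) return(NA_real_)
  if (location %in% hosts) return(0)
  d <- shortest_travel_times(net, location)
  d <- d[names(d) %in% hosts]
  if (!length(d)) return(NA_real_)
  min(d)
}

check_facility_type <- function(facility_type) {
  if (!is.character(facility_type) || length(facility_type) != 1 ||
      !facility_type %in% phc_facility_types)
    stop("unknown facility_type: '", facility_type, "' (expected one of ",
         paste(phc_facility_types, collapse = ", "), ")")
  invisible(facility_type)
}

# Vector of nearest-facility times for every node (multi-source Dijkstra:
# one distances() call from all host municipalities). NA when the type has
# no reachable facility.
nearest_time_vector <- function(net, facilities, facility_type) {
  check_facility_type(facility_type)
  out <- rep(NA_real_, length(net$nodes))
  names(out) <- net$nodes
  hosts <- unique(facilities$municipality_id[
    facilities$facility_type == facility_type])
  hosts <- intersect(hosts, net$nodes)
  if (!length(hosts)) return(out)
  d <- igraph::distances(net$graph, v = hosts,
                         weights = igraph::E(net$graph)$minutes)
  m <- apply(d, 2, min)
  m[!is.finite(m)] <- NA_real_
  out[colnames(d)] <- m
  out
}
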