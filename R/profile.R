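# Profile assembly: one (location, cutoff, optional comparator district)
# request -> the full per-indicator result set of a report; plus the batch
# datapoint table over all municipalities and cutoffs (the single-process
# precomputation feeding the interactive generator).

#' Build a profile request
#'
#' @param location_id Municipality id of the envisaged primary-care site.
#' @param cutoff_minutes Maximum car-travel time in minutes (report levels
#'   default to 10, 15, 20).
#' @param comparator_district_id Optional district id for a head-to-head
#'   comparison.
#' @return A \code{phc_request}.
#' @export
profile_request <- function(location_id, cutoff_minutes,
                            comparator_district_id = NULL) {
  if (!is.numeric(cutoff_minutes) || length(cutoff_minutes) != 1 ||
      cutoff_minutes <= 0)
    stop("cutoff_minutes must be a single positive number")
  structure(list(location_id = location_id,
                 cutoff_minutes = cutoff_minutes,
                 comparator_district_id = comparator_district_id),
            class = "phc_request")
}

#' Build a regional health care profile
#'
#' Computes the isochrone catchment of the request and, for every
#' catalogue indicator in catalogue order: the catchment value and
#' absolute counts, the winsorised district value distribution (range,
#' quartiles, median), the national reference, the rank of the catchment
#' among the districts, and — if requested — the comparator district's
#' value. Outlier cleaning applies to the district value set only; the
#' catchment's own value is never altered. Deterministic for fixed inputs.
#'
#' @param request A \code{phc_request}, or a municipality id (then
#'   \code{cutoff}/\code{comparator} are used).
#' @param catalogue A \code{phc_catalogue}.
#' @param country A \code{phc_country} (or equivalent list of fixture
#'   tables).
#' @param cutoff,comparator Convenience arguments when \code{request} is a
#'   bare municipality id.
#' @param outlier_multiplier Tukey fence multiplier for district-set
#'   cleaning (default 3).
#' @return A \code{phc_profile}: the request, the catchment, a
#'   \code{results} data frame (one row per indicator, catalogue order)
#'   with the catchment value, absolute counts, distribution summary,
#'   national value, rank, comparator value and cleaning flag, plus a
#'   cleaning audit table and generation metadata.
#' @export
build_profile <- function(request, catalogue, country, cutoff = NULL,
                          comparator = NULL, outlier_multiplier = 3) {
  if (!inherits(request, "phc_request")) {
    if (is.null(cutoff))
      stop("give a phc_request or a location id plus cutoff")
    request <- profile_request(request, cutoff, comparator)
  }
  stopifnot(inherits(catalogue, "phc_catalogue"))
  mun <- country$municipalities
  net <- country$network
  if (!request$location_id %in% mun$municipality_id)
    stop("unknown municipality id: '", request$location_id, "'")
  comp_id <- request$comparator_district_id
  if (!is.null(comp_id) && !comp_id %in% country$districts$district_id)
    stop("unknown district id: '", comp_id, "'")

  catchment <- compute_catchment(net, request$location_id,
                                 request$cutoff_minutes)
  wide <- values_wide(country$raw_values)
  defs <- catalogue$definitions
  nearest_cache <- new.env(parent = emptyenv())
  nearest_for <- function(ft) {
    if (is.null(nearest_cache[[ft]]))
      nearest_cache[[ft]] <- nearest_time_vector(net, country$facilities,
                                                 ft)
    nearest_cache[[ft]]
  }

  rows <- vector("list", nrow(defs))
  audit <- list()
  for (i in seq_len(nrow(defs))) {
    defn <- defs[i, ]
    nv <- if (defn$aggregation_kind == "nearest_facility_time")
      nearest_for(defn$facility_type) else NULL
    agg <- aggregate_over_region(defn, names(catchment$members), wide,
                                 country$facilities, net,
                                 request$location_id)
    dv <- district_values(defn, mun, wide, country$facilities, net,
                          nearest_vec = nv)
    cleaned <- clean_outliers(dv, multiplier = outlier_multiplier)
    if (length(cleaned$flags))
      audit[[length(audit) + 1]] <- data.frame(
        region_id = cleaned$flags, indicator_id = defn$indicator_id,
        original = unname(dv[cleaned$flags]),
        cleaned = unname(cleaned$values[cleaned$flags]),
        stringsAsFactors = FALSE)
    natv <- national_value(defn, mun, wide, country$facilities, net,
                           nearest_vec = nv)
    dist <- district_distribution(defn, cleaned$values, natv)
    rank <- rank_catchment(agg$value, cleaned$values, defn$polarity)
    compv <- if (is.null(comp_id)) NA_real_ else
      unname(cleaned$values[comp_id])
    rows[[i]] <- data.frame(
      indicator_id = defn$indicator_id, label = defn$label,
      domain = defn$domain, units = defn$units,
      catchment_value = agg$value,
      absolute_numerator = agg$absolute_numerator,
      absolute_denominator = agg$absolute_denominator,
      minimum = dist$minimum, q25 = dist$q25, median = dist$median,
      q75 = dist$q75, maximum = dist$maximum,
      national_value = dist$national_value, rank = rank,
      comparator_value = compv,
      cleaned_flag = length(cleaned$flags) > 0,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(region_id = character(), indicator_id = character(),
               original = numeric(), cleaned = numeric(),
               stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  structure(list(request = request, catchment = catchment,
                 results = results, cleaning_audit = audit,
                 generated_at = Sys.time(),
                 source = if (!is.null(country$seed))
                   paste0("synthetic fixture, seed ", country$seed)
                 else "external fixture"),
            class = "phc_profile")
}

#' @export
print.phc_profile <- function(x, ...) {
  cat(sprintf(
    "Regional health care profile: location %s, cutoff %g min%s\n",
    x$request$location_id, x$request$cutoff_minutes,
    if (is.null(x$request$comparator_district_id)) "" else
      paste0(", comparator ", x$request$comparator_district_id)))
  cat(sprintf("  catchment: %d municipalities; %d indicators; %d cleaned district values\n",
              length(x$catchment$members), nrow(x$results),
              nrow(x$cleaning_audit)))
  invisible(x)
}

#' @export
summary.phc_profile <- function(object, ...) {
  r <- object$results
  data.frame(indicator_id = r$indicator_id,
             catchment = r$catchment_value, national = r$national_value,
             rank = r$rank, stringsAsFactors = FALSE)
}

#' Batch datapoint table over all municipalities and cutoffs
#'
#' Computes, in one process, the catchment value of every indicator for
#' every (municipality, cutoff) pair — the precomputed value grid that
#' feeds the interactive report generator. One shortest-path computation
#' per municipality is shared across cutoffs and indicators; results are
#' identical to calling \code{\link{build_profile}} per municipality.
#' Missing values (e.g. a ratio with zero denominator, or no reachable
#' facility) are kept as empty cells so the row count contract is exact:
#' rows = municipalities x cutoffs x indicators.
#'
#' @param catalogue A \code{phc_catalogue}.
#' @param country A \code{phc_country}.
#' @param cutoffs Numeric vector of cutoff minutes (default 10, 15, 20).
#' @return Data frame \code{municipality_id}, \code{cutoff_minutes},
#'   \code{indicator_id}, \code{value}.
#' @export
generate_all_datapoints <- function(catalogue, country,
                                    cutoffs = c(10, 15, 20)) {
  stopifnot(inherits(catalogue, "phc_catalogue"))
  if (!length(cutoffs) || any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("cutoffs must be a non-empty vector of positive minutes")
  mun <- country$municipalities
  ids <- mun$municipality_id
  net <- country$network
  n <- length(ids)
  defs <- catalogue$definitions
  wide <- values_wide(country$raw_values)[ids, , drop = FALSE]

  tt <- travel_time_matrix(net, origins = ids)[, ids, drop = FALSE]
  # per (origin, cutoff): field totals and member counts over the members
  fields <- colnames(wide)
  n_regions <- n * length(cutoffs)
  sums <- matrix(NA_real_, n_regions, length(fields),
                 dimnames = list(NULL, fields))
  counts <- integer(n_regions)
  reg <- 0L
  origin_of <- integer(n_regions); cutoff_of <- numeric(n_regions)
  for (ci in seq_along(cutoffs)) {
    for (oi in seq_len(n)) {
      reg <- reg + 1L
      members <- which(tt[oi, ] <= cutoffs[ci])
      sums[reg, ] <- colSums(wide[members, , drop = FALSE])
      counts[reg] <- length(members)
      origin_of[reg] <- oi; cutoff_of[reg] <- cutoffs[ci]
    }
  }

  nearest_cache <- list()
  value_cols <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    defn <- defs[i, ]
    value_cols[[i]] <- switch(defn$aggregation_kind,
      mean = sums[, defn$numerator_field] / counts,
      sum = sums[, defn$numerator_field],
      ratio_of_sums = {
        num <- sums[, defn$numerator_field]
        den <- sums[, defn$denominator_field]
        ifelse(den == 0, NA_real_, num / den * defn$scale_per)
      },
      nearest_facility_time = {
        ft <- defn$facility_type
        if (is.null(nearest_cache[[ft]]))
          nearest_cache[[ft]] <- nearest_time_vector(net,
                                                     country$facilities,
                                                     ft)
        nearest_cache[[ft]][ids][origin_of]
      })
  }
  data.frame(
    municipality_id = rep(ids[origin_of], nrow(defs)),
    cutoff_minutes = rep(cutoff_of, nrow(defs)),
    indicator_id = rep(defs$indicator_id, each = n_regions),
    value = unlist(value_cols, use.names = FALSE),
    stringsAsFactors = FALSE)
}
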