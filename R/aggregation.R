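# Regional aggregation: turns raw municipal values into catchment /
# district / national indicator values, winsorises outliers in the district
# value set, summarises the district distribution (range, quartiles,
# median) and ranks the catchment among the districts.

# Long raw-value table -> municipalities x fields matrix.
values_wide <- function(raw_values) {
  munis <- unique(raw_values$municipality_id)
  fields <- unique(raw_values$field_name)
  m <- matrix(NA_real_, length(munis), length(fields),
              dimnames = list(munis, fields))
  m[cbind(match(raw_values$municipality_id, munis),
          match(raw_values$field_name, fields))] <- raw_values$value
  m
}

require_field <- function(wide, field, members) {
  if (!field %in% colnames(wide))
    stop("raw-value table lacks required field '", field, "'")
  v <- wide[members, field]
  if (anyNA(v))
    stop("field '", field, "' missing for municipality ",
         members[which(is.na(v))[1]])
  v
}

#' Aggregate one indicator over a region
#'
#' Applies the indicator's aggregation kind over the member municipalities:
#' \code{mean} is the unweighted arithmetic mean of municipal values;
#' \code{sum} the total; \code{ratio_of_sums} is (sum of numerators / sum
#' of denominators) times \code{scale_per}, with \code{NA} when the
#' denominator total is zero; \code{nearest_facility_time} is the travel
#' time from \code{location} to the nearest facility of the indicator's
#' type (independent of the member set).
#'
#' @param defn One-row indicator definition (see
#'   \code{\link{catalogue_definition}}).
#' @param members Character vector of member municipality ids (non-empty).
#' @param raw_values Long raw-value table
#'   (\code{municipality_id,field_name,value}) or a prebuilt wide matrix.
#' @param facilities Facility table; needed for
#'   \code{nearest_facility_time}.
#' @param net \code{phc_network}; needed for \code{nearest_facility_time}.
#' @param location Location municipality id; needed for
#'   \code{nearest_facility_time}.
#' @return List with \code{value}, \code{absolute_numerator},
#'   \code{absolute_denominator} (absolute counts are \code{NA} where the
#'   kind has no meaningful regional total).
#' @export
aggregate_over_region <- function(defn, members, raw_values,
                                  facilities = NULL, net = NULL,
                                  location = NULL) {
  if (!length(members)) stop("member set must be non-empty")
  wide <- if (is.matrix(raw_values)) raw_values else
    values_wide(raw_values)
  missing_members <- setdiff(members, rownames(wide))
  kind <- defn$aggregation_kind
  if (kind != "nearest_facility_time" && length(missing_members))
    stop("no raw values for municipality ", missing_members[1])
  switch(kind,
    mean = {
      v <- require_field(wide, defn$numerator_field, members)
      list(value = mean(v), absolute_numerator = NA_real_,
           absolute_denominator = NA_real_)
    },
    sum = {
      v <- require_field(wide, defn$numerator_field, members)
      s <- sum(v)
      list(value = s, absolute_numerator = s,
           absolute_denominator = NA_real_)
    },
    ratio_of_sums = {
      num <- sum(require_field(wide, defn$numerator_field, members))
      den <- sum(require_field(wide, defn$denominator_field, members))
      list(value = if (den == 0) NA_real_ else num / den * defn$scale_per,
           absolute_numerator = num, absolute_denominator = den)
    },
    nearest_facility_time = {
      if (is.null(net) || is.null(facilities) || is.null(location))
        stop("nearest_facility_time needs net, facilities and location")
      list(value = nearest_facility_time(net, location, facilities,
                                         defn$facility_type),
           absolute_numerator = NA_real_, absolute_denominator = NA_real_)
    },
    stop("unknown aggregation_kind: ", kind))
}

#' Winsorise outliers at Tukey fences
#'
#' With Q1, Q3 the quartiles (linear interpolation between order
#' statistics, the type-7 convention) and IQR = Q3 - Q1, values above
#' Q3 + multiplier * IQR are set to that upper fence and values below
#' Q1 - multiplier * IQR to the lower fence. Values are capped, never
#' removed, so no region disappears from a report. The operation is
#' idempotent.
#'
#' @param values Named numeric vector (region id -> value); \code{NA}
#'   entries pass through unchanged.
#' @param multiplier Fence multiplier (default 3: far-out fences).
#' @return List with \code{values} (cleaned, same names/order),
#'   \code{flags} (ids whose value was altered), \code{lower},
#'   \code{upper} (the fences; \code{NA} when fewer than one finite
#'   value).
#' @export
clean_outliers <- function(values, multiplier = 3) {
  if (!length(values)) stop("clean_outliers needs at least one value")
  v <- as.numeric(values)
  names(v) <- names(values)
  ok <- !is.na(v)
  if (!any(ok))
    return(list(values = v, flags = character(0), lower = NA_real_,
                upper = NA_real_))
  q <- stats::quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - multiplier * iqr
  upper <- q[2] + multiplier * iqr
  out <- v
  out[ok & v < lower] <- lower
  out[ok & v > upper] <- upper
  flagged <- names(v)[ok & (v < lower | v > upper)]
  if (is.null(flagged)) flagged <- character(0)
  list(values = out, flags = flagged, lower = lower, upper = upper)
}

#' Summarise the district value distribution of one indicator
#'
#' Five-number summary over the (cleaned) district values — minimum, 25\%
#' quantile, median, 75\% quantile, maximum, by linear interpolation
#' between closest order statistics (type 7) — plus the national reference
#' value. The whiskers of the report boxplots depict the full min-max
#' range.
#'
#' @param defn One-row indicator definition (only \code{indicator_id} is
#'   used) or an indicator id string.
#' @param district_values Named numeric vector of district values (>= 2
#'   non-missing).
#' @param national_value National reference value, passed through.
#' @return A \code{phc_distribution}: list with \code{indicator_id},
#'   \code{minimum}, \code{q25}, \code{median}, \code{q75},
#'   \code{maximum}, \code{national_value}.
#' @export
district_distribution <- function(defn, district_values, national_value) {
  id <- if (is.character(defn)) defn else defn$indicator_id
  v <- district_values[!is.na(district_values)]
  if (length(v) < 2)
    stop("district_distribution needs at least 2 district values")
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  structure(list(indicator_id = id, minimum = q[1], q25 = q[2],
                 median = q[3], q75 = q[4], maximum = q[5],
                 national_value = national_value),
            class = "phc_distribution")
}

#' Rank the catchment among the districts
#'
#' The catchment value is inserted among the district values; rank 1 is the
#' most favourable position under the indicator's polarity (highest value
#' for \code{higher_better} and \code{neutral}, lowest for
#' \code{lower_better}). Ties take the best (smallest) rank, so the rank
#' equals 1 + the number of strictly better district values. Missing
#' district values do not count; a missing catchment value yields
#' \code{NA} (rendered "n/a").
#'
#' @param catchment_value Numeric scalar (or \code{NA}).
#' @param district_values Named numeric vector of district values.
#' @param polarity One of \code{\link{phc_polarities}}.
#' @return Integer rank in \code{1..n_districts + 1}, or \code{NA}.
#' @export
rank_catchment <- function(catchment_value, district_values, polarity) {
  if (!polarity %in% phc_polarities)
    stop("unknown polarity: ", polarity)
  if (!length(district_values)) stop("district_values must be non-empty")
  if (is.na(catchment_value)) return(NA_integer_)
  v <- district_values[!is.na(district_values)]
  better <- if (polarity == "lower_better") sum(v < catchment_value)
            else sum(v > catchment_value)
  as.integer(1 + better)
}

# Member municipality sets of every district, in district table order.
district_members <- function(municipalities) {
  split(municipalities$municipality_id, municipalities$district_id)
}

# Per-district values of one indicator: the same aggregation kind applied
# over each district's member municipalities. ratio_of_sums is recomputed
# from district totals (not averaged municipal ratios); for
# nearest-facility indicators the district value is the mean over member
# municipalities' own nearest-facility times.
district_values <- function(defn, municipalities, wide, facilities = NULL,
                            net = NULL, nearest_vec = NULL) {
  dm <- district_members(municipalities)
  if (defn$aggregation_kind == "nearest_facility_time") {
    if (is.null(nearest_vec))
      nearest_vec <- nearest_time_vector(net, facilities,
                                         defn$facility_type)
    return(vapply(dm, function(ms) mean(nearest_vec[ms]), numeric(1)))
  }
  vapply(dm, function(ms)
    aggregate_over_region(defn, ms, wide)$value, numeric(1))
}

# National reference value: mean kinds use the unweighted mean over all
# municipalities; sum and ratio kinds use national totals; nearest-facility
# kinds the mean municipal nearest time (mirrors the per-region rules).
national_value <- function(defn, municipalities, wide, facilities = NULL,
                           net = NULL, nearest_vec = NULL) {
  ids <- municipalities$municipality_id
  if (defn$aggregation_kind == "nearest_facility_time") {
    if (is.null(nearest_vec))
      nearest_vec <- nearest_time_vector(net, facilities,
                                         defn$facility_type)
    return(mean(nearest_vec[ids], na.rm = TRUE))
  }
  aggregate_over_region(defn, ids, wide)$value
}
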