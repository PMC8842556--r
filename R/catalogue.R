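# Indicator catalogue: the 35 indicators in five health / health-service
# domains that make up one regional profile, plus the per-indicator metadata
# (aggregation kind, input fields, units, polarity, reporting scale, source
# granularity, record-linkage flag) that drives aggregation and rendering.

#' The five indicator domains, in catalogue order
#' @export
phc_domains <- c(
  "Demography, Socio-Economics",
  "Disease Prevention and Risk Factors",
  "Epidemiology and Mortality",
  "Health Care Service Supply",
  "Outpatient Care Utilisation"
)

#' Aggregation kinds an indicator may declare
#' @export
phc_aggregation_kinds <- c("mean", "sum", "ratio_of_sums",
                           "nearest_facility_time")

#' Indicator polarities (rank direction only; values are never altered)
#' @export
phc_polarities <- c("higher_better", "lower_better", "neutral")

#' Facility types recognised by the geography and generator modules
#' @export
phc_facility_types <- c("general_practice", "private_gp", "paediatrics",
                        "internal_medicine", "hospital", "pharmacy",
                        "nursing_home")

# One row per indicator; columns mirror the IndicatorDefinition fields.
ind <- function(id, label, domain, kind, num, den = "", fac = "", units,
                polarity, scale_per = 1, gran = "municipality",
                linkage = FALSE, text) {
  data.frame(indicator_id = id, label = label, domain = domain,
             aggregation_kind = kind, numerator_field = num,
             denominator_field = den, facility_type = fac, units = units,
             polarity = polarity, scale_per = scale_per,
             source_granularity = gran, linkage_flag = linkage,
             definition_text = text, stringsAsFactors = FALSE)
}

#' Build the default 35-indicator catalogue
#'
#' Returns the built-in catalogue of 35 indicators grouped under the five
#' domains. Aggregation kinds follow the semantics of each quantity:
#' percentages, prevalences, rates and life expectancies are averaged
#' (unweighted) over the municipalities of a region; population and facility
#' counts are summed; "X per Y" supply and utilisation indicators are
#' ratio-of-sums (regional totals divided, avoiding division by zero in
#' municipalities without providers); "distance to the nearest ..."
#' indicators are travel times from the location municipality. Eight
#' survey-derived indicators are flagged \code{supra_municipal}: their
#' source data exist only above municipality level and are carried down
#' unchanged to member municipalities. Four inpatient-rate indicators carry
#' the person-level record-linkage flag of the original reporting system.
#'
#' @return A \code{phc_catalogue} object.
#' @export
default_catalogue <- function() {
  d1 <- phc_domains[1]; d2 <- phc_domains[2]; d3 <- phc_domains[3]
  d4 <- phc_domains[4]; d5 <- phc_domains[5]
  defs <- rbind(
    ind("pop_total", "Population of the catchment area", d1, "sum",
        "pop_total", units = "persons", polarity = "neutral",
        text = "Total resident population of the region, summed over all municipalities of the catchment area."),
    ind("pct_under15", "Proportion of children under 14 years (<15a)", d1,
        "mean", "pct_under15", units = "%", polarity = "neutral",
        text = "Share of residents younger than 15 years, in percent of the municipal population."),
    ind("pct_65plus", "Percentage of population aged 65 and over", d1,
        "mean", "pct_65plus", units = "%", polarity = "neutral",
        text = "Share of residents aged 65 years or older, in percent of the municipal population."),
    ind("pct_75plus", "Percentage of population aged 75 and over", d1,
        "mean", "pct_75plus", units = "%", polarity = "neutral",
        text = "Share of residents aged 75 years or older, in percent of the municipal population."),
    ind("pct_65plus_single_hh",
        "Percentage of population aged 65 and over in one-person households",
        d1, "mean", "pct_65plus_single_hh", units = "%",
        polarity = "neutral",
        text = "Share of residents aged 65 or older who live in single-person households; points to people living alone with potentially limited support."),
    ind("avg_income", "Average income per income-receiver", d1, "mean",
        "avg_income", units = "EUR/year", polarity = "higher_better",
        text = "Mean annual net income per income-receiving resident; describes the income situation of the regional population."),

    ind("pct_bad_health",
        "Percentage with “very bad” or “bad” self-reported health, inhabitants ≥15a",
        d2, "mean", "pct_bad_health", units = "%",
        polarity = "lower_better", gran = "supra_municipal",
        text = "Survey share of inhabitants aged 15+ rating their own health as bad or very bad; interpolated from supra-municipal survey regions."),
    ind("pct_smokers",
        "Percentage of persons who smoke daily or occasionally, inhabitants >=15a",
        d2, "mean", "pct_smokers", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey share of inhabitants aged 15+ who smoke daily or occasionally; interpolated from supra-municipal survey regions."),
    ind("pct_low_exercise",
        "Percentage of population ≥ 15a with too little exercise", d2,
        "mean", "pct_low_exercise", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey share of inhabitants aged 15+ not reaching recommended physical-activity levels; interpolated from supra-municipal survey regions."),
    ind("pct_obese", "Percentage of population ≥ 15a with obesity", d2,
        "mean", "pct_obese", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey share of inhabitants aged 15+ with obesity (BMI >= 30); interpolated from supra-municipal survey regions."),

    ind("life_exp_men", "Life expectancy at birth (men)", d3, "mean",
        "life_exp_men", units = "years", polarity = "higher_better",
        text = "Period life expectancy at birth of male residents, in years."),
    ind("life_exp_women", "Life expectancy at birth (women)", d3, "mean",
        "life_exp_women", units = "years", polarity = "higher_better",
        text = "Period life expectancy at birth of female residents, in years."),
    ind("prev_diabetes2", "Prevalence of diabetes mellitus Type 2", d3,
        "mean", "prev_diabetes2", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey-derived share of residents with diabetes mellitus type 2; interpolated from supra-municipal survey regions."),
    ind("prev_mental", "Prevalence of mental disorders", d3, "mean",
        "prev_mental", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey-derived share of residents with a mental disorder; interpolated from supra-municipal survey regions."),
    ind("prev_musculoskeletal",
        "Prevalence of disorders of the musculoskeletal system", d3, "mean",
        "prev_musculoskeletal", units = "%", polarity = "lower_better",
        gran = "supra_municipal",
        text = "Survey-derived share of residents with a musculoskeletal disorder; interpolated from supra-municipal survey regions."),
    ind("prev_chronic_pain",
        "Prevalence of chronic head-, neck- and backaches in population ≥ 15a",
        d3, "mean", "prev_chronic_pain", units = "%",
        polarity = "lower_better", gran = "supra_municipal",
        text = "Survey-derived share of inhabitants aged 15+ with chronic head, neck or back pain; interpolated from supra-municipal survey regions."),
    ind("pct_ltc_level1_3",
        "Percentage of long-term care benefit recipients / level 1–3",
        d3, "mean", "pct_ltc_level1_3", units = "%",
        polarity = "lower_better",
        text = "Share of residents receiving long-term care allowance at levels 1-3 (lower care needs)."),
    ind("pct_ltc_level4_7",
        "Percentage of long-term care benefit recipients / level 4–7",
        d3, "mean", "pct_ltc_level4_7", units = "%",
        polarity = "lower_better",
        text = "Share of residents receiving long-term care allowance at levels 4-7 (higher care needs)."),
    ind("rate_inpatients_heart",
        "Rate of inpatients with heart disease within 2 years", d3, "mean",
        "rate_inpatients_heart", units = "per 100,000 in 2 years",
        polarity = "lower_better", linkage = TRUE,
        text = "Residents with at least one inpatient stay for heart disease within two years, per 100,000 population; built on person-level record linkage of hospital episodes."),
    ind("rate_inpatients_femoral",
        "Rate of inpatients aged 65 and above with femoral neck fracture within 2 years",
        d3, "mean", "rate_inpatients_femoral",
        units = "per 100,000 aged 65+ in 2 years",
        polarity = "lower_better", linkage = TRUE,
        text = "Residents aged 65+ with at least one inpatient stay for femoral neck fracture within two years, per 100,000 of that age group; built on person-level record linkage."),
    ind("rate_inpatients_cerebro",
        "Rate of inpatients with cerebrovascular disease within 2 years",
        d3, "mean", "rate_inpatients_cerebro",
        units = "per 100,000 in 2 years", polarity = "lower_better",
        linkage = TRUE,
        text = "Residents with at least one inpatient stay for cerebrovascular disease within two years, per 100,000 population; built on person-level record linkage."),
    ind("rate_inpatients_cancer",
        "Rate of inpatients with cancer within 2 years", d3, "mean",
        "rate_inpatients_cancer", units = "per 100,000 in 2 years",
        polarity = "lower_better", linkage = TRUE,
        text = "Residents with at least one inpatient stay for cancer within two years, per 100,000 population; built on person-level record linkage."),

    ind("inhab_per_gp", "Inhabitants per general practitioner", d4,
        "ratio_of_sums", "pop_total", "n_gp", units = "inhabitants/GP",
        polarity = "lower_better",
        text = "Regional population divided by the number of statutory health insurance general practitioners in the region."),
    ind("pct_shi_gp_55plus",
        "Percentage of statutory health insurance general practitioners aged 55 +",
        d4, "mean", "pct_shi_gp_55plus", units = "%",
        polarity = "lower_better",
        text = "Share of statutory health insurance general practitioners aged 55 or older; a proxy for upcoming retirement-driven supply gaps."),
    ind("inhab_per_private_gp",
        "Inhabitants per private general practitioner", d4, "ratio_of_sums",
        "pop_total", "n_private_gp", units = "inhabitants/GP",
        polarity = "lower_better",
        text = "Regional population divided by the number of private (non-contracted) general practitioners in the region."),
    ind("children_per_paediatrician", "Children per paediatrician", d4,
        "ratio_of_sums", "pop_under15", "n_paediatrician",
        units = "children/paediatrician", polarity = "lower_better",
        text = "Children under 15 in the region divided by the number of paediatricians practising there."),
    ind("inhab_per_internist",
        "Inhabitants per statutory health insurance internist", d4,
        "ratio_of_sums", "pop_total", "n_internist",
        units = "inhabitants/internist", polarity = "lower_better",
        text = "Regional population divided by the number of statutory health insurance internists in the region."),
    ind("time_to_hospital",
        "Distance to the nearest acute care hospital (incl. branch hospitals), minutes by car",
        d4, "nearest_facility_time", "", fac = "hospital",
        units = "minutes", polarity = "lower_better",
        text = "Car travel time from the location municipality to the nearest municipality hosting an acute care hospital (including branch hospitals)."),
    ind("n_pharmacies",
        "Number of pharmacies in the catchment area (excluding hospital pharmacies)",
        d4, "sum", "n_pharmacy", fac = "pharmacy", units = "pharmacies",
        polarity = "higher_better",
        text = "Count of public pharmacies (excluding hospital pharmacies) located in the municipalities of the catchment area."),
    ind("time_to_nursing_home",
        "Distance to the nearest nursing home (minutes by car)", d4,
        "nearest_facility_time", "", fac = "nursing_home",
        units = "minutes", polarity = "lower_better",
        text = "Car travel time from the location municipality to the nearest municipality hosting a retirement or nursing home."),
    ind("inhab65_per_nursing_home",
        "Inhabitants aged 65 and over per retirement home or nursing home in the catchment area",
        d4, "ratio_of_sums", "pop_65plus", "n_nursing_home",
        units = "inhabitants 65+/home", polarity = "lower_better",
        text = "Residents aged 65+ in the region divided by the number of retirement and nursing homes located there."),

    ind("pct_visiting_shi_gp",
        "Percentage of population visiting statutory health insurance general practitioners",
        d5, "mean", "pct_visiting_shi_gp", units = "%",
        polarity = "neutral",
        text = "Share of residents with at least one contact with a statutory health insurance general practitioner in the reference year."),
    ind("gp_equiv_per_100k",
        "General practitioner equivalents per 100,000 population (incl. hospital outpatient departments)",
        d5, "ratio_of_sums", "gp_equivalents", "pop_total",
        units = "FTE per 100,000", polarity = "neutral",
        scale_per = 100000,
        text = "Full-time-equivalent general practitioner capacity, including hospital outpatient departments, per 100,000 residents."),
    ind("paed_equiv_per_100k",
        "Paediatrician equivalents per 100,000 children (<15a; incl. hospital outpatient departments)",
        d5, "ratio_of_sums", "paed_equivalents", "pop_under15",
        units = "FTE per 100,000 children", polarity = "neutral",
        scale_per = 100000,
        text = "Full-time-equivalent paediatric capacity, including hospital outpatient departments, per 100,000 children under 15."),
    ind("internist_equiv_per_100k",
        "Internist equivalents per 100,000 population (incl. hospital outpatient departments)",
        d5, "ratio_of_sums", "internist_equivalents", "pop_total",
        units = "FTE per 100,000", polarity = "neutral",
        scale_per = 100000,
        text = "Full-time-equivalent internal-medicine capacity, including hospital outpatient departments, per 100,000 residents.")
  )
  new_catalogue(defs, phc_domains)
}

new_catalogue <- function(definitions, domain_order) {
  obj <- structure(list(definitions = definitions,
                        domain_order = domain_order),
                   class = "phc_catalogue")
  validate_catalogue(obj)
  obj
}

validate_catalogue <- function(cat) {
  defs <- cat$definitions
  required <- c("indicator_id", "label", "domain", "aggregation_kind",
                "numerator_field", "denominator_field", "facility_type",
                "units", "polarity", "scale_per", "source_granularity",
                "linkage_flag", "definition_text")
  missing <- setdiff(required, names(defs))
  if (length(missing))
    stop("catalogue is missing fields: ", paste(missing, collapse = ", "))
  dup <- defs$indicator_id[duplicated(defs$indicator_id)]
  if (length(dup))
    stop("duplicate indicator_id in catalogue: ",
         paste(unique(dup), collapse = ", "))
  bad_kind <- setdiff(defs$aggregation_kind, phc_aggregation_kinds)
  if (length(bad_kind))
    stop("unknown aggregation_kind: ", paste(bad_kind, collapse = ", "))
  bad_dom <- setdiff(defs$domain, cat$domain_order)
  if (length(bad_dom))
    stop("unknown domain: ", paste(bad_dom, collapse = ", "))
  bad_pol <- setdiff(defs$polarity, phc_polarities)
  if (length(bad_pol))
    stop("unknown polarity: ", paste(bad_pol, collapse = ", "))
  ratio <- defs$aggregation_kind == "ratio_of_sums"
  if (any(ratio & !nzchar(defs$denominator_field)))
    stop("ratio_of_sums indicator without denominator_field: ",
         paste(defs$indicator_id[ratio & !nzchar(defs$denominator_field)],
               collapse = ", "))
  nft <- defs$aggregation_kind == "nearest_facility_time"
  if (any(nft & !nzchar(defs$facility_type)))
    stop("nearest_facility_time indicator without facility_type: ",
         paste(defs$indicator_id[nft & !nzchar(defs$facility_type)],
               collapse = ", "))
  bad_gran <- setdiff(defs$source_granularity,
                      c("municipality", "supra_municipal"))
  if (length(bad_gran))
    stop("unknown source_granularity: ", paste(bad_gran, collapse = ", "))
  # domains must appear contiguously, in domain_order
  if (nrow(defs)) {
    runs <- rle(defs$domain)$values
    if (anyDuplicated(runs))
      stop("catalogue domains are not contiguous")
    if (!identical(runs,
                   cat$domain_order[cat$domain_order %in% runs]))
      stop("catalogue domains are not in domain_order")
  }
  invisible(cat)
}

#' Load an indicator catalogue
#'
#' Reads a catalogue from a YAML or JSON file, or returns the built-in
#' default when \code{path = "default"}. The file holds \code{domain_order}
#' (a character vector) and \code{indicators}, a list of records each
#' carrying the full set of indicator fields (see
#' \code{\link{default_catalogue}}). Missing optional fields
#' (\code{denominator_field}, \code{facility_type}) default to empty;
#' \code{scale_per} defaults to 1, \code{source_granularity} to
#' \code{"municipality"}, \code{linkage_flag} to \code{FALSE}.
#'
#' @param path Path to a \code{.yaml}/\code{.yml}/\code{.json} catalogue
#'   file, or \code{"default"}.
#' @return A validated \code{phc_catalogue}.
#' @export
load_catalogue <- function(path = "default") {
  if (identical(path, "default")) return(default_catalogue())
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$indicators))
    stop("catalogue file has no 'indicators' list: ", path)
  one <- function(rec) {
    ind(id = as.character(rec$indicator_id),
        label = as.character(rec$label),
        domain = as.character(rec$domain),
        kind = as.character(rec$aggregation_kind),
        num = as.character(rec$numerator_field %||% ""),
        den = as.character(rec$denominator_field %||% ""),
        fac = as.character(rec$facility_type %||% ""),
        units = as.character(rec$units %||% ""),
        polarity = as.character(rec$polarity %||% "neutral"),
        scale_per = as.numeric(rec$scale_per %||% 1),
        gran = as.character(rec$source_granularity %||% "municipality"),
        linkage = isTRUE(rec$linkage_flag),
        text = as.character(rec$definition_text %||% ""))
  }
  defs <- do.call(rbind, lapply(raw$indicators, one))
  domain_order <- as.character(raw$domain_order %||% unique(defs$domain))
  new_catalogue(defs, domain_order)
}

#' Write a catalogue to a YAML file
#'
#' Serialises a catalogue so that \code{\link{load_catalogue}} reads back an
#' identical object (round-trip).
#'
#' @param cat A \code{phc_catalogue}.
#' @param path Output file path (\code{.yaml}).
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "phc_catalogue"))
  recs <- lapply(seq_len(nrow(cat$definitions)), function(i)
    as.list(cat$definitions[i, ]))
  yaml::write_yaml(list(domain_order = cat$domain_order,
                        indicators = recs), path)
  invisible(path)
}

#' Count catalogue indicators per domain
#'
#' @param cat A \code{phc_catalogue}.
#' @return Named integer vector over \code{cat$domain_order}; counts sum to
#'   the catalogue size.
#' @export
domain_counts <- function(cat) {
  stopifnot(inherits(cat, "phc_catalogue"))
  counts <- vapply(cat$domain_order,
                   function(d) sum(cat$definitions$domain == d), integer(1))
  names(counts) <- cat$domain_order
  counts
}

#' @export
print.phc_catalogue <- function(x, ...) {
  cat("Indicator catalogue:", nrow(x$definitions), "indicators in",
      length(x$domain_order), "domains\n")
  dc <- domain_counts(x)
  for (d in names(dc)) cat(sprintf("  %-38s %d\n", d, dc[[d]]))
  invisible(x)
}

#' Look up one indicator definition by id
#' @param cat A \code{phc_catalogue}.
#' @param indicator_id Indicator token.
#' @return One-row data frame with the definition.
#' @export
catalogue_definition <- function(cat, indicator_id) {
  i <- match(indicator_id, cat$definitions$indicator_id)
  if (is.na(i)) stop("unknown indicator_id: ", indicator_id)
  cat$definitions[i, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
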