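# Seeded synthetic country generator. Emulates an Austria-scale fixture:
# 2122 municipalities partitioned into 116 districts, a sparse connected
# road network with travel minutes, log-normal populations with a smooth
# regional age structure, facilities placed with probability increasing in
# population, and spatially autocorrelated indicator raw values so that
# nearby municipalities resemble each other. Everything downstream is
# testable on this fixture; no restricted administrative data is involved.

#' Generator settings
#'
#' Defaults emulate the scale and texture of the Austrian municipality
#' landscape. All lengths are in kilometres, travel in minutes.
#'
#' @param extent_km Width/height of the rectangular country (default
#'   600 x 300 km, roughly the Austrian east-west extent).
#' @param k_neighbours k of the k-nearest-neighbour road graph (default 4);
#'   the graph is augmented with shortest bridging edges until connected.
#' @param speed_kmh Assumed average car speed converting centroid distance
#'   to minutes (default 60).
#' @param edge_noise_sdlog SD of the multiplicative log-normal noise on
#'   edge minutes (default 0.15), emulating road-quality variation.
#' @param pop_meanlog,pop_sdlog Log-normal municipal population parameters
#'   (defaults log(1700) and 0.9: median ~1700 inhabitants, right-skewed).
#' @param autocorr_range_km Range of the exponential-decay spatial
#'   correlation of indicator fields (default 60 km).
#' @param age_share_base Mean population shares of the four age bands
#'   (<15, 15-64, 65-74, 75+).
#' @param age_share_spread Scale of the spatially correlated perturbation
#'   of the age-band logits (default 0.2).
#' @param facility_rates Named per-inhabitant Poisson rates for facility
#'   counts per municipality, one per facility type.
#' @param district_pop_ratio_bound Documented upper bound on the ratio of
#'   largest to smallest district population under default settings;
#'   districts are meant to be of a comparable order of magnitude.
#' @param field_levels Named list of \code{c(mean, sd)} pairs giving the
#'   plausible scale of each generated indicator raw field.
#' @return Named list of settings for \code{\link{generate_country}}.
#' @export
country_params <- function(extent_km = c(600, 300),
                           k_neighbours = 4,
                           speed_kmh = 60,
                           edge_noise_sdlog = 0.15,
                           pop_meanlog = log(1700),
                           pop_sdlog = 0.9,
                           autocorr_range_km = 60,
                           age_share_base = c(under15 = 0.145,
                                              a15_64 = 0.655,
                                              a65_74 = 0.105,
                                              a75plus = 0.095),
                           age_share_spread = 0.2,
                           facility_rates = c(general_practice = 1 / 1700,
                                              private_gp = 1 / 4000,
                                              paediatrics = 1 / 8000,
                                              internal_medicine = 1 / 7000,
                                              hospital = 1 / 33000,
                                              pharmacy = 1 / 5500,
                                              nursing_home = 1 / 8000),
                           district_pop_ratio_bound = 100,
                           field_levels = default_field_levels()) {
  list(extent_km = extent_km, k_neighbours = k_neighbours,
       speed_kmh = speed_kmh, edge_noise_sdlog = edge_noise_sdlog,
       pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
       autocorr_range_km = autocorr_range_km,
       age_share_base = age_share_base,
       age_share_spread = age_share_spread,
       facility_rates = facility_rates,
       district_pop_ratio_bound = district_pop_ratio_bound,
       field_levels = field_levels)
}

# Plausible level (mean, sd) of each continuous raw field. Percentages are
# later clipped to [0, 100]; all values are fictive by construction.
default_field_levels <- function() {
  list(
    pct_65plus_single_hh = c(27, 5),
    avg_income = c(23000, 2500),
    life_exp_men = c(79.3, 1.1),
    life_exp_women = c(84.2, 0.9),
    pct_ltc_level1_3 = c(3.4, 0.7),
    pct_ltc_level4_7 = c(1.9, 0.4),
    rate_inpatients_heart = c(2600, 380),
    rate_inpatients_femoral = c(1500, 240),
    rate_inpatients_cerebro = c(1650, 280),
    rate_inpatients_cancer = c(3800, 480),
    pct_shi_gp_55plus = c(45, 8),
    pct_visiting_shi_gp = c(78, 6),
    gp_equiv_rate_per_100k = c(70, 8),
    paed_equiv_rate_per_100k = c(25, 5),
    internist_equiv_rate_per_100k = c(26, 5),
    # survey-derived, generated at district level (supra-municipal sources)
    pct_bad_health = c(8.5, 1.8),
    pct_smokers = c(21, 3),
    pct_low_exercise = c(50, 7),
    pct_obese = c(17, 3),
    prev_diabetes2 = c(7, 1.4),
    prev_mental = c(15, 3),
    prev_musculoskeletal = c(21, 4),
    prev_chronic_pain = c(25, 4)
  )
}

# Fields drawn at district level and copied to member municipalities,
# emulating indicators interpolated from supra-municipal survey regions.
supra_municipal_fields <- c("pct_bad_health", "pct_smokers",
                            "pct_low_exercise", "pct_obese",
                            "prev_diabetes2", "prev_mental",
                            "prev_musculoskeletal", "prev_chronic_pain")

# Per-component child seed so reordering generation steps does not silently
# change other components' draws.
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

with_child_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(child_seed(seed, name))
  expr
}

#' Generate a synthetic country fixture
#'
#' Deterministic given \code{(seed, params)}. Municipality centroids are
#' uniform in a rectangle; districts are contiguous planar clusters
#' (farthest-point-seeded Lloyd iterations on the coordinates); the road
#' network is the symmetric k-nearest-neighbour graph augmented to
#' connectivity, with edge minutes = Euclidean distance / speed times
#' multiplicative log-normal noise; populations are log-normal; facilities
#' are Poisson-placed with intensity proportional to population; indicator
#' raw values come from a spatially autocorrelated Gaussian field
#' (exponential-decay correlation) shifted to each field's plausible scale.
#' Survey-derived fields are drawn at district level and copied to member
#' municipalities (constant within a district).
#'
#' @param seed Integer root seed; every component derives its own stream.
#' @param n_municipalities Number of municipalities (default 2122).
#' @param n_districts Number of districts (default 116).
#' @param params Settings from \code{\link{country_params}}.
#' @return A \code{phc_country}: list with \code{municipalities},
#'   \code{districts}, \code{network}, \code{facilities},
#'   \code{raw_values}, \code{seed}, \code{params}.
#' @export
generate_country <- function(seed, n_municipalities = 2122,
                             n_districts = 116,
                             params = country_params()) {
  if (!is.numeric(n_municipalities) || n_municipalities < 1 ||
      !is.numeric(n_districts) || n_districts < 1)
    stop("counts must be positive")
  if (n_districts > n_municipalities)
    stop("n_districts (", n_districts, ") exceeds n_municipalities (",
         n_municipalities, ")")
  n <- as.integer(n_municipalities)
  nd <- as.integer(n_districts)

  muni_ids <- sprintf("M%04d", seq_len(n))
  coords <- with_child_seed(seed, "coords", {
    cbind(x = round(stats::runif(n, 0, params$extent_km[1] * 1000)),
          y = round(stats::runif(n, 0, params$extent_km[2] * 1000)))
  })
  rownames(coords) <- muni_ids

  district_of <- with_child_seed(seed, "districts",
                                 lloyd_districts(coords, nd))
  district_ids <- sprintf("D%03d", seq_len(nd))
  districts <- data.frame(district_id = district_ids,
                          name = sprintf("District %03d", seq_len(nd)),
                          stringsAsFactors = FALSE)

  network <- with_child_seed(seed, "network",
                             build_road_network(coords, params))

  pops <- with_child_seed(seed, "population", {
    pop_total <- pmax(50L, as.integer(round(stats::rlnorm(
      n, params$pop_meanlog, params$pop_sdlog))))
    shares <- age_share_matrix(coords, params)
    bands <- t(vapply(seq_len(n), function(i)
      largest_remainder(pop_total[i] * shares[i, ]), integer(4)))
    colnames(bands) <- c("pop_under15", "pop_15_64", "pop_65_74",
                         "pop_75plus")
    cbind(pop_total = pop_total, bands)
  })

  municipalities <- data.frame(
    municipality_id = muni_ids,
    name = sprintf("Municipality %04d", seq_len(n)),
    district_id = district_ids[district_of],
    x = coords[, "x"], y = coords[, "y"],
    pop_under15 = pops[, "pop_under15"],
    pop_15_64 = pops[, "pop_15_64"],
    pop_65_74 = pops[, "pop_65_74"],
    pop_75plus = pops[, "pop_75plus"],
    pop_total = pops[, "pop_total"],
    row.names = NULL, stringsAsFactors = FALSE)

  facilities <- with_child_seed(seed, "facilities",
    place_facilities(muni_ids, municipalities$pop_total,
                     params$facility_rates))

  raw_values <- with_child_seed(seed, "fields",
    generate_raw_values(municipalities, district_of, coords, facilities,
                        params))

  structure(list(municipalities = municipalities, districts = districts,
                 network = network, facilities = facilities,
                 raw_values = raw_values, seed = seed, params = params),
            class = "phc_country")
}

#' @export
print.phc_country <- function(x, ...) {
  cat("Synthetic country:", nrow(x$municipalities), "municipalities,",
      nrow(x$districts), "districts,", nrow(x$network$edges), "road edges,",
      nrow(x$facilities), "facilities\n")
  invisible(x)
}

# Farthest-point-seeded Lloyd clustering of planar points into k contiguous,
# non-empty groups. Returns the cluster index of each point.
lloyd_districts <- function(coords, k, iters = 15) {
  n <- nrow(coords)
  if (k == n) return(seq_len(n))
  first <- sample.int(n, 1)
  centers <- coords[first, , drop = FALSE]
  mind <- sq_dist_to(coords, centers[1, ])
  for (j in seq_len(k - 1)) {
    nxt <- which.max(mind)
    centers <- rbind(centers, coords[nxt, ])
    mind <- pmin(mind, sq_dist_to(coords, coords[nxt, ]))
  }
  assign_nearest <- function(centers) {
    d <- outer(coords[, 1], centers[, 1], "-")^2 +
      outer(coords[, 2], centers[, 2], "-")^2
    max.col(-d, ties.method = "first")
  }
  cl <- assign_nearest(centers)
  for (it in seq_len(iters)) {
    for (j in seq_len(k)) {
      idx <- cl == j
      if (any(idx)) centers[j, ] <- colMeans(coords[idx, , drop = FALSE])
    }
    cl_new <- assign_nearest(centers)
    # a centre may end up with no nearest points: give it its closest point
    for (j in which(tabulate(cl_new, k) == 0)) {
      donor <- which.min(sq_dist_to(coords, centers[j, ]))
      cl_new[donor] <- j
    }
    if (identical(cl_new, cl)) break
    cl <- cl_new
  }
  cl
}

sq_dist_to <- function(coords, p) {
  (coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2
}

# Symmetric kNN graph on centroids, augmented with shortest bridging edges
# until connected; minutes = km / speed * 60 * lognormal noise.
build_road_network <- function(coords, params) {
  n <- nrow(coords)
  ids <- rownames(coords)
  if (n == 1)
    return(travel_network(
      data.frame(from_id = character(), to_id = character(),
                 minutes = numeric()), municipality_ids = ids))
  D <- as.matrix(stats::dist(coords))
  k <- min(params$k_neighbours, n - 1)
  pair_i <- integer(0); pair_j <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    pair_i <- c(pair_i, rep(i, k)); pair_j <- c(pair_j, nb)
  }
  a <- pmin(pair_i, pair_j); b <- pmax(pair_i, pair_j)
  keep <- !duplicated(a * (n + 1) + b)
  a <- a[keep]; b <- b[keep]
  # bridge components with the shortest available cross edge
  repeat {
    g0 <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
    g0 <- igraph::add_vertices(g0, max(0, n - igraph::vcount(g0)))
    comp <- igraph::components(g0)$membership
    if (max(comp) == 1) break
    main <- which(comp == comp[which.max(tabulate(comp))])
    rest <- setdiff(seq_len(n), main)
    sub <- D[rest, main, drop = FALSE]
    w <- arrayInd(which.min(sub), dim(sub))
    a <- c(a, min(rest[w[1]], main[w[2]]))
    b <- c(b, max(rest[w[1]], main[w[2]]))
  }
  km <- D[cbind(a, b)] / 1000
  minutes <- round(km / params$speed_kmh * 60 *
                     stats::rlnorm(length(km), 0, params$edge_noise_sdlog),
                   3)
  minutes <- pmax(minutes, 0.001)
  travel_network(data.frame(from_id = ids[a], to_id = ids[b],
                            minutes = minutes, stringsAsFactors = FALSE),
                 municipality_ids = ids)
}

# Spatially smooth age-band shares: perturb base logits with correlated
# fields, softmax back to shares.
age_share_matrix <- function(coords, params) {
  base <- params$age_share_base
  z <- correlated_fields(coords, 4, params$autocorr_range_km)
  logit <- matrix(log(base), nrow(coords), 4, byrow = TRUE) +
    params$age_share_spread * z
  e <- exp(logit)
  e / rowSums(e)
}

# k spatially autocorrelated standard-normal fields over the points:
# covariance exp(-d / range_km), drawn via one Cholesky factor.
correlated_fields <- function(coords, k, range_km) {
  n <- nrow(coords)
  if (n == 1) return(matrix(stats::rnorm(k), 1, k))
  C <- exp(-as.matrix(stats::dist(coords)) / (range_km * 1000))
  diag(C) <- diag(C) + 1e-8
  L <- chol(C)
  crossprod(L, matrix(stats::rnorm(n * k), n, k))
}

# Integer apportionment of tot into shares, preserving the total.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  as.integer(fl)
}

place_facilities <- function(muni_ids, pop, rates) {
  recs <- list()
  for (ft in names(rates)) {
    counts <- stats::rpois(length(pop), pop * rates[[ft]])
    host <- rep(muni_ids, counts)
    if (length(host))
      recs[[ft]] <- data.frame(facility_type = ft, municipality_id = host,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(facility_type = character(), municipality_id = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  data.frame(facility_id = sprintf("F%05d", seq_len(nrow(out))), out,
             stringsAsFactors = FALSE)
}

# Long raw-value table covering every field the default catalogue
# references, for every municipality.
generate_raw_values <- function(municipalities, district_of, coords,
                                facilities, params) {
  n <- nrow(municipalities)
  lv <- params$field_levels
  muni_fields <- setdiff(names(lv), supra_municipal_fields)
  z <- correlated_fields(coords, length(muni_fields),
                         params$autocorr_range_km)
  colnames(z) <- muni_fields
  wide <- matrix(NA_real_, n, 0)
  for (f in muni_fields) {
    v <- lv[[f]][1] + lv[[f]][2] * z[, f]
    if (grepl("^pct_", f)) v <- pmin(pmax(v, 0), 100)
    if (grepl("^rate_", f)) v <- pmax(v, 0)
    wide <- cbind(wide, round(v, 4))
    colnames(wide)[ncol(wide)] <- f
  }
  # district-level survey fields, copied down to member municipalities
  nd <- max(district_of)
  dcent <- t(vapply(seq_len(nd), function(j)
    colMeans(coords[district_of == j, , drop = FALSE]), numeric(2)))
  zd <- correlated_fields(dcent, length(supra_municipal_fields),
                          params$autocorr_range_km)
  colnames(zd) <- supra_municipal_fields
  for (f in supra_municipal_fields) {
    vd <- lv[[f]][1] + lv[[f]][2] * zd[, f]
    vd <- pmin(pmax(vd, 0), 100)
    wide <- cbind(wide, round(vd[district_of], 4))
    colnames(wide)[ncol(wide)] <- f
  }
  # demographic fields derived from the population bands (consistent)
  pt <- municipalities$pop_total
  derived <- cbind(
    pop_total = pt,
    pop_under15 = municipalities$pop_under15,
    pop_65plus = municipalities$pop_65_74 + municipalities$pop_75plus,
    pct_under15 = round(100 * municipalities$pop_under15 / pt, 4),
    pct_65plus = round(100 * (municipalities$pop_65_74 +
                                municipalities$pop_75plus) / pt, 4),
    pct_75plus = round(100 * municipalities$pop_75plus / pt, 4))
  # provider counts from the facility table (consistent with it)
  count_of <- function(ft) {
    tab <- table(factor(
      facilities$municipality_id[facilities$facility_type == ft],
      levels = municipalities$municipality_id))
    as.integer(tab)
  }
  counts <- cbind(n_gp = count_of("general_practice"),
                  n_private_gp = count_of("private_gp"),
                  n_paediatrician = count_of("paediatrics"),
                  n_internist = count_of("internal_medicine"),
                  n_pharmacy = count_of("pharmacy"),
                  n_nursing_home = count_of("nursing_home"))
  # provider capacity (FTE equivalents) scaled to the population at risk
  equiv <- cbind(
    gp_equivalents = round(pt * wide[, "gp_equiv_rate_per_100k"] / 1e5, 4),
    paed_equivalents = round(municipalities$pop_under15 *
                               wide[, "paed_equiv_rate_per_100k"] / 1e5, 4),
    internist_equivalents = round(
      pt * wide[, "internist_equiv_rate_per_100k"] / 1e5, 4))
  wide <- cbind(wide, derived, counts, equiv)
  long <- data.frame(
    municipality_id = rep(municipalities$municipality_id, ncol(wide)),
    field_name = rep(colnames(wide), each = n),
    value = as.numeric(wide), stringsAsFactors = FALSE)
  long
}

#' Write a country fixture to plain-text files
#'
#' Emits six files into \code{directory}: \code{municipalities.csv},
#' \code{municipalities.geojson} (point features in the planar metre CRS),
#' \code{districts.csv}, \code{network_edges.csv}, \code{facilities.csv}
#' and \code{raw_values.csv}. \code{\link{read_fixture}} reads them back
#' into an equivalent fixture.
#'
#' @param country A \code{phc_country}.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(country, directory) {
  stopifnot(inherits(country, "phc_country"))
  if (!nzchar(directory)) stop("directory must be a non-empty path")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  utils::write.csv(country$municipalities, p("municipalities.csv"),
                   row.names = FALSE)
  utils::write.csv(country$districts, p("districts.csv"),
                   row.names = FALSE)
  utils::write.csv(country$network$edges, p("network_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(country$facilities, p("facilities.csv"),
                   row.names = FALSE)
  utils::write.csv(country$raw_values, p("raw_values.csv"),
                   row.names = FALSE)
  write_municipality_geojson(country$municipalities,
                             p("municipalities.geojson"))
  invisible(c(p("municipalities.csv"), p("municipalities.geojson"),
              p("districts.csv"), p("network_edges.csv"),
              p("facilities.csv"), p("raw_values.csv")))
}

write_municipality_geojson <- function(mun, path) {
  feats <- lapply(seq_len(nrow(mun)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(mun$x[i], mun$y[i])),
    properties = list(municipality_id = mun$municipality_id[i],
                      name = mun$name[i],
                      district_id = mun$district_id[i],
                      pop_total = mun$pop_total[i])))
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(
                          name = "urn:phcprofile:planar-metres")),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a country fixture back from \code{\link{write_fixture}} output
#'
#' @param directory Directory holding the fixture files.
#' @return A \code{phc_country} (generator \code{seed}/\code{params} are
#'   not serialised and come back as \code{NULL}).
#' @export
read_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("municipalities.csv", "districts.csv", "network_edges.csv",
              "facilities.csv", "raw_values.csv"))
    if (!file.exists(p(f))) stop("fixture file missing: ", p(f))
  mun <- utils::read.csv(p("municipalities.csv"), stringsAsFactors = FALSE,
                         colClasses = c(municipality_id = "character",
                                        district_id = "character"))
  dis <- utils::read.csv(p("districts.csv"), stringsAsFactors = FALSE,
                         colClasses = c(district_id = "character"))
  edges <- utils::read.csv(p("network_edges.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(from_id = "character",
                                          to_id = "character"))
  fac <- utils::read.csv(p("facilities.csv"), stringsAsFactors = FALSE,
                         colClasses = c(facility_id = "character",
                                        municipality_id = "character"))
  raw <- utils::read.csv(p("raw_values.csv"), stringsAsFactors = FALSE,
                         colClasses = c(municipality_id = "character"))
  structure(list(municipalities = mun, districts = dis,
                 network = travel_network(edges, mun$municipality_id),
                 facilities = fac, raw_values = raw,
                 seed = NULL, params = NULL),
            class = "phc_country")
}
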