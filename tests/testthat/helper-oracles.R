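# Independent oracles and small fixtures shared across the suite. Oracles
# are deliberately naive (exhaustive relaxation, sort-and-interpolate,
# brute-force counting) and share no code with the implementation paths
# they check.

# Brute-force all-pairs shortest paths: Floyd-Warshall relaxation on the
# dense minute matrix. Rows/cols named by node id; Inf = unreachable.
oracle_all_pairs <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$from_id[r]; j <- edges$to_id[r]; w <- edges$minutes[r]
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Quantile by explicit sort + linear interpolation between the closest
# order statistics (h = (n-1)p + 1).
oracle_quantile <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# Rank = 1 + number of strictly better district values under polarity.
oracle_rank <- function(catchment_value, district_values, polarity) {
  v <- district_values[!is.na(district_values)]
  if (polarity == "lower_better") 1L + sum(v < catchment_value)
  else 1L + sum(v > catchment_value)
}

# Random connected undirected network with minute weights.
random_network <- function(seed, n, extra_edges = n) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  # random spanning tree guarantees connectivity
  perm <- sample(n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    j <- sample(i, 1)
    from <- c(from, perm[j]); to <- c(to, perm[i + 1])
  }
  for (e in seq_len(extra_edges)) {
    ij <- sample(n, 2)
    from <- c(from, ij[1]); to <- c(to, ij[2])
  }
  keep <- from != to
  edges <- data.frame(from_id = nodes[from[keep]], to_id = nodes[to[keep]],
                      minutes = round(stats::runif(sum(keep), 1, 20), 2),
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(pmin(edges$from_id, edges$to_id),
                                   pmax(edges$from_id, edges$to_id))), ]
  travel_network(edges, nodes)
}

line_network <- function() {
  travel_network(data.frame(from_id = c("A", "B"), to_id = c("B", "C"),
                            minutes = c(4, 5), stringsAsFactors = FALSE))
}

# Small but full-featured synthetic countries, shared across files. The
# extent shrinks with the municipality count so the settlement density
# (hence catchment sizes at 10/15/20 minutes) resembles the full-scale
# fixture.
tiny_country <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- generate_country(7, 30, 5,
                                  country_params(extent_km = c(80, 40)))
    cached
  }
})

mid_country <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- generate_country(11, 300, 20,
                                  country_params(extent_km = c(220, 110)))
    cached
  }
})

# Compare two travel-time mappings irrespective of element order.
expect_same_mapping <- function(got, want, tolerance = 1e-12) {
  expect_equal(got[order(names(got))], want[order(names(want))],
               tolerance = tolerance)
}

# Minimal one-indicator catalogue file for custom-catalogue tests.
write_mini_catalogue <- function(path) {
  yaml::write_yaml(list(
    domain_order = list("Epidemiology and Mortality"),
    indicators = list(list(
      indicator_id = "life_exp_men",
      label = "Life expectancy at birth (men)",
      domain = "Epidemiology and Mortality",
      aggregation_kind = "mean",
      numerator_field = "life_exp_men",
      units = "years", polarity = "higher_better"))), path)
  path
}
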