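# Raw-value fixture helpers for aggregation tests.
raw_table <- function(ids, ...) {
  fields <- list(...)
  do.call(rbind, lapply(names(fields), function(f)
    data.frame(municipality_id = ids, field_name = f,
               value = fields[[f]], stringsAsFactors = FALSE)))
}

defn_of <- function(kind, num = "v", den = "", fac = "", scale_per = 1) {
  data.frame(indicator_id = "test", label = "test", domain = "d",
             aggregation_kind = kind, numerator_field = num,
             denominator_field = den, facility_type = fac, units = "u",
             polarity = "neutral", scale_per = scale_per,
             source_granularity = "municipality", linkage_flag = FALSE,
             definition_text = "", stringsAsFactors = FALSE)
}

test_that("regional aggregation follows each kind's rule", {
  ids <- c("M1", "M2", "M3")
  raw <- raw_table(ids, v = c(10, 20, 99), num = c(500, 300, 0),
                   den = c(1, 0, 4), pharm = c(1, 0, 2))
  expect_equal(aggregate_over_region(defn_of("mean"), c("M1", "M2"),
                                     raw)$value, 15)
  s <- aggregate_over_region(defn_of("sum", num = "pharm"), ids, raw)
  expect_equal(s$value, 3)
  expect_equal(s$absolute_numerator, 3)
  r <- aggregate_over_region(defn_of("ratio_of_sums", "num", "den"),
                             c("M1", "M2"), raw)
  expect_equal(r$value, 800)  # (500+300)/(1+0)
  expect_equal(r$absolute_numerator, 800)
  expect_equal(r$absolute_denominator, 1)
  # zero denominator total -> missing value, absolutes still reported
  z <- aggregate_over_region(defn_of("ratio_of_sums", "num", "den"),
                             "M2", raw)
  expect_true(is.na(z$value))
  expect_equal(z$absolute_denominator, 0)
  # scale_per applied to the ratio
  k <- aggregate_over_region(defn_of("ratio_of_sums", "num", "den",
                                     scale_per = 100),
                             c("M1", "M3"), raw)
  expect_equal(k$value, (500 + 0) / (1 + 4) * 100)
  expect_error(aggregate_over_region(defn_of("mean"), character(0), raw),
               "non-empty")
  expect_error(aggregate_over_region(defn_of("mean", num = "absent"),
                                     ids, raw), "absent")
})

test_that("ratio_of_sums on a singleton region equals the municipal ratio", {
  ids <- sprintf("M%d", 1:6)
  set.seed(5)
  raw <- raw_table(ids, num = runif(6, 10, 100), den = runif(6, 1, 9))
  d <- defn_of("ratio_of_sums", "num", "den", scale_per = 10)
  for (m in ids) {
    own <- raw$value[raw$field_name == "num" & raw$municipality_id == m] /
      raw$value[raw$field_name == "den" & raw$municipality_id == m] * 10
    expect_equal(aggregate_over_region(d, m, raw)$value, own)
  }
})

test_that("aggregation is invariant to input row order", {
  ids <- sprintf("M%d", 1:8)
  set.seed(9)
  raw <- raw_table(ids, v = rnorm(8), num = runif(8), den = runif(8))
  shuffled <- raw[sample(nrow(raw)), ]
  for (d in list(defn_of("mean"), defn_of("sum"),
                 defn_of("ratio_of_sums", "num", "den"))) {
    expect_equal(aggregate_over_region(d, ids, shuffled)$value,
                 aggregate_over_region(d, ids, raw)$value)
    expect_equal(aggregate_over_region(d, rev(ids), raw)$value,
                 aggregate_over_region(d, ids, raw)$value)
  }
})

test_that("outlier cleaning winsorises at the declared Tukey fences", {
  v <- c(a = 1, b = 2, c = 3, d = 4, e = 100)
  q <- oracle_quantile(v, c(0.25, 0.75))
  upper <- q[2] + 3 * (q[2] - q[1])
  out <- clean_outliers(v, multiplier = 3)
  expect_equal(unname(out$values["e"]), upper)
  expect_equal(out$flags, "e")
  expect_equal(out$values[c("a", "b", "c", "d")], v[c("a", "b", "c", "d")])
  expect_equal(out$upper, upper)
  # symmetric case for the lower fence
  low <- c(a = -100, b = 1, c = 2, d = 3, e = 4)
  ql <- oracle_quantile(low, c(0.25, 0.75))
  out2 <- clean_outliers(low, multiplier = 3)
  expect_equal(unname(out2$values["a"]), ql[1] - 3 * (ql[2] - ql[1]))
  expect_equal(out2$flags, "a")
})

test_that("cleaning constant input changes nothing and empty input errors", {
  v <- rep(7, 10); names(v) <- letters[1:10]
  out <- clean_outliers(v)
  expect_equal(out$values, v)
  expect_length(out$flags, 0)
  expect_error(clean_outliers(numeric(0)), "at least one")
})

test_that("outlier cleaning is idempotent and fence-contained on random inputs", {
  set.seed(123)
  cases <- c(
    lapply(1:60, function(i) {
      n <- sample(1:40, 1)
      stats::rnorm(n) * 10^sample(-1:3, 1) +
        if (i %% 3 == 0) c(rep(0, n - 1), 1e4) else 0
    }),
    list(5, c(2, 2, 2), rep(-3, 8), c(1, 1e6), stats::rcauchy(25)))
  for (v in cases) {
    names(v) <- sprintf("r%02d", seq_along(v))
    once <- clean_outliers(v)
    twice <- clean_outliers(once$values)
    expect_equal(twice$values, once$values)
    expect_length(twice$flags, 0)
    expect_true(all(once$values >= once$lower - 1e-9))
    expect_true(all(once$values <= once$upper + 1e-9))
    # winsorisation never moves a value across the median
    med <- stats::median(v)
    moved <- once$flags
    expect_true(all(sign(once$values[moved] - med) ==
                      sign(v[moved] - med) |
                      once$values[moved] == med))
  }
})

test_that("district distributions match the sort-and-interpolate oracle", {
  expect_equal(
    unclass(district_distribution("i", c(d1 = 1, d2 = 2, d3 = 3, d4 = 4,
                                         d5 = 5), 3))[
      c("minimum", "q25", "median", "q75", "maximum")],
    list(minimum = 1, q25 = 2, median = 3, q75 = 4, maximum = 5))
  const <- rep(4.2, 9); names(const) <- sprintf("d%d", 1:9)
  dd <- district_distribution("i", const, 4.2)
  expect_equal(c(dd$minimum, dd$q25, dd$median, dd$q75, dd$maximum),
               rep(4.2, 5))
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:116, 1)
    v <- stats::rnorm(n, sd = 10^sample(-2:2, 1))
    names(v) <- sprintf("d%03d", seq_len(n))
    dd <- district_distribution("i", v, mean(v))
    want <- oracle_quantile(v, c(0, 0.25, 0.5, 0.75, 1))
    expect_equal(c(dd$minimum, dd$q25, dd$median, dd$q75, dd$maximum),
                 want)
    expect_true(dd$minimum <= dd$q25 && dd$q25 <= dd$median &&
                  dd$median <= dd$q75 && dd$q75 <= dd$maximum)
  }
  expect_error(district_distribution("i", c(d1 = 1), 1), "at least 2")
})

test_that("mean-kind aggregation and summaries are scale-equivariant", {
  ids <- sprintf("M%d", 1:12)
  set.seed(21)
  vals <- stats::runif(12, 5, 50)
  raw1 <- raw_table(ids, v = vals)
  raw2 <- raw_table(ids, v = vals * 3.7)
  d <- defn_of("mean")
  a1 <- aggregate_over_region(d, ids[1:4], raw1)$value
  a2 <- aggregate_over_region(d, ids[1:4], raw2)$value
  expect_equal(a2, 3.7 * a1)
  dv1 <- vals; names(dv1) <- ids
  s1 <- district_distribution("i", dv1, mean(dv1))
  s2 <- district_distribution("i", dv1 * 3.7, mean(dv1) * 3.7)
  for (f in c("minimum", "q25", "median", "q75", "maximum",
              "national_value"))
    expect_equal(s2[[f]], 3.7 * s1[[f]])
})

test_that("catchment ranks equal the brute-force strict-better count", {
  d116 <- stats::rnorm(116); names(d116) <- sprintf("d%03d", 1:116)
  expect_equal(rank_catchment(max(d116) + 1, d116, "higher_better"), 1L)
  expect_equal(rank_catchment(max(d116), d116, "higher_better"), 1L)
  expect_equal(rank_catchment(min(d116) - 1, d116, "lower_better"), 1L)
  expect_equal(rank_catchment(min(d116) - 1, d116, "higher_better"), 117L)
  expect_true(is.na(rank_catchment(NA, d116, "neutral")))
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:116, 1)
    v <- round(stats::rnorm(n), sample(0:2, 1))  # rounding forces ties
    names(v) <- sprintf("d%03d", seq_len(n))
    cv <- if (i %% 4 == 0) sample(v, 1) else stats::rnorm(1)
    pol <- sample(phc_polarities, 1)
    got <- rank_catchment(cv, v, pol)
    expect_equal(got, oracle_rank(cv, v, pol))
    expect_true(got >= 1 && got <= n + 1)
  }
  expect_error(rank_catchment(1, c(d1 = 1), "sideways"), "polarity")
})
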