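test_that("generation is deterministic under a fixed seed", {
  a <- generate_country(3, 40, 6)
  b <- generate_country(3, 40, 6)
  expect_identical(a$municipalities, b$municipalities)
  expect_identical(a$districts, b$districts)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$raw_values, b$raw_values)
  c <- generate_country(4, 40, 6)
  expect_false(identical(a$municipalities, c$municipalities))
})

test_that("generated country satisfies its structural invariants", {
  co <- tiny_country()
  mun <- co$municipalities
  expect_equal(nrow(mun), 30)
  expect_equal(nrow(co$districts), 5)
  # each municipality in exactly one existing district; none empty
  expect_true(all(mun$district_id %in% co$districts$district_id))
  expect_true(all(co$districts$district_id %in% mun$district_id))
  # age bands are non-negative and sum to the total population
  bands <- mun[, c("pop_under15", "pop_15_64", "pop_65_74", "pop_75plus")]
  expect_true(all(bands >= 0))
  expect_equal(rowSums(bands), as.numeric(mun$pop_total))
  # network connected and covering every municipality
  expect_equal(igraph::components(co$network$graph)$no, 1)
  expect_setequal(co$network$nodes, mun$municipality_id)
  expect_true(all(co$network$edges$minutes > 0))
  # facilities reference existing municipalities and known types
  expect_true(all(co$facilities$municipality_id %in% mun$municipality_id))
  expect_true(all(co$facilities$facility_type %in% phc_facility_types))
})

test_that("raw values cover every field the default catalogue references", {
  co <- tiny_country()
  defs <- load_catalogue("default")$definitions
  need <- setdiff(unique(c(defs$numerator_field, defs$denominator_field)),
                  "")
  have <- unique(co$raw_values$field_name)
  expect_true(all(need %in% have))
  # every field present for every municipality, no missing values
  counts <- table(co$raw_values$field_name)
  expect_true(all(counts == nrow(co$municipalities)))
  expect_false(anyNA(co$raw_values$value))
})

test_that("supra-municipal survey fields are constant within a district", {
  co <- tiny_country()
  mun <- co$municipalities
  supra <- c("pct_bad_health", "pct_smokers", "pct_low_exercise",
             "pct_obese", "prev_diabetes2", "prev_mental",
             "prev_musculoskeletal", "prev_chronic_pain")
  for (f in supra) {
    v <- co$raw_values[co$raw_values$field_name == f, ]
    d <- mun$district_id[match(v$municipality_id, mun$municipality_id)]
    per_district <- tapply(v$value, d, function(x) length(unique(x)))
    expect_true(all(per_district == 1), info = f)
  }
  # a municipality-level field is NOT constant within districts
  v <- co$raw_values[co$raw_values$field_name == "avg_income", ]
  d <- mun$district_id[match(v$municipality_id, mun$municipality_id)]
  expect_true(any(tapply(v$value, d, function(x) length(unique(x))) > 1))
})

test_that("district populations are of a comparable order of magnitude", {
  co <- mid_country()
  dp <- tapply(co$municipalities$pop_total,
               co$municipalities$district_id, sum)
  expect_true(max(dp) / min(dp) <=
                country_params()$district_pop_ratio_bound)
})

test_that("indicator fields are spatially autocorrelated", {
  co <- mid_country()
  mun <- co$municipalities
  edges <- co$network$edges
  i <- match(edges$from_id, mun$municipality_id)
  j <- match(edges$to_id, mun$municipality_id)
  set.seed(1)
  ri <- sample(nrow(mun), 2000, replace = TRUE)
  rj <- sample(nrow(mun), 2000, replace = TRUE)
  for (f in c("avg_income", "life_exp_men", "pct_visiting_shi_gp")) {
    v <- co$raw_values$value[co$raw_values$field_name == f]
    v <- v[match(mun$municipality_id,
                 co$raw_values$municipality_id[
                   co$raw_values$field_name == f])]
    adj_cor <- stats::cor(v[i], v[j])
    rand_cor <- stats::cor(v[ri], v[rj])
    expect_gt(adj_cor, rand_cor)
    expect_gt(adj_cor, 0.3)
  }
})

test_that("generator argument errors are reported", {
  expect_error(generate_country(1, 10, 20), "exceeds")
  expect_error(generate_country(1, 0, 0), "positive")
  expect_error(generate_country(1, -5, 2), "positive")
})

test_that("fixtures round-trip through write_fixture/read_fixture", {
  co <- tiny_country()
  dir <- withr::local_tempdir()
  files <- write_fixture(co, dir)
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
  # municipalities CSV has one data row per municipality
  lines <- readLines(file.path(dir, "municipalities.csv"))
  expect_equal(length(lines) - 1, nrow(co$municipalities))
  back <- read_fixture(dir)
  expect_equal(back$municipalities, co$municipalities)
  expect_equal(back$districts, co$districts)
  expect_equal(back$network$edges, co$network$edges)
  expect_equal(back$facilities, co$facilities)
  expect_equal(back$raw_values, co$raw_values)
  # GeoJSON points carry coordinates and district membership
  gj <- jsonlite::read_json(file.path(dir, "municipalities.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(co$municipalities))
  f1 <- gj$features[[1]]
  expect_equal(f1$properties$municipality_id,
               co$municipalities$municipality_id[1])
  expect_equal(f1$geometry$coordinates[[1]], co$municipalities$x[1])
  expect_error(write_fixture(co, ""), "non-empty")
})

test_that("profiles built from a re-read fixture match the original", {
  co <- tiny_country()
  dir <- withr::local_tempdir()
  write_fixture(co, dir)
  back <- read_fixture(dir)
  cat0 <- load_catalogue("default")
  loc <- co$municipalities$municipality_id[5]
  p1 <- build_profile(profile_request(loc, 20), cat0, co)
  p2 <- build_profile(profile_request(loc, 20), cat0, back)
  expect_equal(p2$results, p1$results)
})
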