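make_geo <- function(n = 12, seed = 7) {
  set.seed(seed)
  dplyr::tibble(site_id = sprintf("S%02d", 1:n),
                elevation = runif(n, 50, 410),
                dist_coast = runif(n, 0.3, 27.9),
                dist_road = runif(n, 0.3, 22),
                dist_forest = runif(n, 0, 11.3),
                prop_productive = runif(n, 0, 0.66),
                x = runif(n, 0, 6e4), y = runif(n, 0, 6e4))
}

test_that("geographic PCA respects sign conventions and is order-invariant", {
  geo <- make_geo()
  sc <- geographic_pca(geo)
  ve <- attr(sc, "variance_explained")
  expect_length(ve, 5)
  expect_equal(sum(ve), 1)
  expect_true(all(diff(ve) <= 1e-12))
  # CLG increases inland, TFG increases toward forest
  expect_gt(attr(sc, "loadings")["dist_coast", 1], 0)
  expect_lt(attr(sc, "loadings")["dist_forest", 2], 0)

  perm <- sample(nrow(geo))
  sc2 <- geographic_pca(geo[perm, ])
  expect_equal(sc2$CLG, sc$CLG[perm])
  expect_equal(sc2$TFG, sc$TFG[perm])

  dup <- geographic_pca(dplyr::bind_rows(geo, geo[1, ]))
  expect_equal(dup$CLG[nrow(geo) + 1], dup$CLG[1])
})

test_that("geographic PCA rejects degenerate inputs", {
  geo <- make_geo()
  expect_error(geographic_pca(geo[1:3, ]), "at least as many sites")
  geo$elevation <- 100
  expect_error(geographic_pca(geo), "constant")
})

test_that("feeding index is a time-gated additive Gaussian kernel", {
  sites <- dplyr::tibble(site_id = "S01", x = 10000, y = 10000)
  st1 <- dplyr::tibble(x = 11000, y = 10900, start_year = 2018)
  # station not yet active -> exactly zero
  expect_equal(feeding_index(st1, sites, 2018)$feeding, 0)
  expect_equal(feeding_index(st1, sites, 2017)$feeding, 0)

  # station at the site's cell center gives exactly the kernel peak value
  h <- 15000
  at_center <- dplyr::tibble(x = 11000, y = 11000, start_year = 2018)
  expect_equal(feeding_index(at_center, sites, 2019)$feeding /
                 (1 / (2 * pi * h^2)), 1, tolerance = 1e-12)
  central <- feeding_index(st1, sites, 2019)$feeding
  expect_equal(central / (1 / (2 * pi * h^2)), 1, tolerance = 1e-4)

  # two co-located stations double the value
  st2 <- dplyr::bind_rows(st1, st1)
  expect_equal(feeding_index(st2, sites, 2019)$feeding, 2 * central)

  # monotone non-increasing in distance
  dists <- seq(0, 6e4, by = 5000)
  vals <- vapply(dists, function(d)
    feeding_index(dplyr::tibble(x = 11000 + d, y = 10900,
                                start_year = 2018),
                  sites, 2019)$feeding, numeric(1))
  expect_true(all(diff(vals) <= 1e-15))

  expect_error(feeding_index(dplyr::tibble(x = 29.5, y = 70.4,
                                           start_year = 2018),
                             dplyr::tibble(site_id = "S01", x = 29.9,
                                           y = 70.2), 2019),
               "longitude/latitude")
})

test_that("rodent index sums species within site then averages sites", {
  traps <- dplyr::tibble(
    site = rep(c("T1", "T2"), each = 3),
    year = 2018, season = "fall",
    species = rep(c("tundra_vole", "gray_sided_vole", "lemming"), 2),
    captures = c(5, 0, 0, 3, 3, 1.5),
    trap_nights = 250)
  # T1: 5/250*100 = 2; T2: 7.5/250*100 = 3 -> mean 2.5
  expect_equal(rodent_index(traps, 2019), 2.5)

  # all-zero captures -> 0
  traps0 <- dplyr::mutate(traps, captures = 0)
  expect_equal(rodent_index(traps0, 2019), 0)

  # zero trap-nights: site skipped with a warning
  traps$trap_nights[traps$site == "T2"] <- 0
  expect_warning(idx <- rodent_index(traps, 2019), "T2")
  expect_equal(idx, 2)

  # no fall rows for the preceding year -> NA
  expect_true(is.na(rodent_index(traps, 2018)))
})

test_that("standardization uses the sample-SD convention and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)

  set.seed(1)
  x <- rnorm(50, 10, 3)
  z1 <- as.numeric(standardize(x))
  expect_equal(mean(z1), 0)
  expect_equal(sd(z1), 1)
  expect_equal(as.numeric(standardize(z1)), z1, tolerance = 1e-12)
  # affine invariance
  expect_equal(as.numeric(standardize(5 - 2 * x)), -z1, tolerance = 1e-12)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("the assembled covariate table is standardized per camera-winter", {
  geo <- make_geo()
  winters <- tidyr::expand_grid(site_id = geo$site_id, year = 2015:2020)
  stations <- dplyr::tibble(x = c(1e4, 3e4), y = c(2e4, 4e4),
                            start_year = c(2017, 2019))
  traps <- tidyr::expand_grid(site = c("T1", "T2"), year = 2014:2019,
                              species = c("a", "b", "c")) |>
    dplyr::mutate(season = "fall", trap_nights = 250,
                  captures = rpois(dplyr::n(), 3))
  cov <- build_covariates(winters, geo, stations, traps)
  expect_equal(nrow(cov), nrow(winters))
  for (v in c("CLG", "TFG", "rodent", "feeding")) {
    expect_equal(mean(cov[[v]]), 0, tolerance = 1e-12)
    expect_equal(sd(cov[[v]]), 1, tolerance = 1e-12)
  }
  tr <- attr(cov, "transforms")
  expect_equal(cov$feeding_raw,
               cov$feeding * tr$feeding$scale + tr$feeding$center,
               tolerance = 1e-12)
  # feeding is zero before any station starts
  expect_true(all(cov$feeding_raw[cov$year <= 2017] == 0))
})
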