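test_that("climatology generation is deterministic and depth-monotone", {
  spec <- tiny_spec()
  c1 <- generate_climatology(spec)
  c2 <- generate_climatology(spec)
  expect_identical(c1, c2)
  # strictly decreasing temperature in every ocean column, every month
  tarr <- c1$fields$temperature
  for (mi in seq_along(c1$months)) {
    cols <- matrix(tarr[, , , mi], ncol = dim(tarr)[3])
    ok <- stats::complete.cases(cols)
    expect_true(all(apply(cols[ok, , drop = FALSE], 1, diff) < 0))
  }
  # land cells are NA everywhere, ocean cells complete
  expect_true(all(is.na(tarr[!c1$ocean])))
  expect_false(any(is.na(tarr[array(rep(c1$ocean, prod(dim(tarr)[3:4])),
                                    dim(tarr))])))
  expect_error(synthetic_world_spec(lat_range = c(0, 0)), "lat_range")
})

test_that("different seeds give different worlds", {
  c1 <- generate_climatology(tiny_spec(seed = 1))
  c2 <- generate_climatology(tiny_spec(seed = 2))
  expect_false(identical(c1$ocean, c2$ocean))
})

test_that("lookups return constant fields and interpolate depth linearly", {
  lat <- c(-5, 5); lon <- c(-5, 5)
  # constant 10 C field
  clim <- manual_clim(lat, lon)
  expect_equal(clim_lookup(clim, "temperature",
                           runif(20, -10, 10), runif(20, -10, 10),
                           depth = runif(20, 0, 1000)),
               rep(10, 20))
  # linear lapse 20 C at 0 m to 4 C at 800 m: 400 m -> 12 C
  lapse <- manual_clim(lat, lon, depths = c(0, 800),
                       temp_fun = function(d) 20 - 16 * d / 800)
  expect_equal(clim_lookup(lapse, "temperature", 0, 0, depth = 400), 12)
  expect_equal(clim_lookup(lapse, "temperature", 0, 0, depth = 0), 20)
  # constant extrapolation below the deepest level
  expect_equal(clim_lookup(lapse, "temperature", 0, 0, depth = 2000), 4)
  expect_error(clim_lookup(lapse, "banana", 0, 0), "unknown")
})

test_that("profile sampling is reproducible and respects its contracts", {
  w <- tiny_world()
  s1 <- sample_profiles(w$spec, 40, w$clim, seed = 99)
  s2 <- sample_profiles(w$spec, 40, w$clim, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$objects$esd_um,
    sample_profiles(w$spec, 40, w$clim, seed = 100)$objects$esd_um))

  obj <- s1$objects
  expect_true(all(obj$esd_um >= 600 & obj$esd_um <= 20000))
  expect_true(all(obj$depth_m <= s1$profiles$max_depth[1]))
  expect_true(all(obj$depth_m >= 0))
  # areas invert exactly to the drawn ESD
  expect_equal(esd_from_area(obj$area_um2), obj$esd_um, tolerance = 1e-12)
  # profiles sit on ocean cells
  cells <- assign_cell(s1$profiles$lat, s1$profiles$lon, w$clim)
  expect_false(any(cells$reassigned))
})

test_that("a null response yields zero objects", {
  resp <- default_response()
  for (t in names(resp)) resp[[t]]$b0 <- -Inf
  spec <- tiny_spec(response = resp)
  sim <- sample_profiles(spec, 10)
  expect_equal(nrow(sim$objects), 0L)
  # and a zero true budget
  clim <- generate_climatology(spec)
  expect_equal(true_budget(spec, clim, "carbon")$total, 0)
})

test_that("object counts are Poisson with rate = response x volume", {
  # flat response: lambda independent of the environment
  resp <- list(Aulacanthidae = list(
    b0 = log(0.8), temp = 0, log_chl = 0, interaction = 0,
    layer_offset = c(epipelagic = 0, mesopelagic = 0)))
  taxa <- data.frame(taxon = "Aulacanthidae", median_esd_mm = 1.4,
                     sdlog = 0.3)
  spec <- tiny_spec(taxa = taxa, response = resp)
  n <- 4000
  sim <- sample_profiles(spec, n, seed = 5)
  # mesopelagic volume per profile: 800 m x 0.01 m^3/m
  lambda_v <- 0.8 * 800 * 0.01
  meso_counts <- table(factor(
    sim$objects$profile_id[sim$objects$depth_m >= 200],
    levels = sim$profiles$profile_id))
  se <- sqrt(lambda_v / n)
  expect_lt(abs(mean(meso_counts) - lambda_v), 3 * se)
})

test_that("true budgets match the analytic product on degenerate worlds", {
  # fixed content (zero-spread spectrum), flat density d per m^3
  d <- 0.37
  resp <- list(Aulacanthidae = list(
    b0 = log(d), temp = 0, log_chl = 0, interaction = 0,
    layer_offset = c(epipelagic = 0, mesopelagic = 0)))
  taxa <- data.frame(taxon = "Aulacanthidae", median_esd_mm = 2, sdlog = 0)
  spec <- tiny_spec(taxa = taxa, response = resp, land_fraction = 0)
  clim <- generate_climatology(spec)
  q <- carbon_content(sphere_volume(2))          # ug C per individual
  res <- spec$resolution
  area <- sum(cell_area(spec$lat - res / 2, spec$lat + res / 2,
                        dlon = res)) * length(spec$lon)
  tb <- true_budget(spec, clim, "carbon", unit = "ug")
  expect_equal(tb$epipelagic, d * q * 200 * area, tolerance = 1e-12)
  expect_equal(tb$mesopelagic, d * q * 800 * area, tolerance = 1e-12)

  # doubling the density doubles the total
  resp2 <- resp; resp2$Aulacanthidae$b0 <- log(2 * d)
  spec2 <- tiny_spec(taxa = taxa, response = resp2, land_fraction = 0)
  tb2 <- true_budget(spec2, generate_climatology(spec2), "carbon",
                     unit = "ug")
  expect_equal(tb2$total, 2 * tb$total, tolerance = 1e-12)
})

test_that("truncated lognormal moments agree with numeric integration", {
  for (p in c(0.5, 1, 1.365, 3)) {
    for (sdlog in c(0.2, 0.5)) {
      meanlog <- log(1.6)
      dens <- function(x) stats::dlnorm(x, meanlog, sdlog)
      z <- stats::integrate(dens, 0.6, 20)$value
      num <- stats::integrate(function(x) x^p * dens(x), 0.6, 20)$value / z
      expect_equal(tlnorm_moment(p, meanlog, sdlog, 0.6, 20), num,
                   tolerance = 1e-7)
    }
  }
  # degenerate spectrum is a point mass at the median
  expect_equal(tlnorm_moment(2, log(3), 0, 0.6, 20), 9)
})

test_that("empirical cell concentrations converge to the true response", {
  # one-cell world, many profiles: mean concentration within 5%
  resp <- list(Aulacanthidae = list(
    b0 = log(1.2), temp = 0, log_chl = 0, interaction = 0,
    layer_offset = c(epipelagic = 0, mesopelagic = 0)))
  taxa <- data.frame(taxon = "Aulacanthidae", median_esd_mm = 1.4,
                     sdlog = 0.3)
  spec <- synthetic_world_spec(resolution = 30, lat_range = c(0, 30),
                               lon_range = c(0, 30), months = 1,
                               depths = seq(0, 800, 400),
                               land_fraction = 0, taxa = taxa,
                               response = resp, seed = 3)
  clim <- generate_climatology(spec)
  sim <- sample_profiles(spec, 2000, clim, seed = 4)
  qobj <- quantify_objects(sim$objects, clim)
  pc <- profile_layer_concentration(qobj, sim$volumes, "q_c")
  cl <- cell_layer_average(pc, sim$profiles, clim, "q_c")
  truth <- true_concentration(spec, clim, "carbon")
  for (ly in c("epipelagic", "mesopelagic")) {
    obs <- cl$q_c[cl$layer == ly]
    expected <- truth$conc[truth$layer == ly]
    expect_equal(obs, expected, tolerance = 0.05)
  }
})

test_that("climatology CSV serialization is faithful", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  write_climatology_csv(w$clim, dir)
  f <- utils::read.csv(file.path(dir, "fields.csv"))
  expect_equal(nrow(f), length(w$clim$lat) * length(w$clim$lon) *
                 length(w$clim$depths) * length(w$clim$months))
  i <- 1000
  expect_equal(f$temperature[i],
               clim_lookup(w$clim, "temperature", f$lat[i], f$lon[i],
                           f$month[i], f$depth[i]))
})
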