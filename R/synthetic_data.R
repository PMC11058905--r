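# Synthetic world: gridded climatology, UVP-style profiles and imaged
# objects with a known environment -> abundance response, plus the
# closed-form budgets that response implies. Every downstream stage of
# the pipeline can be exercised and validated against these ground
# truths without any external data.

#' Specify a synthetic world
#'
#' Defines the grid, the smooth environmental field generators, the taxa
#' with their size spectra, and the true response linking environmental
#' predictors to expected abundance. The true response for each taxon is
#' log-linear in layer-mean temperature and log10 surface chlorophyll
#' with one interaction, plus a per-layer offset:
#' \deqn{\log \lambda = b_0 + b_T T + b_C \log_{10}(chl)
#'       + b_{TC} \, T \log_{10}(chl) + o_{layer}}
#' where \eqn{\lambda} is the expected number of individuals per m^3.
#' Coefficients live in the spec, not in code.
#'
#' @param resolution Grid resolution in degrees (default 2).
#' @param lat_range,lon_range Extents in degrees (defaults c(-80, 80),
#'   c(-180, 180)).
#' @param depths Depth levels of the climatology in metres (default
#'   0--800 by 100, mirroring nutrient climatologies that stop at 800 m).
#' @param months Month set (default 1:12).
#' @param land_fraction Fraction of cells masked as land (default 0.2).
#' @param noise_sd Named list of field noise SDs: `temperature` (degrees
#'   C, constant within a water column so the vertical gradient is
#'   preserved), `log_chl` (multiplicative, log scale), `response`
#'   (lognormal spatial heterogeneity of the true rate; 0 = noiseless).
#' @param taxa data.frame with columns `taxon`, `median_esd_mm`,
#'   `sdlog` (lognormal size spectrum, truncated to 0.6--20 mm).
#' @param response Named list (one element per taxon) of coefficient
#'   lists: `b0`, `temp`, `log_chl`, `interaction`, and `layer_offset`
#'   (named vector over layers).
#' @param pixel_mm Camera pixel size, mm per pixel (default 0.088, a
#'   realistic UVP5 value).
#' @param bin_thickness Depth-bin thickness for volume bookkeeping, m.
#' @param volume_per_m Imaged water volume per metre of descent, m^3
#'   (default 0.01: about one litre every 10 cm).
#' @param max_depth Profile depth, m (default 1000).
#' @param seed Integer seed; a fixed seed makes every generated dataset
#'   reproducible.
#' @return An object of class `rz_world_spec`.
#' @export
synthetic_world_spec <- function(resolution = 2,
                                 lat_range = c(-80, 80),
                                 lon_range = c(-180, 180),
                                 depths = seq(0, 800, by = 100),
                                 months = 1:12,
                                 land_fraction = 0.2,
                                 noise_sd = list(temperature = 0.3,
                                                 log_chl = 0.15,
                                                 response = 0),
                                 taxa = default_taxa(),
                                 response = default_response(),
                                 pixel_mm = 0.088,
                                 bin_thickness = 25,
                                 volume_per_m = 0.01,
                                 max_depth = 1000,
                                 seed = 1L) {
  stopifnot(resolution > 0, diff(lat_range) > 0, diff(lon_range) > 0,
            length(depths) >= 2, length(months) >= 1,
            land_fraction >= 0, land_fraction < 1,
            nrow(taxa) >= 1, all(c("taxon", "median_esd_mm", "sdlog")
                                 %in% names(taxa)))
  if (any(taxa$median_esd_mm < 0.6) || any(taxa$median_esd_mm > 20))
    stop("size-spectrum medians must lie within the 0.6-20 mm window")
  if (!all(taxa$taxon %in% names(response)))
    stop("every taxon needs a response coefficient set")
  lat <- seq(lat_range[1] + resolution / 2, lat_range[2], by = resolution)
  lon <- seq(lon_range[1] + resolution / 2, lon_range[2], by = resolution)
  if (!length(lat) || !length(lon)) stop("degenerate grid: zero cells")
  defaults <- list(temperature = 0.3, log_chl = 0.15, response = 0)
  noise_sd <- utils::modifyList(defaults, as.list(noise_sd))
  structure(list(resolution = resolution, lat = lat, lon = lon,
                 lat_range = lat_range, lon_range = lon_range,
                 depths = depths, months = months,
                 land_fraction = land_fraction, noise_sd = noise_sd,
                 taxa = taxa, response = response, pixel_mm = pixel_mm,
                 bin_thickness = bin_thickness, volume_per_m = volume_per_m,
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "rz_world_spec")
}

#' Default synthetic taxa: a mesopelagic flux-feeding phaeodarian and an
#' epipelagic mixotrophic collodarian, with lognormal size spectra.
#' @return data.frame of taxa and size-spectrum parameters.
#' @export
default_taxa <- function() {
  data.frame(taxon = c("Aulacanthidae", "Collodaria_colonial"),
             median_esd_mm = c(1.4, 2.5),
             sdlog = c(0.35, 0.45),
             stringsAsFactors = FALSE)
}

#' Default true-response coefficients (log individuals per m^3)
#'
#' The phaeodarian peaks in cold, productive waters and lives mostly in
#' the mesopelagic; the collodarian prefers warm surface waters.
#' @return Named list of coefficient lists.
#' @export
default_response <- function() {
  list(
    Aulacanthidae = list(b0 = 0.2, temp = -0.06, log_chl = 0.8,
                         interaction = 0.01,
                         layer_offset = c(epipelagic = -1.2, mesopelagic = 0)),
    Collodaria_colonial = list(b0 = -2.6, temp = 0.10, log_chl = 0.3,
                               interaction = 0,
                               layer_offset = c(epipelagic = 0,
                                                mesopelagic = -2.5))
  )
}

# --- climatology ------------------------------------------------------------

# Smooth deterministic surface fields; latitudinal + seasonal structure.
surface_temperature <- function(lat, month) {
  2.5 + 25.5 * cos(lat * pi / 180)^2 +
    1.0 * sin(2 * pi * (month - 4) / 12) * sign(lat + 1e-9)
}

surface_chl <- function(lat, month) {
  0.06 + 0.55 * exp(-((abs(lat) - 52) / 12)^2) +
    0.35 * exp(-(lat / 10)^2) +
    0.10 * (1 + sin(2 * pi * (month - 5) / 12) * sign(lat + 1e-9)) / 2
}

#' Generate a gridded monthly climatology
#'
#' Builds smooth temperature, salinity, oxygen and nutrient fields on the
#' spec's lat x lon x depth x month grid, surface chlorophyll-a and
#' bathymetry on lat x lon (x month), and a seeded random land mask.
#' Default temperature decays exponentially towards a deep value, so it
#' is strictly decreasing with depth in every water column; its noise is
#' drawn once per column, preserving that monotonicity.
#'
#' @param spec A [synthetic_world_spec()].
#' @return An object of class `rz_climatology`: grid axes, a `fields`
#'   list of 4-d arrays (lat, lon, depth, month), `chl` (lat, lon,
#'   month), `bathymetry` and logical `ocean` matrices.
#' @export
generate_climatology <- function(spec) {
  stopifnot(inherits(spec, "rz_world_spec"))
  set.seed(spec$seed)
  nlat <- length(spec$lat); nlon <- length(spec$lon)
  nd <- length(spec$depths); nm <- length(spec$months)
  dim4 <- c(nlat, nlon, nd, nm)

  ocean <- matrix(stats::runif(nlat * nlon) >= spec$land_fraction,
                  nlat, nlon)
  t_noise <- matrix(stats::rnorm(nlat * nlon, 0, spec$noise_sd$temperature),
                    nlat, nlon)
  chl_noise <- matrix(stats::rnorm(nlat * nlon, 0, spec$noise_sd$log_chl),
                      nlat, nlon)

  fld <- function(f) {
    a <- array(NA_real_, dim4)
    for (mi in seq_len(nm)) for (di in seq_len(nd))
      a[, , di, mi] <- outer(spec$lat, spec$lon, function(la, lo)
        f(la, lo, spec$depths[di], spec$months[mi]))
    a
  }
  decay <- function(depth) exp(-depth / 300)
  fields <- list(
    temperature = fld(function(la, lo, d, m)
      1 + (pmax(surface_temperature(la, m) + t_noise[cbind(
        match(la, spec$lat), match(lo, spec$lon))], 1.2) - 1) * decay(d)),
    salinity = fld(function(la, lo, d, m)
      34 + 1.6 * cos(la * pi / 180)^2 * exp(-d / 400) - 0.2 * decay(d)),
    oxygen = fld(function(la, lo, d, m)
      320 - 60 * cos(la * pi / 180)^2 -
        140 * exp(-((d - 450) / 280)^2)),
    silicate = fld(function(la, lo, d, m)
      2 + 60 * (abs(la) / 90)^2 + 80 * (1 - exp(-d / 600))),
    phosphate = fld(function(la, lo, d, m)
      0.2 + 1.2 * (abs(la) / 90) + 1.8 * (1 - exp(-d / 500))),
    nitrate = fld(function(la, lo, d, m)
      1 + 12 * (abs(la) / 90) + 25 * (1 - exp(-d / 500)))
  )
  chl <- array(NA_real_, c(nlat, nlon, nm))
  for (mi in seq_len(nm))
    chl[, , mi] <- outer(spec$lat, spec$lon, function(la, lo)
      surface_chl(la, spec$months[mi])) * exp(chl_noise)
  bathy <- outer(spec$lat, spec$lon, function(la, lo)
    3500 + 1200 * cos(lo * pi / 180) * sin(la * pi / 90))
  bathy[!ocean] <- 0
  mask4 <- array(rep(ocean, nd * nm), dim4)
  for (f in names(fields)) fields[[f]][!mask4] <- NA_real_
  chl[array(rep(ocean, nm), c(nlat, nlon, nm)) == FALSE] <- NA_real_

  structure(list(lat = spec$lat, lon = spec$lon, depths = spec$depths,
                 months = spec$months, resolution = spec$resolution,
                 fields = fields, chl = chl, bathymetry = bathy,
                 ocean = ocean),
            class = "rz_climatology")
}

#' Look up a climatology field at arbitrary points
#'
#' Nearest grid node in latitude, longitude and month; linear
#' interpolation in depth; constant extrapolation beyond the shallowest
#' and deepest climatology levels (nutrient climatologies stop at 800 m,
#' so deeper queries hold the 800 m value).
#'
#' @param clim An `rz_climatology`.
#' @param field Field name (e.g. `"temperature"`), `"chl"` or
#'   `"bathymetry"`.
#' @param lat,lon,month,depth Vectors of query coordinates (recycled to
#'   a common length; `depth`/`month` ignored where the field lacks that
#'   axis).
#' @return Numeric vector of field values (`NA` over land).
#' @export
clim_lookup <- function(clim, field, lat, lon, month = clim$months[1],
                        depth = 0) {
  stopifnot(inherits(clim, "rz_climatology"))
  n <- max(length(lat), length(lon), length(month), length(depth))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  month <- rep_len(month, n); depth <- rep_len(depth, n)
  li <- nearest_index(lat, clim$lat)
  oi <- nearest_index(lon, clim$lon)
  mi <- nearest_index(month, clim$months)
  if (identical(field, "bathymetry"))
    return(clim$bathymetry[cbind(li, oi)])
  if (identical(field, "chl"))
    return(clim$chl[cbind(li, oi, mi)])
  arr <- clim$fields[[field]]
  if (is.null(arr)) stop("unknown climatology field: ", field)
  d <- pmin(pmax(depth, min(clim$depths)), max(clim$depths))
  i0 <- findInterval(d, clim$depths, rightmost.closed = TRUE)
  i1 <- pmin(i0 + 1, length(clim$depths))
  w <- ifelse(i1 == i0, 0,
              (d - clim$depths[i0]) / (clim$depths[i1] - clim$depths[i0]))
  v0 <- arr[cbind(li, oi, i0, mi)]
  v1 <- arr[cbind(li, oi, i1, mi)]
  (1 - w) * v0 + w * v1
}

nearest_index <- function(x, grid) {
  idx <- findInterval(x, c(-Inf, grid[-1] - diff(grid) / 2))
  pmin(pmax(idx, 1L), length(grid))
}

# --- true response ----------------------------------------------------------

# Layer-mean predictors per cell: WOA-style fields averaged over the
# layer's depth range and all months; chl over all months at the surface.
layer_predictors <- function(clim, layers = layer_defs()) {
  out <- list()
  for (i in seq_len(nrow(layers))) {
    sel <- clim$depths >= layers$depth_min[i] & clim$depths < layers$depth_max[i]
    if (!any(sel)) sel <- which.min(abs(clim$depths - layers$depth_min[i]))
    rows <- expand.grid(lat = clim$lat, lon = clim$lon,
                        KEEP.OUT.ATTRS = FALSE)
    for (f in names(clim$fields))
      rows[[f]] <- as.vector(apply(clim$fields[[f]][, , sel, , drop = FALSE],
                                   c(1, 2), mean))
    rows$chl <- as.vector(apply(clim$chl, c(1, 2), mean))
    rows$bathymetry <- as.vector(clim$bathymetry)
    rows$ocean <- as.vector(clim$ocean)
    rows$layer <- layers$layer[i]
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

# Expected individuals per m^3 for one taxon from layer-mean predictors.
true_rate <- function(spec, taxon, temperature, chl, layer) {
  cf <- spec$response[[taxon]]
  if (is.null(cf)) stop("no response coefficients for taxon ", taxon)
  lc <- log10(chl)
  off <- cf$layer_offset[layer]
  exp(cf$b0 + cf$temp * temperature + cf$log_chl * lc +
        cf$interaction * temperature * lc + off)
}

#' Per-cell true expected concentrations implied by the world spec
#'
#' Evaluates, per ocean cell and layer, the expected abundance of each
#' taxon (individuals per m^3) and the expected concentration of a
#' quantity (ug m^-3), using the closed-form moments of the truncated
#' lognormal size spectrum; no sampling is involved.
#'
#' @param spec A [synthetic_world_spec()].
#' @param clim Matching [generate_climatology()] output.
#' @param quantity `"carbon"` (ug C m^-3, all taxa), `"bsi"`
#'   (ug Si m^-3, Phaeodaria only), `"carbon_demand"` (ug C m^-3 d^-1,
#'   Phaeodaria, layer-mean temperature), or `"bsi_production"`
#'   (ug Si m^-3 d^-1, Phaeodaria).
#' @param params [rate_params()] used for the rate quantities.
#' @param convention Sphere-volume convention, see [sphere_volume()].
#' @return data.frame: `lat`, `lon`, `layer`, `conc` (ocean cells only).
#' @export
true_concentration <- function(spec, clim, quantity = "carbon",
                               params = rate_params(),
                               convention = "as_printed") {
  env <- layer_predictors(clim)
  env <- env[env$ocean, , drop = FALSE]
  conc <- numeric(nrow(env))
  for (t in seq_len(nrow(spec$taxa))) {
    taxon <- spec$taxa$taxon[t]
    grp <- taxon_group(taxon)
    if (quantity != "carbon" && grp != "Phaeodaria") next
    lam <- true_rate(spec, taxon, env$temperature, env$chl, env$layer)
    q <- expected_individual_quantity(spec$taxa[t, ], quantity,
                                      env$temperature, params, convention)
    conc <- conc + lam * q
  }
  data.frame(lat = env$lat, lon = env$lon, layer = env$layer, conc = conc,
             stringsAsFactors = FALSE)
}

# E[quantity per individual] under the taxon's truncated lognormal size
# spectrum; temperature enters only the rate quantities.
expected_individual_quantity <- function(taxon_row, quantity, temperature,
                                         params, convention) {
  meanlog <- log(taxon_row$median_esd_mm)
  sdlog <- taxon_row$sdlog
  vol_coef <- if (convention == "as_printed") (4 / 3) * pi else pi / 6
  switch(quantity,
    carbon = {
      b <- 0.455
      10^0.958 * vol_coef^b * tlnorm_moment(3 * b, meanlog, sdlog, 0.6, 20)
    },
    bsi = {
      b <- 0.52
      10^-4.05 * vol_coef^b * tlnorm_moment(3 * b, meanlog, sdlog, 0.6, 20)
    },
    carbon_demand = {
      b <- 0.455
      eqc <- 10^0.958 * vol_coef^b * tlnorm_moment(3 * b, meanlog, sdlog, 0.6, 20)
      eqc / (params$gge * q10_turnover(params$tau, temperature,
                                       params$t_ref, params$q10))
    },
    bsi_production = bsi_production(params$rho_si[["mid"]], temperature,
                                    params$t_ref, params$q10),
    stop("unknown quantity: ", quantity)
  )
}

#' Moments of a truncated lognormal
#'
#' `E[X^p | L <= X <= U]` for `X ~ lognormal(meanlog, sdlog)` truncated
#' to `[L, U]`, in closed form via the lognormal partial-moment identity.
#'
#' @param p Moment order (any real).
#' @param meanlog,sdlog Lognormal parameters.
#' @param lower,upper Truncation bounds, `0 < lower < upper`.
#' @return The conditional moment.
#' @export
tlnorm_moment <- function(p, meanlog, sdlog, lower, upper) {
  stopifnot(lower > 0, upper > lower, sdlog >= 0)
  if (sdlog == 0) {  # point mass at the median
    x <- min(max(exp(meanlog), lower), upper)
    return(x^p)
  }
  a <- (log(lower) - meanlog) / sdlog
  b <- (log(upper) - meanlog) / sdlog
  num <- stats::pnorm(b - p * sdlog) - stats::pnorm(a - p * sdlog)
  den <- stats::pnorm(b) - stats::pnorm(a)
  exp(p * meanlog + p^2 * sdlog^2 / 2) * num / den
}

# Truncated lognormal sampler (inverse-CDF).
rtrunclnorm <- function(n, meanlog, sdlog, lower, upper) {
  if (sdlog == 0)
    return(rep(min(max(exp(meanlog), lower), upper), n))
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# --- profile sampling -------------------------------------------------------

#' Simulate UVP-style vertical profiles with imaged objects
#'
#' Places `n_profiles` casts on random ocean cells (uniform over cells,
#' position jittered within the cell, month uniform over the spec's
#' month set). Each cast images `volume_per_m` m^3 per metre of descent,
#' bookkept in depth bins of `bin_thickness`. Object counts per bin and
#' taxon are Poisson with rate = true response (for the cast's cell and
#' the bin's layer) x bin volume; ESDs are drawn from the taxon's
#' truncated lognormal and pixel areas back-computed so that
#' [esd_from_area()] inverts the drawn ESD exactly.
#'
#' @param spec A [synthetic_world_spec()].
#' @param n_profiles Number of casts (>= 1).
#' @param clim Matching climatology (generated from `spec` if omitted).
#' @param seed Seed (defaults to `spec$seed + 1`).
#' @return An object of class `rz_profiles`: data.frames `profiles`
#'   (`profile_id`, `lat`, `lon`, `month`, `date`, `max_depth`),
#'   `volumes` (`profile_id`, `depth_min`, `depth_max`, `volume_m3`) and
#'   `objects` (`object_id`, `taxon`, `group`, `esd_um`, `area_um2`,
#'   `area_px`, `depth_m`, `profile_id`, `lat`, `lon`, `month`, `date`).
#' @export
sample_profiles <- function(spec, n_profiles, clim = NULL,
                            seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "rz_world_spec"), n_profiles >= 1)
  if (is.null(clim)) clim <- generate_climatology(spec)
  set.seed(as.integer(seed))
  ocean_idx <- which(clim$ocean, arr.ind = TRUE)
  if (!nrow(ocean_idx)) stop("no ocean cells in this world")
  pick <- ocean_idx[sample.int(nrow(ocean_idx), n_profiles, replace = TRUE),
                    , drop = FALSE]
  jit <- spec$resolution / 2
  plat <- clim$lat[pick[, 1]] + stats::runif(n_profiles, -jit, jit)
  plon <- clim$lon[pick[, 2]] + stats::runif(n_profiles, -jit, jit)
  pmonth <- sample(spec$months, n_profiles, replace = TRUE)
  profiles <- data.frame(
    profile_id = sprintf("prof%05d", seq_len(n_profiles)),
    lat = plat, lon = plon, month = pmonth,
    date = sprintf("2020-%02d-15", pmonth),
    max_depth = spec$max_depth, stringsAsFactors = FALSE)

  bins <- seq(0, spec$max_depth, by = spec$bin_thickness)
  bin_lo <- bins[-length(bins)]; bin_hi <- bins[-1]
  bin_vol <- (bin_hi - bin_lo) * spec$volume_per_m
  bin_layer <- assign_layer(bin_lo)
  nb <- length(bin_lo)
  volumes <- data.frame(
    profile_id = rep(profiles$profile_id, each = nb),
    depth_min = rep(bin_lo, n_profiles), depth_max = rep(bin_hi, n_profiles),
    volume_m3 = rep(bin_vol, n_profiles), stringsAsFactors = FALSE)

  # layer-mean predictors at each cast's cell
  env <- layer_predictors(clim)
  key <- paste(env$lat, env$lon, env$layer)
  obj <- list()
  resp_sd <- spec$noise_sd$response
  for (t in seq_len(nrow(spec$taxa))) {
    taxon <- spec$taxa$taxon[t]
    lam_layer <- matrix(0, n_profiles, 2,
                        dimnames = list(NULL, c("epipelagic", "mesopelagic")))
    for (ly in colnames(lam_layer)) {
      k <- match(paste(clim$lat[pick[, 1]], clim$lon[pick[, 2]], ly), key)
      lam_layer[, ly] <- true_rate(spec, taxon, env$temperature[k],
                                   env$chl[k], ly)
    }
    if (resp_sd > 0)
      lam_layer <- lam_layer *
        exp(stats::rnorm(length(lam_layer), -resp_sd^2 / 2, resp_sd))
    lam_bins <- lam_layer[, bin_layer, drop = FALSE]  # n_profiles x nb
    counts <- stats::rpois(length(lam_bins),
                           as.vector(t(lam_bins)) * rep(bin_vol, n_profiles))
    if (sum(counts) == 0) next
    prof_i <- rep(rep(seq_len(n_profiles), each = nb), counts)
    bin_i <- rep(rep(seq_len(nb), n_profiles), counts)
    nobj <- length(prof_i)
    esd_mm <- rtrunclnorm(nobj, log(spec$taxa$median_esd_mm[t]),
                          spec$taxa$sdlog[t], 0.6, 20)
    esd_um <- esd_mm * 1000
    area_um2 <- pi / 4 * esd_um^2
    obj[[taxon]] <- data.frame(
      taxon = taxon, group = taxon_group(taxon),
      esd_um = esd_um, area_um2 = area_um2,
      area_px = area_um2 / (spec$pixel_mm * 1000)^2,
      depth_m = bin_lo[bin_i] +
        stats::runif(nobj, 0, spec$bin_thickness),
      profile_id = profiles$profile_id[prof_i],
      lat = profiles$lat[prof_i], lon = profiles$lon[prof_i],
      month = profiles$month[prof_i], date = profiles$date[prof_i],
      stringsAsFactors = FALSE)
  }
  objects <- if (length(obj)) do.call(rbind, obj) else
    data.frame(taxon = character(), group = character(), esd_um = numeric(),
               area_um2 = numeric(), area_px = numeric(), depth_m = numeric(),
               profile_id = character(), lat = numeric(), lon = numeric(),
               month = integer(), date = character(),
               stringsAsFactors = FALSE)
  if (nrow(objects)) {
    objects <- objects[order(objects$profile_id, objects$depth_m), ]
    objects$object_id <- sprintf("obj%07d", seq_len(nrow(objects)))
    rownames(objects) <- NULL
    objects <- objects[, c("object_id", setdiff(names(objects), "object_id"))]
  } else objects$object_id <- character()
  structure(list(profiles = profiles, volumes = volumes, objects = objects,
                 pixel_mm = spec$pixel_mm),
            class = "rz_profiles")
}

#' True global budgets implied by the world spec
#'
#' Closed-form expectation of the globally integrated stock (or rate)
#' per layer: expected per-individual content x expected abundance,
#' integrated over the layer thickness and the ocean cell areas. Ground
#' truth for parameter-recovery checks of the mapped predictions.
#'
#' @inheritParams true_concentration
#' @param unit Output mass unit (default `"Pg"` for carbon, use `"Tg"`
#'   for silica).
#' @return Named list: per-layer totals and `total` (their sum), in
#'   `unit` (per day for the rate quantities).
#' @export
true_budget <- function(spec, clim, quantity = "carbon",
                        params = rate_params(), convention = "as_printed",
                        unit = "Pg") {
  tc <- true_concentration(spec, clim, quantity, params, convention)
  ld <- layer_defs()
  res <- spec$resolution
  area <- cell_area(tc$lat - res / 2, tc$lat + res / 2, dlon = res)
  thick <- ld$thickness[match(tc$layer, ld$layer)]
  totals <- tapply(tc$conc * thick * area, tc$layer, sum)
  out <- as.list(convert_mass(as.numeric(totals), "ug", unit))
  names(out) <- names(totals)
  out$total <- sum(unlist(out))
  out
}

# --- serialization ----------------------------------------------------------

#' Write simulated objects as an EcoTaxa-style TSV
#'
#' Columns: `object_id`, `object_annotation_category`, `object_area`
#' (pixels), `object_depth_min` (m), `acq_pixel` (mm per pixel),
#' `sample_id`, `object_lat`, `object_lon`, `object_date`. Round-trips
#' through [read_ecotaxa()].
#'
#' @param sim An `rz_profiles` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecotaxa_tsv <- function(sim, path) {
  o <- sim$objects
  out <- data.frame(object_id = o$object_id,
                    object_annotation_category = o$taxon,
                    object_area = o$area_px,
                    object_depth_min = o$depth_m,
                    acq_pixel = sim$pixel_mm,
                    sample_id = o$profile_id,
                    object_lat = o$lat, object_lon = o$lon,
                    object_date = o$date, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a climatology as long-format CSV tables
#'
#' Plain-text representation: one `fields.csv` (lat, lon, depth, month,
#' one column per field), one `surface.csv` (lat, lon, month, chl) and
#' one `cells.csv` (lat, lon, bathymetry, ocean).
#'
#' @param clim An `rz_climatology`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_climatology_csv <- function(clim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- expand.grid(lat = clim$lat, lon = clim$lon, depth = clim$depths,
                   month = clim$months, KEEP.OUT.ATTRS = FALSE)
  for (f in names(clim$fields)) g[[f]] <- as.vector(clim$fields[[f]])
  utils::write.csv(g, file.path(dir, "fields.csv"), row.names = FALSE)
  s <- expand.grid(lat = clim$lat, lon = clim$lon, month = clim$months,
                   KEEP.OUT.ATTRS = FALSE)
  s$chl <- as.vector(clim$chl)
  utils::write.csv(s, file.path(dir, "surface.csv"), row.names = FALSE)
  cells <- expand.grid(lat = clim$lat, lon = clim$lon, KEEP.OUT.ATTRS = FALSE)
  cells$bathymetry <- as.vector(clim$bathymetry)
  cells$ocean <- as.vector(clim$ocean)
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}
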