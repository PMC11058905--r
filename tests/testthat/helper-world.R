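# Shared synthetic worlds, built once per test run.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

# Default study-condition world (2 degree grid).
default_world <- function() {
  cached("default", {
    spec <- synthetic_world_spec()
    list(spec = spec, clim = generate_climatology(spec))
  })
}

default_sim <- function() {
  cached("default_sim", {
    w <- default_world()
    sample_profiles(w$spec, 300, w$clim)
  })
}

# Small, fast world for structural tests.
tiny_spec <- function(seed = 7, land_fraction = 0.2, ...) {
  synthetic_world_spec(resolution = 10, depths = seq(0, 800, 200),
                       months = 1:3, land_fraction = land_fraction,
                       seed = seed, ...)
}

tiny_world <- function() {
  cached("tiny", {
    spec <- tiny_spec()
    list(spec = spec, clim = generate_climatology(spec))
  })
}

default_sim_small <- function() {
  cached("tiny_sim", {
    w <- tiny_world()
    sample_profiles(w$spec, 80, w$clim)
  })
}

# Hand-built climatology: full control over fields and mask.
manual_clim <- function(lat, lon, depths = c(0, 800), months = 1L,
                        temp_fun = function(d) rep(10, length(d)),
                        ocean = NULL) {
  nlat <- length(lat); nlon <- length(lon)
  nd <- length(depths); nm <- length(months)
  if (is.null(ocean)) ocean <- matrix(TRUE, nlat, nlon)
  tarr <- array(NA_real_, c(nlat, nlon, nd, nm))
  for (di in seq_len(nd)) tarr[, , di, ] <- temp_fun(depths[di])
  fields <- list(temperature = tarr)
  for (f in c("salinity", "oxygen", "silicate", "phosphate", "nitrate")) {
    a <- array(1, c(nlat, nlon, nd, nm))
    fields[[f]] <- a
  }
  mask4 <- array(rep(ocean, nd * nm), c(nlat, nlon, nd, nm))
  for (f in names(fields)) fields[[f]][!mask4] <- NA_real_
  chl <- array(0.2, c(nlat, nlon, nm))
  structure(list(lat = lat, lon = lon, depths = depths, months = months,
                 resolution = if (nlat > 1) diff(lat)[1] else 1,
                 fields = fields, chl = chl,
                 bathymetry = matrix(4000, nlat, nlon), ocean = ocean),
            class = "rz_climatology")
}

# Noiseless model table: true concentrations joined to predictors.
noiseless_table <- function(quantity = "carbon") {
  cached(paste0("noiseless_", quantity), {
    w <- default_world()
    tc <- true_concentration(w$spec, w$clim, quantity)
    env <- layer_predictors_tbl(w$clim)
    k <- match(paste(tc$lat, tc$lon, tc$layer),
               paste(env$lat, env$lon, env$layer))
    tab <- cbind(tc, env[k, brt_predictors()])
    tab$cell_lat <- tab$lat
    tab$cell_lon <- tab$lon
    tab
  })
}

layer_predictors_tbl <- function(clim) {
  env <- getFromNamespace("layer_predictors", "rhizcensus")(clim)
  env[env$ocean, , drop = FALSE]
}
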