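# Aggregation of per-individual quantities into per-cell, per-layer
# concentrations matched to environmental predictors.

# Great-circle distance (haversine), metres.
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Assign positions to grid cells
#'
#' Floor-based binning onto the climatology grid: a position belongs to
#' the cell whose \eqn{[lower, upper)} bounds contain it. Positions that
#' land on a masked (land) cell are reassigned to the nearest ocean cell
#' by great-circle distance between cell centres (ties broken by lowest
#' cell index); positions with no ocean cell within `max_reassign_km`
#' are dropped (`NA`) with a warning.
#'
#' @param lat,lon Position vectors, degrees.
#' @param clim An `rz_climatology` providing the grid and ocean mask.
#' @param max_reassign_km Search radius for the nearest-ocean-cell
#'   fallback (default 1500 km).
#' @return data.frame with `cell_lat`, `cell_lon` (cell centres, `NA` if
#'   dropped) and logical `reassigned`.
#' @export
assign_cell <- function(lat, lon, clim, max_reassign_km = 1500) {
  res <- clim$resolution
  lat0 <- clim$lat[1] - res / 2
  lon0 <- clim$lon[1] - res / 2
  li <- pmin(pmax(floor((lat - lat0) / res) + 1, 1L), length(clim$lat))
  oi <- pmin(pmax(floor((lon - lon0) / res) + 1, 1L), length(clim$lon))
  on_land <- !clim$ocean[cbind(li, oi)]
  reassigned <- rep(FALSE, length(lat))
  if (any(on_land)) {
    oc <- which(clim$ocean, arr.ind = TRUE)  # ordered by column-major index
    oc_lat <- clim$lat[oc[, 1]]; oc_lon <- clim$lon[oc[, 2]]
    for (i in which(on_land)) {
      d <- haversine_m(clim$lat[li[i]], clim$lon[oi[i]], oc_lat, oc_lon)
      j <- which.min(d)  # first minimum = lowest cell index on ties
      if (d[j] > max_reassign_km * 1000) {
        li[i] <- NA; oi[i] <- NA
        warning("position (", lat[i], ", ", lon[i],
                ") has no ocean cell within ", max_reassign_km,
                " km; dropped")
      } else {
        li[i] <- oc[j, 1]; oi[i] <- oc[j, 2]
        reassigned[i] <- TRUE
      }
    }
  }
  data.frame(cell_lat = clim$lat[li], cell_lon = clim$lon[oi],
             reassigned = reassigned)
}

#' Attach per-individual elemental and rate quantities to objects
#'
#' Computes, per imaged object: biovolume (mm^3, from ESD under the
#' chosen sphere convention), carbon content `q_c` (ug C), silica
#' content `q_bsi` (ug Si; Phaeodaria only, 0 otherwise), carbon demand
#' `cd` (ug C d^-1; Phaeodaria, using the temperature looked up from
#' the climatology at the object's position, month and depth; 0 in the
#' epipelagic unless `include_epipelagic_demand`), and silica production
#' `rho` (ug Si d^-1; Phaeodaria, mid reference rate).
#'
#' @param objects data.frame with `taxon`, `esd_um`, `depth_m`, `lat`,
#'   `lon`, `month` columns (e.g. from [sample_profiles()] or
#'   [read_ecotaxa()] plus a month column).
#' @param clim Climatology for temperature lookup.
#' @param params [rate_params()].
#' @param convention Sphere-volume convention (see [sphere_volume()]).
#' @param include_epipelagic_demand Count epipelagic Phaeodaria carbon
#'   demand too (off by default: demand is a mesopelagic estimate).
#' @return `objects` with columns `volume_mm3`, `q_c`, `q_bsi`, `cd`,
#'   `rho`, `t_obs`, `layer` appended.
#' @export
quantify_objects <- function(objects, clim, params = rate_params(),
                             convention = "as_printed",
                             include_epipelagic_demand = FALSE) {
  stopifnot(all(c("taxon", "esd_um", "depth_m", "lat", "lon", "month")
                %in% names(objects)))
  grp <- taxon_group(objects$taxon)
  esd_mm <- objects$esd_um / 1000
  v_mm3 <- sphere_volume(esd_mm, convention)
  out <- objects
  out$group <- grp
  out$volume_mm3 <- v_mm3
  out$layer <- assign_layer(objects$depth_m)
  out$q_c <- carbon_content(v_mm3)
  out$t_obs <- clim_lookup(clim, "temperature", objects$lat, objects$lon,
                           objects$month, objects$depth_m)
  is_phaeo <- grp == "Phaeodaria"
  out$q_bsi <- 0
  out$q_bsi[is_phaeo] <- bsi_content(v_mm3[is_phaeo])
  tau_t <- q10_turnover(params$tau, out$t_obs, params$t_ref, params$q10)
  out$cd <- 0
  demand_rows <- is_phaeo &
    (include_epipelagic_demand | out$layer != "epipelagic")
  out$cd[demand_rows] <- carbon_demand(out$q_c[demand_rows], params$gge,
                                       tau_t[demand_rows])
  out$rho <- 0
  out$rho[is_phaeo] <- bsi_production(params$rho_si[["mid"]],
                                      out$t_obs[is_phaeo],
                                      params$t_ref, params$q10)
  out
}

#' Per-profile, per-layer concentrations
#'
#' For every profile and layer, divides the summed per-individual
#' quantities by the total imaged volume in that layer:
#' `conc = sum(q) / sum(volume)` in ug m^-3 (or ug m^-3 d^-1 for
#' rates). A layer with positive imaged volume and zero objects yields a
#' structural zero, kept as data; objects in a layer with no recorded
#' volume are a bookkeeping error. Layers whose summed bin volume covers
#' less than `coverage` of the nominal layer volume are dropped (the
#' profile did not sample that layer fully).
#'
#' @param objects Quantified objects (see [quantify_objects()]) with a
#'   `profile_id` column.
#' @param volumes data.frame `profile_id`, `depth_min`, `depth_max`,
#'   `volume_m3` (per depth bin).
#' @param quantities Character vector of object columns to aggregate.
#' @param layers Layer table, default [layer_defs()].
#' @param coverage Minimum fraction of the layer's depth range that must
#'   be volume-sampled (default 0.9).
#' @return data.frame: `profile_id`, `layer`, `volume_m3`, one column
#'   per quantity.
#' @export
profile_layer_concentration <- function(objects, volumes,
                                        quantities = c("q_c", "q_bsi",
                                                       "cd", "rho"),
                                        layers = layer_defs(),
                                        coverage = 0.9) {
  stopifnot(all(quantities %in% names(objects)))
  volumes$layer <- assign_layer(volumes$depth_min, layers)
  volumes <- volumes[!is.na(volumes$layer), , drop = FALSE]
  vol_key <- interaction(volumes$profile_id, volumes$layer, drop = FALSE)
  vol <- tapply(volumes$volume_m3, vol_key, sum)
  span <- tapply(volumes$depth_max - volumes$depth_min, vol_key, sum)

  grid <- expand.grid(profile_id = unique(volumes$profile_id),
                      layer = layers$layer, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- paste(grid$profile_id, grid$layer, sep = ".")
  grid$volume_m3 <- as.numeric(vol[key])
  grid$span <- as.numeric(span[key])
  thick <- layers$thickness[match(grid$layer, layers$layer)]

  obj_layer <- if (nrow(objects)) assign_layer(objects$depth_m, layers)
               else character()
  okey <- paste(objects$profile_id, obj_layer, sep = ".")
  orphan <- nrow(objects) &&
    any(!is.na(obj_layer) & (is.na(vol[okey]) | vol[okey] <= 0))
  if (isTRUE(orphan))
    stop("objects recorded in a layer with no imaged volume ",
         "(volume bookkeeping error)")
  for (q in quantities) {
    s <- if (nrow(objects))
      tapply(objects[[q]], okey, sum) else numeric()
    v <- s[key]
    grid[[q]] <- ifelse(is.na(v), 0, as.numeric(v)) / grid$volume_m3
  }
  ok <- !is.na(grid$volume_m3) & grid$volume_m3 > 0 &
    grid$span >= coverage * thick
  out <- grid[ok, c("profile_id", "layer", "volume_m3", quantities)]
  rownames(out) <- NULL
  out
}

#' Average profile concentrations within grid cells
#'
#' Assigns each profile to a grid cell (with the nearest-ocean-cell
#' fallback of [assign_cell()]) and averages the per-profile layer
#' concentrations within each cell x layer. The default is the
#' unweighted mean across profiles; `weighting = "volume"` weights each
#' profile by its imaged volume, which makes the cell concentration the
#' pooled `sum(q)/sum(v)` and conserves total mass exactly.
#'
#' @param prof_conc Output of [profile_layer_concentration()].
#' @param profiles data.frame `profile_id`, `lat`, `lon` (one row per
#'   profile).
#' @param clim Climatology providing grid and mask.
#' @param quantities Columns of `prof_conc` to average.
#' @param weighting `"unweighted"` (default) or `"volume"`.
#' @return data.frame: `cell_lat`, `cell_lon`, `layer`, `n_profiles`,
#'   one column per quantity.
#' @export
cell_layer_average <- function(prof_conc, profiles, clim,
                               quantities = c("q_c", "q_bsi", "cd", "rho"),
                               weighting = c("unweighted", "volume")) {
  weighting <- match.arg(weighting)
  cells <- assign_cell(profiles$lat, profiles$lon, clim)
  m <- match(prof_conc$profile_id, profiles$profile_id)
  df <- cbind(prof_conc,
              cell_lat = cells$cell_lat[m], cell_lon = cells$cell_lon[m])
  df <- df[!is.na(df$cell_lat), , drop = FALSE]
  key <- paste(df$cell_lat, df$cell_lon, df$layer, sep = "|")
  w <- if (weighting == "volume") df$volume_m3 else rep(1, nrow(df))
  agg <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(df)), key)
  agg <- agg[match(names(idx), agg$key), , drop = FALSE]
  parts <- do.call(rbind, strsplit(names(idx), "|", fixed = TRUE))
  out <- data.frame(cell_lat = as.numeric(parts[, 1]),
                    cell_lon = as.numeric(parts[, 2]),
                    layer = parts[, 3],
                    n_profiles = lengths(idx),
                    stringsAsFactors = FALSE)
  for (q in quantities)
    out[[q]] <- vapply(idx, function(i)
      sum(df[[q]][i] * w[i]) / sum(w[i]), numeric(1))
  rownames(out) <- NULL
  out
}

#' Build the model table: responses plus environmental predictors
#'
#' Runs quantification, per-profile layer concentration and cell
#' averaging, then joins the layer-mean environmental predictors
#' (temperature, salinity, oxygen, silicate, phosphate, nitrate averaged
#' over the layer's depth range and the climatology's months; surface
#' chlorophyll-a; bathymetry). Cells with incomplete predictors are
#' excluded with a message. One row per cell x layer.
#'
#' @param sim An `rz_profiles` object (or a list with `objects`,
#'   `volumes`, `profiles`).
#' @param clim Climatology.
#' @param params [rate_params()].
#' @param quantities Response columns to build.
#' @param weighting Passed to [cell_layer_average()].
#' @param convention Sphere-volume convention.
#' @return data.frame with responses, predictors and `n_profiles`.
#' @export
build_model_table <- function(sim, clim, params = rate_params(),
                              quantities = c("q_c", "q_bsi", "cd", "rho"),
                              weighting = "unweighted",
                              convention = "as_printed") {
  qobj <- quantify_objects(sim$objects, clim, params, convention)
  pc <- profile_layer_concentration(qobj, sim$volumes, quantities)
  cl <- cell_layer_average(pc, sim$profiles, clim, quantities, weighting)
  env <- layer_predictors(clim)
  k <- match(paste(cl$cell_lat, cl$cell_lon, cl$layer),
             paste(env$lat, env$lon, env$layer))
  pred_cols <- c(names(clim$fields), "chl", "bathymetry")
  for (p in pred_cols) cl[[p]] <- env[[p]][k]
  complete <- stats::complete.cases(cl[, pred_cols])
  if (any(!complete))
    message(sum(!complete), " cell-layer record(s) dropped for ",
            "incomplete predictors")
  cl[complete, , drop = FALSE]
}
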