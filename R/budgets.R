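# Layer integration, cell areas, global/regional sums, attenuation ratios.

EARTH_RADIUS_M <- 6371000

#' Depth layer definitions
#'
#' The two canonical pelagic layers used throughout: epipelagic
#' \eqn{[0, 200)} m and mesopelagic \eqn{[200, 1000)} m, with integration
#' thicknesses 200 m and 800 m. Depth bins are half-open on the upper
#' bound, so an object at exactly 200 m is mesopelagic.
#'
#' @return data.frame with columns `layer`, `depth_min`, `depth_max`,
#'   `thickness`.
#' @export
layer_defs <- function() {
  data.frame(layer = c("epipelagic", "mesopelagic"),
             depth_min = c(0, 200), depth_max = c(200, 1000),
             thickness = c(200, 800), stringsAsFactors = FALSE)
}

#' Assign depths to layers
#' @param depth_m Numeric depths in metres.
#' @param layers Layer table, default [layer_defs()].
#' @return Character vector of layer names (`NA` below the deepest layer).
#' @export
assign_layer <- function(depth_m, layers = layer_defs()) {
  out <- rep(NA_character_, length(depth_m))
  for (i in seq_len(nrow(layers)))
    out[depth_m >= layers$depth_min[i] & depth_m < layers$depth_max[i]] <-
      layers$layer[i]
  out
}

#' Integrate a concentration over a layer
#'
#' Exact product of a mean concentration (ug m^-3) and the layer
#' thickness (m), giving ug m^-2.
#'
#' @param conc Concentration(s), ug m^-3, non-negative.
#' @param thickness Layer thickness in metres (200 epipelagic, 800
#'   mesopelagic), or a layer name from [layer_defs()].
#' @return Integrated value, ug m^-2.
#' @export
integrate_layer <- function(conc, thickness) {
  if (is.character(thickness)) {
    ld <- layer_defs()
    idx <- match(thickness, ld$layer)
    if (any(is.na(idx))) stop("unknown layer name")
    thickness <- ld$thickness[idx]
  }
  if (any(conc < 0, na.rm = TRUE))
    stop("negative concentration: floor predictions at 0 upstream")
  conc * thickness
}

#' Integrate the top 500 m
#'
#' Epipelagic concentration over its full 200 m plus the mesopelagic
#' concentration over the top 300 m of that layer:
#' `epi * 200 + meso * 300` (ug m^-2). Missing layers propagate `NA`.
#'
#' @param epi_conc,meso_conc Layer mean concentrations, ug m^-3.
#' @return Integrated value, ug m^-2.
#' @export
integrate_top500 <- function(epi_conc, meso_conc) {
  integrate_layer(epi_conc, 200) + integrate_layer(meso_conc, 300)
}

#' Area of a 1-degree (or custom) latitude-longitude cell
#'
#' Spherical formula `A = R^2 * dlon * (sin(lat_max) - sin(lat_min))`
#' with R = 6,371,000 m: decreasing toward the poles and symmetric
#' between hemispheres; summed over all bands and 360 degrees of
#' longitude it closes to the sphere area 4 pi R^2.
#'
#' @param lat_min Southern edge of the band, degrees.
#' @param lat_max Northern edge, degrees; default `lat_min + dlat`.
#' @param dlon Cell width in degrees of longitude (default 1).
#' @param dlat Band height in degrees (default 1), used when `lat_max`
#'   is missing.
#' @return Cell area in m^2.
#' @export
cell_area <- function(lat_min, lat_max = lat_min + dlat, dlon = 1, dlat = 1) {
  if (any(abs(lat_min) > 90) || any(abs(lat_max) > 90))
    stop("latitudes must lie in [-90, 90]")
  if (any(lat_max <= lat_min)) stop("inverted latitude band")
  EARTH_RADIUS_M^2 * (dlon * pi / 180) *
    (sin(lat_max * pi / 180) - sin(lat_min * pi / 180))
}

#' Multiply a daily quantity by 365 for a yearly one (exact).
#' @param x Daily value(s).
#' @return Yearly value(s).
#' @export
annualize <- function(x) x * 365

#' Exact decimal unit conversions for mass totals
#'
#' Central helper for ug <-> mg/g/Tg/Pg conversions (1 Pg = 1e21 ug,
#' 1 Tg = 1e18 ug, exact decimal factors).
#'
#' @param x Numeric value(s).
#' @param from,to One of `"ug"`, `"mg"`, `"g"`, `"kg"`, `"t"`, `"Tg"`,
#'   `"Pg"`.
#' @return Converted value(s).
#' @export
convert_mass <- function(x, from, to) {
  ug <- c(ug = 1, mg = 1e3, g = 1e6, kg = 1e9, t = 1e12, Tg = 1e18, Pg = 1e21)
  if (!from %in% names(ug) || !to %in% names(ug)) stop("unknown mass unit")
  x * ug[[from]] / ug[[to]]
}

#' Global (or masked) sum of an integrated map
#'
#' Sums `integrated * area` over cells. With `sd` supplied, uncertainty
#' bounds are computed per cell as mean +/- SD, floored at 0, before
#' summation (cell-level bounds, not bounds on the total's sampling
#' distribution).
#'
#' @param integrated Per-cell integrated values, ug m^-2.
#' @param area Per-cell areas, m^2 (same length).
#' @param sd Optional per-cell integrated SD, ug m^-2.
#' @param unit Output mass unit (default `"Pg"`); input is ug.
#' @return Named list `total` (and `low`, `high` when `sd` given), in
#'   `unit`.
#' @export
global_sum <- function(integrated, area, sd = NULL, unit = "Pg") {
  if (length(integrated) != length(area))
    stop("integrated map and cell areas are misaligned")
  ok <- is.finite(integrated) & is.finite(area)
  total <- sum(integrated[ok] * area[ok])
  out <- list(total = convert_mass(total, "ug", unit))
  if (!is.null(sd)) {
    if (length(sd) != length(integrated)) stop("sd map misaligned")
    low <- pmax(integrated - sd, 0)
    high <- integrated + sd
    out$low <- convert_mass(sum(low[ok] * area[ok]), "ug", unit)
    out$high <- convert_mass(sum(high[ok] * area[ok]), "ug", unit)
  }
  out
}

#' Regional sums over a partition
#'
#' Partitions cells by a region id (Longhurst-like province mask) and
#' sums `integrated * area` within each region. Over any partition the
#' regional totals sum exactly (to machine precision) to the global
#' total.
#'
#' @param integrated,area As in [global_sum()].
#' @param region Region id per cell (character or factor).
#' @param unit Output mass unit (default `"Pg"`).
#' @return data.frame with columns `region`, `total`.
#' @export
region_sum <- function(integrated, area, region, unit = "Pg") {
  if (length(region) != length(integrated)) stop("region mask misaligned")
  ok <- is.finite(integrated) & is.finite(area)
  totals <- tapply(integrated[ok] * area[ok], region[ok], sum)
  data.frame(region = names(totals),
             total = convert_mass(as.numeric(totals), "ug", unit),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' POC flux-attenuation ratio
#'
#' Percentage of the gravitational particulate-organic-carbon export
#' intercepted by flux-feeders: `100 * demand / export`. With a set of
#' export values the central ratio uses the median export, and the range
#' comes from the extreme exports (max export -> lowest attenuation).
#'
#' @param demand Annual carbon demand, Pg C per year.
#' @param export Annual POC export, Pg C per year: a single value or a
#'   set of literature values (> 0, non-empty).
#' @return List with `ratio` (percent, vs median export) and, when
#'   several export values are given, `low` and `high` (percent).
#' @export
attenuation_ratio <- function(demand, export) {
  if (length(export) == 0) stop("empty export set")
  if (any(export <= 0)) stop("export must be > 0")
  out <- list(ratio = 100 * demand / stats::median(export))
  if (length(export) > 1) {
    out$low <- 100 * demand / max(export)
    out$high <- 100 * demand / min(export)
  }
  out
}
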