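# Allometric biovolume -> elemental content conversions.

#' Allometric power-law parameters
#'
#' Describes an allometry `Q = 10^a * V^b` mapping a biovolume `V`
#' (expressed in `volume_unit`) to an elemental content per cell.
#'
#' @param a Intercept exponent (log10 units of the output at `V = 1`).
#' @param b Dimensionless slope, strictly positive.
#' @param volume_unit `"mm3"` or `"um3"`: the unit `V` must be supplied in.
#' @param output_unit Free-text label of the output unit (bookkeeping).
#' @param label Preset name carried into logs and reports.
#' @return An object of class `rz_allometry`.
#' @export
allometric_params <- function(a, b, volume_unit = c("mm3", "um3"),
                              output_unit = "ug", label = "custom") {
  volume_unit <- match.arg(volume_unit)
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L,
            b > 0)
  structure(list(a = a, b = b, volume_unit = volume_unit,
                 output_unit = output_unit, label = label),
            class = "rz_allometry")
}

#' @export
print.rz_allometry <- function(x, ...) {
  cat(sprintf("Allometry '%s': Q = 10^%g * V^%g  [V in %s -> %s/cell]\n",
              x$label, x$a, x$b, x$volume_unit, x$output_unit))
  invisible(x)
}

#' Carbon allometry preset: Q_C = 10^0.958 * V^0.455 (ug C per cell).
#'
#' The default volume unit is mm^3: evaluated in mm^3 a 1-mm cell yields
#' on the order of 17 ug C, consistent with the low cellular carbon
#' density measured on living Rhizaria, whereas um^3 would give an
#' implausible ~0.2 g C. See the methods vignette on the unit convention.
#' @param volume_unit `"mm3"` (default) or `"um3"`.
#' @return An `rz_allometry`.
#' @export
allometry_carbon <- function(volume_unit = "mm3") {
  allometric_params(0.958, 0.455, volume_unit, "ug C", "CARBON")
}

#' Biogenic-silica allometry preset: Q_bSi = 10^-4.05 * V^0.52 (ug Si per
#' cell), V in mm^3. Applies to silicifying Phaeodaria only.
#' @param volume_unit `"mm3"` (default) or `"um3"`.
#' @return An `rz_allometry`.
#' @export
allometry_bsi <- function(volume_unit = "mm3") {
  allometric_params(-4.05, 0.52, volume_unit, "ug Si", "BSI")
}

eval_allometry <- function(volume, params, volume_unit) {
  if (!inherits(params, "rz_allometry")) stop("params must be an rz_allometry")
  if (!identical(volume_unit, params$volume_unit))
    stop("volume supplied in ", volume_unit, " but allometry '",
         params$label, "' expects ", params$volume_unit)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be finite and strictly positive")
  10^params$a * volume^params$b
}

#' Individual carbon content from biovolume
#'
#' Power-law allometry `Q_C = 10^0.958 * V^0.455` in ug C per cell
#' (default preset). Strictly increasing in `V`, with the power-law ratio
#' `Q_C(10 V) / Q_C(V) = 10^0.455`.
#'
#' @param volume Biovolume per cell, in the unit declared by
#'   `volume_unit`; must match the allometry's expected unit.
#' @param params An [allometric_params()] object, default
#'   [allometry_carbon()].
#' @param volume_unit Unit `volume` is expressed in (`"mm3"` or `"um3"`);
#'   a mismatch with `params$volume_unit` is an error, not a silent
#'   conversion.
#' @return Carbon content in ug C per cell.
#' @export
carbon_content <- function(volume, params = allometry_carbon(),
                           volume_unit = "mm3") {
  eval_allometry(volume, params, volume_unit)
}

#' Individual biogenic-silica content from biovolume
#'
#' `Q_bSi = 10^-4.05 * V^0.52` in ug Si per cell, for Phaeodaria. All
#' Phaeodaria silicify, while silicified Collodaria cannot be told apart
#' from naked ones on UVP5 images, so the conversion is restricted to
#' Phaeodaria taxa by default.
#'
#' @param volume Biovolume per cell in `volume_unit`.
#' @param taxon Optional taxon label(s); when supplied, non-Phaeodaria
#'   labels are rejected unless `allow_non_phaeodaria = TRUE`.
#' @param params Default [allometry_bsi()].
#' @param volume_unit Unit of `volume`.
#' @param allow_non_phaeodaria Override the taxonomic restriction.
#' @return Silica content in ug Si per cell.
#' @export
bsi_content <- function(volume, taxon = NULL, params = allometry_bsi(),
                        volume_unit = "mm3", allow_non_phaeodaria = FALSE) {
  if (!is.null(taxon) && !allow_non_phaeodaria) {
    grp <- taxon_group(taxon)
    if (any(grp != "Phaeodaria"))
      stop("bSi allometry applies to Phaeodaria only; offending taxa: ",
           paste(unique(taxon[grp != "Phaeodaria"]), collapse = ", "),
           " (set allow_non_phaeodaria = TRUE to override)")
  }
  eval_allometry(volume, params, volume_unit)
}

#' Convert a volume between um^3 and mm^3 (exact factor 1e9).
#' @param volume Numeric vector.
#' @param from,to `"um3"` or `"mm3"`.
#' @return Converted volume.
#' @export
convert_volume <- function(volume, from, to) {
  units <- c(um3 = 1, mm3 = 1e9)  # um^3 per unit
  if (!from %in% names(units) || !to %in% names(units))
    stop("units must be 'um3' or 'mm3'")
  volume * units[[from]] / units[[to]]
}
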