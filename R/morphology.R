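#' Segment the cell from its quantitative phase image
#'
#' Thresholds the phase map (Otsu's method on the normalised phase by
#' default, or an explicit threshold in radians), keeps the largest
#' connected component and fills its holes.
#'
#' @param field A [complex_field()].
#' @param method `"otsu_phase"` (default) or `"threshold"`.
#' @param threshold Phase threshold in radians, required for
#'   `method = "threshold"`.
#' @return A list of class `cell_mask` with logical `mask`, `area_um2`
#'   (pixel count times pixel area) and `equivalent_radius_um`
#'   (`sqrt(area / pi)`).
#' @export
segment_cell <- function(field, method = c("otsu_phase", "threshold"),
                         threshold = NULL) {
  method <- match.arg(method)
  phi <- field$phase
  rng <- range(phi)
  if (method == "otsu_phase") {
    if (diff(rng) <= 0) {
      abort("uniform phase image cannot be segmented",
            class = "fractometry_degenerate_error")
    }
    phin <- (phi - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(phin), range = c(0, 1))
    bin <- phin > th
  } else {
    if (is.null(threshold)) {
      abort("method = \"threshold\" needs `threshold` (radians)",
            class = "fractometry_parameter_error")
    }
    bin <- phi > threshold
  }
  if (!any(bin)) {
    abort("segmentation produced an empty mask",
          class = "fractometry_degenerate_error")
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::fillHull(lab)
  counts <- table(as.integer(lab)[as.integer(lab) > 0])
  keep <- as.integer(names(counts)[which.max(counts)])
  mask <- matrix(as.integer(lab) == keep, nrow(phi), ncol(phi))
  area <- sum(mask) * field$pixel_um^2
  structure(list(
    mask = mask, area_um2 = area,
    equivalent_radius_um = sqrt(area / pi),
    pixel_um = field$pixel_um
  ), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat("<cell_mask> ", sum(x$mask), " px, area ", signif(x$area_um2, 4),
      " um^2, equivalent radius ", signif(x$equivalent_radius_um, 4),
      " um\n", sep = "")
  invisible(x)
}

#' Bulk dry-mass morphology of a segmented cell
#'
#' Converts the quantitative phase into an optical path length profile,
#' OPL = phi * lambda / (2 * pi), and into a dry-mass surface density
#' through the specific refractive increment of biomolecules
#' (~0.19 ml/g): sigma = OPL / increment, with 0.19 ml/g equal to
#' 0.19 um^3/pg so that a 4 nm optical path step maps to ~0.021 pg/um^2.
#' Dry mass is the surface density integrated over the mask.
#'
#' @param field A [complex_field()].
#' @param mask A [segment_cell()] result (nonempty).
#' @param refractive_increment_ml_per_g Specific refractive increment
#'   (default 0.19 ml/g).
#' @return A one-row tibble with `area_um2`, `opl_mean_nm`, `opl_max_nm`,
#'   `dry_mass_pg`, `dry_mass_density_pg_per_um2`, `amplitude_mean`.
#' @export
dry_mass <- function(field, mask, refractive_increment_ml_per_g = 0.19) {
  if (!is.numeric(refractive_increment_ml_per_g) ||
      refractive_increment_ml_per_g <= 0) {
    abort("refractive increment must be positive",
          class = "fractometry_parameter_error")
  }
  if (!any(mask$mask)) {
    abort("empty mask", class = "fractometry_degenerate_error")
  }
  opl_um <- field$phase * field$wavelength_um / (2 * pi)
  # 0.19 ml/g == 0.19 um^3/pg, so sigma [pg/um^2] = OPL [um] / increment
  sigma <- opl_um / refractive_increment_ml_per_g
  inmask <- mask$mask
  mass_pg <- sum(sigma[inmask]) * field$pixel_um^2
  tibble::tibble(
    area_um2 = mask$area_um2,
    opl_mean_nm = mean(opl_um[inmask]) * 1e3,
    opl_max_nm = max(opl_um[inmask]) * 1e3,
    dry_mass_pg = mass_pg,
    dry_mass_density_pg_per_um2 = mass_pg / mask$area_um2,
    amplitude_mean = mean(field$amplitude[inmask])
  )
}
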