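# TIFF stack + JSON sidecar I/O.
# Stacks are multi-page 32-bit TIFFs; since the writer stores values in
# [0, 1], every page is affinely rescaled and the per-page (offset, scale)
# pairs live in the sidecar, which also carries the acquisition metadata.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

write_stack <- function(pages, path, metadata = list()) {
  enc <- lapply(pages, function(m) {
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    list(page = (m - lo) / scale, offset = lo, scale = scale)
  })
  tiff::writeTIFF(lapply(enc, `[[`, "page"), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  metadata$pages <- names(pages)
  metadata$offset <- vapply(enc, `[[`, numeric(1), "offset")
  metadata$scale <- vapply(enc, `[[`, numeric(1), "scale")
  jsonlite::write_json(metadata, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$pages)) {
    abort("TIFF page count does not match its sidecar",
          class = "fractometry_structural_error")
  }
  pages <- purrr::map(seq_along(pages), function(i)
    pages[[i]] * meta$scale[i] + meta$offset[i])
  names(pages) <- meta$pages
  list(pages = pages, metadata = meta)
}

#' Write / read a knife-edge set as a multi-page float TIFF
#'
#' Page order: Ix+, Ix-, Iy+, Iy-, background. Acquisition metadata
#' (`wavelength_um`, `pixel_um`, `gain`, `cf`, ...) and the per-page
#' rescaling go into a JSON sidecar next to the TIFF.
#'
#' @param ke A [knife_edge_set()].
#' @param path Output `.tif` path.
#' @param metadata Named list of acquisition metadata.
#' @return `path`, invisibly (writer); a list with `ke` and `metadata`
#'   (reader).
#' @export
write_knife_edge_tiff <- function(ke, path, metadata = list()) {
  write_stack(list(ix_plus = ke$ix_plus, ix_minus = ke$ix_minus,
                   iy_plus = ke$iy_plus, iy_minus = ke$iy_minus,
                   background = ke$background),
              path, c(metadata, list(kind = "knife_edge_set")))
}

#' @rdname write_knife_edge_tiff
#' @export
read_knife_edge_tiff <- function(path) {
  st <- read_stack(path)
  p <- st$pages
  list(ke = knife_edge_set(p$ix_plus, p$ix_minus, p$iy_plus, p$iy_minus,
                           pmax(p$background, .Machine$double.eps)),
       metadata = st$metadata)
}

#' Write / read a complex field as a multi-page float TIFF
#'
#' Page order: amplitude, phase. Wavelength and pixel pitch live in the
#' JSON sidecar.
#'
#' @param field A [complex_field()].
#' @param path Output `.tif` path.
#' @param metadata Extra metadata merged into the sidecar.
#' @return `path`, invisibly (writer); a [complex_field()] (reader).
#' @export
write_field_tiff <- function(field, path, metadata = list()) {
  write_stack(list(amplitude = field$amplitude, phase = field$phase),
              path,
              c(metadata, list(kind = "complex_field",
                               wavelength_um = field$wavelength_um,
                               pixel_um = field$pixel_um)))
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  st <- read_stack(path)
  complex_field(pmax(st$pages$amplitude, 0), st$pages$phase,
                st$metadata$wavelength_um, st$metadata$pixel_um)
}

#' Serialise an ALS profile or correlation curve to CSV
#'
#' Two-column CSV (plus counts where present) preceded by `#`-prefixed
#' header metadata lines (wavelength, pixel pitch, bin width).
#'
#' @param x An `als_profile` or `correlation_curve` tibble.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  hdr <- character()
  if (!is.null(attr(x, "wavelength_um"))) {
    hdr <- c(hdr, paste0("# wavelength_um: ", attr(x, "wavelength_um")))
  }
  if (!is.null(attr(x, "pixel_um"))) {
    hdr <- c(hdr, paste0("# pixel_um: ", attr(x, "pixel_um")))
  }
  if (!is.null(attr(x, "bin_width"))) {
    hdr <- c(hdr, paste0("# bin_width: ", attr(x, "bin_width")))
  }
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
                       col.names = TRUE, append = TRUE, quote = FALSE)
  )
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Column order: `cell_id`, `label`, `source` (where present), then the
#' named features. Deterministic formatting so identical tables give
#' byte-identical files.
#'
#' @param data A feature tibble.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(data, path) {
  lead <- intersect(c("cell_id", "label", "source"), names(data))
  data <- data[c(lead, setdiff(names(data), lead))]
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
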