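#' Read and write angiogram images
#'
#' Angiograms travel as 16-bit grayscale TIFF, with frame stacks as
#' multi-page TIFF; masks as PNG. Intensities map linearly between
#' \[0, 1\] and the integer range.
#'
#' @param ang An [enface_angiogram()].
#' @param path Output TIFF path.
#' @rdname angiogram_io
#' @export
write_angiogram_tiff <- function(ang, path) {
  pages <- c(list(ang$image), ang$frames %||% list())
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @param pixel_pitch_um,plexus,quality Metadata to attach on read.
#' @rdname angiogram_io
#' @export
read_angiogram_tiff <- function(path, pixel_pitch_um = 5.7,
                                plexus = "SCP", quality = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse RGB grayscale
    p
  })
  enface_angiogram(pages[[1L]],
                   frames = if (length(pages) > 1L) pages[-1L] else NULL,
                   pixel_pitch_um = pixel_pitch_um, plexus = plexus,
                   quality = quality)
}

#' Write a boolean mask as PNG
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a boolean mask from PNG
#'
#' @param path PNG path; any nonzero pixel is foreground.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Write / read a simulation config as YAML
#'
#' @param config A [simulation_config()]; `path` a file path.
#' @rdname config_yaml
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$group_effects <- as.list(lst$group_effects)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @param path File path.
#' @rdname config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$group_effects <- as.data.frame(lst$group_effects)
  do.call(simulation_config, lst)
}
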