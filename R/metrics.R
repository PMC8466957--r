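#' Vessel density of a region
#'
#' VD = 100 x (vessel pixels in region) / (region pixel count): the
#' percentage of the analyzed region occupied by white (vessel) pixels of
#' the binary vessel map.
#'
#' @param map A `vessel_map` (or a logical matrix).
#' @param region_pixels Logical matrix (same shape) or integer index vector
#'   selecting the region's pixels.
#' @return Percentage in \[0, 100\].
#' @export
vessel_density <- function(map, region_pixels) {
  mask <- if (is.list(map)) map$mask else map
  sel <- if (is.logical(region_pixels)) which(region_pixels) else region_pixels
  if (!length(sel)) stop("empty region")
  100 * sum(mask[sel]) / length(sel)
}

#' Perfusion density of a region
#'
#' PD = 100 x (perfused vessel pixels in region) / (region pixel count).
#' Because the perfusion mask is a subset of the vessel mask, PD <= VD for
#' every region.
#'
#' @param map A `perfusion_map` (or a logical matrix).
#' @inheritParams vessel_density
#' @return Percentage in \[0, 100\].
#' @export
perfusion_density <- function(map, region_pixels) {
  vessel_density(map, region_pixels)
}

#' Per-region VD/PD table over the sector grid
#'
#' @param vessels A `vessel_map`.
#' @param perfusion A `perfusion_map` or `NULL` (PD columns become `NA`;
#'   perfusion density is never silently equated to vessel density).
#' @param regions Output of [rasterize_regions()].
#' @return Data frame with one row per sector (8), per zone total (2), and
#'   the whole-grid total: `zone`, `quadrant_name`, `pixel_count`,
#'   `vd_percent`, `pd_percent`.
#' @export
region_metrics <- function(vessels, perfusion, regions) {
  zone <- regions$zone; quad <- regions$quadrant
  sel_list <- list()
  meta <- list()
  qn <- regions$counts$quadrant_name[match(0:3, regions$counts$quadrant)]
  for (z in 1:2) {
    zname <- c("foveal", "parafoveal")[z]
    for (q in 0:3) {
      sel_list[[length(sel_list) + 1L]] <- which(zone == z & quad == q)
      meta[[length(meta) + 1L]] <- c(zname, qn[q + 1L])
    }
    sel_list[[length(sel_list) + 1L]] <- which(zone == z)
    meta[[length(meta) + 1L]] <- c(zname, "total")
  }
  sel_list[[length(sel_list) + 1L]] <- which(zone > 0)
  meta[[length(meta) + 1L]] <- c("grid", "total")
  vd <- vapply(sel_list, function(s) vessel_density(vessels, s), numeric(1L))
  pd <- if (is.null(perfusion)) rep(NA_real_, length(sel_list)) else {
    vapply(sel_list, function(s) perfusion_density(perfusion, s), numeric(1L))
  }
  data.frame(zone = vapply(meta, `[`, "", 1L),
             quadrant_name = vapply(meta, `[`, "", 2L),
             pixel_count = lengths(sel_list),
             vd_percent = vd, pd_percent = pd)
}

#' Capillary-free-zone morphometry from a vessel map
#'
#' Automated stand-in for manual CFZ contouring, used on synthetic data:
#' the avascular component containing `seed_point_mm` is flood-filled
#' (4-connectivity) over non-vessel pixels, lightly smoothed, and its
#' border extracted as a sub-pixel marching-squares contour at level 0.5
#' (boundary-pixel counting would inflate the perimeter by ~27 percent and
#' destroy circularity). Area, perimeter and circularity come from the
#' contour polygon.
#'
#' @param vessels A `vessel_map`.
#' @param seed_point_mm `(x, y)` in mm, inside the avascular zone.
#' @param smooth_sigma_px Gaussian sigma for pre-contour smoothing.
#' @param close_px Box side of the morphological closing applied to the
#'   vessel mask before flood-filling; seals 1-2 px segmentation breaks in
#'   the perifoveal capillary ring that would let the fill leak into
#'   neighboring inter-vessel pockets. 0 disables.
#' @return List with `area_mm2`, `perimeter_mm`, `circularity`, `polygon`.
#' @export
cfz_from_mask <- function(vessels, seed_point_mm, smooth_sigma_px = 1,
                          close_px = 3L) {
  mask <- vessels$mask
  if (close_px > 0L) {
    mask <- EBImage::closing(mask * 1,
                             EBImage::makeBrush(close_px, "box")) > 0.5
  }
  pitch <- vessels$pixel_pitch_um / 1000
  j <- ceiling(seed_point_mm[1L] / pitch)  # x -> column
  i <- ceiling(seed_point_mm[2L] / pitch)  # y -> row
  if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask)) {
    stop("seed point outside the image")
  }
  if (mask[i, j]) stop("seed point lies on a vessel pixel")
  lab <- EBImage::bwlabel((!mask) * 1)
  comp <- lab == lab[i, j]
  if (any(comp[1L, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1L]) || any(comp[, ncol(comp)])) {
    stop("avascular component touches the image border: unbounded CFZ")
  }
  z <- comp * 1
  if (smooth_sigma_px > 0) {
    z <- as.matrix(EBImage::gblur(z, sigma = smooth_sigma_px))
  }
  ys <- (seq_len(nrow(mask)) - 0.5) * pitch
  xs <- (seq_len(ncol(mask)) - 0.5) * pitch
  cl <- grDevices::contourLines(ys, xs, z, levels = 0.5)
  if (!length(cl)) stop("no closed contour found around the seed point")
  # contourLines' x follows rows (our y); swap into (x_mm, y_mm)
  polys <- lapply(cl, function(co) as_polygon2d(cbind(co$y, co$x)))
  containing <- vapply(polys, function(p) {
    points_in_polygon(p, seed_point_mm[1L], seed_point_mm[2L])
  }, logical(1L))
  if (!any(containing)) containing <- rep(TRUE, length(polys))
  areas <- vapply(polys[containing],
                  function(p) polygon_area(p, check_simple = FALSE),
                  numeric(1L))
  poly <- polys[containing][[which.max(areas)]]
  m <- polygon_metrics(poly)
  c(m, list(polygon = poly))
}
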