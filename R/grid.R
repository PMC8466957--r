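#' Foveal/parafoveal sector grid
#'
#' The analysis grid is a 1 mm-diameter foveal disc and a parafoveal ring
#' out to 2.9 mm diameter, each split into 4 quadrants by diagonal
#' (ETDRS-style) boundaries at 45/135/225/315 degrees plus an optional
#' rotation offset. When a tissue-loss direction `roi_angle_deg` is given,
#' the quadrant containing it becomes the region of interest (ROI), its two
#' neighbours R1 and R2, and the opposite quadrant R3.
#'
#' Radial intervals are inner-inclusive/outer-exclusive and angular arcs
#' are half-open `(a, a + 90]`, so the eight regions partition the disc
#' exactly.
#'
#' @param center_mm Grid center (x, y) in mm.
#' @param roi_angle_deg Optional direction (degrees, counterclockwise from
#'   +x) of the tissue-loss quadrant.
#' @param foveal_radius_mm,parafoveal_outer_radius_mm Ring radii (mm).
#' @param rotation_offset_deg Extra rotation of the quadrant boundaries.
#' @return A `sector_grid` list; `roi_quadrant` is the 0-based quadrant
#'   index containing `roi_angle_deg` (or `NA`).
#' @export
build_grid <- function(center_mm, roi_angle_deg = NULL,
                       foveal_radius_mm = 0.5,
                       parafoveal_outer_radius_mm = 1.45,
                       rotation_offset_deg = 0) {
  if (foveal_radius_mm <= 0 || parafoveal_outer_radius_mm <= foveal_radius_mm) {
    stop("need 0 < foveal radius < parafoveal outer radius")
  }
  boundaries <- (c(45, 135, 225, 315) + rotation_offset_deg) %% 360
  g <- list(center_mm = as.numeric(center_mm),
            foveal_radius_mm = foveal_radius_mm,
            parafoveal_outer_radius_mm = parafoveal_outer_radius_mm,
            quadrant_boundaries_deg = boundaries,
            rotation_offset_deg = rotation_offset_deg,
            roi_quadrant = NA_integer_)
  class(g) <- "sector_grid"
  if (!is.null(roi_angle_deg)) {
    g$roi_quadrant <- quadrant_of_angle(g, roi_angle_deg)
  }
  g
}

#' Quadrant index of a polar angle
#'
#' Quadrant 0 is the arc `(315, 45]` degrees (before rotation offset), then
#' counterclockwise. Arcs are half-open `(a, a + 90]`, so a boundary angle
#' belongs to the arc it closes.
#'
#' @param grid A [build_grid()] object.
#' @param angle_deg Angle(s) in degrees.
#' @return Integer quadrant index 0-3.
#' @export
quadrant_of_angle <- function(grid, angle_deg) {
  phi <- (angle_deg - grid$rotation_offset_deg + 45) %% 360
  q <- floor(phi / 90)
  on_boundary <- phi %% 90 == 0
  q[on_boundary] <- (q[on_boundary] - 1) %% 4
  as.integer(q %% 4)
}

#' Names of the four quadrants relative to the ROI
#'
#' @param grid A grid with `roi_quadrant` set.
#' @return Character vector of length 4 mapping quadrant index 0-3 to
#'   `"ROI"`, `"R1"`, `"R2"`, `"R3"` (R3 opposite the ROI), or `"Q0"`..
#'   `"Q3"` when no ROI is set.
#' @export
quadrant_names <- function(grid) {
  if (is.na(grid$roi_quadrant)) return(paste0("Q", 0:3))
  out <- character(4L)
  roi <- grid$roi_quadrant
  out[roi + 1L] <- "ROI"
  out[(roi + 1L) %% 4L + 1L] <- "R1"
  out[(roi + 3L) %% 4L + 1L] <- "R2"
  out[(roi + 2L) %% 4L + 1L] <- "R3"
  out
}

#' Zone and quadrant of points
#'
#' @param grid A [build_grid()] object.
#' @param x_mm,y_mm Point coordinates (mm), vectorized.
#' @return Data frame with `zone` (`foveal` iff r < foveal radius,
#'   `parafoveal` iff r < outer radius, else `outside`) and `quadrant`
#'   (0-3; `NA` outside the grid).
#' @export
label_pixel <- function(grid, x_mm, y_mm) {
  dx <- x_mm - grid$center_mm[1L]
  dy <- y_mm - grid$center_mm[2L]
  r <- sqrt(dx^2 + dy^2)
  zone <- ifelse(r < grid$foveal_radius_mm, "foveal",
                 ifelse(r < grid$parafoveal_outer_radius_mm,
                        "parafoveal", "outside"))
  q <- quadrant_of_angle(grid, atan2(dy, dx) * 180 / pi)
  q[zone == "outside"] <- NA_integer_
  data.frame(zone = zone, quadrant = q)
}

#' Rasterize the sector grid onto a pixel raster
#'
#' Pixel `(i, j)` (1-based row, column) is assigned by its center
#' `((j - 0.5) * pitch, (i - 0.5) * pitch)` in mm, x along columns.
#'
#' @param grid A [build_grid()] object.
#' @param shape_px Raster dimensions `c(rows, cols)` (a single integer is
#'   squared).
#' @param pixel_pitch_um Pixel pitch (um).
#' @return List with `zone` (integer matrix: 0 outside, 1 foveal,
#'   2 parafoveal), `quadrant` (integer matrix, `NA` outside) and `counts`
#'   (data frame: zone, quadrant, quadrant_name, pixel_count, area_mm2).
#' @export
rasterize_regions <- function(grid, shape_px, pixel_pitch_um) {
  if (length(shape_px) == 1L) shape_px <- c(shape_px, shape_px)
  pitch <- pixel_pitch_um / 1000
  ext <- shape_px * pitch
  cm <- grid$center_mm
  if (cm[1L] - grid$parafoveal_outer_radius_mm < 0 ||
      cm[2L] - grid$parafoveal_outer_radius_mm < 0 ||
      cm[1L] + grid$parafoveal_outer_radius_mm > ext[2L] ||
      cm[2L] + grid$parafoveal_outer_radius_mm > ext[1L]) {
    stop("sector grid exceeds the raster")
  }
  xs <- (seq_len(shape_px[2L]) - 0.5) * pitch
  ys <- (seq_len(shape_px[1L]) - 0.5) * pitch
  X <- matrix(xs, shape_px[1L], shape_px[2L], byrow = TRUE)
  Y <- matrix(ys, shape_px[1L], shape_px[2L])
  lab <- label_pixel(grid, as.vector(X), as.vector(Y))
  zone <- matrix(match(lab$zone, c("outside", "foveal", "parafoveal")) - 1L,
                 shape_px[1L], shape_px[2L])
  quad <- matrix(lab$quadrant, shape_px[1L], shape_px[2L])
  qn <- quadrant_names(grid)
  counts <- expand.grid(zone = c("foveal", "parafoveal"), quadrant = 0:3,
                        stringsAsFactors = FALSE)
  counts$quadrant_name <- qn[counts$quadrant + 1L]
  counts$pixel_count <- mapply(function(z, q) {
    sum(zone == match(z, c("outside", "foveal", "parafoveal")) - 1L &
          quad == q, na.rm = TRUE)
  }, counts$zone, counts$quadrant)
  counts$area_mm2 <- counts$pixel_count * pitch^2
  list(zone = zone, quadrant = quad, counts = counts)
}
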