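#' Simulation configuration
#'
#' One object holds every knob of the synthetic study: acquisition geometry,
#' vascular ground-truth parameters, rendering noise, cohort size and
#' group-level effects. Defaults reproduce the study conditions: a 512 px
#' raster at 5.7 um/pixel (2.92 mm field; the 2.9 mm analysis grid, not the
#' raster edge, defines the analyzed extent), two groups of 14 eyes, and
#' group effects encoding the published per-group distributions.
#'
#' @param seed Master integer seed.
#' @param image_size_px Square raster side in pixels.
#' @param pixel_pitch_um Lateral resolution (um per pixel).
#' @param n_frames Frames per acquisition used for decorrelation.
#' @param faz_area_mm2,faz_circularity Ground-truth capillary-free-zone
#'   area (mm^2) and circularity in (0, 1].
#' @param vessel_fraction Target fraction of pixels covered by vessels.
#' @param perfused_fraction_of_vessels Share of vessel pixels flagged
#'   perfused, in \[0, 1\].
#' @param noise_sd Additive Gaussian noise SD on rendered images.
#' @param speckle_sd SD of the mean-one multiplicative per-frame speckle
#'   applied to perfused pixels.
#' @param n_per_group Patients per group in the simulated cohort.
#' @param group_effects Per-variable location/scale table, see
#'   [default_group_effects()].
#' @param follow_up_years_range Range (years) of the uniform follow-up
#'   duration.
#' @param grader_noise_sd_mm2 Per-grader measurement noise for tissue-loss
#'   contouring (mm^2).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              image_size_px = 512L,
                              pixel_pitch_um = 5.7,
                              n_frames = 8L,
                              faz_area_mm2 = 0.45,
                              faz_circularity = 0.55,
                              vessel_fraction = 0.25,
                              perfused_fraction_of_vessels = 0.8,
                              noise_sd = 0.02,
                              speckle_sd = 0.6,
                              n_per_group = 14L,
                              group_effects = default_group_effects(),
                              follow_up_years_range = c(1.6, 2.9),
                              grader_noise_sd_mm2 = NULL) {
  cfg <- list(seed = as.integer(seed),
              image_size_px = as.integer(image_size_px),
              pixel_pitch_um = pixel_pitch_um,
              n_frames = as.integer(n_frames),
              faz_area_mm2 = faz_area_mm2,
              faz_circularity = faz_circularity,
              vessel_fraction = vessel_fraction,
              perfused_fraction_of_vessels = perfused_fraction_of_vessels,
              noise_sd = noise_sd,
              speckle_sd = speckle_sd,
              n_per_group = as.integer(n_per_group),
              group_effects = group_effects,
              follow_up_years_range = follow_up_years_range,
              grader_noise_sd_mm2 = grader_noise_sd_mm2)
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (image_size_px * pixel_pitch_um / 1000 < 2.9) {
      stop("raster too small: the 2.9 mm analysis grid must fit")
    }
    if (faz_circularity <= 0 || faz_circularity > 1) {
      stop("faz_circularity must lie in (0, 1]")
    }
    if (vessel_fraction < 0 || vessel_fraction >= 1) {
      stop("vessel_fraction must lie in [0, 1)")
    }
    if (perfused_fraction_of_vessels < 0 || perfused_fraction_of_vessels > 1) {
      stop("perfused_fraction_of_vessels must lie in [0, 1]")
    }
    if (noise_sd < 0 || speckle_sd < 0) stop("noise scales must be >= 0")
    if (n_frames < 1L) stop("n_frames must be >= 1")
    if (diff(follow_up_years_range) < 0 || any(follow_up_years_range <= 0)) {
      stop("follow_up_years_range must be positive and ordered")
    }
  })
  invisible(cfg)
}

#' Grow a synthetic capillary network around an avascular zone
#'
#' Branching trees are grown from the image border toward the FAZ border:
#' tips advance in fixed-length steps with angular jitter, branch with a
#' fixed probability, and die on leaving the raster or entering the FAZ.
#' Segments are rasterized at 1-3 px width. Trees are added until the
#' vessel pixel fraction reaches the configured target (within -20 percent);
#' if the target is unreachable within the iteration bound, a warning is
#' raised and the achieved fraction is reported. A random subset of
#' branches totalling `perfused_fraction_of_vessels` of vessel pixels is
#' flagged perfused.
#'
#' @param config A [simulation_config()].
#' @param faz Optional FAZ polygon; generated from the config when `NULL`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `ground_truth` list: `vessel_mask`, `perfused_mask` (logical
#'   matrices, perfused subset of vessel, FAZ interior vessel-free),
#'   `faz_polygon`, `faz_area_mm2`, `faz_perimeter_mm`,
#'   `achieved_vessel_fraction`.
#' @export
generate_vessel_network <- function(config, faz = NULL, seed = config$seed) {
  n <- config$image_size_px
  pitch <- config$pixel_pitch_um / 1000
  extent <- n * pitch
  center <- extent / 2
  if (is.null(faz)) {
    faz <- generate_faz_polygon(config$faz_area_mm2, config$faz_circularity,
                                seed = derive_seed(seed, 101L),
                                center_mm = c(center, center))
  }
  if (any(faz[, 1L] < 0 | faz[, 1L] > extent |
          faz[, 2L] < 0 | faz[, 2L] > extent)) {
    stop("FAZ polygon does not fit inside the image")
  }
  old <- local_seed(derive_seed(seed, 202L))
  on.exit(restore_seed(old))

  vessel <- matrix(FALSE, n, n)
  branch_pixels <- list()   # linear pixel indices per branch
  target_px <- config$vessel_fraction * n * n
  if (target_px > 0) {
    # terminal capillary ring: a continuous vessel ring just outside the
    # FAZ border, closing the avascular zone the way the perifoveal
    # capillary arcade does (and making the CFZ a bounded region)
    ring <- faz_ring_pixels(faz, pitch, n)
    vessel[ring] <- TRUE
    branch_pixels[[1L]] <- ring
  }
  if (target_px > 0) {
    step_px <- 5
    max_trees <- 400L
    trees <- 0L
    while (sum(vessel) < 0.95 * target_px && trees < max_trees) {
      trees <- trees + 1L
      px <- grow_tree(n, center / pitch, faz, faz_bbox(faz), pitch, step_px)
      for (b in px) {
        vessel[b] <- TRUE
        branch_pixels[[length(branch_pixels) + 1L]] <- b
      }
    }
    if (sum(vessel) < 0.8 * target_px) {
      warning(sprintf("vessel_fraction %.3f unreachable; achieved %.3f",
                      config$vessel_fraction, sum(vessel) / (n * n)))
    }
  }
  # enforce the avascular zone exactly on pixel centers
  idx <- which(vessel)
  if (length(idx)) {
    xs <- (((idx - 1L) %/% n) + 0.5) * pitch  # column -> x
    ys <- (((idx - 1L) %% n) + 0.5) * pitch   # row -> y
    inside <- points_in_polygon(faz, xs, ys)
    vessel[idx[inside]] <- FALSE
  }
  branch_pixels <- lapply(branch_pixels, function(b) unique(b[vessel[b]]))
  branch_pixels <- branch_pixels[lengths(branch_pixels) > 0L]

  perfused <- matrix(FALSE, n, n)
  pf <- config$perfused_fraction_of_vessels
  total <- sum(vessel)
  if (pf >= 1) {
    perfused <- vessel
  } else if (pf > 0 && total > 0L) {
    ord <- sample.int(length(branch_pixels))
    got <- 0L
    for (k in ord) {
      b <- branch_pixels[[k]]
      add <- sum(!perfused[b])
      if (abs(got + add - pf * total) < abs(got - pf * total)) {
        perfused[b] <- TRUE
        got <- got + add
      }
      if (got >= pf * total) break
    }
  }
  perfused <- perfused & vessel
  structure(list(vessel_mask = vessel,
                 perfused_mask = perfused,
                 faz_polygon = faz,
                 faz_area_mm2 = attr(faz, "area_mm2") %||%
                   polygon_area(faz, check_simple = FALSE),
                 faz_perimeter_mm = attr(faz, "perimeter_mm") %||%
                   polygon_perimeter(faz),
                 achieved_vessel_fraction = sum(vessel) / (n * n)),
            class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rasterize the FAZ border offset outward by 2 px along vertex normals at
# 3 px width; a fixed normal offset stays tight and gap-free even in the
# concave lobes of low-circularity shapes (radial scaling does not)
faz_ring_pixels <- function(faz, pitch, n) {
  m <- nrow(faz)
  p <- unclass(faz)
  nxt <- p[c(2:m, 1L), , drop = FALSE]
  prv <- p[c(m, 1:(m - 1L)), , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(tang[, 2L], -tang[, 1L])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  cen <- colMeans(p)
  outward <- rowSums(nrm * sweep(p, 2L, cen, `-`)) > 0
  nrm[!outward, ] <- -nrm[!outward, ]
  ring <- p + 2 * pitch * nrm
  v <- rbind(ring, ring[1L, ])
  px <- integer(0)
  for (i in seq_len(m)) {
    px <- c(px, rasterize_segment(v[i, 1L] / pitch, v[i, 2L] / pitch,
                                  v[i + 1L, 1L] / pitch, v[i + 1L, 2L] / pitch,
                                  3L, n))
  }
  unique(px)
}

faz_bbox <- function(faz) {
  c(min(faz[, 1L]), max(faz[, 1L]), min(faz[, 2L]), max(faz[, 2L]))
}

# containment test with bounding-box quick reject (tips are mostly far
# from the FAZ; the exact test is only run inside its bounding box)
in_faz <- function(faz, bbox, x_mm, y_mm) {
  if (x_mm < bbox[1L] || x_mm > bbox[2L] ||
      y_mm < bbox[3L] || y_mm > bbox[4L]) return(FALSE)
  points_in_polygon(faz, x_mm, y_mm)
}

# one tree from a random border point; returns a list of linear-index
# vectors, one per branch
grow_tree <- function(n, center_px, faz, bbox, pitch, step_px) {
  side <- sample.int(4L, 1L)
  u <- stats::runif(1, 1, n)
  start <- switch(side, c(u, 1), c(u, n), c(1, u), c(n, u))  # (x=col, y=row)
  aim <- atan2(center_px - start[2L], center_px - start[1L])
  tips <- list(list(x = start[1L], y = start[2L],
                    ang = aim + stats::rnorm(1, 0, 0.3),
                    w = sample(1:3, 1L, prob = c(0.5, 0.35, 0.15))))
  branches <- list()
  cur <- rep(list(integer(0)), length(tips))
  steps <- 0L
  while (length(tips) && steps < 300L) {
    steps <- steps + 1L
    new_tips <- list(); new_cur <- list()
    for (k in seq_along(tips)) {
      t <- tips[[k]]
      ang <- t$ang + stats::rnorm(1, 0, 0.35)
      x2 <- t$x + step_px * cos(ang)
      y2 <- t$y + step_px * sin(ang)
      dead <- x2 < 1 || x2 > n || y2 < 1 || y2 > n ||
        in_faz(faz, bbox, x2 * pitch, y2 * pitch)
      if (dead) { branches[[length(branches) + 1L]] <- cur[[k]]; next }
      seg <- rasterize_segment(t$x, t$y, x2, y2, t$w, n)
      cur_k <- c(cur[[k]], seg)
      if (stats::runif(1) < 0.12) {  # branch: split the tip
        for (s in c(-1, 1)) {
          new_tips[[length(new_tips) + 1L]] <-
            list(x = x2, y = y2, ang = ang + s * stats::runif(1, 0.3, 0.7),
                 w = max(1L, t$w - sample(0:1, 1L)))
          new_cur[[length(new_cur) + 1L]] <- integer(0)
        }
        branches[[length(branches) + 1L]] <- cur_k
      } else {
        new_tips[[length(new_tips) + 1L]] <-
          list(x = x2, y = y2, ang = ang, w = t$w)
        new_cur[[length(new_cur) + 1L]] <- cur_k
      }
      if (length(new_tips) > 24L) break  # bound tree width
    }
    tips <- new_tips; cur <- new_cur
  }
  branches <- c(branches, cur)
  branches[lengths(branches) > 0L]
}

# linear pixel indices covered by a width-w segment (column-major, x=col)
rasterize_segment <- function(x1, y1, x2, y2, w, n) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  m <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = m)
  xs <- x1 + t * (x2 - x1)
  ys <- y1 + t * (y2 - y1)
  if (w > 1L) {
    r <- (w - 1) / 2
    off <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.26, ]
    xs <- outer(xs, off$dx, `+`); ys <- outer(ys, off$dy, `+`)
  }
  i <- round(ys); j <- round(xs)
  ok <- i >= 1 & i <= n & j >= 1 & j <= n
  unique((j[ok] - 1L) * n + i[ok])
}

#' Render an en-face angiogram (and frame stack) from ground truth
#'
#' Vessel pixels are drawn bright (0.9) on a dark background (0.15). The
#' frame stack emulates OCTA's motion contrast: perfused pixels receive
#' independent per-frame multiplicative speckle (|N(1, speckle_sd)|) while
#' non-perfused pixels are identical across frames up to the additive
#' Gaussian read noise applied everywhere. All outputs are clipped to
#' \[0, 1\].
#'
#' @param truth A `ground_truth` from [generate_vessel_network()].
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An [enface_angiogram()] with `image` and `frames`.
#' @export
render_angiogram <- function(truth, config, seed = config$seed) {
  old <- local_seed(derive_seed(seed, 303L))
  on.exit(restore_seed(old))
  n <- config$image_size_px
  base <- matrix(0.15, n, n)
  base[truth$vessel_mask] <- 0.9
  clip01 <- function(m) {
    m[m < 0] <- 0; m[m > 1] <- 1; m
  }
  image <- clip01(base + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n))
  # frames use a lower vessel amplitude so the multiplicative speckle is
  # not flattened by the [0, 1] clip (clipping would suppress decorrelation)
  fbase <- matrix(0.15, n, n)
  fbase[truth$vessel_mask] <- 0.45
  frames <- vector("list", config$n_frames)
  pidx <- which(truth$perfused_mask)
  for (f in seq_len(config$n_frames)) {
    fr <- fbase
    if (length(pidx) && config$speckle_sd > 0) {
      fr[pidx] <- fr[pidx] * abs(stats::rnorm(length(pidx), 1,
                                              config$speckle_sd))
    }
    if (config$noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    }
    frames[[f]] <- clip01(fr)
  }
  enface_angiogram(image, frames = frames,
                   pixel_pitch_um = config$pixel_pitch_um, plexus = "SCP")
}
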