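#' En-face angiogram container
#'
#' A calibrated grayscale en-face OCTA image for one capillary plexus, with
#' an optional frame stack used to compute inter-frame decorrelation. Layer
#' segmentation that produced the slab is upstream of this package; only
#' the plexus label is carried.
#'
#' @param image Numeric matrix, intensities in \[0, 1\].
#' @param frames Optional list of matrices (same shape) — the per-frame
#'   acquisitions.
#' @param pixel_pitch_um Lateral resolution, um per pixel (> 0).
#' @param plexus `"SCP"` or `"DCP"`.
#' @param quality Optional device quality score (pass-through field).
#' @return An `enface_angiogram` list.
#' @export
enface_angiogram <- function(image, frames = NULL, pixel_pitch_um = 5.7,
                             plexus = c("SCP", "DCP"), quality = NULL) {
  plexus <- match.arg(plexus)
  image <- as.matrix(image)
  if (!is.numeric(image) || !length(image)) stop("image must be numeric")
  if (min(image) < 0 || max(image) > 1) {
    stop("intensities must lie in [0, 1]; run normalize_image() first")
  }
  if (!is.null(frames)) {
    if (!all(vapply(frames, function(f) identical(dim(f), dim(image)),
                    logical(1L)))) {
      stop("all frames must share the image's shape")
    }
  }
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be > 0")
  structure(list(image = image, frames = frames,
                 pixel_pitch_um = pixel_pitch_um, plexus = plexus,
                 quality = quality),
            class = "enface_angiogram")
}

#' Min-max normalize an image to \[0, 1\]
#'
#' @param raw Numeric matrix with at least one pixel.
#' @return Matrix rescaled so min -> 0, max -> 1. A constant image becomes
#'   all zeros with a warning and a `degenerate` attribute.
#' @export
normalize_image <- function(raw) {
  raw <- as.matrix(raw)
  if (!length(raw)) stop("empty image")
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("constant image: normalized to all zeros")
    out <- array(0, dim(raw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (raw - rng[1L]) / diff(rng)
}

#' Global white-pixel threshold
#'
#' Marks the white-pixel band of the normalized image: intensities in
#' \[0.7, 1.0\] (lower bound inclusive).
#'
#' @param img Normalized numeric matrix.
#' @param cut Lower bound of the band.
#' @return Logical matrix.
#' @export
global_threshold <- function(img, cut = 0.7) {
  as.matrix(img) >= cut
}

# separable Gaussian-derivative convolution kernels for the Hessian
hessian_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  d2 <- (x^2 / sigma^4 - 1 / sigma^2) * g  # second derivative of Gaussian
  d2 <- d2 - mean(d2)  # exact zero response on constant images
  d1 <- (-x / sigma^2) * g
  list(xx = outer(g, d2), yy = outer(d2, g), xy = outer(d1, d1))
}

#' Multiscale Hessian vesselness (Frangi-type ridge filter)
#'
#' For each scale, the image is convolved with scale-normalized Gaussian
#' second-derivative kernels; the Hessian eigenvalues (ordered
#' `|l1| <= |l2|`) feed the bright-ridge response
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with
#' `S = sqrt(l1^2 + l2^2)` and `c` half the per-scale maximum of `S`;
#' pixels with `l2 >= 0` (not bright-on-dark) respond 0. The maximum over
#' scales is rescaled to \[0, 1\].
#'
#' @param img Normalized numeric matrix.
#' @param scales_px Gaussian scales (pixels), each < min(dim)/4.
#' @param beta Blobness sensitivity (default 0.5).
#' @return Numeric matrix in \[0, 1\].
#' @export
hessian_vesselness <- function(img, scales_px = c(1, 2, 3), beta = 0.5) {
  img <- as.matrix(img)
  if (!length(scales_px)) stop("need at least one scale")
  if (any(scales_px <= 0)) stop("scales must be positive")
  if (any(scales_px > min(dim(img)) / 4)) {
    stop("scale larger than a quarter of the image size")
  }
  out <- array(0, dim(img))
  for (s in scales_px) {
    k <- hessian_kernels(s)
    norm <- s^2  # gamma-normalized derivatives
    Ixx <- norm * EBImage::filter2(img, k$xx, boundary = "replicate")
    Iyy <- norm * EBImage::filter2(img, k$yy, boundary = "replicate")
    Ixy <- norm * EBImage::filter2(img, k$xy, boundary = "replicate")
    tmp <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    mu <- (Ixx + Iyy) / 2
    e1 <- mu + tmp; e2 <- mu - tmp
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)  # smaller magnitude
    l2 <- ifelse(swap, e1, e2)  # larger magnitude
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4  # c = max(S)/2
    if (c2 < 1e-16) next  # flat image: zero Hessian up to FFT noise
    v <- if (c2 > 0) {
      exp(-(l1 / l2)^2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    } else array(0, dim(img))
    v[l2 >= 0 | !is.finite(v)] <- 0
    out <- pmax(out, v)
  }
  m <- max(out)
  if (m > 0) out <- out / m
  out
}

#' Adaptive (local-mean) threshold
#'
#' A pixel is foreground when it exceeds the local mean over a `window_px`
#' square by more than `offset`; the border is handled by reflective
#' padding. Thin bright vessels exceed their local mean, uniform areas do
#' not.
#'
#' @param img Normalized numeric matrix.
#' @param window_px Odd window side >= 3.
#' @param offset Excess over the local mean required for foreground.
#' @return Logical matrix.
#' @export
adaptive_threshold <- function(img, window_px = 15L, offset = 0.02) {
  img <- as.matrix(img)
  if (window_px %% 2L != 1L || window_px < 3L) {
    stop("window_px must be an odd integer >= 3")
  }
  img > box_mean(img, window_px) + offset
}

#' Fuse the three operators into a binary vessel map
#'
#' A pixel is vessel when it passes the global white-pixel threshold OR
#' passes the adaptive threshold with vesselness at least `vesselness_cut`.
#' Connected components smaller than `min_component_px` pixels
#' (4-connectivity) are then removed as speckle.
#'
#' @param global Logical matrix from [global_threshold()].
#' @param vesselness Numeric matrix from [hessian_vesselness()].
#' @param adaptive Logical matrix from [adaptive_threshold()].
#' @param vesselness_cut Vesselness level required alongside the adaptive
#'   threshold.
#' @param pixel_pitch_um Pixel pitch carried into the map.
#' @param min_component_px Minimum surviving component size.
#' @return A `vessel_map`: list with `mask`, `pixel_pitch_um`, `provenance`.
#' @export
fuse_vessel_map <- function(global, vesselness, adaptive,
                            vesselness_cut = 0.05, pixel_pitch_um = 5.7,
                            min_component_px = 5L) {
  if (!identical(dim(global), dim(vesselness)) ||
      !identical(dim(global), dim(adaptive))) {
    stop("shape mismatch between fusion inputs")
  }
  mask <- global | (adaptive & vesselness >= vesselness_cut)
  if (min_component_px > 1L && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)  # 4-connected labeling
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_component_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  structure(list(mask = mask, pixel_pitch_um = pixel_pitch_um,
                 provenance = list(vesselness_cut = vesselness_cut,
                                   min_component_px = min_component_px)),
            class = "vessel_map")
}

#' Inter-frame decorrelation map
#'
#' Per pixel, `D = 1 - mean_t[ 2 f_t f_(t+1) / (f_t^2 + f_(t+1)^2) ]` over
#' consecutive frame pairs, with the pairwise term set to 0 where both
#' frames are 0; values are clipped to \[0, 1\]. Static pixels give D = 0;
#' moving blood fluctuates between frames and gives D > 0 — the OCTA
#' motion-contrast signal.
#'
#' @param frames List (or 3-D array) of at least 2 same-shape matrices.
#' @return Numeric matrix in \[0, 1\].
#' @export
decorrelation_map <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  }
  if (length(frames) < 2L) stop("decorrelation needs at least 2 frames")
  acc <- array(0, dim(frames[[1L]]))
  for (t in seq_len(length(frames) - 1L)) {
    a <- frames[[t]]; b <- frames[[t + 1L]]
    den <- a^2 + b^2
    d <- 1 - 2 * a * b / den
    d[den == 0] <- 0
    acc <- acc + d
  }
  D <- acc / (length(frames) - 1L)
  D[D < 0] <- 0; D[D > 1] <- 1
  D
}

#' Perfusion map: perfused vessel pixels
#'
#' A vessel pixel is perfused when its decorrelation reaches `tau_d`. The
#' perfusion mask is a subset of the vessel mask by construction.
#'
#' @param vessels A `vessel_map` from [fuse_vessel_map()].
#' @param decorr Decorrelation matrix from [decorrelation_map()].
#' @param tau_d Decorrelation threshold in \[0, 1\].
#' @return A `perfusion_map`: list with `mask` and `decorrelation`.
#' @export
perfusion_map <- function(vessels, decorr, tau_d = 0.05) {
  if (tau_d < 0 || tau_d > 1) stop("tau_d must lie in [0, 1]")
  if (!identical(dim(vessels$mask), dim(decorr))) stop("shape mismatch")
  structure(list(mask = vessels$mask & decorr >= tau_d,
                 decorrelation = decorr),
            class = "perfusion_map")
}

#' One-call binarization of an angiogram
#'
#' Runs normalize -> global threshold -> Hessian vesselness -> adaptive
#' threshold -> fusion, and (when a frame stack is present) the
#' decorrelation-based perfusion map. Perfusion density is refused — not
#' silently equated to vessel density — when no frame stack exists.
#'
#' @param ang An [enface_angiogram()].
#' @param global_cut,scales_px,beta,window_px,offset,vesselness_cut,tau_d
#'   Stage parameters; defaults as documented on each stage.
#' @param min_component_px Speckle-removal size.
#' @return List with `vessels` (a `vessel_map`) and `perfusion` (a
#'   `perfusion_map`, or `NULL` without frames).
#' @export
binarize_angiogram <- function(ang, global_cut = 0.7,
                               scales_px = c(1, 2, 3), beta = 0.5,
                               window_px = 15L, offset = 0.02,
                               vesselness_cut = 0.05, tau_d = 0.05,
                               min_component_px = 5L) {
  img <- normalize_image(ang$image)
  g <- global_threshold(img, global_cut)
  v <- hessian_vesselness(img, scales_px, beta)
  a <- adaptive_threshold(img, window_px, offset)
  vm <- fuse_vessel_map(g, v, a, vesselness_cut, ang$pixel_pitch_um,
                        min_component_px)
  vm$provenance <- c(vm$provenance,
                     list(global_cut = global_cut, scales_px = scales_px,
                          beta = beta, window_px = window_px,
                          offset = offset, plexus = ang$plexus))
  pm <- NULL
  if (!is.null(ang$frames) && length(ang$frames) >= 2L) {
    pm <- perfusion_map(vm, decorrelation_map(ang$frames), tau_d)
  }
  list(vessels = vm, perfusion = pm)
}
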