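#' Polygon geometry for CFZ borders and B-scan gap contours
#'
#' Contours are plain two-column matrices (`x_mm`, `y_mm`) of vertices of a
#' simple closed polygon; the closing edge back to the first vertex is
#' implicit. All coordinates are in millimetres.
#'
#' @param x A two-column numeric matrix (or object coercible to one) of
#'   vertices.
#' @return A `polygon2d`: a numeric matrix with columns `x_mm`, `y_mm`.
#' @export
as_polygon2d <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 2L || nrow(m) < 3L || !is.numeric(m) || anyNA(m)) {
    stop("a polygon needs a numeric 2-column matrix with >= 3 vertices")
  }
  colnames(m) <- c("x_mm", "y_mm")
  class(m) <- c("polygon2d", class(m))
  m
}

# drop consecutive duplicate vertices (and a duplicated closing vertex)
dedupe_vertices <- function(poly) {
  n <- nrow(poly)
  keep <- c(TRUE, rowSums(abs(poly[-1L, , drop = FALSE] -
                              poly[-n, , drop = FALSE])) > 0)
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  if (n > 1L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly A [as_polygon2d()] matrix.
#' @param check_simple Verify the polygon has no self-intersections before
#'   computing (O(n^2) segment test). Contours produced internally are
#'   simple by construction and skip the check.
#' @return Area in mm^2 (absolute value).
#' @export
polygon_area <- function(poly, check_simple = TRUE) {
  poly <- dedupe_vertices(as_polygon2d(poly))
  if (check_simple) {
    hit <- polygon_self_intersection(poly)
    if (!is.null(hit)) {
      stop(sprintf("self-intersecting polygon: edge %d crosses edge %d",
                   hit[1L], hit[2L]))
    }
  }
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon perimeter (closing edge included)
#'
#' @inheritParams polygon_area
#' @return Perimeter in mm.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon2d(poly)
  d <- poly[c(seq_len(nrow(poly))[-1L], 1L), ] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Shape circularity 4*pi*A/P^2
#'
#' Equals 1 for a circle and approaches 0 as the contour becomes less round
#' or less smooth (isoperimetric inequality). The value is not clamped:
#' results above 1 (beyond discretization allowance) indicate a contour
#' error and raise a warning.
#'
#' @param area_mm2 Area A in mm^2 (>= 0).
#' @param perimeter_mm Perimeter P in mm (> 0).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area_mm2, perimeter_mm) {
  if (any(perimeter_mm <= 0)) stop("perimeter must be > 0")
  if (any(area_mm2 < 0)) stop("area must be >= 0")
  C <- 4 * pi * area_mm2 / perimeter_mm^2
  if (any(C > 1.02)) {
    warning("circularity > 1: contour is not a valid simple closed curve")
  }
  C
}

#' CFZ-style morphometry of a contour
#'
#' @inheritParams polygon_area
#' @return A list with `area_mm2`, `perimeter_mm`, `circularity`.
#' @export
polygon_metrics <- function(poly, check_simple = FALSE) {
  A <- polygon_area(poly, check_simple = check_simple)
  P <- polygon_perimeter(poly)
  list(area_mm2 = A, perimeter_mm = P, circularity = circularity(A, P))
}

# first pair of properly crossing edges, or NULL; shared endpoints between
# adjacent edges are not crossings
polygon_self_intersection <- function(poly) {
  poly <- dedupe_vertices(as_polygon2d(poly))
  n <- nrow(poly)
  p <- poly
  q <- poly[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n shares vertex 1 with edge 1
    if (!length(js)) next
    rX <- q[i, 1L] - p[i, 1L]; rY <- q[i, 2L] - p[i, 2L]
    sX <- q[js, 1L] - p[js, 1L]; sY <- q[js, 2L] - p[js, 2L]
    qpX <- p[js, 1L] - p[i, 1L]; qpY <- p[js, 2L] - p[i, 2L]
    den <- cross2(rX, rY, sX, sY)
    t <- cross2(qpX, qpY, sX, sY) / den
    u <- cross2(qpX, qpY, rX, rY) / den
    ok <- is.finite(t) & is.finite(u) & t > 0 & t < 1 & u > 0 & u < 1
    if (any(ok)) return(c(i, js[which(ok)[1L]]))
  }
  NULL
}

#' Points-in-polygon test
#'
#' Vectorized ray-casting via [mgcv::in.out()].
#'
#' @param poly A [as_polygon2d()] matrix.
#' @param x,y Point coordinates in mm.
#' @return Logical vector, `TRUE` for points strictly inside.
#' @export
points_in_polygon <- function(poly, x, y) {
  poly <- as_polygon2d(poly)
  bnd <- rbind(unclass(poly), unclass(poly)[1L, ])
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Generate a closed FAZ/CFZ-like contour with prescribed area and circularity
#'
#' Builds a star-shaped polygon by radial sinusoidal perturbation of a
#' circle: `r(theta) = 1 + a * (sin(k1 theta + phi1) + 0.5 sin(k2 theta +
#' phi2))` with seed-dependent phases. The amplitude `a` is solved
#' numerically (on the polygon itself, so discretization is accounted for)
#' to meet the requested circularity, then the contour is scaled uniformly
#' to the requested area; scaling leaves circularity unchanged.
#'
#' @param target_area_mm2 Requested area (mm^2, > 0).
#' @param target_circularity Requested circularity in (0, 1].
#' @param n_vertices Number of vertices (>= 8; more vertices give a smoother
#'   contour and a wider feasible circularity range).
#' @param seed Integer seed for the perturbation phases.
#' @param center_mm Contour centroid (x, y) in mm.
#' @return A [as_polygon2d()] matrix; attributes `area_mm2`,
#'   `perimeter_mm`, `circularity` carry the achieved values.
#' @export
generate_faz_polygon <- function(target_area_mm2, target_circularity,
                                 n_vertices = 256L, seed = 1L,
                                 center_mm = c(0, 0)) {
  stopifnot(target_area_mm2 > 0, n_vertices >= 8L)
  if (target_circularity <= 0 || target_circularity > 1) {
    stop("target_circularity must lie in (0, 1]")
  }
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  phi <- stats::runif(2, 0, 2 * pi)
  k1 <- 5; k2 <- 8
  shape <- function(a) {
    r <- 1 + a * (sin(k1 * theta + phi[1L]) + 0.5 * sin(k2 * theta + phi[2L]))
    as_polygon2d(cbind(r * cos(theta), r * sin(theta)))
  }
  circ_of <- function(a) {
    p <- shape(a)
    circularity(polygon_area(p, check_simple = FALSE), polygon_perimeter(p))
  }
  a_max <- 0.6  # keeps r(theta) > 0.1 and the contour star-shaped (simple)
  c0 <- circ_of(0)
  if (target_circularity >= c0) {
    if (target_circularity - c0 > 0.05 * target_circularity) {
      stop(sprintf(paste0("circularity %.4f infeasible with %d vertices ",
                          "(polygonal maximum %.4f)"),
                   target_circularity, n_vertices, c0))
    }
    a <- 0
  } else if (circ_of(a_max) > target_circularity) {
    stop(sprintf("circularity %.3f below the reachable range for this shape",
                 target_circularity))
  } else {
    a <- stats::uniroot(function(a) circ_of(a) - target_circularity,
                        c(0, a_max), tol = 1e-10)$root
  }
  p <- shape(a)
  s <- sqrt(target_area_mm2 / polygon_area(p, check_simple = FALSE))
  p <- as_polygon2d(sweep(unclass(p) * s, 2L, center_mm, `+`))
  m <- polygon_metrics(p)
  attr(p, "area_mm2") <- m$area_mm2
  attr(p, "perimeter_mm") <- m$perimeter_mm
  attr(p, "circularity") <- m$circularity
  p
}

#' Read / write polygons as JSON vertex lists
#'
#' The on-disk form is a JSON array of `[x_mm, y_mm]` pairs; closure is
#' implicit.
#'
#' @param poly A polygon; `path` a file path.
#' @rdname polygon_json
#' @export
write_polygon_json <- function(poly, path) {
  poly <- as_polygon2d(poly)
  jsonlite::write_json(unname(apply(unclass(poly), 1L, c, simplify = FALSE)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @param path File path.
#' @rdname polygon_json
#' @export
read_polygon_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_polygon2d(v)
}
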