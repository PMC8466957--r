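# Seed hygiene: generators take explicit seeds but must not disturb the
# caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

#' Truncated percentage of a count over a total
#'
#' Percentage truncated (not rounded) at `digits` decimals, the convention
#' under which prevalences are printed in clinical tables (10/28 prints as
#' 35.71 percent at 2 decimals, 35.7 at 1).
#'
#' @param n,total Count and total.
#' @param digits Decimals kept after truncation.
#' @return Numeric percentage.
#' @export
pct_truncated <- function(n, total, digits = 2L) {
  trunc(n / total * 100 * 10^digits) / 10^digits
}

# reflective padding of a matrix by k rows/cols on each side
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop("padding exceeds image size")
  ri <- c(k:1, seq_len(nr), nr:(nr - k + 1L))
  ci <- c(k:1, seq_len(nc), nc:(nc - k + 1L))
  m[ri, ci, drop = FALSE]
}

# local mean over a w x w window (w odd) with reflective border handling
box_mean <- function(m, w) {
  if (w %% 2L != 1L || w < 3L) stop("window must be an odd integer >= 3")
  k <- (w - 1L) %/% 2L
  p <- pad_reflect(m, k)
  # separable running sum via cumsum along each dimension
  cs <- apply(p, 2L, cumsum)
  rows <- cs[(2L * k + 1L):nrow(p), , drop = FALSE] -
    rbind(0, cs[seq_len(nrow(p) - 2L * k - 1L), , drop = FALSE])
  cs2 <- t(apply(rows, 1L, cumsum))
  out <- cs2[, (2L * k + 1L):ncol(p), drop = FALSE] -
    cbind(0, cs2[, seq_len(ncol(p) - 2L * k - 1L), drop = FALSE])
  out / w^2
}
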