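# Shared numeric helpers: Gaussian smoothing, circular geometry, seed streams.

#' Gaussian smoothing of a regularly sampled series
#'
#' Finite-impulse-response Gaussian filter with kernel truncated at 4 SD and
#' renormalised at the edges (or wrapped, for circular series such as tuning
#' curves on a looped track).  `NA` samples are ignored and renormalised out,
#' so missing bins do not bleed zeros into their neighbours.
#'
#' @param x numeric vector.
#' @param sd kernel standard deviation in samples; `sd <= 0` returns `x`.
#' @param circular wrap the kernel around the ends (use for spatial bins on a
#'   circular track).
#' @return smoothed vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sd, circular = FALSE) {
  if (sd <= 0 || length(x) < 2L) return(x)
  half <- max(1L, ceiling(4 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  na <- is.na(x)
  w <- as.numeric(!na)
  x0 <- ifelse(na, 0, x)
  if (circular) {
    conv <- function(v) {
      vp <- c(v[(n - min(half, n - 1L) + 1L):n], v, v[1L:min(half, n)])
      # if half >= n, recycle whole copies
      if (half >= n) {
        reps <- ceiling(half / n)
        vp <- c(rep(v, reps), v, rep(v, reps))
        vp <- vp[(reps * n - half + 1L):(reps * n + n + half)]
      }
      stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
    }
  } else {
    conv <- function(v) {
      vp <- c(rep(0, half), v, rep(0, half))
      stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
    }
  }
  num <- as.numeric(conv(x0))
  den <- as.numeric(conv(w))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Circular distance on a looped track
#'
#' @param a,b positions in cm.
#' @param track_length loop length in cm.
#' @return elementwise shortest distance, in `[0, track_length/2]`.
#' @export
circular_distance <- function(a, b, track_length = 400) {
  d <- abs(a - b) %% track_length
  pmin(d, track_length - d)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483647)
}

# Occupancy-weighted mean tuning curve from a trials x bins rate map with
# matching occupancy (seconds).  Bins never occupied come back NA.
weighted_tuning <- function(rate, occupancy) {
  occ <- occupancy
  occ[is.na(rate)] <- 0
  r0 <- ifelse(is.na(rate), 0, rate)
  tot <- colSums(occ)
  out <- colSums(r0 * occ) / tot
  out[tot == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
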