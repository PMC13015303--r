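#' Plant overlapping networks and synthesize BOLD data
#'
#' Creates K spatially contiguous network supports on the gray matter of a toy
#' geometry, with a controlled fraction of gray-matter vertices participating
#' in two networks (connector-hub ground truth), then synthesizes BOLD as
#' timecourses x support maps plus AR(1) Gaussian noise at a controlled SNR.
#' The planted per-vertex participation count k is recorded so recovery of the
#' k-hubness map can be scored exactly.
#'
#' SNR is defined per vertex as planted-signal standard deviation over noise
#' standard deviation; `snr = Inf` turns noise off, making the data the exact
#' product of timecourses and supports.
#'
#' @param geom A [make_geometry()] object.
#' @param K Number of planted networks (at least 2).
#' @param overlap_frac Fraction of gray-matter vertices belonging to two
#'   networks, in `[0, 1)`.
#' @param T_frames Number of frames; must be at least `2 * K`.
#' @param tr Repetition time (seconds).
#' @param snr Signal-to-noise ratio (positive; `Inf` for noiseless).
#' @param ar1 AR(1) coefficient of the noise, in `[0, 1)` (default 0.4).
#' @param seed Integer seed.
#'
#' @return A list with `ts` (a [bold_ts()]) and `truth` (a `ground_truth`
#'   object with `planted_supports` K x V logical, `planted_timecourses`
#'   T x K, and `planted_k` per-vertex counts).
#' @export
plant_networks_and_bold <- function(geom, K, overlap_frac, T_frames, tr = 2,
                                    snr = 2, ar1 = 0.4, seed = 1L) {
  stopifnot(inherits(geom, "toy_geometry"))
  K <- assert_positive_int(K, "K")
  if (K < 2) abort("`K` must be at least 2.", class = "netdax_error_argument")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1).", class = "netdax_error_argument")
  }
  T_frames <- assert_positive_int(T_frames, "T_frames")
  if (T_frames < 2 * K) {
    abort("Need at least 2*K frames to identify K networks.",
          class = "netdax_error_argument")
  }
  if (!(snr > 0)) abort("`snr` must be positive.", class = "netdax_error_argument")
  if (ar1 < 0 || ar1 >= 1) {
    abort("`ar1` must be in [0, 1).", class = "netdax_error_argument")
  }
  v <- nrow(geom$coords)
  gm <- which(geom$gm_mask)
  with_seed(seed, {
    centers <- geom$coords[sample(gm, K), , drop = FALSE]
    d <- cross_dist(geom$coords[gm, , drop = FALSE], centers)
    nearest <- max.col(-d, ties.method = "first")
    second <- vapply(seq_along(gm), function(i) order(d[i, ])[2L], integer(1))

    supports <- matrix(FALSE, K, v)
    supports[cbind(nearest, gm)] <- TRUE
    n_ov <- round(overlap_frac * length(gm))
    if (n_ov > 0) {
      ov <- sample(seq_along(gm), n_ov)
      supports[cbind(second[ov], gm[ov])] <- TRUE
    }
    planted_k <- colSums(supports)

    # smooth, roughly uncorrelated timecourses: Gaussian-kernel-filtered white
    # noise (keeps low-frequency structure), standardized per network
    kern <- dnorm(seq(-3, 3, length.out = 9))
    kern <- kern / sum(kern)
    tc <- vapply(seq_len(K), function(k) {
      x <- stats::filter(rnorm(T_frames + 16), kern, sides = 2)
      x <- x[9:(T_frames + 8)]
      (x - mean(x)) / sd(x)
    }, numeric(T_frames))

    signal <- tc %*% (supports * 1)
    if (is.finite(snr)) {
      sig_sd <- apply(signal, 2, sd)
      ref_sd <- mean(sig_sd[geom$gm_mask & sig_sd > 0])
      noise_sd <- ifelse(sig_sd > 0, sig_sd / snr, ref_sd / snr)
      innov_scale <- sqrt(1 - ar1^2)
      noise <- vapply(seq_len(v), function(j) {
        e <- numeric(T_frames)
        e[1] <- rnorm(1)
        if (T_frames > 1) {
          z <- rnorm(T_frames - 1) * innov_scale
          for (t in 2:T_frames) e[t] <- ar1 * e[t - 1] + z[t - 1]
        }
        e * noise_sd[j]
      }, numeric(T_frames))
      data <- signal + noise
    } else {
      data <- signal
    }
    truth <- structure(
      list(planted_supports = supports,
           planted_timecourses = tc,
           planted_k = planted_k),
      class = "ground_truth"
    )
    list(ts = bold_ts(data, tr = tr, mask = geom$gm_mask), truth = truth)
  })
}
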