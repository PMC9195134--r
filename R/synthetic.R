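#' Simulate a diverged nucleotide sequence pair with known K2P distance
#'
#' Divergence is parametrized directly by per-site change proportions
#' rather than by rate times time: each site of `seq_b` is, independently,
#' the transition partner of the `seq_a` base with probability `p`
#' (A<->G, C<->T), one of its two transversion partners (equiprobably) with
#' probability `q`, and unchanged otherwise. The Kimura two-parameter
#' distance implied by `(p, q)` is then available in closed form as the
#' exact ground truth, with no matrix exponentials involved. Base
#' composition of `seq_a` is uniform over A/C/G/T; no indels are
#' introduced.
#'
#' @param length number of sites, `>= 1`.
#' @param p,q transition and transversion change probabilities; must
#'   satisfy `2p + q < 1` and `2q < 1` so the implied distance exists.
#' @param seed optional integer seed; a fixed seed reproduces the pair
#'   bitwise.
#' @return An object of class `simulated_pair`: list with `seq_a`, `seq_b`,
#'   `true_p`, `true_q`, `true_d`, `seed`.
#' @examples
#' sp <- simulate_pair(1000, p = 0.04, q = 0.02, seed = 1)
#' sp$true_d
#' @export
simulate_pair <- function(length, p, q, seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (p < 0 || q < 0 || 2 * p + q >= 1 || 2 * q >= 1)
    stop(sprintf(
      "invalid (p, q) = (%.4g, %.4g): need p, q >= 0, 2p + q < 1, 2q < 1",
      p, q), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ts_map <- c(A = "G", C = "T", G = "A", T = "C")
  # the two transversion partners of each base, as columns
  tv_map <- cbind(A = c("C", "T"), C = c("A", "G"),
                  G = c("C", "T"), T = c("A", "G"))
  a <- sample(bases, length, replace = TRUE)
  u <- stats::runif(length)
  pick <- 1L + (stats::runif(length) < 0.5)
  b <- a
  is_ts <- u < p
  is_tv <- !is_ts & u < p + q
  b[is_ts] <- ts_map[a[is_ts]]
  if (any(is_tv))
    b[is_tv] <- tv_map[cbind(pick[is_tv], match(a[is_tv], bases))]
  structure(list(
    seq_a = paste(a, collapse = ""),
    seq_b = paste(b, collapse = ""),
    true_p = p, true_q = q,
    true_d = if (p == 0 && q == 0) 0 else k2p_from_proportions(p, q),
    seed = seed
  ), class = "simulated_pair")
}

#' Monte Carlo recovery of the K2P distance estimator
#'
#' Simulates `replicates` independent sequence pairs at the same `(p, q)`,
#' estimates the K2P distance of each through the site-classification
#' pipeline ([classify_sites()] + [k2p_distance()]), and summarizes the
#' estimates against the closed-form generating distance. Replicates whose
#' distance is inestimable (saturation) are counted and excluded from the
#' summary.
#'
#' @param length sites per replicate.
#' @param p,q generating change proportions.
#' @param replicates number of replicates, `>= 2`.
#' @param seed integer seed for the whole experiment.
#' @return List with `true_d`, `mean_d`, `relative_bias`
#'   (`(mean_d - true_d)/true_d`, 0 when `true_d` is 0 and all estimates
#'   are 0), `sd_d`, `n_used`, `n_saturated`.
#' @export
recovery_experiment <- function(length, p, q, replicates, seed = NULL) {
  if (replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  est <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    sp <- simulate_pair(length, p, q)
    est[r] <- tryCatch(
      k2p_distance(classify_sites(sp$seq_a, sp$seq_b)),
      error = function(e) NA_real_)
  }
  used <- est[!is.na(est)]
  true_d <- if (p == 0 && q == 0) 0 else k2p_from_proportions(p, q)
  mean_d <- mean(used)
  rel_bias <- if (true_d == 0) {
    if (mean_d == 0) 0 else Inf
  } else (mean_d - true_d) / true_d
  list(true_d = true_d, mean_d = mean_d, relative_bias = rel_bias,
       sd_d = stats::sd(used), n_used = length(used),
       n_saturated = sum(is.na(est)))
}

#' Simulate a strain-pair metric table with a known exponential link
#'
#' Emulates the statistical structure of the packaged 80-pair table: ANIm
#' values drawn uniformly over `anim_range`, dDDH generated from ANIm
#' through the exponential link `ddh = link_a * exp(link_b * anim)` plus
#' Gaussian noise of sd `sigma` (truncated to \[0, 100\], with truncation
#' recorded per record), and the MLSA distance generated from dDDH through
#' a second exponential link (`mlsa_link_a`, `mlsa_link_b`, noise
#' `mlsa_sigma`, floored at 0). Default link parameters are rounded values
#' of the fits obtained on the packaged table, so the simulated tables look
#' like the calibration data. The noiseless dDDH curve must stay inside
#' (0, 100\] over `anim_range`.
#'
#' @param n number of pairs, `>= 3`.
#' @param anim_range length-2 numeric, ANIm sampling interval.
#' @param link_a,link_b dDDH-on-ANIm link parameters, `link_a > 0`.
#' @param sigma dDDH noise sd (percentage points).
#' @param mlsa_link_a,mlsa_link_b,mlsa_sigma MLSA-on-dDDH link and noise.
#' @param seed integer seed.
#' @return A `pair_metric_table` with synthetic species labels; attributes
#'   `link` (the generating parameters) and `truncated` (logical vector
#'   marking records whose noisy dDDH was clipped).
#' @export
simulate_metric_table <- function(n = 80L, anim_range = c(90, 100),
                                  link_a = 0.00282, link_b = 0.1045,
                                  sigma = 0.5,
                                  mlsa_link_a = 0.287,
                                  mlsa_link_b = -0.0508,
                                  mlsa_sigma = 0.002,
                                  seed = NULL) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (link_a <= 0) stop("link_a must be > 0", call. = FALSE)
  stopifnot(length(anim_range) == 2L, anim_range[1L] < anim_range[2L])
  curve_ends <- link_a * exp(link_b * anim_range)
  if (any(curve_ends <= 0) || any(curve_ends > 100))
    stop(sprintf(
      "noiseless dDDH curve leaves (0, 100] on anim_range (ends %.3g, %.3g)",
      curve_ends[1L], curve_ends[2L]), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  anim <- stats::runif(n, anim_range[1L], anim_range[2L])
  ddh_raw <- link_a * exp(link_b * anim) + stats::rnorm(n, 0, sigma)
  truncated <- ddh_raw < 0 | ddh_raw > 100
  ddh <- pmin(pmax(ddh_raw, 0), 100)
  mlsa <- pmax(mlsa_link_a * exp(mlsa_link_b * ddh) +
                 stats::rnorm(n, 0, mlsa_sigma), 0)
  tbl <- metric_table(
    species_a = sprintf("Synthetic sp. %03da", seq_len(n)),
    species_b = sprintf("Synthetic sp. %03db", seq_len(n)),
    anim = anim, mlsa = mlsa, ddh = ddh,
    source = "simulated")
  attr(tbl, "link") <- list(link_a = link_a, link_b = link_b, sigma = sigma,
                            mlsa_link_a = mlsa_link_a,
                            mlsa_link_b = mlsa_link_b,
                            mlsa_sigma = mlsa_sigma, seed = seed)
  attr(tbl, "truncated") <- truncated
  tbl
}
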