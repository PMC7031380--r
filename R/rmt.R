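# Random-matrix-theory threshold selection for co-occurrence networks.
#
# As the correlation matrix is hard-thresholded at increasing cutoffs s, the
# nearest-neighbour spacing distribution (NNSD) of its unfolded eigenvalues
# crosses from the Wigner-Dyson (GOE) form characteristic of random matrices,
# P(s) = (pi s / 2) exp(-pi s^2 / 4), to the Poisson form, P(s) = exp(-s),
# characteristic of modular (block / localized) structure. The network
# threshold is the smallest cutoff at which the spectrum has become Poisson
# and GOE is rejected.

#' Unfolded nearest-neighbour eigenvalue spacings
#'
#' Deduplicates eigenvalues (thresholded matrices are highly degenerate),
#' fits a cubic smoothing spline to the cumulative spectral density
#' (staircase) to unfold the spectrum to unit mean density, and returns the
#' successive spacings (negative spacings from spline wiggle are clipped at
#' zero, then rescaled to mean 1).
#'
#' @param ev Numeric eigenvalues.
#' @param unfold_df Effective degrees of freedom of the smoothing spline.
#' @param dedup_tol Eigenvalues closer than this are merged.
#' @return Numeric spacings with mean 1, or `NULL` when fewer than 15
#'   distinct eigenvalues remain.
#' @export
nnsd_spacings <- function(ev, unfold_df = 10, dedup_tol = 1e-8) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > dedup_tol)]
  n <- length(ev)
  if (n < 15) return(NULL)
  staircase <- (seq_len(n) - 0.5) / n
  fit <- stats::smooth.spline(ev, staircase, df = min(unfold_df, n - 4))
  unfolded <- n * stats::predict(fit, ev)$y
  s <- diff(unfolded)
  s[s < 0] <- 0
  if (mean(s) <= 0) return(NULL)
  s / mean(s)
}

#' Chi-square goodness of fit of spacings to Poisson and GOE forms
#'
#' Bins the spacings into equal-probability bins under each candidate
#' distribution (Poisson: CDF 1 - exp(-s); GOE Wigner surmise: CDF
#' 1 - exp(-pi s^2 / 4)) and computes Pearson chi-square p-values.
#'
#' @param spacings Unit-mean spacings from [nnsd_spacings()].
#' @param nbins Number of equal-probability bins (default 20; clamped so
#'   each bin expects >= 2 spacings).
#' @return List with `p_poisson`, `p_goe`, `chisq_poisson`, `chisq_goe`,
#'   `nbins`.
#' @export
nnsd_fit <- function(spacings, nbins = 20) {
  ns <- length(spacings)
  abort_if(ns < 10, "nnsd_fit: too few spacings")
  nb <- max(5L, min(as.integer(nbins), floor(ns / 2)))
  probs <- seq(0, 1, length.out = nb + 1L)
  chisq_p <- function(qfun) {
    brk <- qfun(probs)
    brk[1L] <- -Inf
    brk[nb + 1L] <- Inf
    obs <- tabulate(findInterval(spacings, brk, rightmost.closed = TRUE),
                    nbins = nb)
    expd <- ns / nb
    stat <- sum((obs - expd)^2 / expd)
    list(stat = stat, p = stats::pchisq(stat, df = nb - 1L, lower.tail = FALSE))
  }
  pois <- chisq_p(function(p) -log(1 - p))
  goe <- chisq_p(function(p) sqrt(-4 * log(1 - p) / pi))
  list(p_poisson = pois$p, p_goe = goe$p,
       chisq_poisson = pois$stat, chisq_goe = goe$stat, nbins = nb)
}

#' RMT threshold for a correlation matrix
#'
#' Scans candidate thresholds from `s_range[1]` upward in steps of
#' `grid_step`. At each candidate, entries with `|rho| < s` are zeroed
#' (diagonal kept), the eigenvalue spectrum is unfolded, and the NNSD is
#' tested against the Poisson and GOE forms. Returns the smallest candidate
#' at which the NNSD is consistent with Poisson (p > `alpha`) while GOE is
#' rejected (p < `alpha`) - the GOE-to-Poisson transition.
#'
#' @param rho Symmetric correlation matrix, at least 20 x 20.
#' @param grid_step Scan step (default 0.01).
#' @param s_range Scan range (default c(0.3, 0.99)).
#' @param nbins NNSD chi-square bins (default 20).
#' @param unfold_df Spline degrees of freedom for unfolding (default 10).
#' @param alpha Decision level for both goodness-of-fit tests.
#' @return List (`rmt_threshold`): `threshold` and `scan`, a data.frame of
#'   (s, p_poisson, p_goe, n_spacings) over the evaluated candidates.
#' @export
rmt_threshold <- function(rho, grid_step = 0.01, s_range = c(0.3, 0.99),
                          nbins = 20, unfold_df = 10, alpha = 0.05) {
  abort_if(!is_square_symmetric(rho, tol = 1e-8),
           "rmt_threshold: rho must be symmetric")
  n <- nrow(rho)
  abort_if(n < 20,
           "rmt_threshold: matrix below 20 x 20; spectra too sparse for RMT - ",
           "choose a threshold manually")
  off <- abs(rho[upper.tri(rho)])
  abort_if(max(off) <= s_range[1L],
           "rmt_threshold: no off-diagonal signal above scan range ",
           "(degenerate spectrum)")
  grid <- seq(s_range[1L], s_range[2L], by = grid_step)
  scan <- data.frame(s = grid, p_poisson = NA_real_, p_goe = NA_real_,
                     n_spacings = NA_integer_)
  threshold <- NA_real_
  for (i in seq_along(grid)) {
    s <- grid[i]
    m <- rho
    m[abs(m) < s] <- 0
    diag(m) <- 1
    sp <- nnsd_spacings(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                        unfold_df = unfold_df)
    if (is.null(sp)) next
    fit <- nnsd_fit(sp, nbins = nbins)
    scan$p_poisson[i] <- fit$p_poisson
    scan$p_goe[i] <- fit$p_goe
    scan$n_spacings[i] <- length(sp)
    if (is.na(threshold) && fit$p_poisson > alpha && fit$p_goe < alpha) {
      threshold <- s
      break
    }
  }
  abort_if(is.na(threshold),
           "rmt_threshold: no GOE-to-Poisson transition found in s_range; ",
           "widen the range or inspect the scan")
  structure(list(threshold = threshold, scan = scan[!is.na(scan$p_poisson) |
                                                      scan$s <= threshold, ]),
            class = "rmt_threshold")
}
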