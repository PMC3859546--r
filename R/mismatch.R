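## Mismatch distributions and the sudden-expansion model: observed
## pairwise-difference histograms, the transient expectation of the
## sudden-expansion (pure demographic) model, least-squares fitting of
## (tau, theta0, theta1), and the parametric-bootstrap SSD goodness-of-fit
## test.
##
## Model.  A population at scaled size theta0 = 2N0*u expands instantly to
## theta1 = 2N1*u at time tau = 2*u*t (mutational units) before sampling.
## For a random pair of sequences, with Fhat_j(theta) = theta^j /
## (1+theta)^(j+1) the geometric equilibrium distribution, the transient
## distribution is
##   F_j(tau) = Fhat_j(theta1)
##            + exp(-tau (theta1+1)/theta1)
##              * sum_{i=0..j} tau^(j-i)/(j-i)! * [Fhat_i(theta0) - Fhat_i(theta1)]
## (derived from the pair coalescent with a piecewise-constant size; at
## tau = 0 it reduces to Fhat(theta0), and to Fhat(theta1) as tau grows).
## The transcription is validated against the package's own coalescent
## simulator in the test suite.

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all unordered pairs,
#' pairwise deletion for missing data.
#'
#' @param seqs Named character vector of aligned sequences (n >= 2).
#' @return Object of class `mismatch_distribution`: list with `counts`
#'   (frequency of difference j, j = 0..j_max), `freq` (normalised),
#'   `n_pairs`, `mean`.
#' @export
observed_mismatch <- function(seqs) {
  if (length(seqs) < 2) stop("mismatch distribution needs n >= 2")
  mat <- seq_matrix(seqs)
  pd <- pairwise_diffs(mat)
  mismatch_from_d(pd$d)
}

mismatch_from_d <- function(d) {
  vals <- d[upper.tri(d)]
  j_max <- max(vals)
  counts <- tabulate(vals + 1L, nbins = j_max + 1L)
  freq <- counts / length(vals)
  structure(list(counts = counts, freq = freq,
                 n_pairs = length(vals),
                 mean = sum((0:j_max) * freq)),
            class = "mismatch_distribution")
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat("mismatch distribution:", x$n_pairs, "pairs, mean",
      format(x$mean, digits = 4), ", range 0 -", length(x$counts) - 1, "\n")
  invisible(x)
}

#' Expected mismatch distribution under sudden expansion
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Scaled sizes before/after expansion (> 0).
#' @param j_max Largest difference class.
#' @return Numeric probability vector over j = 0..j_max, renormalised.
#' @export
expected_mismatch <- function(tau, theta0, theta1, j_max) {
  if (!all(is.finite(c(tau, theta0, theta1))) ||
      tau < 0 || theta0 <= 0 || theta1 <= 0)
    stop("non-finite or non-positive mismatch parameters")
  j <- 0:j_max
  fhat <- function(theta) exp(j * log(theta) - (j + 1) * log1p(theta))
  f1 <- fhat(theta1)
  if (tau == 0) {
    f <- fhat(theta0)
    return(f / sum(f))
  }
  f0 <- fhat(theta0)
  lam <- tau * (theta1 + 1) / theta1
  ## p_m = exp(-lam) tau^m / m!  (bounded above by exp(-tau/theta1) <= 1)
  m <- 0:j_max
  pm <- exp(-lam + m * log(tau) - lgamma(m + 1))
  diff0 <- f0 - f1
  ## F_j = f1_j + sum_{m=0..j} pm_m * diff0_{j-m}  (discrete convolution)
  conv <- stats::convolve(pm, rev(diff0), type = "open")[seq_len(j_max + 1)]
  f <- f1 + conv
  f[f < 0] <- 0
  f / sum(f)
}

ssd_value <- function(freq_obs, tau, theta0, theta1) {
  fe <- expected_mismatch(tau, theta0, theta1, length(freq_obs) - 1L)
  sum((freq_obs - fe)^2)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Minimises `SSD = sum_j (f_obs_j - f_exp_j)^2` over (tau, theta0,
#' theta1): a coarse deterministic grid (tau over [0, 2*mean], theta0 over
#' (0, mean], theta1 in mean * {10, 100, 1000}) followed by Nelder-Mead
#' refinement with box penalties (theta0 <= theta1 <= `theta1_cap` *
#' mean).  Deterministic given the input.
#'
#' @param obs A `mismatch_distribution` (or a raw frequency vector).
#' @param theta1_cap Upper bound for theta1, as a multiple of the observed
#'   mean (default 1e5; an unbounded theta1 is unidentifiable because the
#'   likelihood surface flattens into a ridge).
#' @return Object of class `mismatch_fit`: list with `tau`, `theta0`,
#'   `theta1`, `ssd`, `freq_obs` (`p_ssd`/`n_boot` are filled by
#'   [ssd_test()]).
#' @export
fit_expansion <- function(obs, theta1_cap = 1e5) {
  freq <- if (inherits(obs, "mismatch_distribution")) obs$freq else obs
  if (abs(sum(freq) - 1) > 1e-8) stop("observed frequencies must sum to 1")
  mu <- sum((seq_along(freq) - 1) * freq)
  if (sum(freq > 0) < 2 || mu == 0) {
    warning("degenerate mismatch distribution; tau fixed at the 0 boundary")
    fit <- list(tau = 0, theta0 = 1e-6, theta1 = 1e-6,
                ssd = ssd_value(freq, 0, 1e-6, 1e-6), freq_obs = freq,
                p_ssd = NA_real_, n_boot = 0L)
    return(structure(fit, class = "mismatch_fit"))
  }
  cap <- theta1_cap * mu
  obj <- function(p) {
    tau <- p[1]; th0 <- p[2]; th1 <- p[3]
    if (tau < 0 || th0 <= 0 || th1 < th0 || th1 > cap) return(1e6)
    ssd_value(freq, tau, th0, th1)
  }
  grid_tau <- seq(0, 2 * mu, length.out = 7)
  grid_th0 <- mu * c(0.02, 0.1, 0.5, 1)
  grid_th1 <- pmin(mu * c(10, 100, 1000), cap)
  best <- NULL; best_val <- Inf
  for (tt in grid_tau) for (t0 in grid_th0) for (t1 in grid_th1) {
    v <- obj(c(tt, t0, t1))
    if (v < best_val) { best_val <- v; best <- c(tt, t0, t1) }
  }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 1500, reltol = 1e-12))
  p <- opt$par
  v <- opt$value
  structure(list(tau = max(p[1], 0), theta0 = p[2], theta1 = p[3],
                 ssd = v, freq_obs = freq,
                 p_ssd = NA_real_, n_boot = 0L),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("sudden-expansion fit: tau =", format(x$tau, digits = 4),
      ", theta0 =", format(x$theta0, digits = 4),
      ", theta1 =", format(x$theta1, digits = 4),
      "\n  SSD =", format(x$ssd, digits = 4),
      if (!is.na(x$p_ssd)) paste0(", p(SSD) = ", format(x$p_ssd, digits = 3),
                                  " (", x$n_boot, " bootstraps)") else "",
      "\n")
  invisible(x)
}

#' Parametric-bootstrap SSD goodness-of-fit test
#'
#' Simulates `n_boot` coalescent datasets of the same sample size under
#' the fitted (tau, theta0, theta1), refits the sudden-expansion model to
#' each, and reports the fraction of replicates whose refitted SSD is at
#' least the observed SSD.
#'
#' @param n Sample size the observed distribution came from.
#' @param fit A `mismatch_fit` (from [fit_expansion()]).
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return The `mismatch_fit` with `p_ssd` and `n_boot` filled in.
#' @export
ssd_test <- function(n, fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "mismatch_fit"), n >= 2)
  if (n_boot < 100) stop("n_boot < 100 gives an unstable p-value")
  old <- .int_seed(seed)
  on.exit(.restore_seed(old))
  th0 <- max(fit$theta0, 1e-6); th1 <- max(fit$theta1, th0)
  sims <- vapply(seq_len(n_boot), function(b) {
    M <- sim_coal_M(n, theta0 = th0, theta1 = th1, tau = fit$tau,
                    model = if (fit$tau > 0 || th1 > th0)
                      "sudden_expansion" else "constant")
    d <- M_pairwise(M)
    obs_b <- mismatch_from_d(d)
    fb <- suppressWarnings(fit_expansion(obs_b))
    fb$ssd
  }, numeric(1))
  ## Monte-Carlo p with the observed dataset included in the reference set
  fit$p_ssd <- (1 + sum(sims >= fit$ssd)) / (n_boot + 1)
  fit$n_boot <- as.integer(n_boot)
  fit
}

#' Mismatch analysis of one group of sequences
#'
#' Observed distribution, sudden-expansion fit, and (optionally) the SSD
#' bootstrap p-value.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param n_boot Bootstrap replicates (0 skips the test).
#' @param seed Integer seed.
#' @return A `mismatch_fit` with the observed distribution in
#'   `freq_obs` and `mean_mismatch` attached.
#' @export
mismatch_analysis <- function(seqs, n_boot = 1000, seed = 1) {
  obs <- observed_mismatch(seqs)
  fit <- suppressWarnings(fit_expansion(obs))
  fit$mean_mismatch <- obs$mean
  if (n_boot >= 100) fit <- ssd_test(length(seqs), fit, n_boot, seed)
  fit
}
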