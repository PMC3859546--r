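## Neutrality tests: Tajima's D and Fu's Fs, with p-values obtained by
## coalescent simulation (the approach of the standard population-genetics
## packages), seed-controlled.

#' Tajima (1989) normalising constants
#' @param n Sample size.
#' @return Named list: a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

## D from summary statistics (S = segregating sites, theta_pi = mean
## pairwise differences, absolute).
tajima_d_stat <- function(n, S, theta_pi) {
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  (theta_pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

## Segregating sites under pairwise deletion: a site segregates when it
## shows >= 2 distinct non-missing bases.
count_segregating <- function(mat) {
  sum(apply(mat, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2
  }))
}

#' Tajima's D test
#'
#' `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the constants of
#' Tajima (1989).  The two-tailed p-value is the fraction of constant-size
#' coalescent replicates (theta set to the Watterson estimate `S/a1`,
#' conditioned on `n`) with `|D_sim| >= |D_obs|`.
#'
#' @param seqs Named character vector of aligned sequences (n >= 4).
#' @param n_reps Coalescent replicates for the p-value (default 10000).
#' @param seed Integer seed for the replicates.
#' @param p_value Compute the simulation p-value (set `FALSE` to skip).
#' @return Object of class `neutrality_result`: list with
#'   `statistic_name`, `value` (NA when S = 0), `p_value`, `n`, `S`,
#'   `theta_pi`.
#' @export
tajimas_d <- function(seqs, n_reps = 10000, seed = 1, p_value = TRUE) {
  if (length(seqs) < 4) stop("Tajima's D needs n >= 4")
  mat <- seq_matrix(seqs)
  n <- nrow(mat)
  S <- count_segregating(mat)
  pd <- pairwise_diffs(mat)
  theta_pi <- sum(pd$d[upper.tri(pd$d)]) / choose(n, 2)
  D <- tajima_d_stat(n, S, theta_pi)
  p <- NA_real_
  if (!is.na(D) && p_value && n_reps > 0) {
    k <- tajima_constants(n)
    theta_w <- S / k$a1
    old <- .int_seed(seed)
    on.exit(.restore_seed(old))
    sims <- vapply(seq_len(n_reps), function(i) {
      M <- sim_coal_M(n, theta_w)
      tajima_d_stat(n, nrow(M), M_theta_pi(M))
    }, numeric(1))
    sims <- sims[!is.na(sims)]
    p <- (1 + sum(abs(sims) >= abs(D))) / (length(sims) + 1)
  }
  structure(list(statistic_name = "TajimaD", value = D, p_value = p,
                 n = n, S = S, theta_pi = theta_pi),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(x$statistic_name, "=",
      if (is.na(x$value)) "undefined" else format(x$value, digits = 4),
      if (!is.na(x$p_value)) paste0("(p = ", format(x$p_value, digits = 3), ")")
      else "", "\n  n =", x$n, ", S =", x$S,
      ", mean pairwise differences =", format(x$theta_pi, digits = 4), "\n")
  invisible(x)
}

## Log unsigned Stirling numbers of the first kind, row n: returns a
## vector l[k] = log |s(n, k)| for k = 1..n.  Rows are built by the
## recurrence |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)| in log space, cached.
ln_stirling1 <- function(n) {
  stopifnot(n >= 1)
  cache <- get0(".stirling_rows", envir = .pkg_cache)
  if (is.null(cache)) cache <- list(`1` = 0)
  have <- length(cache)
  if (have >= n) return(cache[[n]])
  row <- cache[[have]]
  for (m in have:(n - 1)) {
    ## row for m -> row for m+1
    new <- numeric(m + 1)
    new[1] <- log(m) + row[1]                        # k = 1
    if (m >= 2)
      for (k in 2:m)
        new[k] <- logsumexp2(log(m) + row[k], row[k - 1])
    new[m + 1] <- row[m]                             # k = m+1 (leading 1)
    cache[[as.character(m + 1)]] <- new
    row <- new
  }
  assign(".stirling_rows", cache, envir = .pkg_cache)
  row
}

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Ewens tail probability and Fu's Fs core
#'
#' `S' = P(K >= k_obs | theta, n)` under the Ewens sampling formula,
#' `P(K = k) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1))`,
#' evaluated in log space with unsigned Stirling numbers of the first
#' kind; `Fs = ln(S' / (1 - S'))`.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (Fu's choice: mean pairwise
#'   differences).
#' @param k_obs Observed number of distinct haplotypes.
#' @return List with `s_prime` and `fs` (`fs` is NA at the `k_obs = 1`
#'   boundary where S' = 1).
#' @export
fs_core <- function(n, theta, k_obs) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (theta <= 0) return(list(s_prime = NA_real_, fs = NA_real_))
  lrow <- ln_stirling1(n)
  denom <- sum(log(theta + 0:(n - 1)))
  lp <- lrow + (1:n) * log(theta) - denom          # log P(K = k)
  ltail <- lse(lp[k_obs:n])
  lall <- lse(lp)                                   # ~0; guards rounding
  ls <- ltail - lall
  if (k_obs == 1) return(list(s_prime = 1, fs = NA_real_))
  ## fs = log(S') - log(1 - S'), stable in both tails
  l1m <- if (k_obs > 1) lse(lp[1:(k_obs - 1)]) - lall else -Inf
  list(s_prime = exp(ls), fs = ls - l1m)
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs test
#'
#' With `theta` estimated by the mean number of pairwise differences and
#' `k_obs` the number of distinct haplotypes (same collapsing rules as
#' [collapse_haplotypes()]), `Fs = ln(S'/(1-S'))` where
#' `S' = P(K >= k_obs)` under the Ewens sampling formula.  The p-value is
#' the fraction of constant-size coalescent replicates (theta fixed at the
#' observed estimate) with simulated `Fs <= Fs_obs`.
#'
#' @inheritParams tajimas_d
#' @return A `neutrality_result` (value is NA when `theta_pi = 0`).
#' @export
fus_fs <- function(seqs, n_reps = 10000, seed = 1, p_value = TRUE) {
  if (length(seqs) < 2) stop("Fu's Fs needs n >= 2")
  mat <- seq_matrix(seqs)
  n <- nrow(mat)
  pd <- pairwise_diffs(mat)
  theta_pi <- sum(pd$d[upper.tri(pd$d)]) / choose(n, 2)
  S <- count_segregating(mat)
  k_obs <- length(collapse_haplotypes(seqs)$counts)
  core <- if (theta_pi > 0) fs_core(n, theta_pi, k_obs)
  else list(s_prime = NA_real_, fs = NA_real_)
  p <- NA_real_
  if (!is.na(core$fs) && p_value && n_reps > 0) {
    old <- .int_seed(seed)
    on.exit(.restore_seed(old))
    sims <- vapply(seq_len(n_reps), function(i) {
      M <- sim_coal_M(n, theta_pi)
      tp <- M_theta_pi(M)
      if (tp <= 0) return(NA_real_)
      fs_core(n, tp, M_n_haplotypes(M))$fs
    }, numeric(1))
    sims <- sims[!is.na(sims)]
    p <- (1 + sum(sims <= core$fs)) / (length(sims) + 1)
  }
  structure(list(statistic_name = "FuFs", value = core$fs, p_value = p,
                 n = n, S = S, theta_pi = theta_pi, k = k_obs,
                 s_prime = core$s_prime),
            class = "neutrality_result")
}

#' Neutrality report for grouped sequences
#'
#' @param seqs Named character vector of aligned sequences.
#' @param groups Group labels parallel to `seqs`.
#' @param n_reps Coalescent replicates per test.
#' @param seed Master seed (stage-deterministic per group).
#' @return data.frame: group, n, S, theta_pi, D, D_p, Fs, Fs_p.
#' @export
neutrality_report <- function(seqs, groups, n_reps = 1000, seed = 1) {
  rows <- lapply(unique(groups), function(g) {
    sub <- seqs[groups == g]
    if (length(sub) < 4)
      return(data.frame(group = g, n = length(sub), S = NA, theta_pi = NA,
                        D = NA, D_p = NA, Fs = NA, Fs_p = NA))
    d <- tajimas_d(sub, n_reps = n_reps, seed = seed)
    f <- fus_fs(sub, n_reps = n_reps, seed = seed + 1)
    data.frame(group = g, n = d$n, S = d$S, theta_pi = d$theta_pi,
               D = d$value, D_p = d$p_value, Fs = f$value, Fs_p = f$p_value)
  })
  do.call(rbind, rows)
}
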