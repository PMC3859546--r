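## Multivariate spatial autocorrelation of haplogroup composition
## (Smouse & Peakall 1999): a squared genetic distance matrix is
## double-centred into a covariance matrix C, and for each geographic
## distance class h the autocorrelation coefficient is
##   r(h) = sum_{pairs (i,j) in h} c_ij / sum_{pairs (i,j) in h} (c_ii + c_jj)/2 .
## Significance: a permutation belt (individuals shuffled over locations)
## and per-class bootstrap CIs (pairs resampled within class).

#' Binary haploid squared-distance matrix from haplogroup labels
#'
#' `d^2(i,j) = 0` for the same haplogroup, 1 otherwise.  Individuals with
#' label `"unassigned"` or `NA` are excluded with a warning; the retained
#' indices are stored in attribute `kept`.
#'
#' @param labels Character vector of haplogroup labels.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
genetic_distance_matrix <- function(labels) {
  keep <- !is.na(labels) & labels != "unassigned"
  if (sum(!keep) > 0)
    warning(sum(!keep), " unassigned individual(s) excluded")
  lab <- labels[keep]
  if (length(lab) < 2) stop("need >= 2 labelled individuals")
  d2 <- outer(lab, lab, "!=") * 1
  diag(d2) <- 0
  attr(d2, "kept") <- which(keep)
  d2
}

double_center <- function(d2) {
  n <- nrow(d2)
  rm_ <- rowMeans(d2); gm <- mean(d2)
  -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
}

#' Spatial autocorrelogram of genetic similarity
#'
#' @param d2 Squared genetic distance matrix ([genetic_distance_matrix()]).
#' @param coords Two-column matrix of coordinates for the same individuals:
#'   `lon`/`lat` in degrees for `metric = "great_circle"`, or planar
#'   x/y in km for `metric = "planar"`.  Individuals of one flock may share
#'   coordinates (their pairs fall in the first class).
#' @param class_width_km Distance class width in km (default 150).
#' @param n_classes Number of classes (default: enough to cover the data).
#' @param metric `"great_circle"` (haversine) or `"planar"`.
#' @param n_perm Label permutations for the null belt (default 999).
#' @param n_boot Bootstrap replicates for per-class CIs (default 1000).
#' @param seed Integer seed.
#' @return Object of class `autocorrelogram`: data.frame with one row per
#'   class: `class`, `d_max_km`, `n_pairs`, `r`, `belt_lo`, `belt_hi`,
#'   `ci_lo`, `ci_hi`, `p` (one-tailed upper permutation p-value).
#' @export
autocorrelogram <- function(d2, coords, class_width_km = 150,
                            n_classes = NULL,
                            metric = c("great_circle", "planar"),
                            n_perm = 999, n_boot = 1000, seed = 1) {
  metric <- match.arg(metric)
  n <- nrow(d2)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n, ncol(coords) == 2)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  C <- double_center(d2)
  if (sum(abs(C)) < 1e-12) stop("zero total genetic variance")
  geo <- if (metric == "great_circle") {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      m[i, (i + 1):n] <- geosphere::distHaversine(
        coords[i, , drop = FALSE], coords[(i + 1):n, , drop = FALSE]) / 1000
    }
    m + t(m)
  } else {
    as.matrix(stats::dist(coords))
  }
  if (is.null(n_classes))
    n_classes <- max(1L, ceiling(max(geo) / class_width_km + 1e-9))
  ut <- which(upper.tri(geo), arr.ind = TRUE)
  ## half-open bins [k*w, (k+1)*w); boundary pairs go up
  cls <- pmin(floor(geo[ut] / class_width_km) + 1L, n_classes + 1L)
  cls[cls > n_classes] <- NA_integer_  # beyond the correlogram range
  diag_c <- diag(C)

  r_of <- function(perm = seq_len(n), idx_by_class) {
    vapply(idx_by_class, function(idx) {
      if (length(idx) == 0) return(NA_real_)
      i <- perm[ut[idx, 1]]; j <- perm[ut[idx, 2]]
      num <- sum(C[cbind(i, j)])
      den <- sum((diag_c[i] + diag_c[j]) / 2)
      if (den == 0) return(NA_real_)
      num / den
    }, numeric(1))
  }
  idx_by_class <- lapply(seq_len(n_classes), function(k) which(!is.na(cls) & cls == k))
  r_obs <- r_of(idx_by_class = idx_by_class)

  old <- .int_seed(seed)
  on.exit(.restore_seed(old))
  perm_r <- matrix(NA_real_, n_perm, n_classes)
  for (p in seq_len(n_perm))
    perm_r[p, ] <- r_of(sample.int(n), idx_by_class)
  belt_lo <- apply(perm_r, 2, quantile, 0.025, na.rm = TRUE)
  belt_hi <- apply(perm_r, 2, quantile, 0.975, na.rm = TRUE)
  pvals <- vapply(seq_len(n_classes), function(k) {
    if (is.na(r_obs[k])) return(NA_real_)
    (1 + sum(perm_r[, k] >= r_obs[k], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))

  ci_lo <- ci_hi <- rep(NA_real_, n_classes)
  for (k in seq_len(n_classes)) {
    idx <- idx_by_class[[k]]
    if (length(idx) < 2) next
    boot_r <- vapply(seq_len(n_boot), function(b) {
      take <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      i <- ut[take, 1]; j <- ut[take, 2]
      den <- sum((diag_c[i] + diag_c[j]) / 2)
      if (den == 0) return(NA_real_)
      sum(C[cbind(i, j)]) / den
    }, numeric(1))
    ci_lo[k] <- quantile(boot_r, 0.025, na.rm = TRUE)
    ci_hi[k] <- quantile(boot_r, 0.975, na.rm = TRUE)
  }

  out <- data.frame(
    class = seq_len(n_classes),
    d_max_km = class_width_km * seq_len(n_classes),
    n_pairs = vapply(idx_by_class, length, integer(1)),
    r = r_obs, belt_lo = belt_lo, belt_hi = belt_hi,
    ci_lo = ci_lo, ci_hi = ci_hi, p = pvals)
  class(out) <- c("autocorrelogram", "data.frame")
  attr(out, "n_perm") <- n_perm
  attr(out, "n_boot") <- n_boot
  out
}

#' Plot an autocorrelogram
#'
#' r per distance class with the permutation belt (dashed) and bootstrap
#' CIs (vertical bars).
#'
#' @param x An `autocorrelogram`.
#' @param ... Passed to `plot()`.
#' @export
plot.autocorrelogram <- function(x, ...) {
  graphics::plot(x$d_max_km, x$r, type = "b", pch = 16,
                 xlab = "distance class upper bound (km)",
                 ylab = "autocorrelation r",
                 ylim = range(c(x$r, x$belt_lo, x$belt_hi, x$ci_lo, x$ci_hi),
                              na.rm = TRUE), ...)
  graphics::lines(x$d_max_km, x$belt_lo, lty = 2)
  graphics::lines(x$d_max_km, x$belt_hi, lty = 2)
  graphics::segments(x$d_max_km, x$ci_lo, x$d_max_km, x$ci_hi)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
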