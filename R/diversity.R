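## Haplotype collapsing and diversity statistics: haplotype diversity (h),
## nucleotide diversity (pi) and between-group divergence (Dxy), with the
## standard-error expressions of Nei (1987).  Missing data (N, -, ?) are
## deleted pairwise throughout, the convention of DnaSP.

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at all mutually non-missing sites are merged
#' (pairwise-deletion rule).  Because pairwise compatibility is not
#' transitive in the presence of missing data, merging is greedy in input
#' order: each sequence joins the first existing haplotype it is compatible
#' with, and fills that haplotype's missing sites where it can -- a
#' deterministic rule for a fundamentally ambiguous situation.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Object of class `haplotype_table`: list with `haplotypes`
#'   (representative strings), `counts`, `members` (list of ids), `n`, `L`.
#' @export
collapse_haplotypes <- function(seqs) {
  mat <- seq_matrix(seqs)
  n <- nrow(mat)
  reps <- list(); members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      ok <- !is.na(reps[[k]]) & !is.na(mat[i, ])
      if (all(reps[[k]][ok] == mat[i, ok])) {
        fill <- is.na(reps[[k]]) & !is.na(mat[i, ])
        reps[[k]][fill] <- mat[i, fill]
        members[[k]] <- c(members[[k]], rownames(mat)[i] %||% i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1]] <- mat[i, ]
      members[[length(members) + 1]] <- rownames(mat)[i] %||% i
    }
  }
  structure(list(
    haplotypes = vapply(reps, function(r)
      paste(ifelse(is.na(r), "N", r), collapse = ""), character(1)),
    counts = vapply(members, length, integer(1)),
    members = members, n = n, L = ncol(mat)),
    class = "haplotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype table:", length(x$counts), "haplotypes /", x$n,
      "sequences; counts:", paste(sort(x$counts, decreasing = TRUE),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype (gene) diversity with standard deviation
#'
#' `h = n (1 - sum p_i^2) / (n - 1)`; the sampling variance is Nei (1987)
#' eq. 8.12:
#' `V(h) = 2/(n(n-1)) * { 2(n-2) [sum p^3 - (sum p^2)^2] + sum p^2 - (sum p^2)^2 }`.
#'
#' @param tab A `haplotype_table`, or an integer vector of haplotype counts.
#' @return List with `h` and `sd`.
#' @export
haplotype_diversity <- function(tab) {
  counts <- if (inherits(tab, "haplotype_table")) tab$counts else tab
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2")
  p <- counts / n
  sp2 <- sum(p^2); sp3 <- sum(p^3)
  h <- n * (1 - sp2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  list(h = h, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity (pi) per site with standard deviation
#'
#' `pi = sum_{i<j} d_ij / C(n,2) / Lbar` with pairwise deletion (`Lbar` =
#' mean number of mutually compared sites).  The standard deviation uses
#' Nei (1987) eq. 10.7:
#' `V(pi) = (n+1) pi / (3 (n-1) L) + 2 (n^2 + n + 3) pi^2 / (9 n (n-1))`.
#'
#' @param seqs Named character vector of aligned sequences (n >= 2).
#' @return List with `pi` (per site), `sd`, `theta_pi` (mean pairwise
#'   differences, absolute) and `Lbar`.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2) stop("nucleotide diversity needs n >= 2")
  mat <- seq_matrix(seqs)
  pd <- pairwise_diffs(mat)
  n <- nrow(mat)
  ut <- upper.tri(pd$d)
  theta_pi <- sum(pd$d[ut]) / choose(n, 2)
  Lbar <- mean(pd$L[ut])
  pi <- if (Lbar > 0) theta_pi / Lbar else 0
  v <- (n + 1) * pi / (3 * (n - 1) * Lbar) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, sd = sqrt(max(v, 0)), theta_pi = theta_pi, Lbar = Lbar)
}

#' Average pairwise divergence per site between two groups (Dxy)
#'
#' `Dxy = sum_{i in X, j in Y} d_ij / (n_x n_y) / Lbar` with pairwise
#' deletion.  Symmetric in its arguments.
#'
#' @param x,y Named character vectors of mutually aligned sequences.
#' @return Dxy (per site).
#' @export
dxy <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group in dxy")
  Lx <- unique(nchar(c(x, y)))
  if (length(Lx) != 1) stop("groups are not mutually aligned")
  mx <- seq_matrix(c(x, y))
  nx <- length(x); ny <- length(y)
  tot <- 0; totL <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    a <- mx[i, ]; b <- mx[nx + j, ]
    ok <- !is.na(a) & !is.na(b)
    tot <- tot + sum(a[ok] != b[ok])
    totL <- totL + sum(ok)
  }
  if (totL == 0) return(0)
  (tot / (nx * ny)) / (totL / (nx * ny))
}

#' Mask the tandem-repeat region of anchored sequences
#'
#' Replaces the repeat array (located with [parse_repeats()]) by `N`s so
#' that diversity statistics and tree construction exclude it; sequence
#' length is preserved so alignments stay intact.  Sequences in which no
#' repeat array can be located are returned unchanged.
#'
#' @param seqs Named character vector.
#' @param maps List of `coord_map`s parallel to `seqs` (or `NULL` when all
#'   sequences share `start_col`).
#' @param ... Passed to [parse_repeats()].
#' @return Named character vector with repeat regions masked.
#' @export
mask_repeat_region <- function(seqs, maps = NULL, ...) {
  out <- seqs
  for (i in seq_along(seqs)) {
    prof <- tryCatch(
      parse_repeats(seqs[[i]], map = if (is.null(maps)) NULL else maps[[i]],
                    ...),
      error = function(e) NULL)
    if (is.null(prof)) next
    from <- prof$start_col
    to <- from + sum(prof$unit_lengths) - 1L
    substr(out[[i]], from, to) <- paste(rep("N", to - from + 1L),
                                        collapse = "")
  }
  out
}

#' Per-group diversity report
#'
#' Convenience wrapper producing one row per group: n, number of
#' haplotypes, h +/- SD, pi +/- SD.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param groups Vector of group labels parallel to `seqs`.
#' @return data.frame.
#' @export
diversity_report <- function(seqs, groups) {
  stopifnot(length(groups) == length(seqs))
  rows <- lapply(unique(groups), function(g) {
    sub <- seqs[groups == g]
    if (length(sub) < 2)
      return(data.frame(group = g, n = length(sub), k = NA_integer_,
                        h = NA_real_, h_sd = NA_real_,
                        pi = NA_real_, pi_sd = NA_real_))
    tab <- collapse_haplotypes(sub)
    hd <- haplotype_diversity(tab)
    nd <- nucleotide_diversity(sub)
    data.frame(group = g, n = length(sub), k = length(tab$counts),
               h = hd$h, h_sd = hd$sd, pi = nd$pi, pi_sd = nd$sd)
  })
  do.call(rbind, rows)
}
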