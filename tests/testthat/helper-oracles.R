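## Independent oracles.  Each re-implements a quantity from first
## principles, in code deliberately separate from the package's own path.

## Semi-global Needleman-Wunsch in pure R (match 1 / mismatch -1 / gap -2,
## free end gaps in the reference, N neutral), returning the reference
## position aligned to each seq column.
nw_oracle <- function(seq, ref) {
  s <- strsplit(seq, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(s); m <- length(r)
  S <- matrix(0, n + 1, m + 1); Tb <- matrix(0L, n + 1, m + 1)
  S[1, ] <- 0; S[, 1] <- (0:n) * -2
  Tb[1, ] <- 2L; Tb[, 1] <- 1L; Tb[1, 1] <- 0L
  for (i in 1:n) for (j in 1:m) {
    sub <- if (s[i] == "N" || r[j] == "N") 0 else if (s[i] == r[j]) 1 else -1
    cand <- c(S[i, j] + sub, S[i, j + 1] - 2, S[i + 1, j] - 2)
    w <- which.max(cand)
    S[i + 1, j + 1] <- cand[w]; Tb[i + 1, j + 1] <- w - 1L
  }
  out <- rep(NA_integer_, n)
  i <- n; j <- which.max(S[n + 1, ]) - 1L
  while (i > 0) {
    tb <- Tb[i + 1, j + 1]
    if (i > 0 && j > 0 && tb == 0) { out[i] <- as.integer(j); i <- i - 1; j <- j - 1 }
    else if (i > 0 && (j == 0 || tb == 1)) i <- i - 1
    else j <- j - 1
  }
  out
}

## Brute-force Tajima's D straight from the 1989 definitions.
tajima_oracle <- function(seqs) {
  ch <- lapply(seqs, function(x) strsplit(x, "")[[1]])
  n <- length(ch); L <- length(ch[[1]])
  miss <- function(b) b %in% c("N", "-", "?")
  S <- 0
  for (p in 1:L) {
    col <- vapply(ch, `[`, character(1), p)
    col <- col[!miss(col)]
    if (length(unique(col)) >= 2) S <- S + 1
  }
  tot <- 0; npair <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- ch[[i]]; b <- ch[[j]]
    ok <- !miss(a) & !miss(b)
    tot <- tot + sum(a[ok] != b[ok]); npair <- npair + 1
  }
  k_hat <- tot / npair
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(NA_real_)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Ewens sampling formula by direct polynomial expansion of
## theta (theta+1) ... (theta+n-1): coefficient of theta^k is |s(n,k)|.
stirling_oracle <- function(n) {
  coefs <- 1                      # polynomial "1"
  for (i in 0:(n - 1)) {
    ## multiply by (x + i): new_k = old_{k-1} + i * old_k
    coefs <- c(0, coefs) + i * c(coefs, 0)
  }
  coefs[-1]                       # drop theta^0 term (zero), k = 1..n
}

ewens_tail_oracle <- function(n, theta, k_obs) {
  s <- stirling_oracle(n)
  pk <- s * theta^(1:n) / prod(theta + 0:(n - 1))
  sum(pk[k_obs:n]) / sum(pk)
}

## TN93 closed form, independently transcribed, operating on raw strings.
tn93_oracle <- function(a, b, freqs) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]; n <- length(av)
  is_ts1 <- (av == "A" & bv == "G") | (av == "G" & bv == "A")
  is_ts2 <- (av == "C" & bv == "T") | (av == "T" & bv == "C")
  is_tv <- av != bv & !is_ts1 & !is_ts2
  P1 <- mean(is_ts1); P2 <- mean(is_ts2); Q <- mean(is_tv)
  pA <- freqs[["A"]]; pC <- freqs[["C"]]; pG <- freqs[["G"]]; pT <- freqs[["T"]]
  gR <- pA + pG; gY <- pC + pT
  a1 <- 1 - gR * P1 / (2 * pA * pG) - Q / (2 * gR)
  a2 <- 1 - gY * P2 / (2 * pC * pT) - Q / (2 * gY)
  bb <- 1 - Q / (2 * gR * gY)
  -2 * pA * pG / gR * log(a1) - 2 * pC * pT / gY * log(a2) -
    2 * (gR * gY - pA * pG * gY / gR - pC * pT * gR / gY) * log(bb)
}

## Exhaustive Steiner search: minimum MST total cost over the observed
## haplotypes plus at most one internal node drawn from all state
## combinations seen per position.
steiner_oracle <- function(haps, weights) {
  mat <- do.call(rbind, strsplit(haps, ""))
  wham <- function(x, y) sum(weights[x != y])
  mst_total <- function(m) {
    n <- nrow(m)
    D <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- wham(m[i, ], m[j, ])
    in_tree <- c(TRUE, rep(FALSE, n - 1)); tot <- 0
    best <- D[1, ]
    for (k in 1:(n - 1)) {
      v <- which(!in_tree)[which.min(best[!in_tree])]
      tot <- tot + best[v]; in_tree[v] <- TRUE
      best <- pmin(best, D[v, ])
    }
    tot
  }
  cand <- expand.grid(lapply(seq_len(ncol(mat)), function(p)
    unique(mat[, p])), stringsAsFactors = FALSE)
  best <- mst_total(mat)
  for (r in seq_len(nrow(cand))) {
    node <- as.character(unlist(cand[r, ]))
    if (any(apply(mat, 1, function(x) all(x == node)))) next
    best <- min(best, mst_total(rbind(mat, node)))
  }
  best
}

## Total connection cost (sum of MSN-required links) of a haplo_network's
## spanning structure = its MST total over the final node set.
network_mst_total <- function(net) {
  mat <- do.call(rbind, strsplit(net$nodes$sequence, ""))
  w <- net$weights
  n <- nrow(mat)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(w[mat[i, ] != mat[j, ]])
  ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                            weighted = TRUE)
  sum(igraph::E(igraph::mst(ig))$weight)
}

## Random aligned sequences (A/C/G/T) for property loops.
random_seqs <- function(n, L) {
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), sprintf("r%02d", seq_len(n)))
}
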