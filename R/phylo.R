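## Tamura-Nei (1993) distances, neighbor-joining with bootstrap support,
## and median-joining haplotype networks.
##
## The TN93 distance is computed from the two transition proportions
## (P1: A<->G, P2: C<->T), the transversion proportion Q, and empirical
## base frequencies pooled over the whole collection; no rate
## heterogeneity.  Pairs where a logarithm argument becomes non-positive
## (saturation) get an infinite distance and a flag.

tn93_pair <- function(a, b, freqs) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 1) stop("no overlapping non-missing sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  pur <- c("A", "G"); pyr <- c("C", "T")
  P1 <- sum(diff & a %in% pur & b %in% pur) / n
  P2 <- sum(diff & a %in% pyr & b %in% pyr) / n
  Q <- sum(diff & ((a %in% pur) != (b %in% pur))) / n
  gA <- freqs["A"]; gC <- freqs["C"]; gG <- freqs["G"]; gT <- freqs["T"]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    return(structure(Inf, saturated = TRUE))
  unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

#' Empirical base frequencies of a sequence collection
#' @param seqs Named character vector.
#' @return Named numeric vector over A, C, G, T (sums to 1).
#' @export
base_frequencies <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs), ""), use.names = FALSE)
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  as.numeric(tab) / sum(tab) -> f
  setNames(f, c("A", "C", "G", "T"))
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' @param a,b Aligned sequence strings.
#' @param freqs Base frequencies (default: empirical from the pair; for a
#'   collection use pooled frequencies via [tn93_matrix()]).
#' @return The TN93 distance (substitutions/site); `Inf` with attribute
#'   `saturated = TRUE` when the distance is undefined (saturation).
#' @export
tn93_distance <- function(a, b, freqs = NULL) {
  stopifnot(nchar(a) == nchar(b))
  if (is.null(freqs)) freqs <- base_frequencies(c(a, b))
  m <- seq_matrix(c(x = a, y = b))
  tn93_pair(m[1, ], m[2, ], freqs)
}

#' TN93 distance matrix with pooled base frequencies
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric distance matrix; saturated pairs are `Inf` and
#'   reported in attribute `saturated` (pair index matrix).
#' @export
tn93_matrix <- function(seqs) {
  mat <- seq_matrix(seqs)
  freqs <- base_frequencies(seqs)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tn93_pair(mat[i, ], mat[j, ], freqs)
    if (is.infinite(d)) sat <- rbind(sat, c(i, j))
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via the standard implementation in ape) on a
#' distance matrix; negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param D Symmetric distance matrix (>= 3 taxa, finite).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor-joining needs >= 3 taxa")
  if (!all(is.finite(D))) stop("non-finite distances (saturation?)")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the TN93 + NJ
#' tree for each replicate, and reports for every internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `tree` (original `phylo`, node labels set to the
#'   support percentages) and `support` (numeric vector, one per internal
#'   node; `NA` for the root node of the unrooted representation).
#' @export
bootstrap_support <- function(seqs, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  mat <- seq_matrix(seqs)
  if (ncol(mat) < 2) stop("alignment too short to resample")
  orig <- nj_tree(tn93_matrix(seqs))
  old <- .int_seed(seed)
  on.exit(.restore_seed(old))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    sub <- apply(mat[, cols, drop = FALSE], 1, function(r)
      paste(ifelse(is.na(r), "N", r), collapse = ""))
    boots[[b]] <- suppressWarnings(nj_tree(tn93_matrix(sub)))
  }
  counts <- ape::prop.clades(orig, boots, rooted = FALSE)
  support <- 100 * counts / n_reps
  orig$node.label <- ifelse(is.na(support), "",
                            formatC(support, format = "f", digits = 0))
  list(tree = orig, support = support)
}

## Median-joining networks ----------------------------------------------------

whamming <- function(a, b, w) sum(w[a != b])

wham_matrix <- function(mat, w) {
  n <- nrow(mat)
  D <- matrix(0, n, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- whamming(mat[i, ], mat[j, ], w)
  D
}

## Prim MST; returns edge list (i, j, w) and total weight.  Deterministic:
## smallest index wins ties.
prim_mst <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- NULL
  best_w <- D[1, ]; best_from <- rep(1L, n)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges <- rbind(edges, c(best_from[v], v, best_w[v]))
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_w
    best_from[upd] <- v
    best_w[upd] <- D[v, upd]
  }
  list(edges = edges, total = sum(edges[, 3]))
}

## Epsilon-relaxed minimum spanning network: edge (u,v) is kept iff
## d(u,v) <= minimax(u,v) + epsilon, where minimax(u,v) is the largest
## edge on the MST path between u and v (the single-linkage merge level).
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  mst <- prim_mst(D)
  adj <- vector("list", n)
  for (e in seq_len(nrow(mst$edges))) {
    i <- mst$edges[e, 1]; j <- mst$edges[e, 2]; w <- mst$edges[e, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  minimax <- matrix(0, n, n)
  for (s in seq_len(n)) {          # DFS from s carrying the running max
    stack <- list(c(s, 0))
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1]; mx <- top[2]
      if (!is.null(adj[[v]])) for (e in seq_len(nrow(adj[[v]]))) {
        u <- adj[[v]][e, 1]
        if (!seen[u]) {
          seen[u] <- TRUE
          m2 <- max(mx, adj[[v]][e, 2])
          minimax[s, u] <- m2
          stack[[length(stack) + 1]] <- c(u, m2)
        }
      }
    }
  }
  keep <- which(upper.tri(D) & D <= minimax + epsilon + 1e-12, arr.ind = TRUE)
  cbind(i = keep[, 1], j = keep[, 2], w = D[keep])
}

#' Median-joining haplotype network
#'
#' Bandelt-Forster-Röhl construction: an epsilon-relaxed minimum spanning
#' network over weighted Hamming distances, iteratively augmented with
#' quasi-median (Steiner) vectors -- the positionwise majority state of
#' linked node triplets -- whenever adding one strictly reduces the total
#' connection cost, then pruned of median vectors with network degree < 3.
#'
#' @param haplotypes Named character vector of *distinct* aligned
#'   haplotype sequences.
#' @param counts Optional integer vector of observed counts (default 1).
#' @param weights Per-position weights (default uniform 10, the convention
#'   of the standard network software).
#' @param epsilon Relaxation parameter (default 0).
#' @param max_medians Safety cap on added median vectors.
#' @return Object of class `haplo_network`: list with `nodes` (data.frame:
#'   `id`, `sequence`, `count`, `type` observed/median) and `edges`
#'   (data.frame: `from`, `to`, `weight`, `n_mut`, `positions`).
#' @export
mj_network <- function(haplotypes, counts = NULL, weights = NULL,
                       epsilon = 0, max_medians = 200) {
  if (length(haplotypes) < 2) stop("need >= 2 haplotypes")
  if (anyDuplicated(haplotypes))
    stop("duplicate haplotype sequences; collapse them first")
  if (is.null(names(haplotypes)))
    names(haplotypes) <- sprintf("H%02d", seq_along(haplotypes))
  if (is.null(counts)) counts <- rep(1L, length(haplotypes))
  mat0 <- seq_matrix(haplotypes)
  ## complete deletion: drop positions with any missing state so the
  ## weighted Hamming distance stays a metric
  keep_cols <- colSums(is.na(mat0)) == 0
  mat <- mat0[, keep_cols, drop = FALSE]
  L <- ncol(mat)
  if (is.null(weights)) weights <- rep(10, L) else {
    stopifnot(all(weights > 0))
    weights <- weights[keep_cols]
  }
  nodes <- mat
  node_type <- rep("observed", nrow(mat))
  node_id <- names(haplotypes)

  seq_key <- function(r) paste(r, collapse = "")
  known <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nodes))) assign(seq_key(nodes[i, ]), TRUE, known)

  n_med <- 0L
  repeat {
    D <- wham_matrix(nodes, weights)
    mst_now <- prim_mst(D)
    ed <- msn_edges(D, epsilon)
    ## candidate medians from linked triplets u - v - w
    adj <- vector("list", nrow(nodes))
    for (e in seq_len(nrow(ed))) {
      adj[[ed[e, 1]]] <- c(adj[[ed[e, 1]]], ed[e, 2])
      adj[[ed[e, 2]]] <- c(adj[[ed[e, 2]]], ed[e, 1])
    }
    best_gain <- 0; best_m <- NULL
    for (v in seq_len(nrow(nodes))) {
      nb <- adj[[v]]
      if (length(nb) < 2) next
      prs <- combn(sort(nb), 2)
      for (cc in seq_len(ncol(prs))) {
        trip <- nodes[c(prs[1, cc], v, prs[2, cc]), , drop = FALSE]
        med <- apply(trip, 2, function(col) {
          tb <- table(col)
          if (max(tb) >= 2) names(tb)[which.max(tb)] else col[2]
        })
        key <- seq_key(med)
        if (!is.null(get0(key, envir = known))) next
        D2 <- rbind(cbind(D, 0), 0)
        dv <- apply(nodes, 1, whamming, b = med, w = weights)
        D2[nrow(D2), seq_along(dv)] <- dv
        D2[seq_along(dv), ncol(D2)] <- dv
        gain <- mst_now$total - prim_mst(D2)$total
        if (gain > best_gain + 1e-9) {
          best_gain <- gain; best_m <- med
        }
      }
    }
    if (is.null(best_m) || n_med >= max_medians) break
    nodes <- rbind(nodes, best_m)
    assign(seq_key(best_m), TRUE, known)
    node_type <- c(node_type, "median")
    n_med <- n_med + 1L
    node_id <- c(node_id, sprintf("mv%02d", n_med))
  }

  ## prune median vectors with degree < 3
  repeat {
    D <- wham_matrix(nodes, weights)
    ed <- msn_edges(D, epsilon)
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(nodes))
    drop <- which(node_type == "median" & deg < 3)
    if (length(drop) == 0) break
    nodes <- nodes[-drop, , drop = FALSE]
    node_type <- node_type[-drop]
    node_id <- node_id[-drop]
  }

  D <- wham_matrix(nodes, weights)
  ed <- msn_edges(D, epsilon)
  pos_orig <- which(keep_cols)
  edges <- data.frame(
    from = node_id[ed[, 1]], to = node_id[ed[, 2]], weight = ed[, 3],
    n_mut = vapply(seq_len(nrow(ed)), function(e)
      sum(nodes[ed[e, 1], ] != nodes[ed[e, 2], ]), integer(1)),
    positions = vapply(seq_len(nrow(ed)), function(e)
      paste(pos_orig[nodes[ed[e, 1], ] != nodes[ed[e, 2], ]],
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  node_df <- data.frame(
    id = node_id,
    sequence = apply(nodes, 1, paste, collapse = ""),
    count = c(counts, rep(0L, nrow(nodes) - length(counts))),
    type = node_type, stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = edges, epsilon = epsilon,
                 weights = weights),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("median-joining network:", sum(x$nodes$type == "observed"),
      "observed haplotypes,", sum(x$nodes$type == "median"),
      "median vectors,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Shortest path length between two nodes of a network (by edge weight)
#'
#' Dijkstra over the network's edge list; used for metric-consistency
#' checks (a path can never be shorter than the direct weighted Hamming
#' distance).
#'
#' @param net A `haplo_network`.
#' @param from,to Node ids.
#' @return Numeric path length (`Inf` if disconnected).
#' @export
network_path_length <- function(net, from, to) {
  ids <- net$nodes$id
  n <- length(ids)
  W <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(W) <- 0
  for (e in seq_len(nrow(net$edges)))
    W[net$edges$from[e], net$edges$to[e]] <-
      W[net$edges$to[e], net$edges$from[e]] <- net$edges$weight[e]
  dist <- rep(Inf, n); names(dist) <- ids
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    v <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[v])) break
    done[v] <- TRUE
    upd <- dist[v] + W[v, ] < dist
    dist[upd] <- dist[v] + W[v, upd]
  }
  unname(dist[to])
}
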