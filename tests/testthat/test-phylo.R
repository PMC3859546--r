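test_that("TN93 distance matches the closed form and the ape implementation", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)

  ## one A<->G transition in 20 bp, frequencies supplied
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGTACGTACGTACAT"   # pos 19 G -> A
  fr <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  expect_equal(tn93_distance(a, b, fr), tn93_oracle(a, b, fr),
               tolerance = 1e-10)

  ## pooled-frequency matrix agrees with ape::dist.dna on clean data
  seqs <- gen_coalescent(8, L = 500, theta0 = 4, seed = 8)
  D <- tn93_matrix(seqs)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(unname(seqs)), ""),
                                 identity)))
  Dape <- as.matrix(ape::dist.dna(bin, model = "TN93"))
  expect_equal(unname(D), unname(Dape), tolerance = 1e-9)

  ## saturation flags an infinite distance
  sat <- tn93_distance(strrep("A", 30), strrep("G", 30),
                       c(A = .25, C = .25, G = .25, T = .25))
  expect_true(is.infinite(sat))
  expect_true(isTRUE(attr(sat, "saturated")))
})

test_that("TN93 never undershoots the p-distance on unsaturated pairs", {
  set.seed(26)
  for (r in 1:20) {
    x <- random_seqs(2, 200)
    p <- mean(strsplit(x[[1]], "")[[1]] != strsplit(x[[2]], "")[[1]])
    d <- tn93_matrix(x)[1, 2]
    if (is.finite(d)) expect_gte(d, p * (1 - 1e-9))
  }
})

test_that("three-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  ## la = (dab + dac - dbc)/2 = 1, lb = 2, lc = 3
  tips <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(tips[c("a", "b", "c")], c(a = 1, b = 2, c = 3),
               tolerance = 1e-10)
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers additive distances exactly (4 taxa) and is deterministic on ties", {
  set.seed(12)
  true <- ape::rtree(4, rooted = FALSE)
  D <- ape::cophenetic.phylo(true)
  rec <- nj_tree(D)
  expect_equal(ape::dist.topo(true, rec), setNames(0, "PH85"),
               ignore_attr = TRUE)
  expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-10)

  tie <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(tie) <- 0
  expect_identical(ape::write.tree(suppressWarnings(nj_tree(tie))),
                   ape::write.tree(suppressWarnings(nj_tree(tie))))
})

test_that("NJ recovers random additive trees (50 seeds, 6-10 taxa)", {
  ok <- vapply(1:50, function(i) {
    set.seed(7000 + i)
    tr <- ape::rtree(sample(6:10, 1), rooted = FALSE)
    rec <- nj_tree(ape::cophenetic.phylo(tr))
    ape::dist.topo(tr, rec) == 0
  }, logical(1))
  expect_equal(sum(ok), 50)
})

test_that("bootstrap support saturates for a well-separated clade", {
  ## clade {x1, x2} separated by 10 fixed differences
  base <- strrep("ACGT", 15)
  clade <- paste0(strrep("T", 10), substr(base, 11, 60))
  seqs <- c(x1 = clade, x2 = clade, y1 = base, y2 = base,
            y3 = paste0(substr(base, 1, 59), "C"))
  bs <- suppressWarnings(bootstrap_support(seqs, n_reps = 200, seed = 3))
  expect_true(all(bs$support >= 0 & bs$support <= 100, na.rm = TRUE))
  expect_gte(max(bs$support, na.rm = TRUE), 99)
  bs2 <- suppressWarnings(bootstrap_support(seqs, n_reps = 200, seed = 3))
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(seqs, n_reps = 0), "n_reps")
})

test_that("NJ trees round-trip through Newick", {
  seqs <- gen_coalescent(6, L = 300, theta0 = 4, seed = 13)
  tr <- suppressWarnings(nj_tree(tn93_matrix(seqs)))
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(tr, back), setNames(0, "PH85"),
               ignore_attr = TRUE)
})

test_that("a 1-mutation pair yields a single edge", {
  net <- mj_network(c(h1 = "AAAA", h2 = "AAAT"), weights = rep(1, 4))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  expect_equal(net$edges$n_mut, 1)
  expect_error(mj_network(c(a = "AAAA", b = "AAAA")), "duplicate")
})

test_that("the 3-haplotype toy reproduces the exhaustively verified Steiner solution", {
  haps <- c(a = "AAA", b = "TTA", c = "ATT")   # 000 / 110 / 011
  w <- rep(1, 3)
  net <- mj_network(haps, weights = w)
  ## one median vector = positionwise majority (010 ~ "ATA"), degree 3
  med <- net$nodes[net$nodes$type == "median", ]
  expect_equal(nrow(med), 1)
  expect_equal(med$sequence, "ATA")
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  ## total connection cost equals the exhaustive Steiner optimum (3 < 4)
  expect_equal(network_mst_total(net), steiner_oracle(unname(haps), w))
  expect_equal(network_mst_total(net), 3)
})

test_that("the network always contains an MST of its node set (igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (r in 1:8) {
    haps <- unique(random_seqs(6, 12))
    if (length(haps) < 3) next
    net <- mj_network(haps, weights = rep(1, 12))
    mat <- do.call(rbind, strsplit(net$nodes$sequence, ""))
    n <- nrow(mat)
    D <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sum(mat[i, ] != mat[j, ])
    ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
    mst <- igraph::mst(ig)
    el <- igraph::as_edgelist(mst)
    mst_pairs <- paste(pmin(as.integer(el[, 1]), as.integer(el[, 2])),
                       pmax(as.integer(el[, 1]), as.integer(el[, 2])))
    net_pairs <- paste(pmin(match(net$edges$from, net$nodes$id),
                            match(net$edges$to, net$nodes$id)),
                       pmax(match(net$edges$from, net$nodes$id),
                            match(net$edges$to, net$nodes$id)))
    ## every edge of an independently computed MST lies in the network
    expect_true(all(mst_pairs %in% net_pairs))
    ## and the network is connected over all observed haplotypes
    expect_lte(network_mst_total(net), sum(igraph::E(mst)$weight))
  }
})

test_that("network path lengths respect the weighted Hamming metric", {
  set.seed(77)
  haps <- unique(random_seqs(5, 10))
  net <- mj_network(haps, weights = rep(1, 10))
  mat <- do.call(rbind, strsplit(haps, ""))
  obs_ids <- net$nodes$id[net$nodes$type == "observed"]
  for (i in 1:(length(haps) - 1)) for (j in (i + 1):length(haps)) {
    direct <- sum(mat[i, ] != mat[j, ])
    path <- network_path_length(net, obs_ids[i], obs_ids[j])
    expect_gte(path + 1e-9, direct)
  }
})
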