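## Synthetic-data generators.  These emulate the statistical structure the
## analyses assume -- haplogroup-structured control-region sequences with
## diagnostic bases and 75/76 bp tandem-repeat units, coalescent samples
## under constant-size and sudden-expansion demographies, and flocks on a
## map with a haplogroup-frequency cline -- so that the complete pipeline is
## testable without any external data.  Every generator is a pure function
## of its parameters and seed.

## Region layout used by the synthetic reference (AF010406 coordinates).
.SYN_REF_START <- 15301L
.SYN_REF_END <- 16616L
.REPEAT_START <- 15650L
.REPEAT_UNIT <- 75L
.DIAG_POSITIONS <- c(15459L, 15476L, 15484L, 15509L, 15512L)
## Reference (haplogroup B-like) bases at the diagnostic sites; chosen to
## differ from every derived state used by the shipped diagnostic table.
.DIAG_REF_BASES <- c(`15459` = "C", `15476` = "G", `15484` = "C",
                     `15509` = "C", `15512` = "C")

#' Synthetic control-region reference sequence
#'
#' A deterministic synthetic stand-in for the AF010406 mitochondrial
#' reference over positions 15301-16616 (tRNA-Pro through the control
#' region).  It carries the reference state at the five diagnostic
#' haplogroup positions (15459, 15476, 15484, 15509, 15512) and four exact
#' copies of a 75 bp tandem-repeat unit starting at position 15650.  It is
#' *not* the real AF010406 sequence; it reproduces only the coordinate
#' layout and site structure the analyses rely on.
#'
#' @return List with `seq` (character string) and `ref_start` (15301).
#' @export
synthetic_reference <- function() {
  state <- get0(".syn_ref_cache", envir = .pkg_cache)
  if (!is.null(state)) return(state)
  withr_seed <- .int_seed(920731L)
  bases <- c("A", "C", "G", "T")
  L <- .SYN_REF_END - .SYN_REF_START + 1L
  s <- sample(bases, L, replace = TRUE, prob = c(.33, .26, .13, .28))
  pos <- function(p) p - .SYN_REF_START + 1L
  s[pos(.DIAG_POSITIONS)] <- .DIAG_REF_BASES
  unit <- sample(bases, .REPEAT_UNIT, replace = TRUE)
  rep_cols <- pos(.REPEAT_START):(pos(.REPEAT_START) + 4L * .REPEAT_UNIT - 1L)
  s[rep_cols] <- rep(unit, 4L)
  .restore_seed(withr_seed)
  out <- list(seq = paste(s, collapse = ""), ref_start = .SYN_REF_START,
              repeat_unit = paste(unit, collapse = ""))
  assign(".syn_ref_cache", out, envir = .pkg_cache)
  out
}

.pkg_cache <- new.env(parent = emptyenv())

## Seed scoping: save the caller's RNG state, set a local seed, and restore.
.int_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Default haplogroup specifications for the synthetic generator
#'
#' Encodes the field's five-site control-region scheme: HPG A (15459 T,
#' 15484 A), HPG B (reference state everywhere), HPG C (15509 G), HPG E
#' (15476 C, 15509 G).  The length of the second and subsequent repeat
#' units is 75 bp for the first maternal cluster (A, B, D) and 76 bp for
#' the second (C, E, and the wild X haplotype).  `X` has no diagnostic
#' signature in the five-site scheme and is excluded from the default panel.
#'
#' @param include_x Include the wild `X` haplotype spec (76 bp repeats, no
#'   diagnostic signature) in the returned panel.
#' @return Named list of specs: each has `name`, `diagnostic_bases` (named
#'   character vector, possibly empty), `repeat_unit_length` (75 or 76) and
#'   `base_frequency`.
#' @export
default_haplogroup_specs <- function(include_x = FALSE) {
  specs <- list(
    A = list(name = "A", diagnostic_bases = c(`15459` = "T", `15484` = "A"),
             repeat_unit_length = 75L, base_frequency = 0.30),
    B = list(name = "B", diagnostic_bases = character(0),
             repeat_unit_length = 75L, base_frequency = 0.40),
    C = list(name = "C", diagnostic_bases = c(`15509` = "G"),
             repeat_unit_length = 76L, base_frequency = 0.20),
    E = list(name = "E", diagnostic_bases = c(`15476` = "C", `15509` = "G"),
             repeat_unit_length = 76L, base_frequency = 0.10))
  if (include_x) {
    specs <- lapply(specs, function(sp) {
      sp$base_frequency <- sp$base_frequency * 0.9; sp })
    specs$X <- list(name = "X", diagnostic_bases = character(0),
                    repeat_unit_length = 76L, base_frequency = 0.10)
  }
  specs
}

#' Generate a haplogroup-structured control-region panel
#'
#' Each simulated sequence spans AF010406 positions 15391-16616 of the
#' synthetic reference, carries its haplogroup's diagnostic bases, a first
#' repeat unit of 75 bp followed by 2-4 further units of the haplogroup's
#' unit length (75 or 76 bp; total units 3-5, four being by far the most
#' frequent), and `Poisson(private_mut_rate)` private substitutions at
#' non-diagnostic, non-repeat sites.
#'
#' @param specs List of haplogroup specs (see [default_haplogroup_specs()]).
#' @param n Number of individuals.
#' @param private_mut_rate Mean number of private substitutions per sequence.
#' @param seed Integer seed; same seed, same output.
#' @return List with `seqs` (named character vector), `meta` (data.frame:
#'   `id`, `true_hpg`), `ref` (the synthetic reference list).
#' @export
gen_haplogroup_panel <- function(specs = default_haplogroup_specs(), n = 100,
                                 private_mut_rate = 2, seed = 1) {
  stopifnot(n >= 1)
  sigs <- vapply(specs, function(sp)
    paste(names(sp$diagnostic_bases), sp$diagnostic_bases,
          sep = ":", collapse = ";"), character(1))
  if (anyDuplicated(sigs))
    stop("two haplogroup specs share an identical diagnostic signature: ",
         paste(names(specs)[duplicated(sigs) | duplicated(sigs, fromLast = TRUE)],
               collapse = ", "))
  ref <- synthetic_reference()
  old <- .int_seed(seed)
  on.exit(.restore_seed(old))

  freqs <- vapply(specs, `[[`, numeric(1), "base_frequency")
  freqs <- freqs / sum(freqs)
  labels <- sample(names(specs), n, replace = TRUE, prob = freqs)

  pos0 <- 15391L - ref$ref_start + 1L       # first emitted column
  rep0 <- .REPEAT_START - ref$ref_start + 1L
  pre <- substr(ref$seq, pos0, rep0 - 1L)    # 15391 .. 15649
  post <- substr(ref$seq, rep0 + 4L * .REPEAT_UNIT, nchar(ref$seq))
  unit75 <- ref$repeat_unit
  ## The 76 bp unit is the 75 bp unit with one extra base inserted mid-unit.
  unit76 <- paste0(substr(unit75, 1, 37), "T", substr(unit75, 38, 75))
  bases <- c("A", "C", "G", "T")
  diag_cols_local <- .DIAG_POSITIONS - 15391L + 1L

  seqs <- character(n)
  for (i in seq_len(n)) {
    sp <- specs[[labels[i]]]
    head_chars <- strsplit(pre, "")[[1]]
    for (p in names(sp$diagnostic_bases))
      head_chars[as.integer(p) - 15391L + 1L] <- sp$diagnostic_bases[[p]]
    ## total units 3-5; 4 dominates; 5 only in the 76 bp cluster
    tot <- sample(3:5, 1, prob = c(0.05, 0.90, 0.05))
    if (tot == 5L && sp$repeat_unit_length == 75L) tot <- 4L
    extra_unit <- if (sp$repeat_unit_length == 76L) unit76 else unit75
    repeats <- paste0(unit75, paste(rep(extra_unit, tot - 1L), collapse = ""))
    tail_chars <- strsplit(post, "")[[1]]
    ## private substitutions outside diagnostic sites and the repeat region
    nmut <- rpois(1, private_mut_rate)
    head_ok <- setdiff(seq_along(head_chars), diag_cols_local)
    segs <- c(rep("h", length(head_ok)), rep("t", length(tail_chars)))
    idx <- c(head_ok, seq_along(tail_chars))
    if (nmut > 0) {
      hit <- sample(length(idx), min(nmut, length(idx)))
      for (h in hit) {
        if (segs[h] == "h") {
          j <- idx[h]
          head_chars[j] <- sample(setdiff(bases, head_chars[j]), 1)
        } else {
          j <- idx[h]
          tail_chars[j] <- sample(setdiff(bases, tail_chars[j]), 1)
        }
      }
    }
    seqs[i] <- paste0(paste(head_chars, collapse = ""), repeats,
                      paste(tail_chars, collapse = ""))
  }
  ids <- sprintf("S%03d", seq_len(n))
  list(seqs = setNames(seqs, ids),
       meta = data.frame(id = ids, true_hpg = labels,
                         stringsAsFactors = FALSE),
       ref = ref)
}

## Coalescent machinery -------------------------------------------------------
##
## Time is measured in mutational units: s = u * t, the expected number of
## mutations per lineage accumulated over t generations (u = per-sequence
## mutation rate).  Mutations fall on branches at rate 1 per unit s.  With
## theta = 2Nu, k lineages coalesce at rate k(k-1)/theta per unit s, which
## gives E(pairwise differences) = theta and E(S) = a1 * theta at
## equilibrium.  Under sudden expansion the (backward-time) size switches
## from the theta1 scale to the theta0 scale at s = tau/2, so that the
## fitted mismatch parameter tau = 2ut is directly comparable to the
## generator's tau.

## One coalescent genealogy + infinite-sites mutations.  Returns the S x n
## logical matrix M of mutation incidence (row = mutation, col = sample).
## Uses the current RNG state (callers scope the seed).
sim_coal_M <- function(n, theta0, theta1 = theta0, tau = 0,
                       model = c("constant", "sudden_expansion")) {
  model <- match.arg(model)
  stopifnot(n >= 2, theta0 > 0, theta1 > 0, tau >= 0)
  boundary <- if (model == "sudden_expansion") tau / 2 else Inf
  theta_cur <- if (model == "sudden_expansion") theta1 else theta0
  members <- lapply(seq_len(n), identity)   # tip sets of active lineages
  birth <- numeric(n)                       # time each lineage appeared
  s <- 0; k <- n
  mut_sets <- vector("list", 0)
  past_boundary <- !is.finite(boundary)
  while (k > 1) {
    rate <- k * (k - 1) / theta_cur
    dt <- rexp(1, rate)
    if (!past_boundary && s + dt > boundary) {
      s <- boundary
      theta_cur <- theta0
      past_boundary <- TRUE
      next
    }
    s <- s + dt
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    for (idx in c(i, j)) {
      len <- s - birth[idx]
      nm <- rpois(1, len)
      if (nm > 0)
        mut_sets <- c(mut_sets, rep(list(members[[idx]]), nm))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    birth[i] <- s
    members[[j]] <- NULL
    birth <- birth[-j]
    k <- k - 1
  }
  S <- length(mut_sets)
  M <- matrix(FALSE, nrow = S, ncol = n)
  for (r in seq_len(S)) M[r, mut_sets[[r]]] <- TRUE
  M
}

## Summaries computed directly from a mutation-incidence matrix.
M_pairwise <- function(M) {
  n <- ncol(M)
  if (nrow(M) == 0) return(matrix(0, n, n))
  storage.mode(M) <- "integer"
  shared <- crossprod(M)
  cnt <- diag(shared)
  outer(cnt, cnt, "+") - 2 * shared
}
M_theta_pi <- function(M) {
  n <- ncol(M)
  d <- M_pairwise(M)
  sum(d[upper.tri(d)]) / choose(n, 2)
}
M_n_haplotypes <- function(M) {
  if (nrow(M) == 0) return(1L)
  length(unique(apply(M, 2, paste, collapse = "")))
}

#' Generate a coalescent sample of sequences
#'
#' Standard n-coalescent with infinite-sites mutations.  Under
#' `sudden_expansion` the population size switches (looking backward) from
#' the `theta1` scale to the `theta0` scale at time `tau/2` in mutational
#' units, the parameterisation under which the mismatch-distribution
#' expansion time is `tau = 2ut`.
#'
#' @param n Sample size (>= 2).
#' @param L Sequence length in bp; mutations map to distinct columns.
#' @param theta0 Scaled population size (2Nu) before the expansion (the only
#'   size under the constant model).
#' @param theta1 Scaled size after the expansion.
#' @param tau Expansion time in mutational units (ignored under `constant`).
#' @param model `"constant"` or `"sudden_expansion"`.
#' @param seed Integer seed.
#' @return Named character vector of `n` sequences of length `L`, with the
#'   mutation-incidence matrix in attribute `M`.
#' @export
gen_coalescent <- function(n, L = 1000, theta0 = 5, theta1 = theta0, tau = 0,
                           model = c("constant", "sudden_expansion"),
                           seed = 1) {
  model <- match.arg(model)
  old <- .int_seed(seed)
  on.exit(.restore_seed(old))
  M <- sim_coal_M(n, theta0, theta1, tau, model)
  S <- nrow(M)
  if (S > L)
    stop("realized mutation count (", S, ") exceeds L = ", L,
         "; increase L")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  cols <- if (S > 0) sample.int(L, S) else integer(0)
  seqs <- matrix(rep(anc, each = n), nrow = n)
  for (r in seq_len(S)) {
    derived <- sample(setdiff(bases, anc[cols[r]]), 1)
    seqs[M[r, ], cols[r]] <- derived
  }
  out <- setNames(apply(seqs, 1, paste, collapse = ""),
                  sprintf("C%03d", seq_len(n)))
  attr(out, "M") <- M
  out
}

#' Generate a spatial panel of flocks with a haplogroup-frequency cline
#'
#' Flocks are placed uniformly on a square plane of side `extent_km`; each
#' individual's haplogroup is drawn from a location-dependent frequency
#' vector in which the frequency of `cline$haplogroup` changes linearly
#' from west to east by a total of `cline$delta` (other haplogroups are
#' rescaled to keep the vector a distribution).  `cline$delta = 0` gives a
#' spatially homogeneous null panel.
#'
#' @param n_flocks Number of flocks (>= 2).
#' @param flock_size Individuals per flock.
#' @param cline List: `haplogroup` (label) and `delta` (total west-to-east
#'   frequency change, may be 0).
#' @param extent_km Side of the square study area, in km (> 0).
#' @param base_freqs Named baseline haplogroup frequencies.
#' @param seed Integer seed.
#' @return List with `meta` (data.frame: `id`, `flock`, `hpg`, `x_km`,
#'   `y_km`) and `coords` (flock coordinate matrix).  Individuals within a
#'   flock share the flock's coordinates.
#' @export
gen_spatial_panel <- function(n_flocks = 20, flock_size = 15,
                              cline = list(haplogroup = "B", delta = 0),
                              extent_km = 1500,
                              base_freqs = c(A = 0.30, B = 0.40,
                                             C = 0.20, E = 0.10),
                              seed = 1) {
  stopifnot(n_flocks >= 2, flock_size >= 1)
  if (extent_km <= 0) stop("degenerate extent: extent_km must be > 0")
  if (!cline$haplogroup %in% names(base_freqs))
    stop("cline haplogroup not among base_freqs")
  old <- .int_seed(seed)
  on.exit(.restore_seed(old))
  fx <- runif(n_flocks, 0, extent_km)
  fy <- runif(n_flocks, 0, extent_km)
  target <- cline$haplogroup
  rows <- vector("list", n_flocks)
  for (f in seq_len(n_flocks)) {
    p <- base_freqs
    shift <- cline$delta * (0.5 - fx[f] / extent_km)  # west high, east low
    p[target] <- max(p[target] + shift, 0.02)
    others <- setdiff(names(p), target)
    p[others] <- p[others] * (1 - p[target]) / sum(p[others])
    lab <- sample(names(p), flock_size, replace = TRUE, prob = p)
    rows[[f]] <- data.frame(
      id = sprintf("F%02dI%02d", f, seq_len(flock_size)),
      flock = sprintf("F%02d", f), hpg = lab,
      x_km = fx[f], y_km = fy[f], stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  list(meta = meta,
       coords = cbind(x_km = fx, y_km = fy))
}
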