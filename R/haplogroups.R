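## Haplogroup classification from diagnostic control-region sites, and
## tandem-repeat-unit length parsing.  The shipped scheme uses the five
## AF010406 positions 15459, 15476, 15484, 15509 and 15512: HPG A carries
## 15459 T + 15484 A, HPG C carries 15509 G, HPG E carries 15476 C +
## 15509 G, and HPG B is the all-reference signature.  HPG D and the wild
## X haplotype have no published signature in this five-site scheme; their
## slots ship empty and such samples fall to "unassigned" unless the user
## supplies rules.

#' Build a diagnostic-site table
#'
#' @param rules Named list: haplogroup label -> named character vector of
#'   required derived bases (`c("15459" = "T", ...)`); an empty vector means
#'   "no known signature" (never matched).
#' @param reference_haplogroup Label assigned when every diagnostic site
#'   carries the reference base.
#' @return Object of class `diagnostic_table`.
#' @export
diagnostic_table <- function(rules, reference_haplogroup = "B") {
  stopifnot(is.list(rules), !is.null(names(rules)))
  rules <- lapply(rules, function(r) {
    if (length(r) == 0) return(character(0))
    r <- r[order(as.integer(names(r)))]
    stopifnot(all(r %in% c("A", "C", "G", "T")))
    r
  })
  sigs <- vapply(rules, function(r)
    paste(names(r), r, sep = ":", collapse = ";"), character(1))
  nonempty <- sigs[sigs != ""]
  if (anyDuplicated(nonempty))
    stop("two haplogroups share an identical signature")
  positions <- sort(unique(as.integer(unlist(lapply(rules, names)))))
  structure(list(rules = rules, positions = positions,
                 reference_haplogroup = reference_haplogroup),
            class = "diagnostic_table")
}

#' Default five-site diagnostic table (HPG A, B, C, E; D and X empty)
#' @return A `diagnostic_table`.
#' @export
default_diagnostic_table <- function() {
  diagnostic_table(list(
    A = c(`15459` = "T", `15484` = "A"),
    C = c(`15509` = "G"),
    E = c(`15476` = "C", `15509` = "G"),
    D = character(0),
    X = character(0)),
    reference_haplogroup = "B")
}

## Core matching rule.  `obs` is a named character vector over the table's
## positions with values in {A,C,G,T} or "." (= reference base) or NA
## (unreadable).  A haplogroup matches iff the sample carries ALL of its
## required derived bases; among several matches the maximal signature (by
## set inclusion) wins; incomparable ties and partial matches fall to
## "unassigned".  The reference haplogroup is called only when every
## readable site is the reference base and nothing is missing beyond
## max_missing.
match_haplogroup <- function(obs, table, max_missing = 0) {
  n_missing <- sum(is.na(obs))
  if (n_missing > max_missing)
    return(list(haplogroup = "unassigned", n_missing = n_missing))
  matched <- character(0)
  for (h in names(table$rules)) {
    r <- table$rules[[h]]
    if (length(r) == 0) next
    o <- obs[names(r)]
    if (all(!is.na(o) & o == r)) matched <- c(matched, h)
  }
  if (length(matched) == 0) {
    readable <- obs[!is.na(obs)]
    if (length(readable) > 0 && all(readable == "."))
      return(list(haplogroup = table$reference_haplogroup,
                  n_missing = n_missing))
    return(list(haplogroup = "unassigned", n_missing = n_missing))
  }
  if (length(matched) == 1)
    return(list(haplogroup = matched, n_missing = n_missing))
  ## maximal signature by inclusion
  sig <- lapply(table$rules[matched], names)
  is_max <- vapply(seq_along(matched), function(i)
    !any(vapply(seq_along(matched), function(j)
      i != j && all(sig[[i]] %in% sig[[j]]), logical(1))), logical(1))
  if (sum(is_max) == 1)
    return(list(haplogroup = matched[is_max], n_missing = n_missing))
  list(haplogroup = "unassigned", n_missing = n_missing)
}

#' Classify an anchored sequence into a haplogroup
#'
#' @param seq Sequence string.
#' @param map `coord_map` anchoring `seq` to AF010406 coordinates.
#' @param ref Reference sequence string (same coordinates as the map), used
#'   to decide whether an observed base is the reference state.
#' @param ref_start Reference coordinate of `ref`'s first base.
#' @param table A `diagnostic_table`.
#' @param max_missing Maximum unreadable diagnostic sites before the call
#'   falls to "unassigned" (default 0).
#' @param id Sample id for the returned row.
#' @return One-row data.frame: `id`, `haplogroup`, `observed` (evidence
#'   string, "." for reference base), `n_missing`.
#' @export
classify <- function(seq, map, ref, ref_start = 1,
                     table = default_diagnostic_table(),
                     max_missing = 0, id = "sample") {
  cols <- map_column(map, table$positions)
  obs <- rep(NA_character_, length(table$positions))
  names(obs) <- as.character(table$positions)
  for (i in seq_along(cols)) {
    if (is.na(cols[i])) next
    b <- substr(seq, cols[i], cols[i])
    if (!b %in% c("A", "C", "G", "T")) next
    refb <- substr(ref, table$positions[i] - ref_start + 1L,
                   table$positions[i] - ref_start + 1L)
    obs[i] <- if (b == refb) "." else b
  }
  m <- match_haplogroup(obs, table, max_missing)
  data.frame(id = id, haplogroup = m$haplogroup,
             observed = paste(ifelse(is.na(obs), "?", obs), collapse = " "),
             n_missing = m$n_missing, stringsAsFactors = FALSE)
}

#' Classify a collection of sequences
#'
#' Anchors each sequence to the reference and classifies it.
#'
#' @param seqs Named character vector of sequences.
#' @param ref Reference sequence string.
#' @param ref_start Reference coordinate of `ref`'s first base.
#' @inheritParams classify
#' @return data.frame of calls, one row per sequence.
#' @export
classify_panel <- function(seqs, ref, ref_start = 1,
                           table = default_diagnostic_table(),
                           max_missing = 0) {
  rows <- lapply(names(seqs), function(id) {
    map <- anchor_to_reference(seqs[[id]], ref, ref_start = ref_start)
    classify(seqs[[id]], map, ref, ref_start, table, max_missing, id = id)
  })
  do.call(rbind, rows)
}

#' Classify genotype-table rows (reference-dot notation)
#'
#' Classifies samples typed only at the diagnostic positions, given as a
#' table with one column per position (`p15459`, ...) holding the observed
#' base, `"."` for the reference base, or `"?"`/`NA` for unreadable.  This
#' is the form in which ancient-DNA genotypes are usually published.
#'
#' @param geno data.frame with an `id` column and one `p<position>` column
#'   per diagnostic position.
#' @param table A `diagnostic_table`.
#' @param max_missing Maximum unreadable sites (default 0).
#' @return data.frame of calls, one row per sample.
#' @export
classify_genotypes <- function(geno, table = default_diagnostic_table(),
                               max_missing = 0) {
  stopifnot("id" %in% names(geno))
  cols <- paste0("p", table$positions)
  missing_cols <- setdiff(cols, names(geno))
  if (length(missing_cols) > 0)
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  rows <- lapply(seq_len(nrow(geno)), function(i) {
    obs <- as.character(unlist(geno[i, cols]))
    obs[obs %in% c("?", "", NA)] <- NA_character_
    names(obs) <- as.character(table$positions)
    m <- match_haplogroup(obs, table, max_missing)
    data.frame(id = geno$id[i], haplogroup = m$haplogroup,
               observed = paste(ifelse(is.na(obs), "?", obs), collapse = " "),
               n_missing = m$n_missing, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published genotypes of the 33 ancient Oylum Höyük sheep
#'
#' The five-site diagnostic genotypes (AF010406 positions 15459, 15476,
#' 15484, 15509, 15512; `"."` = reference base) and archaeological date
#' ranges of the 33 ancient sheep from the Oylum Höyük mound (Kilis,
#' Southeastern Turkey), 1800-30 BCE, together with the haplogroup each
#' sample was assigned in the original report (`published_hpg`, kept for
#' cross-checking only -- the classifier never reads it).
#'
#' @return data.frame with columns `id`, `p15459`, `p15476`, `p15484`,
#'   `p15509`, `p15512`, `published_hpg`, `date_from_bce`, `date_to_bce`.
#' @export
oylum_genotypes <- function() {
  path <- system.file("extdata", "oylum_adna_genotypes.tsv",
                      package = "ovismthap")
  geno <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
  geno$date_from_bce <- as.integer(geno$date_from_bce)
  geno$date_to_bce <- as.integer(geno$date_to_bce)
  geno
}

#' Stratify dated samples into BCE eras
#'
#' A sample belongs to a stratum when its date range `[from, to]` (BCE
#' years, `from >= to`) lies entirely inside the stratum.
#'
#' @param from,to Integer vectors of BCE years (older first).
#' @param strata List of `c(older, younger)` BCE boundaries, e.g.
#'   `list(c(1800, 1200), c(1200, 330))`.
#' @return Character vector of stratum labels (`"1800-1200 BCE"` style),
#'   `NA` for samples falling in no stratum.
#' @export
era_stratum <- function(from, to,
                        strata = list(c(1800, 1200), c(1200, 330))) {
  labels <- vapply(strata, function(s) paste0(s[1], "-", s[2], " BCE"),
                   character(1))
  out <- rep(NA_character_, length(from))
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    hit <- from <= s[1] & to >= s[2] & is.na(out)
    out[hit] <- labels[k]
  }
  out
}

#' Haplogroup frequency table
#'
#' @param calls data.frame of calls (needs a `haplogroup` column).
#' @param strata Optional vector (length `nrow(calls)`) of stratum labels;
#'   `NA` rows are dropped from stratified counts.
#' @return data.frame: `stratum`, `haplogroup`, `count`, `pct` (percentage
#'   of the stratum total, unassigned included in the denominator and
#'   reported as its own row).
#' @export
frequency_table <- function(calls, strata = NULL) {
  if (is.null(calls) || nrow(calls) == 0) stop("no calls to tabulate")
  if (is.null(strata)) strata <- rep("all", nrow(calls))
  keep <- !is.na(strata)
  calls <- calls[keep, , drop = FALSE]
  strata <- strata[keep]
  out <- list()
  for (s in unique(strata)) {
    sub <- calls$haplogroup[strata == s]
    tab <- table(sub)
    out[[s]] <- data.frame(stratum = s, haplogroup = names(tab),
                           count = as.integer(tab),
                           pct = 100 * as.integer(tab) / length(sub),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Repeat-unit parsing --------------------------------------------------------

#' Parse the control-region tandem-repeat units
#'
#' Locates the 75 bp repeat array by self-similarity within a +/- `window`
#' bp neighbourhood of the expected start (AF010406 position 15650; the
#' literature also quotes 15650 as the 213th CR base, so a fixed coordinate
#' is not trusted), then greedily matches successive units of length 75 or
#' 76 allowing up to `d_max` internal mismatches per unit.  The length of
#' the second and subsequent units assigns the sequence to repeat cluster
#' "i" (all 75 bp; haplogroups A, B, D) or "ii" (all 76 bp; C, E, X).
#'
#' @param seq Sequence string.
#' @param map `coord_map` anchoring `seq` (used to find the expected start);
#'   may be `NULL` if `start_col` is given.
#' @param repeat_start Expected reference position of the first unit.
#' @param start_col Expected column of the first unit (overrides `map`).
#' @param window Search half-window around the expected start, bp.
#' @param d_max Maximum mismatches tolerated per unit.
#' @return Object of class `repeat_profile`: list with `unit_lengths`,
#'   `n_units`, `cluster` ("i", "ii" or "undetermined") and `start_col`.
#' @export
parse_repeats <- function(seq, map = NULL, repeat_start = 15650,
                          start_col = NULL, window = 30, d_max = 5) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (is.null(start_col)) {
    if (is.null(map)) stop("supply either a coord_map or start_col")
    start_col <- map_column(map, repeat_start)
    if (is.na(start_col)) {
      mapped <- map$col_to_ref[!is.na(map$col_to_ref)]
      near <- which.min(abs(mapped - repeat_start))
      start_col <- which(!is.na(map$col_to_ref))[near]
    }
  }
  U <- 75L
  cand <- max(1L, start_col - window):(start_col + window)
  cand <- cand[cand + 2L * U - 1L <= length(chars)]
  if (length(cand) == 0) stop("repeat region not found")
  score1 <- vapply(cand, function(s) {
    u1 <- chars[s:(s + U - 1L)]
    nxt75 <- chars[(s + U):(s + 2L * U - 1L)]
    s75 <- sum(u1 != nxt75)
    s76 <- if (s + U + U <= length(chars))
      min_del_hamming(chars[(s + U):(s + U + U)], u1) else Inf
    min(s75, s76)
  }, numeric(1))
  best <- which.min(score1)
  if (score1[best] > d_max) stop("repeat region not found")
  s0 <- cand[best]
  unit1 <- chars[s0:(s0 + U - 1L)]
  lengths <- U
  p <- s0 + U
  repeat {
    s75 <- if (p + U - 1L <= length(chars))
      sum(chars[p:(p + U - 1L)] != unit1) else Inf
    s76 <- if (p + U <= length(chars))
      min_del_hamming(chars[p:(p + U)], unit1) else Inf
    if (min(s75, s76) > d_max) break
    if (s75 <= s76) { lengths <- c(lengths, U); p <- p + U }
    else { lengths <- c(lengths, U + 1L); p <- p + U + 1L }
  }
  n_units <- length(lengths)
  if (n_units < 3 || n_units > 5)
    warning("number of repeat units (", n_units,
            ") outside the usual 3-5 range")
  later <- lengths[-1]
  cluster <- if (length(later) == 0) "undetermined"
  else if (all(later == 75L)) "i"
  else if (all(later == 76L)) "ii"
  else "undetermined"
  structure(list(unit_lengths = as.integer(lengths),
                 n_units = n_units, cluster = cluster,
                 start_col = s0),
            class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat("repeat profile:", x$n_units, "units (",
      paste(x$unit_lengths, collapse = ", "), "bp ), cluster", x$cluster, "\n")
  invisible(x)
}

## Best Hamming distance of a (len+1)-window against a len-unit, over all
## single-base deletions from the window (exact; len is only 75).
min_del_hamming <- function(window, unit) {
  L <- length(unit)
  stopifnot(length(window) == L + 1L)
  best <- Inf
  for (d in seq_len(L + 1L)) {
    w <- window[-d]
    h <- sum(w != unit)
    if (h < best) best <- h
    if (best == 0) break
  }
  best
}
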