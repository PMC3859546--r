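## Sequence and metadata I/O, and anchoring of sequences to AF010406
## coordinates so that every downstream position (diagnostic sites, repeat
## region, trimming windows) is unambiguous.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on load; gap characters (`-`) are retained so
#' pre-aligned input passes through unchanged.  Record ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty). Names are
#'   record ids (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) return(setNames(character(0), character(0)))
  dna <- ape::read.FASTA(path)
  ids <- sub("\\s.*$", "", names(dna))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- vapply(as.character(dna),
                 function(x) paste(toupper(x), collapse = ""), character(1))
  if (any(nchar(seqs) == 0)) stop("zero-length sequence in ", path)
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated with a header; an `id` column is required, `group`, `lat`,
#' `lon` and `era` are optional.  Latitude must lie in [-90, 90], longitude
#' in [-180, 180].
#'
#' @param path Path to a TSV file.
#' @param seq_ids Optional character vector of sequence ids; metadata ids not
#'   found among them trigger a warning.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path, seq_ids = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(md)) stop("metadata must have an 'id' column")
  for (cc in c("lat", "lon")) {
    if (cc %in% names(md)) {
      raw <- md[[cc]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- !is.na(raw) & raw != "" & is.na(val)
      if (any(bad))
        stop("malformed coordinate in column '", cc, "': ",
             paste(unique(raw[bad]), collapse = ", "))
      md[[cc]] <- val
    }
  }
  if ("lat" %in% names(md) && any(abs(md$lat) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if ("lon" %in% names(md) && any(abs(md$lon) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  if (!is.null(seq_ids)) {
    missing <- setdiff(md$id, seq_ids)
    if (length(missing) > 0)
      warning("metadata ids absent from sequences: ",
              paste(missing, collapse = ", "))
  }
  md
}

#' Anchor a sequence to reference coordinates
#'
#' Locates the sequence on the reference by an exact k-mer seed and extends
#' with a global alignment, producing a per-column coordinate map.  If `seq`
#' and the reference have equal length the input is taken as pre-aligned
#' (column i maps to reference position `ref_start + i - 1`).
#'
#' @param seq A single sequence string.
#' @param ref Reference sequence string (ungapped).
#' @param k Seed k-mer length (default 20).
#' @param ref_start 1-based reference coordinate of `ref`'s first base
#'   (e.g. 15437 when `ref` is the AF010406 control region).
#' @param pad Extension padding (bp) around the seeded window.
#' @return An object of class `coord_map`: list with `col_to_ref` (integer
#'   vector, one entry per sequence column, `NA` for insertions relative to
#'   the reference) and `ref_start`.
#' @export
anchor_to_reference <- function(seq, ref, k = 20, ref_start = 1, pad = 60) {
  stopifnot(length(seq) == 1, length(ref) == 1)
  seq <- toupper(seq); ref <- toupper(ref)
  n <- nchar(seq); m <- nchar(ref)
  if (n == 0 || m == 0) stop("empty sequence")
  if (n == m) {
    keep <- strsplit(seq, "")[[1]] != "-"
    col_to_ref <- ifelse(keep, seq_len(n) + ref_start - 1L, NA_integer_)
    return(new_coord_map(col_to_ref, ref_start))
  }
  offset <- find_seed_offset(seq, ref, k)
  if (is.na(offset))
    stop("no ", k, "-mer anchor shared with the reference; ",
         "pre-align the sequence to the reference and retry")
  w_start <- max(1L, offset + 1L - pad)
  w_end <- min(m, offset + n + pad)
  path <- nw_map(gsub("-", "N", seq), substr(ref, w_start, w_end))
  col_to_ref <- path + (w_start - 1L) + (ref_start - 1L)
  gaps <- strsplit(seq, "")[[1]] == "-"
  col_to_ref[gaps] <- NA_integer_
  new_coord_map(col_to_ref, ref_start)
}

new_coord_map <- function(col_to_ref, ref_start) {
  mapped <- col_to_ref[!is.na(col_to_ref)]
  if (length(mapped) == 0) stop("coordinate map has no mapped columns")
  if (any(diff(mapped) <= 0))
    stop("mapped reference positions are not strictly increasing")
  structure(list(col_to_ref = as.integer(col_to_ref),
                 ref_start = as.integer(ref_start)),
            class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  mapped <- x$col_to_ref[!is.na(x$col_to_ref)]
  cat("coordinate map:", length(x$col_to_ref), "columns,",
      length(mapped), "mapped to reference positions",
      min(mapped), "-", max(mapped), "\n")
  invisible(x)
}

#' Column index of a reference position
#'
#' @param map A `coord_map`.
#' @param pos Reference position(s), 1-based.
#' @return Integer column index(es); `NA` where the position is not covered.
#' @export
map_column <- function(map, pos) {
  stopifnot(inherits(map, "coord_map"))
  match(as.integer(pos), map$col_to_ref)
}

#' Extract a reference-coordinate region from an anchored sequence
#'
#' @param seq Sequence string the map was built for.
#' @param map `coord_map` from [anchor_to_reference()].
#' @param start,end 1-based inclusive reference positions, `start <= end`.
#' @return The subsequence covering `[start, end]` (insertions between the
#'   boundary columns are retained; flanking gap columns are not).
#' @export
extract_region <- function(seq, map, start, end) {
  stopifnot(inherits(map, "coord_map"))
  if (start > end) stop("start > end in extract_region")
  inside <- which(!is.na(map$col_to_ref) &
                    map$col_to_ref >= start & map$col_to_ref <= end)
  if (length(inside) == 0 ||
      min(map$col_to_ref, na.rm = TRUE) > start ||
      max(map$col_to_ref, na.rm = TRUE) < end)
    stop("region [", start, ", ", end, "] not fully covered by the map")
  substr(seq, min(inside), max(inside))
}

## Global alignment path (C backend): per-seq-column 1-based ref position,
## NA for insertions relative to ref.
nw_map <- function(seq, ref, match = 1L, mismatch = -1L, gap = -2L) {
  .Call(C_nw_map, seq, ref, as.integer(c(match, mismatch, gap)))
}

find_seed_offset <- function(seq, ref, k) {
  n <- nchar(seq)
  if (n < k) return(NA_integer_)
  ref_kmers <- substring(ref, 1:(nchar(ref) - k + 1), k:nchar(ref))
  starts <- unique(c(seq(1, n - k + 1, by = k), n - k + 1))
  for (s in starts) {
    kmer <- substr(seq, s, s + k - 1)
    if (grepl("[^ACGT]", kmer)) next
    hits <- which(ref_kmers == kmer)
    if (length(hits) == 1) return(hits[1] - s)  # ref position = seq position + offset
  }
  NA_integer_
}

## Aligned collections -------------------------------------------------------

## Character matrix (n x L) from an aligned set; N and - become NA (missing
## data are deleted pairwise from every distance/difference count).
seq_matrix <- function(seqs) {
  if (length(seqs) < 1) stop("empty sequence collection")
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("sequences are not aligned (unequal lengths)")
  m <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE,
              dimnames = list(names(seqs), NULL))
  m[m %in% c("N", "-", "?")] <- NA_character_
  m
}

## Pairwise difference matrix under pairwise deletion, plus the number of
## mutually compared sites for each pair.
pairwise_diffs <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n); L <- matrix(ncol(mat), n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok])
      L[i, j] <- L[j, i] <- sum(ok)
    }
  }
  list(d = d, L = L)
}
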