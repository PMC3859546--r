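## End-to-end orchestration: one declarative (YAML) config drives
## classify -> repeats -> diversity -> neutrality -> mismatch -> spatial ->
## tree/network, with a single master seed expanded into per-stage seeds by
## a fixed counter scheme so every stage is reproducible independently of
## stage order.

.STAGE_INDEX <- c(classify = 1L, repeats = 2L, diversity = 3L,
                  neutrality = 4L, mismatch = 5L, spatial = 6L,
                  tree = 7L, network = 8L, fixtures = 9L)

#' Per-stage seed derived from a master seed
#'
#' `seed_stage = (master + 10007 * stage_index) mod (2^31 - 1)`.
#'
#' @param master Integer master seed.
#' @param stage Stage name (see names of the internal stage table).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  idx <- .STAGE_INDEX[[stage]]
  as.integer((as.numeric(master) + 10007 * idx) %% 2147483647)
}

#' Run the full analysis pipeline from a config
#'
#' The config (YAML file or list) names the inputs and toggles the
#' analyses:
#' \preformatted{
#' sequences: panel.fasta        # aligned or anchorable CR sequences
#' reference: ref.fasta          # reference (single record)
#' ref_start: 15301              # AF010406 coordinate of reference base 1
#' metadata: meta.tsv            # id [group lat lon era]
#' genotypes: geno.tsv           # optional: diagnostic-site genotype table
#' out_dir: results/
#' seed: 1
#' analyses: [classify, diversity, neutrality, mismatch]
#' params:
#'   neutrality: {n_reps: 1000}
#'   mismatch: {n_boot: 200}
#'   spatial: {class_width_km: 150, n_perm: 999, n_boot: 1000,
#'             metric: planar}
#' }
#' Every enabled stage writes a TSV/JSON report into `out_dir`, plus a
#' `manifest.json` recording inputs, parameters and the derived seeds.
#' A failing stage writes a `<stage>.FAILED` marker, later stages still
#' run, and the function signals an error at the end.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return (Invisibly) a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg), !is.null(cfg$out_dir))
  analyses <- cfg$analyses %||% c("classify", "diversity")
  seed <- cfg$seed %||% 1L
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("sequences", "reference", "metadata", "genotypes")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config input does not exist: ", f, " = ", cfg[[f]])
  }
  pars <- cfg$params %||% list()
  seqs <- if (!is.null(cfg$sequences)) read_fasta(cfg$sequences) else NULL
  ref <- NULL; ref_start <- cfg$ref_start %||% 1L
  if (!is.null(cfg$reference)) {
    rf <- read_fasta(cfg$reference)
    if (length(rf) != 1) stop("reference FASTA must hold one record")
    ref <- rf[[1]]
  }
  meta <- if (!is.null(cfg$metadata))
    read_metadata(cfg$metadata, seq_ids = names(seqs)) else NULL

  results <- list(); failed <- character(0)
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      writeLines(conditionMessage(out),
                 file.path(cfg$out_dir, paste0(name, ".FAILED")))
      failed <<- c(failed, name)
      NULL
    } else out
  }
  tsv <- function(df, name) {
    write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  calls <- NULL
  if ("classify" %in% analyses) {
    results$classify <- run_stage("classify", function() {
      calls <<- if (!is.null(cfg$genotypes)) {
        geno <- read.delim(cfg$genotypes, stringsAsFactors = FALSE,
                           colClasses = "character")
        classify_genotypes(geno)
      } else {
        stopifnot(!is.null(seqs), !is.null(ref))
        classify_panel(seqs, ref, ref_start)
      }
      tsv(calls, "haplogroup_calls.tsv")
      tsv(frequency_table(calls), "haplogroup_frequencies.tsv")
      calls
    })
  }
  if ("repeats" %in% analyses && !is.null(seqs)) {
    results$repeats <- run_stage("repeats", function() {
      rows <- lapply(names(seqs), function(id) {
        map <- anchor_to_reference(seqs[[id]], ref, ref_start = ref_start)
        pr <- suppressWarnings(parse_repeats(seqs[[id]], map))
        data.frame(id = id, n_units = pr$n_units,
                   unit_lengths = paste(pr$unit_lengths, collapse = ","),
                   cluster = pr$cluster)
      })
      out <- do.call(rbind, rows)
      tsv(out, "repeat_profiles.tsv")
      out
    })
  }
  groups <- NULL
  if (!is.null(calls)) groups <- setNames(calls$haplogroup, calls$id)
  else if (!is.null(meta) && "group" %in% names(meta))
    groups <- setNames(meta$group, meta$id)

  aligned <- NULL
  if (!is.null(seqs) &&
      any(c("diversity", "neutrality", "mismatch") %in% analyses)) {
    ## anchor everything into common reference columns, mask repeats
    aligned <- run_stage("align", function() {
      maps <- lapply(seqs, anchor_to_reference, ref = ref,
                     ref_start = ref_start)
      masked <- mask_repeat_region(seqs, maps)
      to_ref_columns(masked, maps, ref_start, nchar(ref))
    })
  }
  if ("diversity" %in% analyses && !is.null(aligned)) {
    results$diversity <- run_stage("diversity", function() {
      g <- groups[names(aligned)]
      out <- diversity_report(aligned, g)
      tsv(out, "diversity.tsv")
      out
    })
  }
  if ("neutrality" %in% analyses && !is.null(aligned)) {
    results$neutrality <- run_stage("neutrality", function() {
      p <- pars$neutrality %||% list()
      out <- neutrality_report(aligned, groups[names(aligned)],
                               n_reps = p$n_reps %||% 1000,
                               seed = derive_seed(seed, "neutrality"))
      tsv(out, "neutrality.tsv")
      out
    })
  }
  if ("mismatch" %in% analyses && !is.null(aligned)) {
    results$mismatch <- run_stage("mismatch", function() {
      p <- pars$mismatch %||% list()
      g <- groups[names(aligned)]
      fits <- lapply(unique(g[!is.na(g)]), function(grp) {
        sub <- aligned[which(g == grp)]
        if (length(sub) < 3) return(NULL)
        fit <- mismatch_analysis(sub, n_boot = p$n_boot %||% 1000,
                                 seed = derive_seed(seed, "mismatch"))
        list(group = grp, tau = fit$tau, theta0 = fit$theta0,
             theta1 = fit$theta1, ssd = fit$ssd, p_ssd = fit$p_ssd,
             mean_mismatch = fit$mean_mismatch)
      })
      fits <- Filter(Negate(is.null), fits)
      jsonlite::write_json(fits, file.path(cfg$out_dir, "mismatch_fits.json"),
                           auto_unbox = TRUE, digits = NA)
      fits
    })
  }
  if ("spatial" %in% analyses) {
    results$spatial <- run_stage("spatial", function() {
      p <- pars$spatial %||% list()
      stopifnot(!is.null(meta), !is.null(groups))
      coord_cols <- if (!is.null(p$metric) && p$metric == "planar")
        c("lon", "lat") else c("lon", "lat")
      d2 <- genetic_distance_matrix(groups[meta$id])
      kept <- attr(d2, "kept")
      ac <- autocorrelogram(
        d2, as.matrix(meta[kept, coord_cols]),
        class_width_km = p$class_width_km %||% 150,
        metric = p$metric %||% "great_circle",
        n_perm = p$n_perm %||% 999, n_boot = p$n_boot %||% 1000,
        seed = derive_seed(seed, "spatial"))
      tsv(as.data.frame(ac), "correlogram.tsv")
      ac
    })
  }
  if ("tree" %in% analyses && !is.null(aligned)) {
    results$tree <- run_stage("tree", function() {
      p <- pars$tree %||% list()
      bs <- bootstrap_support(aligned, n_reps = p$n_reps %||% 1000,
                              seed = derive_seed(seed, "tree"))
      ape::write.tree(bs$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
      bs
    })
  }
  if ("network" %in% analyses && !is.null(aligned)) {
    results$network <- run_stage("network", function() {
      tab <- collapse_haplotypes(aligned)
      net <- mj_network(setNames(tab$haplotypes,
                                 sprintf("H%02d", seq_along(tab$haplotypes))),
                        counts = tab$counts)
      tsv(net$edges, "mj_network_edges.tsv")
      tsv(net$nodes, "mj_network_nodes.tsv")
      net
    })
  }

  manifest <- list(
    inputs = cfg[intersect(names(cfg),
                           c("sequences", "reference", "metadata",
                             "genotypes", "ref_start"))],
    analyses = analyses, params = pars, master_seed = seed,
    stage_seeds = setNames(
      lapply(names(.STAGE_INDEX), derive_seed, master = seed),
      names(.STAGE_INDEX)),
    package_version = as.character(utils::packageVersion("ovismthap")),
    failed = failed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(failed) > 0)
    stop("pipeline stage(s) failed: ", paste(failed, collapse = ", "),
         " (partial outputs retained in ", cfg$out_dir, ")")
  invisible(results)
}

## Project anchored, masked sequences onto common reference columns
## (ref_start .. ref_start + ref_len - 1), N where uncovered, so that
## variable repeat-array lengths do not break downstream alignment.
to_ref_columns <- function(seqs, maps, ref_start, ref_len) {
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    cols <- rep("N", ref_len)
    ctr <- maps[[i]]$col_to_ref
    ok <- !is.na(ctr) & ctr >= ref_start & ctr <= ref_start + ref_len - 1
    chars <- strsplit(seqs[[i]], "")[[1]]
    cols[ctr[ok] - ref_start + 1L] <- chars[ok]
    out[i] <- paste(cols, collapse = "")
  }
  setNames(out, names(seqs))
}

#' Write the packaged test fixtures to a directory
#'
#' Writes (1) the published ancient-genotype table, (2) a small toy
#' control-region alignment, and (3) a seeded synthetic haplogroup panel
#' (FASTA + metadata TSV) flowing through the same entry points as real
#' data.  Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory.
#' @param seed Integer seed for the synthetic panel.
#' @return (Invisibly) the paths written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  g <- oylum_genotypes()
  p <- file.path(dir, "oylum_adna_genotypes.tsv")
  write.table(g, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  ref <- synthetic_reference()
  p <- file.path(dir, "reference_cr_synthetic.fasta")
  write_fasta(setNames(ref$seq, "SYNREF_CR"), p)
  paths <- c(paths, p)

  panel <- gen_haplogroup_panel(n = 60, seed = derive_seed(seed, "fixtures"))
  p <- file.path(dir, "panel_synthetic.fasta")
  write_fasta(panel$seqs, p)
  paths <- c(paths, p)
  p <- file.path(dir, "panel_synthetic_meta.tsv")
  write.table(panel$meta, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  toy <- c(t1 = "ACGTACGTACGTACGTACGT", t2 = "ACGTACGTACGTACGTACGA",
           t3 = "ACGTACGGACGTACGTACGA", t4 = "ACTTACGGACGTACGTACGA")
  p <- file.path(dir, "toy_alignment.fasta")
  write_fasta(toy, p)
  paths <- c(paths, p)
  invisible(paths)
}
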