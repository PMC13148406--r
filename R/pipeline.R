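#' Pipeline run configuration
#'
#' Collects everything a run needs: the marker profile directory, the input
#' sample files, the sequence type, thresholds, mode, and the single seed
#' from which every stochastic step (bootstrap, sCF quartet sampling) flows.
#'
#' @param marker_dir Directory of `.hmm` marker profiles.
#' @param input_files Named character vector: sample label -> FASTA path
#'   (peptide, or CDS when `seqtype = "cds"`). Unnamed vectors are labeled
#'   by file base name.
#' @param seqtype `"pep"` or `"cds"`.
#' @param threshold Bit-score floor, or `NULL` for per-marker gathering
#'   cutoffs (10-bit fallback).
#' @param min_taxa Minimum samples per marker (default 4).
#' @param top_n Markers kept after filtering (default all).
#' @param mode `"consensus"` or `"concat"`.
#' @param threads CPUs requested; [plan_search_workers()] decides the split.
#' @param seed Integer seed.
#' @param output_dir Where stage outputs are written.
#' @param checkpoint Path of the search checkpoint file (default
#'   `<output_dir>/search.ckpt`).
#' @param force Discard a parameter-mismatched checkpoint instead of
#'   refusing.
#' @return A `run_config`.
#' @export
run_config <- function(marker_dir, input_files, seqtype = c("pep", "cds"),
                       threshold = NULL, min_taxa = 4L, top_n = Inf,
                       mode = c("consensus", "concat"), threads = 1L,
                       seed = 1L, output_dir = tempfile("markerphylo_run_"),
                       checkpoint = NULL, force = FALSE) {
  seqtype <- match.arg(seqtype)
  mode <- match.arg(mode)
  if (is.null(names(input_files)))
    names(input_files) <- sub("\\.[^.]*(\\.gz)?$", "", basename(input_files))
  if (anyDuplicated(names(input_files)))
    stop("duplicate sample labels among input files", call. = FALSE)
  if (is.null(checkpoint)) checkpoint <- file.path(output_dir, "search.ckpt")
  structure(list(marker_dir = marker_dir, input_files = input_files,
                 seqtype = seqtype, threshold = threshold,
                 min_taxa = as.integer(min_taxa), top_n = top_n, mode = mode,
                 threads = as.integer(threads), seed = as.integer(seed),
                 output_dir = output_dir, checkpoint = checkpoint,
                 force = isTRUE(force)),
            class = "run_config")
}

# Read sample sequences as amino acids, translating CDS inputs (standard
# code); returns list(sample -> named AA vector), plus the raw CDS when
# translating (for codon back-threading).
load_samples <- function(cfg) {
  out <- list(aa = list(), cds = list())
  for (lbl in names(cfg$input_files)) {
    path <- cfg$input_files[[lbl]]
    if (identical(cfg$seqtype, "pep")) {
      out$aa[[lbl]] <- read_fasta_vector(path, type = "AA")
    } else {
      nt <- read_fasta_vector(path, type = "DNA")
      aa <- vapply(nt, function(s) {
        n <- nchar(s) - nchar(s) %% 3
        as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, 1, n)),
          if.fuzzy.codon = "solve"))
      }, character(1))
      aa <- gsub("\\*$", "", aa)
      keep <- !grepl("\\*", aa)
      out$aa[[lbl]] <- aa[keep]
      out$cds[[lbl]] <- nt[keep]
    }
  }
  out
}

#' Run the align stage
#'
#' The core of the pipeline: identifies orthologs by profile search against
#' the marker set (reusing checkpointed hits for byte-identical samples),
#' enforces single-copy orthology, extracts the hit sequences, aligns each
#' marker in profile match-state coordinates, and trims to
#' parsimony-informative sites. At least four samples are required for a
#' meaningful species tree. Intermediates (hit table, per-marker FASTA,
#' checkpoint) are written under `cfg$output_dir`.
#'
#' @param cfg A `run_config`.
#' @return List with `msas` (named list of trimmed `marker_alignment`s),
#'   `untrimmed`, `hits` (single-copy hit table), `checkpoint`, and `log`
#'   (per-stage counts).
#' @export
run_align <- function(cfg) {
  if (length(cfg$input_files) < 4L)
    stop("the pipeline requires a minimum of four samples (got ",
         length(cfg$input_files), ")", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  mdb <- load_marker_dir(cfg$marker_dir)
  fp <- params_fingerprint(mdb$digest, cfg$threshold, cfg$seqtype)
  ckpt <- if (file.exists(cfg$checkpoint)) load_checkpoint(cfg$checkpoint)
    else NULL
  diff <- checkpoint_diff(ckpt, cfg$input_files, fp, force = cfg$force)
  if (is.null(ckpt) ||
      (!identical(ckpt$params_fingerprint, fp) && cfg$force)) {
    ckpt <- new_checkpoint(mdb$digest, cfg$threshold, cfg$seqtype)
  }
  plan <- plan_search_workers(cfg$threads)
  samples <- load_samples(cfg)

  new_entries <- list()
  for (lbl in names(diff$to_search)) {
    hits <- search_sample(mdb$markers, samples$aa[[lbl]], sample_id = lbl,
                          threshold = cfg$threshold)
    new_entries[[diff$hashes[[lbl]]]] <- list(labels = lbl, hits = hits)
  }
  ckpt <- merge_checkpoint(ckpt, new_entries)
  save_checkpoint(ckpt, cfg$checkpoint)

  all_hits <- hits_from_checkpoint(ckpt, diff$hashes)
  sc_hits <- enforce_single_copy(all_hits)
  keep <- select_markers(sc_hits, min_taxa = cfg$min_taxa)
  sc_hits <- sc_hits[sc_hits$marker_id %in% keep, , drop = FALSE]
  write_hit_table(sc_hits, file.path(cfg$output_dir, "hits.tsv"))

  seq_groups <- extract_hit_sequences(samples$aa, sc_hits)
  msas <- list()
  untrimmed <- list()
  kept_cols <- list()
  aln_dir <- file.path(cfg$output_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (mk in names(seq_groups)) {
    al <- align_to_profile(mdb$markers[[mk]], seq_groups[[mk]])
    tr <- trim_parsimony_informative(al)
    trimmed <- tr$trimmed
    if (identical(cfg$seqtype, "cds")) {
      # peptide-space trim mask carries over to codons by column triple
      cds_for <- vapply(names(seq_groups[[mk]]), function(lbl) {
        sid <- sc_hits$seq_id[sc_hits$marker_id == mk &
                                sc_hits$sample_id == lbl]
        samples$cds[[lbl]][[sid]]
      }, character(1))
      al <- backthread_codons(al, cds_for)
      idx <- as.vector(rbind(3L * tr$kept - 2L, 3L * tr$kept - 1L,
                             3L * tr$kept))
      trimmed <- marker_alignment(al$matrix[, idx, drop = FALSE],
                                  marker_id = mk, seqtype = "cds-codon",
                                  column_source = idx)
    }
    untrimmed[[mk]] <- al
    msas[[mk]] <- trimmed
    kept_cols[[mk]] <- tr$kept
    write_fasta_vector(alignment_strings(al),
                       file.path(aln_dir, paste0(mk, ".aln.faa")),
                       type = if (identical(cfg$seqtype, "pep")) "AA" else "DNA")
    write_fasta_vector(alignment_strings(trimmed),
                       file.path(aln_dir, paste0(mk, ".trim.faa")),
                       type = if (identical(cfg$seqtype, "pep")) "AA" else "DNA")
  }
  kept_df <- data.frame(
    marker_id = rep(names(kept_cols), lengths(kept_cols)),
    column = unlist(kept_cols), row.names = NULL)
  utils::write.table(kept_df, file.path(cfg$output_dir, "kept_columns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(msas = msas, untrimmed = untrimmed, hits = sc_hits, checkpoint = ckpt,
       log = list(n_samples = length(cfg$input_files),
                  n_searched = length(diff$to_search),
                  n_reused = length(diff$reusable),
                  n_removed = length(diff$removed),
                  worker_plan = plan,
                  n_markers_kept = length(keep)))
}

#' Run the filter stage
#'
#' Builds a gene tree per trimmed marker alignment, scores each marker by
#' treeness over RCV, ranks them, and keeps the best `top_n` (default all).
#' The score table is written to `<output_dir>/marker_scores.tsv`.
#'
#' @param cfg A `run_config`.
#' @param msas Trimmed alignments from [run_align()].
#' @return List with `selected` (named list of `marker_alignment`s, best
#'   first), `scores` (data frame with `rank`), `gene_trees`.
#' @export
run_filter <- function(cfg, msas) {
  usable <- msas[vapply(msas, function(m)
    ncol(m$matrix) >= 1L && nrow(m$matrix) >= 3L, logical(1))]
  gene_trees <- list()
  scores <- list()
  for (mk in names(usable)) {
    gt <- build_gene_tree(usable[[mk]])
    gene_trees[[mk]] <- gt
    scores[[mk]] <- score_marker(usable[[mk]], gene_tree = gt)
  }
  scores <- do.call(rbind, c(scores, make.row.names = FALSE))
  ids <- rank_markers(scores, cfg$top_n)
  scores <- scores[match(ids, scores$marker_id), , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scores, file.path(cfg$output_dir, "marker_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(selected = usable[ids], scores = scores, gene_trees = gene_trees[ids])
}

#' Run the tree stage
#'
#' Consensus mode infers per-marker gene trees and a quartet-maximizing
#' species tree; concat mode builds the supermatrix (written as FASTA with a
#' RAxML-style partition file for external ML tools), infers a
#' distance-based tree, and annotates nonparametric bootstrap support and
#' site concordance factors. The species tree is written as newick.
#'
#' @param cfg A `run_config`.
#' @param msas Named list of (filtered) trimmed alignments.
#' @param gene_trees Optional precomputed gene trees (consensus mode).
#' @return List with `tree` (a `phylo`), and in concat mode `supermatrix`,
#'   `support` and `scf` tables.
#' @export
run_tree <- function(cfg, msas, gene_trees = NULL) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- sort(unique(unlist(lapply(msas, function(m) rownames(m$matrix)))))
  if (length(taxa) < 4L)
    stop("fewer than four taxa remain across markers", call. = FALSE)
  if (identical(cfg$mode, "consensus")) {
    if (is.null(gene_trees))
      gene_trees <- lapply(msas, build_gene_tree)
    tree <- infer_consensus_tree(gene_trees)
    ape::write.tree(tree, file.path(cfg$output_dir, "species_consensus.nwk"))
    return(list(tree = tree, gene_trees = gene_trees))
  }
  sm <- concat_supermatrix(msas, taxa = taxa)
  write_fasta_vector(alignment_strings(sm$alignment),
                     file.path(cfg$output_dir, "supermatrix.fasta"),
                     type = if (identical(sm$alignment$seqtype, "pep"))
                       "AA" else "DNA")
  write_partition_file(sm, file.path(cfg$output_dir, "supermatrix.partitions"))
  tree <- bootstrap_support(sm, B = 100L, seed = cfg$seed)
  scf <- site_concordance(tree, sm, q = 100L, seed = cfg$seed + 1L)
  support <- attr(tree, "support")
  utils::write.table(support, file.path(cfg$output_dir, "branch_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scf, file.path(cfg$output_dir, "site_concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(tree, file.path(cfg$output_dir, "species_concat.nwk"))
  list(tree = tree, supermatrix = sm, support = support, scf = scf)
}
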