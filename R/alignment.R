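#' Marker alignments
#'
#' A `marker_alignment` is a fixed-width multiple sequence alignment of one
#' marker across samples, stored as a character matrix of single residues
#' (gap `"-"`), with rownames the sample labels. After profile alignment the
#' columns are the profile's match states 1..M; after trimming,
#' `column_source` records each kept column's original match-state index.
#'
#' @param mat Character matrix of single residues, rownames = taxa.
#' @param marker_id Marker identifier.
#' @param seqtype `"pep"` or `"cds-codon"`.
#' @param column_source Integer vector, per-column origin index (optional).
#' @return An object of class `marker_alignment`.
#' @export
marker_alignment <- function(mat, marker_id = "marker", seqtype = "pep",
                             column_source = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon labels in alignment", call. = FALSE)
  if (is.null(column_source)) column_source <- seq_len(ncol(mat))
  structure(list(marker_id = marker_id, seqtype = seqtype, matrix = mat,
                 column_source = as.integer(column_source)),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s: %d taxa x %d columns (%s)\n",
              x$marker_id, nrow(x$matrix), ncol(x$matrix), x$seqtype))
  invisible(x)
}

# Accept a marker_alignment, a character matrix, or a character vector of
# equal-length aligned strings.
as_alignment_matrix <- function(x) {
  if (inherits(x, "marker_alignment")) return(x$matrix)
  if (is.matrix(x)) return(x)
  if (is.character(x)) {
    if (length(unique(nchar(x))) != 1L)
      stop("aligned sequences must have equal length", call. = FALSE)
    mat <- do.call(rbind, strsplit(x, ""))
    rownames(mat) <- names(x)
    return(mat)
  }
  stop("cannot interpret object as an alignment", call. = FALSE)
}

alignment_strings <- function(msa) {
  apply(as_alignment_matrix(msa), 1L, paste, collapse = "")
}

#' Extract the sequences behind surviving hits
#'
#' Pulls, for every (marker, sample) cell of a hit table, the hit sequence
#' from that sample's FASTA file and relabels it with the sample label. Run
#' after [enforce_single_copy()], so each cell holds exactly one hit.
#'
#' @param fasta_files Named character vector: sample label -> FASTA path.
#'   (Alternatively a named list of named sequence vectors, keyed by sample.)
#' @param hits A hit table as returned by [search_sample()].
#' @return Named list: marker id -> named character vector of sequences
#'   (names are sample labels).
#' @export
extract_hit_sequences <- function(fasta_files, hits) {
  if (anyDuplicated(names(fasta_files)))
    stop("duplicate sample labels among input files", call. = FALSE)
  seqs_by_sample <- lapply(fasta_files, function(f) {
    if (is.character(f) && length(f) == 1L && is.null(names(f)))
      read_fasta_vector(f) else f
  })
  out <- list()
  for (marker in sort(unique(hits$marker_id))) {
    mh <- hits[hits$marker_id == marker, , drop = FALSE]
    recs <- character(0)
    for (r in seq_len(nrow(mh))) {
      smp <- mh$sample_id[r]
      pool <- seqs_by_sample[[smp]]
      if (is.null(pool))
        stop(sprintf("no input file for sample '%s'", smp), call. = FALSE)
      s <- if (mh$seq_id[r] %in% names(pool)) pool[[mh$seq_id[r]]] else NULL
      if (is.null(s) || is.na(s))
        stop(sprintf("sequence '%s' not found in sample '%s'",
                     mh$seq_id[r], smp), call. = FALSE)
      recs[smp] <- s
    }
    out[[marker]] <- recs
  }
  out
}

#' Align sequences to a marker profile in match-state coordinates
#'
#' Threads each sequence through its Viterbi path against the profile: column
#' `k` of the result holds the residue emitted at match state `k`, or `"-"`
#' when the path deleted node `k`. Insert-state residues are discarded, so
#' every output row has width `M` regardless of input lengths (the profile
#' equivalent of hmmalign's match-column output).
#'
#' @param model A `profile_hmm`.
#' @param seqs Named character vector of (unaligned) sequences; names become
#'   taxa labels.
#' @param seqtype Recorded on the result, default `"pep"`.
#' @return A `marker_alignment` of width `model$M`.
#' @export
align_to_profile <- function(model, seqs, seqtype = "pep") {
  if (length(seqs) < 2L)
    stop("need at least two sequences to align", call. = FALSE)
  rows <- matrix("-", length(seqs), model$M,
                 dimnames = list(names(seqs), NULL))
  drop <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    vt <- viterbi(model, seqs[[i]])
    if (!is.finite(vt$bit_score)) { drop[i] <- TRUE; next }
    chars <- strsplit(seqs[[i]], "")[[1]]
    has <- !is.na(vt$match_residue)
    rows[i, has] <- chars[vt$match_residue[has]]
  }
  if (any(drop)) {
    warning(sprintf("dropped %d sequence(s) that failed to align to %s",
                    sum(drop), model$marker_id))
    rows <- rows[!drop, , drop = FALSE]
  }
  marker_alignment(rows, marker_id = model$marker_id, seqtype = seqtype)
}

#' Trim an alignment to its parsimony-informative sites
#'
#' A column is parsimony-informative when it shows at least two distinct
#' non-gap, non-ambiguous residue states, each present in at least two rows.
#' All other columns are removed. Ambiguity codes (X/B/Z/... for protein,
#' N/IUPAC for nucleotide) count as missing. Trimming is idempotent.
#'
#' @param msa A `marker_alignment`.
#' @return List with `trimmed` (the reduced `marker_alignment`, whose
#'   `column_source` maps back to the input columns) and `kept` (1-based
#'   ascending indices of retained columns).
#' @export
trim_parsimony_informative <- function(msa) {
  mat <- as_alignment_matrix(msa)
  seqtype <- if (inherits(msa, "marker_alignment")) msa$seqtype else "pep"
  alphabet <- if (identical(seqtype, "pep")) "amino20" else "dna4"
  valid <- alphabet_residues(alphabet)
  kept <- which(vapply(seq_len(ncol(mat)), function(j) {
    obs <- toupper(mat[, j])
    obs <- obs[obs %in% valid]
    if (length(obs) < 4L) return(FALSE)
    tab <- table(obs)
    sum(tab >= 2L) >= 2L
  }, logical(1)))
  src <- if (inherits(msa, "marker_alignment")) msa$column_source
    else seq_len(ncol(mat))
  trimmed <- marker_alignment(
    mat[, kept, drop = FALSE],
    marker_id = if (inherits(msa, "marker_alignment")) msa$marker_id else "marker",
    seqtype = seqtype, column_source = src[kept]
  )
  list(trimmed = trimmed, kept = as.integer(kept))
}

#' Back-thread codons onto a peptide alignment
#'
#' Replaces every aligned amino-acid column by the corresponding codon triple
#' from each taxon's coding sequence; peptide gaps become `"---"`. A trailing
#' stop codon in the CDS is tolerated and dropped. Translating the result
#' codon-by-codon reproduces the gapped peptide rows.
#'
#' @param pep_msa A peptide `marker_alignment`.
#' @param cds Named character vector: taxon -> nucleotide coding sequence.
#' @param allow_internal_stop Keep taxa whose CDS contains an internal stop
#'   codon (default `FALSE`: error).
#' @return A `marker_alignment` with `seqtype = "cds-codon"` and width
#'   `3 * ncol(pep_msa)`.
#' @export
backthread_codons <- function(pep_msa, cds, allow_internal_stop = FALSE) {
  mat <- as_alignment_matrix(pep_msa)
  out <- matrix("-", nrow(mat), 3L * ncol(mat),
                dimnames = list(rownames(mat), NULL))
  stops <- c("TAA", "TAG", "TGA")
  for (tx in rownames(mat)) {
    nt <- toupper(gsub("\\s", "", cds[[tx]]))
    if (is.null(nt) || is.na(nt))
      stop(sprintf("no coding sequence supplied for taxon '%s'", tx),
           call. = FALSE)
    n_res <- sum(mat[tx, ] != "-")
    if (nchar(nt) == 3L * (n_res + 1L) &&
        substr(nt, nchar(nt) - 2L, nchar(nt)) %in% stops)
      nt <- substr(nt, 1L, nchar(nt) - 3L)
    if (nchar(nt) != 3L * n_res)
      stop(sprintf(
        "taxon '%s': CDS length %d does not match 3 x %d aligned residues",
        tx, nchar(nt), n_res), call. = FALSE)
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    if (!allow_internal_stop && any(codons %in% stops))
      stop(sprintf("taxon '%s': internal stop codon in CDS", tx),
           call. = FALSE)
    ci <- 0L
    for (j in seq_len(ncol(mat))) {
      if (mat[tx, j] != "-") {
        ci <- ci + 1L
        out[tx, (3L * j - 2L):(3L * j)] <- strsplit(codons[ci], "")[[1]]
      }
    }
  }
  src <- if (inherits(pep_msa, "marker_alignment")) pep_msa$column_source
    else seq_len(ncol(mat))
  marker_alignment(out,
                   marker_id = if (inherits(pep_msa, "marker_alignment"))
                     pep_msa$marker_id else "marker",
                   seqtype = "cds-codon",
                   column_source = as.integer(rbind(3L * src - 2L,
                                                    3L * src - 1L, 3L * src)))
}
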