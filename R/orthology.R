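#' Enforce strict single-copy orthology
#'
#' Any sample exhibiting multiple passing hits to the same marker profile is
#' excluded for that marker: the whole (marker, sample) cell is removed,
#' because multiple copies indicate duplication or contamination and the true
#' ortholog cannot be told apart. Cells with exactly one hit pass through
#' unchanged, so the operation is idempotent and only ever removes rows.
#'
#' @param hits A hit table (data frame with at least `marker_id`,
#'   `sample_id`).
#' @return The filtered hit table.
#' @export
enforce_single_copy <- function(hits) {
  if (!nrow(hits)) return(hits)
  key <- paste(hits$marker_id, hits$sample_id, sep = "\r")
  counts <- table(key)
  keep <- key %in% names(counts)[counts == 1L]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select markers with sufficient taxon coverage
#'
#' Retains markers represented (after single-copy filtering) in at least
#' `min_taxa` samples. Species-tree inference needs at least four taxa, so
#' the default floor is 4.
#'
#' @param hits A single-copy hit table.
#' @param min_taxa Minimum number of samples per marker (default 4).
#' @return Character vector of retained marker ids, sorted.
#' @export
select_markers <- function(hits, min_taxa = 4L) {
  cov <- tapply(hits$sample_id, hits$marker_id,
                function(s) length(unique(s)))
  keep <- sort(names(cov)[cov >= min_taxa])
  if (!length(keep))
    stop("no marker is represented in >= ", min_taxa, " samples; ",
         "consider a marker set better matched to these genomes",
         call. = FALSE)
  keep
}

# ---- checkpoint -------------------------------------------------------------

CHECKPOINT_FORMAT_VERSION <- 1L

#' Content hash of a sample file
#'
#' SHA-256 digest of the raw file bytes. Hits are associated with samples by
#' this digest rather than by file name or path, so byte-identical files are
#' recognised wherever they live and checkpoints stay portable and shareable.
#' Compressed inputs are hashed as stored, not decompressed.
#'
#' @param path File path.
#' @return Lower-case hex digest string.
#' @export
content_hash <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  digest::digest(path, algo = "sha256", file = TRUE)
}

params_fingerprint <- function(marker_digest, threshold, seqtype) {
  digest::digest(list(marker_digest = marker_digest,
                      threshold = threshold, seqtype = seqtype),
                 algo = "sha256")
}

#' Create an empty search checkpoint
#'
#' @param marker_digest Digest identifying the marker set searched.
#' @param threshold Reporting threshold in force (`NULL` for per-marker
#'   gathering cutoffs).
#' @param seqtype `"pep"` or `"cds"`.
#' @return A `checkpoint` object.
#' @export
new_checkpoint <- function(marker_digest = "", threshold = NULL,
                           seqtype = "pep") {
  structure(list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    params_fingerprint = params_fingerprint(marker_digest, threshold, seqtype),
    entries = list()
  ), class = "checkpoint")
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf("<checkpoint> v%d, %d sample entr%s\n", x$format_version,
              length(x$entries), if (length(x$entries) == 1) "y" else "ies"))
  invisible(x)
}

#' Classify input samples against a checkpoint
#'
#' Partitions the run's input files into those whose search results can be
#' reused (content hash already present in the checkpoint), those that must
#' be searched, and checkpoint entries with no matching input file (whose
#' hits are dropped from this run but stay in the checkpoint). Renamed but
#' byte-identical files are reusable.
#'
#' @param ckpt A `checkpoint` or `NULL` (everything is searched).
#' @param samples Named character vector: sample label -> file path.
#' @param params_fingerprint Fingerprint of the current run parameters.
#' @param force With a fingerprint mismatch, `TRUE` discards the checkpoint
#'   and re-searches everything; `FALSE` (default) refuses.
#' @return List with `to_search` (label -> path), `reusable` (label -> hash)
#'   and `removed` (hashes present only in the checkpoint).
#' @export
checkpoint_diff <- function(ckpt, samples, params_fingerprint = NULL,
                            force = FALSE) {
  hashes <- vapply(samples, content_hash, character(1))
  if (is.null(ckpt))
    return(list(to_search = samples, reusable = character(0),
                removed = character(0), hashes = hashes))
  if (!is.null(params_fingerprint) &&
      !identical(ckpt$params_fingerprint, params_fingerprint)) {
    if (!force)
      stop("checkpoint was written under different search parameters ",
           "(marker set, threshold or sequence type); rerun with force ",
           "to discard it", call. = FALSE)
    return(list(to_search = samples, reusable = character(0),
                removed = character(0), hashes = hashes))
  }
  known <- names(ckpt$entries)
  reuse <- hashes[hashes %in% known]
  list(to_search = samples[!hashes %in% known],
       reusable = reuse,
       removed = setdiff(known, hashes),
       hashes = hashes)
}

#' Merge freshly searched hits into a checkpoint
#'
#' Adds one entry per newly searched sample, keyed by content hash. Merging
#' the same results twice is a no-op. A hash already present under a
#' different label keeps both labels (byte-identical files are one sample).
#'
#' @param ckpt A `checkpoint`.
#' @param new_hits Named list: content hash -> list(label, hits data frame).
#' @return The updated `checkpoint`.
#' @export
merge_checkpoint <- function(ckpt, new_hits) {
  for (h in names(new_hits)) {
    entry <- new_hits[[h]]
    if (!is.null(ckpt$entries[[h]])) {
      old <- ckpt$entries[[h]]
      labels <- union(old$labels, entry$labels)
      if (!setequal(old$labels, entry$labels))
        warning(sprintf("hash %s seen under labels %s; keeping all",
                        substr(h, 1, 12), paste(labels, collapse = ", ")))
      ckpt$entries[[h]]$labels <- labels
    } else {
      ckpt$entries[[h]] <- list(labels = entry$labels, hits = entry$hits)
    }
  }
  ckpt$entries <- ckpt$entries[order(names(ckpt$entries))]
  ckpt
}

#' Save / load a checkpoint
#'
#' The on-disk format is a one-line JSON header (format version and
#' parameter fingerprint) followed by one JSON line per sample entry: its
#' content hash, sample label(s), and hit rows. Plain text, diff-able, and
#' independent of file paths.
#'
#' @param ckpt A `checkpoint`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `checkpoint`.
#' @export
save_checkpoint <- function(ckpt, path) {
  hdr <- jsonlite::toJSON(list(format_version = ckpt$format_version,
                               params_fingerprint = ckpt$params_fingerprint),
                          auto_unbox = TRUE)
  body <- vapply(names(ckpt$entries), function(h) {
    e <- ckpt$entries[[h]]
    jsonlite::toJSON(list(hash = h, labels = e$labels,
                          hits = e$hits), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(as.integer(hdr$format_version), CHECKPOINT_FORMAT_VERSION))
    stop("unsupported checkpoint format version: ", hdr$format_version,
         call. = FALSE)
  ckpt <- structure(list(format_version = CHECKPOINT_FORMAT_VERSION,
                         params_fingerprint = hdr$params_fingerprint,
                         entries = list()), class = "checkpoint")
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    e <- jsonlite::fromJSON(ln)
    hits <- as.data.frame(e$hits, stringsAsFactors = FALSE)
    if (!nrow(hits)) hits <- empty_hits()
    ckpt$entries[[e$hash]] <- list(labels = e$labels, hits = hits)
  }
  ckpt
}

# Assemble the run's hit table from checkpoint entries for the current
# label -> hash mapping (labels in the hits are rewritten to the run labels).
hits_from_checkpoint <- function(ckpt, label_hashes) {
  rows <- lapply(names(label_hashes), function(lbl) {
    e <- ckpt$entries[[label_hashes[[lbl]]]]
    if (is.null(e) || !nrow(e$hits)) return(NULL)
    h <- e$hits
    h$sample_id <- lbl
    h
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$marker_id, out$sample_id, out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a hit table as TSV
#'
#' @param hits Hit table data frame.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
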