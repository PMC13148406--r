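# log-odds matrices handed to the C++ kernels; -Inf encodes probability 0
model_lodds <- function(model) {
  lnull <- log(model$null_freq)
  list(
    match = log(model$match_emission) - rep(lnull, each = model$M),
    ins   = log(model$insert_emission) - rep(lnull, each = model$M),
    tr    = log(model$transitions)
  )
}

#' Score a sequence against a profile HMM (Viterbi)
#'
#' Finds the maximum-probability glocal alignment of a sequence to the
#' profile: the model is traversed in full through match/delete states while
#' flanking residues are absorbed by free loop states emitting at the null
#' frequency. The bit score is the log base-2 odds of the best path against
#' the null model.
#'
#' @param model A `profile_hmm`.
#' @param seq A single residue string over the model's alphabet.
#' @return A list with `bit_score`, `state_path` (character vector of states
#'   `"B"`, `"Mk"`, `"Ik"`, `"Dk"`, `"N"`/`"C"` flank emissions, `"E"`),
#'   `match_residue` (for `k` in `1..M`, the 1-based sequence index emitted
#'   at match state `k`, or `NA` if the path deleted node `k`), and
#'   `model_span` (the 1-based match-state range, here always `c(1, M)`).
#' @seealso [forward_bits()] for the all-paths score.
#' @export
viterbi <- function(model, seq) {
  stopifnot(inherits(model, "profile_hmm"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be a single non-empty residue string", call. = FALSE)
  codes <- encode_seq(seq, model$alphabet)
  lo <- model_lodds(model)
  out <- viterbi_lodds_cpp(lo$match, lo$ins, lo$tr, codes)
  L <- length(codes)
  lab <- character(length(out$type))
  lab[out$type == 0L] <- paste0("M", out$pos[out$type == 0L])
  lab[out$type == 1L] <- paste0("I", out$pos[out$type == 1L])
  lab[out$type == 2L] <- paste0("D", out$pos[out$type == 2L])
  lab[out$type == 3L] <- "I0"
  emitted <- out$res[out$type %in% c(0L, 1L, 3L)]
  first_core <- if (length(emitted)) min(emitted) else Inf
  last_core <- if (length(emitted)) max(emitted) else -Inf
  n_flank <- if (is.finite(first_core)) first_core - 1L else L
  c_flank <- if (is.finite(last_core)) L - last_core else 0L
  path <- c("B", rep("N", n_flank), lab, rep("C", c_flank), "E")
  mres <- rep(NA_integer_, model$M)
  mm <- out$type == 0L
  mres[out$pos[mm]] <- out$res[mm]
  list(bit_score = out$score / log(2), state_path = path,
       match_residue = mres, model_span = c(1L, model$M))
}

#' Score a sequence against a profile HMM (forward)
#'
#' Total log base-2 odds of the sequence under the profile versus the null
#' model, summed over all glocal alignments (log-sum-exp over paths). Always
#' at least the Viterbi bit score.
#'
#' @inheritParams viterbi
#' @return The forward bit score (a single number).
#' @export
forward_bits <- function(model, seq) {
  stopifnot(inherits(model, "profile_hmm"))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be a single non-empty residue string", call. = FALSE)
  codes <- encode_seq(seq, model$alphabet)
  lo <- model_lodds(model)
  forward_lodds_cpp(lo$match, lo$ins, lo$tr, codes) / log(2)
}

#' Search a sample's sequences against a set of marker profiles
#'
#' Scores every sequence of a proteome (or translated CDS set) against every
#' profile with the forward algorithm and reports all pairs passing the
#' reporting threshold. Multiple passing sequences for one marker are all
#' retained here; single-copy enforcement happens downstream
#' ([enforce_single_copy()]). A cheap Viterbi bound prefilters clearly
#' failing sequences before the exact forward score is computed (forward
#' never falls below Viterbi, so passing sequences survive the prefilter).
#'
#' The default threshold for a marker is its gathering cutoff (`GA` line)
#' when present, else a flat bit-score floor of 10 bits.
#'
#' @param markers Named list of `profile_hmm` objects.
#' @param proteome Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param sample_id Label recorded in the hits; defaults to the file base
#'   name without extension.
#' @param threshold Bit-score floor overriding gathering cutoffs, or `NULL`
#'   (default) for per-marker gathering cutoffs with a 10-bit fallback.
#' @return A hit table: data frame with columns `sample_id`, `seq_id`,
#'   `marker_id`, `bit_score`, `span_start`, `span_end`.
#' @export
search_sample <- function(markers, proteome, sample_id = NULL,
                          threshold = NULL) {
  if (is.character(proteome) && length(proteome) == 1L && is.null(names(proteome))) {
    if (!file.exists(proteome))
      stop("no such FASTA file: ", proteome, call. = FALSE)
    if (is.null(sample_id))
      sample_id <- sub("\\.(fa|faa|fasta|fna|pep)(\\.gz)?$", "",
                       basename(proteome))
    seqs <- read_fasta_vector(proteome)
  } else {
    seqs <- proteome
  }
  if (!length(seqs)) stop("empty proteome", call. = FALSE)
  if (is.null(sample_id)) sample_id <- "sample"
  alph <- markers[[1L]]$alphabet
  coded <- lapply(seqs, encode_seq, alphabet = alph)

  out <- list()
  for (m in markers) {
    floor_bits <- if (!is.null(threshold)) threshold
      else if (!is.null(m$gathering_cutoff)) m$gathering_cutoff else 10
    lo <- model_lodds(m)
    bits <- batch_forward_cpp(lo$match, lo$ins, lo$tr, coded,
                              floor_bits * log(2), 30 * log(2)) / log(2)
    pass <- which(bits >= floor_bits)
    if (length(pass)) {
      out[[m$marker_id]] <- data.frame(
        sample_id = sample_id, seq_id = names(seqs)[pass],
        marker_id = m$marker_id, bit_score = bits[pass],
        span_start = 1L, span_end = m$M, stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
    else empty_hits()
  hits
}

empty_hits <- function() {
  data.frame(sample_id = character(), seq_id = character(),
             marker_id = character(), bit_score = numeric(),
             span_start = integer(), span_end = integer(),
             stringsAsFactors = FALSE)
}

#' Plan parallel search worker allocation
#'
#' Mirrors the pipeline's dynamic CPU allocation rule: with fewer than eight
#' CPUs a single search instance uses all available cores; with eight or
#' more, the pool is divided into `floor(n_cpus / 4)` parallel instances of
#' four cores each (running one large search instance on many cores scales
#' poorly, so the pool is split instead).
#'
#' @param n_cpus Number of CPUs requested (positive integer).
#' @return A list with `n_instances` and `cores_per_instance`.
#' @export
plan_search_workers <- function(n_cpus) {
  if (!is.numeric(n_cpus) || length(n_cpus) != 1L || is.na(n_cpus) ||
      n_cpus < 1 || n_cpus != floor(n_cpus))
    stop("n_cpus must be a positive integer", call. = FALSE)
  n_cpus <- as.integer(n_cpus)
  if (n_cpus < 8L) list(n_instances = 1L, cores_per_instance = n_cpus)
  else list(n_instances = n_cpus %/% 4L, cores_per_instance = 4L)
}
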