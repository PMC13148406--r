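#' Build a profile HMM from a seed alignment
#'
#' Estimates match-state emissions from alignment columns by maximum
#' likelihood with a flat additive pseudocount: columns with a gap fraction
#' of at most 0.5 become match states, and the emission probability of
#' residue `a` at a match column is `(count_a + alpha) / (n_obs + K * alpha)`
#' where `K` is the alphabet size and `n_obs` the number of non-gap,
#' non-ambiguous residues observed in the column. Insert emissions are set to
#' the null frequencies and transitions to fixed defaults (M->M 0.9,
#' M->I 0.05, M->D 0.05; I->M 0.8, I->I 0.2; D->M 0.8, D->D 0.2; at the final
#' node the M->D and D->D mass is reassigned to the end state). This is a
#' seed-alignment profile builder in the BUSCO-marker mould, not a
#' full Dirichlet-mixture/entropy-weighted estimator.
#'
#' @param seed_alignment A [marker_alignment] (or plain character matrix of
#'   single residues with rownames) holding the seed MSA.
#' @param alpha Additive pseudocount, non-negative. Default 1.
#' @param alphabet Alphabet of the model; default `"amino20"`.
#' @param marker_id Marker name; defaults to the alignment's marker id.
#' @param null_freq Background frequencies; default uniform.
#' @return A `profile_hmm`.
#' @export
build_hmm <- function(seed_alignment, alpha = 1, alphabet = "amino20",
                      marker_id = NULL, null_freq = NULL) {
  mat <- as_alignment_matrix(seed_alignment)
  if (is.null(marker_id)) {
    marker_id <- if (inherits(seed_alignment, "marker_alignment"))
      seed_alignment$marker_id else "marker"
  }
  if (!nrow(mat) || !ncol(mat)) stop("empty seed alignment", call. = FALSE)
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  res <- alphabet_residues(alphabet)
  K <- length(res)
  if (is.null(null_freq)) null_freq <- rep(1 / K, K)

  is_gap <- mat == "-" | mat == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols))
    stop("seed alignment has no match columns (all columns >50% gaps)",
         call. = FALSE)
  M <- length(match_cols)
  match_emission <- matrix(0, M, K)
  for (j in seq_len(M)) {
    obs <- toupper(mat[, match_cols[j]])
    obs <- obs[obs %in% res]
    counts <- table(factor(obs, levels = res))
    match_emission[j, ] <- (as.numeric(counts) + alpha) /
      (length(obs) + K * alpha)
    if (alpha == 0) {  # guard: column of only ambiguity codes
      s <- sum(match_emission[j, ])
      if (s == 0) match_emission[j, ] <- null_freq
      else match_emission[j, ] <- match_emission[j, ] / s
    }
  }
  insert_emission <- matrix(rep(null_freq, each = M), M, K)
  transitions <- matrix(rep(c(0.9, 0.05, 0.05, 0.8, 0.2, 0.8, 0.2), each = M + 1L),
                        M + 1L, 7L)
  transitions[M + 1L, ] <- c(0.95, 0.05, 0, 0.8, 0.2, 1, 0)
  profile_hmm(marker_id, alphabet, match_emission, insert_emission,
              transitions, null_freq)
}
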