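#' Pairwise distances from an alignment
#'
#' Distances are computed over the columns where both rows carry unambiguous
#' residues. `p` is the raw mismatch fraction; `poisson` applies the
#' multiple-hit correction `d = -ln(1 - p)` (protein sequences); `jc69` the
#' nucleotide Jukes-Cantor correction `d = -(3/4) ln(1 - 4p/3)`. Saturated
#' pairs (beyond the model's domain) are capped at `max_dist` with a warning
#' rather than made infinite, so downstream tree building stays finite.
#'
#' @param msa A `marker_alignment` (or character matrix).
#' @param model `"p"`, `"poisson"`, or `"jc69"`.
#' @param max_dist Cap for saturated corrected distances (default 10).
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_distance <- function(msa, model = c("poisson", "p", "jc69"),
                              max_dist = 10) {
  model <- match.arg(model)
  mat <- as_alignment_matrix(msa)
  n <- nrow(mat)
  if (n < 2L) stop("need at least two rows", call. = FALSE)
  seqtype <- if (inherits(msa, "marker_alignment")) msa$seqtype else "pep"
  valid <- alphabet_residues(if (identical(seqtype, "pep")) "amino20" else "dna4")
  ok <- matrix(toupper(mat) %in% valid, n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    if (!any(shared))
      stop(sprintf("rows '%s' and '%s' share no comparable columns",
                   rownames(mat)[i], rownames(mat)[j]), call. = FALSE)
    p <- mean(mat[i, shared] != mat[j, shared])
    v <- switch(model,
      p = p,
      poisson = if (p >= 1) { saturated <- TRUE; max_dist }
        else min(-log(1 - p), max_dist),
      jc69 = if (p >= 0.75) { saturated <- TRUE; max_dist }
        else min(-0.75 * log(1 - 4 * p / 3), max_dist)
    )
    d[i, j] <- d[j, i] <- v
  }
  if (saturated)
    warning("saturated distance(s) capped at ", max_dist)
  d
}

#' Neighbor-joining gene tree
#'
#' Builds an unrooted neighbor-joining tree from a distance matrix (the
#' internal gene-tree builder used for marker scoring and supermatrix
#' trees). Negative estimated branch lengths are clamped to zero. Additive
#' matrices are recovered exactly.
#'
#' @param d Symmetric numeric distance matrix with taxa dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  if (nrow(d) < 3L) stop("need at least three taxa", call. = FALSE)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Distance-plus-parsimony gene tree
#'
#' The pipeline's internal tree builder: a neighbor-joining starting tree
#' from corrected pairwise distances, refined by nearest-neighbor-
#' interchange maximum parsimony, with branch lengths re-fit to the
#' distance matrix by unweighted least squares (negatives clamped to zero).
#'
#' The parsimony refinement matters because the pipeline trims alignments
#' to parsimony-informative sites before tree inference: distances measured
#' on such censored columns are systematically non-additive and can mislead
#' pure neighbor joining, whereas the parsimony criterion is invariant to
#' removing parsimony-uninformative sites.
#'
#' @param msa A (typically trimmed) `marker_alignment` with at least three
#'   rows.
#' @param model Distance model passed to [pairwise_distance()]; default
#'   chosen from the seqtype (`poisson` for peptide, `jc69` for codon).
#' @return An unrooted `phylo` with branch lengths.
#' @export
build_gene_tree <- function(msa, model = NULL) {
  if (is.null(model))
    model <- if (identical(msa$seqtype, "pep")) "poisson" else "jc69"
  d <- suppressWarnings(pairwise_distance(msa, model))
  tr <- nj_tree(d)
  if (ape::Ntip(tr) > 3L && ncol(msa$matrix) > 0L) {
    pd <- phangorn::phyDat(msa$matrix,
                           type = if (identical(msa$seqtype, "pep"))
                             "AA" else "DNA")
    tr <- phangorn::optim.parsimony(tr, pd, rearrangements = "NNI",
                                    trace = 0)
    tr <- phangorn::nnls.tree(d, tr, method = "unrooted")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Treeness of a phylogeny
#'
#' The fraction of total tree length contributed by internal branches:
#' `sum(internal) / sum(all)`. High treeness indicates strong tree-like
#' signal; a star tree has treeness 0. A tree of total length zero is
#' defined to have treeness 0 (with a warning).
#'
#' @param tree A `phylo` with non-negative branch lengths.
#' @return A number in `[0, 1]`.
#' @export
treeness <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  total <- sum(tree$edge.length)
  if (total == 0) {
    warning("tree has zero total branch length; treeness defined as 0")
    return(0)
  }
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  sum(tree$edge.length[internal]) / total
}

#' Relative composition variability (RCV) of an alignment
#'
#' The mean absolute deviation of per-taxon residue counts from the
#' alignment-wide mean, normalised by taxa x sites:
#' `sum_j sum_i |c_ij - mean_j(c)| / (n * t)` over residue states `j` and
#' taxa `i`, with `n` taxa and `t` sites. Gaps and ambiguity codes are
#' excluded from the counts. Zero iff every taxon has identical residue
#' counts; low values indicate compositional homogeneity.
#'
#' @param msa A `marker_alignment` (or character matrix).
#' @return A non-negative number.
#' @export
rcv <- function(msa) {
  mat <- as_alignment_matrix(msa)
  if (!nrow(mat) || !ncol(mat)) stop("empty alignment", call. = FALSE)
  seqtype <- if (inherits(msa, "marker_alignment")) msa$seqtype else "pep"
  valid <- alphabet_residues(if (identical(seqtype, "pep")) "amino20" else "dna4")
  counts <- t(apply(mat, 1L, function(r) {
    r <- toupper(r)
    table(factor(r[r %in% valid], levels = valid))
  }))
  colmeans <- colMeans(counts)
  sum(abs(sweep(counts, 2L, colmeans))) / (nrow(mat) * ncol(mat))
}

#' Score and rank markers by treeness / RCV
#'
#' `score_marker` computes, for one trimmed marker alignment, a gene tree
#' (neighbor joining on Poisson/JC69 distances unless one is supplied), its
#' treeness, the alignment's RCV, and the ratio `treeness / max(rcv, eps)`.
#' The epsilon guard (default 1e-9) makes perfectly homogeneous composition
#' (RCV 0) rank above every positive-RCV marker of equal treeness instead of
#' dividing by zero.
#'
#' @param msa A trimmed `marker_alignment`.
#' @param gene_tree Optional externally supplied gene tree (`phylo`); by
#'   default one is built with [nj_tree()].
#' @param eps Floor for the RCV denominator.
#' @return A one-row data frame: `marker_id`, `treeness`, `rcv`, `score`.
#' @export
score_marker <- function(msa, gene_tree = NULL, eps = 1e-9) {
  if (is.null(gene_tree)) {
    mdl <- if (identical(msa$seqtype, "pep")) "poisson" else "jc69"
    gene_tree <- nj_tree(pairwise_distance(msa, mdl))
  }
  tn <- treeness(gene_tree)
  rc <- rcv(msa)
  data.frame(marker_id = msa$marker_id, treeness = tn, rcv = rc,
             score = tn / max(rc, eps), stringsAsFactors = FALSE)
}

#' Rank markers and keep the top n
#'
#' Orders markers by descending treeness/RCV score, breaking ties
#' lexicographically by marker id, and returns at most `top_n` ids. By
#' default all markers are kept (filtering is opt-in: aggressive top-n
#' filtering can discard genuine signal).
#'
#' @param scores Data frame with columns `marker_id` and `score` (as rows
#'   from [score_marker()]).
#' @param top_n Maximum number of markers to keep; default all.
#' @return Character vector of marker ids, best first.
#' @export
rank_markers <- function(scores, top_n = Inf) {
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  ord <- order(-scores$score, scores$marker_id)
  ids <- scores$marker_id[ord]
  utils::head(ids, n = if (is.finite(top_n)) top_n else length(ids))
}
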