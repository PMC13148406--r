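# ---- bipartition utilities --------------------------------------------------

# Canonical string keys for the (optionally trivial) bipartitions of an
# unrooted tree: each split is keyed by the sorted tip labels of the side
# NOT containing the alphabetically first tip.
tree_splits <- function(tree, trivial = FALSE) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- tree$tip.label[idx]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sizes <- vapply(strsplit(keys, "[|]"), length, integer(1))
  lo <- if (trivial) 1L else 2L
  unique(keys[sizes >= lo & sizes <= length(tips) - lo])
}

split_key <- function(side, tips) {
  ref <- tips[1L]
  if (ref %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "|")
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference between the non-trivial bipartition
#' sets of two unrooted trees on the same tips, plus the conventional
#' normalisation by `2(n - 3)` (the maximum for binary trees).
#'
#' @param t1,t2 `phylo` trees with identical tip sets.
#' @return List with `raw` (integer) and `normalized` (in `[0, 1]` for
#'   binary trees).
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip sets", call. = FALSE)
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  n <- length(t1$tip.label)
  denom <- 2L * (n - 3L)
  list(raw = as.integer(raw),
       normalized = if (denom > 0) raw / denom else 0)
}

#' Assess monophyly of tip groups
#'
#' A group is monophyletic on an unrooted tree iff its tips form one side of
#' some (possibly trivial) bipartition; singleton groups are monophyletic by
#' convention.
#'
#' @param tree A `phylo`.
#' @param groups Named character vector: tip label -> group label. Every tip
#'   must be labeled.
#' @return Data frame with `group`, `n_tips`, `monophyletic`.
#' @export
check_monophyly <- function(tree, groups) {
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing))
    stop("unlabeled tip(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tips <- sort(tree$tip.label)
  splits <- tree_splits(tree, trivial = TRUE)
  out <- lapply(sort(unique(unname(groups[tree$tip.label]))), function(g) {
    members <- intersect(tree$tip.label, names(groups)[groups == g])
    mono <- length(members) <= 1L || length(members) >= length(tips) ||
      split_key(members, tips) %in% splits
    data.frame(group = g, n_tips = length(members), monophyletic = mono,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- supermatrix ------------------------------------------------------------

#' Concatenate marker alignments into a supermatrix
#'
#' Joins per-marker alignments (in sorted marker-id order) into one matrix
#' over the union of taxa; a taxon absent from a marker is filled with gaps
#' across that marker's partition. Partitions are recorded with 1-based
#' inclusive coordinates and tile the matrix exactly.
#'
#' @param msas List of `marker_alignment`s of one seqtype.
#' @param taxa Optional taxon ordering; default sorted union.
#' @return A `supermatrix`: list with `alignment` (a `marker_alignment`) and
#'   `partitions` (data frame `marker_id`, `start`, `end`).
#' @export
concat_supermatrix <- function(msas, taxa = NULL) {
  if (!length(msas)) stop("no alignments to concatenate", call. = FALSE)
  sq <- unique(vapply(msas, function(m) m$seqtype, character(1)))
  if (length(sq) != 1L)
    stop("conflicting seqtypes among alignments: ",
         paste(sq, collapse = ", "), call. = FALSE)
  ids <- vapply(msas, function(m) m$marker_id, character(1))
  msas <- msas[order(ids)]
  ids <- sort(ids)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(msas, function(m) rownames(m$matrix)))))
  widths <- vapply(msas, function(m) ncol(m$matrix), integer(1))
  total <- sum(widths)
  big <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  at <- 0L
  parts <- data.frame(marker_id = ids, start = integer(length(ids)),
                      end = integer(length(ids)), stringsAsFactors = FALSE)
  for (i in seq_along(msas)) {
    w <- widths[i]
    if (w > 0L) {
      rows <- intersect(taxa, rownames(msas[[i]]$matrix))
      big[rows, (at + 1L):(at + w)] <- msas[[i]]$matrix[rows, , drop = FALSE]
    }
    parts$start[i] <- at + 1L
    parts$end[i] <- at + w
    at <- at + w
  }
  structure(list(
    alignment = marker_alignment(big, marker_id = "supermatrix", seqtype = sq),
    partitions = parts
  ), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              nrow(x$alignment$matrix), ncol(x$alignment$matrix),
              nrow(x$partitions)))
  invisible(x)
}

#' Write / read a RAxML-style partition file
#'
#' One line per marker: `PROT, marker = start-end` (or `DNA,` for
#' nucleotide supermatrices), 1-based inclusive, for use by external
#' partitioned maximum-likelihood tools.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_partition_file <- function(sm, path) {
  kind <- if (identical(sm$alignment$seqtype, "pep")) "PROT" else "DNA"
  writeLines(sprintf("%s, %s = %d-%d", kind, sm$partitions$marker_id,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}

#' @rdname write_partition_file
#' @return `read_partition_file` returns the partitions data frame.
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- regmatches(lines,
                  regexec("^\\s*\\w+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)", lines))
  ok <- lengths(m) == 4L
  if (!all(ok)) stop("malformed partition line: ", lines[!ok][1], call. = FALSE)
  data.frame(marker_id = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

# ---- quartets ---------------------------------------------------------------

# cache for per-n quartet index tables and candidate topology profiles
.mp_cache <- new.env(parent = emptyenv())

quartet_index <- function(n) {
  key <- paste0("q", n)
  if (is.null(.mp_cache[[key]]))
    .mp_cache[[key]] <- utils::combn(n, 4L)
  .mp_cache[[key]]
}

# Induced quartet topologies of `tree` over positions of `universe` (sorted
# labels). Returns an integer vector over the quartet index: 1 = (ab|cd),
# 2 = (ac|bd), 3 = (ad|bc) in position order, 0 = unresolved, NA = tip absent.
quartet_profile <- function(tree, universe) {
  n <- length(universe)
  q <- quartet_index(n)
  prof <- rep(NA_integer_, ncol(q))
  pos <- match(tree$tip.label, universe)
  t2 <- tree
  t2$edge.length <- rep(1, nrow(tree$edge))
  D0 <- ape::cophenetic.phylo(t2)
  D <- matrix(NA_real_, n, n)
  D[pos, pos] <- D0[tree$tip.label, tree$tip.label]
  a <- q[1L, ]; b <- q[2L, ]; c <- q[3L, ]; d <- q[4L, ]
  s1 <- D[cbind(a, b)] + D[cbind(c, d)]
  s2 <- D[cbind(a, c)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, c)]
  have <- !is.na(s1) & !is.na(s2) & !is.na(s3)
  p <- integer(sum(have))
  m1 <- s1[have]; m2 <- s2[have]; m3 <- s3[have]
  mn <- pmin(m1, m2, m3)
  p[m1 == mn & m2 > mn & m3 > mn] <- 1L
  p[m2 == mn & m1 > mn & m3 > mn] <- 2L
  p[m3 == mn & m1 > mn & m2 > mn] <- 3L
  prof[have] <- p
  prof
}

# Accumulated quartet-pairing counts over a set of gene trees: a matrix
# n_quartets x 3 of how many gene trees resolve each quartet each way.
gene_quartet_counts <- function(gene_trees, universe) {
  n <- length(universe)
  q <- quartet_index(n)
  counts <- matrix(0L, ncol(q), 3L)
  for (gt in gene_trees) {
    prof <- quartet_profile(gt, universe)
    res <- which(!is.na(prof) & prof > 0L)
    if (length(res))
      counts[cbind(res, prof[res])] <- counts[cbind(res, prof[res])] + 1L
  }
  counts
}

#' Quartet score of a species tree against gene trees
#'
#' The number of induced 4-taxon topologies shared between the species tree
#' and the gene trees, summed over gene trees (the quartet-maximization
#' objective of coalescent-aware consensus methods). Only quartets resolved
#' in both trees count; gene-tree tips must be a subset of the species-tree
#' tips.
#'
#' @param species A `phylo` species tree.
#' @param gene_trees A list of `phylo` gene trees (or a `multiPhylo`).
#' @return Integer quartet score.
#' @export
quartet_score <- function(species, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  universe <- sort(species$tip.label)
  for (gt in gene_trees) {
    extra <- setdiff(gt$tip.label, universe)
    if (length(extra))
      stop("gene-tree tip(s) absent from species tree: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  counts <- gene_quartet_counts(gene_trees, universe)
  sp <- quartet_profile(species, universe)
  res <- which(sp > 0L)
  sum(counts[cbind(res, sp[res])])
}

# all unrooted binary topologies on `universe`, profiles cached per n
candidate_profiles <- function(n) {
  key <- paste0("cand", n)
  if (is.null(.mp_cache[[key]])) {
    universe <- paste0("t", seq_len(n))  # positional labels
    cands <- phangorn::allTrees(n, tip.label = universe)
    profs <- matrix(0L, length(cands), ncol(quartet_index(n)))
    for (i in seq_along(cands))
      profs[i, ] <- quartet_profile(cands[[i]], universe)
    .mp_cache[[key]] <- list(trees = cands, profiles = profs)
  }
  .mp_cache[[key]]
}

score_profile <- function(prof, counts) {
  res <- which(prof > 0L)
  sum(counts[cbind(res, prof[res])])
}

#' Infer a consensus species tree by quartet maximization
#'
#' Returns a species tree maximizing the quartet score against the gene
#' trees. For 8 or fewer taxa the search is exhaustive over all unrooted
#' binary topologies; beyond that, a hill climb over nearest-neighbor
#' interchanges from a distance-based starting tree finds a local optimum
#' (a desk-scale stand-in for large-sample quartet methods; an externally
#' computed species tree can be supplied to [quartet_score()] directly for
#' comparison).
#'
#' @param gene_trees List of `phylo` gene trees (tips may differ; at least
#'   four distinct tips overall).
#' @return A `phylo` species tree (no branch lengths; topology only).
#' @export
infer_consensus_tree <- function(gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("no gene trees", call. = FALSE)
  universe <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(universe)
  if (n < 4L) stop("need at least four distinct tips", call. = FALSE)
  counts <- gene_quartet_counts(gene_trees, universe)
  if (n <= 8L) {
    cand <- candidate_profiles(n)
    scores <- vapply(seq_len(nrow(cand$profiles)), function(i)
      score_profile(cand$profiles[i, ], counts), numeric(1))
    best <- cand$trees[[which.max(scores)]]
    best$tip.label <- universe[match(best$tip.label,
                                     paste0("t", seq_len(n)))]
    return(best)
  }
  # heuristic: NJ on mean topological distances, then NNI hill climb
  Dsum <- matrix(0, n, n, dimnames = list(universe, universe))
  Dn <- matrix(0, n, n, dimnames = list(universe, universe))
  for (gt in gene_trees) {
    t2 <- gt
    t2$edge.length <- rep(1, nrow(gt$edge))
    D0 <- ape::cophenetic.phylo(t2)
    lb <- gt$tip.label
    Dsum[lb, lb] <- Dsum[lb, lb] + D0[lb, lb]
    Dn[lb, lb] <- Dn[lb, lb] + 1
  }
  if (any(Dn == 0 & row(Dn) != col(Dn)))
    stop("some taxon pairs never co-occur in a gene tree", call. = FALSE)
  diag(Dn) <- 1
  cur <- ape::unroot(nj_tree(Dsum / Dn))
  cur$edge.length <- NULL
  cur_score <- score_profile(quartet_profile(cur, universe), counts)
  repeat {
    nbs <- phangorn::nni(cur)
    sc <- vapply(nbs, function(tr)
      score_profile(quartet_profile(tr, universe), counts), numeric(1))
    if (max(sc) <= cur_score) break
    cur <- nbs[[which.max(sc)]]
    cur_score <- max(sc)
  }
  cur
}

# ---- branch support ---------------------------------------------------------

default_tree_builder <- function(seqtype) {
  function(msa) build_gene_tree(msa)
}

# attach per-split percentages as node labels of `tree`
annotate_supports <- function(tree, values_by_key, fmt = "%.0f") {
  tips <- sort(tree$tip.label)
  ntip <- ape::Ntip(tree)
  lab <- rep("", tree$Nnode)
  pp <- ape::prop.part(tree)
  for (i in seq_along(pp)) {
    node <- ntip + i
    side <- tree$tip.label[pp[[i]]]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    key <- split_key(side, tips)
    v <- values_by_key[[key]]
    if (!is.null(v) && !is.na(v)) lab[i] <- sprintf(fmt, v)
  }
  tree$node.label <- lab
  tree
}

#' Nonparametric bootstrap support on a supermatrix tree
#'
#' Resamples supermatrix columns with replacement `B` times, rebuilds a tree
#' from each replicate with `builder`, and annotates each internal branch of
#' the point-estimate tree with the percentage of replicate trees containing
#' that bipartition. Deterministic for a given `seed`.
#'
#' @param sm A `supermatrix`.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param builder Function mapping a `marker_alignment` to a `phylo`;
#'   default: neighbor joining on corrected distances.
#' @return The point-estimate `phylo` with `node.label` holding support
#'   percentages and an attribute `"support"` (data frame split -> percent).
#' @export
bootstrap_support <- function(sm, B = 100L, seed = 1L, builder = NULL) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (is.null(builder)) builder <- default_tree_builder(sm$alignment$seqtype)
  main <- builder(sm$alignment)
  tips <- sort(main$tip.label)
  keys <- tree_splits(main)
  hit <- stats::setNames(numeric(length(keys)), keys)
  mat <- sm$alignment$matrix
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_msa <- marker_alignment(mat[, cols, drop = FALSE],
                                marker_id = "bootstrap",
                                seqtype = sm$alignment$seqtype)
    rt <- builder(rep_msa)
    rs <- tree_splits(rt)
    common <- intersect(keys, rs)
    hit[common] <- hit[common] + 1
  }
  pct <- 100 * hit / B
  out <- annotate_supports(main, as.list(pct))
  support <- data.frame(split = names(pct), support_pct = unname(pct),
                        stringsAsFactors = FALSE)
  attr(out, "support") <- support
  out
}

# ---- site concordance factor ------------------------------------------------

# tip sets of the four subtrees around each internal edge of a binary
# unrooted tree
internal_edge_contexts <- function(tree) {
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  adj <- vector("list", max(edge))
  for (r in seq_len(nrow(edge))) {
    adj[[edge[r, 1]]] <- c(adj[[edge[r, 1]]], edge[r, 2])
    adj[[edge[r, 2]]] <- c(adj[[edge[r, 2]]], edge[r, 1])
  }
  tips_from <- function(start, avoid) {
    seen <- c(avoid)
    stack <- start
    tips <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v <= ntip) tips <- c(tips, v)
      stack <- c(stack, setdiff(adj[[v]], seen))
    }
    tree$tip.label[tips]
  }
  ctx <- list()
  for (r in seq_len(nrow(edge))) {
    u <- edge[r, 1]; v <- edge[r, 2]
    if (u <= ntip || v <= ntip) next
    un <- setdiff(adj[[u]], v)
    vn <- setdiff(adj[[v]], u)
    if (length(un) != 2L || length(vn) != 2L) next  # only binary contexts
    ctx[[length(ctx) + 1L]] <- list(
      edge_row = r, u = u, v = v,
      A1 = tips_from(un[1], u), A2 = tips_from(un[2], u),
      B1 = tips_from(vn[1], v), B2 = tips_from(vn[2], v))
  }
  ctx
}

#' Site concordance factors
#'
#' For each internal branch, samples `q` quartets with one tip drawn from
#' each of the four subtrees surrounding the branch, and over the decisive
#' alignment sites (sites with exactly two residue states among the four
#' sampled rows, each state in two rows) computes the percentage supporting
#' the branch's own pairing. The sCF of the branch is the mean over sampled
#' quartets; branches where no sampled quartet has any decisive site are
#' reported as `NA`.
#'
#' @param tree A binary `phylo` whose tips are the supermatrix taxa.
#' @param sm A `supermatrix`.
#' @param q Quartets sampled per branch (default 100).
#' @param seed RNG seed.
#' @return Data frame per internal branch: `split` (canonical key), `scf`
#'   (percent or `NA`), `n_quartets` (quartets with decisive sites).
#' @export
site_concordance <- function(tree, sm, q = 100L, seed = 1L) {
  mat <- sm$alignment$matrix
  if (!setequal(rownames(mat), tree$tip.label))
    stop("tree tips and supermatrix taxa differ", call. = FALSE)
  valid <- alphabet_residues(
    if (identical(sm$alignment$seqtype, "pep")) "amino20" else "dna4")
  tips <- sort(tree$tip.label)
  ctx <- internal_edge_contexts(tree)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- lapply(ctx, function(cx) {
    vals <- numeric(0)
    for (s in seq_len(q)) {
      a1 <- mat[sample(cx$A1, 1L), ]; a2 <- mat[sample(cx$A2, 1L), ]
      b1 <- mat[sample(cx$B1, 1L), ]; b2 <- mat[sample(cx$B2, 1L), ]
      okc <- a1 %in% valid & a2 %in% valid & b1 %in% valid & b2 %in% valid
      conc <- a1 == a2 & b1 == b2 & a1 != b1
      d2 <- a1 == b1 & a2 == b2 & a1 != a2
      d3 <- a1 == b2 & a2 == b1 & a1 != a2
      decisive <- okc & (conc | d2 | d3)
      if (any(decisive))
        vals <- c(vals, 100 * sum(conc & okc) / sum(decisive))
    }
    key <- split_key(c(cx$A1, cx$A2), tips)
    data.frame(split = key,
               scf = if (length(vals)) mean(vals) else NA_real_,
               n_quartets = length(vals), stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(split = character(), scf = numeric(),
                      n_quartets = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
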