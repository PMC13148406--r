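test_that("pairwise distances follow their closed forms", {
  mat <- aln_matrix("AAAA", "AAAA", taxa = c("a", "b"))
  expect_equal(unname(pairwise_distance(mat, "p")["a", "b"]), 0)
  # p = 0.75 under poisson: -ln(0.25)
  mat2 <- aln_matrix("AAAA", "ACDE", taxa = c("a", "b"))
  expect_equal(unname(pairwise_distance(mat2, "poisson")["a", "b"]),
               -log(0.25), tolerance = 1e-12)
  # jc69 saturates at p >= 3/4 and is capped
  dn <- marker_alignment(aln_matrix("AAAA", "CCGT", taxa = c("a", "b")),
                         seqtype = "cds-codon")
  expect_warning(d <- pairwise_distance(dn, "jc69"), "capped")
  expect_equal(unname(d["a", "b"]), 10)
  # gapped columns are excluded pairwise
  mat3 <- aln_matrix("A-CD", "AAC-", taxa = c("a", "b"))
  expect_equal(unname(pairwise_distance(mat3, "p")["a", "b"]), 0)
  expect_error(pairwise_distance(aln_matrix("A-", "-A", taxa = c("a", "b")), "p"),
               "share no comparable")
})

test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(11)
  for (n in c(5, 6, 8)) {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(tr)
    est <- nj_tree(d)
    expect_equal(rf_distance(est, tr)$raw, 0L)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
  expect_error(nj_tree(matrix(NaN, 4, 4)), "finite")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(rbind(cbind(bad, 1), 1)), "symmetric|three")
})

test_that("treeness matches hand-computed values and bounds", {
  # 4-taxon tree: one internal branch 1.0, four terminals 1.0 -> 1/5
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  expect_equal(treeness(tr), 0.2)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(treeness(star), 0)
  spike <- ape::read.tree(text = "((a:0,b:0):2,c:0,d:0);")
  expect_equal(treeness(spike), 1)
  zero <- ape::read.tree(text = "((a:0,b:0):0,c:0,d:0);")
  expect_warning(expect_equal(treeness(zero), 0), "zero")
  # invariant under uniform rescaling
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7.3
  expect_equal(treeness(tr2), treeness(tr))
})

test_that("RCV matches the worked example and its invariances", {
  expect_equal(rcv(aln_matrix("AC", "CA", taxa = c("a", "b"))), 0)
  expect_equal(rcv(aln_matrix("AA", "CC", taxa = c("a", "b"))), 1)
  set.seed(13)
  mat <- matrix(sample(c("A", "C", "D", "E"), 6 * 20, replace = TRUE), 6, 20,
                dimnames = list(paste0("t", 1:6), NULL))
  base <- rcv(mat)
  expect_gte(base, 0)
  # row reordering and column permutation change nothing
  expect_equal(rcv(mat[sample(6), ]), base)
  expect_equal(rcv(mat[, sample(20)]), base)
  # duplicating an existing row cannot increase RCV (its counts equal its own
  # mean contribution); check by brute force over several rows
  for (i in 1:3) {
    aug <- rbind(mat, mat[i, , drop = FALSE])
    rownames(aug) <- c(rownames(mat), "dup")
    expect_lte(rcv(aug), base + 1e-12)
  }
})

test_that("marker ranking is score-descending with lexicographic ties", {
  sc <- data.frame(marker_id = c("mB", "mA", "mC"),
                   score = c(2, 2, 5), stringsAsFactors = FALSE)
  expect_equal(rank_markers(sc), c("mC", "mA", "mB"))
  expect_equal(rank_markers(sc, top_n = 2), c("mC", "mA"))
  expect_error(rank_markers(sc, top_n = 0), "top_n")
  # rcv = 0 ranks via the epsilon guard above positive-rcv equals
  a <- marker_alignment(aln_matrix("AC", "CA", taxa = c("x", "y", "z", "w")[1:2]))
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  s0 <- score_marker(marker_alignment(aln_matrix("AC", "CA", "AC", "CA")),
                     gene_tree = tr)
  s1 <- score_marker(marker_alignment(aln_matrix("AA", "CC", "AA", "CC")),
                     gene_tree = tr)
  expect_equal(s0$rcv, 0)
  expect_gt(s0$score, s1$score)
  expect_equal(s0$score, s0$treeness / 1e-9)
})

test_that("markers evolved with more divergence score lower on average", {
  # same tree, one marker set at low rate (clean signal), one at a rate high
  # enough to saturate composition differences
  slow <- make_pipeline_fixture(n_markers = 6L, seed = 21L, key = "slow")
  scores_by_rate <- function(rate, seed) {
    spec <- simulation_spec(n_taxa = 6L, n_markers = 6L, marker_length = 60L,
                            substitution_rate = rate, n_decoys = 0L,
                            seed = seed)
    tree <- simulate_species_tree(6L, seed)
    aln <- evolve_marker_alignments(tree, spec)
    mean(vapply(aln, function(a) score_marker(a)$score, numeric(1)))
  }
  lo <- mean(vapply(21:24, function(s) scores_by_rate(0.3, s), numeric(1)))
  hi <- mean(vapply(21:24, function(s) scores_by_rate(4, s), numeric(1)))
  expect_gt(lo, hi)
})
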