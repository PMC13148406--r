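test_that("supermatrix concatenation tiles partitions exactly", {
  m1 <- marker_alignment(aln_matrix("ACDEFGHIKL", "ACDEFGHIKL",
                                    taxa = c("a", "b")), marker_id = "m1")
  m2 <- marker_alignment(aln_matrix("MKVLAWQHNPQRSTV", "MKVLAWQHNPQRSTV",
                                    taxa = c("a", "c")), marker_id = "m2")
  sm <- concat_supermatrix(list(m2, m1))  # order normalised to m1, m2
  expect_equal(ncol(sm$alignment$matrix), 25L)
  expect_equal(sm$partitions$marker_id, c("m1", "m2"))
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 25L))
  # taxon missing from a marker is gap-filled exactly over its partition
  expect_equal(paste(sm$alignment$matrix["c", 1:10], collapse = ""),
               strrep("-", 10))
  expect_equal(paste(sm$alignment$matrix["b", 11:25], collapse = ""),
               strrep("-", 15))
  # single marker: identity with one partition
  sm1 <- concat_supermatrix(list(m1))
  expect_equal(sm1$alignment$matrix, m1$matrix)
  expect_equal(nrow(sm1$partitions), 1L)
  # conflicting seqtypes refused
  m3 <- marker_alignment(aln_matrix("ACG", "ACG", taxa = c("a", "b")),
                         marker_id = "m3", seqtype = "cds-codon")
  expect_error(concat_supermatrix(list(m1, m3)), "seqtype")
  # partition file round-trip is lossless
  path <- withr::local_tempfile(fileext = ".part")
  write_partition_file(sm, path)
  expect_equal(read_partition_file(path), sm$partitions)
})

test_that("quartet score equals brute-force enumeration", {
  set.seed(31)
  # identical resolved trees: n_genes * choose(5, 4)
  sp <- ape::rtree(5)
  expect_equal(quartet_score(sp, list(sp, sp, sp)), 3L * 5L)
  # random 6-taxon instances against the pruning oracle
  for (r in 1:10) {
    sp <- ape::rtree(6)
    gts <- lapply(1:4, function(i) ape::rtree(6, tip.label = sp$tip.label))
    expect_equal(quartet_score(sp, gts), quartet_score_oracle(sp, gts))
  }
  # symmetry on equal tip sets
  a <- ape::rtree(6); b <- ape::rtree(6, tip.label = a$tip.label)
  expect_equal(quartet_score(a, list(b)), quartet_score(b, list(a)))
  # unknown tips rejected
  odd <- ape::rtree(4, tip.label = paste0("zz", 1:4))
  expect_error(quartet_score(sp, list(odd)), "absent")
})

test_that("consensus inference is exhaustively optimal on small instances", {
  set.seed(33)
  # unanimous gene trees: unique maximizer
  sp <- ape::rtree(6)
  gts <- lapply(1:5, function(i) sp)
  expect_equal(rf_distance(infer_consensus_tree(gts), sp)$raw, 0L)
  # random instances: score matches the exhaustive optimum
  for (r in 1:5) {
    gts <- lapply(1:10, function(i) ape::rtree(6, tip.label = paste0("s", 1:6)))
    est <- infer_consensus_tree(gts)
    cands <- phangorn::allTrees(6, tip.label = paste0("s", 1:6))
    best <- max(vapply(cands, function(tr) quartet_score(tr, gts), numeric(1)))
    expect_equal(quartet_score(est, gts), as.integer(best))
  }
  # disjoint minority conflicts: the majority topology wins
  major <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  minor1 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  minor2 <- ape::read.tree(text = "((a,b),(c,e),(d,f));")
  gts <- c(rep(list(major), 6), list(minor1), list(minor2))
  expect_equal(rf_distance(infer_consensus_tree(gts), major)$raw, 0L)
  expect_error(infer_consensus_tree(list(ape::rtree(3))), "four")
})

test_that("consensus hill climb handles more than eight taxa", {
  set.seed(34)
  sp <- ape::rtree(10)
  gts <- lapply(1:8, function(i) sp)
  est <- infer_consensus_tree(gts)
  expect_equal(rf_distance(est, sp)$raw, 0L)
})

test_that("RF distance is a sane metric and agrees with phangorn", {
  t1 <- ape::rtree(4, tip.label = letters[1:4])
  expect_equal(rf_distance(t1, t1), list(raw = 0L, normalized = 0))
  t2 <- ape::read.tree(text = "((a,c),b,d);")
  t1b <- ape::read.tree(text = "((a,b),c,d);")
  expect_equal(rf_distance(t1b, t2), list(raw = 2L, normalized = 1))
  set.seed(35)
  for (r in 1:10) {
    n <- sample(5:9, 1)
    a <- ape::rtree(n); b <- ape::rtree(n, tip.label = a$tip.label)
    c_ <- ape::rtree(n, tip.label = a$tip.label)
    rab <- rf_distance(a, b)$raw
    expect_equal(rab, rf_distance(b, a)$raw)
    expect_equal(rab,
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
    expect_lte(rf_distance(a, c_)$raw, rab + rf_distance(b, c_)$raw)
  }
  expect_error(rf_distance(a, ape::rtree(4)), "tip sets")
})

test_that("monophyly follows bipartitions of the unrooted tree", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(a3,c1),c2);")
  groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B",
              c1 = "C", c2 = "C")
  st <- check_monophyly(tr, groups)
  expect_equal(st$monophyletic[st$group == "B"], TRUE)
  expect_equal(st$monophyletic[st$group == "A"], FALSE)  # a3 sits elsewhere
  # interleaved groups on a caterpillar: both fail
  cat_tree <- ape::read.tree(text = "(x1,(y1,(x2,(y2,(x3,y3)))));")
  st2 <- check_monophyly(cat_tree, c(x1 = "X", x2 = "X", x3 = "X",
                                     y1 = "Y", y2 = "Y", y3 = "Y"))
  expect_false(any(st2$monophyletic))
  # singleton convention and label checks
  st3 <- check_monophyly(tr, c(groups[-7], c2 = "solo"))
  expect_true(st3$monophyletic[st3$group == "solo"])
  expect_error(check_monophyly(tr, groups[-1]), "unlabeled")
})

test_that("bootstrap support is deterministic, bounded, and high for clean signal", {
  fx <- make_pipeline_fixture(n_markers = 6L, marker_length = 150L,
                              seed = 41L, key = "boot")
  sm <- concat_supermatrix(fx$alignments)
  b1 <- bootstrap_support(sm, B = 60L, seed = 5L)
  b2 <- bootstrap_support(sm, B = 60L, seed = 5L)
  expect_equal(ape::write.tree(b1), ape::write.tree(b2))
  sup <- attr(b1, "support")$support_pct
  expect_true(all(sup >= 0 & sup <= 100))
  # long conflict-free alignment: every true split at >= 95%
  expect_equal(rf_distance(b1, fx$tree)$raw, 0L)
  expect_true(all(sup >= 95))
})

test_that("site concordance is high without homoplasy and missing when undecidable", {
  # perfect split characters: every decisive site concordant on every branch
  tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f),g);")
  splits <- markerphylo:::tree_splits(tr)
  cols <- lapply(splits, function(k) {
    side <- strsplit(k, "[|]")[[1]]
    ifelse(tr$tip.label %in% side, "K", "E")
  })
  mat <- do.call(cbind, rep(cols, 10L))
  rownames(mat) <- tr$tip.label
  sm <- structure(list(alignment = marker_alignment(mat),
                       partitions = data.frame(marker_id = "m",
                                               start = 1L,
                                               end = ncol(mat))),
                  class = "supermatrix")
  scf <- site_concordance(tr, sm, q = 50L, seed = 3L)
  expect_true(all(scf$scf > 90))
  # identical draws for identical seeds
  scf2 <- site_concordance(tr, sm, q = 50L, seed = 3L)
  expect_equal(scf, scf2)
  # all-constant alignment: no decisive sites anywhere
  const <- matrix("A", length(tr$tip.label), 30,
                  dimnames = list(tr$tip.label, NULL))
  smc <- structure(list(alignment = marker_alignment(const),
                        partitions = data.frame(marker_id = "m", start = 1L,
                                                end = 30L)),
                   class = "supermatrix")
  scf3 <- site_concordance(tr, smc, q = 20L, seed = 3L)
  expect_true(all(is.na(scf3$scf)))
  expect_true(all(scf3$n_quartets == 0L))
})
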