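test_that("hit-sequence extraction relabels by sample and checks ids", {
  pools <- list(S1 = c(g1 = "MKVA", g2 = "WWWW"),
                S2 = c(g3 = "MKVG"), S3 = c(g4 = "MRVA"))
  hits <- data.frame(sample_id = c("S1", "S2", "S3"),
                     seq_id = c("g1", "g3", "g4"),
                     marker_id = "X", bit_score = 50,
                     span_start = 1L, span_end = 4L,
                     stringsAsFactors = FALSE)
  got <- extract_hit_sequences(pools, hits)
  expect_named(got, "X")
  expect_equal(got$X, c(S1 = "MKVA", S2 = "MKVG", S3 = "MRVA"))
  bad <- hits; bad$seq_id[2] <- "missing"
  expect_error(extract_hit_sequences(pools, bad), "missing.*S2|S2.*missing")
  expect_error(extract_hit_sequences(pools[c(1, 1)], hits), "duplicate")
})

test_that("profile alignment has width M and places deletions as gaps", {
  fx <- make_pipeline_fixture(key = "base")
  m <- build_hmm(fx$alignments[[1]], alpha = 0.5)
  seqs <- apply(fx$alignments[[1]]$matrix, 1, paste, collapse = "")
  al <- align_to_profile(m, seqs)
  expect_equal(ncol(al$matrix), m$M)
  expect_equal(al$matrix, fx$alignments[[1]]$matrix)  # gap-free truth recovered

  # a sequence missing an internal stretch aligns with '-' at those nodes,
  # and different input lengths still give identical width
  short <- substr(seqs[[1]], 6, nchar(seqs[[1]]))  # drop first five residues
  al2 <- align_to_profile(m, c(full = unname(seqs[[1]]), short = short))
  expect_equal(ncol(al2$matrix), m$M)
  expect_equal(sum(al2$matrix["short", ] == "-"), 5L)
  expect_true(all(al2$matrix["full", ] != "-"))
  expect_error(align_to_profile(m, seqs[1]), "two")
})

test_that("deletion columns follow the viterbi state path exactly", {
  fx <- make_pipeline_fixture(key = "base")
  m <- build_hmm(fx$alignments[[2]], alpha = 0.5)
  s <- paste(fx$alignments[[2]]$matrix[3, ], collapse = "")
  mangled <- paste0(substr(s, 1, 19), substr(s, 30, nchar(s)))
  vt <- viterbi(m, mangled)
  al <- align_to_profile(m, c(a = s, b = mangled))
  expect_equal(unname(al$matrix["b", ] == "-"), is.na(vt$match_residue))
})

test_that("parsimony-informative trimming matches its definition and oracle", {
  mat <- aln_matrix("AAKA", "AAKC", "AKKA", "AKKC", "AAKA")
  # col1 constant; col2 A,A,K,K,A informative; col3 constant; col4 A,C,A,C,A informative
  got <- trim_parsimony_informative(marker_alignment(mat))
  expect_equal(got$kept, c(2L, 4L))
  expect_equal(ncol(got$trimmed$matrix), 2L)
  # A,A,G,C column: only one state reaches two copies -> dropped
  mat2 <- aln_matrix("AA", "AA", "GA", "CA")
  expect_equal(trim_parsimony_informative(marker_alignment(mat2))$kept,
               integer(0))
  # idempotence and oracle agreement on random alignments
  set.seed(5)
  for (r in 1:20) {
    rm <- matrix(sample(c("A", "C", "D", "E", "-", "X"), 8 * 12,
                        replace = TRUE, prob = c(rep(0.22, 4), 0.08, 0.04)),
                 8, 12, dimnames = list(paste0("t", 1:8), NULL))
    tr <- trim_parsimony_informative(marker_alignment(rm))
    oracle <- informative_columns_oracle(rm, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    expect_equal(tr$kept, as.integer(oracle))
    again <- trim_parsimony_informative(tr$trimmed)
    expect_equal(again$trimmed$matrix, tr$trimmed$matrix)
  }
})

test_that("codon back-threading follows gaps and survives translation", {
  pep <- marker_alignment(aln_matrix("M-K", "MAK", taxa = c("a", "b")))
  cds <- c(a = "ATGAAA", b = "ATGGCTAAA")
  out <- backthread_codons(pep, cds)
  expect_equal(ncol(out$matrix), 9L)
  expect_equal(paste(out$matrix["a", ], collapse = ""), "ATG---AAA")
  expect_equal(paste(out$matrix["b", ], collapse = ""), "ATGGCTAAA")
  expect_equal(out$seqtype, "cds-codon")
  # trailing stop tolerated; wrong length and internal stops rejected
  expect_silent(backthread_codons(pep, c(a = "ATGAAATAA", b = "ATGGCTAAA")))
  expect_error(backthread_codons(pep, c(a = "ATGAA", b = "ATGGCTAAA")), "length")
  expect_error(backthread_codons(pep, c(a = "TGAAAA", b = "ATGGCTAAA")), "stop")
  # translating each codon row reproduces the gapped peptide row
  fx <- make_pipeline_fixture(key = "base")
  spec <- fx$spec
  cds_files <- emit_sample_cds(fx$alignments, spec, file.path(fx$dir, "cds"))
  al <- fx$alignments[[1]]
  nt1 <- markerphylo:::read_fasta_vector(cds_files[["S1"]], type = "DNA")
  nt2 <- markerphylo:::read_fasta_vector(cds_files[["S2"]], type = "DNA")
  out2 <- backthread_codons(
    marker_alignment(al$matrix[c("S1", "S2"), , drop = FALSE],
                     marker_id = al$marker_id),
    c(S1 = nt1[[al$marker_id]], S2 = nt2[[al$marker_id]]))
  for (tx in c("S1", "S2")) {
    row <- gsub("-", "", paste(out2$matrix[tx, ], collapse = ""))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(row)))
    expect_equal(aa, paste(al$matrix[tx, al$matrix[tx, ] != "-"],
                           collapse = ""))
  }
})
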