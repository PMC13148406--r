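mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[1], seq_id = r[2], marker_id = r[3],
               bit_score = 50, span_start = 1L, span_end = 10L,
               stringsAsFactors = FALSE)))
}

test_that("multi-hit cells are excluded per marker, not per sample", {
  hits <- mk_hits(c("S1", "g1", "X"), c("S1", "g2", "Y"), c("S1", "g3", "Y"),
                  c("S2", "g4", "X"), c("S2", "g5", "Y"))
  out <- enforce_single_copy(hits)
  # S1 keeps X (one hit) but loses Y entirely (two hits); S2 untouched
  expect_equal(nrow(out), 3L)
  expect_false(any(out$sample_id == "S1" & out$marker_id == "Y"))
  expect_true(any(out$sample_id == "S1" & out$marker_id == "X"))
  expect_true(any(out$sample_id == "S2" & out$marker_id == "Y"))
  # idempotent, and the identity on clean tables
  expect_equal(enforce_single_copy(out), out)
  clean <- mk_hits(c("S1", "g1", "X"), c("S2", "g2", "X"))
  expect_equal(enforce_single_copy(clean), clean)
})

test_that("marker selection enforces the taxon floor", {
  hits <- mk_hits(c("S1", "g1", "X"), c("S2", "g2", "X"), c("S3", "g3", "X"),
                  c("S4", "g4", "X"), c("S1", "g5", "Y"), c("S2", "g6", "Y"),
                  c("S3", "g7", "Y"))
  expect_equal(select_markers(hits, min_taxa = 4L), "X")  # Y covers only 3
  expect_equal(select_markers(hits, min_taxa = 3L), c("X", "Y"))
  expect_error(select_markers(hits, min_taxa = 5L), "marker")
})

test_that("content hashing identifies bytes, not names", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa"); f3 <- file.path(d, "c.fa")
  writeLines(c(">x", "MKV"), f1)
  file.copy(f1, f2)
  writeLines(c(">x", "MKW"), f3)
  expect_equal(content_hash(f1), content_hash(f2))
  expect_false(content_hash(f1) == content_hash(f3))
})

test_that("checkpoint diff classifies new, reusable and removed samples", {
  d <- withr::local_tempdir()
  paths <- sapply(1:3, function(i) {
    p <- file.path(d, paste0("s", i, ".fa"))
    writeLines(c(">g", strrep("MKV", i)), p)
    p
  })
  names(paths) <- paste0("S", 1:3)
  ck <- new_checkpoint("digest", NULL, "pep")
  h12 <- sapply(paths[1:2], content_hash)
  ck <- merge_checkpoint(ck, stats::setNames(
    lapply(names(h12), function(l) list(labels = l, hits = mk_hits(c(l, "g", "X")))),
    unname(h12)))
  diff <- checkpoint_diff(ck, paths, ck$params_fingerprint)
  expect_equal(names(diff$to_search), "S3")
  expect_equal(names(diff$reusable), c("S1", "S2"))
  expect_equal(diff$removed, character(0))
  # dropping S1 marks its entry as removed; renaming S2 still reuses it
  p2 <- paths[2:3]
  file.rename(p2["S2"], file.path(d, "other_name.fa"))
  p2["S2"] <- file.path(d, "other_name.fa")
  diff2 <- checkpoint_diff(ck, p2, ck$params_fingerprint)
  expect_equal(names(diff2$reusable), "S2")
  expect_equal(diff2$removed, unname(h12["S1"]))
  # a fingerprint mismatch refuses unless forced
  expect_error(checkpoint_diff(ck, p2, "other-fingerprint"), "parameters")
  forced <- checkpoint_diff(ck, p2, "other-fingerprint", force = TRUE)
  expect_equal(names(forced$to_search), c("S2", "S3"))
})

test_that("merging is idempotent and checkpoints round-trip through disk", {
  ck <- new_checkpoint("digest", 10, "pep")
  entry <- list(labels = "S1", hits = mk_hits(c("S1", "g1", "X")))
  ck1 <- merge_checkpoint(ck, list(abc123 = entry))
  ck2 <- merge_checkpoint(ck1, list(abc123 = entry))
  expect_equal(ck1, ck2)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(ck1, path)
  back <- load_checkpoint(path)
  expect_equal(back$params_fingerprint, ck1$params_fingerprint)
  expect_equal(back$entries$abc123$labels, "S1")
  expect_equal(back$entries$abc123$hits, ck1$entries$abc123$hits)
  # saving the loaded checkpoint reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("same hash under two labels keeps both with a warning", {
  ck <- new_checkpoint()
  ck <- merge_checkpoint(ck, list(h1 = list(labels = "A", hits = empty_hits_df())))
  expect_warning(
    ck <- merge_checkpoint(ck, list(h1 = list(labels = "B", hits = empty_hits_df()))),
    "labels")
  expect_setequal(ck$entries$h1$labels, c("A", "B"))
})
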