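# Shared synthetic pipeline fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# Simulate a full input set (proteomes + marker db + truth tree) for the
# given spec; returns paths and in-memory objects.
make_pipeline_fixture <- function(n_taxa = 6L, n_markers = 4L,
                                  marker_length = 60L, n_decoys = 4L,
                                  paralogs = NULL, seed = 7L,
                                  key = NULL) {
  if (!is.null(key) && !is.null(.fixture_cache[[key]]))
    return(.fixture_cache[[key]])
  spec <- simulation_spec(n_taxa = n_taxa, n_markers = n_markers,
                          marker_length = marker_length,
                          n_decoys = n_decoys, paralogs = paralogs,
                          seed = seed)
  tree <- simulate_species_tree(spec$n_taxa, spec$seed)
  aln <- evolve_marker_alignments(tree, spec)
  dir <- tempfile("fixture_")
  prot <- emit_sample_proteomes(aln, spec, file.path(dir, "proteomes"))
  db <- build_marker_db(aln, out_dir = file.path(dir, "markers"))
  fx <- list(spec = spec, tree = tree, alignments = aln, proteomes = prot,
             marker_dir = db$dir, db = db, dir = dir)
  if (!is.null(key)) .fixture_cache[[key]] <- fx
  fx
}

fixture_config <- function(fx, out = tempfile("run_"), ...) {
  run_config(fx$marker_dir, fx$proteomes, output_dir = out, ...)
}

empty_hits_df <- function() markerphylo:::empty_hits()

# small deterministic peptide alignment matrix
aln_matrix <- function(..., taxa = NULL) {
  rows <- c(...)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- if (is.null(taxa)) paste0("t", seq_along(rows)) else taxa
  mat
}
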