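#' Simulation specification for synthetic marker data
#'
#' Bundles the knobs of the synthetic-data generator: a known species tree,
#' per-marker gene families evolved along it under an equal-rate 20-state
#' substitution process, decoy sequences, and optional injected paralogs.
#' Every downstream draw is a pure function of `seed`.
#'
#' @param n_taxa Number of species (>= 2).
#' @param n_markers Number of single-copy marker families.
#' @param marker_length Sites per marker.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length. The default 0.5 puts the default eight-taxon fixture (whose
#'   Yule trees have mean root-to-tip depth near 0.57) at roughly 0.28
#'   expected substitutions per site from root to tip -- the low-divergence
#'   regime single-copy marker pipelines are built for.
#' @param n_decoys Background sequences added to every sample proteome.
#' @param paralogs Optional data frame (`sample`, `marker`) of near-identical
#'   duplicates to inject.
#' @param seed Integer seed fixing all draws.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_taxa = 8L, n_markers = 50L,
                            marker_length = 200L, substitution_rate = 0.5,
                            n_decoys = 10L, paralogs = NULL, seed = 1L) {
  stopifnot(n_taxa >= 2L, n_markers >= 1L, marker_length >= 1L,
            substitution_rate >= 0, n_decoys >= 0L)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_markers = as.integer(n_markers),
                 marker_length = as.integer(marker_length),
                 substitution_rate = substitution_rate,
                 n_decoys = as.integer(n_decoys),
                 paralogs = paralogs, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a species tree (Yule process)
#'
#' Grows a binary tree by repeatedly splitting a uniformly chosen extant
#' lineage until `n_taxa` tips exist. Branch lengths are drawn as
#' `0.01 + Exponential(rate = 1/0.09)` (mean 0.1 with a 0.01 floor so every
#' branch carries at least a little expected signal at fixture scale). Tips
#' are labeled `S1..Sn`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A rooted binary `phylo` with branch lengths.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # grow in newick text: split random extant tip until n_taxa reached
  labels <- paste0("S", seq_len(n_taxa))
  nwk <- sprintf("(%s,%s);", labels[1], labels[2])
  for (k in 3:max(3L, n_taxa)) {
    if (k > n_taxa) break
    pick <- sample(k - 1L, 1L)
    nwk <- sub(paste0("\\b", labels[pick], "\\b"),
               sprintf("(%s,%s)", labels[pick], labels[k]), nwk)
  }
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- 0.01 + stats::rexp(nrow(tr$edge), rate = 1 / 0.09)
  tr
}

# per-branch substitution probability of the K-state equal-rate process
subst_prob <- function(b, rate, K = 20) {
  ((K - 1) / K) * (1 - exp(-K * rate * b / (K - 1)))
}

#' Evolve marker alignments along a species tree
#'
#' Each marker's root sequence is drawn from uniform residue frequencies;
#' along each branch of length `b` every site substitutes, independently,
#' with probability `p(b) = (19/20) (1 - exp(-20 rate b / 19))` to a residue
#' drawn uniformly from the 19 alternatives (the 20-state analogue of the
#' Jukes-Cantor process, so `p(b)` is the exact closed-form mismatch
#' probability). No indels are simulated: alignments are gap-free and
#' columnar-homologous by construction.
#'
#' @param tree A `phylo` with branch lengths (tips become taxa labels).
#' @param spec A `simulation_spec`.
#' @return Named list of `marker_alignment`s (`M001`, `M002`, ...).
#' @export
evolve_marker_alignments <- function(tree, spec) {
  res <- ALPHABETS$amino20
  K <- length(res)
  L <- spec$marker_length
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed + 1L)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edge_order <- ape::reorder.phylo(tree, "cladewise")
  out <- list()
  for (m in seq_len(spec$n_markers)) {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(K, L, replace = TRUE)
    for (r in seq_len(nrow(edge_order$edge))) {
      par <- edge_order$edge[r, 1L]
      child <- edge_order$edge[r, 2L]
      b <- edge_order$edge.length[r]
      p <- subst_prob(b, spec$substitution_rate, K)
      s <- seqs[[par]]
      hit <- stats::runif(L) < p
      if (any(hit)) {
        # uniform among the 19 alternatives
        shift <- sample(K - 1L, sum(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% K) + 1L
      }
      seqs[[child]] <- s
    }
    mat <- do.call(rbind, lapply(seq_len(ntip), function(i) res[seqs[[i]]]))
    rownames(mat) <- tree$tip.label
    id <- sprintf("M%03d", m)
    out[[id]] <- marker_alignment(mat, marker_id = id, seqtype = "pep")
  }
  out
}

#' Emit per-sample proteome FASTA files
#'
#' Writes one FASTA per sample containing its (ungapped) marker sequences
#' under opaque shuffled ids, plus `n_decoys` random background sequences
#' drawn from the same uniform residue frequencies as the markers (so search
#' specificity is genuinely exercised). Paralog entries add a near-identical
#' duplicate (1 percent point mutations) of the named marker's gene to the
#' named sample.
#'
#' @param alignments Named list of `marker_alignment`s (the true families).
#' @param spec A `simulation_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector: sample label -> FASTA path.
#' @export
emit_sample_proteomes <- function(alignments, spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- ALPHABETS$amino20
  taxa <- rownames(alignments[[1L]]$matrix)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed + 2L)
  paths <- character(0)
  for (tx in taxa) {
    seqs <- vapply(alignments, function(al)
      paste(al$matrix[tx, al$matrix[tx, ] != "-"], collapse = ""),
      character(1))
    names(seqs) <- names(alignments)
    if (!is.null(spec$paralogs)) {
      pl <- spec$paralogs[spec$paralogs$sample == tx, , drop = FALSE]
      for (mk in pl$marker) {
        s <- strsplit(seqs[[mk]], "")[[1]]
        nmut <- max(1L, round(0.01 * length(s)))
        at <- sample(length(s), nmut)
        s[at] <- res[((match(s[at], res) - 1L +
                       sample(19L, nmut, replace = TRUE)) %% 20L) + 1L]
        seqs[[paste0(mk, "_dup")]] <- paste(s, collapse = "")
      }
    }
    if (spec$n_decoys > 0L) {
      dec <- vapply(seq_len(spec$n_decoys), function(i)
        paste(sample(res, spec$marker_length, replace = TRUE), collapse = ""),
        character(1))
      names(dec) <- paste0("decoy", seq_len(spec$n_decoys))
      seqs <- c(seqs, dec)
    }
    seqs <- seqs[sample(length(seqs))]
    names(seqs) <- sprintf("%s_g%03d", tx, seq_along(seqs))
    path <- file.path(out_dir, paste0(tx, ".faa"))
    write_fasta_vector(seqs, path, type = "AA")
    paths[tx] <- path
  }
  paths
}

#' Back-translate marker families to coding sequences
#'
#' Generates per-sample CDS FASTA files matching the proteomes: each amino
#' acid is back-translated with a uniformly random synonymous codon
#' (standard genetic code), deterministically from the spec seed.
#'
#' @inheritParams emit_sample_proteomes
#' @return Named character vector: sample label -> CDS FASTA path. The ids
#'   inside match the corresponding proteome files.
#' @export
emit_sample_cds <- function(alignments, spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- standard_codon_table()
  taxa <- rownames(alignments[[1L]]$matrix)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed + 3L)
  paths <- character(0)
  for (tx in taxa) {
    nt <- vapply(names(alignments), function(id) {
      aa <- alignments[[id]]$matrix[tx, ]
      aa <- aa[aa != "-"]
      paste(vapply(aa, function(a) sample(code[[a]], 1L), character(1)),
            collapse = "")
    }, character(1))
    path <- file.path(out_dir, paste0(tx, ".fna"))
    write_fasta_vector(nt, path, type = "DNA")
    paths[tx] <- path
  }
  paths
}

standard_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"),
    "")[[1]]
  split(codons[aa != "*"], aa[aa != "*"])
}

#' Build a marker profile database from seed alignments
#'
#' One profile HMM per marker family ([build_hmm()] then [write_hmm()]),
#' plus a JSON manifest listing marker ids and file digests (the manifest
#' digest changes iff any profile file changes).
#'
#' @param alignments Named list of `marker_alignment`s.
#' @param alpha Pseudocount passed to [build_hmm()].
#' @param out_dir Output directory.
#' @return List with `dir`, `files` (named paths), `manifest` (path) and
#'   `digest` (digest over all profile files).
#' @export
build_marker_db <- function(alignments, alpha = 1, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (id in names(alignments)) {
    m <- build_hmm(alignments[[id]], alpha = alpha, marker_id = id)
    path <- file.path(out_dir, paste0(id, ".hmm"))
    write_hmm(m, path)
    files[id] <- path
  }
  digests <- vapply(files, content_hash, character(1))
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(markers = names(files),
         files = basename(unname(files)),
         sha256 = unname(digests)),
    manifest, auto_unbox = FALSE, pretty = TRUE)
  list(dir = out_dir, files = files, manifest = manifest,
       digest = digest::digest(unname(digests), algo = "sha256"))
}

#' Load a marker profile directory
#'
#' Reads every `.hmm` file in a directory (each may hold several records)
#' into one named list of `profile_hmm`s, and computes the marker-set digest
#' used in checkpoint parameter fingerprints.
#'
#' @param dir Directory of HMMER3 text files.
#' @return List with `markers` (named list of models) and `digest`.
#' @export
load_marker_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.hmm$", full.names = TRUE))
  if (!length(files)) stop("no .hmm files in ", dir, call. = FALSE)
  markers <- list()
  for (f in files) markers <- c(markers, read_hmm(f))
  if (anyDuplicated(names(markers)))
    stop("duplicate marker ids across profile files", call. = FALSE)
  digests <- vapply(files, content_hash, character(1))
  list(markers = markers, digest = digest::digest(unname(digests),
                                                  algo = "sha256"))
}
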