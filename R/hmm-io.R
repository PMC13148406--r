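#' Profile hidden Markov models of marker gene families
#'
#' A `profile_hmm` holds one marker's position-specific model: per-position
#' match and insert emission probabilities, the seven core transition
#' probabilities per node, the background (null) frequencies scored against,
#' and an optional gathering bit-score cutoff. Models are exchanged in the
#' HMMER3 text format, in which probabilities are stored as negative natural
#' logs and probability zero is written as `*`.
#'
#' The transition matrix has `M + 1` rows. Row `0` holds the begin-state
#' transitions (B to M1/I0/D1); rows `1..M` hold, in order, M->M, M->I, M->D,
#' I->M, I->I, D->M, D->D, where transitions out of node `M` lead to the end
#' state (M->D at node `M` is structurally zero).
#'
#' @param marker_id Marker identifier (the HMMER `NAME`).
#' @param alphabet `"amino20"` or `"dna4"`.
#' @param match_emission `M x K` matrix of match emission probabilities.
#' @param insert_emission `M x K` matrix of insert emission probabilities.
#' @param transitions `(M + 1) x 7` matrix of transition probabilities.
#' @param null_freq Background frequency vector of length `K`.
#' @param gathering_cutoff Optional gathering cutoff in bits (`GA` line).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(marker_id, alphabet, match_emission, insert_emission,
                        transitions, null_freq = NULL,
                        gathering_cutoff = NULL) {
  res <- alphabet_residues(alphabet)
  K <- length(res)
  match_emission <- as.matrix(match_emission)
  insert_emission <- as.matrix(insert_emission)
  transitions <- as.matrix(transitions)
  if (is.null(null_freq)) null_freq <- rep(1 / K, K)
  M <- nrow(match_emission)
  colnames(match_emission) <- colnames(insert_emission) <- res
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  obj <- structure(list(
    marker_id = as.character(marker_id), alphabet = alphabet, M = as.integer(M),
    match_emission = match_emission, insert_emission = insert_emission,
    transitions = transitions, null_freq = stats::setNames(null_freq, res),
    gathering_cutoff = gathering_cutoff
  ), class = "profile_hmm")
  validate_profile_hmm(obj)
  obj
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: %d match states, alphabet %s%s\n",
              x$marker_id, x$M, x$alphabet,
              if (is.null(x$gathering_cutoff)) "" else
                sprintf(", GA %.1f bits", x$gathering_cutoff)))
  invisible(x)
}

validate_profile_hmm <- function(model, tol = 1e-6) {
  K <- length(alphabet_residues(model$alphabet))
  M <- model$M
  stopifnot(M >= 1L)
  if (ncol(model$match_emission) != K || nrow(model$match_emission) != M)
    stop("match_emission must be M x K", call. = FALSE)
  if (ncol(model$insert_emission) != K || nrow(model$insert_emission) != M)
    stop("insert_emission must be M x K", call. = FALSE)
  if (nrow(model$transitions) != M + 1L || ncol(model$transitions) != 7L)
    stop("transitions must be (M + 1) x 7", call. = FALSE)
  chk_rows <- function(mat, what) {
    bad <- which(abs(rowSums(mat) - 1) > tol)
    if (length(bad))
      stop(what, " row(s) ", paste(bad, collapse = ","),
           " do not sum to 1", call. = FALSE)
  }
  chk_rows(model$match_emission, "match_emission")
  chk_rows(model$insert_emission, "insert_emission")
  if (abs(sum(model$null_freq) - 1) > tol)
    stop("null_freq does not sum to 1", call. = FALSE)
  tr <- model$transitions
  chk_rows(tr[, c("MM", "MI", "MD"), drop = FALSE], "transition M->*")
  chk_rows(tr[, c("IM", "II"), drop = FALSE], "transition I->*")
  chk_rows(tr[, c("DM", "DD"), drop = FALSE], "transition D->*")
  if (tr[M + 1L, "MD"] > tol || tr[M + 1L, "DD"] > tol)
    stop("node M cannot transition to a delete state beyond the model",
         call. = FALSE)
  invisible(model)
}

# -ln encoding used by the HMMER3 text format
nlog_fmt <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
nlog_parse <- function(tok, path, lineno) {
  out <- numeric(length(tok))
  star <- tok == "*"
  out[star] <- 0
  vals <- suppressWarnings(as.numeric(tok[!star]))
  if (anyNA(vals))
    stop(sprintf("%s: non-numeric emission/transition field on line %d",
                 path, lineno), call. = FALSE)
  out[!star] <- exp(-vals)
  out
}

#' Write profile HMMs in HMMER3 text format
#'
#' Writes one or more models to a single HMMER3/f flat file. Probabilities
#' are encoded as negative natural logs; exact zeros become `*`. The output
#' is re-readable by [read_hmm()] and by HMMER itself.
#'
#' @param model A `profile_hmm` or a list of them.
#' @param path Output file path.
#' @export
write_hmm <- function(model, path) {
  models <- if (inherits(model, "profile_hmm")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    validate_profile_hmm(m)
    res <- alphabet_residues(m$alphabet)
    alph <- if (m$alphabet == "amino20") "amino" else "DNA"
    lines <- c(
      "HMMER3/f [markerphylo | profile emission/transition flat file]",
      sprintf("NAME  %s", m$marker_id),
      sprintf("LENG  %d", m$M),
      sprintf("ALPH  %s", alph)
    )
    if (!is.null(m$gathering_cutoff))
      lines <- c(lines, sprintf("GA    %.2f %.2f;",
                                m$gathering_cutoff, m$gathering_cutoff))
    fmt_rows <- function(mat) {
      # one string per row, fields right-aligned in 9 characters
      enc <- matrix(sprintf("%9s", nlog_fmt(mat)), nrow(mat), ncol(mat))
      do.call(paste0, as.data.frame(enc, stringsAsFactors = FALSE))
    }
    ks <- seq_len(m$M)
    node_match <- paste0(sprintf("%7d  ", ks),
                         fmt_rows(m$match_emission),
                         sprintf("%7d - - - -", ks))
    node_insert <- paste0("         ", fmt_rows(m$insert_emission))
    node_trans <- paste0("         ",
                         fmt_rows(m$transitions[-1L, , drop = FALSE]))
    body <- as.vector(rbind(node_match, node_insert, node_trans))
    lines <- c(lines,
      paste0("HMM      ", paste(sprintf("%9s", res), collapse = "")),
      paste0("         ", paste(sprintf("%9s",
        c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
        collapse = "")),
      paste0("  COMPO  ", paste(sprintf("%9s", nlog_fmt(m$null_freq)),
                                collapse = "")),
      # node 0: insert-0 emissions (null by convention) + begin transitions
      paste0("         ", paste(sprintf("%9s", nlog_fmt(m$null_freq)),
                                collapse = "")),
      paste0("         ", paste(sprintf("%9s", nlog_fmt(m$transitions[1L, ])),
                                collapse = "")),
      body)
    writeLines(c(lines, "//"), con)
  }
  invisible(path)
}

#' Read profile HMMs from a HMMER3 text file
#'
#' Parses one or more HMMER3/f records. `GA` gathering cutoffs and `COMPO`
#' background frequencies are honoured; `STATS` calibration lines are parsed
#' and ignored (scoring here is on bit scores, not E-values). `*` fields
#' decode to probability zero.
#'
#' @param path Path to a HMMER3 text file.
#' @return A named list of `profile_hmm` objects (names are marker ids).
#' @export
read_hmm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    if (!startsWith(lines[i], "HMMER3"))
      stop(sprintf("%s: malformed header on line %d (expected 'HMMER3/...')",
                   path, i), call. = FALSE)
    i <- i + 1L
    name <- NULL; leng <- NULL; alph <- NULL; ga <- NULL
    while (i <= n && !startsWith(trimws(lines[i]), "HMM ") &&
           trimws(lines[i]) != "HMM") {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) >= 2) {
        key <- toks[1]
        if (key == "NAME") name <- toks[2]
        if (key == "LENG") leng <- as.integer(toks[2])
        if (key == "ALPH") alph <- tolower(toks[2])
        if (key == "GA")   ga <- as.numeric(sub(";$", "", toks[2]))
      }
      i <- i + 1L
    }
    if (i > n) stop(sprintf("%s: record truncated before HMM body", path),
                    call. = FALSE)
    if (is.null(name) || is.null(leng) || is.null(alph))
      stop(sprintf("%s: header missing NAME/LENG/ALPH before line %d", path, i),
           call. = FALSE)
    alphabet <- switch(alph, amino = "amino20", dna = "dna4",
                       stop(sprintf("%s: unsupported alphabet '%s'", path, alph),
                            call. = FALSE))
    K <- length(alphabet_residues(alphabet))
    i <- i + 2L  # skip the residue header and the transition header line
    null_freq <- rep(1 / K, K)
    # optional COMPO line
    if (i <= n && startsWith(trimws(lines[i]), "COMPO")) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
      null_freq <- nlog_parse(toks[seq_len(K)], path, i)
      null_freq <- null_freq / sum(null_freq)
      i <- i + 1L
    }
    i <- i + 1L  # node-0 insert emissions (unused: I_0 scores at null)
    t0_toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    transitions <- matrix(0, leng + 1L, 7L)
    transitions[1L, ] <- nlog_parse(t0_toks[seq_len(7L)], path, i)
    i <- i + 1L
    if (i + 3L * leng - 1L > n)
      stop(sprintf("%s: record truncated in HMM body", path), call. = FALSE)
    block <- lines[i:(i + 3L * leng - 1L)]
    if (any(trimws(block) == "//"))
      stop(sprintf("%s: record truncated at node %d", path,
                   (which(trimws(block) == "//")[1] - 1L) %/% 3L + 1L),
           call. = FALSE)
    toks <- strsplit(trimws(block), "\\s+")
    m_idx <- seq(1L, 3L * leng, by = 3L)
    kseen <- suppressWarnings(as.integer(vapply(toks[m_idx], `[`, "", 1L)))
    if (!identical(kseen, seq_len(leng)))
      stop(sprintf("%s: node numbering broken near line %d", path,
                   i + 3L * (which(kseen != seq_len(leng))[1] - 1L)),
           call. = FALSE)
    grab <- function(rows, from, len, off) {
      flat <- unlist(lapply(toks[rows], function(x) x[from:(from + len - 1L)]))
      matrix(nlog_parse(flat, path, i + off), ncol = len, byrow = TRUE)
    }
    match_emission <- grab(m_idx, 2L, K, 0L)
    insert_emission <- grab(m_idx + 1L, 1L, K, 1L)
    transitions[-1L, ] <- grab(m_idx + 2L, 1L, 7L, 2L)
    i <- i + 3L * leng
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n || trimws(lines[i]) != "//")
      stop(sprintf("%s: missing '//' record terminator for %s", path, name),
           call. = FALSE)
    i <- i + 1L
    # renormalise read emissions (files carry rounded encodings)
    match_emission <- match_emission / rowSums(match_emission)
    ins_rs <- rowSums(insert_emission)
    ins_rs[ins_rs == 0] <- 1
    insert_emission <- insert_emission / ins_rs
    models[[name]] <- profile_hmm(
      marker_id = name, alphabet = alphabet,
      match_emission = match_emission, insert_emission = insert_emission,
      transitions = normalize_transitions(transitions),
      null_freq = null_freq, gathering_cutoff = ga
    )
  }
  if (!length(models)) stop(sprintf("%s: no HMM records found", path),
                            call. = FALSE)
  models
}

# Renormalise each source-state triplet; node-M structural zeros enforced.
normalize_transitions <- function(tr) {
  M1 <- nrow(tr)
  tr[M1, 3L] <- 0; tr[M1, 7L] <- 0
  for (idx in list(1:3, 4:5, 6:7)) {
    s <- rowSums(tr[, idx, drop = FALSE])
    s[s == 0] <- 1
    tr[, idx] <- tr[, idx, drop = FALSE] / s
  }
  tr
}
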