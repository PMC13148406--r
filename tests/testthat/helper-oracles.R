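# Brute-force scoring oracle: enumerates every glocal state path of a
# profile HMM over a sequence and returns max (Viterbi) and log-sum-exp
# (forward) of the path log-odds. Independent of the package's dynamic
# programming; only feasible for tiny models/sequences.
enum_path_scores <- function(model, codes1) {
  M <- model$M
  lmatch <- log(model$match_emission) -
    rep(log(model$null_freq), each = M)
  lins <- log(model$insert_emission) -
    rep(log(model$null_freq), each = M)
  ltr <- log(model$transitions)  # rows 1..M+1 = nodes 0..M
  L <- length(codes1)
  scores <- list()
  rec <- function(type, k, i, acc) {
    if (!is.finite(acc)) return()
    if (type == "E") { scores[[length(scores) + 1L]] <<- acc; return() }
    if (type == "M") {
      if (i >= L) return()
      a <- acc + lmatch[k, codes1[i + 1L]]
      if (k == M) {
        rec("E", 0L, i + 1L, a + ltr[M + 1L, 1L])
        rec("I", M, i + 1L, a + ltr[M + 1L, 2L])
      } else {
        rec("M", k + 1L, i + 1L, a + ltr[k + 1L, 1L])
        rec("I", k, i + 1L, a + ltr[k + 1L, 2L])
        rec("D", k + 1L, i + 1L, a + ltr[k + 1L, 3L])
      }
    } else if (type == "I") {
      if (i >= L) return()
      e <- if (k == 0L) 0 else lins[k, codes1[i + 1L]]
      a <- acc + e
      if (k == M) rec("E", 0L, i + 1L, a + ltr[M + 1L, 4L])
      else rec("M", k + 1L, i + 1L, a + ltr[k + 1L, 4L])
      rec("I", k, i + 1L, a + ltr[k + 1L, 5L])
    } else {
      if (k == M) rec("E", 0L, i, acc + ltr[M + 1L, 6L])
      else rec("M", k + 1L, i, acc + ltr[k + 1L, 6L])
      if (k < M) rec("D", k + 1L, i, acc + ltr[k + 1L, 7L])
    }
  }
  for (f in 0:L) {
    rec("M", 1L, f, ltr[1L, 1L])
    rec("I", 0L, f, ltr[1L, 2L])
    rec("D", 1L, f, ltr[1L, 3L])
  }
  v <- unlist(scores)
  mx <- max(v)
  list(forward = mx + log(sum(exp(v - mx))), viterbi = mx,
       n_paths = length(v))
}

# random normalized profile over the DNA alphabet (small, for oracle tests)
random_dna_model <- function(M) {
  rn <- function(n) { x <- stats::rexp(n); x / sum(x) }
  me <- t(replicate(M, rn(4)))
  ie <- t(replicate(M, rn(4)))
  tr <- matrix(0, M + 1L, 7L)
  for (r in seq_len(M + 1L)) tr[r, ] <- c(rn(3), rn(2), rn(2))
  tr[M + 1L, 1:3] <- c(rn(2), 0)
  tr[M + 1L, 6:7] <- c(1, 0)
  profile_hmm("m", "dna4", me, ie, tr, rn(4))
}

# induced quartet topology by tree pruning (independent of the package's
# distance-based method): returns the quartet's cherry partner of q[1],
# or NA if unresolved
quartet_partner_oracle <- function(tree, q) {
  kt <- ape::unroot(ape::keep.tip(tree, q))
  pp <- ape::prop.part(kt)
  for (idx in pp) {
    side <- kt$tip.label[idx]
    if (length(side) == 2L && all(side %in% q)) {
      if (q[1] %in% side) return(setdiff(side, q[1]))
      return(setdiff(q, c(q[1], side)))
    }
  }
  NA_character_
}

# brute-force quartet score: sum over gene trees and 4-subsets of agreement
quartet_score_oracle <- function(species, gene_trees) {
  total <- 0L
  for (gt in gene_trees) {
    tips <- sort(gt$tip.label)
    if (length(tips) < 4L) next
    qs <- utils::combn(tips, 4L)
    for (j in seq_len(ncol(qs))) {
      q <- qs[, j]
      pg <- quartet_partner_oracle(gt, q)
      ps <- quartet_partner_oracle(species, q)
      if (!is.na(pg) && !is.na(ps) && pg == ps) total <- total + 1L
    }
  }
  total
}

# column-by-column parsimony-informativeness classifier (independent oracle)
informative_columns_oracle <- function(mat, valid) {
  which(vapply(seq_len(ncol(mat)), function(j) {
    obs <- mat[, j]
    obs <- obs[obs %in% valid]
    tab <- table(obs)
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}
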