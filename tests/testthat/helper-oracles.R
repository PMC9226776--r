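# Independent oracles used by the test suite. These deliberately avoid the
# package's own DP/statistics code paths: paths are enumerated explicitly,
# alignments are enumerated over aligned-position subsets, and statistics
# are recomputed from their defining formulas.

# ---- exhaustive path enumeration for the profile-HMM engine ----

# every local path score (bits) of `seq` under `hmm`: entry 1/L into any
# match state, free exit from any match state, Plan7 transitions
enum_hmm_path_scores <- function(hmm, seq) {
  xi <- match(strsplit(seq, "")[[1]], aa_alphabet())
  n <- length(xi)
  L <- hmm$L
  lbg <- log2(hmm$background)
  emitM <- function(k, i) log2(hmm$match_emissions[k, xi[i]]) - lbg[xi[i]]
  emitI <- function(k, i) {
    log2(hmm$insert_emissions[k + 1, xi[i]]) - lbg[xi[i]]
  }
  lt <- lapply(hmm$transitions, log2)
  scores <- numeric(0)
  dfs <- function(state, k, i, sc) {
    if (state == "M") scores[[length(scores) + 1]] <<- sc
    if (state == "M" && k <= L - 1) {
      if (i < n) dfs("M", k + 1, i + 1, sc + lt$tm[k, "MM"] + emitM(k + 1, i + 1))
      if (i < n) dfs("I", k, i + 1, sc + lt$tm[k, "MI"] + emitI(k, i + 1))
      dfs("D", k + 1, i, sc + lt$tm[k, "MD"])
    } else if (state == "I") {
      if (i < n) dfs("M", k + 1, i + 1, sc + lt$ti[k, "IM"] + emitM(k + 1, i + 1))
      if (i < n) dfs("I", k, i + 1, sc + lt$ti[k, "II"] + emitI(k, i + 1))
    } else if (state == "D" && k <= L - 1) {
      if (i < n) dfs("M", k + 1, i + 1, sc + lt$td[k, "DM"] + emitM(k + 1, i + 1))
      dfs("D", k + 1, i, sc + lt$td[k, "DD"])
    }
  }
  for (k0 in seq_len(L)) {
    for (i0 in seq_len(n)) {
      dfs("M", k0, i0, -log2(L) + emitM(k0, i0))
    }
  }
  scores
}

oracle_forward_bits <- function(hmm, seq) {
  log2(sum(2^enum_hmm_path_scores(hmm, seq)))
}

oracle_viterbi_bits <- function(hmm, seq) {
  max(enum_hmm_path_scores(hmm, seq))
}

# a random, fully normalized profile HMM (gamma draws -> simplex rows)
random_hmm <- function(L, seed, concentration = 1) {
  set.seed(seed)
  simplex_rows <- function(nr, nc) {
    m <- matrix(rgamma(nr * nc, shape = concentration) + 1e-6, nr, nc)
    m / rowSums(m)
  }
  me <- simplex_rows(L, 20); colnames(me) <- aa_alphabet()
  ie <- simplex_rows(L + 1, 20); colnames(ie) <- aa_alphabet()
  nt <- max(L - 1, 0)
  tm <- simplex_rows(max(nt, 1), 3)[seq_len(nt), , drop = FALSE]
  ti <- simplex_rows(max(nt, 1), 2)[seq_len(nt), , drop = FALSE]
  td <- simplex_rows(max(nt, 1), 2)[seq_len(nt), , drop = FALSE]
  colnames(tm) <- c("MM", "MI", "MD")
  colnames(ti) <- c("IM", "II")
  colnames(td) <- c("DM", "DD")
  structure(
    list(family_name = paste0("rand", seed), L = L,
         match_emissions = me, insert_emissions = ie,
         transitions = list(tm = tm, ti = ti, td = td),
         background = aa_background(), match_columns = seq_len(L),
         calibration = NULL),
    class = "profile_hmm"
  )
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# ---- brute-force local alignment over aligned-position subsets ----

# optimal local alignment score by enumerating every set of aligned residue
# pairs (increasing in both sequences); affine gap cost open + ext * len on
# each sequence between consecutive pairs
oracle_sw_score <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  for (k in seq_len(min(na, nb))) {
    ia <- utils::combn(na, k, simplify = FALSE)
    ib <- utils::combn(nb, k, simplify = FALSE)
    for (sa in ia) {
      for (sb in ib) {
        sc <- sum(submat[cbind(av[sa], bv[sb])])
        if (k > 1) {
          da <- diff(sa) - 1
          db <- diff(sb) - 1
          sc <- sc - sum(ifelse(da > 0, open + ext * da, 0)) -
            sum(ifelse(db > 0, open + ext * db, 0))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

toy_submatrix <- function(match = 2L, mismatch = -1L) {
  aa <- aa_alphabet()
  m <- matrix(mismatch, 20, 20, dimnames = list(aa, aa))
  diag(m) <- match
  m
}

# global (end-to-end) alignment identity, for twilight-band verification
global_identity <- function(a, b, scheme = scoring_scheme()) {
  p <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  qc <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
  tc <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
  keep <- qc != "-" & tc != "-"
  sum(qc[keep] == tc[keep]) / sum(keep)
}

# ---- ANOSIM from its defining formula, with exhaustive label permutations ----

oracle_anosim_R <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  dv <- dmat[lower.tri(dmat)]
  rk <- rank(dv)
  wi <- outer(groups, groups, "==")[lower.tri(dmat)]
  (mean(rk[!wi]) - mean(rk[wi])) / (n * (n - 1) / 4)
}

# all permutations via recursive insertion (distinct code path from the
# package's lexicographic generator)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1)
  out <- list()
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

oracle_anosim_exact_p <- function(dmat, groups) {
  R_obs <- oracle_anosim_R(dmat, groups)
  Rs <- vapply(oracle_perms(length(groups)),
               function(p) oracle_anosim_R(dmat, groups[p]), numeric(1))
  mean(Rs >= R_obs - 1e-12)
}
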