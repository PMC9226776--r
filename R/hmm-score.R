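# log-odds parameterization handed to the C++ DP kernel
hmm_logodds <- function(hmm) {
  lbg <- log2(hmm$background)
  mlo <- sweep(log2(hmm$match_emissions), 2, lbg)
  L <- hmm$L
  if (L > 1) {
    # insert nodes I_1..I_{L-1} live in rows 2..L of insert_emissions
    ilo <- sweep(log2(hmm$insert_emissions[2:L, , drop = FALSE]), 2, lbg)
    tr <- lapply(hmm$transitions, log2)
    list(mlo = mlo, ilo = ilo,
         tmm = tr$tm[, "MM"], tmi = tr$tm[, "MI"], tmd = tr$tm[, "MD"],
         tim = tr$ti[, "IM"], tii = tr$ti[, "II"],
         tdm = tr$td[, "DM"], tdd = tr$td[, "DD"])
  } else {
    z <- numeric(0)
    list(mlo = mlo, ilo = matrix(0, 0, 20),
         tmm = z, tmi = z, tmd = z, tim = z, tii = z, tdm = z, tdd = z)
  }
}

#' Score a protein against a profile HMM
#'
#' Computes local-alignment log-odds scores in bits: the Viterbi (single
#' best path) score and the forward (all paths) score relative to the
#' background null model, with free entry into and exit from any match
#' state. `forward_bits >= viterbi_bits` always holds, since the forward
#' sum includes the Viterbi path.
#'
#' @param hmm a `profile_hmm` from [build_hmm()].
#' @param seq protein residue string (canonical amino acids).
#' @param path if `TRUE` also return the best state path.
#' @param on_noncanonical `"reject"` (default, error) or `"skip"` (drop
#'   non-canonical residues before scoring).
#' @return a list with `viterbi_bits`, `forward_bits` and (if requested)
#'   `best_path`, a tibble of `state` (`M`/`I`/`D`), `node`, `pos`.
#' @examples
#' m <- msa_family("toy", c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL"))
#' h <- build_hmm(m)
#' hmm_score(h, "ACDEFGHIKL")$viterbi_bits
#' @export
hmm_score <- function(hmm, seq, path = FALSE,
                      on_noncanonical = c("reject", "skip")) {
  stopifnot(inherits(hmm, "profile_hmm"))
  on_noncanonical <- match.arg(on_noncanonical)
  validate_hmm(hmm)
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("seq must be a single non-empty residue string", call. = FALSE)
  }
  idx <- aa_index(seq)
  if (anyNA(idx)) {
    if (on_noncanonical == "reject") {
      check_canonical(seq, "query")  # errors with the offending residues
    }
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) {
      stop("query has no canonical residues left after skipping",
           call. = FALSE)
    }
  }
  lo <- hmm_logodds(hmm)
  if (path) {
    res <- .hmm_dp_path(lo$mlo, lo$ilo, lo$tmm, lo$tmi, lo$tmd,
                        lo$tim, lo$tii, lo$tdm, lo$tdd, idx - 1L)
    bp <- tibble::as_tibble(as.data.frame(res$path))
    bp$state <- c("M", "I", "D")[bp$state]
    list(viterbi_bits = res$viterbi, forward_bits = res$forward,
         best_path = bp)
  } else {
    sc <- .hmm_dp_scores(lo$mlo, lo$ilo, lo$tmm, lo$tmi, lo$tmd,
                         lo$tim, lo$tii, lo$tdm, lo$tdd, idx - 1L)
    list(viterbi_bits = unname(sc["viterbi"]),
         forward_bits = unname(sc["forward"]))
  }
}

# fast path used by scan/calibration: viterbi bits for many sequences
hmm_viterbi_batch <- function(hmm, seqs) {
  lo <- hmm_logodds(hmm)
  idx <- lapply(seqs, function(s) check_canonical(s, "query") - 1L)
  .hmm_viterbi_many(lo$mlo, lo$ilo, lo$tmm, lo$tmi, lo$tmd,
                    lo$tim, lo$tii, lo$tdm, lo$tdd, idx)
}
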