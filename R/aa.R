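#' Amino-acid alphabet and background frequencies
#'
#' The 20 canonical amino acids in the order used throughout the package
#' (the Biostrings `AA_STANDARD` order), and the Robinson-Robinson
#' background frequencies conventionally used as the null model in protein
#' database searching.
#'
#' @return `aa_alphabet()` returns a character vector of length 20.
#'   `aa_background()` returns a named numeric vector of length 20 summing
#'   to 1.
#' @param uniform if `TRUE` return the uniform 1/20 background instead of
#'   the Robinson-Robinson table.
#' @examples
#' aa_alphabet()
#' sum(aa_background())
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aa_alphabet
#' @export
aa_background <- function(uniform = FALSE) {
  if (uniform) {
    return(setNames(rep(1 / 20, 20), aa_alphabet()))
  }
  f <- c(
    A = 0.78054, R = 0.51295, N = 0.44873, D = 0.53640, C = 0.19250,
    Q = 0.42644, E = 0.62949, G = 0.73770, H = 0.21992, I = 0.51420,
    L = 0.90191, K = 0.57438, M = 0.22425, F = 0.38556, P = 0.52028,
    S = 0.71200, T = 0.58413, W = 0.13298, Y = 0.32165, V = 0.64409
  ) / 10
  f / sum(f)
}

# residue string -> 1-based indices into aa_alphabet(); NA for non-canonical
aa_index <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], aa_alphabet())
}

# seeded random protein of length n from a background distribution
random_protein <- function(n, background = aa_background()) {
  paste(sample(aa_alphabet(), n, replace = TRUE, prob = background),
        collapse = "")
}

check_canonical <- function(seq, what = "sequence") {
  idx <- aa_index(seq)
  if (length(idx) == 0) {
    stop(what, " is empty", call. = FALSE)
  }
  if (anyNA(idx)) {
    bad <- unique(strsplit(toupper(seq), "")[[1]][is.na(idx)])
    stop(what, " contains non-canonical residues: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}
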