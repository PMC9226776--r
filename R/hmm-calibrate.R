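# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Calibrate a profile HMM's E-value statistics
#'
#' Fits a Gumbel (type-I extreme value) distribution by maximum likelihood
#' to the Viterbi bit scores of i.i.d. decoy sequences sampled from the
#' model's background distribution. The fitted scale `lambda` (per bit) and
#' location `tau` (bits) convert a bit score into a P-value,
#' `P(S >= s) = 1 - exp(-exp(-lambda (s - tau)))`, and [hmm_evalue()]
#' multiplies by the number of comparisons.
#'
#' @param hmm a `profile_hmm`.
#' @param n_decoys number of decoy sequences (>= 50; default 200).
#' @param decoy_length decoy length in residues (default 350, a typical
#'   alpha/beta-hydrolase length).
#' @param seed RNG seed for the decoy sample (default 42).
#' @return the model with a `calibration` list (`lambda`, `tau`,
#'   `n_decoys`, `decoy_length`, `seed`) attached.
#' @export
calibrate_hmm <- function(hmm, n_decoys = 200, decoy_length = 350,
                          seed = 42) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_decoys < 50) stop("n_decoys must be >= 50", call. = FALSE)
  stopifnot(decoy_length >= 1)
  decoys <- with_seed(seed, {
    replicate(n_decoys, random_protein(decoy_length, hmm$background))
  })
  scores <- hmm_viterbi_batch(hmm, decoys)
  fit <- fit_gumbel(scores)
  hmm$calibration <- list(lambda = fit$lambda, tau = fit$tau,
                          n_decoys = as.integer(n_decoys),
                          decoy_length = as.integer(decoy_length),
                          seed = as.integer(seed))
  hmm
}

# Maximum-likelihood Gumbel fit (maximum convention). Profiles the location
# out of the likelihood and solves the one-dimensional scale equation
#   beta = mean(x) - sum(x exp(-x/beta)) / sum(exp(-x/beta))
fit_gumbel <- function(x) {
  if (length(x) < 2 || stats::sd(x) == 0) {
    stop("degenerate score distribution: cannot calibrate", call. = FALSE)
  }
  xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - xbar) / beta)  # centred for numerical stability
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) / 50
  hi <- stats::sd(x) * 50
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  tau <- xbar - beta * log(mean(exp(-(x - xbar) / beta)))
  list(lambda = 1 / beta, tau = tau)
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `e_value = n_comparisons * (1 - exp(-exp(-lambda (bits - tau))))`:
#' the per-comparison P-value scaled by the number of queries in the scan.
#' Monotone decreasing in `bits` and linear in `n_comparisons`.
#'
#' @param bits Viterbi bit score (vectorized).
#' @param calibration a calibration list from [calibrate_hmm()].
#' @param n_comparisons number of comparisons (queries in the scan).
#' @return numeric vector of E-values.
#' @examples
#' cal <- list(lambda = 0.7, tau = 10)
#' hmm_evalue(10, cal, 1)  # 1 - exp(-1) at the location parameter
#' @export
hmm_evalue <- function(bits, calibration, n_comparisons = 1) {
  stopifnot(is.numeric(bits), calibration$lambda > 0, n_comparisons > 0)
  p <- -expm1(-exp(-calibration$lambda * (bits - calibration$tau)))
  n_comparisons * p
}
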