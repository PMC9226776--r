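#' Build a profile HMM from a family alignment
#'
#' Constructs a Plan7-style profile hidden Markov model from a multiple
#' sequence alignment. Alignment columns whose gap fraction is below
#' `gap_threshold` become match states, in order; residues in the remaining
#' columns are treated as insertions attached to the preceding match node.
#' Emission and transition probabilities are estimated from (optionally
#' weighted) counts with a Laplace pseudocount, so every probability is
#' strictly positive and each distribution sums to one.
#'
#' The model is scored in local mode (free entry into and exit from any
#' match state), which mirrors how protein profiles are searched against
#' metagenomic protein sets.
#'
#' @param msa an [msa_family()]; at least two rows.
#' @param gap_threshold columns with gap fraction strictly below this become
#'   match states (default 0.5).
#' @param pseudocount Laplace pseudocount added to every emission and
#'   transition count (default 1).
#' @param background length-20 background amino-acid distribution; defaults
#'   to [aa_background()].
#' @param weighting `"uniform"` (default) or `"position"`
#'   (Henikoff position-based sequence weights, rescaled to sum to the
#'   number of rows).
#' @return an object of class `profile_hmm` with fields `family_name`, `L`,
#'   `match_emissions` (L x 20), `insert_emissions` ((L+1) x 20, nodes
#'   I0..IL), `transitions` (list of `tm`, `ti`, `td` matrices for nodes
#'   1..L-1), `background`, `match_columns` and `calibration` (`NULL` until
#'   [calibrate_hmm()] is run).
#' @examples
#' m <- msa_family("toy", c("ACDE", "ACDE", "AC-E"))
#' h <- build_hmm(m)
#' h$L
#' @export
build_hmm <- function(msa, gap_threshold = 0.5, pseudocount = 1,
                      background = aa_background(),
                      weighting = c("uniform", "position")) {
  stopifnot(inherits(msa, "msa_family"))
  weighting <- match.arg(weighting)
  if (length(msa$rows) < 2) {
    stop("need at least 2 aligned sequences to build a model for family '",
         msa$family_name, "'", call. = FALSE)
  }
  stopifnot(gap_threshold > 0, gap_threshold < 1, pseudocount > 0)
  aa <- aa_alphabet()
  m <- msa_matrix(msa)
  n_rows <- nrow(m)

  gap_frac <- colMeans(m == "-")
  match_cols <- which(gap_frac < gap_threshold)
  L <- length(match_cols)
  if (L == 0) {
    stop("no alignment column passes the gap threshold for family '",
         msa$family_name, "'", call. = FALSE)
  }

  w <- switch(weighting,
    uniform = rep(1, n_rows),
    position = henikoff_weights(m) * n_rows
  )

  # node index for every column: match columns are 1..L, insert columns take
  # the index of the preceding match node (0 before the first)
  node_of_col <- cumsum(seq_len(ncol(m)) %in% match_cols)
  is_match_col <- seq_len(ncol(m)) %in% match_cols

  # ---- emissions ----
  match_counts <- matrix(0, L, 20, dimnames = list(NULL, aa))
  insert_counts <- matrix(0, L + 1, 20, dimnames = list(NULL, aa))
  for (j in seq_len(ncol(m))) {
    res <- m[, j]
    keep <- res != "-"
    if (!any(keep)) next
    idx <- match(res[keep], aa)
    ww <- w[keep]
    if (is_match_col[j]) {
      k <- node_of_col[j]
      for (u in seq_along(idx)) {
        match_counts[k, idx[u]] <- match_counts[k, idx[u]] + ww[u]
      }
    } else {
      k <- node_of_col[j] + 1L  # row k+1 holds I_k (row 1 = I_0)
      for (u in seq_along(idx)) {
        insert_counts[k, idx[u]] <- insert_counts[k, idx[u]] + ww[u]
      }
    }
  }
  match_emissions <- (match_counts + pseudocount) /
    (rowSums(match_counts) + 20 * pseudocount)
  insert_emissions <- (insert_counts + pseudocount) /
    (rowSums(insert_counts) + 20 * pseudocount)

  # ---- transitions from per-row state paths ----
  # path element encoding: "M<k>", "I<k>", "D<k>"
  cnt <- list(
    tm = matrix(0, max(L - 1, 0), 3, dimnames = list(NULL, c("MM", "MI", "MD"))),
    ti = matrix(0, max(L - 1, 0), 2, dimnames = list(NULL, c("IM", "II"))),
    td = matrix(0, max(L - 1, 0), 2, dimnames = list(NULL, c("DM", "DD")))
  )
  for (r in seq_len(n_rows)) {
    states <- character(0)
    nodes <- integer(0)
    for (j in seq_len(ncol(m))) {
      res <- m[r, j]
      if (is_match_col[j]) {
        states <- c(states, if (res == "-") "D" else "M")
        nodes <- c(nodes, node_of_col[j])
      } else if (res != "-") {
        states <- c(states, "I")
        nodes <- c(nodes, node_of_col[j])
      }
    }
    # trim leading/trailing deletes: local alignments enter/exit at matches
    emit <- which(states != "D")
    if (length(emit) == 0) next
    span <- seq(min(emit), max(emit))
    states <- states[span]; nodes <- nodes[span]
    if (length(states) < 2) next
    for (u in seq_len(length(states) - 1)) {
      from <- states[u]; to <- states[u + 1]; k <- nodes[u]
      if (from == "M" && k >= 1 && k <= L - 1) {
        if (to == "M") cnt$tm[k, "MM"] <- cnt$tm[k, "MM"] + w[r]
        else if (to == "I") cnt$tm[k, "MI"] <- cnt$tm[k, "MI"] + w[r]
        else cnt$tm[k, "MD"] <- cnt$tm[k, "MD"] + w[r]
      } else if (from == "I" && k >= 1 && k <= L - 1) {
        if (to == "M") cnt$ti[k, "IM"] <- cnt$ti[k, "IM"] + w[r]
        else if (to == "I") cnt$ti[k, "II"] <- cnt$ti[k, "II"] + w[r]
        # I -> D has no Plan7 transition; such (rare) pairs are not counted
      } else if (from == "D" && k >= 1 && k <= L - 1) {
        if (to == "M") cnt$td[k, "DM"] <- cnt$td[k, "DM"] + w[r]
        else if (to == "D") cnt$td[k, "DD"] <- cnt$td[k, "DD"] + w[r]
      }
    }
  }
  transitions <- list(
    tm = (cnt$tm + pseudocount) / (rowSums(cnt$tm) + 3 * pseudocount),
    ti = (cnt$ti + pseudocount) / (rowSums(cnt$ti) + 2 * pseudocount),
    td = (cnt$td + pseudocount) / (rowSums(cnt$td) + 2 * pseudocount)
  )

  background <- background / sum(background)
  hmm <- structure(
    list(family_name = msa$family_name, L = L,
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         transitions = transitions,
         background = setNames(as.numeric(background), aa),
         match_columns = match_cols,
         calibration = NULL),
    class = "profile_hmm"
  )
  validate_hmm(hmm)
  hmm
}

# Henikoff & Henikoff position-based weights, normalized to sum to 1
henikoff_weights <- function(m) {
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    keep <- col != "-"
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col[keep]]))
    w[keep] <- w[keep] + contrib
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Validate a profile HMM's probabilistic structure
#'
#' Checks that every emission row and every per-node transition distribution
#' sums to 1 within `tol`, that all probabilities are strictly positive, and
#' that the model has at least one match state.
#'
#' @param hmm a `profile_hmm`.
#' @param tol normalization tolerance (default 1e-12).
#' @return `hmm`, invisibly; errors on violation.
#' @export
validate_hmm <- function(hmm, tol = 1e-12) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (hmm$L < 1) stop("model has no match states", call. = FALSE)
  rows_ok <- function(p) {
    all(abs(rowSums(p) - 1) <= tol) && all(p > 0) && all(p <= 1)
  }
  if (!rows_ok(hmm$match_emissions)) {
    stop("match emissions are not normalized", call. = FALSE)
  }
  if (!rows_ok(hmm$insert_emissions)) {
    stop("insert emissions are not normalized", call. = FALSE)
  }
  if (hmm$L > 1) {
    for (nm in c("tm", "ti", "td")) {
      if (!rows_ok(hmm$transitions[[nm]])) {
        stop("transition block '", nm, "' is not normalized", call. = FALSE)
      }
    }
  }
  if (abs(sum(hmm$background) - 1) > tol) {
    stop("background is not normalized", call. = FALSE)
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$family_name, ": L = ", x$L,
      if (is.null(x$calibration)) " (uncalibrated)" else
        sprintf(" (lambda = %.3f, tau = %.2f bits)",
                x$calibration$lambda, x$calibration$tau),
      "\n", sep = "")
  invisible(x)
}

#' Build a profile database from a directory of family alignments
#'
#' Convenience wrapper: read every aligned FASTA in `dir`, build one profile
#' per family, and optionally calibrate each model's E-value statistics.
#'
#' @inheritParams build_hmm
#' @param dir directory of aligned FASTA files (one family each).
#' @param calibrate if `TRUE` (default) run [calibrate_hmm()] on each model.
#' @param n_decoys,decoy_length,seed calibration settings, see
#'   [calibrate_hmm()].
#' @return a named list of `profile_hmm` objects (class `hmm_db`).
#' @export
build_hmm_db <- function(dir, gap_threshold = 0.5, pseudocount = 1,
                         background = aa_background(), calibrate = TRUE,
                         n_decoys = 200, decoy_length = 350, seed = 42) {
  msas <- read_msa_dir(dir)
  hmm_db(lapply(msas, build_hmm, gap_threshold = gap_threshold,
                pseudocount = pseudocount, background = background),
         calibrate = calibrate, n_decoys = n_decoys,
         decoy_length = decoy_length, seed = seed)
}

#' Assemble profile HMMs into a database
#'
#' @param hmms list of `profile_hmm` objects.
#' @param calibrate if `TRUE` calibrate every uncalibrated member.
#' @inheritParams build_hmm_db
#' @return a named list of class `hmm_db`.
#' @export
hmm_db <- function(hmms, calibrate = FALSE, n_decoys = 200,
                   decoy_length = 350, seed = 42) {
  stopifnot(all(vapply(hmms, inherits, TRUE, "profile_hmm")))
  if (calibrate) {
    hmms <- lapply(hmms, function(h) {
      if (is.null(h$calibration)) {
        calibrate_hmm(h, n_decoys = n_decoys, decoy_length = decoy_length,
                      seed = seed)
      } else h
    })
  }
  names(hmms) <- vapply(hmms, `[[`, "", "family_name")
  structure(hmms[order(names(hmms))], class = c("hmm_db", "list"))
}

#' @export
print.hmm_db <- function(x, ...) {
  cat("<hmm_db> ", length(x), " profile HMMs: ",
      paste(head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
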