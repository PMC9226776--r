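#' Scoring scheme for protein similarity search
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' E-value constants. Defaults are the conventional gapped BLOSUM62/11/1
#' parameters (`lambda = 0.267`, `K = 0.041`).
#'
#' @param matrix_name name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or the name to record for `matrix` if that is
#'   supplied directly.
#' @param matrix optional 20x20 (or larger) symmetric integer substitution
#'   matrix; overrides `matrix_name` lookup.
#' @param gap_open,gap_extend positive gap penalties (opening charged once,
#'   extension per gapped position).
#' @param karlin_lambda,karlin_K Karlin-Altschul constants for
#'   `E = K m n exp(-lambda S)`.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", matrix = NULL,
                           gap_open = 11, gap_extend = 1,
                           karlin_lambda = 0.267, karlin_K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_K > 0)
  if (is.null(matrix)) {
    e <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    matrix <- get(matrix_name, envir = e)
  }
  aa <- aa_alphabet()
  if (!all(aa %in% rownames(matrix))) {
    stop("substitution matrix must cover the 20 canonical amino acids",
         call. = FALSE)
  }
  sub <- matrix[aa, aa]
  if (!isSymmetric(unname(sub))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  structure(
    list(matrix_name = matrix_name, matrix = sub, gap_open = gap_open,
         gap_extend = gap_extend, karlin_lambda = karlin_lambda,
         karlin_K = karlin_K),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$matrix_name, ", gap ", x$gap_open, "/",
      x$gap_extend, ", lambda ", x$karlin_lambda, ", K ", x$karlin_K,
      "\n", sep = "")
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment raw score `S`
#' in a search space of `m * n` residue pairs.
#'
#' @param score raw alignment score (vectorized).
#' @param m,n query length and effective database length (residues).
#' @param scheme a [scoring_scheme()].
#' @return numeric E-values.
#' @export
karlin_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * score)
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman alignment with affine gaps (via Biostrings'
#' dynamic-programming aligner). Identity is counted over aligned
#' residue-pair columns only (gapped columns excluded from the
#' denominator, as in BLAST percent-identity reporting); query coverage is
#' the aligned query span divided by the query length.
#'
#' @param query,target ungapped protein residue strings.
#' @param scheme a [scoring_scheme()].
#' @return a list with `raw_score`, `identity`, `query_coverage`, and the
#'   gapped `query_aln` / `target_aln` strings.
#' @examples
#' sw_align("ACDEFGHIKL", "ACDEFGHIKL")$identity
#' @export
sw_align <- function(query, target, scheme = scoring_scheme()) {
  check_canonical(query, "query")
  check_canonical(target, "target")
  p <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(target),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  qa <- as.character(Biostrings::alignedPattern(p))
  ta <- as.character(Biostrings::alignedSubject(p))
  qc <- strsplit(qa, "")[[1]]
  tc <- strsplit(ta, "")[[1]]
  pair_cols <- qc != "-" & tc != "-"
  n_pairs <- sum(pair_cols)
  identity <- if (n_pairs > 0) sum(qc[pair_cols] == tc[pair_cols]) / n_pairs
              else 0
  list(raw_score = Biostrings::score(p),
       identity = identity,
       query_coverage = sum(qc != "-") / nchar(query),
       query_aln = qa, target_aln = ta)
}

# identity over an end-to-end (global) alignment: matched residue pairs /
# aligned residue-pair columns. Used where full-length similarity is the
# quantity of interest (e.g. twilight-decoy construction).
aln_global_identity <- function(a, b, scheme = scoring_scheme()) {
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

check_reference_set <- function(reference_set) {
  stopifnot(is.data.frame(reference_set))
  need <- c("seq_id", "family_name", "sequence")
  if (!all(need %in% names(reference_set))) {
    stop("reference set needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reference_set) == 0) {
    stop("empty reference set", call. = FALSE)
  }
  invisible(reference_set)
}

#' Similarity search against a family-labelled reference set
#'
#' Aligns each query against every reference sequence and reports the best
#' hit (lowest E-value; ties broken by higher raw score, then by target
#' id). The E-value search space is the query length times the total
#' residue count of the reference set, so within a query the E-value
#' ranking coincides with the raw-score ranking. Queries whose best
#' E-value exceeds `e_cutoff` get no row.
#'
#' @param queries tibble with `protein_id` and `sequence` columns.
#' @param reference_set tibble with `seq_id`, `family_name`, `sequence`.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff E-value threshold (default `1e-10`).
#' @return a tibble of best hits: `protein_id`, `target_id`,
#'   `target_family`, `raw_score`, `e_value`, `identity`, `query_coverage`.
#' @export
sim_search <- function(queries, reference_set, scheme = scoring_scheme(),
                       e_cutoff = 1e-10) {
  stopifnot(is.data.frame(queries),
            all(c("protein_id", "sequence") %in% names(queries)),
            e_cutoff > 0)
  check_reference_set(reference_set)
  refs <- Biostrings::AAStringSet(setNames(reference_set$sequence,
                                           reference_set$seq_id))
  n_db <- sum(Biostrings::width(refs))
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    q <- queries$sequence[i]
    scores <- Biostrings::pairwiseAlignment(
      pattern = refs, subject = Biostrings::AAString(q),
      type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE
    )
    ev <- karlin_evalue(scores, nchar(q), n_db, scheme)
    ord <- order(ev, -scores, reference_set$seq_id)
    best <- ord[1]
    if (ev[best] > e_cutoff) return(NULL)
    aln <- sw_align(q, reference_set$sequence[best], scheme)
    tibble::tibble(
      protein_id = queries$protein_id[i],
      target_id = reference_set$seq_id[best],
      target_family = reference_set$family_name[best],
      raw_score = scores[best],
      e_value = ev[best],
      identity = aln$identity,
      query_coverage = aln$query_coverage
    )
  })
}

#' Best similarity hit for a single query
#'
#' @param query an ungapped protein residue string.
#' @inheritParams sim_search
#' @return a one-row tibble as in [sim_search()], or `NULL` if no hit
#'   passes `e_cutoff`.
#' @export
sim_best_hit <- function(query, reference_set, scheme = scoring_scheme(),
                         e_cutoff = 1e-10) {
  res <- sim_search(tibble::tibble(protein_id = "query", sequence = query),
                    reference_set, scheme, e_cutoff)
  if (nrow(res) == 0) NULL else res
}

#' Read a reference registry (FASTA + family map)
#'
#' @param fasta FASTA of reference protein sequences.
#' @param map_tsv TSV with columns `seq_id`, `family_name`.
#' @return a reference-set tibble for [sim_search()].
#' @export
read_reference_set <- function(fasta, map_tsv) {
  seqs <- read_proteins(fasta)
  map <- readr::read_tsv(map_tsv, show_col_types = FALSE)
  if (!all(c("seq_id", "family_name") %in% names(map))) {
    stop("reference map needs columns seq_id, family_name", call. = FALSE)
  }
  missing <- setdiff(seqs$protein_id, map$seq_id)
  if (length(missing) > 0) {
    stop("reference sequences without family labels: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(
    dplyr::rename(seqs, seq_id = "protein_id"),
    map, by = "seq_id"
  ) |>
    dplyr::select("seq_id", "family_name", "sequence")
}
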