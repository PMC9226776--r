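#' Scan proteins against a profile HMM database
#'
#' Scores every protein against every calibrated profile and reports hits
#' with `e_value <= e_cutoff`. Within a protein, hits are ranked by
#' ascending E-value, ties broken by higher bit score and then by family
#' name, so rank 1 is the protein's best family.
#'
#' @param proteins tibble with `protein_id` and `sequence` columns (e.g.
#'   from [read_proteins()]).
#' @param db an `hmm_db` (all members calibrated).
#' @param e_cutoff E-value threshold; hits above it are dropped
#'   (default `1e-10`).
#' @return a tibble of hits: `protein_id`, `family_name`, `bit_score`,
#'   `e_value`, `rank`, sorted by protein and rank.
#' @export
hmm_scan <- function(proteins, db, e_cutoff = 1e-10) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)),
            e_cutoff > 0)
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein ids in query set", call. = FALSE)
  }
  empty <- tibble::tibble(protein_id = character(), family_name = character(),
                          bit_score = numeric(), e_value = numeric(),
                          rank = integer())
  if (nrow(proteins) == 0) return(empty)
  uncal <- names(db)[vapply(db, function(h) is.null(h$calibration), TRUE)]
  if (length(uncal) > 0) {
    stop("uncalibrated profile(s): ", paste(uncal, collapse = ", "),
         call. = FALSE)
  }
  n_comp <- nrow(proteins)
  hits <- purrr::map_dfr(db, function(h) {
    bits <- hmm_viterbi_batch(h, proteins$sequence)
    tibble::tibble(protein_id = proteins$protein_id,
                   family_name = h$family_name,
                   bit_score = bits,
                   e_value = hmm_evalue(bits, h$calibration, n_comp))
  })
  hits <- dplyr::filter(hits, .data$e_value <= e_cutoff)
  if (nrow(hits) == 0) return(empty)
  hits |>
    dplyr::arrange(.data$protein_id, .data$e_value,
                   dplyr::desc(.data$bit_score), .data$family_name) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Best profile-HMM hit per protein
#'
#' @param hits a hit table from [hmm_scan()].
#' @return the rank-1 row per protein.
#' @export
hmm_best_hits <- function(hits) {
  dplyr::filter(hits, .data$rank == 1L)
}
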