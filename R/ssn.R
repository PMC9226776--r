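#' Build a sequence similarity network
#'
#' All-against-all Smith-Waterman comparison of a protein set. An
#' undirected edge connects two sequences when the pairwise E-value is at
#' most `e_cutoff` and the raw alignment score is at least `min_score`
#' (the EFI-EST-style gates: E <= 1e-10 and score >= 16 for family
#' verification; E <= 1e-16 for the stricter clustering mode). The
#' pairwise E-value search space is the product of the two sequence
#' lengths.
#'
#' @param sequences tibble with `protein_id` and `sequence` columns
#'   (>= 2 rows).
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff pairwise E-value gate (default `1e-10`).
#' @param min_score raw alignment score gate (default 16).
#' @return a tibble of class `lipo_ssn` with one row per edge: `from`,
#'   `to`, `raw_score`, `e_value`, `identity`; all node ids are kept in
#'   the `nodes` attribute so singletons are not lost.
#' @export
build_ssn <- function(sequences, scheme = scoring_scheme(),
                      e_cutoff = 1e-10, min_score = 16) {
  stopifnot(is.data.frame(sequences),
            all(c("protein_id", "sequence") %in% names(sequences)))
  if (nrow(sequences) < 2) {
    stop("need at least 2 sequences to build a network", call. = FALSE)
  }
  n <- nrow(sequences)
  ids <- sequences$protein_id
  seqs <- sequences$sequence
  lens <- nchar(seqs)
  edges <- purrr::map_dfr(seq_len(n - 1), function(i) {
    targets <- Biostrings::AAStringSet(seqs[(i + 1):n])
    scores <- Biostrings::pairwiseAlignment(
      pattern = targets, subject = Biostrings::AAString(seqs[i]),
      type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE
    )
    j <- (i + 1):n
    ev <- karlin_evalue(scores, lens[i], lens[j], scheme)
    keep <- ev <= e_cutoff & scores >= min_score
    if (!any(keep)) return(NULL)
    tibble::tibble(from = ids[i], to = ids[j][keep],
                   raw_score = scores[keep], e_value = ev[keep])
  })
  if (nrow(edges) > 0) {
    edges$identity <- purrr::map2_dbl(edges$from, edges$to, function(a, b) {
      sw_align(seqs[match(a, ids)], seqs[match(b, ids)], scheme)$identity
    })
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            raw_score = numeric(), e_value = numeric(),
                            identity = numeric())
  }
  structure(edges, nodes = ids,
            class = c("lipo_ssn", class(tibble::tibble())))
}

#' Convert a similarity network to an igraph object
#'
#' @param ssn a `lipo_ssn` from [build_ssn()].
#' @return an undirected `igraph` graph with edge attributes `raw_score`,
#'   `e_value`, `identity`; singleton sequences are included as isolated
#'   vertices.
#' @export
ssn_graph <- function(ssn) {
  igraph::graph_from_data_frame(as.data.frame(ssn), directed = FALSE,
                                vertices = attr(ssn, "nodes"))
}

#' Write a similarity network to GraphML and/or TSV
#'
#' @param ssn a `lipo_ssn`.
#' @param graphml,tsv output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_ssn <- function(ssn, graphml = NULL, tsv = NULL) {
  if (!is.null(tsv)) readr::write_tsv(tibble::as_tibble(ssn), tsv)
  if (!is.null(graphml)) {
    igraph::write_graph(ssn_graph(ssn), graphml, format = "graphml")
  }
  invisible(c(graphml = graphml, tsv = tsv))
}
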