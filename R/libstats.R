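#' Hit-rate arithmetic for function-based screening libraries
#'
#' Computes the standard yield statistics of activity-based (tributyrin
#' plate) screening from library bookkeeping records: hits per million
#' clones, gigabases of cloned DNA screened, and hits per gigabase:
#' \deqn{hits/10^6\ clones = hits \times 10^6 / clones}
#' \deqn{Gb\ screened = clones \times insert_{kb} \times 10^3 / 10^9}
#' \deqn{hits/Gb = hits / Gb\ screened}
#'
#' @param records tibble with columns `library_id`, `sample`, `clones`
#'   (> 0), `mean_insert_kb` (> 0) and `confirmed_hits`
#'   (0 <= hits <= clones).
#' @return a tibble with the input columns plus `hits_per_million_clones`,
#'   `gb_screened` and `hits_per_gb` (unrounded; see
#'   [format_library_rates()] for display rounding).
#' @examples
#' recs <- tibble::tibble(library_id = "L1", sample = "compost55",
#'                        clones = 675200, mean_insert_kb = 5.3,
#'                        confirmed_hits = 156)
#' library_hit_rates(recs)$hits_per_gb  # ~43.6
#' @export
library_hit_rates <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("library_id", "sample", "clones", "mean_insert_kb",
                  "confirmed_hits") %in% names(records)))
  if (any(records$clones <= 0)) {
    stop("clone counts must be positive", call. = FALSE)
  }
  stopifnot(all(records$mean_insert_kb > 0),
            all(records$confirmed_hits >= 0),
            all(records$confirmed_hits <= records$clones))
  records |>
    tibble::as_tibble() |>
    dplyr::mutate(
      hits_per_million_clones = .data$confirmed_hits * 1e6 / .data$clones,
      gb_screened = .data$clones * .data$mean_insert_kb * 1e3 / 1e9,
      hits_per_gb = .data$confirmed_hits / .data$gb_screened
    )
}

#' Per-sample totals of screening effort and yield
#'
#' @param rates output of [library_hit_rates()].
#' @return a tibble per `sample`: `n_libraries`, `total_clones`,
#'   `total_gb_screened`, `total_hits`, and the pooled `hits_per_gb`.
#' @export
library_sample_totals <- function(rates) {
  rates |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_libraries = dplyr::n(),
      total_clones = sum(.data$clones),
      total_gb_screened = sum(.data$gb_screened),
      total_hits = sum(.data$confirmed_hits),
      hits_per_gb = sum(.data$confirmed_hits) / sum(.data$gb_screened),
      .groups = "drop"
    )
}

#' Display rounding matching the conventional table layout
#'
#' Hits per million clones to the nearest integer, hits per Gb to one
#' decimal, Gb totals to two decimals.
#'
#' @param rates output of [library_hit_rates()].
#' @return the table with rounded display columns.
#' @export
format_library_rates <- function(rates) {
  rates |>
    dplyr::mutate(
      hits_per_million_clones = round(.data$hits_per_million_clones),
      gb_screened = round(.data$gb_screened, 2),
      hits_per_gb = round(.data$hits_per_gb, 1)
    )
}

#' Read library screening records from TSV
#'
#' @param path TSV with the [library_hit_rates()] input columns.
#' @return a tibble of records.
#' @export
read_library_records <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
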