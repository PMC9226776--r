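#' LPGM abundance normalization
#'
#' Converts raw per-sample screening hit counts into LPGM units
#' (Lipolytic hits Per Gigabase of assembled metagenome per Million
#' predicted genes):
#' \deqn{LPGM = count \times \frac{10^9}{assembly\ bp} \times
#'   \frac{10^6}{gene\ count}}
#' so samples of different assembly size and gene yield become
#' comparable. Zero counts stay zero; the formula is linear in the count
#' and inversely proportional to both normalizers.
#'
#' @param counts long tibble with columns `sample_id`, `category` (family
#'   or genus) and `count` (non-negative).
#' @param metadata tibble with `sample_id`, `habitat`, `assembly_bp`,
#'   `gene_count`; must cover every sample in `counts`.
#' @return a tibble of class `lipo_abundance`: `sample_id`, `habitat`,
#'   `category`, `count`, `lpgm`, with the metadata kept as an attribute.
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", category = "famA",
#'                          count = 1000)
#' meta <- tibble::tibble(sample_id = "s1", habitat = "compost",
#'                        assembly_bp = 1e9, gene_count = 1e6)
#' lpgm_normalize(counts, meta)$lpgm  # 1000
#' @export
lpgm_normalize <- function(counts, metadata) {
  stopifnot(is.data.frame(counts),
            all(c("sample_id", "category", "count") %in% names(counts)),
            all(c("sample_id", "habitat", "assembly_bp", "gene_count") %in%
                  names(metadata)))
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  missing <- setdiff(unique(counts$sample_id), metadata$sample_id)
  if (length(missing) > 0) {
    stop("samples without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(metadata$assembly_bp > 0), all(metadata$gene_count > 0),
            all(nzchar(metadata$habitat)))
  out <- counts |>
    dplyr::inner_join(metadata, by = "sample_id") |>
    dplyr::mutate(lpgm = .data$count * (1e9 / .data$assembly_bp) *
                    (1e6 / .data$gene_count)) |>
    dplyr::select("sample_id", "habitat", "category", "count", "lpgm")
  structure(out, metadata = tibble::as_tibble(metadata),
            class = c("lipo_abundance", class(tibble::tibble())))
}

#' Samples-by-categories abundance matrix
#'
#' @param x a `lipo_abundance` from [lpgm_normalize()], or a long tibble
#'   with `sample_id`, `category` and the value column.
#' @param value which column to spread (default `"lpgm"`).
#' @return a numeric matrix, samples in rows, categories in columns;
#'   missing combinations are 0.
#' @export
abundance_matrix <- function(x, value = "lpgm") {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("sample_id", "category", value)],
    names_from = "category", values_from = dplyr::all_of(value),
    values_fill = 0, values_fn = sum
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m[, order(colnames(m)), drop = FALSE]
}

#' Heatmap transform for LPGM values
#'
#' `log10(x + 1)`: monotone, maps 0 to 0, compresses the heavy right tail
#' of LPGM values for display and clustering.
#'
#' @param x non-negative numeric vector or matrix.
#' @return transformed values of the same shape.
#' @export
lpgm_log10 <- function(x) {
  if (any(x < 0)) stop("LPGM values must be non-negative", call. = FALSE)
  log10(x + 1)
}

#' Heatmap-style plot of an abundance table
#'
#' Tile plot of log10(LPGM + 1) per sample and category, with samples
#' grouped by habitat.
#'
#' @param object a `lipo_abundance`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lipo_abundance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$log_lpgm <- lpgm_log10(df$lpgm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$sample_id,
                                   fill = .data$log_lpgm)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$habitat), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "log10(LPGM + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}
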