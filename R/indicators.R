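#' Point-biserial indicator association analysis
#'
#' Links each category (typically a genus) to the habitat or habitat
#' combination it indicates. For every subset of habitats of size 1 to
#' `max_subset_size` (the full habitat set is never a candidate), the
#' point-biserial correlation `r` between the category's abundance vector
#' and the subset's binary membership vector is computed; each category
#' reports its best subset (maximum `r`). Significance comes from a
#' seeded permutation test of the *selected-maximum* statistic: in every
#' permutation the abundance vector is shuffled across samples and the
#' maximum `r` over all candidate subsets is recomputed, which accounts
#' for the subset selection. A constant abundance vector has `r` defined
#' as 0 and is never significant.
#'
#' @param x a `lipo_abundance` from [lpgm_normalize()], or a
#'   samples-by-categories matrix (then `habitats` is required).
#' @param habitats habitat label per sample (taken from `x` when it is a
#'   `lipo_abundance`).
#' @param max_subset_size largest habitat combination considered
#'   (default 3).
#' @param n_permutations permutations for the p-value (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param func `"r"` (plain point-biserial, default) or `"r.g"`
#'   (group-equalized variant: a weighted correlation in which every
#'   habitat contributes equal total weight regardless of its sample
#'   count).
#' @param keep_all if `TRUE` return every category with its best subset
#'   and p-value; by default only significant positive associations
#'   (positive correlation with p at most `alpha`) are returned.
#' @return a tibble of class `lipo_indicators`: `category`, `habitat_set`
#'   (labels joined with `+`), `n_habitats`, `r`, `p_value`, `mean_lpgm`
#'   (mean abundance across all samples), and `significant`.
#' @export
indicator_analysis <- function(x, habitats = NULL, max_subset_size = 3,
                               n_permutations = 999, alpha = 0.05,
                               seed = 1, func = c("r", "r.g"),
                               keep_all = FALSE) {
  func <- match.arg(func)
  if (inherits(x, "lipo_abundance")) {
    meta <- attr(x, "metadata")
    m <- abundance_matrix(x)
    habitats <- meta$habitat[match(rownames(m), meta$sample_id)]
  } else {
    m <- as.matrix(x)
    if (is.null(habitats)) {
      stop("habitats must be supplied with a plain matrix", call. = FALSE)
    }
  }
  habitats <- as.character(habitats)
  stopifnot(length(habitats) == nrow(m))
  if (any(table(habitats) < 2)) {
    stop("every habitat needs at least 2 samples", call. = FALSE)
  }
  hab_levels <- sort(unique(habitats))
  K <- length(hab_levels)
  max_subset_size <- min(max_subset_size, K - 1)
  if (max_subset_size < 1) {
    stop("need at least 2 distinct habitats", call. = FALSE)
  }

  subsets <- unlist(lapply(seq_len(max_subset_size), function(s) {
    combn(hab_levels, s, simplify = FALSE)
  }), recursive = FALSE)
  memb <- vapply(subsets, function(s) as.numeric(habitats %in% s),
                 numeric(length(habitats)))
  colnames(memb) <- vapply(subsets, paste, "", collapse = "+")

  w <- if (func == "r.g") {
    nk <- table(habitats)
    length(habitats) / (K * as.numeric(nk[habitats]))
  } else {
    rep(1, length(habitats))
  }

  # weighted Pearson correlation of abundance columns against memberships;
  # columns with zero variance get r = 0
  rmat_of <- function(a) {
    wcor_cols(a, memb, w)
  }
  r_obs <- rmat_of(m)  # categories x subsets

  best_idx <- apply(r_obs, 1, which.max)
  best_r <- r_obs[cbind(seq_len(nrow(r_obs)), best_idx)]

  # permutation null of the max-over-subsets statistic, shared across
  # categories: shuffle sample order, recompute every category's max r
  null_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(nrow(m))
      apply(rmat_of(m[perm, , drop = FALSE]), 1, max)
    }, numeric(ncol(m)))
  })  # categories x n_permutations
  null_max <- matrix(null_max, nrow = ncol(m))
  p_value <- (1 + rowSums(null_max >= best_r - 1e-12)) / (1 + n_permutations)
  constant <- apply(m, 2, function(col) stats::sd(col) == 0)
  p_value[constant] <- 1

  out <- tibble::tibble(
    category = colnames(m),
    habitat_set = colnames(memb)[best_idx],
    n_habitats = lengths(subsets)[best_idx],
    r = unname(best_r),
    p_value = unname(p_value),
    mean_lpgm = unname(colMeans(m)),
    significant = best_r > 0 & p_value <= alpha
  )
  if (!keep_all) out <- dplyr::filter(out, .data$significant)
  structure(out, alpha = alpha, habitats = hab_levels,
            class = c("lipo_indicators", class(tibble::tibble())))
}

# weighted Pearson correlation of each column of A against each column of B;
# zero-variance columns yield 0
wcor_cols <- function(A, B, w) {
  w <- w / sum(w)
  Ac <- sweep(A, 2, colSums(A * w))
  Bc <- sweep(B, 2, colSums(B * w))
  cov <- t(Ac * w) %*% Bc
  sa <- sqrt(colSums(Ac^2 * w))
  sb <- sqrt(colSums(Bc^2 * w))
  r <- cov / (sa %o% sb)
  r[!is.finite(r)] <- 0
  r
}

#' @rdname indicator_analysis
#' @param x a `lipo_indicators` object (for the tidier).
#' @param ... unused.
#' @export
glance.lipo_indicators <- function(x, ...) {
  tibble::tibble(n.significant = sum(x$significant),
                 n.unique = sum(x$significant & x$n_habitats == 1),
                 alpha = attr(x, "alpha"))
}

#' Habitat-genus bipartite association network
#'
#' Builds the bipartite network linking habitats to the genera that
#' indicate them: one edge per (habitat, genus) pair in a significant
#' positive association, weighted by the point-biserial `r`. Genera whose
#' mean LPGM across all samples falls below `min_mean_lpgm` (default 0.5)
#' are dropped. Each genus is flagged `unique` (associated with a single
#' habitat), `pair` (two) or `multi` (more than two).
#'
#' @param associations a `lipo_indicators` table (significant rows are
#'   used; pass the default filtered output).
#' @param min_mean_lpgm mean-abundance floor (default 0.5).
#' @return a tibble of class `lipo_bipartite` with `habitat`, `category`,
#'   `r`, `n_habitats`, `association`; the genus flags are also available
#'   via the `genera` attribute.
#' @export
bipartite_network <- function(associations, min_mean_lpgm = 0.5) {
  a <- tibble::as_tibble(associations)
  if ("significant" %in% names(a)) {
    a <- dplyr::filter(a, .data$significant)
  }
  a <- dplyr::filter(a, .data$r > 0, .data$mean_lpgm >= min_mean_lpgm)
  edges <- a |>
    dplyr::mutate(habitat = strsplit(.data$habitat_set, "+", fixed = TRUE)) |>
    tidyr::unnest("habitat") |>
    dplyr::mutate(association = dplyr::case_when(
      .data$n_habitats == 1 ~ "unique",
      .data$n_habitats == 2 ~ "pair",
      TRUE ~ "multi"
    )) |>
    dplyr::select("habitat", category = "category", r = "r",
                  "n_habitats", "association")
  genera <- dplyr::distinct(edges, .data$category, .data$n_habitats,
                            .data$association)
  structure(edges, genera = genera,
            class = c("lipo_bipartite", class(tibble::tibble())))
}

#' Convert a bipartite association network to igraph
#'
#' @param net a `lipo_bipartite` from [bipartite_network()].
#' @return an undirected bipartite `igraph` graph (`type` is `TRUE` for
#'   genera, `FALSE` for habitats; edge weight is `r`).
#' @export
bipartite_graph <- function(net) {
  edges <- tibble::as_tibble(net)
  verts <- dplyr::bind_rows(
    tibble::tibble(name = unique(edges$habitat), type = FALSE),
    tibble::tibble(name = unique(edges$category), type = TRUE)
  )
  igraph::graph_from_data_frame(
    edges[, c("habitat", "category", "r")], directed = FALSE,
    vertices = verts
  )
}

#' Plot a habitat-genus association network
#'
#' @param net a `lipo_bipartite`.
#' @param ... unused.
#' @return a ggplot object (simple bipartite layout).
#' @export
plot_bipartite <- function(net, ...) {
  edges <- tibble::as_tibble(net)
  habs <- sort(unique(edges$habitat))
  gens <- sort(unique(edges$category))
  pos <- dplyr::bind_rows(
    tibble::tibble(name = habs, x = 0,
                   y = seq_along(habs) / (length(habs) + 1), kind = "habitat"),
    tibble::tibble(name = gens, x = 1,
                   y = seq_along(gens) / (length(gens) + 1), kind = "genus")
  )
  seg <- edges |>
    dplyr::left_join(pos[pos$kind == "habitat", ],
                     by = c(habitat = "name")) |>
    dplyr::left_join(pos[pos$kind == "genus", ], by = c(category = "name"),
                     suffix = c("", ".g"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x.g, yend = .data$y.g,
                                       linewidth = .data$r),
                          colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$kind), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       hjust = ifelse(pos$kind == "habitat", 1.2, -0.2),
                       size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}
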