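#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)}: symmetric,
#' zero on the diagonal, bounded between 0 and 1. Computed with
#' \code{vegan::vegdist}. A pair of all-zero samples has an undefined
#' dissimilarity; it is set to 0 with a warning.
#'
#' @param x non-negative samples-by-categories matrix (or a
#'   `lipo_abundance`, which is spread with [abundance_matrix()]).
#' @return a `dist` object.
#' @examples
#' m <- rbind(a = c(1, 2, 0), b = c(3, 0, 0))
#' bray_curtis(m)  # 4/6
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "lipo_abundance")) x <- abundance_matrix(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundance values", call. = FALSE)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d) || any(is.nan(d))) {
    warning("all-zero sample pair(s): their Bray-Curtis distance is set to 0")
    d[is.na(d) | is.nan(d)] <- 0
  }
  d
}

#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the Lance-Williams Ward update applied to
#' the raw dissimilarities (the classic `"ward.D"` convention, no
#' pre-squaring), as conventionally paired with Bray-Curtis profiles.
#'
#' @param d a `dist` object (or square matrix) over at least 2 samples.
#' @return an `hclust` object.
#' @export
ward_cluster <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) {
    stop("need at least 2 samples to cluster", call. = FALSE)
  }
  stats::hclust(d, method = "ward.D")
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` from [ward_cluster()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group versus within-group
#' dissimilarities:
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{n(n-1)/4}}
#' where the ranks (midranks for ties) are taken over all \eqn{n(n-1)/2}
#' pairwise dissimilarities. `R` lies between -1 and 1; values near 1 indicate
#' that samples within a group are more similar than samples from
#' different groups. The p-value is obtained by seeded permutation of the
#' group labels with the add-one convention,
#' `p = (1 + #(R_perm >= R_obs)) / (1 + n_permutations)`, or by exhaustive
#' enumeration of all label permutations when `exact = TRUE` (feasible for
#' small n).
#'
#' @param d a `dist` (or square matrix) of dissimilarities.
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 members each.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param exact if `TRUE`, enumerate all `n!` label permutations instead
#'   of sampling (the p-value is then the exact proportion with
#'   `R_perm >= R_obs`, including the observed arrangement).
#' @return an object of class `lipo_anosim`: `R`, `p_value`,
#'   `n_permutations`, `seed`, `n`, `groups`, `perm_R`.
#' @export
anosim_test <- function(d, groups, n_permutations = 9999, seed = 1,
                        exact = FALSE) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) {
    stop("groups length must match the number of samples", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  if (!exact && n_permutations < 99) {
    stop("n_permutations must be >= 99", call. = FALSE)
  }
  r <- rank(as.vector(d))  # midranks for ties
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, "row"]; j <- pairs[, "col"]
  denom <- n * (n - 1) / 4
  R_of <- function(g) {
    within <- g[i] == g[j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  R_obs <- R_of(groups)
  if (exact) {
    perms <- all_permutations(n)
    perm_R <- apply(perms, 1, function(p) R_of(groups[p]))
    p_value <- mean(perm_R >= R_obs - 1e-12)
    n_permutations <- nrow(perms)
  } else {
    perm_R <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) R_of(groups[sample.int(n)]), numeric(1))
    })
    p_value <- (1 + sum(perm_R >= R_obs - 1e-12)) / (1 + n_permutations)
  }
  structure(
    list(R = R_obs, p_value = p_value,
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), exact = exact, n = n, groups = groups,
         perm_R = perm_R),
    class = "lipo_anosim"
  )
}

# all n! permutations of 1..n as rows (n <= 8 intended)
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration is limited to n <= 8",
                  call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' @export
print.lipo_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations, %d samples, %d groups)\n",
              x$R, x$p_value, if (x$exact) "all " else "",
              x$n_permutations, x$n, length(unique(x$groups))))
  invisible(x)
}

#' @rdname anosim_test
#' @param x a `lipo_anosim` object.
#' @param ... unused.
#' @export
tidy.lipo_anosim <- function(x, ...) {
  tibble::tibble(statistic = x$R, p.value = x$p_value,
                 n.permutations = x$n_permutations)
}

#' @rdname anosim_test
#' @export
glance.lipo_anosim <- function(x, ...) {
  tibble::tibble(statistic = x$R, p.value = x$p_value,
                 n.permutations = x$n_permutations, n = x$n,
                 n.groups = length(unique(x$groups)))
}

#' Histogram of the ANOSIM permutation distribution
#'
#' @param object a `lipo_anosim`.
#' @param ... unused.
#' @return a ggplot object with the observed R marked.
#' @export
autoplot.lipo_anosim <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(R = object$perm_R), ggplot2::aes(.data$R)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$R, colour = "firebrick") +
    ggplot2::labs(x = "permutation R", y = "count",
                  title = sprintf("ANOSIM R = %.3f, p = %.3g",
                                  object$R, object$p_value)) +
    ggplot2::theme_minimal()
}
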