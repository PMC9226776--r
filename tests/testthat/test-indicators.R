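test_that("a perfect indicator has point-biserial correlation 1", {
  m <- matrix(c(1, 1, 0, 0), ncol = 1,
              dimnames = list(paste0("s", 1:4), "gX"))
  res <- indicator_analysis(m, habitats = c("A", "A", "B", "B"),
                            n_permutations = 199, seed = 1,
                            keep_all = TRUE)
  expect_equal(res$r, 1)
  expect_equal(res$habitat_set, "A")
})

test_that("a constant abundance vector has r = 0 and is never significant", {
  m <- cbind(flat = rep(3, 8), real = c(5, 6, 7, 5, 0, 1, 0, 1))
  rownames(m) <- paste0("s", 1:8)
  res <- indicator_analysis(m, habitats = rep(c("A", "B"), each = 4),
                            n_permutations = 199, seed = 1, keep_all = TRUE)
  flat <- res[res$category == "flat", ]
  expect_equal(flat$r, 0)
  expect_false(flat$significant)
  expect_equal(flat$p_value, 1)
})

test_that("best subsets and r match a direct Pearson-formula search", {
  set.seed(12)
  habs <- rep(c("A", "B", "C", "D"), each = 5)
  m <- matrix(rexp(20 * 6, rate = 0.2), nrow = 20,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:6)))
  res <- indicator_analysis(m, habitats = habs, max_subset_size = 3,
                            n_permutations = 99, seed = 1, keep_all = TRUE)
  subsets <- unlist(lapply(1:3, function(s) {
    utils::combn(c("A", "B", "C", "D"), s, simplify = FALSE)
  }), recursive = FALSE)
  for (j in seq_len(ncol(m))) {
    rs <- vapply(subsets, function(S) {
      stats::cor(m[, j], as.numeric(habs %in% S))
    }, numeric(1))
    row <- res[res$category == colnames(m)[j], ]
    expect_equal(row$r, max(rs), tolerance = 1e-12)
    expect_equal(row$habitat_set,
                 paste(subsets[[which.max(rs)]], collapse = "+"))
  }
})

test_that("the full habitat set is never a candidate subset", {
  m <- matrix(rexp(8 * 3), nrow = 8,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:3)))
  res <- indicator_analysis(m, habitats = rep(c("A", "B"), each = 4),
                            max_subset_size = 5, n_permutations = 99,
                            seed = 1, keep_all = TRUE)
  expect_true(all(res$n_habitats == 1))
  expect_error(indicator_analysis(m, habitats = rep("A", 8)),
               "at least 2 distinct habitats")
  expect_error(indicator_analysis(m, habitats = c(rep("A", 7), "B")),
               "at least 2 samples")
})

test_that("group-equalized correlation differs only under unbalanced designs", {
  set.seed(21)
  habs <- c(rep("A", 3), rep("B", 9))
  m <- matrix(rexp(12 * 4), nrow = 12,
              dimnames = list(paste0("s", 1:12), paste0("g", 1:4)))
  plain <- indicator_analysis(m, habitats = habs, n_permutations = 99,
                              seed = 1, func = "r", keep_all = TRUE)
  equal <- indicator_analysis(m, habitats = habs, n_permutations = 99,
                              seed = 1, func = "r.g", keep_all = TRUE)
  expect_false(isTRUE(all.equal(plain$r, equal$r)))
  # balanced design: the two statistics coincide
  habs_b <- rep(c("A", "B"), each = 6)
  p2 <- indicator_analysis(m, habitats = habs_b, n_permutations = 99,
                           seed = 1, func = "r", keep_all = TRUE)
  e2 <- indicator_analysis(m, habitats = habs_b, n_permutations = 99,
                           seed = 1, func = "r.g", keep_all = TRUE)
  expect_equal(p2$r, e2$r, tolerance = 1e-12)
})

test_that("the bipartite network applies the abundance floor and flags genera", {
  assoc <- structure(
    tibble::tibble(
      category = c("gUniq", "gPair", "gMulti", "gRare"),
      habitat_set = c("A", "A+B", "A+B+C", "B"),
      n_habitats = c(1L, 2L, 3L, 1L),
      r = c(0.9, 0.7, 0.5, 0.8),
      p_value = c(0.001, 0.01, 0.02, 0.001),
      mean_lpgm = c(4, 2, 1, 0.3),
      significant = TRUE
    ),
    class = c("lipo_indicators", class(tibble::tibble())), alpha = 0.05)
  net <- bipartite_network(assoc, min_mean_lpgm = 0.5)
  expect_false("gRare" %in% net$category)  # mean LPGM 0.3 < 0.5
  expect_equal(net$association[net$category == "gUniq"], "unique")
  expect_setequal(net$association[net$category == "gPair"],
                  "pair")
  expect_setequal(net$association[net$category == "gMulti"], "multi")
  # total edges = sum of per-genus subset sizes, recounted independently
  kept <- assoc[assoc$mean_lpgm >= 0.5, ]
  expect_equal(nrow(net), sum(kept$n_habitats))
  g <- bipartite_graph(net)
  expect_true(igraph::is_bipartite(g))
  expect_s3_class(plot_bipartite(net), "ggplot")
})
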