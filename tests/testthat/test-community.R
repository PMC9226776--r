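meta_fixture <- function(samples, habitats, bp = 1e9, genes = 1e6) {
  tibble::tibble(sample_id = samples, habitat = habitats,
                 assembly_bp = bp, gene_count = genes)
}

test_that("LPGM normalization evaluates its defining formula", {
  counts <- tibble::tibble(sample_id = c("s1", "s2"),
                           category = "famA", count = c(1000, 50))
  meta <- meta_fixture(c("s1", "s2"), "compost",
                       bp = c(1e9, 5e8), genes = c(1e6, 2e5))
  ab <- lpgm_normalize(counts, meta)
  expect_equal(ab$lpgm[ab$sample_id == "s1"], 1000)
  expect_equal(ab$lpgm[ab$sample_id == "s2"], 500)
  expect_error(lpgm_normalize(counts, meta[1, ]), "without metadata")
  expect_error(
    lpgm_normalize(dplyr::mutate(counts, count = c(-1, 5)), meta),
    "negative")
})

test_that("LPGM is linear in counts and inversely scales with both normalizers", {
  set.seed(2)
  counts <- tibble::tibble(sample_id = "s", category = paste0("c", 1:8),
                           count = rpois(8, 40))
  meta <- meta_fixture("s", "h", bp = 3.2e8, genes = 7.5e4)
  base <- lpgm_normalize(counts, meta)$lpgm
  # scaling the count alone by c scales LPGM by c
  expect_equal(lpgm_normalize(dplyr::mutate(counts, count = count * 3),
                              meta)$lpgm, 3 * base)
  # scaling count, assembly and genes all by c gives LPGM / c
  meta2 <- dplyr::mutate(meta, assembly_bp = assembly_bp * 2,
                         gene_count = gene_count * 2)
  expect_equal(lpgm_normalize(dplyr::mutate(counts, count = count * 2),
                              meta2)$lpgm, base / 2)
  # zero counts stay zero
  expect_equal(lpgm_normalize(dplyr::mutate(counts, count = 0), meta)$lpgm,
               rep(0, 8))
})

test_that("the heatmap transform is monotone and anchors zero", {
  expect_equal(lpgm_log10(0), 0)
  x <- sort(abs(rnorm(50, sd = 100)))
  expect_true(all(diff(lpgm_log10(x)) >= 0))
  expect_error(lpgm_log10(-1), "non-negative")
})

test_that("Bray-Curtis matches hand evaluation of its formula", {
  m <- rbind(a = c(1, 2, 0), b = c(3, 0, 0))
  expect_equal(as.numeric(bray_curtis(m)), 4 / 6)
  # identical rows, disjoint supports
  expect_equal(as.numeric(bray_curtis(rbind(c(2, 1), c(2, 1)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 3)))), 1)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "negative")
  expect_warning(d0 <- bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_equal(as.numeric(d0), 0)
  # random matrices: formula loop vs implementation, plus metric properties
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rpois(6 * 4, 5), nrow = 6)
    rownames(m) <- paste0("s", 1:6)
    d <- as.matrix(bray_curtis(m))
    for (i in 1:6) {
      for (j in 1:6) {
        want <- if (i == j) 0 else {
          sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
        }
        expect_equal(d[i, j], want, tolerance = 1e-12)
      }
    }
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }
})

test_that("Ward clustering merges the closest pair first and heights never decrease", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- ward_cluster(d)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))  # A and B first
  # exact duplicates merge at height zero
  m <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 1, 0))
  hc2 <- ward_cluster(bray_curtis(m))
  expect_equal(hc2$height[1], 0)
  expect_setequal(hc2$labels[abs(hc2$merge[1, ])], c("s1", "s2"))
  # monotone merge heights across seeded random matrices
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rexp(8 * 5), nrow = 8)
    hc3 <- ward_cluster(bray_curtis(m))
    expect_true(all(diff(hc3$height) >= -1e-12))
  }
  expect_error(ward_cluster(stats::as.dist(matrix(0, 1, 1))), "at least 2")
  # newick export preserves the leaves
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("perfect group separation gives ANOSIM R = 1", {
  dm <- matrix(c(0, 1, 5, 6,
                 1, 0, 6, 5,
                 5, 6, 0, 2,
                 6, 5, 2, 0), 4, 4)
  res <- anosim_test(dm, c("g1", "g1", "g2", "g2"), n_permutations = 199,
                     seed = 1)
  expect_equal(res$R, 1)
  expect_error(anosim_test(dm, c("g1", "g1", "g2", "g3")), ">= 2 members")
})

test_that("ANOSIM R and exact p agree with full enumeration on small matrices", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 6
    m <- matrix(rexp(n * 4), nrow = n)
    d <- bray_curtis(m)
    g <- c("a", "a", "a", "b", "b", "b")
    res <- anosim_test(d, g, exact = TRUE)
    expect_equal(res$R, oracle_anosim_R(d, g), tolerance = 1e-12)
    expect_equal(res$p_value, oracle_anosim_exact_p(d, g), tolerance = 1e-12)
    expect_true(res$R >= -1 && res$R <= 1)
  }
  # and with unequal group sizes on 7 samples
  set.seed(8)
  m <- matrix(rexp(7 * 5), nrow = 7)
  d <- bray_curtis(m)
  g <- c("a", "a", "a", "a", "b", "b", "b")
  res <- anosim_test(d, g, exact = TRUE)
  expect_equal(res$p_value, oracle_anosim_exact_p(d, g), tolerance = 1e-12)
})

test_that("the ANOSIM statistic matches vegan's implementation", {
  set.seed(9)
  m <- matrix(rexp(12 * 6), nrow = 12)
  d <- bray_curtis(m)
  g <- rep(c("a", "b", "c"), each = 4)
  ours <- anosim_test(d, g, n_permutations = 99, seed = 1)
  veg <- vegan::anosim(d, grouping = g, permutations = 99)
  expect_equal(ours$R, unname(veg$statistic), tolerance = 1e-12)
})

test_that("ANOSIM permutation p-values are calibrated under the null", {
  set.seed(101)
  rejections <- vapply(seq_len(500), function(trial) {
    m <- matrix(rexp(10 * 5), nrow = 10)
    d <- stats::dist(m)
    g <- rep(c("a", "b"), each = 5)
    anosim_test(d, g, n_permutations = 199, seed = trial)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("tidiers expose the ANOSIM statistic and permutation count", {
  dm <- matrix(c(0, 1, 5, 6, 1, 0, 6, 5, 5, 6, 0, 2, 6, 5, 2, 0), 4, 4)
  res <- anosim_test(dm, c("g1", "g1", "g2", "g2"), n_permutations = 199,
                     seed = 1)
  td <- tidy(res)
  expect_named(td, c("statistic", "p.value", "n.permutations"))
  gl <- glance(res)
  expect_equal(gl$n.groups, 2L)
  expect_s3_class(autoplot(res), "ggplot")
})
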