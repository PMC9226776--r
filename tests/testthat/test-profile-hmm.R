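test_that("match-state selection and pseudocount emissions match hand computation", {
  # 5 rows, column 3 gapped in 3/5 rows (gap fraction 0.6 >= 0.5 threshold)
  rows <- c("ACDE", "ACDE", "AC-E", "AC-E", "AC-E")
  h <- build_hmm(msa_family("toy", rows), gap_threshold = 0.5,
                 pseudocount = 1)
  expect_equal(h$L, 3L)
  expect_equal(h$match_columns, c(1L, 2L, 4L))
  # column 1: 5 x A -> (5+1)/(5+20) for A, 1/25 otherwise
  expect_equal(unname(h$match_emissions[1, "A"]), 6 / 25)
  expect_equal(unname(h$match_emissions[1, "C"]), 1 / 25)
  expect_equal(unname(h$match_emissions[3, "E"]), 6 / 25)
  # the gapped column became an insert attached to node 2: 2 x D residues
  expect_equal(unname(h$insert_emissions[3, "D"]), 3 / 22)
})

test_that("an ungapped identity alignment gives one match state per column", {
  h <- build_hmm(msa_family("id", c("ACD", "ACD", "ACD")))
  expect_equal(h$L, 3L)
  argmax <- apply(h$match_emissions, 1, function(p) names(p)[which.max(p)])
  expect_equal(unname(argmax), c("A", "C", "D"))
})

test_that("building one profile per family alignment scales to a 32-family database", {
  msas <- lapply(seq_len(32), function(i) {
    set.seed(i)
    cons <- paste(sample(aa_alphabet(), 30, replace = TRUE), collapse = "")
    msa_family(sprintf("fam%02d", i), rep(cons, 3))
  })
  db <- hmm_db(lapply(msas, build_hmm))
  expect_length(db, 32L)
  expect_setequal(names(db), sprintf("fam%02d", 1:32))
})

test_that("degenerate alignments are rejected with informative errors", {
  expect_error(msa_family("empty", character(0)), "empty MSA")
  expect_error(msa_family("ragged", c("ACD", "AC")), "differ in length")
  expect_error(build_hmm(msa_family("single", "ACD")), "at least 2")
  expect_error(build_hmm(msa_family("allgap", c("A---", "A---", "A---")),
                         gap_threshold = 0.2),
               NA)  # column 1 survives
  expect_error(build_hmm(msa_family("gap", c("----", "----")), 0.5),
               "invalid|gap threshold")
})

test_that("built models are normalized and scores are finite", {
  for (seed in 1:5) {
    set.seed(seed)
    cons <- sample(aa_alphabet(), 40, replace = TRUE)
    rows <- vapply(1:6, function(r) {
      ch <- cons
      mut <- runif(40) < 0.2
      ch[mut] <- sample(aa_alphabet(), sum(mut), replace = TRUE)
      ch[runif(40) < 0.05] <- "-"
      paste(ch, collapse = "")
    }, "")
    h <- build_hmm(msa_family(paste0("f", seed), rows))
    expect_silent(validate_hmm(h))  # row sums within 1e-12, all p > 0
    sc <- hmm_score(h, paste(cons, collapse = ""))
    expect_true(is.finite(sc$viterbi_bits) && is.finite(sc$forward_bits))
  }
})

test_that("viterbi has a closed form for a single near-deterministic match state", {
  mm <- matrix(1e-12, 1, 20, dimnames = list(NULL, aa_alphabet()))
  mm[1, "A"] <- 1 - 19e-12
  h1 <- structure(
    list(family_name = "one", L = 1L, match_emissions = mm,
         insert_emissions = matrix(1 / 20, 2, 20,
                                   dimnames = list(NULL, aa_alphabet())),
         transitions = list(tm = matrix(numeric(0), 0, 3),
                            ti = matrix(numeric(0), 0, 2),
                            td = matrix(numeric(0), 0, 2)),
         background = aa_background(uniform = TRUE),
         match_columns = 1L, calibration = NULL),
    class = "profile_hmm")
  expect_equal(hmm_score(h1, "A")$viterbi_bits, log2(20), tolerance = 1e-9)
})

test_that("forward equals exhaustive path enumeration on small models", {
  cases <- expand.grid(L = 1:3, n = c(1, 3, 5), seed = 1:3)
  for (u in seq_len(nrow(cases))) {
    h <- random_hmm(cases$L[u], seed = 100 + u)
    s <- random_seq(cases$n[u], seed = 200 + u)
    got <- hmm_score(h, s)
    expect_equal(got$forward_bits, oracle_forward_bits(h, s),
                 tolerance = 1e-9)
    expect_equal(got$viterbi_bits, oracle_viterbi_bits(h, s),
                 tolerance = 1e-9)
  }
})

test_that("forward never falls below viterbi and the best path is consistent", {
  for (seed in 1:10) {
    h <- random_hmm(sample(2:8, 1), seed = seed)
    s <- random_seq(sample(3:20, 1), seed = seed + 50)
    got <- hmm_score(h, s, path = TRUE)
    expect_gte(got$forward_bits, got$viterbi_bits - 1e-12)
    bp <- got$best_path
    expect_equal(bp$state[1], "M")
    expect_equal(bp$state[nrow(bp)], "M")
    # nodes never decrease, and emitted positions are consecutive
    expect_true(all(diff(bp$node) >= 0))
    emitted <- bp$pos[bp$state != "D"]
    expect_equal(emitted, seq(min(emitted), max(emitted)))
  }
})

test_that("a family consensus outscores its residue-shuffled permutation", {
  for (seed in 1:20) {
    set.seed(seed)
    cons <- sample(aa_alphabet(), 60, replace = TRUE)
    rows <- vapply(1:8, function(r) {
      ch <- cons
      mut <- runif(60) < 0.1
      ch[mut] <- sample(aa_alphabet(), sum(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
    h <- build_hmm(msa_family("fam", rows))
    shuffled <- paste(sample(cons), collapse = "")
    expect_gt(hmm_score(h, paste(cons, collapse = ""))$viterbi_bits,
              hmm_score(h, shuffled)$viterbi_bits)
  }
})

test_that("non-canonical residues are rejected by default and skippable on request", {
  h <- build_hmm(msa_family("f", c("ACDEF", "ACDEF", "ACDEF")))
  expect_error(hmm_score(h, "ACXDE"), "non-canonical")
  expect_silent(hmm_score(h, "ACXDE", on_noncanonical = "skip"))
})

test_that("gumbel calibration matches the closed form at its location parameter", {
  cal <- list(lambda = 0.693, tau = 12)
  expect_equal(hmm_evalue(12, cal, 1), 1 - exp(-1), tolerance = 1e-12)
  # linear in the number of comparisons
  expect_equal(hmm_evalue(15, cal, 2), 2 * hmm_evalue(15, cal, 1))
  # monotone decreasing in bits
  bits <- seq(-5, 40, by = 0.5)
  ev <- hmm_evalue(bits, cal, 100)
  expect_true(all(diff(ev) <= 0))
})

test_that("calibration is self-consistent: decoy P-values are uniform", {
  h <- build_hmm(msa_family("f", {
    set.seed(7)
    cons <- sample(aa_alphabet(), 50, replace = TRUE)
    vapply(1:6, function(r) {
      ch <- cons; mut <- runif(50) < 0.15
      ch[mut] <- sample(aa_alphabet(), sum(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
  }))
  hc <- calibrate_hmm(h, n_decoys = 200, decoy_length = 100, seed = 11)
  set.seed(11)
  scores <- liposcan:::hmm_viterbi_batch(
    hc, replicate(200, liposcan:::random_protein(100, hc$background)))
  pvals <- hmm_evalue(scores, hc$calibration, 1)
  expect_lt(abs(mean(pvals <= 0.1) - 0.10), 0.05)
  expect_lt(abs(mean(pvals <= 0.5) - 0.50), 0.10)
})

test_that("degenerate decoy score distributions refuse to calibrate", {
  expect_error(liposcan:::fit_gumbel(rep(3.2, 100)), "degenerate")
})

test_that("scan filters by E-value, ranks per protein, and is deterministic", {
  set.seed(21)
  msas <- lapply(1:3, function(i) {
    cons <- sample(aa_alphabet(), 60, replace = TRUE)
    rows <- vapply(1:6, function(r) {
      ch <- cons; mut <- runif(60) < 0.1
      ch[mut] <- sample(aa_alphabet(), sum(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
    list(name = paste0("fam", i), cons = paste(cons, collapse = ""),
         msa = msa_family(paste0("fam", i), rows))
  })
  db <- hmm_db(lapply(msas, function(m) build_hmm(m$msa)), calibrate = TRUE,
               n_decoys = 100, decoy_length = 60, seed = 5)
  queries <- tibble::tibble(
    protein_id = c("q1", "q2", "q3"),
    sequence = c(msas[[1]]$cons, msas[[2]]$cons, random_seq(60, 99))
  )
  hits <- hmm_scan(queries, db, e_cutoff = 1e-10)
  best <- hmm_best_hits(hits)
  expect_equal(best$family_name[best$protein_id == "q1"], "fam1")
  expect_equal(best$family_name[best$protein_id == "q2"], "fam2")
  # the random decoy has no hit at the cutoff
  expect_false("q3" %in% hits$protein_id)
  # hit set equals an independent all-pairs re-scoring
  manual <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
    do.call(rbind, lapply(db, function(h) {
      bits <- hmm_score(h, queries$sequence[i])$viterbi_bits
      data.frame(protein_id = queries$protein_id[i],
                 family_name = h$family_name,
                 e_value = hmm_evalue(bits, h$calibration, nrow(queries)))
    }))
  }))
  manual <- manual[manual$e_value <= 1e-10, ]
  expect_equal(nrow(hits), nrow(manual))
  expect_setequal(paste(hits$protein_id, hits$family_name),
                  paste(manual$protein_id, manual$family_name))
  # determinism: identical inputs give byte-identical hit tables
  expect_identical(hits, hmm_scan(queries, db, e_cutoff = 1e-10))
  # uncalibrated profiles are refused by family name
  db_uncal <- db
  db_uncal[[2]]$calibration <- NULL
  expect_error(hmm_scan(queries, db_uncal), "fam2")
})
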