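toy_registry <- function() {
  family_registry(tibble::tibble(
    family_name = c("famA", "famB", "NonLipX", "II", "VIII",
                    "patatin_like_protein"),
    category = c("lipolytic_elf", "lipolytic_elf", "non_lipolytic",
                 rep("pfam_route", 3)),
    confirm_profiles = c(NA, NA, NA, "FunFam_II", "FunFam_VIII",
                         "FunFam_patatin"),
    len_min = c(NA, NA, NA, NA, 350, NA),
    len_max = c(NA, NA, NA, NA, 450, NA)
  ))
}

hmm_hit_row <- function(family, e = 1e-30) {
  tibble::tibble(protein_id = "p", family_name = family, bit_score = 100,
                 e_value = e, rank = 1L)
}

sim_hit_row <- function(family, identity, coverage) {
  tibble::tibble(protein_id = "p", target_id = "t", target_family = family,
                 raw_score = 200, e_value = 1e-40, identity = identity,
                 query_coverage = coverage)
}

test_that("the registry always carries the four canonical miscellaneous families", {
  reg <- toy_registry()
  misc <- reg$family_name[reg$category == "miscellaneous"]
  expect_setequal(misc, c("5_AlphaBeta_hydrolase", "6_AlphaBeta_hydrolase",
                          "Abhydrolase_7", "AlphaBeta_hydrolase"))
  expect_error(family_registry(tibble::tibble(family_name = "x",
                                              category = "bogus")),
               "unknown registry categories")
})

test_that("the combined decision rules reproduce the documented rule examples", {
  reg <- toy_registry()
  # same family by both routes, id 0.70 / cov 0.80 -> assigned
  d <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                           sim_hit_row("famA", 0.70, 0.80), reg)
  expect_equal(d$verdict, "assigned")
  expect_equal(d$family, "famA")
  # best similarity in a miscellaneous family -> unassigned
  d <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                           sim_hit_row("5_AlphaBeta_hydrolase", 0.9, 0.9),
                           reg)
  expect_equal(d$verdict, "unassigned")
  expect_equal(d$rule_id, "miscellaneous_best")
  # strong similarity to a non-lipolytic family -> non_lipolytic
  d <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                           sim_hit_row("NonLipX", 0.65, 0.75), reg)
  expect_equal(d$verdict, "non_lipolytic")
  # same family but identity below the gate -> unassigned
  d <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                           sim_hit_row("famA", 0.50, 0.80), reg)
  expect_equal(d$verdict, "unassigned")
  expect_equal(d$rule_id, "weak_similarity")
  # strong similarity to a different lipolytic family -> unassigned
  d <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                           sim_hit_row("famB", 0.9, 0.9), reg)
  expect_equal(d$verdict, "unassigned")
  expect_equal(d$rule_id, "cross_family")
  # unknown family names are a registry error
  expect_error(classify_alpha_beta("p", 300, hmm_hit_row("nope"), NULL, reg),
               "not in registry")
})

test_that("every rule-grid combination fires exactly one rule", {
  reg <- toy_registry()
  th <- lipo_thresholds()
  sim_fams <- c(none = NA, same = "famA", other = "famB",
                misc = "5_AlphaBeta_hydrolase", nonlip = "NonLipX")
  grid <- expand.grid(hmm = c(TRUE, FALSE), sim = names(sim_fams),
                      identity = c(0.5, 0.6, 0.7),
                      coverage = c(0.6, 0.7, 0.8),
                      length = c(150, 300, 400, 500, 900),
                      stringsAsFactors = FALSE)
  known_rules <- c("no_hmm_hit", "no_sim_hit", "hmm_sim_agree",
                   "miscellaneous_best", "weak_similarity",
                   "nonlipolytic_similarity", "cross_family")
  for (u in seq_len(nrow(grid))) {
    g <- grid[u, ]
    if (g$length < th$min_len || g$length > th$max_len) {
      # handled upstream by the length filter; decision engine not reached
      next
    }
    hb <- if (g$hmm) hmm_hit_row("famA") else NULL
    sb <- if (g$sim == "none") NULL else {
      sim_hit_row(sim_fams[[g$sim]], g$identity, g$coverage)
    }
    d <- classify_alpha_beta("p", g$length, hb, sb, reg, th)
    expect_equal(nrow(d), 1L)
    expect_length(d$rule_id, 1L)
    expect_true(d$rule_id %in% known_rules)
    expect_true(d$verdict %in% c("assigned", "unassigned", "non_lipolytic",
                                 "no_hit"))
    if (d$verdict == "assigned") expect_false(is.na(d$family))
  }
})

test_that("raising identity or coverage within the same family never demotes a call", {
  reg <- toy_registry()
  verdict_rank <- c(unassigned = 0, assigned = 1)
  for (id0 in c(0.55, 0.65, 0.8)) {
    for (cov0 in c(0.6, 0.75, 0.9)) {
      v0 <- classify_alpha_beta("p", 300, hmm_hit_row("famA"),
                                sim_hit_row("famA", id0, cov0),
                                reg)$verdict
      for (delta in c(0.05, 0.15)) {
        v1 <- classify_alpha_beta(
          "p", 300, hmm_hit_row("famA"),
          sim_hit_row("famA", min(1, id0 + delta), min(1, cov0 + delta)),
          reg)$verdict
        expect_gte(verdict_rank[[v1]], verdict_rank[[v0]])
      }
    }
  }
})

test_that("pfam-route calls need confirmation and respect the VIII length window", {
  reg <- toy_registry()
  # confirmed beta-lactamase route hit at 400 aa -> family VIII
  d <- classify_pfam_route("p", 400, hmm_hit_row("VIII"), TRUE, reg)
  expect_equal(d$verdict, "assigned")
  expect_equal(d$family, "VIII")
  # same but 500 aa -> outside 350-450 -> non_lipolytic
  d <- classify_pfam_route("p", 500, hmm_hit_row("VIII"), TRUE, reg)
  expect_equal(d$verdict, "non_lipolytic")
  expect_equal(d$rule_id, "route_length_window")
  # route hit without confirmation -> non_lipolytic
  d <- classify_pfam_route("p", 400, hmm_hit_row("VIII"), FALSE, reg)
  expect_equal(d$verdict, "non_lipolytic")
  expect_equal(d$rule_id, "route_no_confirmation")
  # patatin has no length window
  d <- classify_pfam_route("p", 700, hmm_hit_row("patatin_like_protein"),
                           TRUE, reg)
  expect_equal(d$verdict, "assigned")
  # a route family without configured confirmation profiles is an error
  reg2 <- toy_registry()
  reg2$confirm_profiles[reg2$family_name == "VIII"] <- NA
  expect_error(classify_pfam_route("p", 400, hmm_hit_row("VIII"), TRUE, reg2),
               "no configured confirmation")
})

test_that("family determination applies the 60 % identity / 80 % coverage gates", {
  fams <- gen_families(generator_config(seed = 5, n_families = 2,
                                        include_pfam_route = FALSE,
                                        n_nonlipolytic = 0))
  refs <- fams$reference_set
  member <- gsub("-", "", fams$families[[1]]$msa$rows[1], fixed = TRUE)
  # a family member passes both gates
  expect_equal(determine_elf(member, refs), fams$families[[1]]$family_name)
  # a fragment plus a long random tail fails the coverage gate
  set.seed(8)
  frag <- paste0(substr(member, 1, 120), random_seq(250, 808))
  expect_true(is.na(determine_elf(frag, refs)))
  # a twilight-band query fails the identity gate (or the E-value cutoff)
  cons <- strsplit(fams$families[[1]]$consensus, "")[[1]]
  keep <- runif(length(cons)) < 0.2
  cons[!keep] <- vapply(cons[!keep],
                        function(ch) sample(setdiff(aa_alphabet(), ch), 1), "")
  expect_true(is.na(determine_elf(paste(cons, collapse = ""), refs,
                                  e_cutoff = 1)))
})

test_that("the length filter excludes proteins outside 200-800 aa exactly once", {
  cfg <- generator_config(seed = 9, n_families = 2, n_members = 5,
                          n_positives_per_family = 2, n_random_decoys = 2,
                          n_twilight_decoys = 0,
                          include_pfam_route = FALSE, n_nonlipolytic = 0)
  fams <- gen_families(cfg)
  dbs <- synth_hmm_dbs(fams, n_decoys = 60, decoy_length = 80, seed = 3)
  ps <- gen_protein_set(cfg, fams)
  extra <- tibble::tibble(
    protein_id = c("short", "long"),
    sequence = c(random_seq(150, 1), random_seq(900, 2)),
    length = c(150L, 900L)
  )
  proteins <- dplyr::bind_rows(ps$proteins, extra)
  dec <- annotate_proteins(proteins, dbs$elf_db, fams$reference_set,
                           fams$registry)
  expect_equal(nrow(dec), nrow(proteins))
  expect_equal(anyDuplicated(dec$protein_id), 0L)
  expect_equal(dec$verdict[dec$protein_id == "short"], "length_excluded")
  expect_equal(dec$verdict[dec$protein_id == "long"], "length_excluded")
  expect_warning(annotate_proteins(proteins[0, ], dbs$elf_db,
                                   fams$reference_set, fams$registry),
                 "empty protein set")
})
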