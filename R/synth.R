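#' Generator configuration for synthetic benchmark data
#'
#' All knobs of the seeded generators that emulate the inputs of a
#' sequence-based lipolytic screen: family-structured protein sets with
#' labelled decoys, and habitat-structured community count tables.
#' Defaults define the package's standard benchmark conditions:
#' * 6 synthetic lipolytic (ELF-like) families plus the three Pfam-route
#'   families (II, VIII, patatin-like) and 2 non-lipolytic families,
#'   consensus lengths 250-450 aa with a G-x-S-x-G motif;
#' * members mutated at rate 0.10 per site (pairwise identity ~0.8, well
#'   above the 60 % assignment gate) with rare, short, capped indels so
#'   coverage gates are never violated by construction;
#' * twilight decoys in the 20-25 % identity band below the gate, plus
#'   unrelated random decoys;
#' * 4 habitats x 6 samples with 2 planted indicator genera per habitat
#'   and a Dirichlet concentration contrast (`habitat_effect`, 0 makes
#'   samples exchangeable across habitats).
#'
#' @param seed master RNG seed; every generator derives its stream from
#'   it, so outputs are byte-identical for equal seeds.
#' @param n_families number of synthetic lipolytic families.
#' @param family_length length range (aa) for family consensuses.
#' @param n_members aligned sequences per family (the reference set).
#' @param mutation_rate per-site substitution probability for members.
#' @param indel_rate per-site probability of an indel event in a member.
#' @param max_indel_len maximum indel length (aa).
#' @param decoy_identity target identity band of twilight decoys to their
#'   target family consensus.
#' @param n_positives_per_family query proteins drawn from each family.
#' @param n_random_decoys unrelated background-sampled decoys.
#' @param n_twilight_decoys decoys inside the twilight identity band.
#' @param include_pfam_route include families II, VIII and
#'   patatin-like-protein with route + confirmation profiles.
#' @param n_nonlipolytic number of non-lipolytic reference families.
#' @param n_habitats,samples_per_habitat community design.
#' @param n_genera number of genus categories in the community table.
#' @param n_indicators_per_habitat planted indicator genera per habitat.
#' @param alpha_base baseline Dirichlet concentration per genus.
#' @param habitat_effect extra Dirichlet concentration added to a
#'   habitat's planted indicator genera (0 = no habitat structure).
#' @param genes_per_sample predicted genes per sample (also the
#'   multinomial draw size of the count table).
#' @param assembly_bp_per_sample nominal assembly size per sample (bp);
#'   jittered by +/-10 % per sample.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_families = 6,
                             family_length = c(250, 450),
                             n_members = 12,
                             mutation_rate = 0.10,
                             indel_rate = 0.01,
                             max_indel_len = 2,
                             decoy_identity = c(0.20, 0.25),
                             n_positives_per_family = 20,
                             n_random_decoys = 80,
                             n_twilight_decoys = 40,
                             include_pfam_route = TRUE,
                             n_nonlipolytic = 2,
                             n_habitats = 4,
                             samples_per_habitat = 6,
                             n_genera = 30,
                             n_indicators_per_habitat = 2,
                             alpha_base = 2,
                             habitat_effect = 12,
                             genes_per_sample = 50000,
                             assembly_bp_per_sample = 5e7) {
  cfg <- as.list(environment())
  stopifnot(cfg$mutation_rate >= 0, cfg$mutation_rate < 1,
            cfg$indel_rate >= 0, cfg$indel_rate < 1,
            cfg$family_length[1] >= 200, cfg$family_length[2] <= 800,
            cfg$decoy_identity[2] < 0.60,
            cfg$habitat_effect >= 0, cfg$alpha_base > 0,
            cfg$n_habitats >= 2, cfg$samples_per_habitat >= 2,
            cfg$n_genera >= cfg$n_habitats * cfg$n_indicators_per_habitat)
  structure(cfg, class = "generator_config")
}

# family roster implied by a config: name, category, index
family_roster <- function(config) {
  elf <- tibble::tibble(
    family_name = sprintf("ELF_%02d", seq_len(config$n_families)),
    category = "lipolytic_elf"
  )
  nonlip <- if (config$n_nonlipolytic > 0) {
    tibble::tibble(
      family_name = sprintf("NonLip_%02d", seq_len(config$n_nonlipolytic)),
      category = "non_lipolytic"
    )
  } else NULL
  route <- if (config$include_pfam_route) {
    tibble::tibble(
      family_name = c("II", "VIII", "patatin_like_protein"),
      category = "pfam_route"
    )
  } else NULL
  roster <- dplyr::bind_rows(elf, nonlip, route)
  roster$family_index <- seq_len(nrow(roster))
  roster
}

# one twilight decoy: bisection on the kept-position fraction until the
# global-alignment identity to the consensus falls inside the band
make_twilight <- function(cons_chars, band) {
  target_lo <- band[1] + 0.005
  target_hi <- band[2] - 0.005
  lo <- 0.05
  hi <- 0.40
  best <- NULL
  best_miss <- Inf
  consensus <- paste(cons_chars, collapse = "")
  for (iter in 1:12) {
    q <- (lo + hi) / 2
    d <- cons_chars
    keep <- sample(length(d), round(q * length(d)))
    d[-keep] <- vapply(d[-keep], function(ch) {
      sample(setdiff(aa_alphabet(), ch), 1)
    }, "")
    decoy <- paste(d, collapse = "")
    id <- aln_global_identity(decoy, consensus)
    miss <- max(target_lo - id, id - target_hi, 0)
    if (miss < best_miss) {
      best <- decoy
      best_miss <- miss
    }
    if (miss == 0) break
    if (id > target_hi) hi <- q else lo <- q
  }
  best
}

mutate_sequence <- function(chars, rate) {
  aa <- aa_alphabet()
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(aa, ch), 1)
    }, "")
  }
  chars
}

#' Generate one synthetic family alignment
#'
#' Draws a family consensus from the background amino-acid distribution
#' with a G-x-S-x-G catalytic-serine motif embedded at a recorded
#' position (families are modelled as alpha/beta-hydrolase-like), then
#' derives `n_members` aligned members by per-site substitution at the
#' mutation rate plus rare short indels. Deletions per member are capped
#' at 3 % of the consensus length so member lengths, and later coverage
#' gates, stay well-behaved. Deterministic per `(seed, family_index)`.
#'
#' @param config a [generator_config()].
#' @param family_index index into the family roster (lipolytic families
#'   first, then non-lipolytic, then the Pfam-route families).
#' @return a list with `family_name`, `category`, `msa` (an
#'   [msa_family()]), `consensus`, and `motif_start` (consensus position
#'   of the leading motif G).
#' @export
gen_family_msa <- function(config, family_index) {
  roster <- family_roster(config)
  stopifnot(family_index >= 1, family_index <= nrow(roster))
  fam <- roster[family_index, ]
  with_seed(config$seed * 1009L + family_index * 7919L, {
    L <- if (fam$family_name == "VIII") {
      400L  # keep members inside the 350-450 aa window
    } else {
      sample(seq(config$family_length[1], config$family_length[2]), 1)
    }
    cons <- sample(aa_alphabet(), L, replace = TRUE,
                   prob = aa_background())
    motif_start <- sample(seq(20L, L - 24L), 1)
    cons[motif_start] <- "G"
    cons[motif_start + 2L] <- "S"
    cons[motif_start + 4L] <- "G"

    max_del <- floor(0.03 * L)
    members <- lapply(seq_len(config$n_members), function(r) {
      ch <- mutate_sequence(cons, config$mutation_rate)
      del <- which(runif(L) < config$indel_rate / 2)
      if (length(del) > max_del) del <- del[seq_len(max_del)]
      list(chars = ch, del = del,
           ins = which(runif(L) < config$indel_rate / 2))
    })
    # alignment columns: consensus columns plus shared insert columns
    ins_pos <- sort(unique(unlist(lapply(members, `[[`, "ins"))))
    ins_len <- setNames(sample(seq_len(config$max_indel_len),
                               length(ins_pos), replace = TRUE), ins_pos)
    rows <- vapply(members, function(mb) {
      out <- character(0)
      for (p in seq_len(L)) {
        out <- c(out, if (p %in% mb$del) "-" else mb$chars[p])
        if (p %in% ins_pos) {
          w <- ins_len[as.character(p)]
          if (p %in% mb$ins) {
            out <- c(out, sample(aa_alphabet(), w, replace = TRUE,
                                 prob = aa_background()))
          } else {
            out <- c(out, rep("-", w))
          }
        }
      }
      paste(out, collapse = "")
    }, "")
    list(family_name = fam$family_name, category = fam$category,
         msa = msa_family(fam$family_name, rows),
         consensus = paste(cons, collapse = ""),
         motif_start = motif_start)
  })
}

#' Generate the full synthetic family collection
#'
#' Runs [gen_family_msa()] over the whole roster and assembles the
#' reference registry, including the four canonical miscellaneous family
#' names and the confirmation-profile configuration for the Pfam-route
#' families (family VIII carries the 350-450 aa window).
#'
#' @param config a [generator_config()].
#' @return a list with `families` (list of [gen_family_msa()] results),
#'   `registry` (a [family_registry()]) and `reference_set` (degapped MSA
#'   members labelled by family, the similarity-search registry).
#' @export
gen_families <- function(config) {
  roster <- family_roster(config)
  fams <- lapply(roster$family_index, gen_family_msa, config = config)
  names(fams) <- roster$family_name
  reg <- roster[, c("family_name", "category")]
  reg$confirm_profiles <- ifelse(
    reg$category == "pfam_route", paste0("FunFam_", reg$family_name),
    NA_character_
  )
  reg$len_min <- ifelse(reg$family_name == "VIII", 350, NA_real_)
  reg$len_max <- ifelse(reg$family_name == "VIII", 450, NA_real_)
  reference_set <- purrr::map_dfr(fams, function(f) {
    if (f$category == "pfam_route") return(NULL)  # confirmed via profiles
    tibble::tibble(
      seq_id = sprintf("%s_ref%03d", f$family_name,
                       seq_along(f$msa$rows)),
      family_name = f$family_name,
      sequence = gsub("-", "", f$msa$rows, fixed = TRUE)
    )
  })
  list(families = fams, registry = family_registry(reg),
       reference_set = reference_set)
}

#' Generate a labelled synthetic protein benchmark
#'
#' Emits query proteins with complete ground truth: family members
#' (positives, fresh mutants of each family consensus), members of the
#' non-lipolytic families, unrelated random decoys, and twilight decoys
#' constructed inside the configured identity band to a target lipolytic
#' family consensus. Every positive has length within the 200-800 aa
#' screening window by construction.
#'
#' @param config a [generator_config()].
#' @param families output of [gen_families()] (regenerated if missing).
#' @return a list with `proteins` (tibble: `protein_id`, `sequence`,
#'   `length`) and `truth` (tibble: `protein_id`, `class` in
#'   `positive` / `nonlipolytic_member` / `random_decoy` /
#'   `twilight_decoy`, `true_family`, `target_family`).
#' @export
gen_protein_set <- function(config, families = gen_families(config)) {
  fams <- families$families
  roster <- family_roster(config)
  with_seed(config$seed * 2003L + 17L, {
    rows <- list()
    counter <- 0L
    emit <- function(seq, class, true_family = NA_character_,
                     target_family = NA_character_) {
      counter <<- counter + 1L
      rows[[counter]] <<- tibble::tibble(
        protein_id = sprintf("P%05d", counter), sequence = seq,
        class = class, true_family = true_family,
        target_family = target_family
      )
    }
    for (f in fams) {
      n <- if (f$category == "lipolytic_elf") {
        config$n_positives_per_family
      } else {
        max(2L, config$n_positives_per_family %/% 2L)
      }
      cons <- strsplit(f$consensus, "")[[1]]
      L <- length(cons)
      max_del <- floor(0.03 * L)
      for (r in seq_len(n)) {
        ch <- mutate_sequence(cons, config$mutation_rate)
        del <- which(runif(L) < config$indel_rate / 2)
        if (length(del) > max_del) del <- del[seq_len(max_del)]
        if (length(del) > 0) ch <- ch[-del]
        cls <- switch(f$category,
                      lipolytic_elf = "positive",
                      pfam_route = "positive",
                      non_lipolytic = "nonlipolytic_member")
        emit(paste(ch, collapse = ""), cls, true_family = f$family_name)
      }
    }
    for (r in seq_len(config$n_random_decoys)) {
      emit(random_protein(sample(200:800, 1)), "random_decoy")
    }
    # twilight decoys: keep a fraction of consensus positions and replace
    # every other residue with a different one. The aligner pairs up
    # accidental matches, so the alignment-measured identity runs above the
    # positional fraction by a variable amount; the kept fraction is
    # therefore calibrated per decoy (bisection on fresh draws) until the
    # global-alignment identity to the consensus lies inside the band.
    elf_names <- roster$family_name[roster$category == "lipolytic_elf"]
    band <- config$decoy_identity
    for (r in seq_len(config$n_twilight_decoys)) {
      target <- sample(elf_names, 1)
      cons <- strsplit(fams[[target]]$consensus, "")[[1]]
      emit(make_twilight(cons, band), "twilight_decoy",
           target_family = target)
    }
    proteins <- dplyr::bind_rows(rows)
    proteins$length <- nchar(proteins$sequence)
    list(
      proteins = proteins[, c("protein_id", "sequence", "length")],
      truth = proteins[, c("protein_id", "class", "true_family",
                           "target_family")]
    )
  })
}

#' Generate a habitat-structured community count table
#'
#' Draws per-sample genus counts from habitat-specific Dirichlet
#' parameters: every genus has baseline concentration `alpha_base`, and
#' each habitat's planted indicator genera get `alpha_base +
#' habitat_effect` in that habitat only. Counts are multinomial with the
#' configured genes-per-sample draw size, so each sample's counts sum to
#' `genes_per_sample` exactly. With `habitat_effect = 0` the samples are
#' exchangeable across habitats by construction.
#'
#' @param config a [generator_config()].
#' @return a list with `counts` (long tibble: `sample_id`, `category`,
#'   `count`), `metadata` (tibble: `sample_id`, `habitat`, `assembly_bp`,
#'   `gene_count`) and `planted` (tibble: `category`, `habitat` of the
#'   planted indicator genera).
#' @export
gen_community <- function(config) {
  with_seed(config$seed * 3001L + 29L, {
    K <- config$n_habitats
    habs <- paste0("habitat_", LETTERS[seq_len(K)])
    genera <- sprintf("Genus_%03d", seq_len(config$n_genera))
    n_ind <- config$n_indicators_per_habitat
    planted <- tibble::tibble(
      category = genera[seq_len(K * n_ind)],
      habitat = rep(habs, each = n_ind)
    )
    alpha <- matrix(config$alpha_base, nrow = K, ncol = config$n_genera,
                    dimnames = list(habs, genera))
    for (u in seq_len(nrow(planted))) {
      alpha[planted$habitat[u], planted$category[u]] <-
        config$alpha_base + config$habitat_effect
    }
    out <- list(); meta <- list()
    for (h in seq_len(K)) {
      for (s in seq_len(config$samples_per_habitat)) {
        sid <- sprintf("%s_s%02d", habs[h], s)
        g <- rgamma(config$n_genera, shape = alpha[h, ])
        p <- g / sum(g)
        cnt <- as.integer(rmultinom(1, config$genes_per_sample, p))
        out[[sid]] <- tibble::tibble(sample_id = sid, category = genera,
                                     count = cnt)
        meta[[sid]] <- tibble::tibble(
          sample_id = sid, habitat = habs[h],
          assembly_bp = config$assembly_bp_per_sample * runif(1, 0.9, 1.1),
          gene_count = config$genes_per_sample
        )
      }
    }
    list(counts = dplyr::bind_rows(out), metadata = dplyr::bind_rows(meta),
         planted = planted)
  })
}

#' Build profile databases from a synthetic family collection
#'
#' Convenience for the demo pipeline and benchmarks: builds and
#' calibrates the main (ELF) database, the Pfam-route database and the
#' confirmation database from the generated alignments. Route and
#' confirmation profiles for a family are built from the same synthetic
#' alignment (the confirmation profile stands in for an independently
#' curated functional-family model and carries the `FunFam_` prefix).
#'
#' @param families output of [gen_families()].
#' @param n_decoys,decoy_length,seed calibration settings.
#' @return a list with `elf_db`, `route_db`, `confirm_db` (`hmm_db`s;
#'   the latter two are `NULL` when the roster has no route families).
#' @export
synth_hmm_dbs <- function(families, n_decoys = 200, decoy_length = 350,
                          seed = 42) {
  fams <- families$families
  cats <- vapply(fams, `[[`, "", "category")
  build <- function(fs, rename = identity) {
    if (length(fs) == 0) return(NULL)
    hmms <- lapply(fs, function(f) {
      m <- f$msa
      m$family_name <- rename(m$family_name)
      build_hmm(m)
    })
    hmm_db(hmms, calibrate = TRUE, n_decoys = n_decoys,
           decoy_length = decoy_length, seed = seed)
  }
  list(
    elf_db = build(fams[cats == "lipolytic_elf"]),
    route_db = build(fams[cats == "pfam_route"]),
    confirm_db = build(fams[cats == "pfam_route"],
                       rename = function(x) paste0("FunFam_", x))
  )
}
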