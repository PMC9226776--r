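#' Assign a sequence to a lipolytic family by similarity (database build)
#'
#' The rule used while constructing family databases: the best
#' similarity hit's family is returned only when it reaches at least 60 %
#' identity and at least 80 % query coverage; otherwise no family is
#' assigned.
#'
#' @param sequence ungapped protein residue string.
#' @param reference_set family-labelled reference tibble
#'   (`seq_id`, `family_name`, `sequence`).
#' @param scheme a [scoring_scheme()].
#' @param thresholds a [lipo_thresholds()].
#' @param e_cutoff similarity-search E-value cutoff.
#' @return the family name, or `NA_character_` if the gates fail.
#' @export
determine_elf <- function(sequence, reference_set,
                          scheme = scoring_scheme(),
                          thresholds = lipo_thresholds(),
                          e_cutoff = 1e-10) {
  check_reference_set(reference_set)
  hit <- sim_best_hit(sequence, reference_set, scheme, e_cutoff)
  if (is.null(hit)) return(NA_character_)
  if (hit$identity >= thresholds$elf_min_identity &&
      hit$query_coverage >= thresholds$elf_min_coverage_db_build) {
    hit$target_family
  } else {
    NA_character_
  }
}

decision_row <- function(protein_id, verdict, rule_id, family = NA_character_,
                         length = NA_integer_, hmm_family = NA_character_,
                         hmm_evalue = NA_real_, sim_family = NA_character_,
                         identity = NA_real_, coverage = NA_real_) {
  tibble::tibble(protein_id = protein_id, verdict = verdict,
                 family = family, rule_id = rule_id,
                 length = as.integer(length), hmm_family = hmm_family,
                 hmm_evalue = hmm_evalue, sim_family = sim_family,
                 identity = identity, coverage = coverage)
}

#' Combined hmm + similarity decision for an alpha/beta-hydrolase protein
#'
#' The two-tier decision rule for proteins screened against the main
#' family profile database. In order of precedence:
#' \enumerate{
#'   \item no profile hit: `no_hit`;
#'   \item no similarity hit: `unassigned`;
#'   \item profile family and similarity family agree, with identity
#'     >= 60 % and coverage >= 70 %: `assigned` to that family;
#'   \item best similarity hit in a miscellaneous family: `unassigned`;
#'   \item identity or coverage below the gates: `unassigned`;
#'   \item strong similarity to a non-lipolytic family: `non_lipolytic`;
#'   \item strong similarity to a *different* lipolytic family:
#'     `unassigned` (assignment requires both routes to name the same
#'     family).
#' }
#' Exactly one rule fires for every input combination; the fired rule's id
#' is recorded.
#'
#' @param protein_id protein identifier.
#' @param length protein length in residues (recorded in the decision).
#' @param hmm_best one-row tibble from [hmm_best_hits()], or `NULL`.
#' @param sim_best one-row tibble from [sim_search()], or `NULL`.
#' @param registry a [family_registry()].
#' @param thresholds a [lipo_thresholds()].
#' @return a one-row decision tibble.
#' @export
classify_alpha_beta <- function(protein_id, length, hmm_best, sim_best,
                                registry, thresholds = lipo_thresholds()) {
  if (is.null(hmm_best) || nrow(hmm_best) == 0) {
    return(decision_row(protein_id, "no_hit", "no_hmm_hit", length = length))
  }
  hf <- hmm_best$family_name
  he <- hmm_best$e_value
  registry_category(registry, hf)  # errors on unknown family
  if (is.null(sim_best) || nrow(sim_best) == 0) {
    return(decision_row(protein_id, "unassigned", "no_sim_hit",
                        length = length, hmm_family = hf, hmm_evalue = he))
  }
  sf <- sim_best$target_family
  cat_sf <- registry_category(registry, sf)
  id <- sim_best$identity
  cov <- sim_best$query_coverage
  strong <- id >= thresholds$annot_min_identity &&
    cov >= thresholds$annot_min_coverage
  args <- list(protein_id = protein_id, length = length, hmm_family = hf,
               hmm_evalue = he, sim_family = sf, identity = id,
               coverage = cov)
  if (identical(sf, hf) && cat_sf %in% c("lipolytic_elf", "pfam_route") &&
      strong) {
    return(do.call(decision_row, c(args, list(verdict = "assigned",
                                              rule_id = "hmm_sim_agree",
                                              family = hf))))
  }
  if (cat_sf == "miscellaneous") {
    return(do.call(decision_row, c(args, list(verdict = "unassigned",
                                              rule_id = "miscellaneous_best"))))
  }
  if (!strong) {
    return(do.call(decision_row, c(args, list(verdict = "unassigned",
                                              rule_id = "weak_similarity"))))
  }
  if (cat_sf == "non_lipolytic") {
    return(do.call(decision_row, c(args, list(verdict = "non_lipolytic",
                                              rule_id = "nonlipolytic_similarity"))))
  }
  # strong hit to a different lipolytic family
  do.call(decision_row, c(args, list(verdict = "unassigned",
                                     rule_id = "cross_family")))
}

#' Decision for a Pfam-route protein (families II, VIII, patatin)
#'
#' Proteins screened with the route profiles (GDSL, beta-lactamase,
#' patatin) are assigned only if a confirmation hit against the secondary
#' functional-family profile set is also present and, for family VIII, the
#' protein length falls in the configured window (350-450 aa by default).
#' In all other cases with a route hit the protein is grouped with the
#' non-lipolytic proteins.
#'
#' @param protein_id protein identifier.
#' @param length protein length in residues.
#' @param route_hit one-row tibble from [hmm_best_hits()] on the route
#'   database, or `NULL`.
#' @param confirm_hit `TRUE` if the protein hit one of the route family's
#'   configured confirmation profiles.
#' @param registry a [family_registry()]; the route family must be a
#'   `pfam_route` entry with `confirm_profiles` configured.
#' @param thresholds a [lipo_thresholds()].
#' @return a one-row decision tibble.
#' @export
classify_pfam_route <- function(protein_id, length, route_hit, confirm_hit,
                                registry, thresholds = lipo_thresholds()) {
  if (is.null(route_hit) || nrow(route_hit) == 0) {
    return(decision_row(protein_id, "no_hit", "no_route_hit",
                        length = length))
  }
  rf <- route_hit$family_name
  re <- route_hit$e_value
  i <- match(rf, registry$family_name)
  if (is.na(i)) stop("family not in registry: ", rf, call. = FALSE)
  if (registry$category[i] != "pfam_route") {
    stop("family '", rf, "' is not a pfam_route registry entry",
         call. = FALSE)
  }
  if (is.na(registry$confirm_profiles[i]) ||
      !nzchar(registry$confirm_profiles[i])) {
    stop("route family '", rf, "' has no configured confirmation profiles",
         call. = FALSE)
  }
  if (!isTRUE(confirm_hit)) {
    return(decision_row(protein_id, "non_lipolytic", "route_no_confirmation",
                        length = length, hmm_family = rf, hmm_evalue = re))
  }
  lmin <- registry$len_min[i]
  lmax <- registry$len_max[i]
  if (identical(rf, "VIII") && is.na(lmin)) {
    lmin <- thresholds$viii_len_min
    lmax <- thresholds$viii_len_max
  }
  if (!is.na(lmin) && (length < lmin || length > lmax)) {
    return(decision_row(protein_id, "non_lipolytic", "route_length_window",
                        length = length, hmm_family = rf, hmm_evalue = re))
  }
  decision_row(protein_id, "assigned", "route_confirmed", family = rf,
               length = length, hmm_family = rf, hmm_evalue = re)
}

#' Annotate a protein set end to end
#'
#' The full per-protein decision pipeline: length filter (keep 200-800 aa
#' by default), profile-HMM scan against the main family database and (if
#' supplied) the Pfam-route database, similarity search for proteins with
#' a profile hit, and the combined decision rules. Every input protein
#' appears exactly once in the output. When a protein hits both the main
#' and the route database, the route with the lower best E-value decides
#' which path classifies it.
#'
#' @param proteins tibble with `protein_id`, `sequence` (and optionally
#'   `length`) columns.
#' @param hmm_db calibrated `hmm_db` of lipolytic family profiles.
#' @param reference_set family-labelled reference tibble for the
#'   similarity tier.
#' @param registry a [family_registry()].
#' @param thresholds a [lipo_thresholds()].
#' @param route_db optional calibrated `hmm_db` of Pfam-route profiles
#'   (families II, VIII, patatin).
#' @param confirm_db optional calibrated `hmm_db` of confirmation
#'   profiles; a route call is confirmed when the protein hits one of the
#'   profiles named in the registry's `confirm_profiles` for its family.
#' @param scheme a [scoring_scheme()].
#' @return a decision tibble (`protein_id`, `verdict`, `family`,
#'   `rule_id`, `length`, `hmm_family`, `hmm_evalue`, `sim_family`,
#'   `identity`, `coverage`).
#' @export
annotate_proteins <- function(proteins, hmm_db, reference_set, registry,
                              thresholds = lipo_thresholds(),
                              route_db = NULL, confirm_db = NULL,
                              scheme = scoring_scheme()) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) == 0) {
    warning("empty protein set: returning an empty decision table")
    return(decision_row(character(0), character(0), character(0))[0, ])
  }
  if (!"length" %in% names(proteins)) {
    proteins$length <- nchar(proteins$sequence)
  }

  short_long <- proteins$length < thresholds$min_len |
    proteins$length > thresholds$max_len
  excluded <- proteins[short_long, ]
  kept <- proteins[!short_long, ]

  dec_excluded <- if (nrow(excluded) > 0) {
    decision_row(excluded$protein_id, "length_excluded", "length_filter",
                 length = excluded$length)
  } else NULL

  dec_kept <- NULL
  if (nrow(kept) > 0) {
    elf_best <- hmm_best_hits(hmm_scan(kept, hmm_db, thresholds$hmm_e_cutoff))
    route_best <- if (!is.null(route_db)) {
      hmm_best_hits(hmm_scan(kept, route_db, thresholds$hmm_e_cutoff))
    } else {
      tibble::tibble(protein_id = character(), family_name = character(),
                     bit_score = numeric(), e_value = numeric(),
                     rank = integer())
    }
    confirm_hits <- if (!is.null(confirm_db)) {
      hmm_scan(kept, confirm_db, thresholds$hmm_e_cutoff)
    } else NULL

    # route path wins for proteins whose route E-value beats the main one
    route_ids <- if (nrow(route_best) > 0) {
      elf_e <- setNames(elf_best$e_value, elf_best$protein_id)
      keep <- is.na(elf_e[route_best$protein_id]) |
        route_best$e_value < elf_e[route_best$protein_id]
      route_best$protein_id[keep]
    } else character(0)

    need_sim <- setdiff(elf_best$protein_id, route_ids)
    sim_best <- if (length(need_sim) > 0) {
      sim_search(kept[kept$protein_id %in% need_sim, , drop = FALSE],
                 reference_set, scheme, e_cutoff = thresholds$hmm_e_cutoff)
    } else NULL

    dec_kept <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
      pid <- kept$protein_id[i]
      len <- kept$length[i]
      if (pid %in% route_ids) {
        rh <- route_best[route_best$protein_id == pid, , drop = FALSE]
        confirmed <- route_confirmed(pid, rh$family_name, registry,
                                     confirm_hits)
        classify_pfam_route(pid, len, rh, confirmed, registry, thresholds)
      } else {
        hb <- elf_best[elf_best$protein_id == pid, , drop = FALSE]
        sb <- if (!is.null(sim_best)) {
          sim_best[sim_best$protein_id == pid, , drop = FALSE]
        } else NULL
        classify_alpha_beta(pid, len,
                            if (nrow(hb) > 0) hb else NULL,
                            if (!is.null(sb) && nrow(sb) > 0) sb else NULL,
                            registry, thresholds)
      }
    })
  }

  dplyr::bind_rows(dec_kept, dec_excluded) |>
    dplyr::arrange(.data$protein_id)
}

# did this protein hit any of its route family's confirmation profiles?
route_confirmed <- function(protein_id, route_family, registry,
                            confirm_hits) {
  if (is.null(confirm_hits)) return(FALSE)
  i <- match(route_family, registry$family_name)
  if (is.na(i) || is.na(registry$confirm_profiles[i])) return(FALSE)
  conf <- strsplit(registry$confirm_profiles[i], ";")[[1]]
  any(confirm_hits$protein_id == protein_id &
        confirm_hits$family_name %in% trimws(conf))
}

#' Verdict counts of a decision table
#'
#' @param decisions a tibble from [annotate_proteins()].
#' @return a tibble of `verdict`, `n`.
#' @export
verdict_counts <- function(decisions) {
  dplyr::count(decisions, .data$verdict, name = "n")
}

#' Write / read a decision table
#'
#' @param decisions decision tibble.
#' @param path TSV path.
#' @return `path` (write) or the decision tibble (read).
#' @export
write_decisions <- function(decisions, path) {
  readr::write_tsv(decisions, path)
  invisible(path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_id = "c", verdict = "c", family = "c",
                    rule_id = "c", length = "i", hmm_family = "c",
                    hmm_evalue = "d", sim_family = "c", identity = "d",
                    coverage = "d"))
}
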