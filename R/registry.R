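#' Family registry
#'
#' The registry maps every family name that can appear in a profile or
#' similarity hit to one of four categories:
#' \describe{
#'   \item{`lipolytic_elf`}{a lipolytic family in the alpha/beta-hydrolase
#'     (ESTHER-style) classification; the unit of assignment.}
#'   \item{`miscellaneous`}{alpha/beta-hydrolase families of undetermined
#'     function; similarity to these leaves a protein unassigned.}
#'   \item{`non_lipolytic`}{reference families of known non-lipolytic
#'     function.}
#'   \item{`pfam_route`}{families II (GDSL), VIII (beta-lactamase-like) and
#'     patatin-like proteins, screened with separate route profiles and
#'     confirmed against a secondary profile set; `confirm_profiles` lists
#'     the confirming profile names (semicolon separated) and
#'     `len_min`/`len_max` give an optional length window (family VIII:
#'     350-450 aa).}
#' }
#' The four canonical miscellaneous family names
#' (`5_AlphaBeta_hydrolase`, `6_AlphaBeta_hydrolase`, `Abhydrolase_7`,
#' `AlphaBeta_hydrolase`) are always present; they are appended if the
#' input omits them.
#'
#' @param x a data frame with columns `family_name`, `category`, and
#'   optionally `confirm_profiles`, `len_min`, `len_max`.
#' @return a tibble of class `family_registry`.
#' @export
family_registry <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("family_name", "category") %in% names(x)))
  cats <- c("lipolytic_elf", "miscellaneous", "non_lipolytic", "pfam_route")
  bad <- setdiff(unique(x$category), cats)
  if (length(bad) > 0) {
    stop("unknown registry categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$family_name)) {
    stop("duplicate family names in registry", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"confirm_profiles" %in% names(x)) x$confirm_profiles <- NA_character_
  if (!"len_min" %in% names(x)) x$len_min <- NA_real_
  if (!"len_max" %in% names(x)) x$len_max <- NA_real_
  misc <- c("5_AlphaBeta_hydrolase", "6_AlphaBeta_hydrolase",
            "Abhydrolase_7", "AlphaBeta_hydrolase")
  add <- setdiff(misc, x$family_name)
  if (length(add) > 0) {
    x <- dplyr::bind_rows(x, tibble::tibble(
      family_name = add, category = "miscellaneous",
      confirm_profiles = NA_character_, len_min = NA_real_,
      len_max = NA_real_
    ))
  }
  structure(x, class = c("family_registry", class(tibble::tibble())))
}

#' @rdname family_registry
#' @param path TSV file with the registry columns.
#' @export
read_registry <- function(path) {
  family_registry(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname family_registry
#' @param registry a `family_registry`.
#' @export
write_registry <- function(registry, path) {
  readr::write_tsv(registry, path)
  invisible(path)
}

registry_category <- function(registry, family) {
  i <- match(family, registry$family_name)
  if (anyNA(i)) {
    stop("family not in registry: ",
         paste(unique(family[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  registry$category[i]
}

#' Annotation thresholds
#'
#' All tunable gates of the screening and annotation procedure, with the
#' published defaults: proteins of 200-800 aa are screened; profile hits
#' require E <= 1e-10; family determination during database construction
#' requires >= 60 % identity and >= 80 % query coverage; annotation
#' confirmation requires >= 60 % identity and >= 70 % coverage; family
#' VIII calls are restricted to 350-450 aa; sequence similarity network
#' edges require E <= `ssn_e_cutoff` and raw score >= 16.
#'
#' @param min_len,max_len protein length window (aa).
#' @param hmm_e_cutoff profile-HMM scan E-value cutoff.
#' @param elf_min_identity,elf_min_coverage_db_build gates used when
#'   assigning reference sequences to families (database construction).
#' @param annot_min_identity,annot_min_coverage gates used by the
#'   annotation decision rules.
#' @param viii_len_min,viii_len_max family VIII length window (aa).
#' @param ssn_e_cutoff,ssn_min_score sequence-similarity-network edge gates.
#' @return a list of class `lipo_thresholds`.
#' @export
lipo_thresholds <- function(min_len = 200, max_len = 800,
                            hmm_e_cutoff = 1e-10,
                            elf_min_identity = 0.60,
                            elf_min_coverage_db_build = 0.80,
                            annot_min_identity = 0.60,
                            annot_min_coverage = 0.70,
                            viii_len_min = 350, viii_len_max = 450,
                            ssn_e_cutoff = 1e-10, ssn_min_score = 16) {
  th <- list(min_len = min_len, max_len = max_len,
             hmm_e_cutoff = hmm_e_cutoff,
             elf_min_identity = elf_min_identity,
             elf_min_coverage_db_build = elf_min_coverage_db_build,
             annot_min_identity = annot_min_identity,
             annot_min_coverage = annot_min_coverage,
             viii_len_min = viii_len_min, viii_len_max = viii_len_max,
             ssn_e_cutoff = ssn_e_cutoff, ssn_min_score = ssn_min_score)
  with(th, {
    stopifnot(min_len < max_len, hmm_e_cutoff > 0,
              elf_min_identity > 0, elf_min_identity <= 1,
              elf_min_coverage_db_build > 0, elf_min_coverage_db_build <= 1,
              annot_min_identity > 0, annot_min_identity <= 1,
              annot_min_coverage > 0, annot_min_coverage <= 1,
              viii_len_min >= min_len, viii_len_max <= max_len,
              viii_len_min < viii_len_max, ssn_e_cutoff > 0)
  })
  structure(th, class = "lipo_thresholds")
}
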