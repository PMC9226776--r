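#' Pipeline run configuration
#'
#' One object holding every input path, threshold and seed of an
#' end-to-end run. In demo mode (the default) all inputs are synthesized
#' by the generators under the run seed; otherwise paths to an alignment
#' directory, a protein FASTA, a reference registry and (optionally) a
#' community count table must be supplied.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed for generators, calibration and permutation
#'   tests.
#' @param demo if `TRUE` synthesize all inputs with [gen_families()],
#'   [gen_protein_set()] and [gen_community()].
#' @param generator a [generator_config()] (demo mode; defaults to
#'   `generator_config(seed)`).
#' @param thresholds a [lipo_thresholds()].
#' @param msa_dir,proteins,registry,reference_fasta,reference_map paths
#'   for file mode.
#' @param counts,metadata community count and metadata TSVs (file mode).
#' @param anosim_permutations,indicator_permutations permutation counts
#'   for the comparative layer (defaults 9999 and 999).
#' @param calibration_decoys,calibration_decoy_length profile E-value
#'   calibration sample (defaults 200 decoys of 350 aa).
#' @return a list of class `liposcan_config`.
#' @export
liposcan_config <- function(out_dir, seed = 1, demo = TRUE,
                            generator = NULL,
                            thresholds = lipo_thresholds(),
                            msa_dir = NULL, proteins = NULL,
                            registry = NULL, reference_fasta = NULL,
                            reference_map = NULL, counts = NULL,
                            metadata = NULL,
                            anosim_permutations = 9999,
                            indicator_permutations = 999,
                            calibration_decoys = 200,
                            calibration_decoy_length = 350) {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  if (!demo) {
    need <- c(msa_dir = msa_dir, proteins = proteins, registry = registry,
              reference_fasta = reference_fasta,
              reference_map = reference_map)
    missing <- !file.exists(unlist(need))
    if (any(missing)) {
      stop("missing input path(s): ",
           paste(names(need)[missing], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(out_dir = out_dir, seed = seed, demo = demo,
         generator = generator, thresholds = thresholds,
         msa_dir = msa_dir, proteins = proteins, registry = registry,
         reference_fasta = reference_fasta, reference_map = reference_map,
         counts = counts, metadata = metadata,
         anosim_permutations = anosim_permutations,
         indicator_permutations = indicator_permutations,
         calibration_decoys = calibration_decoys,
         calibration_decoy_length = calibration_decoy_length),
    class = "liposcan_config"
  )
}

#' Run the screening pipeline end to end
#'
#' Stages, in order: obtain inputs (synthesize in demo mode), build and
#' calibrate the profile databases, scan and annotate the protein set,
#' normalize the community table to LPGM, and run the comparative layer
#' (Bray-Curtis + Ward dendrogram, ANOSIM, indicator associations,
#' habitat-genus network). Every artifact is written under `out_dir` and
#' listed in the returned manifest; re-running with the same config
#' reproduces identical tables.
#'
#' @param config a [liposcan_config()].
#' @param quiet suppress progress messages.
#' @return a list with `manifest` (tibble of stage, artifact, path),
#'   `decisions`, `verdicts`, `anosim`, `indicators` and `summary`
#'   (the parsed summary also written to `summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "liposcan_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  manifest <- list()
  note <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = artifact, path = path)
  }

  # ---- stage 1: inputs ----
  inputs <- tryCatch({
    if (config$demo) {
      say("inputs", "synthesizing demo inputs (seed ",
          config$generator$seed, ")")
      fams <- gen_families(config$generator)
      prot <- gen_protein_set(config$generator, fams)
      comm <- gen_community(config$generator)
      in_dir <- file.path(out, "inputs")
      dir.create(file.path(in_dir, "msa"), recursive = TRUE,
                 showWarnings = FALSE)
      for (f in fams$families) {
        write_msa(f$msa, file.path(in_dir, "msa",
                                   paste0(f$family_name, ".fasta")))
      }
      write_proteins(prot$proteins, file.path(in_dir, "proteins.faa"))
      readr::write_tsv(prot$truth, file.path(in_dir, "truth.tsv"))
      write_registry(fams$registry, file.path(in_dir, "registry.tsv"))
      write_proteins(
        dplyr::rename(fams$reference_set, protein_id = "seq_id"),
        file.path(in_dir, "reference.faa"))
      readr::write_tsv(fams$reference_set[, c("seq_id", "family_name")],
                       file.path(in_dir, "reference_map.tsv"))
      readr::write_tsv(comm$counts, file.path(in_dir, "counts.tsv"))
      readr::write_tsv(comm$metadata, file.path(in_dir, "metadata.tsv"))
      note("inputs", "msa_dir", file.path(in_dir, "msa"))
      note("inputs", "proteins", file.path(in_dir, "proteins.faa"))
      note("inputs", "truth", file.path(in_dir, "truth.tsv"))
      note("inputs", "registry", file.path(in_dir, "registry.tsv"))
      note("inputs", "counts", file.path(in_dir, "counts.tsv"))
      note("inputs", "metadata", file.path(in_dir, "metadata.tsv"))
      list(families = fams, proteins = prot$proteins, truth = prot$truth,
           registry = fams$registry, reference_set = fams$reference_set,
           counts = comm$counts, metadata = comm$metadata)
    } else {
      say("inputs", "reading inputs")
      reg <- read_registry(config$registry)
      list(families = NULL,
           proteins = read_proteins(config$proteins),
           truth = NULL, registry = reg,
           reference_set = read_reference_set(config$reference_fasta,
                                              config$reference_map),
           counts = if (!is.null(config$counts)) {
             readr::read_tsv(config$counts, show_col_types = FALSE)
           } else NULL,
           metadata = if (!is.null(config$metadata)) {
             readr::read_tsv(config$metadata, show_col_types = FALSE)
           } else NULL)
    }
  }, error = function(e) fail("inputs", e))

  # ---- stage 2: profile databases ----
  dbs <- tryCatch({
    say("build", "building and calibrating profile databases")
    if (config$demo) {
      synth_hmm_dbs(inputs$families, n_decoys = config$calibration_decoys,
                    decoy_length = config$calibration_decoy_length,
                    seed = config$seed + 41L)
    } else {
      db <- build_hmm_db(config$msa_dir,
                         n_decoys = config$calibration_decoys,
                         decoy_length = config$calibration_decoy_length,
                         seed = config$seed + 41L)
      route_fams <- inputs$registry$family_name[
        inputs$registry$category == "pfam_route"]
      list(elf_db = hmm_db(db[setdiff(names(db), route_fams)]),
           route_db = if (any(names(db) %in% route_fams)) {
             hmm_db(db[intersect(names(db), route_fams)])
           } else NULL,
           confirm_db = NULL)
    }
  }, error = function(e) fail("build", e))
  db_path <- file.path(out, "elf_db.hmm")
  write_hmm_db(dbs$elf_db, db_path)
  note("build", "elf_db", db_path)
  if (!is.null(dbs$route_db)) {
    write_hmm_db(dbs$route_db, file.path(out, "route_db.hmm"))
    note("build", "route_db", file.path(out, "route_db.hmm"))
  }
  if (!is.null(dbs$confirm_db)) {
    write_hmm_db(dbs$confirm_db, file.path(out, "confirm_db.hmm"))
    note("build", "confirm_db", file.path(out, "confirm_db.hmm"))
  }

  # ---- stage 3: annotation ----
  decisions <- tryCatch({
    say("annotate", "scanning and annotating ", nrow(inputs$proteins),
        " proteins")
    annotate_proteins(inputs$proteins, dbs$elf_db, inputs$reference_set,
                      inputs$registry, config$thresholds,
                      route_db = dbs$route_db, confirm_db = dbs$confirm_db)
  }, error = function(e) fail("annotate", e))
  write_decisions(decisions, file.path(out, "decisions.tsv"))
  note("annotate", "decisions", file.path(out, "decisions.tsv"))
  verdicts <- verdict_counts(decisions)
  say("annotate", paste(verdicts$verdict, verdicts$n, collapse = ", "))

  # ---- stage 4 + 5: community profile and comparison ----
  anosim_res <- NULL; indic <- NULL; abundance <- NULL
  if (!is.null(inputs$counts) && !is.null(inputs$metadata)) {
    res <- tryCatch({
      say("compare", "LPGM normalization and habitat comparison")
      abundance <- lpgm_normalize(inputs$counts, inputs$metadata)
      m <- abundance_matrix(abundance)
      readr::write_tsv(
        tibble::as_tibble(m, rownames = "sample_id"),
        file.path(out, "abundance_lpgm.tsv"))
      d <- bray_curtis(lpgm_log10(m))
      hc <- ward_cluster(d)
      write_dendrogram_newick(hc, file.path(out, "dendrogram.nwk"))
      meta <- attr(abundance, "metadata")
      groups <- meta$habitat[match(rownames(m), meta$sample_id)]
      an <- anosim_test(d, groups,
                        n_permutations = config$anosim_permutations,
                        seed = config$seed)
      ind <- indicator_analysis(
        abundance, n_permutations = config$indicator_permutations,
        seed = config$seed)
      net <- bipartite_network(ind)
      readr::write_tsv(tibble::as_tibble(ind),
                       file.path(out, "indicators.tsv"))
      readr::write_tsv(tibble::as_tibble(net),
                       file.path(out, "bipartite_edges.tsv"))
      if (nrow(net) > 0) {
        igraph::write_graph(bipartite_graph(net),
                            file.path(out, "bipartite.graphml"),
                            format = "graphml")
        note("compare", "bipartite_graphml",
             file.path(out, "bipartite.graphml"))
      }
      note("compare", "abundance", file.path(out, "abundance_lpgm.tsv"))
      note("compare", "dendrogram", file.path(out, "dendrogram.nwk"))
      note("compare", "indicators", file.path(out, "indicators.tsv"))
      note("compare", "bipartite_edges",
           file.path(out, "bipartite_edges.tsv"))
      say("compare", sprintf("ANOSIM R = %.3f, p = %.4g", an$R, an$p_value))
      list(anosim = an, indicators = ind)
    }, error = function(e) fail("compare", e))
    anosim_res <- res$anosim
    indic <- res$indicators
  }

  summary <- list(
    seed = config$seed,
    n_proteins = nrow(inputs$proteins),
    verdicts = setNames(as.list(verdicts$n), verdicts$verdict),
    assigned_families = as.list(table(
      decisions$family[decisions$verdict == "assigned"])),
    anosim = if (!is.null(anosim_res)) {
      list(R = anosim_res$R, p_value = anosim_res$p_value,
           n_permutations = anosim_res$n_permutations)
    } else NULL,
    n_significant_indicators = if (!is.null(indic)) nrow(indic) else NULL
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("summary", "summary", file.path(out, "summary.json"))
  note("summary", "log", log_path)
  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  say("done", "wrote ", nrow(manifest), " artifacts")

  list(manifest = manifest, decisions = decisions, verdicts = verdicts,
       anosim = anosim_res, indicators = indic, summary = summary)
}

#' Per-sample assigned-family counts from a decision table
#'
#' Aggregates `assigned` decisions into the long count table consumed by
#' [lpgm_normalize()], using a `sample_id` column carried on the protein
#' table.
#'
#' @param decisions decision tibble from [annotate_proteins()].
#' @param proteins protein tibble with `protein_id` and `sample_id`.
#' @return long tibble of `sample_id`, `category` (family), `count`.
#' @export
assigned_family_counts <- function(decisions, proteins) {
  stopifnot("sample_id" %in% names(proteins))
  decisions |>
    dplyr::filter(.data$verdict == "assigned") |>
    dplyr::inner_join(proteins[, c("protein_id", "sample_id")],
                      by = "protein_id") |>
    dplyr::count(.data$sample_id, category = .data$family, name = "count")
}
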