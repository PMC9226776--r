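#' Family multiple sequence alignment
#'
#' A light container for one lipolytic family's multiple sequence alignment:
#' a set of equal-length gapped residue strings (uppercase amino acids plus
#' `-`) under a family name. Profile HMMs are built from these with
#' [build_hmm()].
#'
#' @param family_name family label (an ELF name such as
#'   `"Hormone-sensitive_lipase_like"`).
#' @param rows character vector of gapped, equal-length residue strings.
#' @return an object of class `msa_family` with fields `family_name`,
#'   `rows` and `n_columns`.
#' @examples
#' msa_family("toy", c("ACD-", "AC-E", "ACDE"))
#' @export
msa_family <- function(family_name, rows) {
  stopifnot(is.character(family_name), length(family_name) == 1,
            nzchar(family_name))
  if (length(rows) == 0) {
    stop("empty MSA for family '", family_name, "'", call. = FALSE)
  }
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("MSA rows for family '", family_name,
         "' differ in length: ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  if (widths[1] < 1) {
    stop("MSA for family '", family_name, "' has zero columns", call. = FALSE)
  }
  chars <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(aa_alphabet(), "-"))
  if (length(bad) > 0) {
    stop("MSA for family '", family_name, "' contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(family_name = family_name, rows = unname(rows),
         n_columns = widths[1]),
    class = "msa_family"
  )
}

#' @export
print.msa_family <- function(x, ...) {
  cat("<msa_family> ", x$family_name, ": ", length(x$rows), " sequences x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

# character matrix (rows x columns) view of the alignment
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Majority-rule consensus of an alignment
#'
#' Per-column most frequent residue (gaps excluded; ties broken by alphabet
#' order); all-gap columns are dropped. Used to characterise synthetic
#' families and for twilight-decoy identity checks.
#'
#' @param msa an [msa_family()].
#' @return an ungapped residue string.
#' @export
msa_consensus <- function(msa) {
  m <- msa_matrix(msa)
  cons <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_character_)
    tab <- table(factor(col, levels = aa_alphabet()))
    names(tab)[which.max(tab)]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Read family alignments from a directory of aligned FASTA files
#'
#' One aligned FASTA per family; the family name is the file stem. This is
#' the on-disk layout expected for the profile database build.
#'
#' @param dir directory containing `*.fasta` / `*.fa` / `*.afa` files.
#' @return a named list of [msa_family()] objects.
#' @export
read_msa_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta|afa)$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no FASTA files found in ", dir, call. = FALSE)
  }
  msas <- lapply(files, function(f) {
    seqs <- Biostrings::readAAStringSet(f)
    msa_family(sub("\\.[^.]+$", "", basename(f)), as.character(seqs))
  })
  names(msas) <- vapply(msas, `[[`, "", "family_name")
  msas[order(names(msas))]
}

#' Write one family alignment as aligned FASTA
#'
#' @param msa an [msa_family()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  ids <- sprintf("%s_%03d", msa$family_name, seq_along(msa$rows))
  writeLines(paste0(">", ids, "\n", msa$rows), path)
  invisible(path)
}

#' Read a protein FASTA as a tibble
#'
#' @param path FASTA file of (ungapped) protein sequences.
#' @param sample_id optional sample label attached to every record.
#' @return a tibble with columns `protein_id`, `sequence`, `length` and
#'   `sample_id`.
#' @export
read_proteins <- function(path, sample_id = NA_character_) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(seqs),
    length = Biostrings::width(seqs),
    sample_id = sample_id
  )
}

#' Write a protein tibble as FASTA
#'
#' @param proteins tibble with `protein_id` and `sequence` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence), path)
  invisible(path)
}
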