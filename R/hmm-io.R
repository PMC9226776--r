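#' Profile HMM text format
#'
#' Profiles are stored in a documented HMMER3-flavoured plain-text format.
#' Each record is:
#' \preformatted{
#' LIPOHMM 1.0
#' NAME  <family_name>
#' LENG  <L>
#' ALPH  amino
#' BG    <20 background probabilities>
#' CALIB <lambda> <tau> <n_decoys> <decoy_length> <seed>   (optional)
#' MCOL  <match column indices in the source alignment>
#' NODE  0
#'   INS <20 insert emission probabilities for I_0>
#' NODE  <k>                                    (k = 1..L)
#'   MAT <20 match emission probabilities>
#'   INS <20 insert emission probabilities for I_k>
#'   TRA <MM MI MD IM II DM DD>                 (nodes 1..L-1 only)
#' //
#' }
#' Probabilities are written with 17 significant digits, so a write/read
#' round trip reproduces the model (and therefore all scores) exactly. A
#' database file is simply the concatenation of member records.
#'
#' @param x a `profile_hmm`, an `hmm_db`, or a list of `profile_hmm`s.
#' @param path file path.
#' @return `write_hmm_db()` returns `path` invisibly; `read_hmm_db()`
#'   returns an `hmm_db` (named list of `profile_hmm`s).
#' @name hmm_io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

hmm_record_lines <- function(hmm) {
  validate_hmm(hmm)
  L <- hmm$L
  out <- c(
    "LIPOHMM 1.0",
    paste("NAME ", hmm$family_name),
    paste("LENG ", L),
    "ALPH  amino",
    paste("BG   ", paste(fmt_num(hmm$background), collapse = " "))
  )
  if (!is.null(hmm$calibration)) {
    cal <- hmm$calibration
    out <- c(out, paste("CALIB", fmt_num(cal$lambda), fmt_num(cal$tau),
                        cal$n_decoys, cal$decoy_length, cal$seed))
  }
  if (!is.null(hmm$match_columns)) {
    out <- c(out, paste("MCOL ", paste(hmm$match_columns, collapse = " ")))
  }
  out <- c(out, "NODE  0",
           paste("  INS", paste(fmt_num(hmm$insert_emissions[1, ]),
                                collapse = " ")))
  for (k in seq_len(L)) {
    out <- c(out, paste("NODE ", k),
             paste("  MAT", paste(fmt_num(hmm$match_emissions[k, ]),
                                  collapse = " ")),
             paste("  INS", paste(fmt_num(hmm$insert_emissions[k + 1, ]),
                                  collapse = " ")))
    if (k <= L - 1) {
      tr <- c(hmm$transitions$tm[k, ], hmm$transitions$ti[k, ],
              hmm$transitions$td[k, ])
      out <- c(out, paste("  TRA", paste(fmt_num(tr), collapse = " ")))
    }
  }
  c(out, "//")
}

#' @rdname hmm_io
#' @export
write_hmm_db <- function(x, path) {
  if (inherits(x, "profile_hmm")) x <- list(x)
  lines <- unlist(lapply(x, hmm_record_lines))
  writeLines(lines, path)
  invisible(path)
}

parse_error <- function(lineno, msg) {
  stop("profile parse error at line ", lineno, ": ", msg, call. = FALSE)
}

#' @rdname hmm_io
#' @export
read_hmm_db <- function(path) {
  lines <- readLines(path)
  hmms <- list()
  i <- 1L
  n <- length(lines)
  num_fields <- function(line, lineno, n_expect, tag) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(sub(
      paste0("^\\s*", tag, "\\s+"), "", line)), "\\s+")[[1]]))
    if (length(v) != n_expect || anyNA(v)) {
      parse_error(lineno, paste0("expected ", n_expect,
                                 " numeric fields after ", tag))
    }
    v
  }
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^LIPOHMM", lines[i])) {
      parse_error(i, "expected 'LIPOHMM' record header")
    }
    i <- i + 1L
    name <- NULL; L <- NULL; bg <- NULL; cal <- NULL; mcol <- NULL
    # header block
    while (i <= n && !grepl("^NODE", lines[i])) {
      ln <- lines[i]
      if (grepl("^NAME", ln)) {
        name <- trimws(sub("^NAME\\s+", "", ln))
      } else if (grepl("^LENG", ln)) {
        L <- as.integer(trimws(sub("^LENG\\s+", "", ln)))
      } else if (grepl("^ALPH", ln)) {
        if (trimws(sub("^ALPH\\s+", "", ln)) != "amino") {
          parse_error(i, "only the amino alphabet is supported")
        }
      } else if (grepl("^BG", ln)) {
        bg <- num_fields(ln, i, 20, "BG")
      } else if (grepl("^CALIB", ln)) {
        v <- num_fields(ln, i, 5, "CALIB")
        cal <- list(lambda = v[1], tau = v[2], n_decoys = as.integer(v[3]),
                    decoy_length = as.integer(v[4]), seed = as.integer(v[5]))
      } else if (grepl("^MCOL", ln)) {
        mcol <- as.integer(strsplit(trimws(sub("^MCOL\\s+", "", ln)),
                                    "\\s+")[[1]])
      } else if (nzchar(trimws(ln))) {
        parse_error(i, paste0("unrecognized header line: ", trimws(ln)))
      }
      i <- i + 1L
    }
    if (is.null(name) || is.null(L) || is.null(bg)) {
      parse_error(i, "record is missing NAME, LENG or BG")
    }
    mat <- matrix(NA_real_, L, 20, dimnames = list(NULL, aa_alphabet()))
    ins <- matrix(NA_real_, L + 1, 20, dimnames = list(NULL, aa_alphabet()))
    tm <- matrix(NA_real_, max(L - 1, 0), 3,
                 dimnames = list(NULL, c("MM", "MI", "MD")))
    ti <- matrix(NA_real_, max(L - 1, 0), 2,
                 dimnames = list(NULL, c("IM", "II")))
    td <- matrix(NA_real_, max(L - 1, 0), 2,
                 dimnames = list(NULL, c("DM", "DD")))
    # node blocks
    while (i <= n && !grepl("^//", lines[i])) {
      if (!grepl("^NODE", lines[i])) parse_error(i, "expected NODE or //")
      k <- as.integer(trimws(sub("^NODE\\s+", "", lines[i])))
      if (is.na(k) || k < 0 || k > L) parse_error(i, "node index out of range")
      i <- i + 1L
      if (k >= 1) {
        if (i > n || !grepl("^\\s*MAT", lines[i])) {
          parse_error(i, paste0("truncated node block ", k, ": missing MAT"))
        }
        mat[k, ] <- num_fields(lines[i], i, 20, "MAT"); i <- i + 1L
      }
      if (i > n || !grepl("^\\s*INS", lines[i])) {
        parse_error(i, paste0("truncated node block ", k, ": missing INS"))
      }
      ins[k + 1, ] <- num_fields(lines[i], i, 20, "INS"); i <- i + 1L
      if (k >= 1 && k <= L - 1) {
        if (i > n || !grepl("^\\s*TRA", lines[i])) {
          parse_error(i, paste0("truncated node block ", k, ": missing TRA"))
        }
        v <- num_fields(lines[i], i, 7, "TRA"); i <- i + 1L
        tm[k, ] <- v[1:3]; ti[k, ] <- v[4:5]; td[k, ] <- v[6:7]
      }
    }
    if (i > n) parse_error(i, "missing record terminator //")
    i <- i + 1L
    if (anyNA(mat) || anyNA(ins) || anyNA(tm) || anyNA(ti) || anyNA(td)) {
      parse_error(i - 1L, paste0("record '", name, "' has missing node blocks"))
    }
    hmm <- structure(
      list(family_name = name, L = L, match_emissions = mat,
           insert_emissions = ins,
           transitions = list(tm = tm, ti = ti, td = td),
           background = setNames(bg, aa_alphabet()),
           match_columns = mcol, calibration = cal),
      class = "profile_hmm"
    )
    validate_hmm(hmm, tol = 1e-9)
    hmms[[name]] <- hmm
  }
  if (length(hmms) == 0) {
    stop("no profile records found in ", path, call. = FALSE)
  }
  structure(hmms, class = c("hmm_db", "list"))
}
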