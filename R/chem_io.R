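# Molecule parsing, canonicalization, featurization and CSV exchange.
#
# Features are a 1024-bit circular substructure fingerprint (ECFP4 folded
# from OpenBabel's 4096-bit output) concatenated with a fixed block of
# physicochemical descriptors. Descriptors are z-scored against statistics
# frozen from the training corpus and clipped to [-10, 10]; fingerprint bits
# are left binary.

#' Descriptor names appended by OpenBabel, in feature order
#' @keywords internal
OB_DESCRIPTORS <- c("logP", "TPSA", "MW", "MR", "HBA1", "HBA2", "HBD", "nF",
                    "rotors", "atoms", "bonds", "abonds", "dbonds", "sbonds",
                    "tbonds")

#' Number of folded fingerprint bits
#' @keywords internal
FP_BITS <- 1024L

#' Total feature dimension (fingerprint block + descriptor block)
#'
#' @return integer, the fixed length of every molecule feature vector.
#' @export
feature_dim <- function() FP_BITS + length(OB_DESCRIPTORS)

#' Canonicalize a vector of SMILES strings
#'
#' Runs OpenBabel's canonical SMILES writer on each input. Strings that do
#' not parse as molecules yield `NA`, so a batch never aborts on one bad
#' record (benchmark construction drops such records and reports them).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length; `NA` where the input was
#'   blank or chemically unparsable.
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles)) {
    fsm_stop("invalid_input", "`smiles` must be a character vector")
  }
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  res <- run_obabel(trimws(smiles[idx]), "-ocan")
  if (length(res) == 0L) return(out)
  parts <- strsplit(res, "\t", fixed = TRUE)
  can <- trimws(vapply(parts, `[`, "", 1L))
  ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
  j <- suppressWarnings(as.integer(sub("^i", "", ttl)))
  keep <- !is.na(j) & nzchar(can)
  out[idx[j[keep]]] <- can[keep]
  out
}

#' Parse one SMILES string to canonical form
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES (idempotent: canonicalizing the result again
#'   returns it unchanged).
#' @section Errors: `fewshotmol_empty_input` for blank input,
#'   `fewshotmol_invalid_smiles` for an unparsable string.
#' @examples
#' \dontrun{parse_smiles("C1=CC=CC=C1")  # "c1ccccc1"}
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    fsm_stop("empty_input", "SMILES input is empty or not a single string")
  }
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) {
    fsm_stop("invalid_smiles", sprintf("not a parseable SMILES: '%s'", smiles))
  }
  can
}

# Fingerprints -----------------------------------------------------------

#' Parse obabel's hexadecimal fingerprint dump into a folded bit matrix
#' @keywords internal
parse_fpt_hex <- function(lines, n) {
  hdr <- startsWith(lines, ">")
  grp <- cumsum(hdr)
  titles <- sub("^>(\\S+).*", "\\1", lines[hdr])
  mol_idx <- suppressWarnings(as.integer(sub("^i", "", titles)))
  body <- lines[!hdr]
  bgrp <- grp[!hdr]
  words_by_mol <- vapply(split(body, bgrp), paste, "", collapse = " ")
  fp <- matrix(0, n, FP_BITS)
  for (g in seq_along(words_by_mol)) {
    i <- mol_idx[g]
    if (is.na(i)) next
    w <- strsplit(trimws(words_by_mol[[g]]), "\\s+")[[1]]
    if (length(w) == 0L) next
    hi <- strtoi(substr(w, 1L, 4L), 16L)
    lo <- strtoi(substr(w, 5L, 8L), 16L)
    word0 <- seq_along(w) - 1L
    for (k in 0:15) {
      sl <- which(lo %/% 2^k %% 2 == 1)
      if (length(sl)) fp[i, (word0[sl] * 32L + k) %% FP_BITS + 1L] <- 1
      sh <- which(hi %/% 2^k %% 2 == 1)
      if (length(sh)) fp[i, (word0[sh] * 32L + 16L + k) %% FP_BITS + 1L] <- 1
    }
  }
  fp
}

#' Compute raw (unstandardized) feature vectors for canonical SMILES
#'
#' The first `1024` columns are folded ECFP4 fingerprint bits; the remaining
#' columns are OpenBabel physicochemical descriptors in the order of
#' `OB_DESCRIPTORS`. The map is deterministic: identical SMILES give
#' bit-identical rows.
#'
#' @param canonical_smiles character vector of canonical SMILES (all must
#'   parse; use [canonicalize_smiles()] first).
#' @param chunk_size molecules per obabel invocation.
#' @return numeric matrix `[N x feature_dim()]` with `canonical_smiles` as
#'   row names of the order given.
#' @export
featurize_smiles <- function(canonical_smiles, chunk_size = 5000L) {
  if (!is.character(canonical_smiles) || length(canonical_smiles) == 0L) {
    fsm_stop("invalid_input", "`canonical_smiles` must be a non-empty character vector")
  }
  n <- length(canonical_smiles)
  X <- matrix(NA_real_, n, feature_dim())
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (idx in chunks) {
    smis <- canonical_smiles[idx]
    # fingerprint block
    fl <- run_obabel(smis, c("-ofpt", "-xfECFP4", "-xh"))
    fp <- parse_fpt_hex(fl, length(idx))
    # descriptor block
    dl <- run_obabel(smis, c("-osmi", "--append", paste(OB_DESCRIPTORS, collapse = " ")))
    dm <- matrix(NA_real_, length(idx), length(OB_DESCRIPTORS))
    if (length(dl)) {
      parts <- strsplit(dl, "\t", fixed = TRUE)
      rest <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
      toks <- strsplit(trimws(rest), "\\s+")
      for (t in toks) {
        i <- suppressWarnings(as.integer(sub("^i", "", t[1L])))
        if (is.na(i) || length(t) != length(OB_DESCRIPTORS) + 1L) next
        dm[i, ] <- suppressWarnings(as.numeric(t[-1L]))
      }
    }
    bad <- which(apply(dm, 1L, function(r) any(!is.finite(r))))
    if (length(bad)) {
      fsm_stop("featurization_error",
               sprintf("descriptor computation failed for %d molecule(s), e.g. '%s'",
                       length(bad), smis[bad[1L]]))
    }
    X[idx, ] <- cbind(fp, dm)
  }
  rownames(X) <- canonical_smiles
  colnames(X) <- c(paste0("fp", seq_len(FP_BITS)), OB_DESCRIPTORS)
  X
}

# Standardization --------------------------------------------------------

#' Fit a feature standardizer on a training feature matrix
#'
#' Records per-descriptor mean and standard deviation (constant descriptors
#' get sd 1 so they map to 0). Fingerprint bits are untouched. The fitted
#' object is serialized inside every model checkpoint so prediction-time
#' featurization matches training exactly.
#'
#' @param X raw feature matrix from [featurize_smiles()].
#' @param clip absolute z-score cap applied on transform.
#' @return an object of class `feature_standardizer`.
#' @export
fit_standardizer <- function(X, clip = 10) {
  stopifnot(is.matrix(X), ncol(X) == feature_dim())
  di <- (FP_BITS + 1L):ncol(X)
  mu <- colMeans(X[, di, drop = FALSE])
  sd <- apply(X[, di, drop = FALSE], 2L, stats::sd)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  structure(list(mean = mu, sd = sd, clip = clip, desc_cols = di),
            class = "feature_standardizer")
}

#' Apply a fitted standardizer to a raw feature matrix
#'
#' @param X raw feature matrix.
#' @param std a `feature_standardizer`.
#' @return matrix of the same shape; descriptor block z-scored and clipped,
#'   no non-finite values.
#' @export
standardize_features <- function(X, std) {
  stopifnot(inherits(std, "feature_standardizer"), is.matrix(X))
  if (ncol(X) != feature_dim()) {
    fsm_stop("dimension_mismatch",
             sprintf("feature matrix has %d columns, expected %d", ncol(X), feature_dim()))
  }
  di <- std$desc_cols
  Z <- sweep(X[, di, drop = FALSE], 2L, std$mean, "-")
  Z <- sweep(Z, 2L, std$sd, "/")
  Z[Z > std$clip] <- std$clip
  Z[Z < -std$clip] <- -std$clip
  out <- X
  out[, di] <- Z
  out
}

# CSV exchange -----------------------------------------------------------

#' Read molecules from a CSV file or inline CSV text
#'
#' @param source a file path, or a string containing CSV text (detected by
#'   an embedded newline / non-existence as a file).
#' @param column name of the SMILES column (default `"smiles"`).
#' @return a list with `records` (data.frame: `row`, `input_smiles`,
#'   `canonical_smiles`; input order preserved) and `rejected` (data.frame:
#'   `row`, `input_smiles`, `reason`) — invalid SMILES are reported with
#'   their row numbers, never silently dropped.
#' @section Errors: `fewshotmol_missing_column`, `fewshotmol_empty_file`.
#' @export
read_molecule_csv <- function(source, column = "smiles") {
  con_txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  }
  con_txt <- con_txt[nzchar(trimws(con_txt))]
  if (length(con_txt) == 0L) {
    fsm_stop("empty_file", "CSV source is empty (no header row)")
  }
  df <- utils::read.csv(text = paste(con_txt, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!column %in% names(df)) {
    fsm_stop("missing_column",
             sprintf("CSV has no column '%s' (found: %s)", column,
                     paste(names(df), collapse = ", ")))
  }
  smis <- as.character(df[[column]])
  if (length(smis) == 0L) {
    return(list(
      records = data.frame(row = integer(), input_smiles = character(),
                           canonical_smiles = character(), stringsAsFactors = FALSE),
      rejected = data.frame(row = integer(), input_smiles = character(),
                            reason = character(), stringsAsFactors = FALSE)
    ))
  }
  can <- canonicalize_smiles(smis)
  bad <- is.na(can)
  reason <- ifelse(!nzchar(trimws(ifelse(is.na(smis), "", smis))), "empty", "invalid_smiles")
  list(
    records = data.frame(row = which(!bad), input_smiles = smis[!bad],
                         canonical_smiles = can[!bad], stringsAsFactors = FALSE),
    rejected = data.frame(row = which(bad), input_smiles = smis[bad],
                          reason = reason[bad], stringsAsFactors = FALSE)
  )
}

#' Write a prediction table to CSV
#'
#' Columns `smiles,prediction`, predictions printed with six decimals so a
#' write/read round trip preserves values to 1e-6.
#'
#' @param table data.frame with columns `smiles` and `prediction`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(table, path) {
  stopifnot(is.data.frame(table), all(c("smiles", "prediction") %in% names(table)))
  if (nrow(table) == 0L) {
    fsm_stop("invalid_input", "prediction table is empty")
  }
  lines <- c("smiles,prediction",
             sprintf("%s,%.6f", table$smiles, table$prediction))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fsm_stop("io_error", sprintf("cannot write predictions to '%s'", path))
  invisible(path)
}
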