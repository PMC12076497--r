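#' @keywords internal
"_PACKAGE"

# Typed conditions -------------------------------------------------------

#' Signal a classed error
#'
#' All package errors carry a class of the form `fewshotmol_<what>` so
#' callers (and the command-line wrapper) can dispatch on the failure mode.
#'
#' @param class short error class, e.g. `"invalid_smiles"`.
#' @param msg human-readable message.
#' @param ... fields attached to the condition object.
#' @keywords internal
fsm_stop <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("fewshotmol_", class), "fewshotmol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Seed plumbing ----------------------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' A polynomial rolling hash over the printed representation of the master
#' seed and any number of labels, reduced mod 2^31 - 1. Used to give every
#' source of randomness (weight init, episode sampling, support draws, ...)
#' its own named stream so that adding one consumer does not reshuffle the
#' others.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "|")
  h <- 7
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h + 1)
}

# OpenBabel --------------------------------------------------------------

fsm_env <- new.env(parent = emptyenv())

#' Locate the obabel executable
#' @keywords internal
obabel_path <- function() {
  if (!is.null(fsm_env$obabel)) return(fsm_env$obabel)
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    fsm_stop("missing_obabel",
             "OpenBabel executable 'obabel' not found on PATH; it is required for SMILES handling.")
  }
  fsm_env$obabel <- unname(p)
  fsm_env$obabel
}

#' Run obabel on a set of SMILES and capture stdout
#'
#' Writes a title-tagged .smi file (titles `i1..iN`), runs obabel with `-e`
#' (skip molecules that fail to parse) and returns stdout lines. Warnings
#' obabel prints to stderr are discarded.
#'
#' @keywords internal
run_obabel <- function(smiles, args) {
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(smiles, paste0("i", seq_along(smiles))), inp)
  out <- suppressWarnings(
    system2(obabel_path(), c(inp, args, "-e"), stdout = TRUE, stderr = FALSE)
  )
  if (!is.null(attr(out, "status")) && attr(out, "status") > 1) {
    fsm_stop("obabel_failure", sprintf("obabel exited with status %d", attr(out, "status")))
  }
  out
}
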