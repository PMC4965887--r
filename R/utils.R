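# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("gxs_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_config(...)
  invisible(TRUE)
}

#' QC audit record
#'
#' Every filter in the QC module returns, next to its filtered object, a
#' `qc_report` describing what it did: counts in, counts removed, the
#' threshold applied, and (optionally) per-item reasons. Counts always
#' reconcile: `n_in - n_removed == n_out`.
#'
#' @param stage Character label of the QC stage.
#' @param unit What was filtered (`"snp"`, `"individual"`, `"stratum"`).
#' @param n_in,n_removed Counts before filtering and removed.
#' @param threshold The threshold used, echoed verbatim.
#' @param removed Identifiers of removed items (optional).
#' @param notes Optional free-text notes (e.g. flagged monomorphic SNPs).
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(stage, unit, n_in, n_removed, threshold,
                      removed = NULL, notes = NULL) {
  out <- structure(list(
    stage = stage, unit = unit,
    n_in = as.integer(n_in),
    n_removed = as.integer(n_removed),
    n_out = as.integer(n_in) - as.integer(n_removed),
    threshold = threshold,
    removed = removed,
    notes = notes
  ), class = "qc_report")
  stopifnot(out$n_out >= 0L)
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC stage '%s': %d %s in, %d removed, %d kept (threshold: %s)\n",
              x$stage, x$n_in, x$unit, x$n_removed, x$n_out,
              paste(format(x$threshold), collapse = ", ")))
  if (!is.null(x$notes) && length(x$notes)) {
    cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

# Run code with a temporarily seeded RNG, restoring caller state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
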