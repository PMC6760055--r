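#' Coded value of a process factor
#'
#' Affine map sending a factor's low/mid/high uncoded levels to -1/0/+1.
#'
#' @param spec One row of a factor-specification table (a list or one-row
#'   data.frame with `low`, `mid`, `high`), or the table itself together
#'   with a `symbol`.
#' @param uncoded Uncoded value(s), within `[low, high]`.
#' @param symbol If `spec` is the whole factor table, the factor symbol
#'   (e.g. `"X9"`) naming the row to use.
#' @return Coded value(s) in `[-1, 1]`.
#' @seealso [uncode_factor()]
#' @export
code_factor <- function(spec, uncoded, symbol = NULL) {
  spec <- .factor_row(spec, symbol)
  if (any(uncoded < spec$low - 1e-9 | uncoded > spec$high + 1e-9))
    stop(sprintf("uncoded value outside [%g, %g]", spec$low, spec$high),
         call. = FALSE)
  (uncoded - spec$mid) / ((spec$high - spec$low) / 2)
}

#' Uncoded value of a process factor
#'
#' Inverse of [code_factor()]: maps coded -1/0/+1 back to low/mid/high.
#'
#' @inheritParams code_factor
#' @param coded Coded value(s) in `[-1, 1]`.
#' @return Uncoded value(s).
#' @export
uncode_factor <- function(spec, coded, symbol = NULL) {
  spec <- .factor_row(spec, symbol)
  if (any(abs(coded) > 1 + 1e-9))
    stop("coded value outside [-1, 1]", call. = FALSE)
  spec$mid + coded * (spec$high - spec$low) / 2
}

.factor_row <- function(spec, symbol) {
  if (!is.null(symbol)) {
    stopifnot(is.data.frame(spec), symbol %in% spec$symbol)
    spec <- spec[spec$symbol == symbol, ]
  }
  stopifnot(all(c("low", "mid", "high") %in% names(spec)))
  if (!(spec$low < spec$mid && spec$mid < spec$high))
    stop("factor levels must satisfy low < mid < high", call. = FALSE)
  spec
}

#' Coded design matrix
#'
#' Converts the uncoded factor columns of a design table to coded values.
#'
#' @param design Design data.frame with uncoded columns named by the factor
#'   symbols.
#' @param factors Factor-specification data.frame (`symbol`, `low`, `mid`,
#'   `high`).
#' @return A matrix of coded values, one column per factor.
#' @export
coded_design <- function(design, factors) {
  stopifnot(all(factors$symbol %in% names(design)))
  out <- vapply(seq_len(nrow(factors)), function(j) {
    code_factor(factors[j, ], design[[factors$symbol[j]]])
  }, numeric(nrow(design)))
  colnames(out) <- factors$symbol
  out
}

#' Validate definitive-screening-design structure
#'
#' Reports, for a candidate definitive screening design (DSD):
#' the center runs (all factors at their mid level); for every non-center
#' run, how many factors sit at the mid level (a textbook DSD run has
#' exactly one); and the fold-over pairing (for each non-center run, whether
#' its coded mirror image is also in the design). The check is report-only:
#' designs that deviate are described, not rejected, because published
#' screening tables are sometimes augmented with extra two-level runs.
#'
#' @param design Design data.frame (uncoded), one row per run, with a
#'   `run_id` column and one column per factor symbol.
#' @param factors Factor-specification data.frame.
#' @param tol Tolerance for matching coded levels.
#' @return An object of class `dsd_validation`: list with `n_runs`,
#'   `center_runs` (run ids), `mid_counts` (per non-center run),
#'   `flagged_runs` (non-center runs whose mid-level count is not 1),
#'   `foldover_pairs` (two-column matrix of run ids), `unpaired_runs`.
#' @export
validate_dsd <- function(design, factors, tol = 1e-8) {
  stopifnot(nrow(design) > 0)
  cd <- coded_design(design, factors)
  run_id <- if ("run_id" %in% names(design)) design$run_id else seq_len(nrow(design))
  is_mid <- abs(cd) < tol
  center <- rowSums(is_mid) == ncol(cd)
  mid_counts <- rowSums(is_mid)[!center]
  names(mid_counts) <- run_id[!center]
  flagged <- names(mid_counts)[mid_counts != 1]

  # fold-over pairing among non-center runs: mirror = sign-negated coded row
  nc <- which(!center)
  key <- apply(round(cd, 8), 1, paste, collapse = ",")
  mirror_key <- apply(round(-cd, 8), 1, paste, collapse = ",")
  pairs <- NULL; paired <- logical(length(key))
  for (i in nc) {
    if (paired[i]) next
    j <- setdiff(which(key == mirror_key[i]), i)
    j <- j[!paired[j]]
    if (length(j)) {
      j <- j[1]
      pairs <- rbind(pairs, c(run_id[i], run_id[j]))
      paired[c(i, j)] <- TRUE
    }
  }
  structure(list(
    n_runs = nrow(design),
    center_runs = run_id[center],
    mid_counts = mid_counts,
    flagged_runs = flagged,
    foldover_pairs = pairs,
    unpaired_runs = run_id[nc][!paired[nc]]
  ), class = "dsd_validation")
}

#' @export
print.dsd_validation <- function(x, ...) {
  cat(sprintf("DSD structure report: %d runs\n", x$n_runs))
  cat(sprintf("  center runs (%d): %s\n", length(x$center_runs),
              paste(x$center_runs, collapse = ", ")))
  cat(sprintf("  non-center runs with exactly one mid-level factor: %d of %d\n",
              sum(x$mid_counts == 1), length(x$mid_counts)))
  if (length(x$flagged_runs))
    cat(sprintf("  flagged (mid-level count != 1): runs %s\n",
                paste(x$flagged_runs, collapse = ", ")))
  cat(sprintf("  fold-over pairs: %d; unpaired non-center runs: %s\n",
              NROW(x$foldover_pairs),
              if (length(x$unpaired_runs)) paste(x$unpaired_runs, collapse = ", ")
              else "none"))
  invisible(x)
}
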