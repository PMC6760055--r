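#' Perturb measured responses with multiplicative Gaussian noise
#'
#' Each measured response value `y` is replaced by an independent draw from
#' `Normal(mean = y, sd = rsd * y)`, emulating the run-to-run analytical
#' error of the quality measurements. Uses the current RNG state; call
#' `set.seed()` (or use the `seed` argument of
#' [monte_carlo_design_space()]) for reproducibility.
#'
#' @param responses Numeric vector (or matrix) of positive measured values.
#' @param rsd Relative standard deviation of the noise (>= 0).
#' @return Perturbed values, same shape as `responses`.
#' @export
perturb_responses <- function(responses, rsd) {
  if (rsd < 0) stop("rsd must be non-negative", call. = FALSE)
  if (any(responses <= 0)) stop("responses must be positive", call. = FALSE)
  if (rsd == 0) return(responses)
  responses * (1 + stats::rnorm(length(responses), 0, rsd))
}

#' Rectangular grid over critical process parameters
#'
#' Builds the evaluation grid for the design-space computation. The default
#' spans the investigated ranges of the three CPPs at 1-unit steps for the
#' two ethanol concentrations and 5-min steps for elution time
#' (11 x 11 x 13 points).
#'
#' @param ... Named numeric vectors of grid points, one per CPP (uncoded).
#' @return Data frame, one row per grid cell, ordered lexicographically by
#'   the axes as given.
#' @examples
#' g <- cpp_grid(X1 = c(80, 90), X9 = c(55, 65), X10 = c(120, 180))
#' nrow(g)
#' @export
cpp_grid <- function(...) {
  axes <- list(...)
  if (!length(axes))
    axes <- list(X1 = seq(80, 90, by = 1), X9 = seq(55, 65, by = 1),
                 X10 = seq(120, 180, by = 5))
  stopifnot(!is.null(names(axes)), all(nzchar(names(axes))))
  # lexicographic in the order given: first axis varies slowest
  g <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(axes)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Monte Carlo probability-based design space
#'
#' For a fixed material (its attribute values `Z`), computes the
#' probability, over the measurement-error distribution, that every process
#' CQA meets its lower limit at each grid point of the critical process
#' parameters. In each of `n_sim` iterations all measured responses are
#' perturbed with multiplicative Gaussian noise ([perturb_responses()]),
#' each CQA model is refitted by OLS on its fixed (previously selected)
#' term set, and the refitted models are evaluated on the grid; a cell's
#' probability is the fraction of iterations in which all limits hold. The
#' design space is the cell set with probability at least `threshold`.
#'
#' With `rsd = 0` the refits equal the central fit and every probability is
#' 0 or 1 (the central-model indicator).
#'
#' @param data Fitting data (runs joined with material attributes and
#'   measured responses as fractions).
#' @param models Named list of `screening_model` objects, one per CQA,
#'   whose names match `limits`; their term sets are held fixed across
#'   refits.
#' @param limits Named numeric vector of lower CQA limits (fractions), e.g.
#'   [nts_cqa_limits()].
#' @param grid Data frame of CPP settings ([cpp_grid()]).
#' @param Z Named numeric vector (or one-row data frame) of the material's
#'   attribute values, mg/g.
#' @param n_sim Number of Monte Carlo iterations (default 1000).
#' @param rsd Relative SD of response noise (default 0.04).
#' @param seed Optional integer seed; if supplied the computation is
#'   reproducible (and recorded in the result).
#' @param threshold Acceptance probability defining the design space
#'   (default 0.90, compared as `>=`).
#' @return An object of class `probability_grid`: the grid with columns
#'   `prob` and `in_design_space`, plus attributes `threshold`, `n_sim`,
#'   `rsd`, `seed`, `fixed_Z`.
#' @examples
#' study <- nts_study()
#' m1 <- fit_fixed(study$data, "rd_purity", c("X1", "X9", "X10", "Z5", "Z6"))
#' m2 <- fit_fixed(study$data, "total_saponin_purity",
#'                 c("X1", "Z1", "Z2", "Z4"))
#' z <- unlist(study$batches[study$batches$batch_id == "PN7", -1])
#' ds <- monte_carlo_design_space(
#'   study$data, list(rd_purity = m1, total_saponin_purity = m2),
#'   nts_cqa_limits(), cpp_grid(X1 = c(85, 90), X9 = c(60, 65),
#'   X10 = c(150, 180)), z, n_sim = 200, seed = 1)
#' head(ds)
#' @export
monte_carlo_design_space <- function(data, models, limits, grid, Z,
                                     n_sim = 1000, rsd = 0.04, seed = NULL,
                                     threshold = 0.90) {
  stopifnot(n_sim >= 1, is.data.frame(grid), nrow(grid) >= 1)
  if (rsd < 0) stop("rsd must be non-negative", call. = FALSE)
  stopifnot(!is.null(names(models)), all(names(limits) %in% names(models)))
  if (!is.null(seed)) set.seed(seed)
  Z <- unlist(as.data.frame(as.list(Z)))

  # grid rows completed with the material's fixed attributes
  newdata <- grid
  for (v in names(Z)) newdata[[v]] <- Z[[v]]

  pass_all <- matrix(TRUE, nrow(grid), n_sim)
  for (cqa in names(limits)) {
    m <- models[[cqa]]
    y <- .var(data, m$response)
    mm <- cbind(`(Intercept)` = 1, .term_matrix(m$terms, data))
    .check_rank(mm)
    # fixed design matrix: refit is a linear map of the perturbed responses
    proj <- chol2inv(chol(crossprod(mm))) %*% t(mm)
    G <- cbind(1, .term_matrix(m$terms, newdata))
    Ysim <- if (rsd == 0) matrix(y, length(y), n_sim)
            else matrix(perturb_responses(rep(y, n_sim), rsd), length(y))
    B <- proj %*% Ysim                       # p x n_sim coefficient draws
    pass_all <- pass_all & (G %*% B >= limits[[cqa]])
  }
  grid$prob <- rowMeans(pass_all)
  grid$in_design_space <- grid$prob >= threshold
  structure(grid, class = c("probability_grid", "data.frame"),
            threshold = threshold, n_sim = n_sim, rsd = rsd,
            seed = if (is.null(seed)) NA_integer_ else seed, fixed_Z = Z)
}

#' Export a probability grid as a design-space listing
#'
#' Writes (or returns) one row per grid cell with the CPP settings, the
#' acceptance probability and the design-space flag, ordered
#' lexicographically by the axes. The flag is recomputed from the exported
#' probabilities and the grid's threshold.
#'
#' @param grid A `probability_grid`.
#' @param path Optional file path; if given, the listing is written as CSV
#'   (with a `#`-prefixed header line recording `n_sim`, `rsd`, `seed`,
#'   `threshold`) and returned invisibly.
#' @return The listing data frame.
#' @export
export_grid <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "probability_grid"))
  axes <- setdiff(names(grid), c("prob", "in_design_space"))
  out <- as.data.frame(grid)[do.call(order, as.data.frame(grid)[axes]), ]
  out$in_design_space <- out$prob >= attr(grid, "threshold")
  rownames(out) <- NULL
  if (!is.null(path)) {
    hdr <- sprintf("# ntsqbd design space: n_sim=%d rsd=%g seed=%s threshold=%g",
                   attr(grid, "n_sim"), attr(grid, "rsd"),
                   attr(grid, "seed"), attr(grid, "threshold"))
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(out, path, sep = ",", row.names = FALSE,
                                        qmethod = "double", append = TRUE))
    return(invisible(out))
  }
  out
}

#' @export
print.probability_grid <- function(x, ...) {
  cat(sprintf(
    "Probability-based design space: %d cells, %d in design space (>= %.2f)\n",
    nrow(x), sum(x$in_design_space), attr(x, "threshold")))
  cat(sprintf("  n_sim %d, rsd %g, seed %s\n",
              attr(x, "n_sim"), attr(x, "rsd"), attr(x, "seed")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat(sprintf("  ... %d more cells\n", nrow(x) - 6))
  invisible(x)
}
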