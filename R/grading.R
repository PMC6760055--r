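# Material grading: each process CQA's linear model and lower limit give a
# linear acceptance inequality over process parameters X and material
# attributes Z. With X free inside the investigated box a batch is
# acceptable iff the inequality system is feasible; with X fixed the
# inequalities collapse to conditions on Z alone.

#' Derive material-acceptance inequalities from fitted models
#'
#' Turns each process-CQA model into the linear inequality
#' `predict(model, X, Z) >= limit`. Coefficients are taken from the models
#' unchanged; only linear (main-effect) models are supported, since a
#' quadratic acceptance region is not a finite set of linear inequalities.
#'
#' @param models Named list of `screening_model` objects.
#' @param limits Named numeric vector of lower limits (fractions), names
#'   matching `models`.
#' @return An object of class `grading_inequalities`: a list with one
#'   element per CQA, each holding `cqa`, `x_coef`, `z_coef`, `intercept`
#'   and `bound`.
#' @examples
#' study <- nts_study()
#' derive_inequalities(study$published_models, nts_cqa_limits())
#' @export
derive_inequalities <- function(models, limits) {
  stopifnot(all(names(limits) %in% names(models)))
  ineqs <- lapply(names(limits), function(cqa) {
    m <- models[[cqa]]
    stopifnot(inherits(m, "screening_model"))
    if (any(.term_kind(m$terms) %in% c("square", "interaction")))
      stop(sprintf("model for '%s' has nonlinear terms; use the grid method",
                   cqa), call. = FALSE)
    cf <- m$coefficients
    list(cqa = cqa,
         x_coef = cf[grep("^X", names(cf), value = TRUE)],
         z_coef = cf[grep("^Z", names(cf), value = TRUE)],
         intercept = unname(cf["(Intercept)"]),
         bound = unname(limits[[cqa]]))
  })
  structure(stats::setNames(ineqs, names(limits)),
            class = "grading_inequalities")
}

#' @export
print.grading_inequalities <- function(x, ...) {
  for (iq in x) {
    lhs <- paste(c(sprintf("%+.4g %s", iq$x_coef, names(iq$x_coef)),
                   sprintf("%+.4g %s", iq$z_coef, names(iq$z_coef)),
                   sprintf("%+.4g", iq$intercept)), collapse = " ")
    cat(sprintf("  [%s] %s >= %.4g\n", iq$cqa, lhs, iq$bound))
  }
  invisible(x)
}

# Fourier-Motzkin elimination for a system A x >= b over box lo <= x <= hi.
# Few variables and inequalities only; exact feasibility with a witness.
.fm_feasible <- function(A, b, lo, hi) {
  nv <- ncol(A)
  # box as inequalities: x_j >= lo_j and -x_j >= -hi_j
  for (j in seq_len(nv)) {
    e <- numeric(nv); e[j] <- 1
    A <- rbind(A, e, -e); b <- c(b, lo[j], -hi[j])
  }
  systems <- vector("list", nv + 1)
  systems[[nv + 1]] <- list(A = A, b = b)
  for (j in rev(seq_len(nv))) {          # eliminate x_nv first, down to x_1
    A <- systems[[j + 1]]$A; b <- systems[[j + 1]]$b
    pos <- which(A[, j] > 1e-12); neg <- which(A[, j] < -1e-12)
    zer <- which(abs(A[, j]) <= 1e-12)
    newA <- A[zer, seq_len(j - 1), drop = FALSE]
    newb <- b[zer]
    for (p in pos) for (q in neg) {
      # combine a_p x >= b_p (coef>0) with a_q x >= b_q (coef<0)
      w <- -A[q, j] / A[p, j]
      newA <- rbind(newA, (w * A[p, ] + A[q, ])[seq_len(j - 1)])
      newb <- c(newb, w * b[p] + b[q])
    }
    systems[[j]] <- list(A = newA, b = newb)
  }
  final <- systems[[1]]
  if (length(final$b) && any(final$b > 1e-9)) return(list(feasible = FALSE))
  # back-substitute a witness: systems[[j + 1]] constrains x_1..x_j only;
  # given a prefix satisfying systems[[j]], its x_j interval is nonempty
  x <- numeric(nv)
  for (j in seq_len(nv)) {
    A <- systems[[j + 1]]$A; b <- systems[[j + 1]]$b
    fixed <- if (j > 1 && nrow(A))
      drop(A[, seq_len(j - 1), drop = FALSE] %*% x[seq_len(j - 1)])
    else numeric(nrow(A))
    lb <- -Inf; ub <- Inf
    for (r in seq_len(nrow(A))) {
      cj <- A[r, j]; rhs <- b[r] - fixed[r]
      if (cj > 1e-12) lb <- max(lb, rhs / cj)
      else if (cj < -1e-12) ub <- min(ub, rhs / cj)
    }
    if (lb > ub + 1e-9) return(list(feasible = FALSE))
    x[j] <- if (is.finite(lb) && is.finite(ub)) (lb + ub) / 2
            else if (is.finite(lb)) lb else if (is.finite(ub)) ub else 0
  }
  list(feasible = TRUE, witness = x)
}

#' Grade a batch with process parameters free within their ranges
#'
#' A batch is *acceptable* if some process-parameter setting inside the
#' investigated box satisfies every acceptance inequality simultaneously;
#' otherwise it is *unacceptable* and should not be released. Feasibility
#' of the small linear system is decided exactly (Fourier-Motzkin
#' elimination over the box), and a feasible witness setting is returned.
#' Reported slacks are each inequality's `LHS - bound` maximized
#' individually over the box (an upper bound on the jointly attainable
#' slack; all individual maxima nonnegative is necessary, joint feasibility
#' is what decides).
#'
#' @param ineqs A `grading_inequalities` object.
#' @param Z Named numeric vector of the batch's material attributes, mg/g.
#' @param box Named list (or two-row data frame) of `c(low, high)` ranges
#'   for every X appearing in the inequalities; defaults to the packaged
#'   factor ranges.
#' @param batch_id Optional label.
#' @return An object of class `grade_decision` with `verdict`
#'   (`"acceptable"`/`"unacceptable"`), per-inequality `slack` (at the
#'   witness when feasible), and `witness` X values when acceptable.
#' @examples
#' study <- nts_study()
#' iq <- derive_inequalities(study$published_models, nts_cqa_limits())
#' z <- unlist(study$grading_examples[2, c("Z1","Z2","Z4","Z5","Z6")])
#' feasibility_variable(iq, z, batch_id = "PN18")
#' @export
feasibility_variable <- function(ineqs, Z, box = NULL, batch_id = NA) {
  stopifnot(inherits(ineqs, "grading_inequalities"))
  Z <- unlist(as.data.frame(as.list(Z)))
  xvars <- sort(unique(unlist(lapply(ineqs, function(iq) names(iq$x_coef)))))
  xvars <- xvars[order(as.integer(sub("^X", "", xvars)))]
  if (is.null(box)) {
    f <- nts_study()$factors
    box <- stats::setNames(lapply(xvars, function(v)
      c(f$low[f$symbol == v], f$high[f$symbol == v])), xvars)
  }
  box <- lapply(box, as.numeric)
  if (!all(xvars %in% names(box)))
    stop("box must cover every process parameter in the inequalities",
         call. = FALSE)
  lo <- vapply(box[xvars], `[`, numeric(1), 1)
  hi <- vapply(box[xvars], `[`, numeric(1), 2)
  if (any(lo > hi)) stop("empty box", call. = FALSE)

  # constants: intercept + Z part - bound; inequality is x_coef . x >= -const
  A <- matrix(0, length(ineqs), length(xvars),
              dimnames = list(names(ineqs), xvars))
  for (k in seq_along(ineqs))
    A[k, names(ineqs[[k]]$x_coef)] <- ineqs[[k]]$x_coef
  const <- vapply(ineqs, function(iq) {
    miss <- setdiff(names(iq$z_coef), names(Z))
    if (length(miss))
      stop(sprintf("missing material attributes: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    iq$intercept + sum(iq$z_coef * Z[names(iq$z_coef)]) - iq$bound
  }, numeric(1))
  res <- .fm_feasible(A, -const, lo, hi)

  if (res$feasible) {
    witness <- stats::setNames(res$witness, xvars)
    slack <- drop(A %*% res$witness) + const
  } else {
    witness <- NULL
    # best attainable slack per inequality, individually over the box
    slack <- vapply(seq_along(ineqs), function(k)
      sum(pmax(A[k, ] * hi, A[k, ] * lo)) + const[k], numeric(1))
  }
  structure(list(batch_id = batch_id, mode = "variable-parameter",
                 verdict = if (res$feasible) "acceptable" else "unacceptable",
                 slack = stats::setNames(slack, names(ineqs)),
                 witness = witness),
            class = "grade_decision")
}

#' Simplify acceptance inequalities for a fixed process
#'
#' Folds fixed process-parameter values into each inequality's constant,
#' leaving conditions on the material attributes Z alone:
#' `sum(z_coef * Z) + constant >= 0`, with
#' `constant = intercept + sum(x_coef * X_fixed) - bound`. Constants are
#' always recomputed from the model coefficients. A reporting `scale`
#' multiplies both coefficients and constant (e.g. `1e5` to quote the Rd
#' purity inequality in customary units).
#'
#' @param ineqs A `grading_inequalities` object.
#' @param fixed Named numeric vector of fixed process-parameter values,
#'   e.g. [nts_fixed_process()].
#' @param scale Reporting multiplier applied to each inequality (scalar or
#'   one value per inequality).
#' @return Data frame of class `simplified_inequalities`: one row per CQA
#'   with the scaled Z coefficients (columns named by attribute) and
#'   `constant`.
#' @examples
#' study <- nts_study()
#' iq <- derive_inequalities(study$published_models, nts_cqa_limits())
#' simplify_fixed(iq, nts_fixed_process(), scale = c(1e5, 1e3))
#' @export
simplify_fixed <- function(ineqs, fixed, scale = 1) {
  stopifnot(inherits(ineqs, "grading_inequalities"))
  fixed <- unlist(as.data.frame(as.list(fixed)))
  scale <- rep_len(scale, length(ineqs))
  zvars <- sort(unique(unlist(lapply(ineqs, function(iq) names(iq$z_coef)))))
  zvars <- zvars[order(as.integer(sub("^Z", "", zvars)))]
  rows <- lapply(seq_along(ineqs), function(k) {
    iq <- ineqs[[k]]
    miss <- setdiff(names(iq$x_coef), names(fixed))
    if (length(miss))
      stop(sprintf("fixed process is missing %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    z <- stats::setNames(rep(NA_real_, length(zvars)), zvars)
    z[names(iq$z_coef)] <- iq$z_coef * scale[k]
    const <- (iq$intercept + sum(iq$x_coef * fixed[names(iq$x_coef)]) -
                iq$bound) * scale[k]
    data.frame(cqa = iq$cqa, t(z), constant = const, scale = scale[k])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("simplified_inequalities", "data.frame")
  out
}

#' Grade a batch under the fixed-parameter strategy
#'
#' A batch is *high* quality for the parameter-fixing process iff every
#' simplified inequality's left-hand side is nonnegative (boundary counts
#' as passing); otherwise *low* quality and not released. Slacks are
#' reported on the fraction scale (each inequality's scaled LHS divided by
#' its reporting scale).
#'
#' @param simplified A `simplified_inequalities` data frame from
#'   [simplify_fixed()].
#' @param batch Named numeric vector of the batch's attributes (or a
#'   one-row data frame including `batch_id`).
#' @param batch_id Optional label (taken from `batch` if present there).
#' @return A `grade_decision` with verdict `"high"` or `"low"`.
#' @export
classify_fixed <- function(simplified, batch, batch_id = NA) {
  stopifnot(inherits(simplified, "simplified_inequalities"))
  b <- as.data.frame(as.list(batch))
  if ("batch_id" %in% names(b) && is.na(batch_id)) batch_id <- b$batch_id
  zcols <- setdiff(names(simplified), c("cqa", "constant", "scale"))
  slack <- vapply(seq_len(nrow(simplified)), function(k) {
    cf <- unlist(simplified[k, zcols, drop = FALSE])
    used <- zcols[!is.na(cf)]
    miss <- setdiff(used, names(b))
    if (length(miss))
      stop(sprintf("batch is missing attributes: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    lhs <- sum(cf[used] * unlist(b[used])) + simplified$constant[k]
    lhs / simplified$scale[k]   # back to the fraction scale
  }, numeric(1))
  structure(list(batch_id = batch_id, mode = "fixed-parameter",
                 verdict = if (all(slack >= 0)) "high" else "low",
                 slack = stats::setNames(slack, simplified$cqa),
                 witness = NULL),
            class = "grade_decision")
}

#' @export
print.grade_decision <- function(x, ...) {
  cat(sprintf("Batch %s (%s mode): %s\n", x$batch_id, x$mode, x$verdict))
  cat("  slack (fraction scale):",
      paste(sprintf("%s %+0.4g", names(x$slack), x$slack), collapse = "; "),
      "\n")
  if (!is.null(x$witness))
    cat("  witness:",
        paste(sprintf("%s=%g", names(x$witness), x$witness), collapse = ", "),
        "\n")
  invisible(x)
}

#' Blend material batches
#'
#' Attributes of a mass-weighted mixture of lots: the weighted mean of the
#' component attribute vectors. Used to rework low-quality lots by mixing
#' with better ones before grading the blend.
#'
#' @param batches Data frame with `batch_id` and attribute columns.
#' @param masses Numeric vector of component masses (same order).
#' @param batch_id Label for the blend.
#' @return One-row data frame with the blended attributes.
#' @export
blend_batches <- function(batches, masses, batch_id = "blend") {
  stopifnot(nrow(batches) == length(masses), all(masses >= 0),
            sum(masses) > 0)
  num <- vapply(batches, is.numeric, logical(1))
  z <- colSums(batches[, num, drop = FALSE] * masses) / sum(masses)
  out <- data.frame(batch_id = batch_id, t(z))
  names(out) <- c("batch_id", names(batches)[num])
  out
}
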