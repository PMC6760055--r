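# Term labels are canonical strings: main effects "X1".."X10", "Z1".."Z6";
# squares "X9^2"; pairwise interactions "X1:X9" (lower index first). Model
# matrices are built from these labels directly, so squares may be retained
# without their parent main effect (as stepwise sometimes decides).

.term_kind <- function(label) {
  ifelse(grepl("\\^2$", label), "square",
         ifelse(grepl(":", label), "interaction",
                ifelse(grepl("^X", label), "main-X", "main-Z")))
}

# numeric matrix with one column per term label
.term_matrix <- function(terms, data) {
  cols <- lapply(terms, function(tm) {
    if (grepl("\\^2$", tm)) {
      v <- sub("\\^2$", "", tm)
      .var(data, v)^2
    } else if (grepl(":", tm)) {
      v <- strsplit(tm, ":", fixed = TRUE)[[1]]
      .var(data, v[1]) * .var(data, v[2])
    } else .var(data, tm)
  })
  m <- do.call(cbind, c(cols, list(deparse.level = 0)))
  colnames(m) <- terms
  m
}

.var <- function(data, v) {
  if (!v %in% names(data))
    stop(sprintf("variable '%s' not found in data", v), call. = FALSE)
  as.numeric(data[[v]])
}

# error naming aliased columns if the design matrix is rank deficient
.check_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop(sprintf("design matrix is rank deficient; collinear terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(q)
}

# OLS of data[[response]] on intercept + terms, with the ANOVA quantities
# the screening report needs
.ols <- function(data, response, terms) {
  y <- .var(data, response)
  mm <- cbind(`(Intercept)` = 1, .term_matrix(terms, data))
  .check_rank(mm)
  fit <- stats::lm.fit(mm, y)
  n <- length(y); p <- length(terms)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p - 1)
  f <- if (p > 0) ((tss - rss) / p) / sigma2 else NA_real_
  list(
    coefficients = fit$coefficients,
    se = se, t = tval, p = pval,
    r.squared = 1 - rss / tss,
    adj.r.squared = 1 - (rss / (n - p - 1)) / (tss / (n - 1)),
    sigma = sqrt(sigma2),
    fstatistic = f,
    model.p = if (p > 0) stats::pf(f, p, n - p - 1, lower.tail = FALSE) else NA_real_,
    rss = rss, df.residual = n - p - 1, n = n,
    residuals = fit$residuals, fitted = fit$fitted.values)
}

.new_screening_model <- function(response, terms, coefficients, stats = NULL) {
  structure(list(response = response, terms = terms,
                 coefficients = coefficients, stats = stats),
            class = "screening_model")
}

#' Construct a screening model from explicit coefficients
#'
#' Builds a `screening_model` from a named coefficient vector (for example,
#' coefficients reported by an external fit), so it can be used with
#' [predict.screening_model()], [derive_inequalities()] and the design-space
#' functions without refitting.
#'
#' @param response Name of the process CQA (e.g. `"rd_purity"`), on the
#'   fraction scale.
#' @param coefficients Named numeric vector; must include `"(Intercept)"`,
#'   other names are term labels (`"X1"`, `"Z5"`, `"X9^2"`, `"X1:X9"`).
#' @return A `screening_model` (without fit statistics).
#' @export
screening_model <- function(response, coefficients) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            "(Intercept)" %in% names(coefficients))
  terms <- setdiff(names(coefficients), "(Intercept)")
  .new_screening_model(response, terms,
                       coefficients[c("(Intercept)", terms)])
}

#' Fit a process-CQA model on a fixed term set
#'
#' Ordinary least squares of one process CQA on an explicit list of terms
#' (plus intercept), with the usual ANOVA summary. Fitting is on uncoded
#' process parameters `X1..X10`, raw material attributes `Z1..Z6` (mg/g),
#' and the response as a fraction.
#'
#' @param data Data frame of runs joined with material attributes; must
#'   contain the response column and every variable used by `terms`.
#' @param response Response column name.
#' @param terms Character vector of term labels.
#' @return A `screening_model` with a `stats` element (R-squared, adjusted
#'   R-squared, model p-value, per-coefficient SE/t/p, residual SD).
#' @examples
#' study <- nts_study()
#' m <- fit_fixed(study$data, "rd_purity", c("X1", "X9", "X10", "Z5", "Z6"))
#' m$stats$r.squared
#' @export
fit_fixed <- function(data, response, terms) {
  stopifnot(length(terms) >= 1)
  if (nrow(data) < length(terms) + 2)
    stop("need at least 2 more observations than terms", call. = FALSE)
  fit <- .ols(data, response, terms)
  .new_screening_model(response, terms, fit$coefficients,
                       stats = fit[c("r.squared", "adj.r.squared", "sigma",
                                     "fstatistic", "model.p", "se", "t", "p",
                                     "rss", "df.residual", "n")])
}

#' Bidirectional stepwise model selection at fixed significance levels
#'
#' Selects terms for one process CQA by p-value based bidirectional
#' stepwise regression: alternately remove the included term with the
#' largest partial p-value above `alpha_remove`, and add the excluded
#' candidate with the smallest partial p-value below `alpha_enter`, until
#' the model is stable. By default selection starts from the full candidate
#' model, so insignificant variables are removed from it (with re-entry
#' allowed); `start = "empty"` gives the forward-first variant. Ties in
#' p-value are broken by candidate order, so selection is deterministic.
#' Revisiting a previously seen term set terminates the loop (no add/drop
#' cycling).
#'
#' @inheritParams fit_fixed
#' @param candidates Character vector of candidate term labels.
#' @param alpha_enter Significance level to add a term (default 0.05).
#' @param alpha_remove Significance level to remove a term (default 0.05).
#' @param start `"full"` (default) to start from all candidates, `"empty"`
#'   to start from the intercept-only model, or a character vector of term
#'   labels to warm-start from.
#' @return A `screening_model` fitted by OLS on the final term set (empty
#'   term sets give an intercept-only model with `stats = NULL` apart from
#'   basic fields).
#' @examples
#' study <- nts_study()
#' m <- stepwise_fit(study$data, "rd_purity",
#'                   c(paste0("X", 1:10), paste0("Z", 1:6)))
#' m$terms
#' @export
stepwise_fit <- function(data, response, candidates,
                         alpha_enter = 0.05, alpha_remove = 0.05,
                         start = "full") {
  stopifnot(length(candidates) >= 1, alpha_enter > 0, alpha_remove > 0)
  if (nrow(data) < length(candidates) + 2)
    stop("need at least 2 more observations than candidate terms", call. = FALSE)
  const <- vapply(candidates,
                  function(tm) stats::var(.term_matrix(tm, data)) < 1e-30,
                  logical(1))
  if (any(const))
    stop(sprintf("constant-valued candidate terms: %s",
                 paste(candidates[const], collapse = ", ")), call. = FALSE)

  terms <- if (identical(start, "full")) candidates
           else if (identical(start, "empty")) character(0)
           else { stopifnot(all(start %in% candidates)); start }
  seen <- character(0)
  repeat {
    changed <- FALSE
    # backward purge: one removal at a time, worst p first
    while (length(terms)) {
      p <- .ols(data, response, terms)$p[terms]
      if (max(p) <= alpha_remove) break
      terms <- setdiff(terms, terms[which.max(p)])
      changed <- TRUE
    }
    # forward step: best remaining candidate, smallest partial p
    rem <- setdiff(candidates, terms)
    if (length(rem)) {
      p_add <- vapply(rem, function(tm) {
        fit <- tryCatch(.ols(data, response, c(terms, tm)),
                        error = function(e) NULL)  # aliased candidate: skip
        if (is.null(fit)) NA_real_ else unname(fit$p[tm])
      }, numeric(1))
      ok <- !is.na(p_add) & p_add < alpha_enter
      if (any(ok)) {
        terms <- c(terms, rem[ok][which.min(p_add[ok])])
        changed <- TRUE
      }
    }
    state <- paste(sort(terms), collapse = "+")
    if (!changed || state %in% seen) break
    seen <- c(seen, state)
  }
  if (!length(terms)) {
    y <- .var(data, response)
    return(.new_screening_model(response, character(0),
                                c(`(Intercept)` = mean(y))))
  }
  fit_fixed(data, response, terms[order(match(terms, candidates))])
}

#' Augment a screening model with curvature and interaction terms
#'
#' Extends a selected main-effects model with the squares and pairwise
#' interactions of its retained critical process parameters (X terms), then
#' re-runs bidirectional stepwise selection warm-started from the retained
#' terms. Squares and interactions are formed over X terms only; material
#' attributes enter linearly.
#'
#' @param model A `screening_model` with at least one retained X main
#'   effect.
#' @param data The fitting data.
#' @inheritParams stepwise_fit
#' @return The re-selected `screening_model`.
#' @export
augment_and_refit <- function(model, data,
                              alpha_enter = 0.05, alpha_remove = 0.05) {
  stopifnot(inherits(model, "screening_model"))
  xmain <- model$terms[.term_kind(model$terms) == "main-X"]
  if (!length(xmain))
    stop("model has no retained process-parameter main effect", call. = FALSE)
  squares <- paste0(xmain, "^2")
  inter <- if (length(xmain) > 1) {
    cmb <- utils::combn(xmain, 2)
    paste(cmb[1, ], cmb[2, ], sep = ":")
  } else character(0)
  cands <- c(model$terms, squares, inter)
  stepwise_fit(data, model$response, cands,
               alpha_enter = alpha_enter, alpha_remove = alpha_remove,
               start = model$terms)
}

#' Predict a process CQA
#'
#' Evaluates a screening model at given process-parameter and
#' material-attribute values, on the model's own scale (fractions for
#' purity responses; uncoded X, Z in mg/g).
#'
#' @param object A `screening_model`.
#' @param newdata Data frame (or coercible named list) supplying every
#'   variable used by the model's terms.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @examples
#' study <- nts_study()
#' m <- study$published_models$rd_purity
#' predict(m, data.frame(X1 = 90, X9 = 60, X10 = 120, Z5 = 6.43, Z6 = 227))
#' @export
predict.screening_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!length(object$terms))
    return(rep(unname(object$coefficients["(Intercept)"]), nrow(newdata)))
  mm <- cbind(1, .term_matrix(object$terms, newdata))
  drop(mm %*% object$coefficients[c("(Intercept)", object$terms)])
}

#' @export
coef.screening_model <- function(object, ...) object$coefficients

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf("Screening model for '%s'\n", x$response))
  if (!length(x$terms)) {
    cat("  intercept-only model\n")
  } else {
    tab <- data.frame(coefficient = signif(x$coefficients, 4))
    if (!is.null(x$stats))
      tab$p.value <- signif(x$stats$p[rownames(tab)], 3)
    print(tab)
    if (!is.null(x$stats))
      cat(sprintf("  R2 %.4f (adj %.4f), model p %.3g, residual SD %.4g\n",
                  x$stats$r.squared, x$stats$adj.r.squared,
                  x$stats$model.p, x$stats$sigma))
  }
  invisible(x)
}

#' Identify critical process parameters and material attributes
#'
#' The CPPs are the union over all fitted process-CQA models of retained X
#' main effects (a square or interaction also marks its parents as
#' critical); the CMAs are the union of retained Z main effects.
#'
#' @param models List of `screening_model` objects.
#' @return List with character vectors `cpps` and `cmas`, sorted by index.
#' @export
identify_critical <- function(models) {
  stopifnot(length(models) >= 0)
  pull <- function(m) {
    parts <- unlist(strsplit(sub("\\^2$", "", m$terms), ":", fixed = TRUE))
    unique(parts)
  }
  vars <- unique(unlist(lapply(models, pull)))
  srt <- function(v) v[order(as.integer(sub("^[XZ]", "", v)))]
  list(cpps = srt(grep("^X", vars, value = TRUE)),
       cmas = srt(grep("^Z", vars, value = TRUE)))
}
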