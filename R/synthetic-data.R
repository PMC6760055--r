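# Synthetic data with the statistical structure the screening analysis
# assumes: material batches uniform within the observed attribute ranges,
# responses linear in uncoded X and raw Z with multiplicative Gaussian
# noise at a fixed relative SD.

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the packaged study: attribute ranges spanning the 16
#' characterized batches, the two published coefficient sets as the true
#' models, and 4% relative measurement noise.
#'
#' @param n_batches Number of material batches to generate.
#' @param z_ranges 2 x 6 matrix (rows `low`, `high`; columns `Z1..Z6`) of
#'   attribute ranges, mg/g.
#' @param coefficients Named list of true coefficient vectors per response
#'   (each named, including `"(Intercept)"`); defaults to the packaged
#'   published models.
#' @param rsd Relative SD of the multiplicative response noise.
#' @param correlated If `TRUE`, draw attributes from a single-latent-factor
#'   model (one common "richness" factor plus independent noise) instead of
#'   independently; the observed batches show strong inter-saponin
#'   correlation, which the independent default ignores.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_batches = 16,
                           z_ranges = default_z_ranges(),
                           coefficients = NULL,
                           rsd = 0.04,
                           correlated = FALSE) {
  stopifnot(n_batches >= 1, rsd >= 0,
            is.matrix(z_ranges), nrow(z_ranges) == 2)
  if (any(z_ranges <= 0) || any(z_ranges[1, ] >= z_ranges[2, ]))
    stop("z_ranges must be positive with low < high", call. = FALSE)
  if (is.null(coefficients)) {
    pm <- nts_study()$published_models
    coefficients <- lapply(pm, `[[`, "coefficients")
  }
  structure(list(n_batches = n_batches, z_ranges = z_ranges,
                 coefficients = coefficients, rsd = rsd,
                 correlated = correlated),
            class = "generator_spec")
}

#' Default material-attribute ranges
#'
#' Observed spans of the 16 characterized batches (mg/g): Z1 7.2-16,
#' Z2 32-59, Z3 3.2-8.4, Z4 29-53, Z5 5.0-14.2, Z6 185-387.
#'
#' @return 2 x 6 matrix with rows `low`, `high`.
#' @export
default_z_ranges <- function() {
  m <- rbind(low  = c(7.2, 32, 3.2, 29, 5.0, 185),
             high = c(16, 59, 8.4, 53, 14.2, 387))
  colnames(m) <- paste0("Z", 1:6)
  m
}

#' Generate synthetic material batches
#'
#' Attributes are drawn uniformly within the spec's ranges (or from the
#' single-latent-factor model if `correlated`), rejection-sampled so the
#' five saponin contents sum to no more than the extractable dry matter.
#' Deterministic given the RNG state; pass `seed` for reproducibility.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional integer seed.
#' @return Data frame `batch_id`, `Z1..Z6`.
#' @export
generate_batches <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) set.seed(seed)
  lo <- spec$z_ranges[1, ]; hi <- spec$z_ranges[2, ]
  draw <- function(n) {
    if (spec$correlated) {
      f <- stats::runif(n)                       # common richness factor
      e <- matrix(stats::runif(n * 6), n, 6)     # independent part
      u <- 0.7 * f + 0.3 * e                     # still in [0, 1]
    } else {
      u <- matrix(stats::runif(n * 6), n, 6)
    }
    sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  }
  out <- matrix(NA_real_, 0, 6)
  tries <- 0
  while (nrow(out) < spec$n_batches) {
    z <- draw(spec$n_batches)
    ok <- rowSums(z[, 1:5, drop = FALSE]) <= z[, 6]
    out <- rbind(out, z[ok, , drop = FALSE])
    tries <- tries + spec$n_batches
    if (tries > 100 * spec$n_batches && nrow(out) == 0)
      stop("attribute ranges are infeasible (rejection rate > 99%)",
           call. = FALSE)
  }
  out <- out[seq_len(spec$n_batches), , drop = FALSE]
  df <- data.frame(batch_id = paste0("SYN", seq_len(spec$n_batches)), out)
  names(df) <- c("batch_id", paste0("Z", 1:6))
  df
}

#' Synthesize an extraction record that reproduces given attributes
#'
#' Inverse of the material-characterization formulas: concentrations are
#' chosen so that [extractable_dry_matter()] and
#' [extractable_saponin_content()] recover the batch's `Z1..Z6` exactly for
#' the given masses.
#'
#' @param batch One-row data frame (or named vector/list) with `Z1..Z6`,
#'   mg/g.
#' @param material_mass Material mass, g (default 100).
#' @param extract_mass Combined extract mass, g (default 500).
#' @return An [extraction_record()].
#' @export
generate_extraction_record <- function(batch, material_mass = 100,
                                       extract_mass = 500) {
  stopifnot(material_mass > 0, extract_mass > 0)
  b <- as.data.frame(as.list(batch))
  z <- unlist(b[paste0("Z", 1:6)])
  dm <- z[["Z6"]] * material_mass / (1000 * extract_mass)   # g/g
  if (dm > 1)
    stop("implied dry-matter concentration exceeds 1 g/g; increase extract_mass",
         call. = FALSE)
  sc <- z[1:5] * material_mass / extract_mass               # mg/g
  extraction_record(material_mass, extract_mass, dm, unname(sc))
}

#' Generate response values for a design from a true linear model
#'
#' For each run, the linear predictor `a0 + sum(b_i X_i) + sum(c_k Z_k)`
#' (evaluated on uncoded X and raw Z) is observed with multiplicative
#' Gaussian noise: `y = mu * (1 + e)`, `e ~ Normal(0, rsd)`, redrawn while
#' `y <= 0`.
#'
#' @param design Data frame with `batch_id` and uncoded `X` columns.
#' @param batches Data frame with `batch_id` and `Z` columns.
#' @param coefficients Named list of true coefficient vectors per response.
#' @param rsd Relative SD of the noise.
#' @param seed Optional integer seed.
#' @return Data frame with `run_id` (if present in `design`) and one column
#'   per response.
#' @export
generate_responses <- function(design, batches, coefficients, rsd = 0.04,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rsd >= 0, all(design$batch_id %in% batches$batch_id))
  dat <- cbind(design,
               batches[match(design$batch_id, batches$batch_id),
                       setdiff(names(batches), "batch_id"), drop = FALSE])
  out <- data.frame(row.names = seq_len(nrow(design)))
  if ("run_id" %in% names(design)) out$run_id <- design$run_id
  for (resp in names(coefficients)) {
    cf <- coefficients[[resp]]
    m <- screening_model(resp, cf)
    vars <- unique(unlist(strsplit(sub("\\^2$", "", m$terms), ":",
                                   fixed = TRUE)))
    miss <- setdiff(vars, names(dat))
    if (length(miss))
      stop(sprintf("design/batches lack variables: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    mu <- predict(m, dat)
    if (any(mu <= 0))
      stop("true model gives non-positive mean response", call. = FALSE)
    y <- mu * (1 + stats::rnorm(length(mu), 0, rsd))
    while (any(bad <- y <= 0))
      y[bad] <- mu[bad] * (1 + stats::rnorm(sum(bad), 0, rsd))
    out[[resp]] <- y
  }
  out
}

#' Generate a complete synthetic screening dataset
#'
#' Draws material batches, assigns them to the packaged 32-run design
#' layout (round-robin over the generated batches, preserving the design's
#' run structure), and generates responses from the spec's true models.
#'
#' @param spec A [generator_spec()].
#' @param design Optional design data.frame; defaults to the packaged
#'   32-run design (with its batch column replaced by generated batches).
#' @param seed Optional integer seed covering batch and response draws.
#' @return List of class `synthetic_dataset`: `batches`, `design`,
#'   `responses`, `data` (joined analysis table), `truth` (the generating
#'   coefficients), `rsd`, `seed`.
#' @export
generate_dataset <- function(spec, design = NULL, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design)) design <- nts_study()$design
  batches <- generate_batches(spec)
  design$batch_id <- batches$batch_id[
    (match(design$batch_id, unique(design$batch_id)) - 1) %%
      nrow(batches) + 1]
  responses <- generate_responses(design, batches, spec$coefficients,
                                  rsd = spec$rsd)
  data <- merge(design, batches, by = "batch_id")
  data <- merge(data, responses, by = "run_id")
  data <- data[order(data$run_id), ]
  rownames(data) <- NULL
  structure(list(batches = batches, design = design, responses = responses,
                 data = data, truth = spec$coefficients, rsd = spec$rsd,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "synthetic_dataset")
}
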