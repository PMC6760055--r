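#' The packaged NTS screening study dataset
#'
#' Loads the bundled definitive-screening study of notoginseng total
#' saponin (NTS) manufacturing: the 10 process-factor specifications, the
#' 32-run design with its material batch assignment, the 16 characterized
#' material batches (extractable contents Z1..Z6, mg/g), the 32 runs'
#' eluate quality attributes, the two published process-CQA regression
#' models, the 4 worked grading-example batches, and the two verification
#' prediction points. Basic integrity (row counts, referential integrity of
#' batch ids, purity sums) is checked at load time.
#'
#' File columns store purities in percent to stay comparable with printed
#' reports; the joined analysis table converts them to fractions.
#'
#' @return A list of class `nts_study`:
#'   \describe{
#'     \item{factors}{factor specs: `symbol`, `process`, `name`, `units`,
#'       `low`, `mid`, `high`.}
#'     \item{design}{`run_id`, `batch_id`, uncoded `X1..X10`.}
#'     \item{batches}{`batch_id`, `Z1..Z6` (mg/g).}
#'     \item{quality}{`run_id`, `SP1_pct..SP5_pct`, `TSP_pct`, `DMY_mgg`,
#'       `TSY_mgg`.}
#'     \item{data}{design joined with batches and quality; responses
#'       `rd_purity` and `total_saponin_purity` as fractions.}
#'     \item{published_models}{list of two [screening_model()] objects
#'       built from the published coefficients.}
#'     \item{grading_examples}{`batch_id`, `Z1,Z2,Z4,Z5,Z6`,
#'       `reported_grade`.}
#'     \item{verification_points}{batch, process setting and published
#'       predicted purities (percent).}
#'   }
#' @examples
#' study <- nts_study()
#' nrow(study$design)
#' @export
nts_study <- function() {
  path <- function(f) system.file("extdata", f, package = "ntsqbd",
                                  mustWork = TRUE)
  rd <- function(f) utils::read.csv(path(f), stringsAsFactors = FALSE)
  factors <- rd("process_factors.csv")
  design  <- rd("dsd_design.csv")
  batches <- rd("material_batches.csv")
  quality <- rd("eluate_quality.csv")
  coefs   <- rd("screening_coefficients.csv")
  grading <- rd("grading_examples.csv")
  verif   <- rd("verification_predictions.csv")

  if (nrow(factors) != 10 || nrow(design) != 32 || nrow(batches) != 16 ||
      nrow(quality) != 32)
    stop("bundled study tables are corrupted (unexpected row counts)",
         call. = FALSE)
  if (!all(design$batch_id %in% batches$batch_id))
    stop("design references unknown material batches", call. = FALSE)
  sp_sum <- rowSums(quality[paste0("SP", 1:5, "_pct")])
  if (any(abs(sp_sum - quality$TSP_pct) > 0.05))
    stop("eluate quality table inconsistent: purities do not sum to TSP",
         call. = FALSE)

  data <- merge(design, batches, by = "batch_id")
  data <- merge(data, quality, by = "run_id")
  data <- data[order(data$run_id), ]
  rownames(data) <- NULL
  data$rd_purity <- data$SP5_pct / 100
  data$total_saponin_purity <- data$TSP_pct / 100

  models <- lapply(split(coefs, coefs$response), function(cc) {
    screening_model(cc$response[1],
                    stats::setNames(cc$coefficient, cc$term))
  })

  structure(list(factors = factors, design = design, batches = batches,
                 quality = quality, data = data,
                 published_models = models[c("rd_purity",
                                             "total_saponin_purity")],
                 grading_examples = grading,
                 verification_points = verif),
            class = "nts_study")
}

#' @export
print.nts_study <- function(x, ...) {
  cat("NTS definitive-screening study data:\n")
  cat(sprintf("  %d factors, %d runs, %d material batches\n",
              nrow(x$factors), nrow(x$design), nrow(x$batches)))
  cat(sprintf("  responses: rd_purity, total_saponin_purity (fractions)\n"))
  invisible(x)
}

#' Default CQA lower limits for NTS eluates
#'
#' The release limits for the two process CQAs, as fractions: ginsenoside
#' Rd purity >= 3.5% and total saponin purity >= 85%.
#'
#' @return Named numeric vector of lower bounds (fractions).
#' @export
nts_cqa_limits <- function() {
  c(rd_purity = 0.035, total_saponin_purity = 0.85)
}

#' Fixed manufacturing parameter set for the parameter-fixing strategy
#'
#' The example fixed process (per 100 g material basis): extraction ethanol
#' 88% v/v for 6 h with 672 mL solution, concentrate volume 131 mL, water
#' addition 373 mL, sampling flow 1.7 BV/h, washing flow 1.8 BV/h, wash
#' volume 2.0 BV, elution ethanol 56% v/v for 133 min.
#'
#' @return Named numeric vector `X1..X10` (uncoded).
#' @export
nts_fixed_process <- function() {
  c(X1 = 88, X2 = 6, X3 = 672, X4 = 131, X5 = 373,
    X6 = 1.7, X7 = 1.8, X8 = 2.0, X9 = 56, X10 = 133)
}
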