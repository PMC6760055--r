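#' Run the full QbD analysis pipeline
#'
#' Executes the whole analysis on a study dataset: screen both process
#' CQAs by stepwise regression, attempt the curvature/interaction
#' augmentation, identify CPPs and CMAs, compute the Monte Carlo design
#' space for each requested material, derive the acceptance inequalities
#' and grade the supplied batches in both variable- and fixed-parameter
#' modes. All result tables are written under `output_dir` along with a
#' plain-text summary; every file carries a `#` header line recording the
#' seed and package version.
#'
#' @param output_dir Directory for result files (created if needed).
#' @param study A study list as returned by [nts_study()] (the default).
#' @param responses Character vector of response column names in
#'   `study$data`.
#' @param limits Named lower CQA limits (fractions).
#' @param grade_batches Data frame of batches to grade (default: the
#'   study's worked grading examples).
#' @param design_space_for Character vector of `batch_id`s (from
#'   `grade_batches` or `study$batches`) whose design space to compute;
#'   default none.
#' @param grid CPP grid for the design space ([cpp_grid()]).
#' @param n_sim,rsd Monte Carlo settings.
#' @param fixed Fixed process for the fixed-parameter grading mode.
#' @param seed Integer seed for the Monte Carlo stage.
#' @return Invisibly, a list with the fitted `models`, `critical` set,
#'   `grades` (data frame) and `design_spaces` (named list).
#' @export
run_qbd_pipeline <- function(output_dir,
                             study = nts_study(),
                             responses = c("rd_purity",
                                           "total_saponin_purity"),
                             limits = nts_cqa_limits(),
                             grade_batches = study$grading_examples,
                             design_space_for = character(0),
                             grid = cpp_grid(),
                             n_sim = 1000, rsd = 0.04,
                             fixed = nts_fixed_process(),
                             seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# ntsqbd %s, seed %d",
                 as.character(utils::packageVersion("ntsqbd")), seed)
  put <- function(df, file) {
    p <- file.path(output_dir, file)
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(df, p, sep = ",", row.names = FALSE,
                                        append = TRUE, qmethod = "double"))
  }

  candidates <- c(paste0("X", 1:10), paste0("Z", 1:6))
  models <- lapply(responses, function(r) {
    m <- stepwise_fit(study$data, r, candidates)
    if (any(.term_kind(m$terms) == "main-X")) m <- augment_and_refit(m, study$data)
    m
  })
  names(models) <- responses
  crit <- identify_critical(models)

  coef_tab <- do.call(rbind, lapply(models, function(m)
    data.frame(response = m$response, term = names(m$coefficients),
               coefficient = unname(m$coefficients),
               p_value = c(NA, unname(m$stats$p[m$terms])))))
  put(coef_tab, "screening_models.csv")
  jsonlite::write_json(
    list(models = lapply(models, function(m)
      list(response = m$response, terms = m$terms,
           coefficients = as.list(m$coefficients),
           r.squared = m$stats$r.squared,
           adj.r.squared = m$stats$adj.r.squared,
           scale = "uncoded X, Z mg/g, response fraction")),
      cpps = crit$cpps, cmas = crit$cmas),
    file.path(output_dir, "models.json"), auto_unbox = TRUE, digits = NA)

  ineqs <- derive_inequalities(models, limits)
  simp <- simplify_fixed(ineqs, fixed)
  grades <- do.call(rbind, lapply(seq_len(nrow(grade_batches)), function(i) {
    b <- grade_batches[i, ]
    v <- feasibility_variable(ineqs, b[setdiff(names(b),
                                               c("batch_id", "reported_grade"))],
                              batch_id = b$batch_id)
    f <- classify_fixed(simp, b)
    data.frame(batch_id = b$batch_id,
               variable_mode = v$verdict, fixed_mode = f$verdict,
               min_slack_fixed = min(f$slack))
  }))
  put(grades, "grades.csv")

  all_bat <- rbind(study$batches[intersect(names(study$batches),
                                           names(grade_batches))],
                   grade_batches[intersect(names(study$batches),
                                           names(grade_batches))])
  spaces <- list()
  for (bid in design_space_for) {
    z <- all_bat[all_bat$batch_id == bid, ][1, ]
    ds <- monte_carlo_design_space(study$data, models, limits, grid,
                                   z[setdiff(names(z), "batch_id")],
                                   n_sim = n_sim, rsd = rsd, seed = seed)
    export_grid(ds, file.path(output_dir,
                              sprintf("design_space_%s.csv", bid)))
    spaces[[bid]] <- ds
  }

  summary_lines <- c(
    hdr,
    sprintf("CPPs: %s", paste(crit$cpps, collapse = ", ")),
    sprintf("CMAs: %s", paste(crit$cmas, collapse = ", ")),
    vapply(models, function(m)
      sprintf("%s: terms {%s}, R2 %.4f", m$response,
              paste(m$terms, collapse = ", "), m$stats$r.squared),
      character(1)),
    vapply(seq_len(nrow(grades)), function(i)
      sprintf("batch %s: %s (variable), %s (fixed)", grades$batch_id[i],
              grades$variable_mode[i], grades$fixed_mode[i]), character(1)))
  writeLines(summary_lines, file.path(output_dir, "summary.txt"))

  invisible(list(models = models, critical = crit, grades = grades,
                 design_spaces = spaces, inequalities = ineqs,
                 simplified = simp))
}
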