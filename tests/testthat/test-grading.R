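pub <- study$published_models
limits <- nts_cqa_limits()
iq_pub <- derive_inequalities(pub, limits)
fixed_x <- nts_fixed_process()

test_that("inequalities carry the model coefficients and limits unchanged", {
  iq1 <- iq_pub$rd_purity
  expect_identical(iq1$x_coef,
                   pub$rd_purity$coefficients[c("X1", "X9", "X10")])
  expect_identical(iq1$z_coef, pub$rd_purity$coefficients[c("Z5", "Z6")])
  expect_equal(iq1$intercept, -0.12)
  expect_equal(iq1$bound, 0.035)
  expect_equal(names(iq_pub$total_saponin_purity$z_coef),
               c("Z1", "Z2", "Z4"))
  expect_error(
    derive_inequalities(
      list(y = screening_model("y", c("(Intercept)" = 0, "X9^2" = 1))),
      c(y = 0.1)),
    "nonlinear")
})

test_that("a coefficient-free model reduces to an intercept condition", {
  m <- screening_model("y", c("(Intercept)" = 0.5))
  iq <- derive_inequalities(list(y = m), c(y = 0.4))
  d <- classify_fixed(simplify_fixed(iq, fixed_x), c(Z1 = 1))
  expect_equal(d$verdict, "high")
  expect_equal(unname(d$slack), 0.1)
})

test_that("the fixed-process simplification reproduces the reported coefficients", {
  simp <- simplify_fixed(iq_pub, fixed_x, scale = c(1e5, 1e3))
  rd <- simp[simp$cqa == "rd_purity", ]
  expect_equal(rd$Z5, 397.1)
  expect_equal(rd$Z6, -8.607)
  tsp <- simp[simp$cqa == "total_saponin_purity", ]
  expect_equal(tsp$Z1, 10.3)
  expect_equal(tsp$Z2, 5.291)
  expect_equal(tsp$Z4, -11.1)
  # constants are derived from the coefficients, not transcribed
  expect_equal(rd$constant,
               1e5 * (-0.12 + 3.382e-4 * 88 + 1.824e-3 * 56 +
                        1.869e-4 * 133 - 0.035))
  expect_equal(tsp$constant, 1e3 * (0.76 + 2.203e-3 * 88 - 0.85))
  # all-zero fixed process: constant collapses to intercept minus bound
  zero_x <- stats::setNames(rep(0, 10), paste0("X", 1:10))
  s0 <- simplify_fixed(iq_pub, zero_x)
  expect_equal(s0$constant, c(-0.12 - 0.035, 0.76 - 0.85))
})

test_that("the four example batches grade as reported in both modes", {
  simp <- simplify_fixed(iq_pub, fixed_x)
  for (i in seq_len(nrow(study$grading_examples))) {
    b <- study$grading_examples[i, ]
    fixed_verdict <- classify_fixed(simp, b)$verdict
    var_verdict <- feasibility_variable(iq_pub, example_z(b$batch_id),
                                        batch_id = b$batch_id)$verdict
    expect_equal(fixed_verdict, b$reported_grade)
    expect_equal(var_verdict,
                 if (b$reported_grade == "high") "acceptable"
                 else "unacceptable")
  }
})

test_that("fixed-mode slack equals model prediction minus the limit", {
  simp <- simplify_fixed(iq_pub, fixed_x)
  for (i in seq_len(nrow(study$grading_examples))) {
    b <- study$grading_examples[i, ]
    d <- classify_fixed(simp, b)
    nd <- as.data.frame(as.list(c(fixed_x, example_z(b$batch_id))))
    expect_equal(unname(d$slack["rd_purity"]),
                 predict(pub$rd_purity, nd) - limits[["rd_purity"]])
    expect_equal(unname(d$slack["total_saponin_purity"]),
                 predict(pub$total_saponin_purity, nd) -
                   limits[["total_saponin_purity"]])
  }
})

test_that("a boundary batch passes under the >= convention", {
  m <- screening_model("y", c("(Intercept)" = 0, Z1 = 1))
  iq <- derive_inequalities(list(y = m), c(y = 0.5))
  d <- classify_fixed(simplify_fixed(iq, fixed_x), c(Z1 = 0.5))
  expect_equal(unname(d$slack), 0)
  expect_equal(d$verdict, "high")
})

test_that("high quality under fixed parameters implies variable-mode acceptability", {
  simp <- simplify_fixed(iq_pub, fixed_x)
  set.seed(77)
  spec <- generator_spec(n_batches = 30)
  cand <- generate_batches(spec)
  for (i in seq_len(nrow(cand))) {
    b <- cand[i, ]
    if (classify_fixed(simp, b)$verdict == "high") {
      v <- feasibility_variable(iq_pub, unlist(b[-1]))
      expect_equal(v$verdict, "acceptable")
      # the witness satisfies every inequality (nonnegative slack)
      expect_true(all(v$slack >= -1e-12))
    }
  }
})

test_that("dominant material attributes are acceptable at any parameters", {
  z <- c(Z1 = 50, Z2 = 200, Z4 = 1e-3, Z5 = 80, Z6 = 186)
  v <- feasibility_variable(iq_pub, z)
  expect_equal(v$verdict, "acceptable")
})

test_that("feasibility with conflicting coefficient signs is decided exactly", {
  # x appears positively in one inequality and negatively in the other, so
  # no single corner of the box settles it; oracle = dense grid search
  m_up <- screening_model("up", c("(Intercept)" = 0, X9 = 1, Z1 = 1))
  m_dn <- screening_model("dn", c("(Intercept)" = 0, X9 = -1, Z1 = 1))
  iq <- derive_inequalities(list(up = m_up, dn = m_dn),
                            c(up = 60, dn = -54))
  box <- list(X9 = c(55, 65))
  grid_feasible <- function(z1) {
    x <- seq(55, 65, 0.01)
    any(x + z1 >= 60 & -x + z1 >= -54)
  }
  for (z1 in c(0, 1.0, 4.9, 5.1, 8, 20)) {
    v <- feasibility_variable(iq, c(Z1 = z1), box)
    expect_equal(v$verdict == "acceptable", grid_feasible(z1), info = z1)
    if (v$verdict == "acceptable")
      expect_true(all(v$slack >= -1e-9))
  }
})

test_that("blended batches average attributes by mass", {
  two <- study$batches[study$batches$batch_id %in% c("PN2", "PN1"), ]
  bl <- blend_batches(two, c(1, 3))
  expect_equal(bl$Z6, unname((two$Z6[1] + 3 * two$Z6[2]) / 4))
  # blending a failing lot with a strong one can rescue it
  ge <- study$grading_examples
  lowb <- ge[ge$batch_id == "PN19", c("Z1", "Z2", "Z4", "Z5", "Z6")]
  highb <- ge[ge$batch_id == "PN20", c("Z1", "Z2", "Z4", "Z5", "Z6")]
  simp <- simplify_fixed(iq_pub, fixed_x)
  expect_equal(classify_fixed(simp, lowb)$verdict, "low")
  bl2 <- blend_batches(rbind(lowb, highb), c(1, 9), "mix")
  expect_equal(classify_fixed(simp, bl2[-1])$verdict, "high")
})
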