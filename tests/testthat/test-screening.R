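test_that("fixed-term OLS reproduces the published fits on the study data", {
  f1 <- fit_fixed(study$data, "rd_purity", y1_terms)
  f2 <- fit_fixed(study$data, "total_saponin_purity", y2_terms)
  expect_equal(f1$stats$r.squared, 0.9348, tolerance = 0.02)
  expect_equal(f2$stats$r.squared, 0.7460, tolerance = 0.02)
  expect_lt(f1$stats$model.p, 1e-4)
  expect_lt(f2$stats$model.p, 1e-4)
  # refit coefficients agree with the published ones within rounding slack
  pub1 <- study$published_models$rd_purity$coefficients
  for (tm in y1_terms)
    expect_equal(unname(f1$coefficients[tm]), unname(pub1[tm]),
                 tolerance = 0.05)
  pub2 <- study$published_models$total_saponin_purity$coefficients
  for (tm in y2_terms)
    expect_equal(unname(f2$coefficients[tm]), unname(pub2[tm]),
                 tolerance = 0.05)
})

test_that("a noiseless linear response is recovered exactly", {
  d <- data.frame(X1 = rep(c(80, 85, 90), each = 4), e = 1:12)
  d$y <- 0.2 + 0.003 * d$X1
  m <- fit_fixed(d, "y", "X1")
  expect_equal(m$stats$r.squared, 1)
  expect_equal(unname(m$coefficients["X1"]), 0.003)
  expect_equal(unname(m$coefficients["(Intercept)"]), 0.2)
})

test_that("bidirectional stepwise retains the published term sets", {
  m1 <- stepwise_fit(study$data, "rd_purity", all_candidates)
  m2 <- stepwise_fit(study$data, "total_saponin_purity", all_candidates)
  expect_setequal(m1$terms, y1_terms)
  expect_setequal(m2$terms, y2_terms)
  # deterministic: same call, same result
  expect_identical(m1$terms,
                   stepwise_fit(study$data, "rd_purity", all_candidates)$terms)
})

test_that("curvature/interaction augmentation drops all nonlinear terms on the study data", {
  for (resp in c("rd_purity", "total_saponin_purity")) {
    m <- stepwise_fit(study$data, resp, all_candidates)
    a <- augment_and_refit(m, study$data)
    expect_setequal(a$terms, m$terms)
  }
  # single retained CPP yields exactly one extra square candidate
  m2 <- stepwise_fit(study$data, "total_saponin_purity", all_candidates)
  expect_equal(sum(grepl("^X", m2$terms)), 1)
})

test_that("augmentation detects genuine curvature", {
  # truth: published Rd-purity model plus a centred X9 square effect whose
  # raw square coefficient is 5x its standard error on this design
  mm <- cbind(1, as.matrix(study$data[y1_terms]), study$data$X9^2)
  se_unit <- sqrt(diag(solve(crossprod(mm))))[7]
  sigma <- 0.04 * mean(study$data$rd_purity)
  b2 <- 5 * se_unit * sigma
  cf <- lapply(study$published_models, `[[`, "coefficients")
  cf$rd_purity <- c(cf$rd_purity, "X9^2" = b2)
  cf$rd_purity["X9"] <- cf$rd_purity["X9"] - 120 * b2
  cf$rd_purity["(Intercept)"] <- cf$rd_purity["(Intercept)"] + 3600 * b2
  hits <- 0
  for (r in 1:20) {
    dsn <- generate_dataset(generator_spec(coefficients = cf),
                            seed = 2000 + r)
    m0 <- stepwise_fit(dsn$data, "rd_purity", all_candidates)
    a <- augment_and_refit(m0, dsn$data)
    if ("X9^2" %in% a$terms) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("under a pure-noise response stepwise usually selects nothing", {
  # with 3 candidates at alpha 0.05, the empty model is expected in about
  # 0.95^3 ~ 86% of replicates
  set.seed(501)
  empty <- 0
  for (r in 1:100) {
    d <- data.frame(N1 = rnorm(32), N2 = rnorm(32), N3 = rnorm(32),
                    y = rnorm(32))
    m <- stepwise_fit(d, "y", c("N1", "N2", "N3"))
    if (!length(m$terms)) empty <- empty + 1
  }
  expect_gte(empty / 100, 0.65)
})

test_that("a single strong true effect is retained with few false extras", {
  sigma <- 0.04 * 0.06
  seu <- sqrt(diag(solve(crossprod(cbind(1, study$data$X2)))))[2]
  cf <- list(rd_purity = c("(Intercept)" = 0.06, X2 = 5 * seu * sigma))
  kept <- 0; extras <- 0
  for (r in 1:60) {
    dsn <- generate_dataset(generator_spec(coefficients = cf),
                            seed = 3000 + r)
    m <- stepwise_fit(dsn$data, "rd_purity", all_candidates)
    if ("X2" %in% m$terms) kept <- kept + 1
    extras <- extras + length(setdiff(m$terms, "X2"))
  }
  expect_gte(kept / 60, 0.9)
  expect_lte(extras / 60, 1.5)  # ~alpha-level false inclusion only
})

test_that("predictions evaluate the model on its stated scale", {
  pm <- study$published_models
  expect_equal(
    100 * predict(pm$rd_purity,
                  data.frame(X1 = 90, X9 = 60, X10 = 120,
                             Z5 = 6.43, Z6 = 227)),
    4.83, tolerance = 1e-3)
  expect_equal(
    100 * predict(pm$total_saponin_purity,
                  data.frame(X1 = 90, Z1 = 9.09, Z2 = 38.7, Z4 = 32.3)),
    89.81, tolerance = 1e-3)
  # origin evaluates to the intercept
  expect_equal(
    predict(pm$rd_purity,
            data.frame(X1 = 0, X9 = 0, X10 = 0, Z5 = 0, Z6 = 0)),
    unname(pm$rd_purity$coefficients["(Intercept)"]))
  expect_error(predict(pm$rd_purity, data.frame(X1 = 90)), "not found")
})

test_that("critical parameter/attribute identification unions retained main effects", {
  m1 <- stepwise_fit(study$data, "rd_purity", all_candidates)
  m2 <- stepwise_fit(study$data, "total_saponin_purity", all_candidates)
  crit <- identify_critical(list(m1, m2))
  expect_equal(crit$cpps, c("X1", "X9", "X10"))
  expect_equal(crit$cmas, c("Z1", "Z2", "Z4", "Z5", "Z6"))
  empty <- identify_critical(list(screening_model("y", c("(Intercept)" = 1))))
  expect_length(empty$cpps, 0)
  expect_length(empty$cmas, 0)
  # square/interaction labels mark their parent variables as critical
  mq <- screening_model("y", c("(Intercept)" = 0, "X9^2" = 1, "X1:X2" = 1))
  expect_equal(identify_critical(list(mq))$cpps, c("X1", "X2", "X9"))
})

test_that("rank-deficient term sets raise an error naming the collinear terms", {
  d <- study$data
  d$Xdup <- d$X9
  expect_error(fit_fixed(d, "rd_purity", c("X9", "Xdup")), "collinear")
  expect_error(fit_fixed(study$data[1:4, ], "rd_purity", y1_terms),
               "observations")
})

test_that("stepwise matches exhaustive all-significant best-subset search", {
  cands <- c("X1", "X2", "X3", "X9", "X10", "Z1", "Z2", "Z4", "Z5", "Z6")
  # oracle: enumerate every subset, keep those whose coefficients are all
  # significant at 0.05, record the minimum RSS (independent of the
  # stepwise implementation: plain lm + summary)
  best_rss <- function(resp) {
    best <- Inf
    for (k in seq_len(2^length(cands) - 1)) {
      sel <- cands[bitwAnd(k, 2^(seq_along(cands) - 1)) > 0]
      sm <- summary(lm(reformulate(c("1", sel), resp), study$data))
      if (all(stats::coef(sm)[-1, 4] < 0.05)) {
        rss <- sum(sm$residuals^2)
        if (rss < best) best <- rss
      }
    }
    best
  }
  for (resp in c("rd_purity", "total_saponin_purity")) {
    m <- stepwise_fit(study$data, resp, cands)
    expect_lte(m$stats$rss, best_rss(resp) * 1.01)
  }
})
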