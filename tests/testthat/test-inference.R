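test_that("area model reduces to OLS when variance components hit zero", {
  # REML variance estimates from no-cluster-effect data land on the zero
  # boundary about half the time per component; at such a fit the mixed
  # model's fixed effects must equal ordinary least squares exactly.
  found <- FALSE
  for (seed in 1:50) {
    tab <- generate_score_table(
      sd_area = list(scorer = 0, seizure = 0, resid = 0.3), seed = seed)
    fit <- suppressMessages(fit_area_model(tab))
    if (all(fit$ranef_var < 1e-10)) {
      found <- TRUE
      ols <- lm(log_area ~ I(condition == "HD") + as.numeric(multifocal) +
                  as.numeric(overlaps_clinical) + confidence, data = tab)
      expect_equal(unname(fit$coefficients$estimate),
                   unname(coef(ols)), tolerance = 1e-6)
      expect_true(fit$singular)  # variance components at the boundary
      break
    }
  }
  expect_true(found)
})

test_that("model results are invariant to row order", {
  tab <- generate_score_table(seed = 13)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  f1 <- suppressMessages(fit_area_model(tab))
  f2 <- suppressMessages(fit_area_model(shuffled))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("degenerate designs are rejected or flagged, not mis-fit", {
  tab <- generate_score_table(seed = 17)
  hd_only <- tab
  hd_only$condition <- "HD"
  expect_error(fit_area_model(hd_only), "rank deficient|inestimable")

  zero <- tab
  zero$area_px[3] <- 0
  expect_error(fit_area_model(zero), "rows: 3")

  const <- tab
  const$confidence <- 3L
  res <- fit_confidence_model(const)
  expect_false(res$converged)
  expect_match(res$note, "constant outcome")

  few <- tab[tab$scorer_id == "S1", ]
  expect_error(fit_area_model(few), ">= 2 scorers")
})

test_that("confidence model recovers the multifocal effect", {
  est <- vapply(1:60, function(i) {
    tab <- generate_score_table(seed = 3000 + i)
    fit <- suppressMessages(fit_confidence_model(tab))
    fit$coefficients$estimate[fit$coefficients$term == "multifocal"]
  }, 0)
  expect_lt(abs(mean(est) - (-0.873)), 0.1)
})

test_that("Wald tests are calibrated under the null", {
  # zero-effect generator: type-I error of the density test near 5%
  pvals <- vapply(1:400, function(i) {
    tab <- generate_score_table(
      beta_area = list(intercept = 8.5, density = 0, multifocal = 0.2,
                       overlaps = 1.606, confidence = 0.1, carryover = 0),
      seed = 5000 + i)
    fit <- suppressMessages(fit_area_model(tab))
    fit$coefficients$p[fit$coefficients$term == "density_hd"]
  }, 0)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})

test_that("kappa model detects a density effect and stays null-calibrated", {
  sim_kappa_table <- function(effect, seed) {
    withr::with_seed(seed, {
      pairs <- apply(combn(sprintf("S%d", 1:6), 2), 2, paste,
                     collapse = ":")
      d <- expand.grid(pair = pairs, seizure_id = sprintf("Z%02d", 1:10),
                       condition = c("HD", "LD"), stringsAsFactors = FALSE)
      pr <- rnorm(length(pairs), sd = 0.05)
      sz <- rnorm(10, sd = 0.08)
      d$kappa <- 0.45 + effect * (d$condition == "HD") +
        pr[match(d$pair, pairs)] +
        sz[match(d$seizure_id, sprintf("Z%02d", 1:10))] +
        rnorm(nrow(d), sd = 0.08)
      d
    })
  }
  # power at the study-scale effect (kappa difference 0.04)
  hits <- vapply(1:60, function(i) {
    fit <- suppressMessages(fit_kappa_model(sim_kappa_table(0.04, 7000 + i)))
    co <- fit$coefficients[fit$coefficients$term == "density_hd", ]
    co$p < 0.05 && co$estimate > 0
  }, logical(1))
  expect_gt(mean(hits), 0.8)

  # null: the coefficient is centred at zero
  est0 <- vapply(1:60, function(i) {
    fit <- suppressMessages(fit_kappa_model(sim_kappa_table(0, 8000 + i)))
    fit$coefficients$estimate[fit$coefficients$term == "density_hd"]
  }, 0)
  expect_lt(abs(mean(est0)), 0.01)

  # per-scorer aggregation runs on the same table
  f <- suppressMessages(fit_kappa_model(sim_kappa_table(0.04, 1), "scorer"))
  expect_equal(f$model_type, "kappa")

  # single pair, single seizure: paired-difference fallback with warning
  tiny <- data.frame(scorer_a = "S1", scorer_b = "S2",
                     seizure_id = "Z01", condition = c("HD", "LD"),
                     kappa = c(0.5, 0.4))
  expect_warning(res <- fit_kappa_model(tiny), "paired difference")
  expect_equal(res$coefficients$estimate, 0.1)
})

test_that("carryover term is recovered when injected and null otherwise", {
  est <- vapply(1:60, function(i) {
    tab <- generate_score_table(
      beta_area = list(intercept = 8.5, density = 0.227, multifocal = 0.2,
                       overlaps = 1.606, confidence = 0.1, carryover = 0.5),
      seed = 9000 + i)
    fit <- suppressMessages(add_carryover("area", tab))
    fit$coefficients$estimate[fit$coefficients$term == "order_hd_first"]
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.1)

  est0 <- vapply(1:60, function(i) {
    tab <- generate_score_table(seed = 10000 + i)
    fit <- suppressMessages(add_carryover("area", tab))
    fit$coefficients$estimate[fit$coefficients$term == "order_hd_first"]
  }, 0)
  expect_lt(abs(mean(est0)), 0.1)

  tab <- generate_score_table(seed = 1)
  tab$order_first <- "HD"
  expect_error(add_carryover("area", tab), "rank deficient|inestimable")
})

test_that("log-coefficient percent transform matches the reported effect", {
  expect_equal(percent_change_from_log_coef(0), 0)
  expect_equal(percent_change_from_log_coef(log(2)), 100)
  expect_lt(abs(percent_change_from_log_coef(0.227) - 25.4), 0.5)
})

test_that("effective sample size divides by the design effect", {
  expect_equal(effective_sample_size(60, 3), 20)
  expect_equal(effective_sample_size(100, 1), 100)
  expect_equal(effective_sample_size(100, 4), 25)
  expect_error(effective_sample_size(60, 0), "positive")
})

test_that("minimum detectable effect solves the t-test power equation", {
  d <- min_detectable_effect(20, power = 0.8, alpha = 0.05)
  expect_equal(round(d, 1), 0.9)
  # monotone decreasing in n
  ds <- vapply(c(10, 20, 40, 80), min_detectable_effect, 0)
  expect_true(all(diff(ds) < 0))
  expect_error(min_detectable_effect(1), ">= 2")
  expect_error(min_detectable_effect(20, power = 1.2), "power")
})

test_that("score tables and model results survive CSV/JSON round trips", {
  tab <- generate_score_table(seed = 23)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, csv)
  back <- read_score_table(csv)
  expect_equal(back$log_area, tab$log_area)
  expect_equal(back$multifocal, tab$multifocal)

  fit <- suppressMessages(fit_area_model(tab))
  js <- withr::local_tempfile(fileext = ".json")
  write_lmm_json(fit, js)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got$coefficients$estimate, fit$coefficients$estimate)
  expect_equal(got$n, 120L)
})
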