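#' Mixed-model result container
#'
#' Standardised summary of one linear mixed-effects fit: fixed-effect
#' estimates with Wald standard errors, 95% CIs and z-test p-values,
#' random-intercept variances, and fit metadata. The degrees-of-freedom
#' method is Wald z throughout (large-sample normal approximation).
#'
#' @param model_type Character label of the outcome model.
#' @param coefficients Data.frame with columns `term`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p`.
#' @param ranef_var Named numeric vector of random-intercept variances.
#' @param resid_var Residual variance.
#' @param converged,singular Fit flags.
#' @param n Number of observations.
#' @param formula Model formula.
#' @param fit The underlying fit object (or `NULL` for degenerate fits).
#' @param note Optional free-text note (degenerate fits, fallbacks).
#' @return An object of class `lmm_result`.
#' @export
lmm_result <- function(model_type, coefficients, ranef_var, resid_var,
                       converged, singular, n, formula, fit = NULL,
                       note = NULL) {
  stopifnot(all(c("term", "estimate", "se", "ci_lo", "ci_hi", "p") %in%
                  names(coefficients)))
  ok <- is.finite(coefficients$se)
  stopifnot(all(coefficients$ci_lo[ok] <= coefficients$estimate[ok] + 1e-12),
            all(coefficients$ci_hi[ok] >= coefficients$estimate[ok] - 1e-12),
            all(ranef_var >= 0), resid_var >= 0)
  structure(list(model_type = model_type, coefficients = coefficients,
                 ranef_var = ranef_var, resid_var = resid_var,
                 converged = converged, singular = singular, n = n,
                 formula = formula, fit = fit, note = note),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, digits = 4, ...) {
  cat(sprintf("<lmm_result> %s model (n = %d)%s\n", x$model_type, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], round, digits)
  print(co, row.names = FALSE)
  cat(sprintf("  random-intercept variances: %s; residual %.4g\n",
              paste(sprintf("%s %.4g", names(x$ranef_var), x$ranef_var),
                    collapse = ", "), x$resid_var))
  invisible(x)
}

# Check the fixed-effect design for rank deficiency before fitting.
check_full_rank <- function(formula_fixed, data) {
  X <- stats::model.matrix(formula_fixed, data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; inestimable term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Fit an lmer model and package it as an lmm_result (Wald z inference).
fit_lmm <- function(formula, data, model_type, reml = TRUE) {
  fit <- lme4::lmer(formula, data = data, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  co <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se),
                   ci_lo = unname(est - stats::qnorm(0.975) * se),
                   ci_hi = unname(est + stats::qnorm(0.975) * se),
                   p = unname(2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                               vc$grp[vc$grp != "Residual"])
  resid_var <- vc$vcov[vc$grp == "Residual"]
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  lmm_result(model_type, co, ranef_var, resid_var, converged,
             singular = lme4::isSingular(fit), n = nrow(data),
             formula = formula, fit = fit)
}

validate_score_table <- function(t) {
  need <- c("scorer_id", "seizure_id", "condition", "area_px", "log_area",
            "confidence", "multifocal", "overlaps_clinical")
  if (!all(need %in% names(t))) {
    stop("score table missing columns: ",
         paste(setdiff(need, names(t)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(t$scorer_id)) < 2L || length(unique(t$seizure_id)) < 2L) {
    stop("need >= 2 scorers and >= 2 seizures", call. = FALSE)
  }
  invisible(t)
}

# HD indicator with LD as reference level, as a plain numeric column.
prep_density <- function(t) {
  t$density_hd <- as.numeric(t$condition == "HD")
  t$multifocal <- as.numeric(t$multifocal)
  t$overlaps_clinical <- as.numeric(t$overlaps_clinical)
  t
}

#' Mixed model for annotated SOZ area
#'
#' The study's primary area model: natural-log annotation area regressed on
#' density condition (HD vs LD), multifocal designation, overlap with the
#' clinically determined SOZ, and scorer confidence, with uncorrelated
#' random intercepts for scorer and seizure. REML estimation, Wald 95% CIs.
#'
#' @param t A `score_table` data.frame.
#' @return An `lmm_result`; the `density_hd` row is the log-area effect of
#'   the HD condition.
#' @export
fit_area_model <- function(t) {
  validate_score_table(t)
  bad <- which(!(t$area_px > 0))
  if (length(bad) > 0L) {
    stop("zero/negative area in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t <- prep_density(t)
  check_full_rank(~ density_hd + multifocal + overlaps_clinical + confidence, t)
  fit_lmm(log_area ~ density_hd + multifocal + overlaps_clinical +
            confidence + (1 | scorer_id) + (1 | seizure_id),
          t, model_type = "log-area")
}

#' Mixed model for scorer confidence
#'
#' Confidence (Likert 1-5, treated numeric) regressed on density, multifocal
#' designation, clinical overlap, and the scorer's mean pairwise kappa with
#' the other scorers, with random intercepts for scorer and seizure. A
#' constant outcome yields a flagged degenerate result rather than an error.
#'
#' @param t A `score_table` data.frame (needs `scorer_mean_kappa`).
#' @return An `lmm_result`.
#' @export
fit_confidence_model <- function(t) {
  validate_score_table(t)
  t <- prep_density(t)
  check_full_rank(~ density_hd + multifocal + overlaps_clinical +
                    scorer_mean_kappa, t)
  if (stats::sd(t$confidence) == 0) {
    terms <- c("(Intercept)", "density_hd", "multifocal",
               "overlaps_clinical", "scorer_mean_kappa")
    co <- data.frame(term = terms,
                     estimate = c(t$confidence[1], 0, 0, 0, 0),
                     se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     p = NA_real_, stringsAsFactors = FALSE)
    return(lmm_result("confidence", co,
                      ranef_var = c(scorer_id = 0, seizure_id = 0),
                      resid_var = 0, converged = FALSE, singular = TRUE,
                      n = nrow(t), formula = NULL,
                      note = "degenerate fit: constant outcome"))
  }
  fit_lmm(confidence ~ density_hd + multifocal + overlaps_clinical +
            scorer_mean_kappa + (1 | scorer_id) + (1 | seizure_id),
          t, model_type = "confidence")
}

#' Mixed model for pairwise kappa
#'
#' Pair-level analysis of inter-rater agreement: kappa regressed on density
#' with random intercepts for scorer pair and seizure. The study reports
#' only "adjusting for scorer and seizure"; the pair-level random structure
#' is this package's reading, with a per-scorer mean-kappa alternative via
#' `unit = "scorer"`. With a single pair and a single seizure the model is
#' unidentifiable and the function falls back to a paired HD - LD
#' difference with a warning.
#'
#' @param k A long kappa table: columns `scorer_a`, `scorer_b` (or `pair`),
#'   `seizure_id`, `condition` (HD/LD), `kappa`.
#' @param unit `"pair"` (default) or `"scorer"` (rows averaged into
#'   per-scorer mean kappas first).
#' @return An `lmm_result`.
#' @export
fit_kappa_model <- function(k, unit = c("pair", "scorer")) {
  unit <- match.arg(unit)
  k <- as.data.frame(k)
  if (!"pair" %in% names(k)) {
    k$pair <- paste(pmin(k$scorer_a, k$scorer_b),
                    pmax(k$scorer_a, k$scorer_b), sep = ":")
  }
  k <- k[!is.na(k$kappa), , drop = FALSE]
  if (unit == "scorer") {
    if (!all(c("scorer_a", "scorer_b") %in% names(k))) {
      sides <- strsplit(as.character(k$pair), ":", fixed = TRUE)
      k$scorer_a <- vapply(sides, `[`, "", 1L)
      k$scorer_b <- vapply(sides, `[`, "", 2L)
    }
    long <- rbind(
      data.frame(unit_id = k$scorer_a, seizure_id = k$seizure_id,
                 condition = k$condition, kappa = k$kappa),
      data.frame(unit_id = k$scorer_b, seizure_id = k$seizure_id,
                 condition = k$condition, kappa = k$kappa))
    k <- stats::aggregate(kappa ~ unit_id + seizure_id + condition, long, mean)
  } else {
    k$unit_id <- k$pair
  }
  k$density_hd <- as.numeric(k$condition == "HD")
  if (stats::sd(k$density_hd) == 0) {
    stop("density condition is constant; effect inestimable", call. = FALSE)
  }
  if (length(unique(k$unit_id)) < 2L && length(unique(k$seizure_id)) < 2L) {
    warning("single pair and single seizure: falling back to paired difference")
    d <- mean(k$kappa[k$density_hd == 1]) - mean(k$kappa[k$density_hd == 0])
    co <- data.frame(term = "density_hd", estimate = d, se = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    return(lmm_result("kappa", co, ranef_var = numeric(0), resid_var = 0,
                      converged = TRUE, singular = TRUE, n = nrow(k),
                      formula = NULL, note = "paired-difference fallback"))
  }
  fit_lmm(kappa ~ density_hd + (1 | unit_id) + (1 | seizure_id),
          k, model_type = "kappa")
}

#' Carryover check: refit with presentation order as a predictor
#'
#' Crossover designs can carry the first-seen condition's influence into the
#' second viewing; the check adds which condition was presented first
#' (`order_first`) as a fixed effect to the area or confidence model and
#' reports its coefficient and p-value.
#'
#' @param model `"area"` or `"confidence"`, or an `lmm_result` from
#'   [fit_area_model()] / [fit_confidence_model()].
#' @param t A `score_table` with an `order_first` column.
#' @return An `lmm_result` including the `order_hd_first` term.
#' @export
add_carryover <- function(model, t) {
  if (inherits(model, "lmm_result")) {
    model <- if (model$model_type == "log-area") "area" else "confidence"
  }
  model <- match.arg(model, c("area", "confidence"))
  validate_score_table(t)
  if (!"order_first" %in% names(t)) {
    stop("score table has no order_first column", call. = FALSE)
  }
  t <- prep_density(t)
  t$order_hd_first <- as.numeric(t$order_first == "HD")
  if (model == "area") {
    check_full_rank(~ density_hd + multifocal + overlaps_clinical +
                      confidence + order_hd_first, t)
    fit_lmm(log_area ~ density_hd + multifocal + overlaps_clinical +
              confidence + order_hd_first + (1 | scorer_id) + (1 | seizure_id),
            t, model_type = "log-area+carryover")
  } else {
    check_full_rank(~ density_hd + multifocal + overlaps_clinical +
                      scorer_mean_kappa + order_hd_first, t)
    fit_lmm(confidence ~ density_hd + multifocal + overlaps_clinical +
              scorer_mean_kappa + order_hd_first +
              (1 | scorer_id) + (1 | seizure_id),
            t, model_type = "confidence+carryover")
  }
}

#' Percent change implied by a log-scale coefficient
#'
#' `100 * (exp(beta) - 1)`: a log-area coefficient of 0.227 means HD
#' annotations are about 25.5% larger than LD.
#'
#' @param beta Coefficient on the natural-log scale.
#' @return Percent change.
#' @examples
#' percent_change_from_log_coef(0.227)
#' @export
percent_change_from_log_coef <- function(beta) {
  100 * (exp(beta) - 1)
}

#' Effective sample size under a design effect
#'
#' Clustered observations carry less information than independent ones; a
#' design effect DEFF deflates the nominal n to `n / DEFF` (120 crossover
#' observations at DEFF 3.0 give 20 vs 20 effective observations per arm).
#'
#' @param n Nominal number of observations.
#' @param deff Design effect (>= 1 in clustered designs).
#' @return Effective sample size.
#' @export
effective_sample_size <- function(n, deff) {
  if (deff <= 0) stop("design effect must be positive", call. = FALSE)
  n / deff
}

#' Minimum detectable standardised difference of a two-sample t-test
#'
#' Solves the noncentral-t power equation for the standardised difference d
#' detectable with the given per-arm n, power and alpha. With 20 per arm,
#' 80% power and two-sided alpha 0.05 the answer rounds to 0.9 SD.
#'
#' @param n_per_arm Observations per arm (>= 2).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Standardised difference d.
#' @export
min_detectable_effect <- function(n_per_arm, power = 0.8, alpha = 0.05,
                                  two_sided = TRUE) {
  if (!(power > 0 && power < 1)) stop("power must be in (0,1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  stats::power.t.test(n = n_per_arm, power = power, sig.level = alpha,
                      sd = 1, type = "two.sample",
                      alternative = if (two_sided) "two.sided" else "one.sided"
                      )$delta
}

#' Read/write score tables
#'
#' @param t A `score_table`.
#' @param path CSV path.
#' @return `path` / a `score_table`.
#' @export
write_score_table <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  t$multifocal <- as.logical(t$multifocal)
  t$overlaps_clinical <- as.logical(t$overlaps_clinical)
  class(t) <- c("score_table", "data.frame")
  t
}

#' Export a model result as JSON
#'
#' @param res An `lmm_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lmm_json <- function(res, path) {
  jsonlite::write_json(
    list(model_type = res$model_type,
         coefficients = res$coefficients,
         ranef_var = as.list(res$ranef_var),
         resid_var = res$resid_var,
         converged = res$converged, singular = res$singular, n = res$n,
         note = res$note),
    path, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}
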