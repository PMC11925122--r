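#' Seizure simulation configuration
#'
#' Parameters of the synthetic focal seizure generator. The generator is a
#' stand-in for real ictal recordings (available only on request in the
#' study): referential channels with stationary pre-ictal noise and, after
#' onset, an oscillation whose amplitude decays exponentially with distance
#' from a focus and ramps up over `ramp_s` seconds. The model is the
#' simplest one that makes the line-length transform spatially informative;
#' it does not mimic real ictal morphology.
#'
#' @param focus 3D seizure focus position (mm).
#' @param onset_s Onset time in seconds, within `(0, duration_s)`.
#' @param ictal_freq_hz Oscillation frequency (Hz).
#' @param amplitude_uv Oscillation amplitude at the focus (microvolts).
#' @param amplitude_decay_mm Spatial decay constant (mm): amplitude at
#'   distance d is `amplitude_uv * exp(-d / amplitude_decay_mm)`.
#' @param ramp_s Ramp-up time after onset (s).
#' @param noise_sd White-noise SD (microvolts).
#' @param fs_hz Sampling rate (Hz); the study's acquisition rate is 3052.
#' @param duration_s Recording duration (s).
#' @param seed Integer RNG seed.
#' @return A list of class `seizure_sim_config`.
#' @export
seizure_sim_config <- function(focus = c(0, 0, 0), onset_s = 10,
                               ictal_freq_hz = 8, amplitude_uv = 100,
                               amplitude_decay_mm = 10, ramp_s = 5,
                               noise_sd = 5, fs_hz = 3052, duration_s = 30,
                               seed = 1L) {
  focus <- as.numeric(focus)
  if (length(focus) != 3L || !all(is.finite(focus))) {
    stop("focus must be a finite 3D point", call. = FALSE)
  }
  if (!(onset_s > 0 && onset_s < duration_s)) {
    stop("onset_s must lie within (0, duration_s)", call. = FALSE)
  }
  if (amplitude_decay_mm <= 0) stop("decay constant must be > 0", call. = FALSE)
  if (fs_hz <= 2 * ictal_freq_hz) {
    stop("fs_hz must exceed twice the ictal frequency", call. = FALSE)
  }
  structure(list(focus = focus, onset_s = onset_s,
                 ictal_freq_hz = ictal_freq_hz, amplitude_uv = amplitude_uv,
                 amplitude_decay_mm = amplitude_decay_mm, ramp_s = ramp_s,
                 noise_sd = noise_sd, fs_hz = fs_hz, duration_s = duration_s,
                 seed = seed),
            class = "seizure_sim_config")
}

#' Generate a synthetic seizure recording
#'
#' Deterministic under a fixed seed. Pre-onset samples are white noise;
#' post-onset each channel additionally carries the distance-attenuated
#' ramped oscillation of [seizure_sim_config()].
#'
#' @param arrays An `electrode_array` or list of them; channels follow the
#'   arrays' contact order.
#' @param cfg A `seizure_sim_config`.
#' @return An `iceeg_recording` with `baseline_window` spanning the
#'   pre-onset segment.
#' @export
generate_seizure_recording <- function(arrays, cfg) {
  stopifnot(inherits(cfg, "seizure_sim_config"))
  arrays <- if (inherits(arrays, "electrode_array")) list(arrays) else arrays
  if (length(arrays) == 0L) stop("at least one array required", call. = FALSE)
  contacts <- do.call(rbind, lapply(arrays, `[[`, "contacts"))
  labels <- unlist(lapply(arrays, `[[`, "channel_labels"))
  n <- round(cfg$duration_s * cfg$fs_hz)
  tt <- (seq_len(n) - 1L) / cfg$fs_hz
  d <- sqrt(rowSums(sweep(contacts, 2, cfg$focus)^2))
  amp <- cfg$amplitude_uv * exp(-d / cfg$amplitude_decay_mm)
  post <- tt >= cfg$onset_s
  ramp <- pmin((tt - cfg$onset_s) / max(cfg$ramp_s, 1e-9), 1) * post
  osc <- sin(2 * pi * cfg$ictal_freq_hz * (tt - cfg$onset_s)) * ramp
  data <- with_seed(cfg$seed, {
    matrix(stats::rnorm(length(labels) * n, sd = cfg$noise_sd),
           nrow = length(labels))
  })
  data <- data + outer(amp, osc)
  onset_sample <- floor(cfg$onset_s * cfg$fs_hz) + 1L
  iceeg_recording(data, cfg$fs_hz, labels,
                  onset_sample = onset_sample,
                  baseline_window = c(1L, onset_sample - 1L))
}

# Regular polygon approximating a circle, in raster pixel coordinates.
disc_ring <- function(center, radius_px, n_vertices = 180L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius_px * cos(th), center[2] + radius_px * sin(th))
}

#' Generate a ground-truth SOZ mask
#'
#' Produces the "true" seizure-onset-zone raster against which simulated
#' scorer annotations are compared. The source polygon rings are kept on the
#' mask (field `rings`) so that annotation simulation can jitter the smooth
#' geometry rather than the pixelated boundary.
#'
#' @param raster_spec List with `width`, `height` (pixels).
#' @param shape `"disc"` or `"polygon"`.
#' @param center Disc centre `(x, y)` in pixel coordinates.
#' @param radius_px Disc radius in pixels (> 0).
#' @param rings For `shape = "polygon"`: list of n x 2 vertex rings.
#' @param n_vertices Number of vertices of the disc's polygonal boundary.
#' @param ... Passed to [annotation_mask()].
#' @return An `annotation_mask` with a `rings` field; errors if the mask is
#'   empty.
#' @export
generate_true_soz_mask <- function(raster_spec, shape = c("disc", "polygon"),
                                   center = NULL, radius_px = NULL,
                                   rings = NULL, n_vertices = 180L, ...) {
  shape <- match.arg(shape)
  if (shape == "disc") {
    if (is.null(center)) {
      center <- c(raster_spec$width / 2, raster_spec$height / 2)
    }
    if (is.null(radius_px) || radius_px <= 0) {
      stop("disc radius must be > 0 (empty mask rejected)", call. = FALSE)
    }
    rings <- list(disc_ring(center, radius_px, n_vertices))
  } else {
    if (is.null(rings) || length(rings) == 0L) {
      stop("polygon shape requires rings", call. = FALSE)
    }
  }
  mask <- rasterize_polygons(rings, raster_spec, ...)
  if (sum(mask$pixels) == 0L) stop("generated mask is empty", call. = FALSE)
  mask$rings <- rings
  mask$multifocal <- length(rings) > 1L
  mask
}

#' Scorer simulation configuration
#'
#' Controls the simulated annotators. Each scorer's annotation is the true
#' SOZ polygon with (i) smoothed Gaussian boundary displacement along the
#' outward normal (`boundary_jitter_px`), and (ii) an isotropic scaling that
#' makes the expected log-area difference between HD and LD annotations
#' equal `area_log_multiplier_hd` (default 0.227, the study's estimated
#' density effect on log annotation area). Confidence is drawn from a
#' five-point Likert model whose multifocal effect defaults to -0.873, the
#' study's estimated coefficient.
#'
#' @param n_scorers Number of simulated scorers (>= 2; the study had 6).
#' @param boundary_jitter_px Boundary displacement SD in pixels (>= 0).
#' @param area_log_multiplier_hd Expected log-area difference HD - LD.
#' @param scorer_bias_sd SD of a per-scorer log-area bias (applied equally
#'   in both conditions).
#' @param seizure_effect_sd SD of a per-seizure log-area effect used by
#'   [generate_score_table()].
#' @param confidence_model Function `(multifocal, jitter_px)` returning an
#'   integer Likert rating in 1..5; `NULL` for the built-in model.
#' @param seed Integer RNG seed.
#' @return A list of class `scorer_sim_config`.
#' @export
scorer_sim_config <- function(n_scorers = 6L, boundary_jitter_px = 2,
                              area_log_multiplier_hd = 0.227,
                              scorer_bias_sd = 0, seizure_effect_sd = 0,
                              confidence_model = NULL, seed = 1L) {
  if (n_scorers < 2L) stop("n_scorers must be >= 2", call. = FALSE)
  if (boundary_jitter_px < 0) stop("jitter must be >= 0", call. = FALSE)
  structure(list(n_scorers = as.integer(n_scorers),
                 boundary_jitter_px = boundary_jitter_px,
                 area_log_multiplier_hd = area_log_multiplier_hd,
                 scorer_bias_sd = scorer_bias_sd,
                 seizure_effect_sd = seizure_effect_sd,
                 confidence_model = confidence_model, seed = seed),
            class = "scorer_sim_config")
}

# Built-in Likert confidence model: latent normal rating, lowered for
# multifocal SOZs (study-scale effect) and noisy boundaries.
default_confidence_model <- function(multifocal, jitter_px) {
  latent <- 4.3 - 0.873 * as.numeric(multifocal) - 0.15 * jitter_px +
    stats::rnorm(1, sd = 0.6)
  as.integer(pmin(pmax(round(latent), 1), 5))
}

# Extract closed boundary rings from a raster mask (fallback when the mask
# has no stored source polygon).
mask_rings <- function(mask) {
  W <- mask$raster_spec$width; H <- mask$raster_spec$height
  cl <- grDevices::contourLines(x = seq_len(W) - 0.5, y = seq_len(H) - 0.5,
                                z = t(mask$pixels), levels = 0.5)
  lapply(cl, function(cc) cbind(cc$x, cc$y))
}

# Displace one ring: isotropic scale about its centroid, then smoothed
# normal displacement. Returns the new ring.
jitter_ring <- function(ring, scale, jitter_px) {
  nv <- nrow(ring)
  ctr <- colMeans(ring)
  ring <- sweep(sweep(ring, 2, ctr), 1, rep(scale, nv), `*`)
  ring <- sweep(ring, 2, ctr, `+`)
  if (jitter_px > 0 && nv >= 3L) {
    nxt <- c(2:nv, 1L); prv <- c(nv, 1:(nv - 1L))
    tx <- ring[nxt, 1] - ring[prv, 1]
    ty <- ring[nxt, 2] - ring[prv, 2]
    # outward normal: rotate tangent by -90 deg for CCW rings, +90 for CW
    a2 <- sum(ring[, 1] * ring[nxt, 2] - ring[nxt, 1] * ring[, 2])
    sgn <- if (a2 > 0) 1 else -1
    nx <- sgn * ty; ny <- -sgn * tx
    nl <- sqrt(nx^2 + ny^2); nl[nl < 1e-12] <- 1
    nx <- nx / nl; ny <- ny / nl
    delta <- stats::rnorm(nv, sd = jitter_px)
    k <- stats::filter(c(delta, delta, delta), rep(1 / 7, 7), circular = FALSE)
    delta <- as.numeric(k[nv + seq_len(nv)])
    s <- stats::sd(delta)
    if (is.finite(s) && s > 0) delta <- delta * jitter_px / s
    ring <- ring + cbind(delta * nx, delta * ny)
  }
  ring
}

#' Simulate scorer annotations of a true SOZ
#'
#' Each simulated scorer annotates the true SOZ under one density condition.
#' The true polygon is scaled so the expected HD - LD log-area difference is
#' `cfg$area_log_multiplier_hd`, then its boundary is displaced by smoothed
#' normal noise and re-rasterised. Masks that come out empty are
#' regenerated up to `max_retry` times, then an error is raised.
#'
#' @param true_mask An `annotation_mask` from [generate_true_soz_mask()].
#' @param cond `"HD"` or `"LD"`.
#' @param cfg A `scorer_sim_config`.
#' @param seizure_id Optional seizure identifier stamped on the masks.
#' @param max_retry Retry cap for degenerate (empty) masks.
#' @return List of `annotation_mask` (one per scorer) with `confidence` and
#'   `multifocal` filled in.
#' @export
simulate_scorer_annotations <- function(true_mask, cond, cfg,
                                        seizure_id = NA, max_retry = 10L) {
  stopifnot(inherits(true_mask, "annotation_mask"),
            inherits(cfg, "scorer_sim_config"))
  if (sum(true_mask$pixels) == 0L) stop("true mask is empty", call. = FALSE)
  cond <- match.arg(cond, c("HD", "LD"))
  rings <- true_mask$rings %||% mask_rings(true_mask)
  cond_sign <- if (cond == "HD") 1 else -1
  out <- vector("list", cfg$n_scorers)
  for (s in seq_len(cfg$n_scorers)) {
    bias <- with_seed(child_seed(cfg$seed, s),
                      stats::rnorm(1, sd = cfg$scorer_bias_sd))
    scale <- exp(cond_sign * cfg$area_log_multiplier_hd / 4 + bias / 2)
    seed_sc <- child_seed(cfg$seed, 1000L + 2L * s + (cond == "HD"))
    mask <- with_seed(seed_sc, {
      for (attempt in seq_len(max_retry)) {
        new_rings <- lapply(rings, jitter_ring, scale = scale,
                            jitter_px = cfg$boundary_jitter_px)
        m <- rasterize_polygons(new_rings, true_mask$raster_spec)
        if (sum(m$pixels) > 0L) break
        m <- NULL
      }
      if (is.null(m)) {
        stop("mask degenerate after ", max_retry, " retries", call. = FALSE)
      }
      m
    })
    multifocal <- length(rings) > 1L
    conf_model <- cfg$confidence_model %||% default_confidence_model
    confidence <- with_seed(child_seed(cfg$seed, 5000L + 2L * s + (cond == "HD")),
                            conf_model(multifocal, cfg$boundary_jitter_px))
    mask$scorer_id <- sprintf("S%d", s)
    mask$seizure_id <- seizure_id
    mask$condition <- cond
    mask$confidence <- as.integer(confidence)
    mask$multifocal <- multifocal
    out[[s]] <- mask
  }
  out
}

#' Generate a blocked crossover viewing schedule
#'
#' Scorers view each seizure twice: a first pass of all seizures with a
#' balanced random assignment of density conditions (exactly half HD-first),
#' then a second pass in the opposite condition. The permutation is uniform
#' over balanced arrangements given the seed.
#'
#' @param n_seizures Even number of seizures (default 10).
#' @param seed Integer RNG seed.
#' @return An object of class `crossover_schedule`: list with
#'   `first_condition` (per-seizure) and `schedule` (data.frame with
#'   `pass`, `order`, `seizure`, `condition`).
#' @export
generate_crossover_schedule <- function(n_seizures = 10L, seed = 1L) {
  n_seizures <- as.integer(n_seizures)
  if (n_seizures %% 2L != 0L) {
    stop("n_seizures must be even (balanced design required)", call. = FALSE)
  }
  first <- with_seed(seed, sample(rep(c("HD", "LD"), each = n_seizures / 2L)))
  second <- ifelse(first == "HD", "LD", "HD")
  sched <- data.frame(
    pass = rep(1:2, each = n_seizures),
    order = seq_len(2L * n_seizures),
    seizure = rep(seq_len(n_seizures), 2L),
    condition = c(first, second),
    stringsAsFactors = FALSE)
  structure(list(n_seizures = n_seizures, first_condition = first,
                 schedule = sched, seed = seed),
            class = "crossover_schedule")
}

#' @export
print.crossover_schedule <- function(x, ...) {
  cat(sprintf("<crossover_schedule> %d seizures, %d HD-first\n",
              x$n_seizures, sum(x$first_condition == "HD")))
  invisible(x)
}

#' Write a crossover schedule to CSV
#'
#' @param schedule A `crossover_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$schedule, path, row.names = FALSE)
  invisible(path)
}

#' Generate a score table from a known mixed model
#'
#' Parameter-recovery harness for the inference module: draws log-area and
#' confidence outcomes from exactly the mixed models that
#' [fit_area_model()] and [fit_confidence_model()] fit, with known fixed
#' effects, uncorrelated random intercepts for scorer and seizure, and
#' Gaussian residuals. The default design is the study's: 6 scorers x 10
#' seizures x 2 conditions = 120 rows.
#'
#' @param beta_area Named fixed effects of the log-area model: `intercept`,
#'   `density` (HD vs LD), `multifocal`, `overlaps`, `confidence`,
#'   `carryover` (effect of HD-first presentation; 0 in the study model).
#' @param beta_conf Named fixed effects of the confidence model:
#'   `intercept`, `density`, `multifocal`, `overlaps`, `kappa`.
#' @param sd_area,sd_conf Named SDs `scorer`, `seizure`, `resid` of the two
#'   models' variance components.
#' @param n_scorers,n_seizures Design size.
#' @param p_multifocal,p_overlap Bernoulli rates of the binary covariates.
#' @param seed Integer RNG seed.
#' @return A data.frame of class `score_table` with one row per scorer x
#'   seizure x condition.
#' @export
generate_score_table <- function(beta_area = list(intercept = 8.5,
                                                  density = 0.227,
                                                  multifocal = 0.2,
                                                  overlaps = 1.606,
                                                  confidence = 0.1,
                                                  carryover = 0),
                                 beta_conf = list(intercept = 3.3,
                                                  density = 0,
                                                  multifocal = -0.873,
                                                  overlaps = 0,
                                                  kappa = 0.5),
                                 sd_area = list(scorer = 0.3, seizure = 0.4,
                                                resid = 0.35),
                                 sd_conf = list(scorer = 0.4, seizure = 0.3,
                                                resid = 0.5),
                                 n_scorers = 6L, n_seizures = 10L,
                                 p_multifocal = 0.25, p_overlap = 0.917,
                                 seed = 1L) {
  with_seed(seed, {
    sched <- generate_crossover_schedule(n_seizures,
                                         seed = child_seed(seed, 77L))
    df <- expand.grid(scorer_id = sprintf("S%d", seq_len(n_scorers)),
                      seizure_id = sprintf("Z%02d", seq_len(n_seizures)),
                      condition = c("HD", "LD"),
                      stringsAsFactors = FALSE)
    df$order_first <- sched$first_condition[match(df$seizure_id,
                                                  sprintf("Z%02d", sched$schedule$seizure[sched$schedule$pass == 1]))]
    hd <- as.numeric(df$condition == "HD")
    df$multifocal <- stats::rbinom(nrow(df), 1, p_multifocal) == 1
    df$overlaps_clinical <- stats::rbinom(nrow(df), 1, p_overlap) == 1
    df$scorer_mean_kappa <- stats::runif(nrow(df), 0.3, 0.7)
    u_a <- stats::rnorm(n_scorers, sd = sd_area$scorer)
    v_a <- stats::rnorm(n_seizures, sd = sd_area$seizure)
    u_c <- stats::rnorm(n_scorers, sd = sd_conf$scorer)
    v_c <- stats::rnorm(n_seizures, sd = sd_conf$seizure)
    si <- match(df$scorer_id, sprintf("S%d", seq_len(n_scorers)))
    zi <- match(df$seizure_id, sprintf("Z%02d", seq_len(n_seizures)))
    conf_latent <- beta_conf$intercept + beta_conf$density * hd +
      beta_conf$multifocal * df$multifocal +
      beta_conf$overlaps * df$overlaps_clinical +
      beta_conf$kappa * df$scorer_mean_kappa +
      u_c[si] + v_c[zi] + stats::rnorm(nrow(df), sd = sd_conf$resid)
    df$confidence <- as.integer(pmin(pmax(round(conf_latent), 1), 5))
    y <- beta_area$intercept + beta_area$density * hd +
      beta_area$multifocal * df$multifocal +
      beta_area$overlaps * df$overlaps_clinical +
      beta_area$confidence * df$confidence +
      (beta_area$carryover %||% 0) * as.numeric(df$order_first == "HD") +
      u_a[si] + v_a[zi] + stats::rnorm(nrow(df), sd = sd_area$resid)
    df$area_px <- pmax(1, round(exp(y)))
    df$log_area <- log(df$area_px)
    df <- df[, c("scorer_id", "seizure_id", "condition", "order_first",
                 "area_px", "log_area", "confidence", "multifocal",
                 "overlaps_clinical", "scorer_mean_kappa")]
    class(df) <- c("score_table", "data.frame")
    df
  })
}
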