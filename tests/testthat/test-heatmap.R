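test_that("line length sums absolute differences over trailing windows", {
  rec <- iceeg_recording(matrix(5, 1, 100), 10, "a", onset_sample = 90,
                         baseline_window = c(1, 80))
  ll <- line_length(rec, window_s = 0.5, hop_s = 0.1)
  expect_true(all(ll$values == 0))
  expect_equal(ll$frame_times_s[1], 0.5)

  # alternating 0,1 with a 5-sample window covers 4 unit steps
  alt <- iceeg_recording(matrix(rep(c(0, 1), 50), 1, 100), 10, "a",
                         onset_sample = 90, baseline_window = c(1, 80))
  ll2 <- line_length(alt, window_s = 0.5, hop_s = 0.1)
  expect_true(all(ll2$values == 4))

  # homogeneity: doubling the signal doubles line length exactly
  set.seed(3)
  x <- matrix(rnorm(200), 1)
  r1 <- iceeg_recording(x, 10, "a", onset_sample = 190,
                        baseline_window = c(1, 150))
  r2 <- iceeg_recording(2 * x, 10, "a", onset_sample = 190,
                        baseline_window = c(1, 150))
  expect_equal(2 * line_length(r1)$values, line_length(r2)$values)

  expect_error(line_length(rec, window_s = 60), "longer than")
})

test_that("baseline z-scoring centres and scales each channel", {
  sz <- small_seizure(seed = 41)
  ll <- line_length(sz$rec)
  z <- zscore_to_baseline(ll, sz$rec$baseline_window)
  base <- z$values[, z$baseline_frames, drop = FALSE]
  expect_equal(unname(rowMeans(base)), rep(0, nrow(base)), tolerance = 1e-10)
  expect_equal(unname(apply(base, 1, sd)), rep(1, nrow(base)),
               tolerance = 1e-10)

  # the focus channel's ictal z clearly exceeds its baseline distribution
  post <- z$frame_times_s > sz$cfg$onset_s + sz$cfg$ramp_s
  focus_z <- z$values[1, post]
  expect_gt(max(focus_z), quantile(z$values[1, z$baseline_frames], 0.95))

  # zero-SD channel is rejected by name
  flat <- sz$rec
  flat$data[2, ] <- 7
  llf <- line_length(flat)
  expect_error(zscore_to_baseline(llf, flat$baseline_window), "G02")
  expect_error(zscore_to_baseline(ll, c(1, 40)), "frames")
})

test_that("gaussian max projection follows the kernel formula", {
  # single electrode: value at distance 0 is z itself
  expect_equal(project_max_gaussian(3.7, c(0, 0, 0), c(0, 0, 0)), 3.7)
  # z = 4 at d = 5 with sigma = 5: 4 * exp(-0.5)
  v <- project_max_gaussian(4, c(0, 0, 0), c(5, 0, 0), sigma_mm = 5,
                            cutoff_mm = 15)
  expect_equal(v, 4 * exp(-0.5), tolerance = 1e-12)
  # duplicated electrode changes nothing (max idempotence)
  c2 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(project_max_gaussian(c(4, 4), c2, c(5, 0, 0)), v)
  # no contact within cutoff: zero
  expect_equal(project_max_gaussian(4, c(0, 0, 0), c(50, 0, 0)), 0)
  expect_error(project_max_gaussian(numeric(0), matrix(0, 0, 3), c(0, 0, 0)),
               "empty")
})

test_that("projection equals a brute-force loop and is order-invariant", {
  set.seed(13)
  for (rep in 1:5) {
    ct <- matrix(rnorm(24, sd = 8), ncol = 3)
    z <- rnorm(8, mean = 2)
    tg <- matrix(rnorm(45, sd = 8), ncol = 3)
    got <- project_max_gaussian(z, ct, tg, 5, 15)
    want <- sapply(seq_len(nrow(tg)), function(i) {
      d <- sqrt(colSums((t(ct) - tg[i, ])^2))
      vals <- (z * exp(-d^2 / 50))[d <= 15]
      if (length(vals) == 0) 0 else max(vals)
    })
    expect_equal(got, want, tolerance = 1e-12)
    # contact ordering is irrelevant
    p <- sample(8)
    expect_equal(project_max_gaussian(z[p], ct[p, ], tg, 5, 15), got)
  }
})

test_that("projection is local: contacts beyond cutoff never matter", {
  set.seed(17)
  ct <- rbind(matrix(rnorm(15, sd = 5), ncol = 3),
              c(100, 100, 100))
  z <- c(rnorm(5, 2), 50)
  tg <- matrix(rnorm(30, sd = 5), ncol = 3)
  v1 <- project_max_gaussian(z, ct, tg, 5, 15)
  v2 <- project_max_gaussian(z[1:5], ct[1:5, ], tg, 5, 15)
  expect_equal(v1, v2)
})

test_that("removing contacts never increases clamped heat (dominance)", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 12
    ct <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
    z <- rnorm(n, mean = 1, sd = 2)
    tg <- matrix(rnorm(60, sd = 6), ncol = 3)
    keep <- sort(sample(n, 5))
    full <- pmax(project_max_gaussian(z, ct, tg, 5, 15), 0)
    part <- pmax(project_max_gaussian(z[keep], ct[keep, ], tg, 5, 15), 0)
    expect_true(all(part <= full + 1e-12))
  }
})

test_that("surface rendering respects blinding and handles flat frames", {
  set.seed(23)
  mesh <- surface_mesh(matrix(rnorm(150, sd = 20), ncol = 3),
                       matrix(1:3, ncol = 3))
  fr <- heatmap_frame(rep(0, 50), frame_time_s = 12.3)
  img <- render_surface_frame(mesh, fr, blinded = TRUE,
                              contacts = matrix(0, 2, 3), condition = "HD")
  expect_false("electrodes" %in% img$layers)
  expect_null(img$metadata$condition)
  expect_equal(img$metadata$frame_time_s, 12.3)
  # all-zero frame: uniform base colour away from the mesh silhouette
  expect_true(length(unique(as.vector(img$rgb))) <= 4)

  img2 <- render_surface_frame(mesh, fr, blinded = FALSE,
                               contacts = matrix(0, 2, 3), condition = "HD")
  expect_true("electrodes" %in% img2$layers)
  expect_equal(img2$metadata$condition, "HD")

  expect_error(render_surface_frame(mesh, heatmap_frame(rep(0, 3), 1)),
               "match")
})

test_that("omniplanar slices reproduce the projection on the pixel grid", {
  d <- build_depth_array(6, 5, entry = c(2, -1, 4), direction = c(1, 1, 0))
  pl <- omniplanar_basis(d, normal_hint = c(0, 0, 1), extent_mm = 10,
                         res_mm = 2)
  z <- seq(0.5, 3, by = 0.5)
  fr <- render_omniplanar_frame(pl, d$contacts, z, sigma_mm = 5,
                                cutoff_mm = 15)
  # pixel exactly at the first contact (grid origin) carries its z
  pix <- which(apply(fr$pixel_positions, 1,
                     function(p) sqrt(sum((p - d$contacts[1, ])^2))) < 1e-9)
  expect_length(pix, 1L)
  heat_rowmajor <- as.vector(t(fr$heat))
  expect_equal(heat_rowmajor[pix], max(z * exp(-((0:5) * 5)^2 / 50)),
               tolerance = 1e-12)
  # the whole slice equals the projection oracle at every pixel
  want <- project_max_gaussian(z, d$contacts, fr$pixel_positions, 5, 15)
  expect_equal(heat_rowmajor, want, tolerance = 1e-12)

  # no contacts in range: all-zero heat
  far <- render_omniplanar_frame(pl, d$contacts + 1000, z)
  expect_true(all(far$heat == 0))

  expect_error(render_omniplanar_frame(`class<-`(modifyList(unclass(pl),
    list(res_mm = 0)), "omniplanar_plane"), d$contacts, z), "resolution")
})
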