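test_that("polygon rasterisation follows the pixel-centre even-odd rule", {
  rs <- list(width = 30, height = 20)
  # axis-aligned square covering exactly a 10x10 pixel block
  sq <- rasterize_polygons(list(cbind(c(5, 15, 15, 5), c(3, 3, 13, 13))), rs)
  expect_equal(sum(sq$pixels), 100L)
  expect_equal(sum(sq$pixels[4:13, 6:15]), 100L)

  # empty polygon list: all-zero mask
  empty <- rasterize_polygons(list(), rs)
  expect_true(all(empty$pixels == 0L))

  # multiple rings OR together
  two <- rasterize_polygons(list(cbind(c(1, 5, 5, 1), c(1, 1, 5, 5)),
                                 cbind(c(20, 24, 24, 20), c(10, 10, 14, 14))),
                            rs)
  expect_equal(sum(two$pixels), 32L)

  expect_error(rasterize_polygons(list(cbind(c(1, 2), c(1, 2))), rs),
               ">= 3")
})

test_that("rasterisation matches an independent point-in-polygon oracle", {
  skip_if_not_installed("sp")
  rs <- list(width = 40, height = 30)
  set.seed(29)
  for (rep in 1:5) {
    th <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 3, 12)
    ring <- cbind(20 + r * cos(th), 15 + r * sin(th))  # star-convex, simple
    got <- rasterize_polygons(list(ring), rs)$pixels
    want <- matrix(0L, rs$height, rs$width)
    for (i in seq_len(rs$height)) for (j in seq_len(rs$width)) {
      want[i, j] <- as.integer(sp::point.in.polygon(
        j - 0.5, i - 0.5, ring[, 1], ring[, 2]) > 0)
    }
    expect_equal(got, want)
  }
})

test_that("cohen kappa reproduces the contingency formula", {
  m1 <- matrix(0L, 10, 10); m1[1:3, ] <- 1L      # 30 px
  m2 <- matrix(0L, 10, 10); m2[1:2, ] <- 1L; m2[4, ] <- 1L  # 30 px, 20 shared
  a <- mask_of(m1); b <- mask_of(m2)
  # n11=20, n10=10, n01=10, n00=60 -> po=0.80, pe=0.58, kappa=0.22/0.42
  expect_equal(cohen_kappa(a, b), 0.22 / 0.42, tolerance = 1e-12)

  # identical nonempty non-full masks agree perfectly
  expect_equal(cohen_kappa(a, a), 1)

  # complementary halves: po = 0, pe = 0.5, kappa = -1
  left <- matrix(0L, 10, 10); left[, 1:5] <- 1L
  expect_equal(cohen_kappa(mask_of(left), mask_of(1L - left)), -1)

  # undefined when both empty or both full
  z <- mask_of(matrix(0L, 10, 10)); o <- mask_of(matrix(1L, 10, 10))
  expect_error(cohen_kappa(z, z), class = "sozdensity_undefined_kappa")
  expect_error(cohen_kappa(o, o), class = "sozdensity_undefined_kappa")

  # raster mismatch is refused
  expect_error(cohen_kappa(a, mask_of(matrix(0L, 5, 5))), "raster_spec")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (rep in 1:10) {
    a <- matrix(rbinom(400, 1, 0.3), 20)
    b <- matrix(rbinom(400, 1, 0.4), 20)
    got <- cohen_kappa(mask_of(a), mask_of(b))
    tab <- table(factor(a, 0:1), factor(b, 0:1))
    want <- e1071::classAgreement(tab)$kappa
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("padding the raster changes kappa (chance correction is global)", {
  m1 <- matrix(0L, 10, 10); m1[1:3, 1:5] <- 1L
  m2 <- matrix(0L, 10, 10); m2[2:4, 1:5] <- 1L
  k_small <- cohen_kappa(mask_of(m1), mask_of(m2))
  pad <- function(m) rbind(cbind(m, matrix(0L, 10, 20)), matrix(0L, 10, 30))
  k_big <- cohen_kappa(mask_of(pad(m1)), mask_of(pad(m2)))
  expect_false(isTRUE(all.equal(k_small, k_big)))
  expect_gt(k_big, k_small)  # more shared negatives inflate agreement
})

test_that("pairwise kappa yields one result per unordered pair", {
  rs <- small_raster()
  tm <- generate_true_soz_mask(rs, "disc", center = c(60, 45),
                               radius_px = 20)
  ann <- simulate_scorer_annotations(tm, "HD", scorer_sim_config(seed = 3))
  res <- pairwise_kappa(ann)
  expect_s3_class(res, "kappa_results")
  expect_equal(nrow(res), choose(6, 2))
  expect_true(all(res$kappa >= -1 & res$kappa <= 1))

  two <- pairwise_kappa(ann[1:2])
  expect_equal(nrow(two), 1L)
  expect_error(pairwise_kappa(ann[1]), ">= 2")

  # symmetry of the underlying statistic
  expect_equal(cohen_kappa(ann[[1]], ann[[2]]),
               cohen_kappa(ann[[2]], ann[[1]]))
})

test_that("intra-rater kappa compares HD and LD of the same scorer", {
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
  hd <- mask_of(m, scorer_id = "S1", condition = "HD")
  same <- intra_rater_kappa(hd, mask_of(m, scorer_id = "S1", condition = "LD"))
  expect_equal(same$kappa, 1)

  # LD strictly inside HD of double area: kappa computable and < 1
  inner <- matrix(0L, 20, 20); inner[8:12, 6:15] <- 1L  # 50 px vs 100 px
  k <- intra_rater_kappa(hd, mask_of(inner, scorer_id = "S1",
                                     condition = "LD"))$kappa
  n11 <- 50; n00 <- 300; po <- 350 / 400
  pe <- 0.25 * 0.125 + 0.75 * 0.875
  expect_equal(k, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_lt(k, 1)

  # zero-jitter simulated scorers with no density effect agree with
  # themselves across conditions
  rs <- small_raster()
  tm <- generate_true_soz_mask(rs, "disc", center = c(60, 45), radius_px = 18)
  cfg0 <- scorer_sim_config(boundary_jitter_px = 0,
                            area_log_multiplier_hd = 0, seed = 5)
  hd0 <- simulate_scorer_annotations(tm, "HD", cfg0)
  ld0 <- simulate_scorer_annotations(tm, "LD", cfg0)
  ks <- mapply(function(h, l) intra_rater_kappa(h, l)$kappa, hd0, ld0)
  expect_equal(unname(ks), rep(1, 6))
})

test_that("clinical overlap uses the any-pixel rule", {
  a <- matrix(0L, 10, 10); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 10, 10); b[8:9, 8:9] <- 1L
  expect_false(overlaps_clinical(mask_of(a), mask_of(b)))
  b[2, 2] <- 1L
  expect_true(overlaps_clinical(mask_of(a), mask_of(b)))
})

test_that("scorer mean kappa equals the pairwise-matrix row average", {
  rs <- small_raster()
  tm <- generate_true_soz_mask(rs, "disc", center = c(60, 45), radius_px = 20)
  ann <- simulate_scorer_annotations(tm, "LD", scorer_sim_config(seed = 9))
  res <- pairwise_kappa(ann)
  K <- matrix(NA_real_, 6, 6, dimnames = list(sprintf("S%d", 1:6),
                                              sprintf("S%d", 1:6)))
  for (r in seq_len(nrow(res))) {
    K[res$scorer_a[r], res$scorer_b[r]] <- res$kappa[r]
    K[res$scorer_b[r], res$scorer_a[r]] <- res$kappa[r]
  }
  for (s in sprintf("S%d", 1:6)) {
    expect_equal(scorer_mean_kappa(res, s), mean(K[s, ], na.rm = TRUE))
  }
  # constant matrix: the mean is that constant
  resc <- res; resc$kappa <- 0.42
  expect_equal(scorer_mean_kappa(resc, "S3"), 0.42)
})

test_that("mask PNG round trip preserves pixels and metadata", {
  rs <- list(width = 24, height = 16)
  m <- matrix(0L, 16, 24); m[4:9, 6:14] <- 1L
  mask <- annotation_mask(m, rs, scorer_id = "S2", seizure_id = "Z03",
                          condition = "LD", confidence = 4,
                          multifocal = FALSE)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  back <- read_mask(path)
  expect_equal(back$pixels, mask$pixels)
  expect_equal(back$scorer_id, "S2")
  expect_equal(back$condition, "LD")
  expect_equal(back$confidence, 4L)
})
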