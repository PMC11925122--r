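#' Electrode-spacing simulation configuration
#'
#' Configures the spatial-sampling simulation: nested regular lattices of
#' contact positions at several spacings (default 1, 5, 10 mm: very high
#' density, HD, LD), a spherical "true" SOZ swept over radii, and a volume
#' estimator for the SOZ implied by the contacts that fall inside the
#' sphere.
#'
#' @param spacings_mm Lattice spacings in mm; coarser spacings must be
#'   integer multiples of finer ones so the lattices nest.
#' @param extent_mm Half-width of the cubic lattice (lattice spans
#'   `[-extent_mm, extent_mm]` on each axis); must contain the largest
#'   sphere.
#' @param sphere_center Centre of the true SOZ sphere (mm).
#' @param radii_mm Radii of the true SOZ sweep (mm).
#' @param volume_estimator `"convex_hull"` (default) or `"voxel_union"`
#'   (union of spacing-sized cells around positive contacts).
#' @param center_jitter_mm SD of an optional random offset of the sphere
#'   centre (off-lattice centring); 0 keeps the centre fixed.
#' @param seed RNG seed for the centre jitter.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(spacings_mm = c(1, 5, 10), extent_mm = 40,
                       sphere_center = c(0, 0, 0),
                       radii_mm = seq(8, 40, by = 2),
                       volume_estimator = c("convex_hull", "voxel_union"),
                       center_jitter_mm = 0, seed = NULL) {
  volume_estimator <- match.arg(volume_estimator)
  spacings_mm <- sort(as.numeric(spacings_mm))
  if (any(spacings_mm <= 0)) stop("spacings must be positive", call. = FALSE)
  if (any(radii_mm <= 0)) stop("radii must be positive", call. = FALSE)
  for (i in seq_along(spacings_mm)[-1]) {
    r <- spacings_mm[i] / spacings_mm[1]
    if (abs(r - round(r)) > 1e-9) {
      stop("coarser spacings must be integer multiples of the finest",
           call. = FALSE)
    }
  }
  if (max(radii_mm) + max(abs(sphere_center)) + center_jitter_mm * 4 >
      extent_mm + 1e-9) {
    stop("lattice extent must contain the largest sphere", call. = FALSE)
  }
  structure(list(spacings_mm = spacings_mm, extent_mm = extent_mm,
                 sphere_center = as.numeric(sphere_center),
                 radii_mm = as.numeric(radii_mm),
                 volume_estimator = volume_estimator,
                 center_jitter_mm = center_jitter_mm, seed = seed),
            class = "sim_config")
}

#' Build nested contact lattices
#'
#' One cubic lattice per spacing, all sharing the origin, so every coarser
#' lattice is an exact subset of every finer one.
#'
#' @param cfg A `sim_config`.
#' @return Named list (by spacing) of n x 3 position matrices.
#' @export
build_nested_lattices <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- lapply(cfg$spacings_mm, function(s) {
    ax <- seq(-floor(cfg$extent_mm / s) * s, floor(cfg$extent_mm / s) * s,
              by = s)
    as.matrix(expand.grid(x = ax, y = ax, z = ax))
  })
  names(out) <- as.character(cfg$spacings_mm)
  out
}

#' Contacts inside the true SOZ sphere
#'
#' @param lattice n x 3 matrix of contact positions.
#' @param center Sphere centre (mm).
#' @param radius Sphere radius (mm).
#' @return Matrix of the positions with Euclidean distance <= radius.
#' @export
positive_contacts <- function(lattice, center, radius) {
  d2 <- (lattice[, 1] - center[1])^2 + (lattice[, 2] - center[2])^2 +
    (lattice[, 3] - center[3])^2
  lattice[d2 <= radius^2 + 1e-12, , drop = FALSE]
}

# Drop points strictly between two others in the same (x, y) column; such
# points are convex combinations and never hull vertices.
prune_z_extremes <- function(pts) {
  if (nrow(pts) < 8L) return(pts)
  key <- paste(pts[, 1], pts[, 2], sep = "|")
  ord <- order(key, pts[, 3])
  pts <- pts[ord, , drop = FALSE]
  key <- key[ord]
  keep <- !duplicated(key) | !duplicated(key, fromLast = TRUE)
  pts[keep, , drop = FALSE]
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex-hull volume of a 3D point set
#'
#' Incremental convex hull with outward-oriented facets; returns 0 for
#' fewer than 4 non-coplanar points. Points within `eps` of the running
#' hull are treated as interior, which changes the volume by at most
#' O(eps * surface area).
#'
#' @param points n x 3 numeric matrix.
#' @return Hull volume (mm^3 for mm coordinates).
#' @export
convex_hull_volume <- function(points) {
  pts <- unique(rbind(points))
  if (nrow(pts) < 4L) return(0)
  pts <- prune_z_extremes(pts)
  ctr0 <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr0))$d
  diam <- 2 * sv[1] / sqrt(nrow(pts)) + max(abs(pts)) # scale reference
  if (sv[3] < 1e-9 * max(sv[1], 1)) return(0)         # coplanar
  eps <- 1e-9 * max(diam, 1)

  # initial tetrahedron: spread-out extremes
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) return(0)
  ab <- pts[i2, ] - pts[i1, ]
  t3 <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(t3[, 2] * ab[3] - t3[, 3] * ab[2],
              t3[, 3] * ab[1] - t3[, 1] * ab[3],
              t3[, 1] * ab[2] - t3[, 2] * ab[1])
  i3 <- which.max(rowSums(cr^2))
  n0 <- cross3(ab, pts[i3, ] - pts[i1, ])
  h <- abs(as.numeric(t3 %*% n0))
  i4 <- which.max(h)
  if (h[i4] < eps) return(0)
  o <- colMeans(pts[c(i1, i2, i3, i4), ])  # interior reference point

  make_facets <- function(tris) {
    # tris: k x 3 vertex indices; returns oriented (outward) facet data
    V <- matrix(0, nrow(tris), 3); B <- numeric(nrow(tris))
    for (r in seq_len(nrow(tris))) {
      a <- pts[tris[r, 1], ]; b <- pts[tris[r, 2], ]; cc <- pts[tris[r, 3], ]
      n <- cross3(b - a, cc - a)
      nl <- vec_norm(n)
      if (nl < 1e-14) { V[r, ] <- NA; next }
      n <- n / nl
      bb <- sum(n * a)
      if (sum(n * o) > bb) { n <- -n; bb <- -bb; tris[r, 2:3] <- tris[r, 3:2] }
      V[r, ] <- n; B[r] <- bb
    }
    list(tris = tris, N = V, b = B)
  }

  f <- make_facets(rbind(c(i1, i2, i3), c(i1, i2, i4),
                         c(i1, i3, i4), c(i2, i3, i4)))
  tris <- f$tris; N <- f$N; b <- f$b
  done <- c(i1, i2, i3, i4)
  rest <- setdiff(seq_len(nrow(pts)), done)
  d2o <- rowSums(sweep(pts, 2, o)^2)
  rest <- rest[order(-d2o[rest])]  # extremes first: interior rejected sooner

  for (pi in rest) {
    p <- pts[pi, ]
    viol <- as.numeric(N %*% p) - b
    vis <- which(viol > eps)
    if (length(vis) == 0L) next
    vis_tris <- tris[vis, , drop = FALSE]
    edges <- rbind(vis_tris[, c(1, 2)], vis_tris[, c(2, 3)],
                   vis_tris[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]),
                  pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    if (nrow(horizon) < 3L) next  # numerically inconsistent; skip point
    newf <- make_facets(cbind(horizon, pi))
    if (anyNA(newf$N)) next      # degenerate facet; skip point
    keep <- setdiff(seq_len(nrow(tris)), vis)
    tris <- rbind(tris[keep, , drop = FALSE], newf$tris)
    N <- rbind(N[keep, , drop = FALSE], newf$N)
    b <- c(b[keep], newf$b)
  }

  vol <- 0
  for (r in seq_len(nrow(tris))) {
    a <- pts[tris[r, 1], ] - o; bb <- pts[tris[r, 2], ] - o
    cc <- pts[tris[r, 3], ] - o
    vol <- vol + abs(sum(a * cross3(bb, cc))) / 6
  }
  vol
}

#' Estimated SOZ volume from positive contacts
#'
#' @param positions n x 3 positions of contacts inside the true SOZ.
#' @param estimator `"convex_hull"` (volume of the convex hull; 0 for fewer
#'   than 4 non-coplanar points) or `"voxel_union"` (n * spacing^3).
#' @param spacing_mm Required for the voxel-union estimator.
#' @return Estimated volume in mm^3.
#' @export
estimated_volume <- function(positions, estimator = "convex_hull",
                             spacing_mm = NULL) {
  estimator <- match.arg(estimator, c("convex_hull", "voxel_union"))
  if (estimator == "convex_hull") {
    convex_hull_volume(positions)
  } else {
    if (is.null(spacing_mm)) {
      stop("voxel_union needs spacing_mm", call. = FALSE)
    }
    nrow(rbind(positions)) * spacing_mm^3
  }
}

#' Run the electrode-spacing volume sweep
#'
#' For every radius of the true spherical SOZ and every lattice spacing:
#' count the positive contacts, estimate the SOZ volume, and compare with
#' the true volume `(4/3) pi r^3` and between the 5 mm (HD) and 10 mm (LD)
#' conditions.
#'
#' @param cfg A `sim_config`.
#' @return A data.frame of class `sim_result` with columns `radius_mm`,
#'   `spacing_mm`, `n_positive`, `v_est_mm3`, `v_true_mm3`, `pct_vs_true`
#'   (100 * (V_est - V_true) / V_true) and `pct_hd_vs_ld`
#'   (100 * (V_5mm - V_10mm) / V_10mm, `NA` where V_10mm is 0 or the
#'   spacings are absent).
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  center <- cfg$sphere_center
  if (cfg$center_jitter_mm > 0) {
    center <- center + with_seed(cfg$seed %||% 1L,
                                 stats::rnorm(3, sd = cfg$center_jitter_mm))
  }
  lattices <- build_nested_lattices(cfg)
  rows <- list()
  for (r in cfg$radii_mm) {
    if (r + max(abs(center)) > cfg$extent_mm + 1e-9) {
      stop("sphere exceeds lattice extent", call. = FALSE)
    }
    v_true <- 4 / 3 * pi * r^3
    v_by_spacing <- numeric(length(cfg$spacings_mm))
    for (k in seq_along(cfg$spacings_mm)) {
      s <- cfg$spacings_mm[k]
      pos <- positive_contacts(lattices[[as.character(s)]], center, r)
      v_est <- estimated_volume(pos, cfg$volume_estimator, spacing_mm = s)
      v_by_spacing[k] <- v_est
      rows[[length(rows) + 1L]] <- data.frame(
        radius_mm = r, spacing_mm = s, n_positive = nrow(pos),
        v_est_mm3 = v_est, v_true_mm3 = v_true,
        pct_vs_true = 100 * (v_est - v_true) / v_true)
    }
    i5 <- match(5, cfg$spacings_mm); i10 <- match(10, cfg$spacings_mm)
    pct <- if (!is.na(i5) && !is.na(i10) && v_by_spacing[i10] > 0) {
      100 * (v_by_spacing[i5] - v_by_spacing[i10]) / v_by_spacing[i10]
    } else NA_real_
    for (j in seq_along(cfg$spacings_mm)) {
      rows[[length(rows) - length(cfg$spacings_mm) + j]]$pct_hd_vs_ld <- pct
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sim_result", "data.frame")
  out
}

#' Write sweep results to CSV
#'
#' @param result A `sim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
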