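# Shared fixture builders; everything is generated in code at test time.

rms <- function(v) sqrt(mean(v^2))

small_raster <- function(width = 120L, height = 90L) {
  list(width = width, height = height, view_id = "test")
}

# A small HD grid centred near the origin plus its seizure recording.
small_seizure <- function(seed = 1L, fs_hz = 512, duration_s = 16,
                          onset_s = 8, noise_sd = 2, rows = 4L, cols = 4L) {
  grid <- build_grid_array(rows, cols, 4, origin = c(0, 0, 20),
                           array_id = "G")
  cfg <- seizure_sim_config(focus = c(0, 0, 20), onset_s = onset_s,
                            fs_hz = fs_hz, duration_s = duration_s,
                            noise_sd = noise_sd, seed = seed)
  list(grid = grid, cfg = cfg,
       rec = generate_seizure_recording(grid, cfg))
}

# Mask from explicit 0/1 matrix on its own raster.
mask_of <- function(m, ...) {
  annotation_mask(m, list(width = ncol(m), height = nrow(m)), ...)
}

# Voxel-counting oracle for the convex-hull volume, independent of the
# package's incremental algorithm: enumerate all supporting planes by brute
# force over point triples (all other points on one side), then count voxel
# centres that satisfy every half-space.
voxel_hull_volume <- function(pts, res = 0.1) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) return(0)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    u <- b - a; v <- cc - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-12) next
    nrm <- nrm / nl
    s <- as.numeric(pts %*% nrm) - sum(nrm * a)
    if (all(s <= 1e-9)) {
      planes[[length(planes) + 1L]] <- c(nrm, sum(nrm * a))
    } else if (all(s >= -1e-9)) {
      planes[[length(planes) + 1L]] <- c(-nrm, -sum(nrm * a))
    }
  }
  P <- unique(round(do.call(rbind, planes), 7))
  ax <- lapply(1:3, function(d) {
    seq(min(pts[, d]) + res / 2, max(pts[, d]), by = res)
  })
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  s <- vox %*% t(P[, 1:3]) - rep(P[, 4], each = nrow(vox))
  sum(apply(s <= 1e-9, 1, all)) * res^3
}
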