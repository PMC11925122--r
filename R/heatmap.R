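#' Line-length transform
#'
#' Seizure-intensity surrogate: per channel, the sum of absolute
#' consecutive-sample differences over a trailing (causal) window,
#' evaluated every `hop_s` seconds. The first full frame ends at
#' `t = window_s`.
#'
#' @param rec An `iceeg_recording`.
#' @param window_s Window length in seconds (>= 2 samples).
#' @param hop_s Hop between frame ends in seconds.
#' @return An object of class `line_length_series`: list with `values`
#'   (channels x frames, microvolts per window), `window_s`, `hop_s`,
#'   `frame_times_s` (window end times), `frame_end_samples`, `fs_hz`,
#'   `channel_labels`, `zscored` flag.
#' @examples
#' rec <- iceeg_recording(matrix(rep(0:1, 50), nrow = 1), fs_hz = 10,
#'                        channel_labels = "a", onset_sample = 90,
#'                        baseline_window = c(1, 80))
#' ll <- line_length(rec, window_s = 0.5, hop_s = 0.1)
#' ll$values[1, 1]  # 4 unit steps in a 5-sample window
#' @export
line_length <- function(rec, window_s = 1, hop_s = 0.1) {
  stopifnot(inherits(rec, "iceeg_recording"))
  w <- round(window_s * rec$fs_hz)
  hop <- max(1L, round(hop_s * rec$fs_hz))
  n <- ncol(rec$data)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (w > n) stop("window longer than recording", call. = FALSE)
  ends <- seq.int(w, n, by = hop)
  # cumulative |first difference|, so each trailing window is a difference
  # of two cumulative sums
  absdiff <- abs(rec$data[, -1L, drop = FALSE] - rec$data[, -n, drop = FALSE])
  cs <- cbind(0, t(apply(absdiff, 1, cumsum)))  # cs[, k+1] = sum of first k diffs
  # window ending at sample e covers diffs (e-w+1)..(e-1), i.e. w-1 diffs
  vals <- cs[, ends, drop = FALSE] - cs[, ends - w + 1L, drop = FALSE]
  structure(
    list(values = vals, window_s = w / rec$fs_hz, hop_s = hop / rec$fs_hz,
         frame_times_s = ends / rec$fs_hz, frame_end_samples = ends,
         fs_hz = rec$fs_hz, channel_labels = rec$channel_labels,
         zscored = FALSE),
    class = "line_length_series")
}

#' Z-score line length to a pre-ictal baseline
#'
#' Normalises each channel's line-length series to the mean and SD of the
#' frames whose windows lie entirely within the baseline window, making
#' intensities comparable across channels.
#'
#' @param ll A `line_length_series`.
#' @param baseline_window Integer `c(start, end)` sample indices (at the
#'   recording's sampling rate) of the pre-ictal baseline.
#' @param min_frames Minimum number of baseline frames required.
#' @return A `line_length_series` with `zscored = TRUE` and attributes
#'   `baseline_mean`, `baseline_sd` per channel.
#' @export
zscore_to_baseline <- function(ll, baseline_window, min_frames = 10L) {
  stopifnot(inherits(ll, "line_length_series"))
  if (isTRUE(ll$zscored)) stop("series is already z-scored", call. = FALSE)
  w <- round(ll$window_s * ll$fs_hz)
  in_base <- ll$frame_end_samples - w + 1L >= baseline_window[1] &
    ll$frame_end_samples <= baseline_window[2]
  if (sum(in_base) < min_frames) {
    stop(sprintf("baseline contains %d frames; >= %d required",
                 sum(in_base), min_frames), call. = FALSE)
  }
  base <- ll$values[, in_base, drop = FALSE]
  mu <- rowMeans(base)
  sd <- apply(base, 1, stats::sd)
  bad <- sd <= 0
  if (any(bad)) {
    stop("zero baseline SD on channel(s): ",
         paste(ll$channel_labels[bad], collapse = ", "),
         " (exclude these channels first)", call. = FALSE)
  }
  ll$values <- (ll$values - mu) / sd
  ll$zscored <- TRUE
  ll$baseline_mean <- mu
  ll$baseline_sd <- sd
  ll$baseline_frames <- which(in_base)
  ll
}

#' Gaussian maximum projection of electrode intensities onto targets
#'
#' Assigns each target point (mesh vertex or slice pixel) the maximum, over
#' all contacts within `cutoff_mm`, of the contact's intensity attenuated by
#' a distance-based Gaussian drop-off `exp(-d^2 / (2 sigma^2))`. The
#' drop-off is applied before the maximum so distance still matters; targets
#' with no contact in range get 0. Negative z-scores are retained here and
#' clamped to 0 only at display time.
#'
#' @param z Numeric vector: one intensity (z-score) per contact.
#' @param contacts Numeric n x 3 contact positions (mm).
#' @param targets Numeric m x 3 target positions (mm).
#' @param sigma_mm Gaussian kernel width in mm.
#' @param cutoff_mm Maximum contact-target distance considered "in the
#'   vicinity".
#' @return Numeric vector of length m of projected intensities.
#' @export
project_max_gaussian <- function(z, contacts, targets, sigma_mm = 5,
                                 cutoff_mm = 15) {
  contacts <- rbind(contacts)
  targets <- rbind(targets)
  if (nrow(contacts) == 0L) stop("empty contact list", call. = FALSE)
  if (sigma_mm <= 0) stop("sigma_mm must be positive", call. = FALSE)
  if (length(z) != nrow(contacts)) {
    stop("one intensity per contact required", call. = FALSE)
  }
  m <- nrow(targets)
  out <- numeric(m)
  chunk <- max(1L, floor(2e6 / nrow(contacts)))
  for (s in seq.int(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    tg <- targets[s:e, , drop = FALSE]
    d2 <- outer(rowSums(tg^2), rowSums(contacts^2), `+`) -
      2 * tg %*% t(contacts)
    d2[d2 < 0] <- 0
    vals <- sweep(exp(-d2 / (2 * sigma_mm^2)), 2, z, `*`)
    vals[d2 > cutoff_mm^2] <- -Inf
    mx <- apply(vals, 1, max)
    mx[!is.finite(mx)] <- 0
    out[s:e] <- mx
  }
  out
}

#' Heatmap frame
#'
#' Per-vertex (or per-pixel) z-scored seizure intensity at one time point.
#'
#' @param vertex_values Numeric vector, one value per mesh vertex.
#' @param frame_time_s Time of the frame in seconds.
#' @param scale_lims Colour-scale bounds `c(lo, hi)`.
#' @return An object of class `heatmap_frame`.
#' @export
heatmap_frame <- function(vertex_values, frame_time_s, scale_lims = c(0, 8)) {
  if (!all(is.finite(vertex_values))) {
    stop("vertex values must be finite", call. = FALSE)
  }
  structure(list(vertex_values = as.numeric(vertex_values),
                 frame_time_s = frame_time_s, scale_lims = scale_lims),
            class = "heatmap_frame")
}

# Map intensities (clamped at 0 for display) to RGB through a dark-to-hot
# ramp; returns an n x 3 matrix in [0, 1].
heat_colours <- function(vals, lims) {
  v <- pmin(pmax((pmax(vals, 0) - lims[1]) / (lims[2] - lims[1]), 0), 1)
  ramp <- grDevices::colorRamp(c("grey25", "red", "yellow", "white"))
  ramp(v) / 255
}

#' Render a surface heatmap frame
#'
#' Orthographic projection of the mesh along a view axis onto a raster, with
#' per-pixel nearest-to-viewer vertex colouring. When `blinded = TRUE` (the
#' study's presentation mode) no electrode glyphs and no condition metadata
#' are drawn; only the heat layer and the frame time remain, so scorers
#' cannot infer the density condition.
#'
#' @param mesh A `surface_mesh`.
#' @param frame A `heatmap_frame` with one value per mesh vertex.
#' @param blinded Hide electrode locations and condition metadata.
#' @param contacts Optional contact positions, drawn only when
#'   `blinded = FALSE`.
#' @param view Projection axis: `"lateral"` (along x), `"frontal"` (along y)
#'   or `"axial"` (along z).
#' @param width,height Raster size in pixels.
#' @param condition Optional condition label, stored in metadata only when
#'   not blinded.
#' @return An object of class `heatmap_image`: list with `rgb`
#'   (height x width x 3 array), `heat` (height x width raster of projected
#'   intensities), `layers` (manifest of drawn layers), `frame_time_s`,
#'   `blinded`, `metadata`.
#' @export
render_surface_frame <- function(mesh, frame, blinded = TRUE,
                                 contacts = NULL, view = "lateral",
                                 width = 160L, height = 120L,
                                 condition = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "heatmap_frame"))
  if (length(frame$vertex_values) != nrow(mesh$vertices)) {
    stop("frame does not match mesh vertex count", call. = FALSE)
  }
  ax <- match.arg(view, c("lateral", "frontal", "axial"))
  dims <- switch(ax, lateral = c(2L, 3L, 1L), frontal = c(1L, 3L, 2L),
                 axial = c(1L, 2L, 3L))
  V <- mesh$vertices
  uv <- V[, dims[1:2], drop = FALSE]
  depth <- V[, dims[3]]
  rng <- apply(uv, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  px <- pmin(pmax(ceiling((uv[, 1] - rng[1, 1]) / span[1] * (width - 1)) + 1L, 1L), width)
  py <- pmin(pmax(ceiling((rng[2, 2] - uv[, 2]) / span[2] * (height - 1)) + 1L, 1L), height)
  heat <- matrix(NA_real_, height, width)
  zbuf <- matrix(-Inf, height, width)
  ord <- order(depth)  # draw far first, near last
  for (k in ord) {
    if (depth[k] >= zbuf[py[k], px[k]]) {
      zbuf[py[k], px[k]] <- depth[k]
      heat[py[k], px[k]] <- frame$vertex_values[k]
    }
  }
  rgb <- array(0.08, dim = c(height, width, 3))  # background
  filled <- which(!is.na(heat))
  if (length(filled) > 0L) {
    cols <- heat_colours(heat[filled], frame$scale_lims)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[filled] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  layers <- "heat"
  if (!blinded && !is.null(contacts)) {
    contacts <- rbind(contacts)
    cu <- contacts[, dims[1], drop = TRUE]
    cv <- contacts[, dims[2], drop = TRUE]
    cx <- pmin(pmax(ceiling((cu - rng[1, 1]) / span[1] * (width - 1)) + 1L, 1L), width)
    cy <- pmin(pmax(ceiling((rng[2, 2] - cv) / span[2] * (height - 1)) + 1L, 1L), height)
    for (k in seq_along(cx)) {
      rgb[cy[k], cx[k], ] <- c(0, 1, 1)  # electrode glyph
    }
    layers <- c(layers, "electrodes")
  }
  metadata <- list(frame_time_s = frame$frame_time_s)
  if (!blinded && !is.null(condition)) metadata$condition <- condition
  structure(list(rgb = rgb, heat = heat, layers = layers,
                 frame_time_s = frame$frame_time_s, blinded = blinded,
                 metadata = metadata),
            class = "heatmap_image")
}

#' Render an omni-planar slice frame
#'
#' Samples the slice plane on a pixel grid, evaluates the Gaussian maximum
#' projection at each pixel's 3D position, and colour-maps the result over
#' an optional grey-matter background field.
#'
#' @param plane An `omniplanar_plane`.
#' @param contacts Numeric n x 3 contact positions (mm).
#' @param z Numeric vector of per-contact intensities.
#' @param sigma_mm,cutoff_mm Projection kernel parameters.
#' @param anatomy_field Optional function `f(points)` returning a grey-level
#'   in [0, 1] for each 3D point, drawn beneath the heat layer.
#' @param scale_lims Colour-scale bounds.
#' @return A `heatmap_image` whose `heat` matrix holds the raw projected
#'   values on the slice pixel grid; `pixel_positions` carries the 3D
#'   position of every pixel centre (row-major, n_pixels x 3).
#' @export
render_omniplanar_frame <- function(plane, contacts, z, sigma_mm = 5,
                                    cutoff_mm = 15, anatomy_field = NULL,
                                    scale_lims = c(0, 8)) {
  stopifnot(inherits(plane, "omniplanar_plane"))
  if (plane$res_mm <= 0) stop("zero-resolution plane", call. = FALSE)
  us <- seq(-plane$extent_mm, plane$span_mm + plane$extent_mm,
            by = plane$res_mm)
  vs <- seq(-plane$extent_mm, plane$extent_mm, by = plane$res_mm)
  if (length(us) == 0L || length(vs) == 0L) {
    stop("zero-resolution plane", call. = FALSE)
  }
  grid <- expand.grid(u = us, v = vs)
  pts <- outer(grid$u, plane$u) + outer(grid$v, plane$v)
  pts <- sweep(pts, 2, plane$origin, `+`)
  heat_v <- project_max_gaussian(z, contacts, pts, sigma_mm, cutoff_mm)
  heat <- matrix(heat_v, nrow = length(vs), ncol = length(us), byrow = TRUE)
  rgb <- array(0.08, dim = c(length(vs), length(us), 3))
  if (!is.null(anatomy_field)) {
    grey <- matrix(pmin(pmax(anatomy_field(pts), 0), 1),
                   nrow = length(vs), byrow = TRUE)
    for (ch in 1:3) rgb[, , ch] <- grey
  }
  cols <- heat_colours(as.vector(heat), scale_lims)
  visible <- pmax(as.vector(heat), 0) > 0
  for (ch in 1:3) {
    plane_ch <- rgb[, , ch]
    plane_ch[visible] <- cols[visible, ch]
    rgb[, , ch] <- plane_ch
  }
  structure(list(rgb = rgb, heat = heat, layers = "heat",
                 frame_time_s = NA_real_, blinded = TRUE,
                 pixel_positions = pts,
                 metadata = list(array_id = plane$array_id)),
            class = "heatmap_image")
}

#' Write a rendered frame to PNG
#'
#' @param img A `heatmap_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  stopifnot(inherits(img, "heatmap_image"))
  png::writePNG(img$rgb, path)
  invisible(path)
}
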