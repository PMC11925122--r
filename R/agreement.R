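#' Annotation mask
#'
#' One scorer's SOZ annotation as a binary raster, plus the scoring context:
#' condition (HD/LD), five-point Likert confidence, and whether the scorer
#' called the SOZ multifocal.
#'
#' @param pixels Integer/logical matrix (height x width), values 0/1.
#' @param raster_spec List with at least `width`, `height` and optionally a
#'   `view_id`; masks may only be compared when their raster_spec matches.
#' @param scorer_id,seizure_id Identifiers (may be `NA`).
#' @param condition `"HD"`, `"LD"` or `NA`.
#' @param confidence Integer 1-5 Likert confidence or `NA`.
#' @param multifocal Logical flag.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(pixels, raster_spec, scorer_id = NA,
                            seizure_id = NA, condition = NA,
                            confidence = NA, multifocal = FALSE) {
  pixels <- matrix(as.integer(pixels), nrow = nrow(pixels))
  if (!all(pixels %in% c(0L, 1L))) {
    stop("mask pixels must be 0/1", call. = FALSE)
  }
  if (nrow(pixels) != raster_spec$height || ncol(pixels) != raster_spec$width) {
    stop("pixel matrix does not match raster_spec", call. = FALSE)
  }
  if (!is.na(confidence) && !(confidence %in% 1:5)) {
    stop("confidence must be in 1..5", call. = FALSE)
  }
  if (!is.na(condition)) condition <- match.arg(condition, c("HD", "LD"))
  structure(list(pixels = pixels, raster_spec = raster_spec,
                 scorer_id = scorer_id, seizure_id = seizure_id,
                 condition = condition, confidence = confidence,
                 multifocal = isTRUE(multifocal)),
            class = "annotation_mask")
}

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask> %dx%d, %d pixels set (%.1f%%)",
              x$raster_spec$height, x$raster_spec$width, sum(x$pixels),
              100 * mean(x$pixels)))
  if (!is.na(x$scorer_id)) cat(sprintf("; scorer %s", x$scorer_id))
  if (!is.na(x$condition)) cat(sprintf("; %s", x$condition))
  cat("\n")
  invisible(x)
}

same_raster <- function(a, b) {
  identical(a$raster_spec[c("width", "height")],
            b$raster_spec[c("width", "height")])
}

# Even-odd (crossing-number) test of pixel centres against one ring.
# Points are pixel centres (col - 0.5, row - 0.5) in raster coordinates,
# origin top-left, x right, y down. Vectorised over points.
ring_crossings <- function(xp, yp, ring) {
  nv <- nrow(ring)
  inside <- logical(length(xp))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > yp) != (yj > yp)) &
      (xp < (xj - xi) * (yp - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise annotation polygons to a binary mask
#'
#' Fills each polygon ring by the even-odd rule (a pixel is counted when its
#' centre is inside) and ORs the rings together, so multifocal annotations
#' with several rings produce one mask. Ring coordinates are in raster pixel
#' units, 0-based, origin at the top-left corner; vertices outside the
#' raster are clipped to its bounds.
#'
#' @param polygons List of numeric n x 2 matrices (x, y vertex rings with
#'   >= 3 vertices each). An empty list gives an all-zero mask.
#' @param raster_spec List with `width` and `height` (pixels).
#' @param ... Passed to [annotation_mask()] (scorer, condition, ...).
#' @return An `annotation_mask`.
#' @export
rasterize_polygons <- function(polygons, raster_spec, ...) {
  W <- raster_spec$width; H <- raster_spec$height
  px <- matrix(0L, H, W)
  for (ring in polygons) {
    ring <- rbind(ring)
    if (nrow(ring) < 3L) stop("polygon rings need >= 3 vertices", call. = FALSE)
    ring[, 1] <- pmin(pmax(ring[, 1], 0), W)
    ring[, 2] <- pmin(pmax(ring[, 2], 0), H)
    # only pixels inside the ring's bounding box can be covered
    cols <- seq.int(max(1L, floor(min(ring[, 1]) + 0.5)),
                    min(W, ceiling(max(ring[, 1]) + 0.5)))
    rws <- seq.int(max(1L, floor(min(ring[, 2]) + 0.5)),
                   min(H, ceiling(max(ring[, 2]) + 0.5)))
    centres <- expand.grid(x = cols - 0.5, y = rws - 0.5)
    inside <- ring_crossings(centres$x, centres$y, ring)
    sub <- px[rws, cols, drop = FALSE]
    sub[matrix(inside, length(rws), length(cols), byrow = TRUE)] <- 1L
    px[rws, cols] <- sub
  }
  annotation_mask(px, raster_spec, ...)
}

#' Unweighted Cohen's kappa between two annotation masks
#'
#' Chance-corrected agreement over ALL pixels in the raster: each pixel is
#' classified highlighted/not by each scorer, and
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (n11 + n00) / N` and chance agreement
#' `p_e = p_a p_b + (1 - p_a)(1 - p_b)`. When `p_e = 1` (both masks empty or
#' both full) kappa is undefined and an error of class
#' `sozdensity_undefined_kappa` is raised; callers record such pairs as
#' missing, never as zero.
#'
#' @param a,b `annotation_mask` objects on the same raster.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(inherits(a, "annotation_mask"), inherits(b, "annotation_mask"))
  if (!same_raster(a, b)) stop("masks have different raster_spec", call. = FALSE)
  N <- length(a$pixels)
  n11 <- sum(a$pixels == 1L & b$pixels == 1L)
  n00 <- sum(a$pixels == 0L & b$pixels == 0L)
  pa <- sum(a$pixels) / N
  pb <- sum(b$pixels) / N
  po <- (n11 + n00) / N
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (1 - pe < .Machine$double.eps) {
    stop(errorCondition(
      "kappa undefined: chance agreement is 1 (both masks empty or both full)",
      class = "sozdensity_undefined_kappa"))
  }
  (po - pe) / (1 - pe)
}

#' Pairwise Cohen's kappa across scorers
#'
#' One kappa per unordered scorer pair for one seizure and condition:
#' `choose(n, 2)` results (15 pairs for the study's 6 scorers). Undefined
#' kappas propagate as `NA`.
#'
#' @param masks List of `annotation_mask` objects, one per scorer, same
#'   seizure and condition.
#' @return A data.frame of class `kappa_results` with columns `scorer_a`,
#'   `scorer_b`, `seizure_id`, `condition`, `kappa`.
#' @export
pairwise_kappa <- function(masks) {
  n <- length(masks)
  if (n < 2L) stop("need >= 2 scorers", call. = FALSE)
  ids <- vapply(seq_len(n), function(i) {
    id <- masks[[i]]$scorer_id
    if (is.na(id)) as.character(i) else as.character(id)
  }, "")
  pairs <- utils::combn(n, 2)
  res <- data.frame(
    scorer_a = ids[pairs[1, ]], scorer_b = ids[pairs[2, ]],
    seizure_id = masks[[1]]$seizure_id, condition = masks[[1]]$condition,
    kappa = apply(pairs, 2, function(p) {
      tryCatch(cohen_kappa(masks[[p[1]]], masks[[p[2]]]),
               sozdensity_undefined_kappa = function(e) NA_real_)
    }),
    stringsAsFactors = FALSE)
  class(res) <- c("kappa_results", "data.frame")
  res
}

#' Intra-rater kappa: HD vs LD annotations of the same scorer
#'
#' @param hd_mask,ld_mask `annotation_mask` objects from the same scorer and
#'   seizure under the two conditions.
#' @return A one-row `kappa_results` data.frame (condition `"HDvsLD"`);
#'   `kappa` is `NA` when undefined.
#' @export
intra_rater_kappa <- function(hd_mask, ld_mask) {
  k <- tryCatch(cohen_kappa(hd_mask, ld_mask),
                sozdensity_undefined_kappa = function(e) NA_real_)
  res <- data.frame(scorer_a = as.character(hd_mask$scorer_id),
                    scorer_b = as.character(ld_mask$scorer_id),
                    seizure_id = hd_mask$seizure_id,
                    condition = "HDvsLD", kappa = k,
                    stringsAsFactors = FALSE)
  class(res) <- c("kappa_results", "data.frame")
  res
}

#' Does an annotation overlap the clinically determined SOZ?
#'
#' Any-pixel rule: `TRUE` iff the annotation and the clinical region share
#' at least one pixel, mirroring the "any or all of the SOZ anatomic areas"
#' criterion.
#'
#' @param mask,clinical_region `annotation_mask` objects on the same raster.
#' @return Logical flag.
#' @export
overlaps_clinical <- function(mask, clinical_region) {
  if (!same_raster(mask, clinical_region)) {
    stop("masks have different raster_spec", call. = FALSE)
  }
  any(mask$pixels == 1L & clinical_region$pixels == 1L)
}

#' Per-scorer mean pairwise kappa
#'
#' Average of one scorer's pairwise kappas with all other scorers (the
#' row average of the pairwise matrix); missing (undefined) entries are
#' excluded.
#'
#' @param results A `kappa_results` data.frame from [pairwise_kappa()].
#' @param scorer_id Scorer identifier.
#' @return Mean kappa (scalar; `NaN` when all entries are missing).
#' @export
scorer_mean_kappa <- function(results, scorer_id) {
  sel <- results$scorer_a == scorer_id | results$scorer_b == scorer_id
  mean(results$kappa[sel], na.rm = TRUE)
}

#' Read and write annotation masks
#'
#' Masks are stored as PNG (0/255 grey) with a JSON sidecar holding scorer,
#' seizure, condition, confidence and the multifocal flag.
#'
#' @param mask An `annotation_mask`.
#' @param png_path Output PNG path; the sidecar is written next to it with
#'   extension `.json`.
#' @return `png_path`, invisibly.
#' @export
write_mask <- function(mask, png_path) {
  png::writePNG(mask$pixels * 1.0, png_path)
  side <- sub("\\.png$", ".json", png_path)
  jsonlite::write_json(
    list(scorer_id = mask$scorer_id, seizure_id = mask$seizure_id,
         condition = mask$condition, confidence = mask$confidence,
         multifocal = mask$multifocal,
         raster_spec = mask$raster_spec),
    side, auto_unbox = TRUE, null = "null")
  invisible(png_path)
}

#' @rdname write_mask
#' @export
read_mask <- function(png_path) {
  img <- png::readPNG(png_path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side <- sub("\\.png$", ".json", png_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  annotation_mask(matrix(as.integer(img > 0.5), nrow = nrow(img)),
                  raster_spec = as.list(meta$raster_spec),
                  scorer_id = meta$scorer_id %||% NA,
                  seizure_id = meta$seizure_id %||% NA,
                  condition = meta$condition %||% NA,
                  confidence = meta$confidence %||% NA,
                  multifocal = isTRUE(meta$multifocal))
}

#' Write a kappa table to CSV
#'
#' @param results A `kappa_results` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kappa_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
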