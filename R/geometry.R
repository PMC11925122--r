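#' Electrode array objects
#'
#' An `electrode_array` describes the contact geometry of one implanted
#' array: a subdural grid, a subdural strip, or a stereotactic depth probe.
#' Contacts are 3D positions in millimetres, right-handed RAS frame
#' (x = right, y = anterior, z = superior). Grid contacts are stored
#' row-major; all indices in this package are 0-based to match the
#' row/column convention of the electrode table format.
#'
#' @param array_id Character scalar identifying the array.
#' @param kind One of `"grid"`, `"strip"`, `"depth"`.
#' @param contacts Numeric matrix, n x 3, contact positions in mm (RAS).
#' @param spacing_mm Positive inter-contact spacing in mm.
#' @param grid_shape Integer `c(rows, cols)` for grids; contact count for
#'   strips and depths.
#' @param channel_labels Character vector of channel labels, one per contact.
#'
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(array_id, kind, contacts, spacing_mm,
                            grid_shape, channel_labels = NULL) {
  kind <- match.arg(kind, c("grid", "strip", "depth"))
  contacts <- as.matrix(contacts)
  dimnames(contacts) <- NULL
  if (ncol(contacts) != 3L) stop("contacts must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(contacts))) stop("contact coordinates must be finite", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("spacing_mm must be a positive scalar", call. = FALSE)
  }
  n <- nrow(contacts)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("%s%02d", array_id, seq_len(n))
  }
  if (length(channel_labels) != n) {
    stop("channel_labels must have one entry per contact", call. = FALSE)
  }
  obj <- structure(
    list(array_id = as.character(array_id), kind = kind, contacts = contacts,
         spacing_mm = spacing_mm, grid_shape = as.integer(grid_shape),
         channel_labels = as.character(channel_labels)),
    class = "electrode_array")
  validate_electrode_array(obj)
  obj
}

#' Validate electrode array invariants
#'
#' Checks spacing between lattice/contact neighbours (tolerance 1e-6 mm),
#' grid shape consistency, and collinearity of depth probes.
#'
#' @param arr An `electrode_array`.
#' @param tol_mm Spacing tolerance in mm.
#' @return `arr`, invisibly; errors on violation.
#' @export
validate_electrode_array <- function(arr, tol_mm = 1e-6) {
  n <- nrow(arr$contacts)
  if (arr$kind == "grid") {
    if (length(arr$grid_shape) != 2L || prod(arr$grid_shape) != n) {
      stop("grid_shape rows*cols must equal number of contacts", call. = FALSE)
    }
    rows <- arr$grid_shape[1]; cols <- arr$grid_shape[2]
    idx <- function(i, j) i * cols + j + 1L  # row-major, 0-based (i, j)
    for (i in seq_len(rows) - 1L) for (j in seq_len(cols) - 1L) {
      if (j + 1L < cols) {
        d <- vec_norm(arr$contacts[idx(i, j + 1L), ] - arr$contacts[idx(i, j), ])
        if (abs(d - arr$spacing_mm) > tol_mm) {
          stop("adjacent same-row contacts not spacing_mm apart", call. = FALSE)
        }
      }
      if (i + 1L < rows) {
        d <- vec_norm(arr$contacts[idx(i + 1L, j), ] - arr$contacts[idx(i, j), ])
        if (abs(d - arr$spacing_mm) > tol_mm) {
          stop("adjacent same-column contacts not spacing_mm apart", call. = FALSE)
        }
      }
    }
  } else {
    if (n > 1L) {
      d <- sqrt(rowSums((arr$contacts[-1L, , drop = FALSE] -
                         arr$contacts[-n, , drop = FALSE])^2))
      if (any(abs(d - arr$spacing_mm) > tol_mm)) {
        stop("consecutive contacts not spacing_mm apart", call. = FALSE)
      }
    }
    if (arr$kind == "depth" && n > 2L) {
      centred <- sweep(arr$contacts, 2, colMeans(arr$contacts))
      sv <- svd(centred)$d
      if (sv[2] > tol_mm) stop("depth probe contacts not collinear", call. = FALSE)
    }
  }
  invisible(arr)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %s (%s): %d contacts, %.3g mm spacing\n",
              x$array_id, x$kind, nrow(x$contacts), x$spacing_mm))
  if (x$kind == "grid") {
    cat(sprintf("  grid shape %d x %d\n", x$grid_shape[1], x$grid_shape[2]))
  }
  invisible(x)
}

check_orthonormal <- function(a1, a2, tol = 1e-8) {
  if (abs(vec_norm(a1) - 1) > tol || abs(vec_norm(a2) - 1) > tol ||
      abs(sum(a1 * a2)) > tol) {
    stop("axes must be orthonormal unit vectors", call. = FALSE)
  }
}

#' Build a rectangular electrode grid
#'
#' Lays contacts row-major on the lattice `origin + i*spacing*a1 + j*spacing*a2`
#' with 0-based row index `i` and column index `j`. High-density subdural
#' grids have 4 mm spacing; clinical lower-density versions 8 mm.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param spacing_mm Inter-contact spacing in mm.
#' @param origin 3D position of contact (0, 0) in mm.
#' @param axes List of two orthonormal 3D unit vectors: row direction and
#'   column direction.
#' @param array_id Identifier for the array.
#' @return An `electrode_array` of kind `"grid"`.
#' @examples
#' g <- build_grid_array(2, 2, 4)
#' dist(g$contacts)
#' @export
build_grid_array <- function(rows, cols, spacing_mm,
                             origin = c(0, 0, 0),
                             axes = list(c(1, 0, 0), c(0, 1, 0)),
                             array_id = "G") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1", call. = FALSE)
  a1 <- as.numeric(axes[[1]]); a2 <- as.numeric(axes[[2]])
  check_orthonormal(a1, a2)
  ij <- expand.grid(j = seq_len(cols) - 1L, i = seq_len(rows) - 1L)  # row-major
  contacts <- outer(ij$i * spacing_mm, a1) + outer(ij$j * spacing_mm, a2)
  contacts <- sweep(contacts, 2, origin, `+`)
  electrode_array(array_id, "grid", contacts, spacing_mm, c(rows, cols))
}

#' Build a linear depth or strip electrode array
#'
#' Contacts are collinear from `entry` along `direction`, spanning
#' `(n_contacts - 1) * spacing_mm` mm. Depth probes in this study use 5 mm
#' spacing; subdural strips 10 mm.
#'
#' @param n_contacts Number of contacts (>= 1).
#' @param spacing_mm Inter-contact spacing in mm.
#' @param entry 3D position of the first contact in mm.
#' @param direction 3D direction vector (need not be unit length; must be
#'   nonzero).
#' @param array_id Identifier for the array.
#' @param kind `"depth"` (default) or `"strip"`.
#' @return An `electrode_array`.
#' @export
build_depth_array <- function(n_contacts, spacing_mm,
                              entry = c(0, 0, 0), direction = c(0, 0, 1),
                              array_id = "D", kind = c("depth", "strip")) {
  kind <- match.arg(kind)
  n_contacts <- as.integer(n_contacts)
  if (n_contacts < 1L) stop("n_contacts must be >= 1", call. = FALSE)
  u <- unit_vector(as.numeric(direction), "direction")
  contacts <- sweep(outer((seq_len(n_contacts) - 1L) * spacing_mm, u), 2,
                    as.numeric(entry), `+`)
  electrode_array(array_id, kind, contacts, spacing_mm,
                  grid_shape = n_contacts)
}

#' @rdname build_depth_array
#' @export
build_strip_array <- function(n_contacts, spacing_mm,
                              entry = c(0, 0, 0), direction = c(0, 0, 1),
                              array_id = "S") {
  build_depth_array(n_contacts, spacing_mm, entry, direction, array_id,
                    kind = "strip")
}

#' Omni-planar slice basis for a depth probe
#'
#' Builds the 2D slice plane that runs parallel to a depth probe's
#' trajectory, the view used to display deep seizure activity. The in-plane
#' axis `u` is the probe direction; `v` is obtained from `normal_hint` by
#' Gram-Schmidt orthogonalisation against `u`. The choice of plane roll about
#' the probe axis is a convention of this package (the hint vector); any
#' non-parallel hint yields a valid plane containing every contact.
#'
#' @param depth An `electrode_array` of kind `"depth"` with >= 2 contacts.
#' @param normal_hint 3D vector, not parallel to the probe axis.
#' @param extent_mm Half-extent of the slice in mm along each axis beyond the
#'   probe span.
#' @param res_mm Pixel size of the slice raster in mm.
#' @return An object of class `omniplanar_plane` with fields `origin`, `u`,
#'   `v`, `extent_mm`, `res_mm`.
#' @export
omniplanar_basis <- function(depth, normal_hint = c(1, 0, 0),
                             extent_mm = 20, res_mm = 1) {
  if (!inherits(depth, "electrode_array") || depth$kind != "depth") {
    stop("omniplanar_basis requires a depth electrode_array", call. = FALSE)
  }
  n <- nrow(depth$contacts)
  if (n < 2L) stop("depth probe must have >= 2 contacts", call. = FALSE)
  u <- unit_vector(depth$contacts[n, ] - depth$contacts[1, ], "probe axis")
  h <- as.numeric(normal_hint)
  v <- h - sum(h * u) * u
  if (vec_norm(v) < 1e-8) {
    stop("normal_hint is parallel to the probe axis: degenerate basis",
         call. = FALSE)
  }
  v <- v / vec_norm(v)
  span <- vec_norm(depth$contacts[n, ] - depth$contacts[1, ])
  structure(
    list(origin = depth$contacts[1, ], u = u, v = v,
         span_mm = span, extent_mm = extent_mm, res_mm = res_mm,
         array_id = depth$array_id),
    class = "omniplanar_plane")
}

#' Distance of points from an omni-planar plane
#'
#' @param plane An `omniplanar_plane`.
#' @param points Numeric n x 3 matrix.
#' @return Numeric vector of absolute out-of-plane distances (mm).
#' @export
plane_distance <- function(plane, points) {
  points <- rbind(points)
  normal <- c(plane$u[2] * plane$v[3] - plane$u[3] * plane$v[2],
              plane$u[3] * plane$v[1] - plane$u[1] * plane$v[3],
              plane$u[1] * plane$v[2] - plane$u[2] * plane$v[1])
  abs(as.numeric(sweep(points, 2, plane$origin) %*% normal))
}

#' Surface mesh
#'
#' Triangulated brain-surface mesh: vertex positions in mm and 0-based
#' triangle indices (stored 1-based internally, following R convention, but
#' read/written 0-based in PLY).
#'
#' @param vertices Numeric n x 3 matrix (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' Read / write ASCII PLY meshes
#'
#' Minimal ASCII PLY support for triangulated surfaces: `x y z` vertex
#' properties and triangular faces.
#'
#' @param path File path.
#' @return `read_ply`: a `surface_mesh`. `write_ply`: `path`, invisibly.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop("not a PLY file", call. = FALSE)
  }
  fmt <- trimws(lines[2])
  if (!grepl("^format ascii", fmt)) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  end_hdr <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(end_hdr)]
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  body <- lines[(end_hdr + 1L):length(lines)]
  vert <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])
  }))
  faces <- NULL
  if (!is.na(nf) && nf > 0L) {
    faces <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
      v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (v[1] != 3L) stop("only triangular faces are supported", call. = FALSE)
      v[2:4] + 1L
    }))
  } else {
    faces <- matrix(integer(0), ncol = 3L)
  }
  surface_mesh(vert, faces)
}

#' @rdname read_ply
#' @param mesh A `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v) paste(v, collapse = " ")), con)
  if (nrow(mesh$faces) > 0L) {
    writeLines(apply(mesh$faces - 1L, 1, function(f) paste(c(3L, f), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write electrode coordinate tables
#'
#' CSV with columns `label, x, y, z, array_id, kind, row, col` (`row`/`col`
#' empty for depths and strips). Coordinates in mm, RAS; `row`/`col` 0-based.
#'
#' @param path CSV file path.
#' @param spacing_mm Named numeric vector of per-array spacings; if `NULL`,
#'   spacing is inferred from consecutive-contact distances.
#' @return A named list of `electrode_array` objects.
#' @export
read_electrode_table <- function(path, spacing_mm = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "array_id", "kind")
  if (!all(need %in% names(df))) {
    stop("electrode table must have columns label, x, y, z, array_id, kind",
         call. = FALSE)
  }
  out <- list()
  for (aid in unique(df$array_id)) {
    sub <- df[df$array_id == aid, , drop = FALSE]
    kind <- sub$kind[1]
    contacts <- as.matrix(sub[, c("x", "y", "z")])
    if (kind == "grid") {
      rows <- max(sub$row) + 1L; cols <- max(sub$col) + 1L
      ord <- order(sub$row * cols + sub$col)
      sub <- sub[ord, , drop = FALSE]
      contacts <- contacts[ord, , drop = FALSE]
      shape <- c(rows, cols)
    } else {
      shape <- nrow(sub)
    }
    s <- if (!is.null(spacing_mm)) spacing_mm[[aid]] else {
      if (kind == "grid") {
        vec_norm(contacts[2, ] - contacts[1, ])
      } else if (nrow(contacts) > 1L) {
        vec_norm(contacts[2, ] - contacts[1, ])
      } else 1
    }
    out[[aid]] <- electrode_array(aid, kind, contacts, s, shape, sub$label)
  }
  out
}

#' @rdname read_electrode_table
#' @param arrays A list of `electrode_array` objects.
#' @export
write_electrode_table <- function(arrays, path) {
  rows <- lapply(arrays, function(a) {
    n <- nrow(a$contacts)
    if (a$kind == "grid") {
      cols <- a$grid_shape[2]
      r <- (seq_len(n) - 1L) %/% cols
      cl <- (seq_len(n) - 1L) %% cols
    } else {
      r <- rep(NA_integer_, n); cl <- rep(NA_integer_, n)
    }
    data.frame(label = a$channel_labels,
               x = a$contacts[, 1], y = a$contacts[, 2], z = a$contacts[, 3],
               array_id = a$array_id, kind = a$kind, row = r, col = cl,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
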