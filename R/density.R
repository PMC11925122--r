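#' Density condition
#'
#' Records which contacts of a parent (higher-density, HD) array are retained
#' in a decimated (lower-density, LD) version. Retained indices are 0-based
#' into the parent's contact list; the LD set is always a subset of the HD
#' set, the nesting that later guarantees pointwise heatmap dominance.
#'
#' @param label `"HD"` or `"LD"`.
#' @param parent_array_id Identifier of the parent array.
#' @param retained_contact_indices Sorted 0-based indices into the parent's
#'   contacts.
#' @param n_parent Number of contacts in the parent array.
#' @return An object of class `density_condition`.
#' @export
density_condition <- function(label, parent_array_id,
                              retained_contact_indices, n_parent) {
  label <- match.arg(label, c("HD", "LD"))
  idx <- sort(as.integer(retained_contact_indices))
  if (length(idx) == 0L) stop("retained set must be nonempty", call. = FALSE)
  if (min(idx) < 0L || max(idx) >= n_parent) {
    stop("retained indices out of range", call. = FALSE)
  }
  structure(list(label = label, parent_array_id = parent_array_id,
                 retained_contact_indices = idx, n_parent = as.integer(n_parent)),
            class = "density_condition")
}

#' Decimate a grid by omitting every other row and column
#'
#' The study's core manipulation for grids: the clinical system records every
#' other row and column of the research grid, so a 4 mm HD grid becomes an
#' 8 mm LD grid. Rows/columns with even 0-based index (counting from
#' `anchor`) are retained; the anchor row/column is configurable because the
#' clinical convention is not documented.
#'
#' @param arr An `electrode_array` of kind `"grid"`.
#' @param anchor 0-based index of the first retained row/column (default 0).
#' @return A list with elements `array` (the decimated `electrode_array`,
#'   doubled spacing) and `condition` (a `density_condition` labelled LD).
#' @export
subsample_grid <- function(arr, anchor = 0L) {
  if (!inherits(arr, "electrode_array") || arr$kind != "grid") {
    stop("subsample_grid requires a grid electrode_array", call. = FALSE)
  }
  rows <- arr$grid_shape[1]; cols <- arr$grid_shape[2]
  anchor <- as.integer(anchor)
  keep_r <- seq.int(anchor, rows - 1L, by = 2L)
  keep_c <- seq.int(anchor, cols - 1L, by = 2L)
  if (length(keep_r) == 0L || length(keep_c) == 0L) {
    stop("anchor leaves no retained rows or columns", call. = FALSE)
  }
  idx0 <- as.vector(t(outer(keep_r, keep_c, function(i, j) i * cols + j)))
  idx0 <- sort(idx0)
  sub <- electrode_array(
    arr$array_id, "grid", arr$contacts[idx0 + 1L, , drop = FALSE],
    spacing_mm = if (length(keep_r) > 1L || length(keep_c) > 1L) 2 * arr$spacing_mm else arr$spacing_mm,
    grid_shape = c(length(keep_r), length(keep_c)),
    channel_labels = arr$channel_labels[idx0 + 1L])
  list(array = sub,
       condition = density_condition("LD", arr$array_id, idx0,
                                     nrow(arr$contacts)))
}

#' Decimate a linear array by omitting every other contact
#'
#' For depth probes (and optionally strips): retains contacts with even
#' 0-based index counting from `anchor`, doubling the spacing (5 mm depth
#' probes become 10 mm).
#'
#' @param arr An `electrode_array` of kind `"depth"` or `"strip"`.
#' @param anchor 0-based index of the first retained contact.
#' @return As [subsample_grid()].
#' @export
subsample_linear <- function(arr, anchor = 0L) {
  if (!inherits(arr, "electrode_array") || !arr$kind %in% c("depth", "strip")) {
    stop("subsample_linear requires a depth or strip electrode_array",
         call. = FALSE)
  }
  n <- nrow(arr$contacts)
  idx0 <- seq.int(as.integer(anchor), n - 1L, by = 2L)
  if (length(idx0) == 0L) stop("anchor leaves no retained contacts", call. = FALSE)
  sub <- electrode_array(
    arr$array_id, arr$kind, arr$contacts[idx0 + 1L, , drop = FALSE],
    spacing_mm = if (length(idx0) > 1L) 2 * arr$spacing_mm else arr$spacing_mm,
    grid_shape = length(idx0),
    channel_labels = arr$channel_labels[idx0 + 1L])
  list(array = sub,
       condition = density_condition("LD", arr$array_id, idx0, n))
}

#' Decimate an array according to its kind
#'
#' Grids lose every other row and column; depths every other contact. Strips
#' are left intact by default, mirroring the study (strips were recorded at
#' 10 mm on both systems).
#'
#' @param arr An `electrode_array`.
#' @param decimate_strips If `TRUE`, strips are decimated like depths.
#' @param anchor 0-based anchor index.
#' @return As [subsample_grid()]; for an undecimated strip, the condition
#'   retains all contacts.
#' @export
subsample_array <- function(arr, decimate_strips = FALSE, anchor = 0L) {
  if (arr$kind == "grid") {
    subsample_grid(arr, anchor)
  } else if (arr$kind == "depth" || decimate_strips) {
    subsample_linear(arr, anchor)
  } else {
    list(array = arr,
         condition = density_condition("LD", arr$array_id,
                                       seq_len(nrow(arr$contacts)) - 1L,
                                       nrow(arr$contacts)))
  }
}

#' Subsample a recording to a lower-density channel set
#'
#' Restricts an HD recording to the channels retained by the given density
#' conditions. Signal samples are bit-identical to the HD recording on the
#' shared channels: decimation removes channels and nothing else. Channels
#' of arrays without a condition are kept in full.
#'
#' @param rec An `iceeg_recording`.
#' @param arrays List of parent `electrode_array` objects.
#' @param conds List of `density_condition` objects (one per decimated
#'   array).
#' @return An `iceeg_recording` containing only the retained channels.
#' @export
subsample_recording <- function(rec, arrays, conds) {
  stopifnot(inherits(rec, "iceeg_recording"))
  arrays <- if (inherits(arrays, "electrode_array")) list(arrays) else arrays
  conds <- if (inherits(conds, "density_condition")) list(conds) else conds
  cond_by_array <- stats::setNames(conds,
                                   vapply(conds, `[[`, "", "parent_array_id"))
  keep <- character(0)
  for (a in arrays) {
    labels <- a$channel_labels
    cond <- cond_by_array[[a$array_id]]
    if (!is.null(cond)) {
      labels <- labels[cond$retained_contact_indices + 1L]
    }
    keep <- c(keep, labels)
  }
  missing <- setdiff(keep, rec$channel_labels)
  if (length(missing) > 0L) {
    stop("retained contacts with no channel in the recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sel <- match(keep, rec$channel_labels)
  rec$data <- rec$data[sel, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[sel]
  rec
}
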