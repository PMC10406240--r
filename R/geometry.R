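#' Sensor layout
#'
#' Sensor labels with 3-D head-frame coordinates in millimetres (x right,
#' y anterior, z superior in the convention used here).
#'
#' @param labels unique sensor names (>= 2).
#' @param x_mm,y_mm,z_mm finite coordinates in mm.
#' @return A `sensor_layout` data frame with columns `label`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @export
sensor_layout <- function(labels, x_mm, y_mm, z_mm) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stopf("a layout needs >= 2 sensors")
  if (anyDuplicated(labels)) stopf("sensor labels must be unique")
  co <- cbind(x_mm, y_mm, z_mm)
  if (nrow(co) != length(labels) || !all(is.finite(co))) {
    stopf("coordinates must be finite and match the number of labels")
  }
  out <- data.frame(label = labels, x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm), z_mm = as.numeric(z_mm),
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_layout", "data.frame")
  out
}

#' Read / write a sensor layout TSV
#'
#' Tab-separated with a header row `label  x_mm  y_mm  z_mm`.
#'
#' @param path file path.
#' @param layout a [sensor_layout()].
#' @return `read_layout()` returns a [sensor_layout()]; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d))) {
    stopf("layout file must have columns: %s", paste(need, collapse = ", "))
  }
  sensor_layout(d$label, d$x_mm, d$y_mm, d$z_mm)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "sensor_layout"))
  utils::write.table(as.data.frame(layout), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic spherical-cap sensor layout
#'
#' Deterministically places `n` sensors on the upper cap of a sphere of the
#' given radius using a Fibonacci lattice, a stand-in for scalp electrode
#' montages in tests and simulations (it is not any vendor's montage).
#'
#' @param n number of sensors (>= 2).
#' @param radius_mm head radius in mm (default 95).
#' @param cap_fraction fraction of the sphere covered from the vertex down
#'   (default 0.6: from the vertex to somewhat below the equator).
#' @return A [sensor_layout()] with labels `"E001"`, `"E002"`, ...
#' @export
synthetic_layout <- function(n, radius_mm = 95, cap_fraction = 0.6) {
  if (n < 2L) stopf("a layout needs >= 2 sensors")
  i <- seq_len(n) - 0.5
  z_unit <- 1 - cap_fraction * i / n        # from vertex (z = 1) downwards
  phi <- pi * (1 + sqrt(5)) * i             # golden-angle azimuth
  r_unit <- sqrt(pmax(0, 1 - z_unit^2))
  sensor_layout(sprintf("E%03d", seq_len(n)),
                x_mm = radius_mm * r_unit * cos(phi),
                y_mm = radius_mm * r_unit * sin(phi),
                z_mm = radius_mm * z_unit)
}

layout_coords <- function(layout) {
  as.matrix(layout[, c("x_mm", "y_mm", "z_mm")])
}

#' Distance bounds for reported connections
#'
#' Reported connections are restricted to sensor pairs that are neither
#' neighbors (neighboring sensors share similar connectivity patterns, so
#' their close alignment is uninformative) nor very distant (distant pairs
#' dominate the decreased-alignment picture). The maximum distance is
#' `max_frac` times the range of the y (anterior-posterior) coordinate; the
#' minimum is `min_mult` times the smallest pairwise Euclidean distance.
#'
#' @param layout a [sensor_layout()].
#' @param max_frac fraction of the y-coordinate range (default 0.65).
#' @param min_mult multiplier of the smallest sensor distance (default 2.5).
#' @return A `distance_bounds` object: `min_mm`, `max_mm`, `max_frac`,
#'   `min_mult`. Errors if sensors coincide or if `min_mm >= max_mm`
#'   (degenerate layout).
#' @export
distance_bounds <- function(layout, max_frac = 0.65, min_mult = 2.5) {
  stopifnot(inherits(layout, "sensor_layout"))
  co <- layout_coords(layout)
  d <- as.matrix(stats::dist(co))
  dmin <- min(d[upper.tri(d)])
  if (dmin <= 0) stopf("layout contains coincident sensors")
  max_mm <- max_frac * (max(co[, 2L]) - min(co[, 2L]))
  min_mm <- min_mult * dmin
  if (min_mm >= max_mm) {
    stopf("degenerate distance bounds: min %.3g mm >= max %.3g mm",
          min_mm, max_mm)
  }
  structure(list(min_mm = min_mm, max_mm = max_mm,
                 max_frac = max_frac, min_mult = min_mult),
            class = "distance_bounds")
}

#' @export
print.distance_bounds <- function(x, ...) {
  cat(sprintf("distance_bounds: [%.1f, %.1f] mm (%.0f%% of y-range, %.0f%% of min distance)\n",
              x$min_mm, x$max_mm, 100 * x$max_frac, 100 * x$min_mult))
  invisible(x)
}

#' Distance-bounded filtering of a pair list
#'
#' Keeps the pairs whose 3-D Euclidean sensor distance lies in
#' `[min_mm, max_mm]`. Idempotent and independent of row order.
#'
#' @param pairs data frame with columns `chan_a`, `chan_b` (e.g. a
#'   `significance_map` or `consistency_set`); all labels must appear in
#'   the layout.
#' @param layout a [sensor_layout()].
#' @param bounds a [distance_bounds()].
#' @return The filtered data frame with an added `distance_mm` column.
#' @export
filter_edges <- function(pairs, layout, bounds) {
  stopifnot(is.data.frame(pairs), inherits(layout, "sensor_layout"),
            inherits(bounds, "distance_bounds"))
  if (nrow(pairs) == 0L) {
    pairs$distance_mm <- numeric(0)
    return(pairs)
  }
  unknown <- setdiff(unique(c(pairs$chan_a, pairs$chan_b)), layout$label)
  if (length(unknown) > 0L) {
    stopf("label(s) not in layout: %s", paste(unknown, collapse = ", "))
  }
  co <- layout_coords(layout)
  rownames(co) <- layout$label
  dvec <- sqrt(rowSums((co[pairs$chan_a, , drop = FALSE] -
                        co[pairs$chan_b, , drop = FALSE])^2))
  pairs$distance_mm <- unname(dvec)
  out <- pairs[dvec >= bounds$min_mm & dvec <= bounds$max_mm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict an object to a subset of channels
#'
#' Keeps only the named channels, in the order given. Works on
#' [eeg_epochs()], [connectivity_matrix()] and `alignment_matrix` objects.
#'
#' @param obj object to subset.
#' @param keep character vector of >= 2 channel labels, all present.
#' @return Object of the same class restricted to `keep`.
#' @export
subset_channels <- function(obj, keep) UseMethod("subset_channels")

check_subset <- function(labels, keep) {
  keep <- as.character(keep)
  if (length(keep) < 2L) stopf("`keep` must name >= 2 channels")
  if (anyDuplicated(keep)) stopf("`keep` contains duplicate labels")
  unknown <- setdiff(keep, labels)
  if (length(unknown) > 0L) {
    stopf("unknown channel label(s): %s", paste(unknown, collapse = ", "))
  }
  match(keep, labels)
}

#' @export
subset_channels.eeg_epochs <- function(obj, keep) {
  idx <- check_subset(obj$channel_labels, keep)
  eeg_epochs(obj$data[, idx, , drop = FALSE], fs = obj$fs,
             channel_labels = obj$channel_labels[idx])
}

#' @export
subset_channels.connectivity_matrix <- function(obj, keep) {
  idx <- check_subset(obj$channel_labels, keep)
  connectivity_matrix(obj$W[idx, idx, drop = FALSE], measure = obj$measure,
                      band = obj$band,
                      channel_labels = obj$channel_labels[idx])
}

#' @export
subset_channels.alignment_matrix <- function(obj, keep) {
  idx <- check_subset(obj$channel_labels, keep)
  structure(list(theta = obj$theta[idx, idx, drop = FALSE],
                 eig_indices = obj$eig_indices,
                 channel_labels = obj$channel_labels[idx]),
            class = "alignment_matrix")
}

#' @export
subset_channels.sensor_layout <- function(obj, keep) {
  idx <- check_subset(obj$label, keep)
  sensor_layout(obj$label[idx], obj$x_mm[idx], obj$y_mm[idx], obj$z_mm[idx])
}
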