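#' Streamline bundle
#'
#' @param streamlines List of numeric matrices (>= 2 rows, 3 columns), one
#'   per streamline, points in world RAS mm.
#' @param tract Tract name.
#' @param hemisphere "left" or "right".
#' @param affine Reference voxel-to-world affine (kept for serialization).
#' @param ref_dim Reference grid dimensions.
#' @return Object of class `tract_bundle`.
#' @export
tract_bundle <- function(streamlines, tract = "tract", hemisphere = c("left", "right"),
                         affine = diag(4), ref_dim = c(64L, 64L, 64L)) {
  hemisphere <- match.arg(hemisphere)
  if (length(streamlines) < 1) abort("Bundle needs at least one streamline.")
  for (sl in streamlines) {
    if (!is.matrix(sl) || ncol(sl) != 3 || nrow(sl) < 2 || !all(is.finite(sl))) {
      abort("Each streamline must be a finite N x 3 matrix with N >= 2.")
    }
  }
  structure(list(streamlines = streamlines, tract = tract,
                 hemisphere = hemisphere, affine = affine,
                 ref_dim = as.integer(ref_dim)),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  cat(sprintf("<tract_bundle> %s (%s): %d streamlines\n",
              x$tract, x$hemisphere, length(x$streamlines)))
  invisible(x)
}

#' Resample a polyline to equidistant arc-length nodes
#'
#' Returns `n_nodes` points at equal arc-length spacing; the original
#' endpoints are preserved exactly.
#'
#' @param polyline N x 3 matrix of points.
#' @param n_nodes Number of output nodes (>= 2).
#' @return n_nodes x 3 matrix.
#' @export
resample_streamline <- function(polyline, n_nodes = 100) {
  if (n_nodes < 2) abort("`n_nodes` must be at least 2.")
  polyline <- rbind_points(polyline)
  seg <- sqrt(rowSums(diff(polyline)^2))
  len <- sum(seg)
  if (len <= 0) abort("Polyline has zero arc length.")
  s <- c(0, cumsum(seg))
  target <- seq(0, len, length.out = n_nodes)
  out <- vapply(1:3, function(k) approx(s, polyline[, k], xout = target,
                                        ties = "ordered")$y,
                numeric(n_nodes))
  out[1, ] <- polyline[1, ]
  out[n_nodes, ] <- polyline[nrow(polyline), ]
  out
}

#' Orient all streamlines of a bundle consistently
#'
#' Each streamline is flipped so that its start endpoint is the one nearer
#' to the bundle's canonical start (the start of the first streamline, or a
#' supplied reference point, e.g. the mirrored canonical start of the
#' contralateral homologue). Idempotent.
#'
#' @param bundle A `tract_bundle`.
#' @param reference_point Optional 3-vector overriding the canonical start.
#' @return Reoriented `tract_bundle`.
#' @export
orient_bundle <- function(bundle, reference_point = NULL) {
  ref <- if (is.null(reference_point)) bundle$streamlines[[1]][1, ]
         else as.numeric(reference_point)
  bundle$streamlines <- lapply(bundle$streamlines, function(sl) {
    d_start <- sum((sl[1, ] - ref)^2)
    d_end <- sum((sl[nrow(sl), ] - ref)^2)
    if (d_end < d_start) sl[rev(seq_len(nrow(sl))), , drop = FALSE] else sl
  })
  bundle
}

#' Canonical start point of an (oriented) bundle
#' @param bundle A `tract_bundle`.
#' @return Centroid of the streamline start points.
#' @export
canonical_start <- function(bundle) {
  colMeans(do.call(rbind, lapply(bundle$streamlines, function(sl) sl[1, ])))
}

# resample every streamline: returns (n_streamlines * n_nodes) x 3 matrix
# plus node index per row
resampled_points <- function(bundle, n_nodes) {
  pts <- lapply(bundle$streamlines, resample_streamline, n_nodes = n_nodes)
  list(points = do.call(rbind, pts),
       node = rep(seq_len(n_nodes), times = length(pts)))
}

#' Per-node metric values along a bundle
#'
#' Resamples each streamline to `n_nodes` equidistant points, samples the
#' metric volume by trilinear interpolation at each point, and averages
#' (unweighted) over streamlines per node index. Points outside the volume
#' are treated as missing and excluded; a node with no valid point yields
#' `NA`.
#'
#' @param bundle A `tract_bundle`.
#' @param metric_volume An `fw_volume` of type "metric" sharing world space.
#' @param n_nodes Number of nodes (default 100).
#' @return Tibble with columns `node`, `value`, `n_points` (valid points).
#' @export
node_values <- function(bundle, metric_volume, n_nodes = 100) {
  rp <- resampled_points(bundle, n_nodes)
  vals <- sample_trilinear(metric_volume, rp$points)
  tibble::tibble(node = seq_len(n_nodes)) |>
    dplyr::left_join(
      tibble::tibble(node = rp$node, value = vals) |>
        dplyr::group_by(.data$node) |>
        dplyr::summarise(n_points = sum(!is.na(.data$value)),
                         value = if (all(is.na(.data$value))) NA_real_
                                 else mean(.data$value, na.rm = TRUE),
                         .groups = "drop"),
      by = "node")
}

#' Per-node tumor involvement fractions along a bundle
#'
#' A node's spatial extent is the multiset of resampled streamline points
#' with that node index; the fraction per compartment is the share of those
#' points whose containing voxel carries the compartment's label (nearest
#' voxel, labels never interpolated). "combined" uses the union of the
#' three compartments.
#'
#' @param bundle A `tract_bundle`.
#' @param segmentation `fw_volume` of type "label".
#' @param n_nodes Number of nodes.
#' @param label_map Named integer vector mapping compartments to label
#'   codes (default BraTS-style: necrotic = 1, edema = 2, enhancing = 4).
#' @return Tibble with columns `node`, `enhancing`, `necrotic`, `edema`,
#'   `combined`, `n_points`.
#' @export
node_involvement <- function(bundle, segmentation, n_nodes = 100,
                             label_map = c(necrotic = 1L, edema = 2L,
                                           enhancing = 4L)) {
  rp <- resampled_points(bundle, n_nodes)
  lab <- sample_label(segmentation, rp$points)
  tb <- tibble::tibble(node = rp$node, label = lab)
  # out-of-volume points carry NA labels and are excluded from the fraction
  frac_of <- function(lb, codes) {
    lb <- lb[!is.na(lb)]
    if (length(lb) == 0) NA_real_ else mean(lb %in% codes)
  }
  out <- tb |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      enhancing = frac_of(.data$label, label_map[["enhancing"]]),
      necrotic = frac_of(.data$label, label_map[["necrotic"]]),
      edema = frac_of(.data$label, label_map[["edema"]]),
      combined = frac_of(.data$label, unname(label_map)),
      n_points = sum(!is.na(.data$label)),
      .groups = "drop")
  dplyr::left_join(tibble::tibble(node = seq_len(n_nodes)), out, by = "node")
}

#' Is a node tumor-involved at a threshold?
#'
#' Strict reading of "more than": a fraction exactly at the threshold is
#' not involved.
#'
#' @param fraction Involvement fraction(s) in [0, 1].
#' @param threshold Threshold in percent (default 5).
#' @return Logical vector.
#' @export
classify_involved <- function(fraction, threshold = 5) {
  if (any(threshold < 0 | threshold > 100)) {
    abort("`threshold` must lie in [0, 100] percent.")
  }
  fraction > threshold / 100
}

#' Full tract profile: metrics plus involvement, one row per node
#'
#' @param bundle A `tract_bundle`.
#' @param metrics Named list of metric `fw_volume`s (e.g. `fw_fa`, `fw_md`,
#'   `fwf`).
#' @param segmentation Label `fw_volume`, or NULL to skip involvement.
#' @param n_nodes Number of nodes.
#' @param label_map Compartment label codes, see [node_involvement()].
#' @return Tibble with `tract`, `hemisphere`, `node`, one column per
#'   metric, and involvement fraction columns.
#' @export
tract_profile <- function(bundle, metrics, segmentation = NULL,
                          n_nodes = 100,
                          label_map = c(necrotic = 1L, edema = 2L,
                                        enhancing = 4L)) {
  prof <- tibble::tibble(tract = bundle$tract,
                         hemisphere = bundle$hemisphere,
                         node = seq_len(n_nodes))
  for (nm in names(metrics)) {
    prof[[nm]] <- node_values(bundle, metrics[[nm]], n_nodes)$value
  }
  if (!is.null(segmentation)) {
    inv <- node_involvement(bundle, segmentation, n_nodes, label_map)
    prof <- dplyr::left_join(prof, inv, by = "node")
  }
  prof
}
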