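#' Directional percent asymmetry between hemispheres
#'
#' \deqn{A = \frac{ipsi - contra}{(ipsi + contra)/2} \times 100}
#' Positive values indicate higher values in the tumor-bearing
#' (ipsilateral) hemisphere. Bounded in [-200, 200] for non-negative
#' inputs; undefined (NA) when both values are zero.
#'
#' @param ipsi,contra Non-negative metric values (vectorized).
#' @return Percent asymmetry.
#' @export
node_asymmetry <- function(ipsi, contra) {
  if (any(ipsi < 0 | contra < 0, na.rm = TRUE)) {
    abort("Diffusion metric values must be non-negative.")
  }
  denom <- (ipsi + contra) / 2
  out <- (ipsi - contra) / denom * 100
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Average homologous hemisphere values into a bilateral tract group
#'
#' @param left,right Values for the two homologues (vectorized). When one
#'   side is missing the other is used alone.
#' @return Mean of the available sides; NA when both are missing.
#' @export
bilateral_group <- function(left, right) {
  both <- cbind(left, right)
  out <- rowMeans(both, na.rm = TRUE)
  out[rowSums(!is.na(both)) == 0] <- NA_real_
  out
}

#' Subject-level direct tumor involvement per bilateral tract group
#'
#' Pools the nodes of both hemispheres of each tract (200 nodes when both
#' are present), counts nodes whose involvement fraction strictly exceeds
#' the threshold, and binarizes: involved means at least one such node.
#'
#' @param profiles Profile tibble (see [tract_profile()]) for one or more
#'   subjects; a `subject_id` column is honored when present.
#' @param threshold Node-involvement threshold in percent (default 5).
#' @return Tibble with one row per (subject,) tract group and compartment:
#'   `involved`, `proportion_involved`, `n_nodes_total`, `n_hemispheres`,
#'   `threshold`.
#' @export
subject_involvement <- function(profiles, threshold = 5) {
  long <- profiles |>
    tidyr::pivot_longer(dplyr::any_of(c("enhancing", "necrotic", "edema",
                                        "combined")),
                        names_to = "compartment", values_to = "fraction")
  grp <- c(intersect("subject_id", names(long)), "tract", "compartment")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_nodes_total = sum(!is.na(.data$fraction)),
      n_hemispheres = dplyr::n_distinct(.data$hemisphere),
      proportion_involved = mean(classify_involved(.data$fraction, threshold),
                                 na.rm = TRUE),
      involved = .data$proportion_involved > 0,
      .groups = "drop") |>
    dplyr::mutate(threshold = threshold)
}

#' Involvement sensitivity sweep over thresholds
#'
#' @param profiles Profile tibble.
#' @param thresholds Vector of percent thresholds (default 1:15).
#' @return Stacked [subject_involvement()] tables, one per threshold.
#' @export
threshold_sweep <- function(profiles, thresholds = 1:15) {
  if (any(thresholds < 0 | thresholds > 100)) {
    abort("Thresholds must lie in [0, 100] percent.")
  }
  purrr::map_dfr(thresholds, function(th) subject_involvement(profiles, th))
}

#' Mean metric over all contralateral-hemisphere nodes
#'
#' @param profiles Profile tibble for one subject.
#' @param tumor_hemisphere "left" or "right".
#' @param metrics Metric column names to average.
#' @return Tibble with `metric`, `value`, `n_nodes`.
#' @export
contralateral_mean <- function(profiles, tumor_hemisphere,
                               metrics = c("fw_fa", "fw_md", "fwf")) {
  stopifnot(tumor_hemisphere %in% c("left", "right"))
  contra <- profiles |> dplyr::filter(.data$hemisphere != tumor_hemisphere)
  if (nrow(contra) == 0) {
    warn("No contralateral profiles; returning NA means.")
    return(tibble::tibble(metric = metrics, value = NA_real_, n_nodes = 0L))
  }
  contra |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(n_nodes = sum(!is.na(.data$value)),
                     value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::select("metric", "value", "n_nodes")
}

#' Node indices eligible for asymmetry analysis
#'
#' Eligible nodes have ipsilateral combined tumor involvement strictly
#' below the threshold (default "< 5%") and non-missing paired values on
#' both sides for the requested metric.
#'
#' @param profile_ipsi,profile_contra Single-tract single-hemisphere
#'   profile tibbles with equal `n_nodes`.
#' @param metric Metric column to require.
#' @param threshold Eligibility threshold in percent.
#' @param filter_contralateral Also require contralateral combined
#'   involvement below threshold (defensive option; default FALSE since
#'   unilateral inclusion makes contralateral involvement ~ 0).
#' @return Integer vector of eligible node indices (1-based).
#' @export
eligible_node_pairs <- function(profile_ipsi, profile_contra,
                                metric = "fw_fa", threshold = 5,
                                filter_contralateral = FALSE) {
  if (nrow(profile_ipsi) != nrow(profile_contra)) {
    abort("Homologous profiles must have the same number of nodes.")
  }
  i <- profile_ipsi[order(profile_ipsi$node), ]
  c_ <- profile_contra[order(profile_contra$node), ]
  ok <- !is.na(i$combined) & i$combined < threshold / 100 &
    !is.na(i[[metric]]) & !is.na(c_[[metric]])
  if (filter_contralateral) {
    ok <- ok & !is.na(c_$combined) & c_$combined < threshold / 100
  }
  i$node[ok]
}

#' Along-tract node distance to the tumor margin
#'
#' The involved set is the nodes whose combined involvement fraction
#' strictly exceeds the threshold; each node's distance is the minimum
#' index difference to any involved node (0 for involved nodes). When no
#' node is involved the margin is undefined and all distances are NA.
#'
#' @param combined_fraction Per-node combined involvement fractions,
#'   ordered by node index.
#' @param threshold Percent threshold defining the margin (default 5).
#' @return Integer vector of distances in node units (NA if undefined).
#' @export
node_distance_to_margin <- function(combined_fraction, threshold = 5) {
  n <- length(combined_fraction)
  inv <- which(classify_involved(combined_fraction, threshold))
  if (length(inv) == 0) return(rep(NA_integer_, n))
  vapply(seq_len(n), function(i) as.integer(min(abs(i - inv))), integer(1))
}

#' Default along-tract distance segments
#'
#' Closed five-node bins 1-5, 6-10, 11-15, 16-20 and an open >=21 bin.
#'
#' @return Tibble with `segment`, `lo`, `hi`.
#' @export
asym_distance_bins <- function() {
  tibble::tibble(segment = c("1-5", "6-10", "11-15", "16-20", ">=21"),
                 lo = c(1L, 6L, 11L, 16L, 21L),
                 hi = c(5L, 10L, 15L, 20L, Inf))
}

validate_bins <- function(bins) {
  stopifnot(all(c("segment", "lo", "hi") %in% names(bins)))
  b <- bins[order(bins$lo), ]
  if (any(b$lo > b$hi)) abort("Each bin needs lo <= hi.")
  if (nrow(b) > 1 && any(b$lo[-1] <= b$hi[-nrow(b)])) {
    abort("Distance bins must not overlap.")
  }
  if (b$lo[1] != 1 || (nrow(b) > 1 && any(b$lo[-1] != b$hi[-nrow(b)] + 1)) ||
      is.finite(b$hi[nrow(b)])) {
    abort("Distance bins must partition the positive integers.")
  }
  b
}

assign_segment <- function(distance, bins) {
  out <- rep(NA_character_, length(distance))
  for (r in seq_len(nrow(bins))) {
    sel <- !is.na(distance) & distance >= bins$lo[r] & distance <= bins$hi[r]
    out[sel] <- bins$segment[r]
  }
  out
}

# Per-node asymmetry table for one subject: one row per tract, node and
# metric with asymmetry, eligibility and distance-to-margin.
asymmetry_node_table <- function(profiles, tumor_hemisphere, threshold = 5,
                                 metrics = c("fw_fa", "fw_md", "fwf"),
                                 filter_contralateral = FALSE) {
  stopifnot(tumor_hemisphere %in% c("left", "right"))
  ipsi <- profiles |> dplyr::filter(.data$hemisphere == tumor_hemisphere)
  contra <- profiles |> dplyr::filter(.data$hemisphere != tumor_hemisphere)
  if (nrow(ipsi) == 0 || nrow(contra) == 0) {
    return(tibble::tibble(tract = character(), node = integer(),
                          metric = character(), asymmetry = numeric(),
                          eligible = logical(), distance = integer()))
  }
  keep <- c("tract", "node", metrics, "combined")
  joined <- dplyr::inner_join(
    ipsi |> dplyr::select(dplyr::all_of(keep)),
    contra |> dplyr::select(dplyr::all_of(c("tract", "node", metrics, "combined"))),
    by = c("tract", "node"), suffix = c("_ipsi", "_contra"))
  joined <- joined |>
    dplyr::group_by(.data$tract) |>
    dplyr::arrange(.data$node, .by_group = TRUE) |>
    dplyr::mutate(distance = node_distance_to_margin(.data$combined_ipsi,
                                                     threshold)) |>
    dplyr::ungroup()
  purrr::map_dfr(metrics, function(m) {
    vi <- joined[[paste0(m, "_ipsi")]]
    vc <- joined[[paste0(m, "_contra")]]
    elig <- !is.na(joined$combined_ipsi) &
      joined$combined_ipsi < threshold / 100 & !is.na(vi) & !is.na(vc)
    if (filter_contralateral) {
      elig <- elig & !is.na(joined$combined_contra) &
        joined$combined_contra < threshold / 100
    }
    tibble::tibble(tract = joined$tract, node = joined$node, metric = m,
                   asymmetry = node_asymmetry(vi, vc), eligible = elig,
                   distance = joined$distance)
  })
}

#' Whole-tract hemispheric asymmetry per subject
#'
#' Two-stage collapse: node asymmetries at eligible (tumor-free) nodes are
#' averaged within each tract, then the per-tract means are averaged
#' (unweighted) into one subject-level value per metric. A pooled-node
#' alternative is available for comparison but is not the default.
#'
#' @param profiles Profile tibble for one subject (both hemispheres).
#' @param tumor_hemisphere "left" or "right".
#' @param threshold Eligibility threshold in percent (default 5).
#' @param metrics Metric columns.
#' @param pooled If TRUE, average all eligible nodes in one pool instead of
#'   tract-then-subject.
#' @param filter_contralateral See [eligible_node_pairs()].
#' @return Tibble with `metric`, `asymmetry`, `n_tracts`, `n_nodes`.
#' @export
whole_tract_asymmetry <- function(profiles, tumor_hemisphere, threshold = 5,
                                  metrics = c("fw_fa", "fw_md", "fwf"),
                                  pooled = FALSE,
                                  filter_contralateral = FALSE) {
  tab <- asymmetry_node_table(profiles, tumor_hemisphere, threshold, metrics,
                              filter_contralateral) |>
    dplyr::filter(.data$eligible, !is.na(.data$asymmetry))
  if (nrow(tab) == 0) {
    return(tibble::tibble(metric = metrics, asymmetry = NA_real_,
                          n_tracts = 0L, n_nodes = 0L))
  }
  if (pooled) {
    out <- tab |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(asymmetry = mean(.data$asymmetry),
                       n_tracts = dplyr::n_distinct(.data$tract),
                       n_nodes = dplyr::n(), .groups = "drop")
  } else {
    out <- tab |>
      dplyr::group_by(.data$metric, .data$tract) |>
      dplyr::summarise(asymmetry = mean(.data$asymmetry),
                       n_nodes = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(n_tracts = dplyr::n(), n_nodes = sum(.data$n_nodes),
                       asymmetry = mean(.data$asymmetry), .groups = "drop")
  }
  dplyr::left_join(tibble::tibble(metric = metrics), out, by = "metric") |>
    dplyr::mutate(n_tracts = dplyr::coalesce(.data$n_tracts, 0L),
                  n_nodes = dplyr::coalesce(.data$n_nodes, 0L)) |>
    dplyr::select("metric", "asymmetry", "n_tracts", "n_nodes")
}

#' Distance-binned hemispheric asymmetry per subject
#'
#' Eligible node asymmetries are grouped by the node's along-tract distance
#' segment from the tumor margin, averaged per tract within each segment,
#' then across tracts: one value per segment and metric. Tracts with no
#' involved node have no within-tract margin and are excluded by default
#' (`uninvolved = "exclude"`); `uninvolved = "distal"` assigns their nodes
#' to the most distal segment instead.
#'
#' @inheritParams whole_tract_asymmetry
#' @param bins Distance segments, see [asym_distance_bins()].
#' @param uninvolved Handling of tracts without involved nodes.
#' @return Tibble with `segment`, `metric`, `asymmetry`, `n_tracts`,
#'   `n_nodes` (NA asymmetry for empty segments).
#' @export
distance_binned_asymmetry <- function(profiles, tumor_hemisphere,
                                      threshold = 5,
                                      bins = asym_distance_bins(),
                                      metrics = c("fw_fa", "fw_md", "fwf"),
                                      uninvolved = c("exclude", "distal"),
                                      filter_contralateral = FALSE) {
  uninvolved <- match.arg(uninvolved)
  bins <- validate_bins(bins)
  tab <- asymmetry_node_table(profiles, tumor_hemisphere, threshold, metrics,
                              filter_contralateral)
  if (uninvolved == "distal") {
    tab$distance[is.na(tab$distance)] <- as.integer(bins$lo[nrow(bins)])
  }
  tab <- tab |>
    dplyr::filter(.data$eligible, !is.na(.data$asymmetry),
                  !is.na(.data$distance), .data$distance >= 1) |>
    dplyr::mutate(segment = assign_segment(.data$distance, bins))
  shell <- tidyr::expand_grid(segment = bins$segment, metric = metrics)
  if (nrow(tab) == 0) {
    return(shell |> dplyr::mutate(asymmetry = NA_real_, n_tracts = 0L,
                                  n_nodes = 0L))
  }
  out <- tab |>
    dplyr::group_by(.data$segment, .data$metric, .data$tract) |>
    dplyr::summarise(asymmetry = mean(.data$asymmetry),
                     n_nodes = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$segment, .data$metric) |>
    dplyr::summarise(n_tracts = dplyr::n(), n_nodes = sum(.data$n_nodes),
                     asymmetry = mean(.data$asymmetry), .groups = "drop")
  dplyr::left_join(shell, out, by = c("segment", "metric")) |>
    dplyr::mutate(n_tracts = dplyr::coalesce(.data$n_tracts, 0L),
                  n_nodes = dplyr::coalesce(.data$n_nodes, 0L))
}

#' Cohort-level asymmetry tables
#'
#' Maps [whole_tract_asymmetry()] and [distance_binned_asymmetry()] over
#' the subjects of a cohort profile table.
#'
#' @param profiles Profile tibble with a `subject_id` column.
#' @param subjects Tibble with `subject_id`, `tumor_hemisphere` (and
#'   typically `pathology`); extra columns are carried through.
#' @param threshold Eligibility threshold in percent.
#' @param bins Distance segments (NULL for whole-tract only).
#' @param metrics Metric columns.
#' @param ... Passed to the per-subject functions.
#' @return Tibble keyed by subject with asymmetry values (and `segment`
#'   when `bins` is supplied).
#' @export
cohort_asymmetry <- function(profiles, subjects, threshold = 5, bins = NULL,
                             metrics = c("fw_fa", "fw_md", "fwf"), ...) {
  stopifnot(all(c("subject_id", "tumor_hemisphere") %in% names(subjects)))
  per_subject <- function(sid, hemi) {
    p <- profiles |> dplyr::filter(.data$subject_id == sid)
    res <- if (is.null(bins)) {
      whole_tract_asymmetry(p, hemi, threshold, metrics, ...)
    } else {
      distance_binned_asymmetry(p, hemi, threshold, bins, metrics, ...)
    }
    dplyr::mutate(res, subject_id = sid, .before = 1)
  }
  out <- purrr::map2_dfr(subjects$subject_id, subjects$tumor_hemisphere,
                         per_subject)
  dplyr::left_join(out, subjects, by = "subject_id")
}
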