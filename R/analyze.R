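#' Tumor compartment volumes normalized to brain volume
#'
#' Compartment volume as a proportion of total brain volume, where the
#' brain mask is the full grid minus a configurable ventricle ellipsoid at
#' the grid center.
#'
#' @param segmentation Label `fw_volume`.
#' @param config A [cohort_config()] (supplies voxel size and ventricle
#'   radii).
#' @return Tibble with `compartment`, `n_voxels`, `volume_mm3`,
#'   `proportion_brain`.
#' @export
tumor_volume_stats <- function(segmentation, config) {
  vs <- voxel_size(segmentation)
  vox_mm3 <- prod(vs)
  gd <- dim(segmentation$data)
  gw <- grid_world(gd, segmentation$affine)
  vr <- config$ventricle_radii_mm
  ventricle <- (gw$x / vr[1])^2 + (gw$y / vr[2])^2 + (gw$z / vr[3])^2 <= 1
  brain_vox <- sum(!ventricle)
  lab <- segmentation$data
  counts <- c(necrotic = sum(lab == 1L), edema = sum(lab == 2L),
              enhancing = sum(lab == 4L))
  counts <- c(counts, combined = sum(counts))
  tibble::tibble(compartment = names(counts),
                 n_voxels = as.integer(counts),
                 volume_mm3 = counts * vox_mm3,
                 proportion_brain = counts / brain_vox)
}

#' Per-subject Spearman correlation of FWF with edema involvement
#'
#' Correlates free-water-fraction node values with the edema involvement
#' fraction across all nodes of a subject's profiles.
#'
#' @param profiles Cohort profile tibble with `subject_id`.
#' @return Tibble with one row per subject: `rho`, `p`, `n`.
#' @export
fwf_edema_correlation <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$fwf) & !is.na(df$edema)
      if (sum(ok) < 3) {
        return(tibble::tibble(rho = NA_real_, p = NA_real_, n = sum(ok),
                              flag = "too few nodes"))
      }
      spearman_cor(df$fwf[ok], df$edema[ok])
    }) |>
    dplyr::ungroup()
}

#' Full cohort analysis
#'
#' Runs the complete statistical battery on a cohort profile table:
#' direct-involvement summaries (with optional threshold sensitivity
#' sweep), whole-tract and distance-binned hemispheric asymmetry,
#' FWF-edema correlation, Kruskal-Wallis omnibus and pairwise Mann-Whitney
#' group comparisons with family-stratified Benjamini-Hochberg FDR (one
#' family per metric for asymmetry analyses, one per compartment for
#' involvement analyses), and dummy-coded group regressions.
#'
#' @param profiles Cohort profile tibble (with `subject_id`).
#' @param subjects Subject tibble with `subject_id`, `pathology`,
#'   `tumor_hemisphere`, and optionally `age`, `sex`.
#' @param threshold Node-involvement / eligibility threshold in percent.
#' @param bins Distance segments.
#' @param sweep Optional vector of thresholds for the sensitivity sweep.
#' @param metrics Metric columns.
#' @return Named list of tibbles (see Details in the vignette).
#' @export
analyze_cohort <- function(profiles, subjects, threshold = 5,
                           bins = asym_distance_bins(), sweep = NULL,
                           metrics = c("fw_fa", "fw_md", "fwf")) {
  stopifnot(all(c("subject_id", "pathology", "tumor_hemisphere") %in%
                  names(subjects)))
  involvement <- subject_involvement(profiles, threshold) |>
    dplyr::left_join(subjects |> dplyr::select("subject_id", "pathology"),
                     by = "subject_id")
  involvement_sweep <- if (!is.null(sweep)) {
    threshold_sweep(profiles, sweep) |>
      dplyr::left_join(subjects |> dplyr::select("subject_id", "pathology"),
                       by = "subject_id")
  }
  whole_tract <- cohort_asymmetry(profiles, subjects, threshold,
                                  bins = NULL, metrics = metrics)
  distance <- cohort_asymmetry(profiles, subjects, threshold, bins = bins,
                               metrics = metrics)
  fwf_edema <- fwf_edema_correlation(profiles) |>
    dplyr::left_join(subjects |> dplyr::select("subject_id", "pathology"),
                     by = "subject_id")

  # whole-tract asymmetry group tests: one FDR family per metric
  # (contrasts that are not estimable on a tiny cohort are skipped)
  wt_kw <- purrr::map_dfr(metrics, function(m) {
    d <- whole_tract |> dplyr::filter(.data$metric == m,
                                      !is.na(.data$asymmetry))
    if (nrow(d) < 3 || dplyr::n_distinct(d$pathology) < 2) return(NULL)
    kruskal_wallis(d, "asymmetry", "pathology", family = m) |>
      dplyr::mutate(metric = m, .before = 1)
  })
  wt_mw <- purrr::map_dfr(metrics, function(m) {
    d <- whole_tract |> dplyr::filter(.data$metric == m,
                                      !is.na(.data$asymmetry))
    if (nrow(d) < 2 || dplyr::n_distinct(d$pathology) < 2) return(NULL)
    mann_whitney_pairwise(d, "asymmetry", "pathology", family = m) |>
      dplyr::mutate(metric = m, .before = 1)
  })
  if (nrow(wt_mw) > 0) wt_mw <- add_fdr(wt_mw)

  # distance-binned pairwise tests: families stratified by metric
  db_mw <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(unique(distance$segment), function(sg) {
      d <- distance |> dplyr::filter(.data$metric == m,
                                     .data$segment == sg,
                                     !is.na(.data$asymmetry))
      if (dplyr::n_distinct(d$pathology) < 2 || nrow(d) < 3) return(NULL)
      mann_whitney_pairwise(d, "asymmetry", "pathology", family = m) |>
        dplyr::mutate(metric = m, segment = sg, .before = 1)
    })
  })
  if (nrow(db_mw) > 0) db_mw <- add_fdr(db_mw)

  # involvement regressions: logistic (involved) and linear (proportion),
  # one FDR family per compartment
  inv_models <- involvement |>
    dplyr::left_join(subjects |> dplyr::select("subject_id",
                                               dplyr::any_of(c("age", "sex"))),
                     by = "subject_id")
  covs <- intersect(c("age", "sex"), names(inv_models))
  model_rows <- inv_models |>
    dplyr::group_by(.data$tract, .data$compartment) |>
    dplyr::group_modify(function(df, key) {
      df$involved_num <- as.integer(df$involved)
      out <- NULL
      if (dplyr::n_distinct(df$involved_num) > 1) {
        fitl <- tryCatch(group_regression(df, "involved_num", "pathology",
                                          covariates = covs,
                                          family = "logistic"),
                         error = function(e) NULL)
        if (!is.null(fitl)) {
          out <- dplyr::bind_rows(out, tidy(fitl) |>
            dplyr::mutate(model = "logistic_involved",
                          flag = fitl$flag))
        }
      }
      fito <- tryCatch(group_regression(df, "proportion_involved",
                                        "pathology", covariates = covs,
                                        family = "linear"),
                       error = function(e) NULL)
      if (!is.null(fito)) {
        out <- dplyr::bind_rows(out, tidy(fito) |>
          dplyr::mutate(model = "ols_proportion", flag = fito$flag))
      }
      out %||% tibble::tibble()
    }) |>
    dplyr::ungroup()
  if (nrow(model_rows) > 0) {
    model_rows <- model_rows |>
      dplyr::filter(grepl("^pathology", .data$term)) |>
      dplyr::mutate(family = .data$compartment) |>
      add_fdr()
  }

  list(involvement = involvement,
       involvement_sweep = involvement_sweep,
       whole_tract_asymmetry = whole_tract,
       distance_asymmetry = distance,
       fwf_edema = fwf_edema,
       asymmetry_omnibus = wt_kw,
       asymmetry_pairwise = wt_mw,
       distance_pairwise = db_mw,
       involvement_models = model_rows,
       threshold = threshold)
}
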