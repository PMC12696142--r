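profile_key_cols <- c("subject_id", "tract", "hemisphere", "node", "type", "name")

#' Write a profile table to long-format CSV
#'
#' Serializes a wide per-node profile tibble (as produced by
#' [tract_profile()] / [cohort_profiles()]) into long rows: metric rows
#' (type "metric"), involvement rows (type "involvement") and point-count
#' rows (type "meta"). Deterministic: stable row order, floats at 9
#' significant digits, missing values as empty fields.
#'
#' @param profiles Wide profile tibble; a `subject_id` column is added as
#'   "subject" when absent.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (!"subject_id" %in% names(profiles)) profiles$subject_id <- "subject"
  inv_cols <- intersect(c("enhancing", "necrotic", "edema", "combined"),
                        names(profiles))
  meta_cols <- intersect("n_points", names(profiles))
  metric_cols <- setdiff(names(profiles),
                         c("subject_id", "tract", "hemisphere", "node",
                           inv_cols, meta_cols))
  long <- profiles |>
    tidyr::pivot_longer(dplyr::all_of(c(metric_cols, inv_cols, meta_cols)),
                        names_to = "name", values_to = "value") |>
    dplyr::mutate(type = dplyr::case_when(
      .data$name %in% inv_cols ~ "involvement",
      .data$name %in% meta_cols ~ "meta",
      TRUE ~ "metric")) |>
    dplyr::select(dplyr::all_of(c(profile_key_cols, "value"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(profile_key_cols)))
  long$value <- ifelse(is.na(long$value), NA_character_,
                       sprintf("%.9g", long$value))
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Read and validate a long-format profile CSV
#'
#' Checks node bounds (1..n_nodes) and uniqueness of the
#' (subject, tract, hemisphere, node, type, name) key, reporting offending
#' row numbers; unknown extra columns are preserved in the long form but
#' ignored when widening. Empty fields round-trip as missing values.
#'
#' @param path CSV path.
#' @param n_nodes Expected number of nodes per tract.
#' @return Wide profile tibble.
#' @export
read_profiles <- function(path, n_nodes = 100) {
  long <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            subject_id = readr::col_character(),
                            tract = readr::col_character(),
                            hemisphere = readr::col_character(),
                            node = readr::col_integer(),
                            type = readr::col_character(),
                            name = readr::col_character(),
                            value = readr::col_double(),
                            .default = readr::col_guess()))
  missing_cols <- setdiff(c(profile_key_cols, "value"), names(long))
  if (length(missing_cols) > 0) {
    abort(paste0("Profile CSV lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_node <- which(is.na(long$node) | long$node < 1 | long$node > n_nodes)
  if (length(bad_node) > 0) {
    abort(sprintf("Node index out of 1..%d at CSV row(s): %s", n_nodes,
                  paste(head(bad_node, 10) + 1, collapse = ", ")))
  }
  key <- do.call(paste, c(long[profile_key_cols], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("Duplicate (subject, tract, hemisphere, node, type, name) ",
                 "key at CSV row(s): ",
                 paste(head(dup, 10) + 1, collapse = ", ")))
  }
  long |>
    dplyr::select(dplyr::all_of(c(profile_key_cols, "value"))) |>
    dplyr::select(-"type") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value") |>
    dplyr::arrange(.data$subject_id, .data$tract, .data$hemisphere,
                   .data$node)
}
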