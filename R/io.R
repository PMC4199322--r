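# Plain-text exports: cluster tables and artifact reports as CSV,
# proximity results as JSON.

#' Write a cluster table as CSV
#'
#' Columns: cluster_id, size, centroid_x/y/z_mm, radius_mm.
#'
#' @param clusters list of [centroid_radius()] clusters.
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = seq_along(clusters),
    size = vapply(clusters, function(c) c$size, 0L),
    centroid_x_mm = vapply(clusters, function(c) c$centroid[1], 0),
    centroid_y_mm = vapply(clusters, function(c) c$centroid[2], 0),
    centroid_z_mm = vapply(clusters, function(c) c$centroid[3], 0),
    radius_mm = vapply(clusters, function(c) c$mean_radius, 0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Write a proximity result as JSON
#'
#' @param px an `hg_proximity` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_proximity_json <- function(px, path) {
  jsonlite::write_json(
    list(compound_mm = px$compound, pair_distances_mm = px$pair_distances,
         p_value = px$p_value, n_resamples = px$n_resamples,
         seed = px$seed, reason = px$reason),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write a permutation-test result as JSON (and its null histogram as CSV)
#'
#' @param test an `hg_permtest` from [hg_perm_test()].
#' @param path output JSON file.
#' @param null_path optional CSV path for the null maxima (one `max_z`
#'   column).
#' @return the path, invisibly.
#' @export
write_permtest_json <- function(test, path, null_path = NULL) {
  jsonlite::write_json(
    list(observed = test$statistic, argmax = test$argmax,
         p = test$p.value, n_perm = test$n_perm, seed = test$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_path))
    utils::write.csv(data.frame(max_z = test$null_max), null_path,
                     row.names = FALSE)
  invisible(path)
}

#' Write an artifact report as CSV
#'
#' @param report the report data.frame from [detect_artifact_trials()].
#' @param path output file.
#' @return the report, invisibly.
#' @export
write_artifact_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
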