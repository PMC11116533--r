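#' Cohort summary of cluster records
#'
#' Descriptive statistics over per-cluster values: mean/sd/median of area,
#' diameter, counts and molecular density, the fraction of clusters with at
#' most `count_cutoff` channels, an upper-percentile molecular density, and
#' field-level means (cluster density, channel counts per area) when field
#' summaries are supplied. An optional minimum-area filter can be applied
#' before the statistics, mirroring analyses restricted to clusters larger
#' than a given footprint.
#'
#' @param records Cluster-record tibble ([quantify_clusters()] columns).
#' @param fields Optional tibble of [field_summary()] rows.
#' @param count_cutoff Channel-count cutoff for `fraction_leq` (default 10).
#' @param density_quantile Upper quantile of the per-cluster molecular
#'   density (default 0.95).
#' @param min_area_um2 Optional area filter: keep clusters with
#'   `area_um2 > min_area_um2` before computing statistics.
#' @return One-row tibble of summary statistics. With a single cluster the
#'   standard deviations are reported as 0 and `degenerate` is flagged.
#' @export
summarize_clusters <- function(records, fields = NULL, count_cutoff = 10,
                               density_quantile = 0.95,
                               min_area_um2 = NULL) {
  if (nrow(records) == 0L) stop("no cluster records", call. = FALSE)
  if (!is.null(min_area_um2)) {
    records <- dplyr::filter(records, .data$area_um2 > min_area_um2)
    if (nrow(records) == 0L) {
      stop("no cluster records pass the area filter", call. = FALSE)
    }
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- tibble::tibble(
    n_clusters = nrow(records),
    n_fields = if (is.null(fields)) NA_integer_ else nrow(fields),
    mean_area_um2 = mean(records$area_um2),
    sd_area_um2 = sd0(records$area_um2),
    median_area_um2 = stats::median(records$area_um2),
    mean_diameter_nm = mean(records$diameter_nm),
    sd_diameter_nm = sd0(records$diameter_nm),
    mean_counts = mean(records$counts),
    sd_counts = sd0(records$counts),
    median_counts = stats::median(records$counts),
    fraction_leq = mean(records$counts <= count_cutoff),
    mean_density_per_um2 = mean(records$density_per_um2),
    density_percentile = unname(
      stats::quantile(records$density_per_um2, density_quantile,
                      na.rm = TRUE)),
    density_quantile = density_quantile,
    count_cutoff = count_cutoff,
    mean_roundness = mean(records$roundness),
    degenerate = nrow(records) < 2L)
  if (!is.null(fields)) {
    out$mean_cluster_density_per_um2 <- mean(fields$cluster_density_per_um2)
    out$mean_channel_counts_per_um2 <- mean(fields$channel_counts_per_um2)
  }
  out
}

#' Percent change between two values
#'
#' `100 * (before - after) / before`: positive for a reduction.
#'
#' @param before Baseline value (> 0).
#' @param after Comparison value.
#' @return Percent change.
#' @examples
#' percent_change(1.77, 1.08)  # ~39% reduction in cluster density
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("baseline must be positive", call. = FALSE)
  100 * (before - after) / before
}

#' Cluster density as a function of channel counts
#'
#' Bins clusters by their channel counts and reports, per bin, the cluster
#' density (clusters per square micrometre of analyzed area) averaged
#' across fields with its standard error, plus the fraction of the total
#' cluster density carried by bins above `cutoff` counts.
#'
#' @param records Cluster records with a `frame` column.
#' @param field_areas Tibble with columns `frame` and `analyzed_area_um2`.
#' @param breaks Count-bin edges (passed to [cut()], right-open).
#' @param cutoff Channel-count cutoff for the high-count density share.
#' @return List with `histogram` (tibble: `bin`, `mid`,
#'   `density_per_um2` mean across fields, `sem`) and `high_count_share`
#'   (fraction of summed density above `cutoff`). Histogram masses sum to
#'   the mean total cluster density.
#' @export
density_by_count_histogram <- function(records, field_areas,
                                       breaks = seq(0, 50, by = 2),
                                       cutoff = 13) {
  stopifnot(all(c("frame", "analyzed_area_um2") %in% names(field_areas)))
  if (max(records$counts) >= max(breaks)) {
    breaks <- c(breaks, max(records$counts) + 1e-9)
  }
  per_field <- records |>
    dplyr::inner_join(field_areas, by = "frame") |>
    dplyr::mutate(bin = cut(.data$counts, breaks, right = FALSE)) |>
    dplyr::count(.data$frame, .data$analyzed_area_um2, .data$bin,
                 .drop = FALSE) |>
    dplyr::mutate(density = .data$n / .data$analyzed_area_um2)
  hist <- per_field |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(density_per_um2 = mean(.data$density),
                     sem = stats::sd(.data$density) /
                       sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::mutate(sem = ifelse(is.na(.data$sem), 0, .data$sem),
                  mid = (breaks[-length(breaks)] + breaks[-1]) / 2)
  lower <- breaks[-length(breaks)]
  high <- sum(hist$density_per_um2[lower >= cutoff])
  total <- sum(hist$density_per_um2)
  list(histogram = hist,
       high_count_share = if (total > 0) high / total else 0,
       cutoff = cutoff)
}
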