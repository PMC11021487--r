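#' Percent diameter change relative to the pre-ablation baseline
#'
#' For each segment, 100 x (D_day - D_0) / D_0, where day 0 is the
#' pre-ablation measurement. The statistic is scale invariant: multiplying
#' a whole series by a constant leaves it unchanged.
#'
#' @param records Long-format tibble of longitudinal diameter measurements
#'   with columns `segment_id`, `vessel_class`, `day`, `diameter_um`
#'   (optionally `x_um`, `y_um`, `region`). Every segment needs a day-0
#'   entry.
#' @param day Day(s) to evaluate; `NULL` (default) evaluates every
#'   post-baseline day present.
#' @return A tibble `segment_id`, `vessel_class`, `day`, `pct_change`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   segment_id = "v10", vessel_class = "vein",
#'   day = c(0, 23), diameter_um = c(20, 95.8)
#' )
#' percent_diameter_change(rec, 23) # +379%
percent_diameter_change <- function(records, day = NULL) {
  records <- as_tibble(records)
  base <- records |>
    filter(.data$day == 0) |>
    select("segment_id", d0 = "diameter_um")
  no_base <- setdiff(unique(records$segment_id), base$segment_id)
  if (length(no_base) > 0) {
    abort(paste0("no day-0 baseline for segment(s): ", toString(no_base)))
  }
  keep <- records |> filter(.data$day != 0)
  if (!is.null(day)) {
    want <- day
    missing <- setdiff(want, keep$day)
    if (length(missing) > 0) {
      abort(paste0("no measurements at day(s): ", toString(missing)))
    }
    keep <- keep |> filter(.data$day %in% want)
  }
  keep |>
    left_join(base, by = "segment_id") |>
    mutate(pct_change = 100 * (.data$diameter_um - .data$d0) / .data$d0) |>
    select("segment_id", "vessel_class", "day", "pct_change")
}

#' Binned diameter distribution
#'
#' Frequency distribution of vessel inner diameters at one time point, per
#' vessel class. Bins are centered on multiples of `bin_width` (the 30 um
#' bin spans [15, 45) for a 30 um width) and vessels below the resolvable
#' limit `min_diameter` are excluded, matching the quantitative-analysis
#' inclusion rule of intravital measurements (default > 11 um).
#'
#' @param records Long-format diameter records (see
#'   [percent_diameter_change()]).
#' @param day Day to histogram.
#' @param bin_width Bin width and center spacing, um (default 30).
#' @param min_diameter Exclusion threshold, um; vessels with
#'   `diameter_um <= min_diameter` are dropped (default 11).
#' @return A tibble `vessel_class`, `bin_center`, `n`, including empty
#'   bins between the smallest and largest occupied center.
#' @export
diameter_histogram <- function(records, day, bin_width = 30,
                               min_diameter = 11) {
  if (bin_width <= 0) abort("bin_width must be positive")
  d <- day
  rec <- as_tibble(records) |>
    filter(.data$day == d, .data$diameter_um > min_diameter)
  if (nrow(rec) == 0) {
    return(tibble(vessel_class = character(), bin_center = numeric(),
                  n = integer()))
  }
  rec <- rec |>
    mutate(bin_center = round(.data$diameter_um / bin_width) * bin_width)
  centers <- seq(min(rec$bin_center), max(rec$bin_center), by = bin_width)
  tidyr::expand_grid(vessel_class = sort(unique(rec$vessel_class)),
                     bin_center = centers) |>
    left_join(
      rec |> group_by(.data$vessel_class, .data$bin_center) |>
        summarise(n = n(), .groups = "drop"),
      by = c("vessel_class", "bin_center")
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Mean and SD diameter by radial region and vessel class
#'
#' Summarises diameters at one time point for the three equidistant radial
#' regions (proximal/medial/distal distance classes from the nearest
#' ablation site). Sample (n-1) standard deviation; regions with a single
#' record report SD 0, empty combinations report `n = 0` with `NA`
#' mean/SD.
#'
#' @param records Diameter records carrying a `region` column (see
#'   [assign_regions()]).
#' @param day Day to summarise.
#' @return A tibble `region`, `vessel_class`, `n`, `mean_um`, `sd_um`.
#' @export
region_summary <- function(records, day) {
  records <- as_tibble(records)
  if (!"region" %in% names(records)) {
    abort("records carry no region labels; run assign_regions() first")
  }
  d <- day
  rec <- records |> filter(.data$day == d)
  tidyr::expand_grid(region = c("proximal", "medial", "distal"),
                     vessel_class = sort(unique(records$vessel_class))) |>
    left_join(
      rec |> group_by(.data$region, .data$vessel_class) |>
        summarise(n = n(), mean_um = mean(.data$diameter_um),
                  sd_um = if (n() > 1) sd(.data$diameter_um) else 0,
                  .groups = "drop"),
      by = c("region", "vessel_class")
    ) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Assign radial region labels from distance to the nearest ablation
#'
#' Computes the Euclidean distance from each segment's recorded position
#' (its midpoint) to the nearest ablation site, then splits the maximum
#' distance into three equal parts: `[0, max/3]` proximal,
#' `(max/3, 2max/3]` medial, `(2max/3, max]` distal. A segment exactly at
#' a cut point goes to the nearer (lower) class.
#'
#' @param records Diameter records with position columns `x_um`, `y_um`.
#' @param ablation_sites Data frame of ablation coordinates with columns
#'   `x_um`, `y_um`; at least one site required.
#' @return `records` with added `distance_um` and `region` columns.
#' @export
assign_regions <- function(records, ablation_sites) {
  records <- as_tibble(records)
  ablation_sites <- as_tibble(ablation_sites)
  if (nrow(ablation_sites) == 0) abort("at least one ablation site required")
  if (!all(c("x_um", "y_um") %in% names(records))) {
    abort("records need x_um and y_um positions to assign regions")
  }
  dist_to_nearest <- function(x, y) {
    min(sqrt((ablation_sites$x_um - x)^2 + (ablation_sites$y_um - y)^2))
  }
  d <- purrr::map2_dbl(records$x_um, records$y_um, dist_to_nearest)
  dmax <- max(d)
  region <- if (dmax == 0) {
    rep("proximal", length(d))
  } else {
    cut(d, breaks = c(-Inf, dmax / 3, 2 * dmax / 3, Inf),
        labels = c("proximal", "medial", "distal"), right = TRUE) |>
      as.character()
  }
  records$distance_um <- d
  records$region <- region
  records
}

#' Read longitudinal diameter records
#'
#' @param path CSV with columns
#'   `segment_id,vessel_class,day,diameter_um[,x_um,y_um]`.
#' @return A records tibble.
#' @export
read_remodeling_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(rec, c("segment_id", "vessel_class", "day", "diameter_um"),
                basename(path))
  if (any(rec$diameter_um <= 0)) abort("diameters must be positive")
  rec
}
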