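#' Region labels commonly affected in every group
#'
#' The cross-mutagen region comparison is restricted to region labels
#' observed (with nonzero counts) in every group, so the compared
#' distributions share a support. If the intersection is empty all
#' observed regions are returned with a warning.
#'
#' @param annotations Tibble of annotation records with `region` and a
#'   grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return Sorted character vector of common region labels.
#' @export
common_regions <- function(annotations, group = "group") {
  annotations <- tibble::as_tibble(annotations)
  sets <- split(annotations$region, annotations[[group]])
  if (length(sets) < 2) {
    stop("at least 2 groups are required.", call. = FALSE)
  }
  common <- purrr::reduce(purrr::map(sets, unique), intersect)
  if (length(common) == 0) {
    warning("no region label is shared by all groups; returning all ",
            "observed regions.", call. = FALSE)
    return(sort(unique(annotations$region)))
  }
  sort(common)
}

#' Region proportions over commonly affected regions
#'
#' Restricts each group's annotation records to the common region set
#' (see [common_regions()]) and computes each region's percentage of the
#' group's common-region records. `retained_share` reports, per group,
#' the percentage of all records that fall inside the common regions, so
#' the restriction is auditable (it is typically over 99%).
#'
#' @inheritParams common_regions
#' @return Tibble with `group`, `region`, `n`, `pct`, `retained_share`.
#' @export
region_proportions <- function(annotations, group = "group") {
  annotations <- tibble::as_tibble(annotations)
  regions <- common_regions(annotations, group)
  totals <- annotations |>
    dplyr::count(.data[[group]], name = "n_all")
  annotations |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::count(.data[[group]], .data$region, name = "n") |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(totals, by = group) |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::mutate(retained_share = 100 * sum(.data$n) / .data$n_all) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of("n_all"))
}

#' Impact-level counts
#'
#' Tallies annotation records by impact level (MODIFIER, LOW, MODERATE,
#' HIGH) per group, optionally per line.
#'
#' @inheritParams common_regions
#' @param per_line Also break counts down by `sample_id`.
#' @return Tibble of counts with all four levels present (zero-filled).
#' @export
impact_level_counts <- function(annotations, group = "group",
                                per_line = FALSE) {
  annotations <- tibble::as_tibble(annotations)
  annotations$impact <- factor(annotations$impact, levels = impact_levels)
  by <- c(group, if (per_line) "sample_id", "impact")
  annotations |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), name = "count",
                 .drop = FALSE) |>
    dplyr::mutate(impact = as.character(.data$impact))
}

#' Missense-to-silent ratio of coding substitutions
#'
#' @param class_counts Tibble with `functional_class` and `count`
#'   columns, or a named numeric vector with `missense` and `silent`
#'   entries.
#' @return The ratio missense/silent (full precision; reports round to
#'   2 decimals), or `NA` with a warning when no silent SBSs exist.
#' @examples
#' functional_class_ratio(c(missense = 66, silent = 17))  # approx 3.88
#' @export
functional_class_ratio <- function(class_counts) {
  if (is.data.frame(class_counts)) {
    counts <- stats::setNames(class_counts$count,
                              class_counts$functional_class)
  } else {
    counts <- class_counts
  }
  mis <- unname(counts["missense"])
  sil <- unname(counts["silent"])
  if (is.na(mis) || is.na(sil)) {
    stop("`class_counts` must provide missense and silent counts.",
         call. = FALSE)
  }
  if (sil == 0) {
    warning("no silent SBSs: missense/silent ratio is undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  mis / sil
}
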