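category_levels <- c("SBS", "INDEL_deletion", "INDEL_insertion", "MNV",
                     "DEL_SV", "DUP_SV", "BND_SV")

#' Assign each call to a mutation category
#'
#' Adds a `category` column: 1 bp equal-length substitutions are `SBS`;
#' merged runs (or equal-length multi-base substitutions) are `MNV`;
#' length-changing alleles up to 50 bp are `INDEL_deletion` /
#' `INDEL_insertion`; symbolic and breakend records keep their SV subtype
#' (`DEL_SV`, `DUP_SV`, `BND_SV`, all over 50 bp by construction).
#'
#' @param calls Tibble of calls.
#' @return The tibble with a `category` column.
#' @export
classify_variant <- function(calls) {
  calls <- tibble::as_tibble(calls)
  len_ref <- nchar(calls$ref)
  len_alt <- nchar(calls$alt)
  category <- dplyr::case_when(
    calls$sv_type %in% c("DEL_SV", "DUP_SV", "BND_SV") ~ calls$sv_type,
    len_ref == 1 & len_alt == 1 ~ "SBS",
    len_ref == len_alt & len_ref >= 2 ~ "MNV",
    len_ref > len_alt & len_ref - len_alt <= SV_MIN_LEN ~ "INDEL_deletion",
    len_alt > len_ref & len_alt - len_ref <= SV_MIN_LEN ~ "INDEL_insertion",
    TRUE ~ NA_character_
  )
  if (any(is.na(category))) {
    bad <- which(is.na(category))[1]
    stop("unclassifiable allele at ", calls$chrom[bad], ":",
         calls$pos[bad], " (", calls$ref[bad], ">", calls$alt[bad], ")",
         call. = FALSE)
  }
  calls$category <- category
  calls
}

#' Transition/transversion ratio of single-base substitutions
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); everything else is a transversion. Calls that were
#' merged into MNVs must already have been consumed by [merge_mnv()];
#' only rows categorised `SBS` enter the tally. When no transversions are
#' present the ratio is undefined and reported as `Inf` with
#' `undefined = TRUE`.
#'
#' @param calls Tibble of calls with `ref` and `alt` (and optionally a
#'   `category` column, in which case only `SBS` rows are used).
#' @return A one-row tibble: `n_transitions`, `n_transversions`, `ratio`,
#'   `undefined`.
#' @export
ts_tv_ratio <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if ("category" %in% names(calls)) {
    calls <- calls[calls$category == "SBS", , drop = FALSE]
  }
  pair <- paste0(calls$ref, calls$alt)
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- nrow(calls) - ts
  tibble::tibble(
    n_transitions = ts,
    n_transversions = tv,
    ratio = if (tv == 0) Inf else ts / tv,
    undefined = tv == 0
  )
}

#' Length-class breakdown of INDELs and MNVs
#'
#' INDELs are split at 1 bp versus >= 2 bp (per direction); MNVs at 2 bp
#' versus >= 3 bp.
#'
#' @param calls Tibble of categorised calls (see [classify_variant()]).
#' @return Tibble with columns `category`, `length_class`, `n`.
#' @export
length_class_breakdown <- function(calls) {
  calls <- tibble::as_tibble(calls)
  indel <- calls[calls$category %in% c("INDEL_deletion", "INDEL_insertion"), ]
  mnv <- calls[calls$category == "MNV", ]
  out <- list()
  if (nrow(indel)) {
    len <- abs(nchar(indel$alt) - nchar(indel$ref))
    out$indel <- tibble::tibble(
      category = indel$category,
      length_class = ifelse(len == 1, "1 bp", ">=2 bp")
    )
  }
  if (nrow(mnv)) {
    len <- if ("mnv_length" %in% names(mnv)) {
      ifelse(is.na(mnv$mnv_length), nchar(mnv$ref), mnv$mnv_length)
    } else {
      nchar(mnv$ref)
    }
    out$mnv <- tibble::tibble(
      category = "MNV",
      length_class = ifelse(len == 2, "2 bp", ">=3 bp")
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(category = character(),
                          length_class = character(), n = integer()))
  }
  dplyr::bind_rows(out) |>
    dplyr::count(.data$category, .data$length_class, name = "n")
}

#' Aggregate line mutation sets into a spectrum summary
#'
#' Counts calls per category over all lines of a group, within the
#' requested zygosity scope (homozygous only, or homozygous +
#' heterozygous), and computes category proportions of the group total.
#'
#' @param calls Tibble of labelled calls (columns `sample_id`,
#'   `category`, `zygosity`), e.g. `tidy()` of a
#'   [run_mutation_pipeline()] result.
#' @param group_label Label for the group (e.g. the mutagen).
#' @param zygosity_scope `"all"` (homozygous + heterozygous) or
#'   `"homozygous"`.
#' @param per_line Also break counts down by `sample_id`.
#' @return A tibble with `group_label`, `zygosity_scope`, `category`,
#'   `count`, `total` and `proportion` (percent); with
#'   `per_line = TRUE` an additional `sample_id` column and per-line
#'   totals.
#' @export
aggregate_spectrum <- function(calls, group_label = "group",
                               zygosity_scope = c("all", "homozygous"),
                               per_line = FALSE) {
  zygosity_scope <- match.arg(zygosity_scope)
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0 && !per_line) {
    return(tibble::tibble(
      group_label = group_label, zygosity_scope = zygosity_scope,
      category = category_levels, count = 0L, total = 0L,
      proportion = NA_real_))
  }
  if (zygosity_scope == "homozygous") {
    calls <- calls[calls$zygosity == "homozygous", , drop = FALSE]
  }
  calls$category <- factor(calls$category, levels = category_levels)
  if (per_line) {
    counts <- calls |>
      dplyr::count(.data$sample_id, .data$category,
                   name = "count", .drop = FALSE) |>
      dplyr::group_by(.data$sample_id)
  } else {
    counts <- calls |>
      dplyr::count(.data$category, name = "count", .drop = FALSE)
  }
  counts |>
    dplyr::mutate(total = sum(.data$count),
                  proportion = 100 * .data$count / .data$total) |>
    dplyr::ungroup() |>
    dplyr::mutate(group_label = group_label,
                  zygosity_scope = zygosity_scope,
                  category = as.character(.data$category)) |>
    dplyr::relocate(dplyr::all_of(c("group_label", "zygosity_scope")))
}

#' Spectrum summary from a ready-made count table
#'
#' Adds group totals and percent proportions to a long table of
#' per-category counts (such as [soybean_spectrum_counts()]), grouping by
#' every column other than `category` and `count`.
#'
#' @param counts Tibble with a `category` and a `count` column.
#' @return The table with `total` and `proportion` (percent) columns.
#' @examples
#' spectrum_from_counts(soybean_spectrum_counts())
#' @export
spectrum_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("category", "count") %in% names(counts)))
  group_cols <- setdiff(names(counts), c("category", "count"))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(total = sum(.data$count),
                  proportion = 100 * .data$count / .data$total) |>
    dplyr::ungroup()
}

#' Homozygous share of a mutation set
#'
#' Percentage of all detected mutations (homozygous + heterozygous) that
#' are homozygous: `100 * homozygous_total / all_total`.
#'
#' @param homozygous_total Count of homozygous mutations.
#' @param all_total Count of homozygous + heterozygous mutations; > 0.
#' @return Percentage (full precision; reports round to 2 decimals).
#' @examples
#' homozygous_fraction(1988, 9695)  # approx 20.51
#' @export
homozygous_fraction <- function(homozygous_total, all_total) {
  if (any(all_total <= 0)) {
    stop("`all_total` must be positive.", call. = FALSE)
  }
  100 * homozygous_total / all_total
}

#' Percentage of a spectrum total in one category or category set
#'
#' @param summary A spectrum summary tibble with `category`, `count` (as
#'   from [aggregate_spectrum()] or [spectrum_from_counts()]).
#' @param categories Category name(s) whose combined share is wanted,
#'   e.g. `c("DEL_SV", "DUP_SV", "BND_SV")` for all SVs.
#' @return Percentage of the summary total (full precision).
#' @export
category_proportion <- function(summary, categories) {
  summary <- tibble::as_tibble(summary)
  total <- sum(summary$count)
  if (total <= 0) stop("summary total must be positive.", call. = FALSE)
  100 * sum(summary$count[summary$category %in% categories]) / total
}

#' Pearson chi-squared test on a contingency table
#'
#' Uncorrected Pearson chi-squared test of homogeneity on an r x c count
#' table, with `df = (r - 1)(c - 1)` and a significance flag at the 0.05
#' level. Zero row or column marginals make the test inapplicable.
#'
#' @param contingency Matrix or data frame of counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `significant`.
#' @examples
#' chi_squared_test(rbind(c(10, 20), c(30, 60)))  # statistic 0
#' @export
chi_squared_test <- function(contingency) {
  x <- as.matrix(contingency)
  if (any(x < 0)) stop("counts must be non-negative.", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero marginal: chi-squared test is inapplicable.", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    significant = res$p.value < 0.05
  )
}

significance_flag <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "N.S."
  )
}

#' Two-sample t test on per-line values
#'
#' Student's two-sample t test with pooled variance (the convention used
#' for cross-mutagen per-line comparisons; set `var_equal = FALSE` for
#' Welch's test). Significance is flagged at the 0.05 / 0.01 / 0.001
#' levels (`N.S.` for p >= 0.05).
#'
#' @param a,b Numeric vectors of per-line values (each length >= 2).
#' @param var_equal Use the pooled-variance Student's test (default).
#' @return One-row tibble: `t`, `df`, `p_value`, `flag`.
#' @export
two_sample_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 values.", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2,
                          p_value = 1, flag = "N.S."))
  }
  if (var_equal && stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero pooled variance: t test is inapplicable.", call. = FALSE)
  }
  res <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    flag = significance_flag(res$p.value)
  )
}

#' Per-mutagen phenotype-class percentages
#'
#' For a long table of screened phenotypic mutant-family counts, computes
#' each class's share of its mutagen's total (percent).
#'
#' @param table Tibble with columns `phenotype`, `mutagen`, `count`.
#' @return The table with `total` and `pct` columns.
#' @examples
#' phenotype_proportions(soybean_phenotype_counts())
#' @export
phenotype_proportions <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("phenotype", "mutagen", "count") %in% names(table)))
  table |>
    dplyr::group_by(.data$mutagen) |>
    dplyr::mutate(total = sum(.data$count),
                  pct = 100 * .data$count / .data$total) |>
    dplyr::ungroup()
}

#' Mean and error-band half-width
#'
#' Replicate summaries are presented as mean +/- 1.97 x sample standard
#' deviation; this returns the mean and that half-width.
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row tibble: `mean`, `sd`, `half_width`.
#' @export
error_band <- function(values) {
  if (length(values) < 2) {
    stop("at least 2 values are required.", call. = FALSE)
  }
  s <- stats::sd(values)
  tibble::tibble(mean = mean(values), sd = s, half_width = 1.97 * s)
}
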