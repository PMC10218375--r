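#' Bundled count tables from a soybean mutagenesis experiment
#'
#' Small reference tables from a carbon-ion beam versus gamma-ray
#' mutagenesis experiment on Williams 82 soybean, bundled so the package's
#' summary statistics can be exercised on real printed counts without any
#' sequencing data. All constructors return tibbles in long format.
#'
#' * `soybean_phenotype_counts()`: screened phenotypic mutant families in
#'   the M2 generation, per phenotype class and mutagen (column totals 325
#'   carbon, 336 gamma).
#' * `soybean_spectrum_counts()`: final mutation-spectrum counts per
#'   mutagen, zygosity scope and category (SBS, INDEL deletions/insertions,
#'   MNV, DEL_SV, DUP_SV, BND_SV).
#' * `soybean_effect_counts()`: functional-class counts (missense,
#'   nonsense, silent) of coding SBSs per mutagen and zygosity scope.
#' * `soybean_impact_counts()`: annotation impact-level counts (MODIFIER,
#'   LOW, MODERATE, HIGH) per mutagen and zygosity scope.
#' * `soybean_endpoint_doses()`: matched-endpoint doses (Gy) for the two
#'   mutagens (shoulder doses, 50%-effect doses, peak-yield and half-yield
#'   doses), the inputs to [rbe()].
#'
#' @return A tibble; see details above.
#' @name soybean_tables
NULL

#' @rdname soybean_tables
#' @export
soybean_phenotype_counts <- function() {
  tibble::tibble(
    phenotype = rep(c("leaf_color", "late_maturity", "dwarf", "precocity",
                      "height", "infrequent"), each = 2),
    mutagen = rep(c("carbon", "gamma"), times = 6),
    count = c(94L, 91L, 59L, 73L, 23L, 69L, 39L, 35L, 34L, 35L, 76L, 33L)
  )
}

#' @rdname soybean_tables
#' @export
soybean_spectrum_counts <- function() {
  cat_levels <- c("SBS", "INDEL_deletion", "INDEL_insertion", "MNV",
                  "DEL_SV", "DUP_SV", "BND_SV")
  tibble::tibble(
    mutagen = rep(c("carbon", "gamma"), each = 14),
    zygosity_scope = rep(rep(c("homozygous", "all"), each = 7), times = 2),
    category = rep(cat_levels, times = 4),
    count = c(
      # carbon, homozygous-only
      1392L, 462L, 84L, 41L, 3L, 0L, 6L,
      # carbon, homozygous + heterozygous
      5677L, 1892L, 1379L, 139L, 43L, 77L, 488L,
      # gamma, homozygous-only
      3903L, 866L, 385L, 123L, 1L, 1L, 0L,
      # gamma, homozygous + heterozygous
      8947L, 2619L, 1819L, 283L, 40L, 71L, 464L
    )
  )
}

#' @rdname soybean_tables
#' @export
soybean_effect_counts <- function() {
  tibble::tibble(
    mutagen = rep(c("carbon", "gamma"), each = 6),
    zygosity_scope = rep(rep(c("homozygous", "all"), each = 3), times = 2),
    functional_class = rep(c("missense", "nonsense", "silent"), times = 4),
    count = c(
      66L, 3L, 17L,     # carbon homozygous
      164L, 5L, 60L,    # carbon homozygous + heterozygous
      223L, 5L, 85L,    # gamma homozygous
      340L, 11L, 163L   # gamma homozygous + heterozygous
    )
  )
}

#' @rdname soybean_tables
#' @export
soybean_impact_counts <- function() {
  tibble::tibble(
    mutagen = rep(c("carbon", "gamma"), each = 8),
    zygosity_scope = rep(rep(c("homozygous", "all"), each = 4), times = 2),
    impact = rep(c("MODIFIER", "LOW", "MODERATE", "HIGH"), times = 4),
    count = c(
      3810L, 32L, 76L, 41L,        # carbon homozygous
      16814L, 707L, 1166L, 1057L,  # carbon homozygous + heterozygous
      12144L, 119L, 239L, 86L,     # gamma homozygous
      27400L, 857L, 448L, 410L     # gamma homozygous + heterozygous
    )
  )
}

#' @rdname soybean_tables
#' @export
soybean_endpoint_doses <- function() {
  tibble::tibble(
    endpoint = c("survival_shoulder", "survival_half", "fertility_half",
                 "fertility_shoulder", "peak_yield", "yield_half"),
    gamma_dose = c(343, 376, 289, 263, 100, 350),
    carbon_dose = c(115, 142, 111, 101, 40, 120)
  )
}
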