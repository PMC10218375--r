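test_that("calls map to exactly one spectrum category", {
  calls <- bind_rows(
    mk_call(pos = 1, ref = "A", alt = "G"),
    mk_call(pos = 10, ref = "ACGT", alt = "A"),
    mk_call(pos = 20, ref = "A", alt = "ATT"),
    mk_call(pos = 30, ref = "AT", alt = "GC"),
    mk_call(pos = 40, ref = "N", alt = "<DEL>", af = NA, gt = "0/1",
            sv_type = "DEL_SV", sv_end = 240))
  out <- classify_variant(calls)
  expect_equal(out$category,
               c("SBS", "INDEL_deletion", "INDEL_insertion", "MNV", "DEL_SV"))

  too_long <- mk_call(ref = "A", alt = paste(rep("T", 60), collapse = ""))
  expect_error(classify_variant(too_long), "unclassifiable")
})

test_that("Ts/Tv tallies match a per-pair oracle", {
  calls <- bind_rows(mk_call(pos = 1, ref = "A", alt = "G"),
                     mk_call(pos = 2, ref = "C", alt = "T"),
                     mk_call(pos = 3, ref = "A", alt = "C"))
  r <- ts_tv_ratio(calls)
  expect_equal(r$ratio, 2)
  expect_equal(r$n_transitions + r$n_transversions, 3)

  all_ts <- bind_rows(mk_call(pos = 1, ref = "A", alt = "G"),
                      mk_call(pos = 2, ref = "T", alt = "C"))
  expect_true(ts_tv_ratio(all_ts)$undefined)
  expect_equal(ts_tv_ratio(all_ts)$ratio, Inf)

  set.seed(23)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 500, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  calls <- bind_rows(lapply(1:500, function(i)
    mk_call(pos = i * 3, ref = ref[i], alt = alt[i])))
  got <- ts_tv_ratio(calls)
  is_ts <- mapply(function(r, a) {
    (r %in% c("A", "G") && a %in% c("A", "G")) ||
      (r %in% c("C", "T") && a %in% c("C", "T"))
  }, ref, alt)
  expect_equal(got$n_transitions, sum(is_ts))
  expect_equal(got$ratio, sum(is_ts) / sum(!is_ts))
})

test_that("length classes split INDELs at 1 bp and MNVs at 2 bp", {
  calls <- classify_variant(bind_rows(
    mk_call(pos = 1, ref = "AT", alt = "A"),       # 1 bp del
    mk_call(pos = 10, ref = "ATTT", alt = "A"),    # 3 bp del
    mk_call(pos = 20, ref = "A", alt = "ATT"),     # 2 bp ins
    mk_call(pos = 30, ref = "A", alt = "AG"),      # 1 bp ins
    mk_call(pos = 40, ref = "AT", alt = "GC"),     # 2 bp MNV
    mk_call(pos = 50, ref = "ATG", alt = "GCA"))) # 3 bp MNV
  got <- length_class_breakdown(calls)
  expect_equal(got$n[got$category == "INDEL_deletion" &
                       got$length_class == "1 bp"], 1L)
  expect_equal(got$n[got$category == "INDEL_insertion" &
                       got$length_class == ">=2 bp"], 1L)
  expect_equal(got$n[got$category == "MNV" & got$length_class == "2 bp"], 1L)
  expect_equal(got$n[got$category == "MNV" & got$length_class == ">=3 bp"], 1L)
  expect_equal(sum(got$n), 6L)
})

test_that("spectrum totals reproduce the published aggregation identities", {
  s <- spectrum_from_counts(soybean_spectrum_counts())
  total_of <- function(m, z) unique(s$total[s$mutagen == m &
                                              s$zygosity_scope == z])
  expect_equal(total_of("carbon", "homozygous"), 1988L)
  expect_equal(total_of("carbon", "all"), 9695L)
  expect_equal(total_of("gamma", "homozygous"), 5279L)
  expect_equal(total_of("gamma", "all"), 14243L)
  # proportions sum to 100 within each group
  sums <- s |> group_by(mutagen, zygosity_scope) |>
    summarise(p = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$p - 100) < 1e-9))
})

test_that("homozygous fractions and SV proportions match printed percentages", {
  expect_equal(round(homozygous_fraction(1988, 9695), 2), 20.51)
  expect_equal(round(homozygous_fraction(5279, 14243), 2), 37.06)
  expect_equal(homozygous_fraction(5, 5), 100)
  expect_error(homozygous_fraction(1, 0), "positive")

  s <- spectrum_from_counts(soybean_spectrum_counts())
  svs <- c("DEL_SV", "DUP_SV", "BND_SV")
  carbon_all <- s[s$mutagen == "carbon" & s$zygosity_scope == "all", ]
  gamma_homo <- s[s$mutagen == "gamma" & s$zygosity_scope == "homozygous", ]
  expect_equal(round(category_proportion(carbon_all, svs), 2), 6.27)
  expect_equal(round(category_proportion(gamma_homo, svs), 2), 0.04)
  expect_equal(category_proportion(carbon_all, "nonexistent"), 0)
})

test_that("aggregate_spectrum counts calls by scope and is order-invariant", {
  sim <- simulate_mutant_lines(n_lines = 3, seed = 55)
  res <- run_mutation_pipeline(sim$calls, sim$controls, sim$chromosomes)
  agg <- aggregate_spectrum(res$calls, "carbon", "all")
  expect_equal(sum(agg$count), nrow(res$calls))
  expect_equal(unique(agg$total), nrow(res$calls))

  hom <- aggregate_spectrum(res$calls, "carbon", "homozygous")
  expect_equal(sum(hom$count), sum(res$calls$zygosity == "homozygous"))

  shuffled <- res$calls[sample(nrow(res$calls)), ]
  expect_equal(aggregate_spectrum(shuffled, "carbon", "all"), agg)

  per_line <- aggregate_spectrum(res$calls, "carbon", "all", per_line = TRUE)
  expect_equal(sum(per_line$count), sum(agg$count))

  empty <- aggregate_spectrum(res$calls[0, ], "x", "all")
  expect_equal(sum(empty$count), 0)
})

test_that("chi-squared equals the expected-count summation oracle", {
  prop <- chi_squared_test(rbind(c(10, 20), c(30, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_false(prop$significant)

  diag <- chi_squared_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag$statistic, 20)
  expect_equal(diag$df, 1)
  expect_true(diag$significant)

  # the published phenotype table, 6 classes x 2 mutagens
  tab <- soybean_phenotype_counts() |>
    tidyr::pivot_wider(names_from = mutagen, values_from = count)
  m <- as.matrix(tab[, c("carbon", "gamma")])
  got <- chi_squared_test(m)
  expect_equal(got$statistic, chisq_oracle(m))
  expect_equal(got$df, 5)
  expect_true(got$significant)

  set.seed(41)
  for (i in 1:10) {
    m <- matrix(rpois(6, 40) + 1, nrow = 2)
    expect_equal(chi_squared_test(m)$statistic, chisq_oracle(m))
  }
  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("the pooled t test equals the textbook formula oracle", {
  same <- two_sample_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$flag, "N.S.")

  shifted <- two_sample_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_true(shifted$p_value < 0.001)
  expect_equal(shifted$flag, "***")

  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(6, 10, 2); b <- rnorm(8, 11, 2)
    got <- two_sample_t_test(a, b)
    expect_equal(got$t, t_oracle(a, b))
    expect_equal(got$df, 12)
  }
  expect_error(two_sample_t_test(c(1), c(1, 2)), "at least 2")
  expect_error(two_sample_t_test(c(1, 1), c(2, 2)), "inapplicable")
})

test_that("phenotype percentages reproduce the screened-family shares", {
  p <- phenotype_proportions(soybean_phenotype_counts())
  get <- function(ph, m) p$pct[p$phenotype == ph & p$mutagen == m]
  expect_equal(unique(p$total[p$mutagen == "carbon"]), 325L)
  expect_equal(unique(p$total[p$mutagen == "gamma"]), 336L)
  expect_equal(round(get("leaf_color", "carbon"), 1), 28.9)
  expect_equal(round(get("infrequent", "carbon"), 1), 23.4)
  expect_equal(round(get("dwarf", "gamma"), 1), 20.5)
  expect_equal(round(get("dwarf", "carbon"), 1), 7.1)
  expect_equal(round(get("infrequent", "gamma"), 1), 9.8)
})

test_that("error bands are mean plus/minus 1.97 sample SD", {
  expect_equal(error_band(c(4, 4, 4))$half_width, 0)
  band <- error_band(c(0, 2))
  expect_equal(band$mean, 1)
  expect_equal(band$half_width, 1.97 * sqrt(2))
  set.seed(3)
  x <- rnorm(20)
  expect_equal(error_band(x)$half_width, 1.97 * sd(x))
  expect_error(error_band(5), "at least 2")
})
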