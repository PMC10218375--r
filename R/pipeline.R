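#' Zygosity from alternate allele frequency
#'
#' Classifies small-variant calls by allele frequency: `af >= 0.75` is
#' homozygous, `0.25 <= af < 0.75` heterozygous. The boundary at 0.75 goes
#' to the homozygous class because that rule is stated inclusively
#' (`AF >= 75%`). Calls below `discard_below` (default 0.25) are too
#' weakly supported to genotype and are marked `discard`.
#'
#' @param af Numeric vector of allele frequencies in \[0, 1\].
#' @param discard_below Lower bound of the heterozygous band.
#' @return Character vector: `"homozygous"`, `"heterozygous"` or
#'   `"discard"`.
#' @examples
#' classify_zygosity_small(c(0.8, 0.5, 0.75, 0.1))
#' @export
classify_zygosity_small <- function(af, discard_below = 0.25) {
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop("allele frequencies must lie in [0, 1].", call. = FALSE)
  }
  dplyr::case_when(
    af >= 0.75 ~ "homozygous",
    af >= discard_below ~ "heterozygous",
    TRUE ~ "discard"
  )
}

#' Zygosity from a structural-variant genotype string
#'
#' Diploid `GT` strings (as emitted by SV genotypers): a genotype with
#' exactly one reference (`0`) allele is heterozygous, with no reference
#' allele homozygous, with only reference alleles `reference`, and any
#' missing (`.`) allele gives `unknown`.
#'
#' @param gt Character vector of diploid genotypes (`"0/1"`, `"1|1"`, ...).
#' @return Character vector: `"homozygous"`, `"heterozygous"`,
#'   `"reference"` or `"unknown"`.
#' @examples
#' classify_zygosity_sv(c("0/1", "1/1", "0/0", "./."))
#' @export
classify_zygosity_sv <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return("unknown")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2) {
      stop("non-diploid genotype string: ", g, call. = FALSE)
    }
    if (any(alleles == ".")) return("unknown")
    n_ref <- sum(alleles == "0")
    if (n_ref == 2) "reference" else if (n_ref == 1) "heterozygous"
    else "homozygous"
  }, character(1), USE.NAMES = FALSE)
}

#' Equality key for cross-sample variant comparison
#'
#' Small variants are keyed by `(chrom, pos, ref, alt)`. Deletions and
#' duplications over 50 bp are keyed by `(sv_type, chrom, pos, sv_end)`
#' and breakends by both loci. With `sv_tolerance > 0`, SV positions are
#' binned to multiples of the tolerance so near-identical breakpoints
#' compare equal (default 0: exact breakpoints).
#'
#' @param calls Tibble of calls (see [read_vcf_subset()]).
#' @param sv_tolerance Positional bin width in bp for SV keys.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(calls, sv_tolerance = 0) {
  bin <- function(p) {
    if (sv_tolerance > 0) as.integer(round(p / sv_tolerance)) else p
  }
  dplyr::case_when(
    calls$sv_type == "none" ~
      paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"),
    calls$sv_type == "BND_SV" ~
      paste("BND_SV", calls$chrom, bin(calls$pos),
            calls$mate_chrom, bin(calls$mate_pos), sep = ":"),
    TRUE ~
      paste(calls$sv_type, calls$chrom, bin(calls$pos), bin(calls$sv_end),
            sep = ":")
  )
}

#' Remove low-quality calls
#'
#' Calls with `qual` below `min_qual` are dropped; calls at the threshold
#' are kept (`>=` convention). Calls with no quality value are retained
#' and flagged in the `qual_missing` column.
#'
#' @param calls Tibble of calls.
#' @param min_qual Minimum call quality retained (default 20).
#' @return Filtered tibble with an added logical `qual_missing` column.
#' @export
filter_quality <- function(calls, min_qual = 20) {
  calls <- tibble::as_tibble(calls)
  calls$qual_missing <- is.na(calls$qual)
  calls[calls$qual_missing | calls$qual >= min_qual, , drop = FALSE]
}

#' Subtract background variants shared by the control individuals
#'
#' Variants whose equality key is present in the control (CK, unirradiated)
#' individuals are pre-existing background, not induced mutations, and are
#' removed from the mutant-line calls. `mode = "intersection"` (default)
#' subtracts keys common to all control individuals;
#' `mode = "union"` is a stricter option subtracting keys seen in any
#' control.
#'
#' @param line_calls Tibble of calls from one or more mutant lines.
#' @param control_calls Tibble of control calls with a `sample_id`
#'   column distinguishing the CK individuals, or a list of per-control
#'   tibbles.
#' @param mode `"intersection"` or `"union"` of the control key sets.
#' @param sv_tolerance Passed to [variant_key()].
#' @return `line_calls` with background rows removed.
#' @export
subtract_control <- function(line_calls, control_calls,
                             mode = c("intersection", "union"),
                             sv_tolerance = 0) {
  mode <- match.arg(mode)
  if (is.data.frame(control_calls)) {
    control_calls <- split(control_calls, control_calls$sample_id)
  }
  if (length(control_calls) == 0) {
    stop("at least one control call set is required.", call. = FALSE)
  }
  key_sets <- purrr::map(control_calls,
                         ~ unique(variant_key(.x, sv_tolerance)))
  background <- purrr::reduce(
    key_sets, if (mode == "intersection") intersect else union)
  line_calls <- tibble::as_tibble(line_calls)
  line_calls[!variant_key(line_calls, sv_tolerance) %in% background, ,
             drop = FALSE]
}

#' Exclude variants shared between mutant lines
#'
#' An equality key detected in `min_lines` or more distinct mutant lines
#' cannot be an independent induced mutation (it is a shared artefact or
#' residual background) and is removed from every line.
#'
#' @param calls Tibble of calls from all lines, with `sample_id`.
#' @param min_lines Minimum number of distinct lines sharing a key for it
#'   to be excluded; must be >= 2 (default 2).
#' @param sv_tolerance Passed to [variant_key()].
#' @return Filtered tibble.
#' @export
exclude_shared <- function(calls, min_lines = 2, sv_tolerance = 0) {
  if (min_lines < 2) {
    stop("`min_lines` must be at least 2.", call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)
  key <- variant_key(calls, sv_tolerance)
  n_lines <- tapply(calls$sample_id, key,
                    function(s) length(unique(s)))
  shared <- names(n_lines)[n_lines >= min_lines]
  calls[!key %in% shared, , drop = FALSE]
}

#' Merge runs of adjacent SBSs into multinucleotide variants
#'
#' Within each sample and chromosome, maximal runs of single-base
#' substitutions at strictly consecutive positions (`pos`, `pos + 1`, ...)
#' of length >= 2 are merged into one multinucleotide variant (MNV): the
#' reference and alternate runs are concatenated, the merged allele
#' frequency is the mean of the constituents (then re-classified with
#' [classify_zygosity_small()]), and `mnv_length` records the run length.
#' Constituent SBSs are consumed by the merge, so downstream Ts/Tv
#' computations never see them. Singleton SBSs and non-SBS rows pass
#' through unchanged (`mnv_length` is `NA` for them).
#'
#' @param calls Tibble of calls for one or more samples.
#' @return Tibble with MNV rows replacing their constituent SBS rows and
#'   an `mnv_length` column.
#' @export
merge_mnv <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"mnv_length" %in% names(calls)) calls$mnv_length <- NA_integer_
  is_sbs <- calls$sv_type == "none" &
    nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
    grepl("^[ACGT]$", calls$ref) & grepl("^[ACGT]$", calls$alt)
  sbs <- calls[is_sbs, , drop = FALSE]
  rest <- calls[!is_sbs, , drop = FALSE]
  if (nrow(sbs) == 0) return(calls)

  dup <- duplicated(sbs[, c("sample_id", "chrom", "pos")])
  if (any(dup)) {
    stop("duplicate SBS positions within a sample: ",
         paste(utils::head(paste0(sbs$chrom[dup], ":", sbs$pos[dup])),
               collapse = ", "), call. = FALSE)
  }

  sbs <- sbs |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::mutate(.run = cumsum(c(1L, as.integer(diff(.data$pos) != 1L)))) |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$.run) |>
    dplyr::add_tally(name = ".n") |>
    dplyr::ungroup()

  singles <- sbs |>
    dplyr::filter(.data$.n == 1L) |>
    dplyr::select(-dplyr::all_of(c(".run", ".n")))
  carried <- setdiff(names(sbs),
                     c("sample_id", "chrom", ".run", ".n",
                       "pos", "ref", "alt", "af", "qual", "mnv_length"))
  merged <- sbs |>
    dplyr::filter(.data$.n > 1L) |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$.run) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carried), dplyr::first),
      pos = dplyr::first(.data$pos),
      ref = paste(.data$ref, collapse = ""),
      alt = paste(.data$alt, collapse = ""),
      af = mean(.data$af),
      qual = mean(.data$qual),
      mnv_length = dplyr::n(),
      .groups = "drop") |>
    dplyr::select(-dplyr::all_of(".run"))
  if ("zygosity" %in% names(merged) && nrow(merged)) {
    merged$zygosity <- classify_zygosity_small(merged$af)
  }

  dplyr::bind_rows(rest, singles, merged) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos)
}

#' Partition structural variants by scaffold involvement
#'
#' SVs with either end (the record locus, the `END` side, or the breakend
#' mate locus) on a sequence that is not one of the assembled chromosomes
#' are unreliable and are split off. Non-SV rows are always retained.
#'
#' @param calls Tibble of calls.
#' @param chromosome_names Character vector of assembled chromosome names
#'   (20 for soybean).
#' @return A list with tibbles `retained` and `filtered`.
#' @export
filter_scaffold_svs <- function(calls, chromosome_names) {
  if (length(chromosome_names) == 0) {
    stop("`chromosome_names` must list the assembled chromosomes.",
         call. = FALSE)
  }
  calls <- tibble::as_tibble(calls)
  is_sv <- calls$sv_type != "none"
  off <- is_sv & (
    !(calls$chrom %in% chromosome_names) |
      (calls$sv_type == "BND_SV" &
         !is.na(calls$mate_chrom) &
         !(calls$mate_chrom %in% chromosome_names))
  )
  list(
    retained = calls[!off, , drop = FALSE],
    filtered = calls[off, , drop = FALSE]
  )
}

#' Run the full mutation-filtering pipeline
#'
#' Applies, in order: the quality filter, control (CK) background
#' subtraction, cross-line shared-variant exclusion, scaffold SV
#' filtering, zygosity classification (dropping small variants below the
#' heterozygous AF band and SVs typed `reference`/`unknown`), MNV merging
#' and category labelling. Every stage's removals are recorded in the
#' provenance table, so `raw - retained` always equals the summed
#' removals.
#'
#' @param line_calls Tibble of calls from all mutant lines (`sample_id`
#'   distinguishes lines).
#' @param control_calls Control calls; see [subtract_control()].
#' @param chromosome_names Assembled chromosome names; see
#'   [filter_scaffold_svs()].
#' @param min_qual,min_lines,control_mode,sv_tolerance,discard_af_below
#'   Stage parameters (see the individual filter functions).
#' @return An object of class `mutation_sets`: a list with `calls`
#'   (retained, labelled calls), `filtered_svs` (scaffold SVs) and
#'   `provenance` (per-stage removal counts). `tidy()` returns the calls,
#'   `glance()` the provenance.
#' @export
run_mutation_pipeline <- function(line_calls, control_calls,
                                  chromosome_names,
                                  min_qual = 20, min_lines = 2,
                                  control_mode = "intersection",
                                  sv_tolerance = 0,
                                  discard_af_below = 0.25) {
  stages <- character()
  removed <- integer()
  note <- function(stage, before, after) {
    stages <<- c(stages, stage)
    removed <<- c(removed, before - after)
  }

  x <- tibble::as_tibble(line_calls)
  n0 <- nrow(x)

  x1 <- filter_quality(x, min_qual)
  note("quality_filter", nrow(x), nrow(x1))

  x2 <- subtract_control(x1, control_calls, mode = control_mode,
                         sv_tolerance = sv_tolerance)
  note("control_subtraction", nrow(x1), nrow(x2))

  x3 <- exclude_shared(x2, min_lines = min_lines,
                       sv_tolerance = sv_tolerance)
  note("shared_line_exclusion", nrow(x2), nrow(x3))

  part <- filter_scaffold_svs(x3, chromosome_names)
  x4 <- part$retained
  note("scaffold_sv_filter", nrow(x3), nrow(x4))

  small <- x4$sv_type == "none"
  zyg <- character(nrow(x4))
  zyg[small] <- classify_zygosity_small(x4$af[small], discard_af_below)
  zyg[!small] <- classify_zygosity_sv(x4$gt[!small])
  x4$zygosity <- zyg
  x5 <- x4[!(zyg %in% c("discard", "reference", "unknown")), , drop = FALSE]
  note("zygosity_filter", nrow(x4), nrow(x5))

  x6 <- merge_mnv(x5)
  note("mnv_merge", nrow(x5), nrow(x6))

  x6 <- classify_variant(x6)

  structure(
    list(
      calls = x6,
      filtered_svs = part$filtered,
      provenance = tibble::tibble(
        stage = stages, n_removed = removed,
        n_raw = n0, n_retained = nrow(x6))
    ),
    class = "mutation_sets"
  )
}

#' @export
print.mutation_sets <- function(x, ...) {
  cat("Filtered mutation sets:", nrow(x$calls), "calls retained from",
      x$provenance$n_raw[1], "raw calls in",
      length(unique(x$calls$sample_id)), "line(s)\n")
  print(x$provenance[, c("stage", "n_removed")])
  invisible(x)
}

#' @rdname run_mutation_pipeline
#' @param x A `mutation_sets` object.
#' @param ... Unused.
#' @export
tidy.mutation_sets <- function(x, ...) x$calls

#' @rdname run_mutation_pipeline
#' @export
glance.mutation_sets <- function(x, ...) {
  tidyr::pivot_wider(x$provenance[, c("stage", "n_removed")],
                     names_from = "stage", values_from = "n_removed") |>
    dplyr::mutate(n_raw = x$provenance$n_raw[1],
                  n_retained = x$provenance$n_retained[1])
}
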