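#' @importFrom rlang .data
NULL

sv_levels <- c("none", "DEL_SV", "DUP_SV", "BND_SV")
impact_levels <- c("MODIFIER", "LOW", "MODERATE", "HIGH")
functional_levels <- c("missense", "nonsense", "silent", "none")
region_levels <- c("intergenic", "upstream", "downstream", "exon",
                   "intron", "exon_duplication")

# Largest length change still treated as a small INDEL; longer deletions
# and duplications are structural variants.
SV_MIN_LEN <- 50L

info_field <- function(info, key) {
  stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
}

format_field <- function(format, value, key) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  idx <- match(key, keys)
  if (is.na(idx)) return(NA_character_)
  parts <- strsplit(value, ":", fixed = TRUE)[[1]]
  if (idx > length(parts)) NA_character_ else parts[idx]
}

empty_calls <- function() {
  tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), qual = double(), af = double(),
    gt = character(), sv_type = character(), sv_end = integer(),
    mate_chrom = character(), mate_pos = integer()
  )
}

#' Read the constrained VCF subset used by the mutation pipeline
#'
#' Parses a VCF 4.x file into a tibble of calls, one row per record per
#' requested sample. Small variants (substitutions and INDELs up to 50 bp)
#' must carry an alternate allele frequency (per-sample `FORMAT/AF`
#' preferred, `INFO/AF` fallback). Structural variants are recognised from
#' symbolic alleles / `SVTYPE`: `<DEL>` and `<DUP>` records need `END` and
#' a span of at least 50 bp; breakend (`BND`) records are joined with their
#' `MATEID` partner into one call with `mate_chrom` / `mate_pos` filled.
#' Multi-allelic records are split into biallelic calls. Records failing
#' validation are reported together with their file line numbers.
#'
#' @param path Path to a VCF file (plain text).
#' @param sample_id Sample column(s) to extract; default all samples.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `af`, `gt`, `sv_type` (`none`, `DEL_SV`, `DUP_SV`,
#'   `BND_SV`), `sv_end`, `mate_chrom`, `mate_pos`.
#' @export
read_vcf_subset <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      stop("malformed VCF header or body in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_calls())
  gt_mat <- vcf@gt
  samples <- if (!is.null(gt_mat)) colnames(gt_mat)[-1] else character()
  if (is.null(sample_id)) {
    sample_id <- if (length(samples)) samples else basename(path)
  } else if (length(samples) && !all(sample_id %in% samples)) {
    stop("sample(s) not in file: ",
         paste(setdiff(sample_id, samples), collapse = ", "), call. = FALSE)
  }
  n_meta <- length(vcf@meta)

  errors <- character()
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    line_no <- n_meta + 1L + i
    chrom <- unname(fix[i, "CHROM"])
    pos <- as.integer(fix[i, "POS"])
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    info <- unname(fix[i, "INFO"])
    id <- unname(fix[i, "ID"])
    svtype <- info_field(info, "SVTYPE")
    info_af <- info_field(info, "AF")
    info_afs <- if (is.na(info_af)) {
      NULL
    } else {
      suppressWarnings(as.numeric(strsplit(info_af, ",", fixed = TRUE)[[1]]))
    }

    has_fmt <- !is.null(gt_mat) && "FORMAT" %in% colnames(gt_mat)
    for (s in sample_id) {
      fmt_val <- if (has_fmt && s %in% samples) unname(gt_mat[i, s]) else NA
      fmt <- if (has_fmt) unname(gt_mat[i, "FORMAT"]) else NA
      gt_s <- if (!is.na(fmt) && !is.na(fmt_val)) {
        format_field(fmt, fmt_val, "GT")
      } else NA
      af_s <- if (!is.na(fmt) && !is.na(fmt_val)) {
        format_field(fmt, fmt_val, "AF")
      } else NA

      for (k in seq_along(alts)) {
        alt <- alts[k]
        is_bnd <- grepl("[][]", alt) ||
          (!is.na(svtype) && svtype == "BND")
        is_sym <- grepl("^<", alt)

        if (is_bnd) {
          mate <- stringr::str_match(alt, "[\\]\\[]([^:]+):([0-9]+)[\\]\\[]")
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = s, chrom = chrom, pos = pos, ref = ref, alt = alt,
            qual = qual, af = NA_real_,
            gt = if (is.na(gt_s)) NA_character_ else gt_s,
            sv_type = "BND_SV", sv_end = NA_integer_,
            mate_chrom = mate[, 2], mate_pos = as.integer(mate[, 3]),
            .id = id, .mateid = info_field(info, "MATEID")
          )
        } else if (is_sym) {
          end <- suppressWarnings(as.integer(info_field(info, "END")))
          type <- if (grepl("^<DEL", alt)) "DEL_SV"
                  else if (grepl("^<DUP", alt)) "DUP_SV" else NA_character_
          if (is.na(type)) {
            errors <- c(errors, sprintf(
              "line %d: unsupported symbolic allele %s", line_no, alt))
            next
          }
          if (is.na(end)) {
            errors <- c(errors, sprintf(
              "line %d: %s record lacks END", line_no, type))
            next
          }
          if (end - pos < SV_MIN_LEN) {
            errors <- c(errors, sprintf(
              "line %d: %s span %d bp is below the %d bp structural-variant minimum",
              line_no, type, end - pos, SV_MIN_LEN))
            next
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = s, chrom = chrom, pos = pos, ref = ref, alt = alt,
            qual = qual, af = NA_real_,
            gt = if (is.na(gt_s)) NA_character_ else gt_s,
            sv_type = type, sv_end = end,
            mate_chrom = NA_character_, mate_pos = NA_integer_,
            .id = id, .mateid = NA_character_
          )
        } else {
          if (!grepl("^[ACGTNacgtn]+$", ref) || !grepl("^[ACGTNacgtn]+$", alt)) {
            errors <- c(errors, sprintf(
              "line %d: non-nucleotide alleles %s>%s", line_no, ref, alt))
            next
          }
          if (abs(nchar(alt) - nchar(ref)) > SV_MIN_LEN) {
            errors <- c(errors, sprintf(
              "line %d: length change exceeds %d bp; encode as a structural variant",
              line_no, SV_MIN_LEN))
            next
          }
          af_val <- NA_real_
          if (!is.na(af_s)) {
            af_parts <- suppressWarnings(
              as.numeric(strsplit(af_s, ",", fixed = TRUE)[[1]]))
            af_val <- if (length(af_parts) >= k) af_parts[k] else af_parts[1]
          } else if (!is.null(info_afs)) {
            af_val <- if (length(info_afs) >= k) info_afs[k] else info_afs[1]
          }
          if (is.na(af_val)) {
            errors <- c(errors, sprintf(
              "line %d: small variant %s:%d %s>%s has no AF for sample %s",
              line_no, chrom, pos, ref, alt, s))
            next
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = s, chrom = chrom, pos = pos, ref = ref, alt = alt,
            qual = qual, af = af_val,
            gt = if (is.na(gt_s)) NA_character_ else gt_s,
            sv_type = "none", sv_end = NA_integer_,
            mate_chrom = NA_character_, mate_pos = NA_integer_,
            .id = id, .mateid = NA_character_
          )
        }
      }
    }
  }
  if (length(errors)) {
    stop("invalid VCF records:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0) return(empty_calls())

  # Join breakend pairs: drop the partner record of each reciprocal MATEID
  # pair, keeping the first record (its ALT already names the mate locus).
  bnd <- calls$sv_type == "BND_SV" & !is.na(calls$.mateid)
  if (any(bnd)) {
    drop <- rep(FALSE, nrow(calls))
    seen <- character()
    for (j in which(bnd)) {
      if (calls$.mateid[j] %in% seen) {
        drop[j] <- TRUE
      } else {
        seen <- c(seen, calls$.id[j])
      }
    }
    calls <- calls[!drop, , drop = FALSE]
  }
  dplyr::select(calls, -dplyr::all_of(c(".id", ".mateid")))
}

#' Write calls as a minimal VCF 4.2 file
#'
#' Inverse of [read_vcf_subset()] for one sample: small variants carry
#' `FORMAT/AF`, `<DEL>`/`<DUP>` records carry `SVTYPE`/`END` and `GT`,
#' and breakend calls are expanded into a reciprocal `MATEID` pair.
#'
#' @param calls Tibble of calls for a single sample (see
#'   [read_vcf_subset()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(calls, path) {
  calls <- tibble::as_tibble(calls)
  sample <- unique(calls$sample_id)
  if (length(sample) > 1) {
    stop("write_vcf_subset() writes one sample per file.", call. = FALSE)
  }
  if (length(sample) == 0) sample <- "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  qual_chr <- function(q) ifelse(is.na(q), ".", format(q, trim = TRUE))
  recs <- character()
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (r$sv_type == "none") {
      recs <- c(recs, paste(r$chrom, r$pos, ".", r$ref, r$alt,
                            qual_chr(r$qual), "PASS", ".",
                            "AF", format(r$af, trim = TRUE), sep = "\t"))
    } else if (r$sv_type %in% c("DEL_SV", "DUP_SV")) {
      sym <- if (r$sv_type == "DEL_SV") "<DEL>" else "<DUP>"
      svt <- if (r$sv_type == "DEL_SV") "DEL" else "DUP"
      recs <- c(recs, paste(r$chrom, r$pos, ".", "N", sym,
                            qual_chr(r$qual), "PASS",
                            sprintf("SVTYPE=%s;END=%d", svt, r$sv_end),
                            "GT", r$gt, sep = "\t"))
    } else {
      id1 <- sprintf("bnd_%d_1", i)
      id2 <- sprintf("bnd_%d_2", i)
      recs <- c(recs,
        paste(r$chrom, r$pos, id1, "N",
              sprintf("N[%s:%d[", r$mate_chrom, r$mate_pos),
              qual_chr(r$qual), "PASS",
              sprintf("SVTYPE=BND;MATEID=%s", id2), "GT", r$gt, sep = "\t"),
        paste(r$mate_chrom, r$mate_pos, id2, "N",
              sprintf("N]%s:%d]", r$chrom, r$pos),
              qual_chr(r$qual), "PASS",
              sprintf("SVTYPE=BND;MATEID=%s", id1), "GT", r$gt, sep = "\t"))
    }
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Parse SnpEff-style `ANN` sub-fields
#'
#' Extracts the affected region, impact level and (for coding
#' substitutions) functional class from pipe-delimited annotation strings
#' of the form `allele|annotation_term|impact|gene|...`.
#'
#' @param x Character vector of `ANN`-style strings.
#' @return A tibble with columns `region`, `impact`, `functional_class`.
#' @export
parse_ann <- function(x) {
  parts <- stringr::str_split(x, stringr::fixed("|"))
  term <- purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[2] else NA_character_)
  impact <- purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[3] else NA_character_)
  region <- dplyr::case_when(
    term %in% c("intergenic_region", "intergenic_variant") ~ "intergenic",
    term == "downstream_gene_variant" ~ "downstream",
    term == "upstream_gene_variant" ~ "upstream",
    term %in% c("intron_variant", "splice_region_variant") ~ "intron",
    term %in% c("missense_variant", "synonymous_variant", "stop_gained",
                "stop_lost", "exon_variant", "frameshift_variant") ~ "exon",
    term %in% c("duplication", "exon_loss_variant&duplication",
                "exon_duplication") ~ "exon_duplication",
    TRUE ~ term
  )
  functional_class <- dplyr::case_when(
    term == "missense_variant" ~ "missense",
    term %in% c("stop_gained", "stop_lost") ~ "nonsense",
    term == "synonymous_variant" ~ "silent",
    TRUE ~ "none"
  )
  tibble::tibble(region = region, impact = impact,
                 functional_class = functional_class)
}

#' Read annotation records
#'
#' Reads a delimited annotation table emulating annotator output. The file
#' must either contain `region` and `impact` columns directly, or an `ann`
#' column of pipe-delimited sub-fields that is expanded with [parse_ann()].
#' Impact must be one of `MODIFIER`, `LOW`, `MODERATE`, `HIGH` (anything
#' else is an error); `functional_class` defaults to `"none"` when absent.
#' Region labels outside the canonical set (intergenic, upstream,
#' downstream, exon, intron, exon_duplication) are preserved verbatim but
#' flagged in the `region_known` column.
#'
#' @param path Path to a TSV file.
#' @return A tibble of annotation records with a logical `region_known`
#'   column.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("ann" %in% names(ann) && !all(c("region", "impact") %in% names(ann))) {
    ann <- dplyr::bind_cols(
      dplyr::select(ann, -dplyr::any_of(c("region", "impact",
                                          "functional_class", "ann"))),
      parse_ann(ann$ann)
    )
  }
  if (!all(c("region", "impact") %in% names(ann))) {
    stop("annotation file must provide `region` and `impact` ",
         "(directly or via an `ann` column).", call. = FALSE)
  }
  if (!"functional_class" %in% names(ann)) ann$functional_class <- "none"
  bad_imp <- setdiff(unique(ann$impact), impact_levels)
  if (length(bad_imp)) {
    stop("unknown impact level(s): ", paste(bad_imp, collapse = ", "),
         call. = FALSE)
  }
  bad_cls <- setdiff(unique(ann$functional_class), functional_levels)
  if (length(bad_cls)) {
    stop("unknown functional class(es): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  ann$region_known <- ann$region %in% region_levels
  if (any(!ann$region_known)) {
    warning("non-canonical region label(s) kept verbatim: ",
            paste(unique(ann$region[!ann$region_known]), collapse = ", "),
            call. = FALSE)
  }
  tibble::as_tibble(ann)
}

#' Write a report table as deterministic TSV
#'
#' Rows are sorted lexicographically over all columns so repeated runs
#' produce byte-identical files; the table round-trips through
#' [read_report()].
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  table <- tibble::as_tibble(table)
  if (nrow(table) > 1) {
    ord <- do.call(order, lapply(as.list(table), as.character))
    table <- table[ord, , drop = FALSE]
  }
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
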