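#' Default genome model for simulations
#'
#' Twenty 1-Mb chromosomes (named like soybean chromosomes) plus ten
#' unassembled scaffold names. Desk-scale on purpose: large enough that
#' planted variants rarely collide, small enough that every test runs in
#' seconds, while still exercising the scaffold SV filter.
#'
#' @param n_chrom,chrom_length,n_scaffold,scaffold_length Genome layout.
#' @return Tibble with columns `name`, `length`, `is_chromosome`.
#' @export
default_genome <- function(n_chrom = 20, chrom_length = 1e6,
                           n_scaffold = 10, scaffold_length = 5e4) {
  tibble::tibble(
    name = c(sprintf("Gm%02d", seq_len(n_chrom)),
             sprintf("scaffold_%d", seq_len(n_scaffold))),
    length = c(rep(chrom_length, n_chrom),
               rep(scaffold_length, n_scaffold)),
    is_chromosome = rep(c(TRUE, FALSE), c(n_chrom, n_scaffold))
  )
}

#' Per-line expected mutation counts for a mutagen
#'
#' Study-condition defaults for the simulator: expected per-line category
#' counts are the group totals of the bundled spectrum table
#' ([soybean_spectrum_counts()], homozygous + heterozygous scope) divided
#' by the 16 sequenced lines per group, and the homozygous fraction is
#' the group's homozygous share of all mutations (about 0.205 for the
#' carbon-ion beam, 0.371 for gamma rays).
#'
#' @param mutagen `"carbon"` or `"gamma"`.
#' @param n_lines Number of lines the group totals are spread over.
#' @return List with `mutagen`, `expected` (named per-line means) and
#'   `hom_fraction`.
#' @export
mutagen_profile <- function(mutagen = c("carbon", "gamma"), n_lines = 16) {
  mutagen <- match.arg(mutagen)
  counts <- soybean_spectrum_counts()
  all_counts <- counts[counts$mutagen == mutagen &
                         counts$zygosity_scope == "all", ]
  hom_counts <- counts[counts$mutagen == mutagen &
                         counts$zygosity_scope == "homozygous", ]
  list(
    mutagen = mutagen,
    expected = stats::setNames(all_counts$count / n_lines,
                               all_counts$category),
    hom_fraction = sum(hom_counts$count) / sum(all_counts$count)
  )
}

#' Simulate binomially noised dose-response observations
#'
#' Draws, for each dose and replicate, `n_effect ~ Binomial(n_units, p)`
#' with `p = shmt_rate(dose, d0, m)`. The default design mirrors a
#' carbon-ion seed-irradiation assay: doses 0-180 Gy and about 20 seeds
#' per replicate. The generating parameters are attached as the `truth`
#' attribute for parameter-recovery experiments.
#'
#' @param doses Dose grid in Gy.
#' @param d0,m True SHMT parameters (defaults give a shoulder dose of
#'   about 115 Gy).
#' @param n_units Assayed units (seeds) per dose and replicate.
#' @param n_reps Replicates per dose.
#' @param seed Optional integer seed for reproducible draws.
#' @return Tibble with `dose`, `rep`, `n_total`, `n_effect`, `rate`, and
#'   attribute `truth = list(d0, m, dq)`.
#' @export
simulate_dose_response <- function(doses = c(0, 40, 60, 80, 100, 120,
                                             150, 180),
                                   d0 = 62.3, m = 6.33, n_units = 20,
                                   n_reps = 1, seed = NULL) {
  if (any(doses < 0) || n_units < 1 || n_reps < 1) {
    stop("invalid simulation configuration.", call. = FALSE)
  }
  draw <- function() {
    grid <- tidyr::expand_grid(dose = sort(unique(doses)),
                               rep = seq_len(n_reps))
    p <- shmt_rate(grid$dose, d0, m)
    grid$n_total <- n_units
    grid$n_effect <- stats::rbinom(nrow(grid), n_units, p)
    grid$rate <- grid$n_effect / grid$n_total
    grid
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "truth") <- list(d0 = d0, m = m, dq = d0 * log(m))
  out
}

# -- internal helpers for the line simulator --------------------------------

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

draw_alt <- function(ref, transition_prob) {
  if (stats::runif(1) < transition_prob) {
    transition_of[[ref]]
  } else {
    sample(transversions_of[[ref]], 1)
  }
}

# Allocate non-overlapping [start, start+len-1] blocks on the chromosomes,
# with a 1 bp margin so independently planted SBSs are never adjacent
# (adjacency is reserved for deliberately planted MNV runs).
make_allocator <- function(genome, chromosomes_only = TRUE) {
  pool <- if (chromosomes_only) genome[genome$is_chromosome, ] else genome
  used <- new.env(parent = emptyenv())
  function(len) {
    repeat {
      i <- sample.int(nrow(pool), 1, prob = pool$length)
      chrom <- pool$name[i]
      start <- sample.int(pool$length[i] - len - 1, 1) + 1L
      occ <- get0(chrom, envir = used, ifnotfound = integer())
      block <- (start - 1L):(start + len)
      if (!any(block %in% occ)) {
        assign(chrom, c(occ, block), envir = used)
        return(list(chrom = chrom, pos = start))
      }
    }
  }
}

# Rows are accumulated as plain lists and assembled into a tibble once at
# the end; building tens of thousands of one-row tibbles is far too slow.
call_row <- function(sample_id, chrom, pos, ref, alt, qual, af = NA_real_,
                     gt = NA_character_, sv_type = "none",
                     sv_end = NA_integer_, mate_chrom = NA_character_,
                     mate_pos = NA_integer_) {
  list(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
       ref = ref, alt = alt, qual = qual, af = af, gt = gt,
       sv_type = sv_type, sv_end = as.integer(sv_end),
       mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos))
}

rows_to_calls <- function(rows) {
  if (length(rows) == 0) return(empty_calls())
  col <- function(name, fn, na) {
    fn(rows, function(r) if (is.null(r[[name]]) || is.na(r[[name]])) na
       else r[[name]], na)
  }
  chr <- function(name) vapply(rows, function(r) {
    v <- r[[name]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  num <- function(name) vapply(rows, function(r) {
    v <- r[[name]]
    if (is.null(v)) NA_real_ else as.double(v)
  }, double(1))
  int <- function(name) vapply(rows, function(r) {
    v <- r[[name]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  out <- tibble::tibble(
    sample_id = chr("sample_id"), chrom = chr("chrom"), pos = int("pos"),
    ref = chr("ref"), alt = chr("alt"), qual = num("qual"),
    af = num("af"), gt = chr("gt"), sv_type = chr("sv_type"),
    sv_end = int("sv_end"), mate_chrom = chr("mate_chrom"),
    mate_pos = int("mate_pos"))
  if (!is.null(rows[[1]]$origin)) {
    out$origin <- chr("origin")
    out$true_category <- chr("true_category")
    out$true_zygosity <- chr("true_zygosity")
  }
  out
}

#' Simulate per-line variant call sets with ground truth
#'
#' Generates the call sets the mutation pipeline consumes, with every
#' record labelled in an accompanying ground-truth table. Per line,
#' category counts are drawn Poisson around the profile's expectations
#' and placed uniformly along the chromosomes (with a 1 bp spacing margin
#' so runs of adjacent SBSs occur only where planted). Allele frequencies
#' are drawn from zygosity-specific windows inside the classification
#' bands (homozygous `af_hom`, heterozygous `af_het`), MNVs are planted
#' as runs of strictly consecutive SBSs, the configured fraction of SV
#' loci is routed to scaffold names, and the requested numbers of
#' CK-shared (present in every control and one line) and cross-line
#' shared (present in two lines) background keys are injected.
#'
#' @param n_lines Number of mutant lines.
#' @param profile A [mutagen_profile()] list (expected per-line counts
#'   and homozygous fraction).
#' @param af_hom,af_het AF windows for homozygous / heterozygous small
#'   variants. With `adversarial_af = TRUE`, AFs are instead drawn within
#'   0.01 of the 0.25 / 0.75 classification boundaries.
#' @param n_ck_shared Background keys planted in all controls plus one
#'   line.
#' @param n_crossline_shared Background keys planted in two lines.
#' @param n_control_private Private variants per control individual.
#' @param n_controls Number of CK individuals.
#' @param scaffold_fraction Share of SV records with a locus on an
#'   unassembled scaffold.
#' @param mnv_len_probs Named probabilities of planted MNV run lengths.
#' @param transition_prob Probability that an SBS is a transition.
#' @param qual_range Uniform window for call qualities.
#' @param genome Genome model; see [default_genome()].
#' @param adversarial_af Sample AFs near the classification boundaries.
#' @param seed Optional integer seed.
#' @return List with `calls` (all lines), `controls`, `truth` (calls plus
#'   `origin`, `true_category`, `true_zygosity`), `chromosomes`
#'   (assembled chromosome names) and `genome`.
#' @export
simulate_mutant_lines <- function(n_lines = 16,
                                  profile = mutagen_profile("carbon"),
                                  af_hom = c(0.9, 1.0),
                                  af_het = c(0.35, 0.65),
                                  n_ck_shared = 25,
                                  n_crossline_shared = 10,
                                  n_control_private = 20,
                                  n_controls = 2,
                                  scaffold_fraction = 0.02,
                                  mnv_len_probs = c("2" = 0.70, "3" = 0.20,
                                                    "4" = 0.07, "5" = 0.03),
                                  transition_prob = 0.6,
                                  qual_range = c(30, 60),
                                  genome = default_genome(),
                                  adversarial_af = FALSE,
                                  seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_mutant_lines(
      n_lines = n_lines, profile = profile, af_hom = af_hom,
      af_het = af_het, n_ck_shared = n_ck_shared,
      n_crossline_shared = n_crossline_shared,
      n_control_private = n_control_private, n_controls = n_controls,
      scaffold_fraction = scaffold_fraction,
      mnv_len_probs = mnv_len_probs, transition_prob = transition_prob,
      qual_range = qual_range, genome = genome,
      adversarial_af = adversarial_af, seed = NULL)))
  }
  if (abs(sum(mnv_len_probs) - 1) > 1e-8) {
    stop("`mnv_len_probs` must sum to 1.", call. = FALSE)
  }
  if (scaffold_fraction < 0 || scaffold_fraction > 1 ||
      profile$hom_fraction < 0 || profile$hom_fraction > 1) {
    stop("fractions must lie in [0, 1].", call. = FALSE)
  }
  exp_counts <- profile$expected
  chrom_names <- genome$name[genome$is_chromosome]
  scaf_names <- genome$name[!genome$is_chromosome]
  if (length(scaf_names) == 0 && scaffold_fraction > 0) {
    stop("genome has no scaffolds but scaffold_fraction > 0.",
         call. = FALSE)
  }
  alloc <- make_allocator(genome)
  line_ids <- sprintf("%s_line_%02d", profile$mutagen, seq_len(n_lines))

  rqual <- function() round(stats::runif(1, qual_range[1], qual_range[2]), 1)
  raf <- function(zyg) {
    if (adversarial_af) {
      if (zyg == "homozygous") stats::runif(1, 0.75, 0.76)
      else sample(c(stats::runif(1, 0.25, 0.26),
                    stats::runif(1, 0.74, 0.7499)), 1)
    } else if (zyg == "homozygous") {
      stats::runif(1, af_hom[1], af_hom[2])
    } else {
      stats::runif(1, af_het[1], af_het[2])
    }
  }
  rzyg <- function() {
    if (stats::runif(1) < profile$hom_fraction) "homozygous"
    else "heterozygous"
  }

  truth <- list()
  add <- function(row, origin, category, zygosity) {
    row$origin <- origin
    row$true_category <- category
    row$true_zygosity <- zygosity
    truth[[length(truth) + 1L]] <<- row
  }

  new_sbs <- function(sample_id, origin = "induced") {
    loc <- alloc(1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    zyg <- rzyg()
    add(call_row(sample_id, loc$chrom, loc$pos, ref,
                 draw_alt(ref, transition_prob), rqual(), af = raf(zyg)),
        origin, "SBS", zyg)
  }

  for (line in line_ids) {
    n <- stats::rpois(length(exp_counts), exp_counts)
    names(n) <- names(exp_counts)

    for (i in seq_len(n[["SBS"]])) new_sbs(line)

    for (i in seq_len(n[["MNV"]])) {
      len <- as.integer(sample(names(mnv_len_probs), 1,
                               prob = mnv_len_probs))
      loc <- alloc(len)
      zyg <- rzyg()
      for (k in seq_len(len)) {
        ref <- sample(c("A", "C", "G", "T"), 1)
        add(call_row(line, loc$chrom, loc$pos + k - 1L, ref,
                     draw_alt(ref, transition_prob), rqual(),
                     af = raf(zyg)),
            "induced", "MNV", zyg)
      }
    }

    for (dir in c("INDEL_deletion", "INDEL_insertion")) {
      for (i in seq_len(n[[dir]])) {
        len <- if (stats::runif(1) < 0.55) 1L
               else min(1L + stats::rgeom(1, 0.3), 50L)
        loc <- alloc(len + 1L)
        anchor <- sample(c("A", "C", "G", "T"), 1)
        zyg <- rzyg()
        if (dir == "INDEL_deletion") {
          ref <- paste0(anchor, random_bases(len)); alt <- anchor
        } else {
          ref <- anchor; alt <- paste0(anchor, random_bases(len))
        }
        add(call_row(line, loc$chrom, loc$pos, ref, alt, rqual(),
                     af = raf(zyg)),
            "induced", dir, zyg)
      }
    }

    for (svt in c("DEL_SV", "DUP_SV")) {
      for (i in seq_len(n[[svt]])) {
        len <- round(stats::runif(1, 51, 5000))
        zyg <- rzyg()
        gt <- if (zyg == "homozygous") "1/1" else "0/1"
        if (stats::runif(1) < scaffold_fraction) {
          chrom <- sample(scaf_names, 1)
          pos <- sample.int(1e4, 1)
        } else {
          loc <- alloc(1)
          chrom <- loc$chrom; pos <- loc$pos
        }
        add(call_row(line, chrom, pos, "N",
                     if (svt == "DEL_SV") "<DEL>" else "<DUP>",
                     rqual(), gt = gt, sv_type = svt, sv_end = pos + len),
            "induced", svt, zyg)
      }
    }

    for (i in seq_len(n[["BND_SV"]])) {
      loc <- alloc(1)
      zyg <- rzyg()
      gt <- if (zyg == "homozygous") "1/1" else "0/1"
      if (stats::runif(1) < scaffold_fraction) {
        mate_chrom <- sample(scaf_names, 1)
        mate_pos <- sample.int(1e4, 1)
      } else {
        mloc <- alloc(1)
        mate_chrom <- mloc$chrom; mate_pos <- mloc$pos
      }
      add(call_row(line, loc$chrom, loc$pos, "N",
                   sprintf("N[%s:%d[", mate_chrom, mate_pos),
                   rqual(), gt = gt, sv_type = "BND_SV",
                   mate_chrom = mate_chrom, mate_pos = mate_pos),
          "induced", "BND_SV", zyg)
    }
  }

  # Background: CK-shared keys go to every control plus one line;
  # cross-line shared keys go to two distinct lines.
  control_ids <- sprintf("CK_%d", seq_len(n_controls))
  controls <- list()
  for (i in seq_len(n_ck_shared)) {
    loc <- alloc(1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- draw_alt(ref, transition_prob)
    zyg <- rzyg()
    line <- sample(line_ids, 1)
    add(call_row(line, loc$chrom, loc$pos, ref, alt, rqual(),
                 af = raf(zyg)),
        "ck_background", "SBS", zyg)
    for (ck in control_ids) {
      controls[[length(controls) + 1L]] <-
        call_row(ck, loc$chrom, loc$pos, ref, alt, rqual(), af = raf(zyg))
    }
  }
  for (ck in control_ids) {
    for (i in seq_len(n_control_private)) {
      loc <- alloc(1)
      ref <- sample(c("A", "C", "G", "T"), 1)
      controls[[length(controls) + 1L]] <-
        call_row(ck, loc$chrom, loc$pos, ref,
                 draw_alt(ref, transition_prob), rqual(),
                 af = raf(rzyg()))
    }
  }
  if (n_crossline_shared > 0 && n_lines >= 2) {
    for (i in seq_len(n_crossline_shared)) {
      loc <- alloc(1)
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- draw_alt(ref, transition_prob)
      zyg <- rzyg()
      for (line in sample(line_ids, 2)) {
        add(call_row(line, loc$chrom, loc$pos, ref, alt, rqual(),
                     af = raf(zyg)),
            "crossline_background", "SBS", zyg)
      }
    }
  }

  truth <- dplyr::bind_rows(truth)
  list(
    calls = dplyr::select(
      truth, -dplyr::all_of(c("origin", "true_category", "true_zygosity"))),
    controls = if (length(controls)) dplyr::bind_rows(controls)
               else empty_calls(),
    truth = truth,
    chromosomes = chrom_names,
    genome = genome
  )
}

#' Simulate annotation records for a call set
#'
#' Assigns each call a gene region, impact level and (for coding-region
#' SBSs) a functional class by independent categorical draws, emulating
#' annotator output with known marginal frequencies.
#'
#' @param calls Tibble of calls (needs `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`; a `category` column is used to restrict functional
#'   classes to SBSs).
#' @param region_freqs,impact_freqs,class_freqs Named probability vectors
#'   (must each sum to 1). `class_freqs` applies to exon-region SBSs;
#'   all other records get functional class `"none"`.
#' @param seed Optional integer seed.
#' @return Tibble of annotation records.
#' @export
simulate_annotations <- function(calls,
                                 region_freqs = c(intergenic = 0.40,
                                                  downstream = 0.21,
                                                  upstream = 0.18,
                                                  intron = 0.12,
                                                  exon = 0.08,
                                                  exon_duplication = 0.01),
                                 impact_freqs = c(MODIFIER = 0.955,
                                                  LOW = 0.010,
                                                  MODERATE = 0.020,
                                                  HIGH = 0.015),
                                 class_freqs = c(missense = 0.70,
                                                 nonsense = 0.05,
                                                 silent = 0.25),
                                 seed = NULL) {
  for (f in list(region_freqs, impact_freqs, class_freqs)) {
    if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("frequency tables must be named, non-negative and sum to 1.",
           call. = FALSE)
    }
  }
  draw <- function() {
    calls <- tibble::as_tibble(calls)
    n <- nrow(calls)
    region <- sample(names(region_freqs), n, replace = TRUE,
                     prob = region_freqs)
    impact <- sample(names(impact_freqs), n, replace = TRUE,
                     prob = impact_freqs)
    is_sbs <- if ("category" %in% names(calls)) calls$category == "SBS"
              else nchar(calls$ref) == 1 & nchar(calls$alt) == 1
    functional_class <- rep("none", n)
    coding <- which(region == "exon" & is_sbs)
    if (length(coding)) {
      functional_class[coding] <- sample(names(class_freqs),
                                         length(coding), replace = TRUE,
                                         prob = class_freqs)
    }
    tibble::tibble(
      sample_id = calls$sample_id, chrom = calls$chrom, pos = calls$pos,
      ref = calls$ref, alt = calls$alt,
      region = region, impact = impact,
      functional_class = functional_class
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
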