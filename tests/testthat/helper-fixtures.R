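suppressMessages({
  library(dplyr)
  library(tibble)
})

# Quick builder for call tibbles with sensible defaults.
mk_call <- function(sample_id = "L1", chrom = "Gm01", pos = 100L,
                    ref = "A", alt = "G", qual = 50, af = 0.9,
                    gt = NA_character_, sv_type = "none",
                    sv_end = NA_integer_, mate_chrom = NA_character_,
                    mate_pos = NA_integer_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, qual = qual, af = af, gt = gt,
                 sv_type = sv_type, sv_end = as.integer(sv_end),
                 mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos))
}

# Independent SSE oracle: dense grid search over (d0, m).
grid_search_sse <- function(obs, d0_range, m_range, n = 200) {
  d0s <- seq(d0_range[1], d0_range[2], length.out = n)
  ms <- seq(m_range[1], m_range[2], length.out = n)
  best <- Inf
  for (m in ms) {
    pred <- 1 - (1 - exp(-outer(obs$dose, d0s, "/")))^m
    sse <- colSums((obs$rate - pred)^2)
    best <- min(best, min(sse))
  }
  best
}

# Textbook Pearson chi-squared by explicit expected-count summation.
chisq_oracle <- function(x) {
  x <- as.matrix(x)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  sum((x - expected)^2 / expected)
}

# Textbook pooled-variance two-sample t statistic.
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Brute-force run-length scanner over sorted SBS positions.
run_length_oracle <- function(pos) {
  pos <- sort(pos)
  runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
  lengths(runs)
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(sample = "L1") {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"t\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}
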