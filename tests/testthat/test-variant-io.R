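test_that("minimal VCF fixture maps fields onto calls", {
  path <- write_vcf_fixture(c(
    vcf_header("L1"),
    "Gm01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AF\t0/1:0.5",
    "Gm02\t200\t.\tACG\tA\t60\tPASS\t.\tGT:AF\t1/1:0.9",
    "Gm03\t300\t.\tN\t<DEL>\t70\tPASS\tSVTYPE=DEL;END=500\tGT\t0/1"))
  calls <- read_vcf_subset(path)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$sv_type, c("none", "none", "DEL_SV"))
  expect_equal(calls$af[1:2], c(0.5, 0.9))
  expect_equal(calls$sv_end[3], 500L)
  expect_equal(calls$gt[3], "0/1")
  expect_equal(calls$sample_id, rep("L1", 3))
})

test_that("sub-threshold symbolic SVs and missing AF are rejected with line numbers", {
  short <- write_vcf_fixture(c(
    vcf_header(),
    "Gm01\t100\t.\tN\t<DUP>\t50\tPASS\tSVTYPE=DUP;END=149\tGT\t0/1"))
  expect_error(read_vcf_subset(short), "49 bp is below the 50 bp")
  expect_error(read_vcf_subset(short), "line 8")

  noaf <- write_vcf_fixture(c(
    vcf_header(),
    "Gm01\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"))
  expect_error(read_vcf_subset(noaf), "no AF")
})

test_that("reciprocal breakend records join into one call", {
  path <- write_vcf_fixture(c(
    vcf_header(),
    "Gm01\t100\tbnd_a\tN\tN[Gm05:9000[\t50\tPASS\tSVTYPE=BND;MATEID=bnd_b\tGT\t0/1",
    "Gm05\t9000\tbnd_b\tN\tN]Gm01:100]\t50\tPASS\tSVTYPE=BND;MATEID=bnd_a\tGT\t0/1"))
  calls <- read_vcf_subset(path)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sv_type, "BND_SV")
  expect_equal(calls$chrom, "Gm01")
  expect_equal(calls$pos, 100L)
  expect_equal(calls$mate_chrom, "Gm05")
  expect_equal(calls$mate_pos, 9000L)
})

test_that("INFO AF is the fallback and multi-allelic records split", {
  path <- write_vcf_fixture(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"t\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "Gm01\t100\t.\tA\tG,T\t50\tPASS\tAF=0.9,0.4"))
  calls <- read_vcf_subset(path, sample_id = "S")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$alt, c("G", "T"))
  expect_equal(calls$af, c(0.9, 0.4))
})

test_that("VCF writer round-trips through the reader", {
  calls <- bind_rows(
    mk_call(pos = 100, ref = "A", alt = "G", af = 0.5, qual = 31.5),
    mk_call(pos = 200, chrom = "Gm02", ref = "AC", alt = "A", af = 0.9),
    mk_call(pos = 300, chrom = "Gm03", ref = "N", alt = "<DUP>", af = NA,
            gt = "1/1", sv_type = "DUP_SV", sv_end = 900),
    mk_call(pos = 400, chrom = "Gm04", ref = "N", alt = "N[Gm09:777[",
            af = NA, gt = "0/1", sv_type = "BND_SV",
            mate_chrom = "Gm09", mate_pos = 777))
  path <- tempfile(fileext = ".vcf")
  write_vcf_subset(calls, path)
  back <- read_vcf_subset(path)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(variant_key(back), variant_key(calls))
  expect_equal(back$af[1:2], calls$af[1:2])
  expect_equal(back$gt[3:4], calls$gt[3:4])
})

test_that("annotation reader validates enums and flags unknown regions", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(
    sample_id = "L1", chrom = "Gm01", pos = c(1, 2), ref = "A", alt = "G",
    region = c("exon", "intergenic"), impact = c("HIGH", "MODIFIER"),
    functional_class = c("nonsense", "none")), path)
  ann <- read_annotations(path)
  expect_equal(ann$impact, c("HIGH", "MODIFIER"))
  expect_equal(ann$functional_class[1], "nonsense")
  expect_true(all(ann$region_known))

  bad <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(region = "exon", impact = "SEVERE",
                          functional_class = "none"), bad)
  expect_error(read_annotations(bad), "unknown impact")

  odd <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(region = "pseudogene", impact = "LOW"), odd)
  expect_warning(ann2 <- read_annotations(odd), "non-canonical")
  expect_equal(ann2$region, "pseudogene")
  expect_false(ann2$region_known)
})

test_that("ANN-style pipe fields are parsed into region/impact/class", {
  parsed <- parse_ann(c(
    "T|missense_variant|MODERATE|GmGene1|x|transcript",
    "A|intergenic_region|MODIFIER|x|x|x",
    "G|synonymous_variant|LOW|GmGene2|x|transcript",
    "C|stop_gained|HIGH|GmGene3|x|transcript"))
  expect_equal(parsed$region, c("exon", "intergenic", "exon", "exon"))
  expect_equal(parsed$impact, c("MODERATE", "MODIFIER", "LOW", "HIGH"))
  expect_equal(parsed$functional_class,
               c("missense", "none", "silent", "nonsense"))

  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(sample_id = "L1",
                          ann = "T|missense_variant|MODERATE|g|x|t"), path)
  ann <- read_annotations(path)
  expect_equal(ann$region, "exon")
  expect_equal(ann$functional_class, "missense")
})

test_that("report writer is deterministic and round-trips", {
  tbl <- tibble(sample_id = c("ligne_été", "b", "a"),
                n = c(3L, 2L, 1L))
  path <- tempfile(fileext = ".tsv")
  write_report(tbl, path)
  back <- read_report(path)
  expect_setequal(back$sample_id, tbl$sample_id)
  expect_equal(back, back[order(as.character(back$sample_id)), ])

  # writing twice gives identical bytes
  path2 <- tempfile(fileext = ".tsv")
  write_report(tbl[c(2, 3, 1), ], path2)
  expect_identical(readLines(path), readLines(path2))

  empty <- tibble(a = character(), b = integer())
  path3 <- tempfile(fileext = ".tsv")
  write_report(empty, path3)
  expect_equal(length(readLines(path3)), 1)  # header only
})
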