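test_that("sample sheets validate identity, treatments and days", {
  sheet <- make_sheet(n_reps = 6, n_anc = 5)
  expect_s3_class(sheet, "sample_sheet")
  expect_equal(nrow(sheet), 35)

  path <- tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, path)
  back <- read_sample_sheet(path)
  expect_equal(as.data.frame(back), as.data.frame(sheet))

  # header-only file is an empty sheet
  writeLines("sample_id\treplicate_id\ttreatment\tday\tbatch_id", path)
  expect_equal(nrow(read_sample_sheet(path)), 0)

  df <- as.data.frame(sheet)
  df$day[1] <- "abc"
  expect_error(sample_sheet(df), "non-numeric day")
  df <- as.data.frame(sheet); df$sample_id[2] <- df$sample_id[1]
  expect_error(sample_sheet(df), "duplicate sample_id")
  df <- as.data.frame(sheet); df$treatment[1] <- "mystery"
  expect_error(sample_sheet(df), "unknown treatment")
  df <- as.data.frame(sheet); df$day[1] <- NA
  expect_error(sample_sheet(df), "non-ancestor")
})

test_that("VCF reading enforces the quality boundary, depth-based missingness
          and multi-allelic decomposition", {
  sheet <- sample_sheet(data.frame(
    sample_id = c("S1", "S2"), replicate_id = c("R1", "R2"),
    treatment = "weak_demography", day = 12, batch_id = "b1"))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"r\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tG,T\t50\t.\t.\tDP:RO:AO\t100:60:30,10\t7:4:3,0",
    "chr1\t200\t.\tC\tCT\t99\t.\t.\tDP:RO:AO\t10:5:5\t10:5:5",
    "chr1\t300\t.\tG\tA\t19.9\t.\t.\tDP:RO:AO\t100:50:50\t100:50:50",
    "chr1\t400\t.\tG\tA\t20\t.\t.\tDP:RO:AO\t100:50:50\t100:50:50"), vcf)
  expect_message(vt <- read_variant_table(vcf, sheet), "skipped 1")

  # QUAL 19.9 dropped, 20.0 kept; indel skipped; two sites from the
  # multi-allelic record
  expect_equal(vt$sites$pos, c(100L, 100L, 400L))
  expect_equal(vt$sites$alt, c("G", "T", "A"))

  # residual non-focal alternative reads count as reference support
  expect_equal(unname(vt$ref_count[1, "S1"]), 60L + 10L)
  expect_equal(unname(vt$alt_count[1, "S1"]), 30L)
  expect_equal(unname(vt$ref_count[2, "S1"]), 60L + 30L)

  # depth 7 < 10 is a missing estimate, not zero
  af <- allele_freq(vt)
  expect_true(is.na(af[1, "S2"]))
  expect_equal(af[1, "S1"], 0.3, ignore_attr = TRUE)

  sheet2 <- sample_sheet(data.frame(
    sample_id = "S3", replicate_id = "R1", treatment = "weak_demography",
    day = 12, batch_id = "b1"))
  expect_error(read_variant_table(vcf, sheet2), "absent from VCF")
})

test_that("AD-style VCFs are parsed equivalently", {
  sheet <- sample_sheet(data.frame(
    sample_id = "S1", replicate_id = "R1", treatment = "weak_demography",
    day = 12, batch_id = "b1"))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\t.\tA\tC,G\t40\t.\t.\tAD\t70,20,10"), vcf)
  vt <- read_variant_table(vcf, sheet)
  expect_equal(vt$sites$alt, c("C", "G"))
  expect_equal(unname(vt$alt_count[, 1]), c(20L, 10L))
  expect_equal(unname(vt$ref_count[, 1]), c(80L, 90L))
})

test_that("variant tables round-trip exactly through both dialects", {
  sheet <- make_sheet(n_reps = 3, days = c(12, 64), n_anc = 1)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(1:40, 1)
    ref <- sample(BASES_T <- c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES_T, b), 1), "")
    sites <- data.frame(contig = "c1", pos = sort(sample.int(1e5, n)),
                        ref = ref, alt = unname(alt),
                        qual = round(runif(n, 0, 2000), 2),
                        stringsAsFactors = FALSE)
    rc <- matrix(rpois(n * nrow(sheet), 400), n)
    ac <- matrix(rpois(n * nrow(sheet), 60), n)
    # sprinkle sub-threshold depths to exercise missingness
    low <- sample(length(rc), ceiling(length(rc) / 10))
    rc[low] <- 3L; ac[low] <- 2L
    vt <- variant_table(sites, sheet, rc, ac)

    p_tsv <- tempfile(fileext = ".tsv"); p_vcf <- tempfile(fileext = ".vcf")
    write_variant_table(vt, p_tsv, "tsv")
    write_variant_table(vt, p_vcf, "vcf")
    vt_tsv <- read_count_table(p_tsv, sheet)
    vt_vcf <- read_variant_table(p_vcf, sheet, min_qual = 0)
    for (back in list(vt_tsv, vt_vcf)) {
      expect_identical(back$sites, vt$sites)
      expect_identical(back$ref_count, vt$ref_count)
      expect_identical(back$alt_count, vt$alt_count)
      expect_identical(is.na(allele_freq(back)), is.na(allele_freq(vt)))
    }
  }

  # empty table -> header-only file -> empty table
  empty <- subset_sites(table_from_af(matrix(0.5, 1, 4), make_sheet(2, c(12, 64))),
                        integer(0))
  p <- tempfile(fileext = ".tsv")
  write_variant_table(empty, p, "tsv")
  expect_equal(n_sites(read_count_table(p, empty$samples)), 0)
})

test_that("annotation reading assembles ORFs from GFF3 and TSV", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3", "##sequence-region chr1 1 5000",
    "chr1\tsrc\tgene\t1\t28\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=c1;Parent=gene1",
    "chr1\tsrc\tCDS\t20\t28\t.\t+\t0\tID=c2;Parent=gene1",
    "chr1\tsrc\tCDS\t300\t320\t.\t-\t0\tID=c3;Parent=gene2"), gff)
  ann <- read_annotation(gff)
  expect_equal(ann$genome_length, 5000L)
  expect_equal(ann$orfs$gene1$length, 18L)       # two segments, 9 + 9
  expect_equal(nrow(ann$orfs$gene1$segments), 2)
  expect_equal(ann$orfs$gene2$strand, "-")
  expect_true(ann$orfs$gene1$cds_ok && ann$orfs$gene2$cds_ok)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tstrand",
               "A540L\t257,089\t260,859\t−",
               "A078R\t42007\t42183\t"), tsv)
  ann2 <- read_annotation(tsv, genome_length = 330611)
  expect_equal(ann2$orfs$A540L$length, 3771L)
  expect_equal(ann2$orfs$A540L$strand, "-")      # explicit (minus sign) wins
  expect_equal(ann2$orfs$A078R$strand, "+")      # inferred from the R suffix

  # segment outside the contig is a hard error
  expect_error(read_annotation(tsv, genome_length = 100000),
               "outside")
  # non-multiple-of-3 length flags the ORF but keeps it
  writeLines(c("name\tstart\tend", "oddR\t10\t20"), tsv)
  expect_warning(ann3 <- read_annotation(tsv, genome_length = 100),
                 "multiple of 3")
  expect_false(ann3$orfs$oddR$cds_ok)
  expect_equal(length(ann3$orfs), 1)
})

test_that("site keys treat two base changes at one position as distinct", {
  sheet <- make_sheet(1, 12)
  sites <- data.frame(contig = "c", pos = c(5L, 5L), ref = "A",
                      alt = c("G", "T"), qual = 100)
  vt <- variant_table(sites, sheet, matrix(10L, 2, 1), matrix(5L, 2, 1))
  expect_equal(n_sites(vt), 2)
  sites$alt <- c("G", "G")
  expect_error(variant_table(sites, sheet, matrix(10L, 2, 1),
                             matrix(5L, 2, 1)), "duplicate")
})
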