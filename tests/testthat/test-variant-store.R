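test_that("normalization left-aligns and trims to parsimony", {
  r <- ref_seq("c", "GGTCACACACTT")
  # CA-repeat deletion given right-shifted: canonical is leftmost
  n <- normalize_allele(7L, "ACA", "A", r)
  expect_equal(n, list(pos = 3L, ref = "TCA", alt = "T"))
  # shared suffix + prefix trimming
  n2 <- normalize_allele(3L, "TCA", "TGA", r)
  expect_equal(n2$ref, "C"); expect_equal(n2$alt, "G")
  expect_equal(n2$pos, 4L)
  # simple deletion stays put
  n3 <- normalize_allele(2L, "GT", "G", r)
  expect_equal(n3, list(pos = 2L, ref = "GT", alt = "G"))
  expect_error(normalize_allele(2L, "GT", "GT", r), "identical")
})

test_that("multi-allelic records split into per-ALT dosages", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           paste(c("c", "2", ".", "A", "T,G", ".", "PASS", "QS=5,6", "GT",
                   "1/2", "0/1", "./."), collapse = "\t"),
           paste(c("c", "5", ".", "CA", "C", ".", "PASS", "QS=7", "GT",
                   "1/1", "0/0", "0/1"), collapse = "\t"))
  f <- tempfile(fileext = ".vcf"); writeLines(vcf, f)
  got <- read_vcf(f, ref_seq("c", "GATTCAACT"))
  expect_equal(nrow(got$alleles), 3L)
  expect_equal(got$alleles$type, c("SNV", "SNV", "deletion"))
  expect_equal(got$alleles$indel_len[3], 1L)
  expect_equal(got$alleles$qs, c(5, 6, 7))
  expect_equal(unname(got$geno[1, ]), c(1L, 1L, NA))   # allele T
  expect_equal(unname(got$geno[2, ]), c(1L, 0L, NA))   # allele G
  expect_equal(unname(got$geno[3, ]), c(2L, 0L, 1L))
  # splitting conserves per-sample alt dosage at the 1/2 site
  expect_equal(colSums(got$geno[1:2, ], na.rm = TRUE)[1:2],
               c(s1 = 2, s2 = 1))
})

test_that("write then read round-trips the simulated cohort exactly", {
  co <- tiny_cohort()
  f <- tempfile(fileext = ".vcf")
  write_vcf(co$alleles, co$geno, f,
            stats::setNames(ref_length(co$ref), co$ref$name))
  rt <- read_vcf(f, co$ref)
  expect_setequal(allele_key(rt$alleles), co$keys)
  g <- rt$geno[rownames(co$geno), colnames(co$geno)]
  expect_identical(is.na(g), is.na(co$geno))
  expect_true(all(g == co$geno, na.rm = TRUE))
  qs <- rt$alleles$qs[match(co$keys, allele_key(rt$alleles))]
  expect_lt(max(abs(qs - co$alleles$qs)), 1e-4)
})

test_that("read_vcf rejects non-diploid genotypes", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1"), collapse = "\t"),
           paste(c("c", "2", ".", "A", "T", ".", ".", ".", "GT", "0/1/1"),
                 collapse = "\t"))
  f <- tempfile(fileext = ".vcf"); writeLines(vcf, f)
  expect_error(read_vcf(f, ref_seq("c", "GATT")), "non-diploid")
})

test_that("allele counts follow the 2N arithmetic with missing exclusion", {
  # one heterozygous carrier among 614 WGA samples
  dose <- c(rep(0L, 613), 1L, rep(0L, 9004))
  groups <- rep(c("WGA", "DNA"), c(614, 9004))
  cnt <- allele_counts(dose, groups)
  expect_equal(unname(cnt$alt[, "WGA"]), 1)
  expect_equal(unname(cnt$ref[, "WGA"]), 2 * 614 - 1)   # 1227
  expect_equal(unname(cnt$alt[, "DNA"]), 0)
  expect_equal(unname(cnt$ref[, "DNA"]), 2 * 9004)
  # all genotypes missing
  cnt2 <- allele_counts(rep(NA_integer_, 10), rep("WGA", 10))
  expect_equal(unname(cnt2$alt[, "WGA"] + cnt2$ref[, "WGA"]), 0)
})

test_that("group counts match a per-sample summation oracle", {
  set.seed(21)
  g <- matrix(sample(c(0:2, NA), 400, replace = TRUE), nrow = 20)
  grp <- sample(c("A", "B"), 20, replace = TRUE)
  cnt <- allele_counts(g, grp)
  for (lv in c("A", "B")) {
    sub <- g[, grp == lv, drop = FALSE]
    alt <- apply(sub, 1, function(x) sum(x[!is.na(x)]))
    nm <- apply(sub, 1, function(x) sum(!is.na(x)))
    expect_equal(unname(cnt$alt[, lv]), unname(alt))
    expect_equal(unname(cnt$alt[, lv] + cnt$ref[, lv]), unname(2 * nm))
  }
})

test_that("allele frequency excludes missing genotypes", {
  expect_equal(allele_frequency(c(1L, rep(0L, 9))), 0.05)
  expect_equal(allele_frequency(rep(2L, 6)), 1.0)
  expect_equal(allele_frequency(c(1L, 1L, NA, NA)), 0.5)
  expect_warning(af <- allele_frequency(rep(NA_integer_, 4)), "undefined")
  expect_true(is.na(af))
  set.seed(22)
  g <- matrix(sample(c(0:2, NA), 300, replace = TRUE), nrow = 15)
  expect_equal(allele_frequency(g),
               apply(g, 1, function(x)
                 sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))))
})

test_that("quality filter tiers are nested and remove artifacts first", {
  co <- tiny_cohort()
  calib <- co$alleles$qs[co$keys %in% co$truth_panel]
  expect_true(all(apply_quality_filter(co$alleles, 1.0, calib)))
  tiers <- c(0.99, 0.95, 0.90, 0.80)
  kept <- lapply(tiers, function(s)
    co$keys[apply_quality_filter(co$alleles, s, calib)])
  for (i in seq_along(tiers)[-1])
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  art <- co$ledger$key[co$ledger$origin != "true_variant"]
  removed <- vapply(kept, function(k) mean(!(art %in% k)), numeric(1))
  expect_true(all(diff(removed) >= 0))
  expect_gt(removed[length(removed)], removed[1])
  expect_error(apply_quality_filter(co$alleles, 0.9, numeric(0)),
               "empty calibration")
})
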