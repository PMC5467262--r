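test_that("burden counts dosage at rare LOF sites per sample and per gene", {
  r <- ref_seq("c", paste0("ATG", strrep("ACGT", 12), "ATG",
                           strrep("TGCA", 12)))
  genes <- gene_model(c("X", "Y"), "c", c(0, 51), c(51, 102))
  # two 2-bp CDS insertions (frameshift), one per gene
  al <- new_allele_table("c", c(5L, 60L), c("C", "T"),
                         c("CTT", "TCC"), c(10, 10))
  geno <- matrix(c(1L, 0L,    # sample 1: het in X
                   2L, 0L,    # sample 2: hom in X
                   0L, 2L),   # sample 3: hom in Y
                 nrow = 2,
                 dimnames = list(allele_key(al), c("s1", "s2", "s3")))
  cons <- classify_consequence(al, genes, r)
  expect_equal(cons, c("frameshift", "frameshift"))
  # af_max above the tiny cohort's frequencies so both sites qualify
  b <- build_burden(al, geno, cons, genes = genes, af_max = 0.9,
                    per_gene = TRUE)
  expect_equal(b$samples$lof_total, c(1, 2, 2))
  expect_equal(unname(b$gene_matrix["s1", ]), c(1, 0))
  expect_equal(unname(b$gene_matrix["s2", ]), c(2, 0))
  expect_equal(unname(b$gene_matrix["s3", ]), c(0, 2))
  # af_max = 0 empties the table (strict inequality)
  b0 <- build_burden(al, geno, cons, genes = genes, af_max = 0)
  expect_true(all(b0$samples$lof_total == 0))
})

test_that("burden equals a brute-force per-sample recount", {
  co <- tiny_cohort()
  b <- build_burden(co$alleles, co$geno, co$consequence, co$contexts,
                    genes = co$genes)
  af <- allele_frequency(co$geno)
  lof <- is_lof(co$consequence) & af < 0.05
  manual <- vapply(seq_len(ncol(co$geno)), function(j)
    sum(co$geno[lof, j], na.rm = TRUE), numeric(1))
  expect_equal(b$samples$lof_total, manual)
  # additive over the indel taxonomy
  expect_equal(b$samples$lof_indel,
               b$samples$lof_indel_homopolymer_plus +
                 b$samples$lof_indel_large + b$samples$lof_indel_other)
  expect_equal(b$samples$lof_total,
               b$samples$lof_snv + b$samples$lof_indel)
})

test_that("a response equal to one binary factor gives it all the variance", {
  set.seed(71)
  meta <- data.frame(c20x = runif(80), wga = rep(c(TRUE, FALSE), 40),
                     center = sample(c("C1", "C2"), 80, TRUE),
                     bwa_version = sample(c("a", "b"), 80, TRUE),
                     race = sample(c("R1", "R2"), 80, TRUE))
  y <- as.numeric(meta$wga) * 3 + rnorm(80, sd = 1e-4)
  dec <- anova_decomposition(y, meta)
  expect_gt(dec$pct_var_explained[dec$term == "wga"], 0.999)
  expect_equal(sum(dec$pct_var_explained), 1)
  expect_true(all(dec$pct_var_explained >= 0))
})

test_that("Type II equals sequential sums of squares in a balanced design", {
  set.seed(72)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = 1:10, KEEP.OUT.ATTRS = FALSE)
  y <- rnorm(40) + 2 * (d$A == "a2") - 1.5 * (d$B == "b2")
  dec <- anova_decomposition(y, d, factors = c("A", "B"))
  seq_tab <- anova(lm(y ~ A + B, data = d))
  expect_equal(dec$sum_sq[dec$term == "A"], seq_tab["A", "Sum Sq"])
  expect_equal(dec$sum_sq[dec$term == "B"], seq_tab["B", "Sum Sq"])
})

test_that("collinear factors raise an error naming the aliased terms", {
  set.seed(73)
  meta <- data.frame(wga = rep(c(TRUE, FALSE), 30))
  meta$capture_kit <- ifelse(meta$wga, "K1", "K2")  # perfectly confounded
  expect_error(anova_decomposition(rnorm(60), meta,
                                   factors = c("wga", "capture_kit")),
               "collinear|aliased")
})

test_that("WGA dominates LOF indel burden variance but not SNV burden", {
  co <- tiny_cohort()
  b <- build_burden(co$alleles, co$geno, co$consequence, co$contexts,
                    genes = co$genes)
  dec_i <- anova_decomposition(b$samples$lof_indel, co$meta)
  dec_s <- anova_decomposition(b$samples$lof_snv, co$meta)
  fac_i <- dec_i[dec_i$term != "Residuals", ]
  expect_equal(fac_i$term[which.max(fac_i$pct_var_explained)], "wga")
  expect_lt(dec_s$pct_var_explained[dec_s$term == "wga"], 0.05)
})

test_that("basic bootstrap interval is deterministic, centered and calibrated", {
  expect_equal(bootstrap_ci(rep(2.5, 10)), c(2.5, 2.5))
  set.seed(74)
  x <- rnorm(100, mean = 3)
  ci <- bootstrap_ci(x, seed = 5)
  expect_identical(ci, bootstrap_ci(x, seed = 5))
  expect_true(ci[1] < mean(x) && mean(x) < ci[2])
  expect_error(bootstrap_ci(1), "at least 2")
  # coverage study: ~95% of intervals cover the true mean
  set.seed(75)
  covered <- vapply(1:500, function(i) {
    y <- rnorm(200)
    ci <- bootstrap_ci(y, reps = 1000, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})
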