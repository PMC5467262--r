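test_that("taxonomy rules: homopolymer anchoring, length precedence, mixed bases", {
  #          0123456789
  r <- ref_seq("c", "GTAAAAGCCT")
  # insertion of "A" anchored just before the A-run
  ins_a <- new_allele_table("c", 2L, "T", "TA", NA_real_)
  got <- classify_indels(ins_a, r)
  expect_equal(got$category, "HOMOPOLYMER_PLUS")
  expect_true(got$homopolymer_eligible)
  # 16-bp insertion inside the same run: length takes precedence
  ins_big <- new_allele_table("c", 3L, "A", paste0("A", strrep("A", 16)),
                              NA_real_)
  expect_equal(classify_indels(ins_big, r)$category, "LARGE")
  # mixed-base insertion next to the run is ineligible
  ins_ag <- new_allele_table("c", 2L, "T", "TAG", NA_real_)
  got2 <- classify_indels(ins_ag, r)
  expect_equal(got2$category, "OTHER")
  expect_false(got2$homopolymer_eligible)
  # SNVs are rejected
  expect_error(classify_indels(new_allele_table("c", 2L, "T", "A",
                                                NA_real_), r),
               "indels only")
})

test_that("every indel receives exactly one category and LARGE is >= 15 bp", {
  co <- tiny_cohort()
  expect_true(all(co$contexts$category %in%
                    c("HOMOPOLYMER_PLUS", "LARGE", "OTHER")))
  expect_true(all((co$contexts$length >= 15) ==
                    (co$contexts$category == "LARGE")))
  expect_true(all(co$contexts$length[
    co$contexts$category == "HOMOPOLYMER_PLUS"] < 15))
})

test_that("classification agrees with an independent character scan", {
  set.seed(31)
  n_cases <- 2000L
  refstr <- paste0(random_dna(1500), "AAAA", random_dna(50), "CCCCCC",
                   random_dna(50), "TTTTT", random_dna(400))
  r <- ref_seq("c", refstr)
  len <- nchar(refstr)
  pos <- sample(seq(5L, len - 60L), n_cases, replace = TRUE)
  is_ins <- runif(n_cases) < 0.5
  # mix of same-base and mixed-base indel sequences, some large
  L <- sample(c(1:6, 15:20), n_cases, replace = TRUE,
              prob = c(rep(0.12, 6), rep(0.28 / 6, 6)))
  rows <- lapply(seq_len(n_cases), function(i) {
    anchor <- substr(refstr, pos[i], pos[i])
    s <- if (runif(1) < 0.5)
      strrep(sample(c("A", "C", "G", "T"), 1), L[i])
    else paste(sample(c("A", "C", "G", "T"), L[i], replace = TRUE),
               collapse = "")
    if (is_ins[i])
      new_allele_table("c", pos[i], anchor, paste0(anchor, s), NA_real_)
    else
      new_allele_table("c", pos[i],
                       paste0(anchor, substr(refstr, pos[i] + 1L,
                                             pos[i] + L[i])),
                       anchor, NA_real_)
  })
  alleles <- do.call(rbind, rows)
  got <- classify_indels(alleles, r)
  want <- vapply(seq_len(n_cases), function(i)
    oracle_classify_indel(alleles$pos[i], alleles$ref[i], alleles$alt[i],
                          refstr), character(1))
  expect_equal(got$category, want)
  expect_gt(sum(want == "HOMOPOLYMER_PLUS"), 10)  # the scan was exercised
})

test_that("taxonomy summary fractions are normalized per label group", {
  co <- tiny_cohort()
  led <- co$ledger[match(co$contexts$key, co$ledger$key), ]
  ts <- taxonomy_summary(co$contexts, led$origin != "true_variant")
  expect_equal(ts$fractions$frac_other + ts$fractions$frac_homopolymer +
                 ts$fractions$frac_large, c(1, 1))
  only_other <- co$contexts[co$contexts$category == "OTHER", ]
  ts2 <- taxonomy_summary(only_other, rep("x", nrow(only_other)))
  expect_equal(ts2$fractions$frac_other, 1)
  expect_equal(ts2$fractions$frac_homopolymer, 0)
  expect_equal(ts2$fractions$frac_large, 0)
})

test_that("artifact indels have a lower in-frame fraction than true indels", {
  co <- tiny_cohort()
  led <- co$ledger[match(co$contexts$key, co$ledger$key), ]
  ts <- taxonomy_summary(co$contexts,
                         ifelse(led$origin == "true_variant", "true",
                                "artifact"))
  fr <- ts$fractions
  expect_lt(fr$frac_mod3[fr$label == "artifact"],
            fr$frac_mod3[fr$label == "true"])
})
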