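small_cfg <- function(...) {
  sim_config(seed = 5, n_genes = 20, n_dna_samples = 60,
             n_wga_samples = 25, n_pairs_dna_dna = 4,
             n_pairs_wga_dna = 3, n_pairs_wga_wga = 4, ...)
}

test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$geno, b$geno)
  expect_identical(a$meta, b$meta)
  expect_identical(a$ledger, b$ledger)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_reference_fasta(a$ref, fa); write_reference_fasta(b$ref, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("gene layout respects the contig and n_genes = 0 works", {
  rg <- simulate_reference(sim_config(seed = 3, n_genes = 0))
  expect_null(rg$genes)
  expect_error(simulate_reference(sim_config(seed = 3, n_genes = 50,
                                             contig_length = 1000)),
               "infeasible packing")
})

test_that("observed homopolymer tract density matches the request", {
  for (d in c(1 / 500, 1 / 200)) {
    cfg <- sim_config(seed = 17, n_genes = 100, hp_tract_density = d)
    rg <- simulate_reference(cfg)
    n_obs <- nrow(scan_homopolymers(rg$ref, 4))
    lambda <- ref_length(rg$ref) * d
    expect_lt(abs(n_obs - lambda), 3 * sqrt(lambda) + 3)
  }
})

test_that("ledger is complete and artifacts are confined to WGA samples", {
  co <- tiny_cohort()
  expect_setequal(co$ledger$key, rownames(co$geno))
  expect_false(any(duplicated(co$ledger$key)))
  art <- co$ledger$key[co$ledger$origin != "true_variant"]
  non_wga <- co$geno[art, !co$meta$wga, drop = FALSE]
  expect_true(all(is.na(non_wga) | non_wga == 0))
  # replicate samples share true genotypes apart from dropout
  tv <- co$ledger$key[co$ledger$origin == "true_variant"]
  for (i in seq_len(nrow(co$pairs))) {
    ga <- co$geno[tv, co$pairs$sample_a[i]]
    gb <- co$geno[tv, co$pairs$sample_b[i]]
    ok <- !is.na(ga) & !is.na(gb)
    expect_true(all(ga[ok] == gb[ok]))
  }
})

test_that("without injection and with homogeneous depth the groups match", {
  cfg <- small_cfg(hp_error_rate = 0, chimera_rate = 0,
                   depth_mean_wga = 165, depth_sd_wga = 40)
  expect_warning(co <- simulate_cohort(cfg), NA)
  expect_true(all(co$ledger$origin == "true_variant"))
  ind <- co$alleles$type != "SNV"
  burden <- colSums(co$geno[ind, , drop = FALSE] >= 1, na.rm = TRUE)
  w <- stats::wilcox.test(burden[co$meta$wga], burden[!co$meta$wga])
  expect_gt(w$p.value, 0.01)
})

test_that("zero WGA samples with artifact rates warns and injects nothing", {
  cfg <- sim_config(seed = 2, n_genes = 10, n_dna_samples = 30,
                    n_wga_samples = 0, n_pairs_dna_dna = 0,
                    n_pairs_wga_dna = 0, n_pairs_wga_wga = 0)
  expect_warning(co <- simulate_cohort(cfg), "no WGA samples")
  expect_true(all(co$ledger$origin == "true_variant"))
})

test_that("WGA samples carry the excess LOF indel burden", {
  co <- tiny_cohort()
  b <- build_burden(co$alleles, co$geno, co$consequence, co$contexts,
                    genes = co$genes)
  expect_gt(median(b$samples$lof_indel[co$meta$wga]),
            median(b$samples$lof_indel[!co$meta$wga]))
})

test_that("true indels are frame-biased, artifacts are not", {
  co <- default_cohort()
  led <- co$ledger[match(co$contexts$key, co$ledger$key), ]
  true_mod3 <- mean(co$contexts$mod3[led$origin == "true_variant"])
  art_mod3 <- mean(co$contexts$mod3[led$origin != "true_variant"])
  expect_lt(abs(true_mod3 - co$cfg$inframe_bias), 0.07)
  expect_lt(abs(art_mod3 - 1 / 3), 0.07)
})

test_that("chimera copy-origins are proximal: all within 10 kb, most within 2 kb", {
  co <- default_cohort()
  ch <- co$ledger[co$ledger$origin == "chimera_artifact", ]
  al <- co$alleles[match(ch$key, co$keys), ]
  ins <- al$type == "insertion"
  d <- abs(ch$copy_origin[ins] - al$pos[ins])
  expect_true(all(d <= 10000))
  expect_gte(mean(d <= 2000), 0.5)
})

test_that("slippage alleles recur across WGA samples at elevated frequency", {
  co <- default_cohort()
  hp <- co$ledger$key[co$ledger$origin == "hp_artifact"]
  carriers <- rowSums(co$geno[hp, co$meta$wga, drop = FALSE] >= 1,
                      na.rm = TRUE)
  expect_gt(max(carriers), 10)   # heavy-tailed tract propensities
})
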