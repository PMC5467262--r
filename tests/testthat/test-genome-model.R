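test_that("homopolymer scanning finds exactly the maximal runs", {
  r <- ref_seq("c", "AAAAGGGGC")
  tr <- scan_homopolymers(r, min_run = 4)
  expect_equal(tr$start, c(0L, 4L))
  expect_equal(tr$length, c(4L, 4L))
  expect_equal(tr$base, c("A", "G"))
  expect_equal(nrow(scan_homopolymers(ref_seq("c", "ACGT"), 4)), 0L)
})

test_that("homopolymer scan agrees with the naive character scan", {
  set.seed(11)
  for (len in c(200L, 2000L, 10000L)) {
    for (min_run in c(2L, 3L, 4L, 6L)) {
      s <- random_dna(len)
      got <- scan_homopolymers(ref_seq("c", s), min_run)
      want <- oracle_scan_runs(s, min_run)
      expect_equal(got$start, want$start)
      expect_equal(got$length, want$length)
      expect_equal(got$base, want$base)
    }
  }
})

test_that("every reported tract is maximal", {
  set.seed(12)
  s <- random_dna(20000)
  tr <- scan_homopolymers(ref_seq("c", s), 3)
  ch <- strsplit(s, "")[[1]]
  before <- tr$start               # 0-based base before the run is start-1
  ok_left <- tr$start == 0L | ch[tr$start] != tr$base
  after_idx <- tr$start + tr$length + 1L
  ok_right <- after_idx > length(ch) | ch[after_idx] != tr$base
  expect_true(all(ok_left & ok_right))
})

test_that("gene homopolymer content counts pooled G/C and A/T tracts per bp", {
  r <- ref_seq("c", "AAAAGGGGC")
  g <- gene_model("g1", "c", 0, 9)
  expect_equal(gene_homopolymer_content(g, r),
               c(gc = 1 / 9, at = 1 / 9))
  r2 <- ref_seq("c", "ACGTACGTA")
  expect_equal(gene_homopolymer_content(gene_model("g1", "c", 0, 9), r2),
               c(gc = 0, at = 0))
  expect_error(gene_homopolymer_content(gene_model("g", "c", 0, 3),
                                        ref_seq("c", "AC")),
               "outside reference")
})

test_that("gene homopolymer content equals scanning the concatenated exons", {
  set.seed(13)
  s <- random_dna(6000)
  r <- ref_seq("c", s)
  for (i in 1:50) {
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(0, 5800, by = 60), n_ex))
    ends <- starts + sample(30:59, n_ex, replace = TRUE)
    g <- gene_model(rep("g", n_ex), "c", starts, ends,
                    sample(c("+", "-"), 1))
    cds <- gene_cds_seq(g, r)
    tr <- oracle_scan_runs(cds, 4)
    expect_equal(gene_homopolymer_content(g, r),
                 c(gc = sum(tr$base %in% c("G", "C")) / nchar(cds),
                   at = sum(tr$base %in% c("A", "T")) / nchar(cds)))
  }
})

test_that("window GC is the direct count, clipped at contig ends", {
  expect_equal(window_gc(ref_seq("c", strrep("G", 30)), 15), 1.0)
  expect_equal(window_gc(ref_seq("c", strrep("A", 30)), 15), 0.0)
  s <- "ACGTACGTACGTACGTACGTA"
  expect_equal(window_gc(ref_seq("c", s), 10, 10),
               oracle_window_gc(s, 10, 10))
  set.seed(14)
  s <- random_dna(500)
  for (pos in c(0, 3, 250, 495, 499))
    expect_equal(window_gc(ref_seq("c", s), pos, 10),
                 oracle_window_gc(s, pos, 10))
  expect_error(window_gc(ref_seq("c", "ACGT"), 4), "outside contig")
})

test_that("consequence rule classifies CDS indels by frame and SNVs by codon", {
  # gene spans [10, 40); codons from position 10
  s <- paste0(strrep("A", 10), "ATGTACGGATCCTTAGCAGGCATCGATCGA",
              strrep("A", 10))
  r <- ref_seq("c", s)
  g <- gene_model("g1", "c", 10, 40)
  al <- new_allele_table(
    contig = "c",
    pos = c(15L, 15L, 20L, 16L, 5L, 25L),
    ref = c("A", "ACGGA", "T", "C", "A", substr(s, 25, 28)),
    alt = c("ACGTA", "A", "A", "A", "T", substr(s, 25, 25)),
    qs = NA_real_)
  got <- classify_consequence(al, g, r)
  expect_equal(got, c("frameshift",     # 4 bp CDS insertion
                      "frameshift",     # 4 bp CDS deletion
                      "missense",       # TCC -> ACC
                      "stop_gained",    # TAC -> TAA
                      "noncoding",      # SNV outside the gene
                      "inframe_indel")) # 3 bp CDS deletion
})

test_that("stop-gained detection uses the mutated codon", {
  # CDS = ATG TAC GGA: TAC with C->A at third base becomes TAA
  r <- ref_seq("c", "ATGTACGGA")
  g <- gene_model("g1", "c", 0, 9)
  al <- new_allele_table("c", 6L, "C", "A", NA_real_)
  expect_equal(classify_consequence(al, g, r), "stop_gained")
  al2 <- new_allele_table("c", 4L, "A", "C", NA_real_)  # TAC -> CAC
  expect_equal(classify_consequence(al2, g, r), "missense")
  al3 <- new_allele_table("c", 9L, "A", "G", NA_real_)  # GGA -> GGG (Gly)
  expect_equal(classify_consequence(al3, g, r), "silent")
})

test_that("frameshift is equivalent to indel length not divisible by 3 in CDS", {
  co <- tiny_cohort()
  ind <- co$alleles$type != "SNV"
  cons <- co$consequence[ind]
  len <- co$alleles$indel_len[ind]
  in_cds <- cons != "noncoding"
  expect_true(all((cons[in_cds] == "frameshift") == (len[in_cds] %% 3 != 0)))
  # partition: every variant gets exactly one known label
  expect_true(all(co$consequence %in%
                    c("stop_gained", "frameshift", "inframe_indel",
                      "missense", "silent", "noncoding")))
})
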