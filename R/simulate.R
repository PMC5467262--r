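#' Simulate the reference contig and gene layout
#'
#' One contig of background sequence with bounded run lengths (no
#' background run reaches 3 bases), homopolymer tracts injected at a
#' controlled density with flanks forced to differ (so the observed
#' maximal-run density matches the requested density), and
#' `n_genes` non-overlapping single-exon plus-strand genes.
#'
#' @param cfg a [sim_config()].
#' @return list with `ref` (a [ref_seq()]) and `genes` (gene model).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "reference"))
  margin <- 5000L
  need <- 2L * margin +
    cfg$n_genes * (cfg$gene_length + cfg$intergenic)
  len <- if (is.null(cfg$contig_length)) need else as.integer(cfg$contig_length)
  if (len < need)
    stop("infeasible packing: ", cfg$n_genes, " genes need ", need,
         " bp but contig_length is ", len)

  bases <- c("A", "C", "G", "T")
  # background with maximal run length 2: draw, then re-draw the third
  # base of any run of three or more until none remain
  s <- sample(bases, len, replace = TRUE)
  repeat {
    run3 <- which(s[-c(1L, 2L)] == s[-c(1L, len)] &
                    s[-c(1L, len)] == s[-c(len - 1L, len)]) + 2L
    if (!length(run3)) break
    s[run3] <- sample(bases, length(run3), replace = TRUE)
  }

  n_tracts <- stats::rpois(1, len * cfg$hp_tract_density)
  if (n_tracts > 0) {
    anchors <- sort(sample(seq(margin, len - margin), n_tracts))
    keep <- c(TRUE, diff(anchors) >= 15L)
    anchors <- anchors[keep]
    tlen <- sample(4:8, length(anchors), replace = TRUE,
                   prob = c(.4, .25, .15, .12, .08))
    tbase <- sample(bases, length(anchors), replace = TRUE)
    for (i in seq_along(anchors)) {
      a <- anchors[i]
      s[a:(a + tlen[i] - 1L)] <- tbase[i]
      for (fl in c(a - 1L, a + tlen[i])) { # force maximality
        excl <- unique(c(tbase[i], s[fl - 1L], s[fl + 1L]))
        s[fl] <- sample(setdiff(bases, excl), 1L)
      }
    }
  }
  ref <- ref_seq("chrSim", paste(s, collapse = ""))

  genes <- NULL
  if (cfg$n_genes > 0) {
    starts <- margin + (seq_len(cfg$n_genes) - 1L) *
      (cfg$gene_length + cfg$intergenic)
    genes <- gene_model(sprintf("g%04d", seq_len(cfg$n_genes)), ref$name,
                        starts, starts + cfg$gene_length, "+")
  }
  list(ref = ref, genes = genes)
}

#' Simulate a diploid cohort with WGA artifacts and a truth ledger
#'
#' Generates the reference, the sample sheet (singleton individuals plus
#' replicate pairs), true variants shared across groups at the
#' configured allele-frequency spectrum, and -- in WGA samples only --
#' the three artifact classes: recurrent homopolymer slippage indels
#' (one canonical allele per slipping tract, carriers drawn per WGA
#' sample from a tract-specific Gamma propensity), chimeric large indels
#' whose inserted sequence is copied verbatim from reference within the
#' configured origin distance, and per-gene coverage dropout (all
#' genotypes of a gene set missing when the sample's simulated depth
#' falls below the threshold). Replicate samples share their
#' individual's true genotypes but re-draw artifacts and missingness
#' independently.
#'
#' Every emitted alternate allele appears exactly once in the truth
#' ledger with its origin class; chimera entries record the copy-origin
#' position.
#'
#' @param cfg a [sim_config()].
#' @return object of class `wga_cohort`: list with `cfg`, `ref`,
#'   `genes`, `alleles`, `geno` (dosage matrix, keys x samples), `meta`,
#'   `pairs`, `ledger`, `truth_panel`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rg <- simulate_reference(cfg)
  ref <- rg$ref; genes <- rg$genes
  meta <- sim_meta(cfg)
  pairs <- attr(meta, "pairs")
  n_ind <- length(unique(meta$individual_id))
  ind_of <- match(meta$individual_id, unique(meta$individual_id))

  tv <- sim_true_variants(cfg, ref, n_ind)
  true_geno <- tv$ind_geno[, ind_of, drop = FALSE]

  wga_cols <- which(meta$wga)
  if (length(wga_cols) == 0 &&
      (cfg$hp_error_rate > 0 || cfg$chimera_rate > 0))
    warning("no WGA samples: artifact rates ignored")

  hp <- sim_hp_artifacts(cfg, ref, n_samples = nrow(meta),
                         wga_cols = wga_cols)
  ch <- sim_chimera_artifacts(cfg, ref, genes, n_samples = nrow(meta),
                              wga_cols = wga_cols)

  alleles <- rbind(tv$alleles, hp$alleles, ch$alleles)
  geno <- rbind(true_geno, hp$geno, ch$geno)
  origin <- c(rep("true_variant", nrow(tv$alleles)),
              rep("hp_artifact", nrow(hp$alleles)),
              rep("chimera_artifact", nrow(ch$alleles)))
  copy_origin <- c(rep(NA_integer_, nrow(tv$alleles) + nrow(hp$alleles)),
                   ch$copy_origin)

  # drop artifact alleles colliding with an earlier allele's key
  dup <- duplicated(allele_key(alleles))
  alleles <- alleles[!dup, , drop = FALSE]
  geno <- geno[!dup, , drop = FALSE]
  origin <- origin[!dup]; copy_origin <- copy_origin[!dup]

  # cap per-sample dosage at 2 where several alleles share a position
  res <- cap_site_dosage(alleles, geno, origin)
  drop <- res$drop
  alleles <- alleles[!drop, , drop = FALSE]
  geno <- res$geno[!drop, , drop = FALSE]
  origin <- origin[!drop]; copy_origin <- copy_origin[!drop]

  # site quality scores: artifacts score lower on average
  set.seed(substream_seed(cfg$seed, "qs"))
  alleles$qs <- stats::rnorm(nrow(alleles),
                             ifelse(origin == "true_variant",
                                    cfg$qs_mean_true, cfg$qs_mean_artifact),
                             cfg$qs_sd)

  # per-gene coverage dropout
  geno <- apply_dropout(cfg, geno, alleles, genes, meta)

  keys <- allele_key(alleles)
  rownames(geno) <- keys
  colnames(geno) <- meta$sample_id
  ledger <- data.frame(key = keys, origin = origin,
                       copy_origin = copy_origin,
                       stringsAsFactors = FALSE)
  set.seed(substream_seed(cfg$seed, "truth_panel"))
  true_keys <- keys[origin == "true_variant"]
  truth_panel <- sort(sample(true_keys,
                             round(cfg$truth_panel_frac * length(true_keys))))

  structure(list(cfg = cfg, ref = ref, genes = genes, alleles = alleles,
                 geno = geno, meta = meta, pairs = pairs, ledger = ledger,
                 truth_panel = truth_panel),
            class = "wga_cohort")
}

#' @export
print.wga_cohort <- function(x, ...) {
  cat(sprintf(paste0("<wga_cohort> %d alleles x %d samples ",
                     "(%d WGA), %d genes, %d replicate pairs\n"),
              nrow(x$alleles), nrow(x$meta), sum(x$meta$wga),
              if (is.null(x$genes)) 0L else length(unique(x$genes$gene_id)),
              nrow(x$pairs)))
  invisible(x)
}

# ---- internal stages ------------------------------------------------------

sim_meta <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "meta"))
  ind <- data.frame(
    individual_id = c(sprintf("D%04d", seq_len(cfg$n_dna_samples)),
                      sprintf("W%04d", seq_len(cfg$n_wga_samples)),
                      sprintf("Pdd%03d", seq_len(cfg$n_pairs_dna_dna)),
                      sprintf("Pwd%03d", seq_len(cfg$n_pairs_wga_dna)),
                      sprintf("Pww%03d", seq_len(cfg$n_pairs_wga_wga))),
    kind = rep(c("dna", "wga", "dd", "wd", "ww"),
               c(cfg$n_dna_samples, cfg$n_wga_samples, cfg$n_pairs_dna_dna,
                 cfg$n_pairs_wga_dna, cfg$n_pairs_wga_wga)),
    stringsAsFactors = FALSE)
  ind$any_wga <- ind$kind %in% c("wga", "wd", "ww")
  groups <- paste0("G", seq_len(cfg$n_groups))
  other <- groups[-1]
  pick_group <- function(p_g1) {
    g1 <- stats::runif(length(p_g1)) < p_g1
    ifelse(g1, "G1", sample(other, length(p_g1), replace = TRUE))
  }
  ind$group <- pick_group(ifelse(ind$any_wga, cfg$phenotype_confound,
                                 cfg$dna_g1_frac))
  ind$race <- sample(c("R1", "R2", "R3"), nrow(ind), replace = TRUE,
                     prob = c(.6, .25, .15))
  ind$age <- sample(30:80, nrow(ind), replace = TRUE)
  ind$sex <- sample(c("F", "M"), nrow(ind), replace = TRUE)

  # expand individuals to samples
  n_samp <- ifelse(ind$kind %in% c("dd", "wd", "ww"), 2L, 1L)
  idx <- rep(seq_len(nrow(ind)), n_samp)
  rep_no <- unlist(lapply(n_samp, seq_len))
  meta <- ind[idx, c("individual_id", "group", "race", "age", "sex")]
  meta$sample_id <- paste0(meta$individual_id, "-", rep_no)
  kind <- ind$kind[idx]
  meta$wga <- kind == "wga" | kind == "ww" | (kind == "wd" & rep_no == 1L)
  meta$is_primary <- rep_no == 1L
  meta$center <- ifelse(meta$wga,
                        sample(c("C1", "C2", "C3"), nrow(meta), TRUE,
                               prob = c(.7, .2, .1)),
                        sample(c("C1", "C2", "C3"), nrow(meta), TRUE,
                               prob = c(.3, .4, .3)))
  meta$bwa_version <- sample(c("0.5.9", "0.7.12"), nrow(meta), TRUE)
  meta$c20x <- ifelse(meta$wga, stats::rbeta(nrow(meta), 12, 2.5),
                      stats::rbeta(nrow(meta), 40, 2))
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "individual_id", "group", "wga", "center",
                   "bwa_version", "c20x", "race", "age", "sex",
                   "is_primary")]
  pk <- which(ind$kind %in% c("dd", "wd", "ww"))
  pid <- ind$individual_id[pk]
  pairs <- data.frame(
    individual_id = pid,
    sample_a = sprintf("%s-1", pid),
    sample_b = sprintf("%s-2", pid),
    pair_type = unname(c(dd = "DNA:DNA", wd = "WGA:DNA",
                         ww = "WGA:WGA")[ind$kind[pk]]),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(meta, "pairs") <- pairs
  meta
}

sim_true_variants <- function(cfg, ref, n_ind) {
  set.seed(substream_seed(cfg$seed, "true_variants"))
  len <- ref_length(ref)
  bases <- c("A", "C", "G", "T")

  # SNVs
  n_snv <- stats::rpois(1, len * cfg$true_snv_rate)
  pos0 <- sample.int(len - 20L, n_snv) + 9L   # keep off the contig ends
  refb <- vapply(pos0, function(p) ref_subseq(ref, p, p + 1L), character(1))
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L),
                 character(1), USE.NAMES = FALSE)
  snv <- new_allele_table(ref$name, pos0 + 1L, refb, altb, NA_real_)

  # coding-biased indels: in-frame with probability inframe_bias
  n_ind_var <- stats::rpois(1, len * cfg$true_indel_rate)
  a0 <- sample.int(len - 30L, n_ind_var) + 9L
  inframe <- stats::runif(n_ind_var) < cfg$inframe_bias
  L <- ifelse(inframe, sample(c(3L, 6L, 9L), n_ind_var, replace = TRUE),
              sample(c(1L, 2L, 4L, 5L, 7L, 8L), n_ind_var, replace = TRUE))
  is_ins <- stats::runif(n_ind_var) < 0.5
  rows <- lapply(seq_len(n_ind_var), function(i) {
    anchor <- ref_subseq(ref, a0[i], a0[i] + 1L)
    if (is_ins[i]) {
      ins <- paste(sample(bases, L[i], replace = TRUE), collapse = "")
      r <- anchor; a <- paste0(anchor, ins)
    } else {
      r <- ref_subseq(ref, a0[i], a0[i] + 1L + L[i]); a <- anchor
    }
    norm <- normalize_allele(a0[i] + 1L, r, a, ref)
    new_allele_table(ref$name, norm$pos, norm$ref, norm$alt, NA_real_)
  })
  alleles <- rbind(snv, do.call(rbind, rows))
  alleles <- alleles[!duplicated(allele_key(alleles)), , drop = FALSE]

  af <- stats::rbeta(nrow(alleles), cfg$af_shape1, cfg$af_shape2)
  ind_geno <- matrix(stats::rbinom(nrow(alleles) * n_ind, 2L, af),
                     nrow = nrow(alleles))
  poly <- rowSums(ind_geno) > 0L
  list(alleles = alleles[poly, , drop = FALSE],
       ind_geno = ind_geno[poly, , drop = FALSE],
       af = af[poly])
}

sim_hp_artifacts <- function(cfg, ref, n_samples, wga_cols) {
  set.seed(substream_seed(cfg$seed, "hp_artifacts"))
  empty <- list(alleles = new_allele_table(character(0), integer(0),
                                           character(0), character(0),
                                           numeric(0)),
                geno = matrix(0L, 0, n_samples))
  if (length(wga_cols) == 0 || cfg$hp_error_rate == 0) return(empty)
  tracts <- scan_homopolymers(ref, min_run = 4L)
  tracts <- tracts[tracts$start >= 1L, , drop = FALSE]
  nt <- nrow(tracts)
  if (nt == 0) return(empty)
  prop <- pmin(0.5, cfg$hp_error_rate *
                 stats::rgamma(nt, shape = cfg$hp_recurrence,
                               rate = cfg$hp_recurrence))
  # one canonical slippage allele per tract, recurrent across carriers
  k <- sample(1:6, nt, replace = TRUE)
  is_ins <- stats::runif(nt) < 0.6
  is_ins[!is_ins & k > tracts$length] <- TRUE   # deletion must fit the run
  carriers <- matrix(stats::rbinom(nt * length(wga_cols), 1L, prop),
                     nrow = nt)
  hit <- rowSums(carriers) > 0L
  if (!any(hit)) return(empty)
  tracts <- tracts[hit, , drop = FALSE]; k <- k[hit]; is_ins <- is_ins[hit]
  carriers <- carriers[hit, , drop = FALSE]
  anchor0 <- tracts$start - 1L
  anchor_base <- vapply(anchor0, function(p) ref_subseq(ref, p, p + 1L),
                        character(1))
  run <- strrep(tracts$base, k)
  refa <- ifelse(is_ins, anchor_base, paste0(anchor_base, run))
  alta <- ifelse(is_ins, paste0(anchor_base, run), anchor_base)
  alleles <- new_allele_table(ref$name, anchor0 + 1L, refa, alta, NA_real_)
  geno <- matrix(0L, nrow(alleles), n_samples)
  geno[, wga_cols] <- carriers
  list(alleles = alleles, geno = geno)
}

sim_chimera_artifacts <- function(cfg, ref, genes, n_samples, wga_cols) {
  set.seed(substream_seed(cfg$seed, "chimera"))
  empty <- list(alleles = new_allele_table(character(0), integer(0),
                                           character(0), character(0),
                                           numeric(0)),
                geno = matrix(0L, 0, n_samples),
                copy_origin = integer(0))
  if (length(wga_cols) == 0 || cfg$chimera_rate == 0) return(empty)
  n_per <- stats::rpois(length(wga_cols), cfg$chimera_rate)
  total <- sum(n_per)
  if (total == 0) return(empty)
  carrier <- rep(wga_cols, n_per)
  len <- ref_length(ref)

  rows <- vector("list", total)
  origins <- integer(total)
  for (i in seq_len(total)) {
    L <- sample(15:44, 1L)
    in_gene <- !is.null(genes) && stats::runif(1) < 0.8
    repeat {
      a0 <- if (in_gene) {
        g <- genes[sample.int(nrow(genes), 1L), ]
        sample(seq(g$start, g$end - 2L), 1L)
      } else sample(seq(100L, len - 100L), 1L)
      d <- min(round(stats::rexp(1, 1 / cfg$chimera_origin_scale)) + L + 1L,
               cfg$chimera_origin_cap)
      o <- a0 + sample(c(-1L, 1L), 1L) * d
      if (o < 0L || o + L > len) next
      anchor <- ref_subseq(ref, a0, a0 + 1L)
      if (stats::runif(1) < cfg$chimera_insertion_frac) {
        s <- ref_subseq(ref, o, o + L)
        # reject representations that are not already left-aligned
        if (substr(s, L, L) == anchor) next
        rows[[i]] <- new_allele_table(ref$name, a0 + 1L, anchor,
                                      paste0(anchor, s), NA_real_)
      } else {
        s <- ref_subseq(ref, a0 + 1L, a0 + 1L + L)
        if (substr(s, L, L) == anchor) next
        rows[[i]] <- new_allele_table(ref$name, a0 + 1L,
                                      paste0(anchor, s), anchor, NA_real_)
        o <- a0 + 1L   # a deletion's "origin" is its own span (excluded
                       # from matching); record the span start
      }
      origins[i] <- o
      break
    }
  }
  alleles <- do.call(rbind, rows)
  geno <- matrix(0L, total, n_samples)
  geno[cbind(seq_len(total), carrier)] <- 1L
  list(alleles = alleles, geno = geno, copy_origin = origins)
}

cap_site_dosage <- function(alleles, geno, origin) {
  site <- paste0(alleles$contig, ":", alleles$pos)
  drop <- rep(FALSE, nrow(alleles))
  for (idx in split(seq_len(nrow(alleles)), site)) {
    if (length(idx) < 2L) next
    d <- geno[idx, , drop = FALSE]
    tot <- colSums(d, na.rm = TRUE)
    over <- which(tot > 2L)
    for (j in over) {
      # reduce artifact rows (later rows) until the site is diploid
      for (r in rev(seq_along(idx))) {
        excess <- sum(d[, j], na.rm = TRUE) - 2L
        if (excess <= 0L) break
        take <- min(excess, d[r, j], na.rm = TRUE)
        if (!is.na(d[r, j])) d[r, j] <- d[r, j] - take
      }
    }
    geno[idx, ] <- d
    zero <- rowSums(d, na.rm = TRUE) == 0L & origin[idx] != "true_variant"
    drop[idx[zero]] <- zero[zero]
  }
  list(geno = geno, drop = drop)
}

apply_dropout <- function(cfg, geno, alleles, genes, meta) {
  if (is.null(genes)) return(geno)
  set.seed(substream_seed(cfg$seed, "depth"))
  ng <- nrow(genes)
  mu <- ifelse(meta$wga, cfg$depth_mean_wga, cfg$depth_mean_dna)
  sd <- ifelse(meta$wga, cfg$depth_sd_wga, cfg$depth_sd_dna)
  depth <- matrix(stats::rnorm(ng * nrow(meta),
                               rep(mu, each = ng), rep(sd, each = ng)),
                  nrow = ng)
  depth <- pmax(depth, 0)
  miss <- depth < cfg$missing_threshold
  gidx <- gene_index(alleles, genes)
  gene_ids <- genes$gene_id[order(genes$start)]
  for (g in seq_len(ng)) {
    cols <- which(miss[g, ])
    if (!length(cols)) next
    rows <- which(!is.na(gidx) & gidx == gene_ids[g])
    if (length(rows)) geno[rows, cols] <- NA_integer_
  }
  geno
}
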