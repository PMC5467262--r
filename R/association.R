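#' One-vs-rest logistic burden association
#'
#' For each eligible gene (at least two carriers in the cohort), fits a
#' logistic regression of the binary phenotype-group indicator on the
#' gene's per-individual LOF burden with race and age covariates, and
#' reports the burden coefficient and its Wald p-value. For
#' sex-specific groups only individuals of the stated sex are compared.
#' Individuals with missing covariates are dropped (count reported as
#' attribute `n_dropped`). Complete separation (common for rare
#' burdens) is detected and re-fit with a Firth-penalized logistic
#' model, flagged in the output.
#'
#' @param gene_matrix individuals x genes LOF count matrix (one row per
#'   individual; see [build_burden()]).
#' @param meta metadata aligned with rows: columns `group`, `race`,
#'   `age`, `sex`.
#' @param group phenotype group label to test against the rest.
#' @param sex_specific optional sex label; restricts the comparison.
#' @return data.frame: `gene_id`, `group`, `beta`, `p`, `n_carriers`,
#'   `tested`, `separation`.
#' @export
one_vs_rest_test <- function(gene_matrix, meta, group,
                             sex_specific = NULL) {
  stopifnot(nrow(meta) == nrow(gene_matrix), group %in% meta$group)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(sex_specific)) keep <- keep & meta$sex == sex_specific
  complete <- !is.na(meta$race) & !is.na(meta$age)
  n_dropped <- sum(keep & !complete)
  keep <- keep & complete
  meta <- meta[keep, , drop = FALSE]
  gene_matrix <- gene_matrix[keep, , drop = FALSE]
  y <- as.integer(meta$group == group)
  race <- factor(meta$race)
  X0 <- stats::model.matrix(~ race + age, data.frame(race = race,
                                                     age = meta$age))
  rows <- lapply(colnames(gene_matrix), function(g) {
    x <- gene_matrix[, g]
    n_carriers <- sum(x >= 1)
    if (n_carriers < 2L)
      return(data.frame(gene_id = g, group = group, beta = NA_real_,
                        p = NA_real_, n_carriers = n_carriers,
                        tested = FALSE, separation = FALSE,
                        stringsAsFactors = FALSE))
    X <- cbind(X0[, 1, drop = FALSE], burden = x, X0[, -1, drop = FALSE])
    fit <- logistic_wald(X, y, coef = "burden")
    data.frame(gene_id = g, group = group, beta = fit$beta, p = fit$p,
               n_carriers = n_carriers, tested = TRUE,
               separation = fit$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- n_dropped
  out
}

# Wald test for one coefficient; falls back to Firth on separation.
logistic_wald <- function(X, y, coef) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15)) separated <- TRUE
  if (separated) {
    f <- firth_logistic(X, y)
    j <- match(coef, colnames(X))
    return(list(beta = f$beta[j], p = f$p[j], separation = TRUE))
  }
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  j <- match(coef, colnames(X))
  z <- beta[j] / se[j]
  list(beta = unname(beta[j]), p = 2 * stats::pnorm(-abs(z)),
       separation = FALSE)
}

#' Firth-penalized logistic regression
#'
#' Jeffreys-prior penalized likelihood fit (hat-value adjusted score),
#' used as the fallback under complete separation; returns Wald
#' statistics from the penalized information matrix.
#'
#' @param X model matrix (with intercept column).
#' @param y binary response vector.
#' @param max_iter,tol Newton iteration controls.
#' @return list with `beta`, `se`, `p` (vectors over columns of `X`).
#' @export
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- numeric(ncol(X))
  I <- NULL
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-10)
    I <- crossprod(X * sqrt(w))
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * X) * w        # hat diagonal
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(Iinv %*% U)
    # dampen oversized steps for stability
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  se <- sqrt(diag(solve(I)))
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni significance cutoff
#'
#' `alpha / (n_groups * n_genes)`; with 31 groups and a rounded 10,000
#' genes at alpha 0.05 this is the conventional 1.61e-7 cutoff.
#'
#' @param n_groups,n_genes positive integers.
#' @param alpha family-wise error target (default 0.05).
#' @return numeric threshold.
#' @export
bonferroni_cutoff <- function(n_groups, n_genes, alpha = 0.05) {
  stopifnot(n_groups >= 1, n_genes >= 1)
  alpha / (n_groups * n_genes)
}

#' Inflation diagnostics across filter tiers
#'
#' For each filter tier's association results: quantile-quantile
#' coordinates of observed vs expected -log10 p, counts of
#' Bonferroni-significant genes per group, and the overlap of
#' significant gene sets between groups.
#'
#' @param results_by_tier named list; each element a data.frame of
#'   [one_vs_rest_test()] rows (possibly several groups bound together).
#' @param alpha family-wise error target (default 0.05).
#' @param n_genes optional fixed gene-count denominator for the cutoff;
#'   defaults to the number of distinct tested genes in each tier.
#' @return list with `qq` (per-tier data.frame), `significant` (tier x
#'   group counts), `cutoffs`, and `overlap` (per tier, matrix of
#'   significant-gene intersection counts between groups).
#' @export
inflation_report <- function(results_by_tier, alpha = 0.05,
                             n_genes = NULL) {
  qq <- list(); sig <- list(); cutoffs <- numeric(0); overlap <- list()
  for (tier in names(results_by_tier)) {
    res <- results_by_tier[[tier]]
    res <- res[res$tested & !is.na(res$p), , drop = FALSE]
    groups <- unique(res$group)
    ng <- if (is.null(n_genes)) length(unique(res$gene_id)) else n_genes
    cutoff <- bonferroni_cutoff(length(groups), ng, alpha)
    cutoffs[tier] <- cutoff
    p <- sort(res$p)   # ascending; row i pairs the i-th smallest p
    qq[[tier]] <- data.frame(
      tier = tier,
      expected = -log10((seq_along(p) - 0.5) / length(p)),
      observed = -log10(p))
    sig_sets <- lapply(groups, function(g)
      unique(res$gene_id[res$group == g & res$p < cutoff]))
    names(sig_sets) <- groups
    sig[[tier]] <- vapply(sig_sets, length, integer(1))
    ov <- outer(groups, groups, Vectorize(function(a, b)
      length(intersect(sig_sets[[a]], sig_sets[[b]]))))
    dimnames(ov) <- list(groups, groups)
    overlap[[tier]] <- ov
  }
  list(qq = do.call(rbind, qq), significant = do.call(rbind, sig),
       cutoffs = cutoffs, overlap = overlap)
}
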