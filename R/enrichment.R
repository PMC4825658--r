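# Differential-abundance testing of sorted pools against the presorted
# library: median-of-ratios size factors, method-of-moments dispersion
# estimation with a fitted mean-dispersion trend, and a conditioned
# negative-binomial exact test (the classic exact-test lineage; no GLM,
# shrinkage, or outlier machinery).

#' Median-of-ratios size factors
#'
#' \eqn{s_j = \mathrm{median}_g \; k_{gj} / (\prod_j k_{gj})^{1/m}} over
#' genes with a positive geometric mean. If no gene is positive in every
#' sample, a documented fallback uses positive counts only, over genes
#' present in at least half the samples.
#'
#' @param counts Integer matrix genes x samples, or `count_table`.
#' @param fallback Use the positive-count fallback instead of erroring
#'   when no gene has all-positive counts (default TRUE with a warning).
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts, fallback = TRUE) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  logk <- log(counts)
  loggeo <- rowMeans(logk)
  usable <- is.finite(loggeo)
  if (any(usable)) {
    sf <- apply(counts, 2L, function(k) {
      exp(stats::median((log(k) - loggeo)[usable]))
    })
  } else if (fallback) {
    warning("no gene has positive counts in every sample; falling back to ",
            "positive-count geometric means over genes present in >= half ",
            "the samples")
    npos <- rowSums(counts > 0)
    sel <- npos >= ncol(counts) / 2
    if (!any(sel)) stop("no gene present in at least half the samples")
    loggeo2 <- rowSums(replace(logk, !is.finite(logk), 0)[sel, , drop = FALSE]) /
      pmax(npos[sel], 1L)
    sf <- apply(counts[sel, , drop = FALSE], 2L, function(k) {
      r <- (log(k) - loggeo2)[k > 0]
      if (!length(r)) return(NA_real_)
      exp(stats::median(r))
    })
    if (anyNA(sf)) stop("size-factor fallback failed for some samples")
  } else {
    stop("no gene has positive counts in every sample; rerun with ",
         "fallback = TRUE to use the positive-count fallback")
  }
  stopifnot(all(sf > 0))
  sf
}

#' Method-of-moments dispersion estimation with a fitted trend
#'
#' Counts are brought to the common scale (divided by size factors).
#' Per gene, the raw NB dispersion is estimated by method of moments,
#' \eqn{\hat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)}, pooled across
#' replicate groups (within-group moments, df-weighted). A parametric
#' trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} is fitted to the positive raw
#' estimates by a gamma-family GLM, and the working dispersion per gene
#' is \eqn{\max(\text{raw}, \text{trend}, \text{floor})}. With fewer
#' than two replicates in every group no group-wise raw estimate exists:
#' the estimator falls back to treating all samples as one group
#' ("blind") and uses the fitted trend only, with a warning.
#'
#' @param counts Integer matrix genes x samples.
#' @param size_factors From [estimate_size_factors()].
#' @param groups Factor/character of length `ncol(counts)` defining
#'   replicate groups.
#' @param floor Minimum working dispersion (default 1e-8).
#' @return List of class `dispersion_model`: `raw`, `trend`, `working`
#'   (per-gene numeric vectors), `base_mean`, `mode` ("pooled"/"blind"),
#'   trend coefficients `a0`, `a1`.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 floor = 1e-8) {
  stopifnot(is.matrix(counts), length(size_factors) == ncol(counts),
            length(groups) == ncol(counts))
  q <- sweep(counts, 2L, size_factors, "/")
  base_mean <- rowMeans(q)
  groups <- as.factor(groups)
  sizes <- table(groups)
  mode <- "pooled"
  if (all(sizes < 2L)) {
    warning("no replicate group has >= 2 samples: blind trend-only ",
            "dispersion mode (single-sample design); per-gene raw ",
            "estimates are unavailable")
    mode <- "blind"
    groups <- factor(rep("all", ncol(counts)))
    sizes <- table(groups)
  }
  use <- names(sizes)[sizes >= 2L]
  num <- rep(0, nrow(counts)); den <- 0
  for (g in use) {
    sel <- groups == g
    mu <- rowMeans(q[, sel, drop = FALSE])
    v <- apply(q[, sel, drop = FALSE], 1L, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- 0
    df <- sum(sel) - 1L
    num <- num + df * a
    den <- den + df
  }
  raw <- pmax(num / den, 0)
  # parametric trend on genes with informative raw estimates
  pos <- which(raw > 1e-8 & base_mean > 0)
  a0 <- 0; a1 <- 0
  if (length(pos) >= 10L) {
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(raw[pos] ~ I(1 / base_mean[pos]),
                   family = stats::Gamma(link = "identity"),
                   start = c(stats::median(raw[pos]), 1))),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      a0 <- max(stats::coef(fit)[1], 0)
      a1 <- max(stats::coef(fit)[2], 0)
    } else {
      a0 <- stats::median(raw[pos])
    }
  } else if (length(pos)) {
    a0 <- stats::median(raw[pos])
  }
  trend <- a0 + a1 / pmax(base_mean, 1e-8)
  working <- if (mode == "blind") pmax(trend, floor) else
    pmax(raw, trend, floor)
  structure(list(raw = raw, trend = trend, working = working,
                 base_mean = base_mean, mode = mode, a0 = a0, a1 = a1,
                 floor = floor),
            class = "dispersion_model")
}

#' Conditioned negative-binomial exact test
#'
#' Tests whether the split of the total count between two sample groups
#' is compatible with no abundance difference. Group totals are modeled
#' as negative binomial with means proportional to the groups' summed
#' size factors and variances implied by the per-sample size factors and
#' the working dispersion \eqn{\alpha}; conditioning on the grand total
#' \eqn{K_S}, the two-sided p-value sums the probabilities of all splits
#' at most as probable as the observed one:
#' \deqn{p = \sum_{a : P(a)P(K_S-a) \le P(K_A)P(K_B)} P(a) P(K_S-a) \big/
#'       \sum_a P(a) P(K_S-a).}
#' At \eqn{\alpha = 0} this reduces to the exact binomial test with
#' success probability \eqn{s_A/(s_A+s_B)}.
#'
#' @param k_A,k_B Integer count vectors (one entry per sample) for the
#'   two groups.
#' @param sf_A,sf_B Size factors of the samples in each group.
#' @param dispersion Working NB dispersion \eqn{\alpha \ge 0}.
#' @return Two-sided p-value in (0, 1].
#' @export
nb_test <- function(k_A, k_B, sf_A, sf_B, dispersion) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(all(k_A >= 0), all(k_B >= 0),
            length(sf_A) == length(k_A), length(sf_B) == length(k_B))
  KA <- sum(k_A); KB <- sum(k_B); KS <- KA + KB
  if (KS == 0L) return(1)
  sA <- sum(sf_A); sB <- sum(sf_B)
  q <- KS / (sA + sB)
  muA <- q * sA; muB <- q * sB
  a <- 0:KS
  if (dispersion == 0) {
    lpA <- stats::dpois(a, muA, log = TRUE)
    lpB <- stats::dpois(KS - a, muB, log = TRUE)
  } else {
    # variance of a group total = sum over samples of mu_i + alpha mu_i^2
    vA <- muA + dispersion * sum((q * sf_A)^2)
    vB <- muB + dispersion * sum((q * sf_B)^2)
    sizeA <- muA^2 / (vA - muA)
    sizeB <- muB^2 / (vB - muB)
    lpA <- stats::dnbinom(a, mu = muA, size = sizeA, log = TRUE)
    lpB <- stats::dnbinom(KS - a, mu = muB, size = sizeB, log = TRUE)
  }
  lp <- lpA + lpB
  lobs <- lp[KA + 1L]
  keep <- lp <= lobs + 1e-7              # tolerate float ties
  p <- exp(log(sum(exp(lp[keep] - lobs))) + lobs -
             (log(sum(exp(lp - lobs))) + lobs))
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values (monotone, order-preserving, `>= p`).
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Test per-gene enrichment of a sorted pool vs the presorted library
#'
#' Per gene: `log2FC` is the pseudocount-stabilized log2 ratio of mean
#' common-scale counts (pool over presorted; the pseudocount never enters
#' the test), `p` from [nb_test()] at the gene's working dispersion,
#' `padj` by Benjamini-Hochberg across the genes tested in this pool, and
#' `rank` by (padj, p, decreasing |log2FC|, gene name) for deterministic
#' ordering.
#'
#' @param counts Integer matrix genes x samples (typically from
#'   [merge_tags()]), already restricted to filter-passing genes.
#' @param pool_samples,presorted_samples Column names of the two groups.
#' @param size_factors Optional precomputed size factors for all used
#'   columns (estimated from `counts` over the used columns otherwise).
#' @param dispersions Optional `dispersion_model`; estimated otherwise
#'   with groups = pool vs presorted.
#' @param pseudocount Common-scale pseudocount for the fold-change display
#'   (default 0.5).
#' @return data.frame: gene, baseMean, log2FC, p, padj, rank; sorted by
#'   rank. Attribute `"dispersion_mode"` records pooled/blind mode.
#' @export
test_enrichment <- function(counts, pool_samples, presorted_samples,
                            size_factors = NULL, dispersions = NULL,
                            pseudocount = 0.5) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (!length(pool_samples) || !length(presorted_samples)) {
    stop("empty design group")
  }
  stopifnot(all(c(pool_samples, presorted_samples) %in% colnames(counts)))
  use <- c(pool_samples, presorted_samples)
  k <- counts[, use, drop = FALSE]
  if (nrow(k) == 0L) {
    out <- data.frame(gene = character(0), baseMean = numeric(0),
                      log2FC = numeric(0), p = numeric(0), padj = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    attr(out, "dispersion_mode") <- "none"
    return(out)
  }
  groups <- rep(c("pool", "presorted"), c(length(pool_samples),
                                          length(presorted_samples)))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(k)
  size_factors <- size_factors[use]
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(k, size_factors, groups)
  }
  q <- sweep(k, 2L, size_factors, "/")
  mean_pool <- rowMeans(q[, groups == "pool", drop = FALSE])
  mean_pre <- rowMeans(q[, groups == "presorted", drop = FALSE])
  lfc <- log2((mean_pool + pseudocount) / (mean_pre + pseudocount))
  pvals <- vapply(seq_len(nrow(k)), function(g) {
    nb_test(k[g, groups == "pool"], k[g, groups == "presorted"],
            size_factors[groups == "pool"], size_factors[groups == "presorted"],
            dispersions$working[g])
  }, numeric(1))
  padj <- benjamini_hochberg(pvals)
  res <- data.frame(gene = rownames(k), baseMean = rowMeans(q),
                    log2FC = lfc, p = pvals, padj = padj,
                    stringsAsFactors = FALSE)
  ord <- order(res$padj, res$p, -abs(res$log2FC), res$gene)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "dispersion_mode") <- dispersions$mode
  res
}

#' Classify mutant phenotypes from per-pool enrichment results
#'
#' Decision table over significant positive enrichments (padj at most
#' `padj_max` and log2FC at least `lfc_min`):
#' enrichment in both negative gates (uninduced and induced) calls
#' `GFP_NEG`; in the induced basal gate only, `NON_INDUCER`; in the
#' uninduced elevated gate (with or without the hyper-induced gate),
#' `HIGH_BASAL`; in the hyper-induced gate only, `HYPER_INDUCER`;
#' anything else is `unclassified`. Overlapping patterns resolve by the
#' priority GFP_NEG > NON_INDUCER > HIGH_BASAL > HYPER_INDUCER
#' (double-pool evidence first); the priority chain also absorbs the
#' physical spillover of each class into neighbouring gates (a
#' non-inducing mutant sitting at the basal level leaks into the induced
#' negative gate, an elevated-basal mutant into the hyper-induced gate).
#'
#' @param results Named list of [test_enrichment()] results, one per pool;
#'   names must include the five pools of [pool_names()].
#' @param padj_max,lfc_min Significance thresholds (defaults 0.05, 1).
#' @return data.frame: gene, call, plus one logical `sig_<pool>` column
#'   per pool.
#' @export
classify_phenotypes <- function(results, padj_max = 0.05, lfc_min = 1) {
  missing_pools <- setdiff(pool_names(), names(results))
  if (length(missing_pools)) {
    stop("missing pool result(s): ", paste(missing_pools, collapse = ", "))
  }
  genes <- sort(unique(unlist(lapply(results, `[[`, "gene"))))
  if (!length(genes)) {
    return(data.frame(gene = character(0), call = character(0),
                      stringsAsFactors = FALSE))
  }
  for (p in pool_names()) {
    if (!setequal(results[[p]]$gene, genes)) {
      stop("gene universe differs across pools (pool ", p, ")")
    }
  }
  sig <- sapply(pool_names(), function(p) {
    r <- results[[p]]
    s <- r$padj <= padj_max & r$log2FC >= lfc_min
    s[match(genes, r$gene)]
  })
  # priority chain: later assignments overwrite earlier (weaker) calls
  call <- rep("unclassified", length(genes))
  call[sig[, "In_Gfp_plusplus"]] <- "HYPER_INDUCER"
  call[sig[, "Un_Gfp_plus"]] <- "HIGH_BASAL"
  call[sig[, "In_Gfp_basal"]] <- "NON_INDUCER"
  call[sig[, "Un_Gfp_neg"] & sig[, "In_Gfp_neg"]] <- "GFP_NEG"
  out <- data.frame(gene = genes, call = call, stringsAsFactors = FALSE)
  colnames(sig) <- paste0("sig_", colnames(sig))
  cbind(out, as.data.frame(sig))
}
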