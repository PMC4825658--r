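test_that("size factors follow the median-of-ratios definition", {
  genes <- paste0("g", 1:5)
  k <- matrix(c(10, 20, 40, 80, 100), 5, 3, dimnames = list(genes, c("a", "b", "c")))
  sf <- estimate_size_factors(k)
  expect_equal(unname(sf), rep(1, 3))           # identical columns

  k2 <- cbind(a = k[, 1], b = 2 * k[, 1])
  sf2 <- estimate_size_factors(k2)
  expect_equal(unname(sf2["b"] / sf2["a"]), 2)

  # 5 genes x 3 samples against a hand computation of the formula
  set.seed(42)
  k3 <- matrix(rpois(15, 50) + 1L, 5, 3, dimnames = list(genes, c("a", "b", "c")))
  hand <- sapply(1:3, function(j) {
    ratios <- sapply(1:5, function(g) {
      k3[g, j] / prod(k3[g, ])^(1 / 3)
    })
    median(ratios)
  })
  expect_equal(unname(estimate_size_factors(k3)), hand)

  # scaling one column scales the size-factor ratio proportionally
  k4 <- k3; k4[, 1] <- k4[, 1] * 7L
  sf3 <- estimate_size_factors(k3); sf4 <- estimate_size_factors(k4)
  expect_equal(unname(sf4["a"] / sf4["b"]), unname(7 * sf3["a"] / sf3["b"]))
  # and leaves common-scale counts of that column invariant
  expect_equal(k4[, 1] / sf4["a"] * (sf4["b"] / k4[, 2] * k3[, 2] / sf3["b"]),
               k3[, 1] / sf3["a"], tolerance = 1e-12)

  # no all-positive gene: documented fallback with warning
  k5 <- matrix(c(0, 5, 8, 7, 0, 9, 6, 10, 0), 3, 3,
               dimnames = list(genes[1:3], c("a", "b", "c")))
  expect_warning(sf5 <- estimate_size_factors(k5), "falling back")
  expect_true(all(sf5 > 0))
  expect_error(estimate_size_factors(k5, fallback = FALSE), "fallback")
})

test_that("dispersion estimation recovers simulated overdispersion", {
  set.seed(7)
  ng <- 2000L
  mu <- rlnorm(ng, log(100), 0.8)
  grp <- rep(c("A", "B"), each = 6)
  # Poisson counts: working dispersion stays near the floor
  kp <- sapply(1:12, function(j) rpois(ng, mu))
  dimnames(kp) <- list(paste0("g", 1:ng), paste0("s", 1:12))
  dp <- estimate_dispersions(kp, rep(1, 12), grp)
  expect_gt(mean(dp$working < 0.02), 0.95)

  # NB alpha = 0.2: median raw estimate within +-0.05 at 6 replicates
  kn <- sapply(1:12, function(j) rnbinom(ng, mu = mu, size = 1 / 0.2))
  dimnames(kn) <- dimnames(kp)
  dn <- estimate_dispersions(kn, rep(1, 12), grp)
  expect_lt(abs(median(dn$raw) - 0.2), 0.05)
  # working >= raw and >= floor always
  expect_true(all(dn$working >= dn$raw - 1e-12))
  expect_true(all(dn$working >= dn$floor))

  # constant counts across replicates: raw dispersion 0
  kc <- matrix(40L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  dc <- estimate_dispersions(kc, rep(1, 4), rep(c("A", "B"), each = 2))
  expect_equal(unname(dc$raw), rep(0, 4))

  # single sample per group: blind trend-only mode with a warning
  expect_warning(
    db <- estimate_dispersions(kn[, c(1, 7), drop = FALSE], rep(1, 2),
                               c("A", "B")),
    "blind")
  expect_equal(db$mode, "blind")
})

test_that("nb_test is symmetric, calibrated at the mode, and matches limits", {
  # equal totals, equal size-factor sums: the observed split is modal -> p = 1
  expect_equal(nb_test(c(10, 10), c(10, 10), c(1, 1), c(1, 1), 0.1), 1)
  # exchange symmetry
  p1 <- nb_test(c(30, 25), c(10, 12, 9), c(1, 1.2), c(0.8, 1, 1.1), 0.07)
  p2 <- nb_test(c(10, 12, 9), c(30, 25), c(0.8, 1, 1.1), c(1, 1.2), 0.07)
  expect_equal(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  # dispersion -> 0 equals the exact binomial test (enumeration)
  for (seed in 1:5) {
    set.seed(seed)
    kA <- rpois(2, 30); kB <- rpois(2, 20)
    sfA <- runif(2, 0.5, 2); sfB <- runif(2, 0.5, 2)
    KS <- sum(kA) + sum(kB)
    d <- dbinom(0:KS, KS, sum(sfA) / (sum(sfA) + sum(sfB)))
    pb <- sum(d[d <= d[sum(kA) + 1] * (1 + 1e-7)])
    expect_equal(nb_test(kA, kB, sfA, sfB, 0), pb, tolerance = 1e-6)
  }
  expect_error(nb_test(1, 1, 1, 1, -0.1), "dispersion")
})

test_that("benjamini_hochberg matches the step-up procedure", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 0)), "0, 1")
  # property check against the reference implementation
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  }
})

test_that("test_enrichment is label-antisymmetric and null on flat tables", {
  set.seed(11)
  ng <- 40L
  k <- matrix(rnbinom(ng * 8, mu = 80, size = 20), ng, 8,
              dimnames = list(paste0("g", 1:ng), paste0("s", 1:8)))
  pool <- paste0("s", 1:4); pre <- paste0("s", 5:8)
  a <- test_enrichment(k, pool, pre)
  b <- test_enrichment(k, pre, pool)
  bb <- b[match(a$gene, b$gene), ]
  expect_equal(a$log2FC, -bb$log2FC, tolerance = 1e-9)
  expect_equal(a$p, bb$p, tolerance = 1e-12)
  expect_true(all(a$padj >= a$p))
  expect_equal(a$rank, seq_len(ng))

  # all-equal counts per gene: every p is 1 and BH keeps it there
  kf <- matrix(rep(c(50L, 80L, 20L, 65L), 8), 4, 8, byrow = FALSE,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  flat <- test_enrichment(kf, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(all(flat$p == 1))
  expect_true(all(flat$padj == 1))

  expect_error(test_enrichment(k, character(0), pre), "empty design")
})

test_that("classify_phenotypes implements the decision table with priority", {
  genes <- paste0("g", 1:6)
  mkres <- function(sig_genes, lfc = 3) {
    data.frame(gene = genes, baseMean = 100,
               log2FC = ifelse(genes %in% sig_genes, lfc, 0),
               p = ifelse(genes %in% sig_genes, 1e-6, 0.9),
               padj = ifelse(genes %in% sig_genes, 1e-5, 0.95),
               rank = seq_along(genes), stringsAsFactors = FALSE)
  }
  results <- list(
    Un_Gfp_neg = mkres(c("g1", "g5")),
    In_Gfp_neg = mkres(c("g1", "g2", "g5")),
    In_Gfp_basal = mkres(c("g2", "g5")),
    Un_Gfp_plus = mkres("g3"),
    In_Gfp_plusplus = mkres(c("g3", "g4")))
  calls <- classify_phenotypes(results)
  got <- setNames(calls$call, calls$gene)
  expect_equal(unname(got["g1"]), "GFP_NEG")       # both negative gates
  expect_equal(unname(got["g2"]), "NON_INDUCER")   # basal gate (+ spillover)
  expect_equal(unname(got["g3"]), "HIGH_BASAL")    # with or without hyper gate
  expect_equal(unname(got["g4"]), "HYPER_INDUCER") # hyper gate only
  expect_equal(unname(got["g5"]), "GFP_NEG")       # priority over NON_INDUCER
  expect_equal(unname(got["g6"]), "unclassified")  # enriched nowhere

  expect_error(classify_phenotypes(results[-1]), "missing pool")
  # significance requires both padj and fold-change thresholds
  weak <- results
  weak$Un_Gfp_plus <- mkres("g3", lfc = 0.5)
  calls2 <- classify_phenotypes(weak)
  expect_equal(calls2$call[calls2$gene == "g3"], "HYPER_INDUCER")
})
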