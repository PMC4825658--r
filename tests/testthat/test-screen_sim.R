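test_that("default fluorescence models encode the expected class contrasts", {
  m <- default_gfp_models()
  loc <- function(cl, cond) gfp_params_for_test(m, cl, cond)
  # documented two-fold basal elevation of the HIGH_BASAL class
  expect_equal(10^(loc("HIGH_BASAL", "uninduced") - loc("WT", "uninduced")), 2.0)
  # non-inducer: identical medians in both conditions
  expect_equal(loc("NON_INDUCER", "induced"), loc("NON_INDUCER", "uninduced"))
  expect_equal(loc("NON_INDUCER", "uninduced"), loc("WT", "uninduced"))
  # reporter-negative class sits at the negative control in both conditions
  expect_equal(loc("GFP_NEG", "induced"), loc("GFP_NEG", "uninduced"))
  expect_equal(loc("GFP_NEG", "uninduced"), unname(m$controls$neg["mean"]))
  # induction separates the wild-type peaks
  expect_gt(loc("WT", "induced"), loc("WT", "uninduced"))
})

test_that("gates derived from controls bracket the control peaks", {
  m <- default_gfp_models()
  ctrl <- simulate_controls(m, n = 50000L, seed = 11L)
  gates <- derive_gates(ctrl)
  expect_equal(gates$name, pool_names())
  expect_true(all(gates$lower < gates$upper))
  # negative gate ends below the basal peak; hyper gate starts above induced
  expect_lt(gates$upper[gates$name == "Un_Gfp_neg"], median(ctrl$basal))
  expect_gt(gates$lower[gates$name == "In_Gfp_plusplus"], median(ctrl$induced))
  # bounds monotone within each condition
  un <- gates[gates$condition == "uninduced", ]
  expect_true(un$upper[un$name == "Un_Gfp_neg"] <=
                un$lower[un$name == "Un_Gfp_plus"])

  # identical control samples -> configuration error
  same <- list(neg = ctrl$basal, basal = ctrl$basal, induced = ctrl$basal)
  expect_error(derive_gates(same), "configuration error")

  # <5% of wild-type basal cells fall in the derived negative gate
  # (Monte-Carlo check of the 1st-percentile gating rule)
  wt <- rgfp(100000L, m, "WT", "uninduced")
  g <- gates[gates$name == "Un_Gfp_neg", ]
  expect_lt(mean(wt >= g$lower & wt < g$upper), 0.05)
})

test_that("simulate_population draws from the class models", {
  m <- default_gfp_models()
  p1 <- mutant_pool("G1", "WT")
  expect_equal(nrow(simulate_population(p1, m, "uninduced", 0L)), 0L)
  cells <- simulate_population(p1, m, "uninduced", 500L, seed = 3L)
  expect_true(all(cells$gene == "G1"))
  # sample median close to the model location at n = 1e5
  big <- simulate_population(p1, m, "uninduced", 100000L, seed = 4L)
  expect_lt(abs(median(big$gfp) - 2.0), 0.02)
  # unknown class errors
  bad <- p1; bad$class <- "NOPE"
  expect_error(simulate_population(bad, m, "uninduced", 10L), "NOPE")
})

test_that("apply_gate is an exact interval filter with analytic capture", {
  m <- default_gfp_models()
  pool <- mutant_pool("G1", "WT")
  cells <- simulate_population(pool, m, "induced", 100000L, seed = 8L)
  expect_identical(apply_gate(cells, list(lower = -Inf, upper = Inf)), cells)
  expect_equal(nrow(apply_gate(cells, list(lower = 99, upper = 100))), 0L)

  gates <- derive_gates(simulate_controls(m, n = 50000L, seed = 12L))
  g <- gates[gates$name == "In_Gfp_basal", ]
  frac <- nrow(apply_gate(cells, g)) / nrow(cells)
  p <- pgfp(g$upper, m, "WT", "induced") - pgfp(g$lower, m, "WT", "induced")
  se <- sqrt(p * (1 - p) / nrow(cells)) + 1e-9
  expect_lt(abs(frac - p), 3 * se + 1e-4)

  # conservation over disjoint gates: no cell in two, counts partition
  ind <- gates[gates$condition == "induced", ]
  caught <- lapply(seq_len(nrow(ind)), function(i) {
    rownames(apply_gate(cells, ind[i, ]))
  })
  expect_equal(length(unlist(caught)), length(unique(unlist(caught))))
  outside <- nrow(cells) - length(unlist(caught))
  expect_equal(sum(lengths(caught)) + outside, nrow(cells))
})

test_that("regrow applies fitness exponentially and drift shrinks with N", {
  x <- c(a = 400L, b = 300L, c = 300L)
  r0 <- regrow(x, fitness = 1, generations = 0L, seed = 1L)
  expect_equal(sum(r0), 1000L)
  expect_equal(names(r0), names(x))

  # one mutant at fitness 2 for 10 generations: expected proportion
  # follows p * 2^10 before renormalization
  counts <- stats::setNames(rep(1000L, 10), paste0("m", 1:10))
  fit <- c(2, rep(1, 9))
  r <- regrow(counts, fit, generations = 10L, seed = 2L)
  w <- counts * fit^10
  expected <- sum(counts) * w[1] / sum(w)
  expect_lt(abs(r[1] - expected) / expected, 0.05)

  # multinomial drift: sd of proportions scales like 1/sqrt(N)
  drift <- function(total, seed) {
    y <- stats::setNames(rep(total / 10L, 10L), paste0("m", 1:10))
    set.seed(seed)
    reps <- replicate(200, {
      r <- regrow(y, 1, 0L)
      r[1] / sum(r)
    })
    sd(reps)
  }
  expect_gt(drift(1000L, 5) / drift(100000L, 6), 5)  # theory: 10x

  expect_equal(length(regrow(integer(0))), 0L)
})

test_that("amplify_and_sequence lays out reads and injects errors at rate", {
  cat3 <- tiny_catalog()
  cfg <- sim_config(seed = 1L, pcr_noise_sd = 0, per_base_error_rate = 0,
                    reads_per_sample = 200L)
  res <- amplify_and_sequence(c(G1 = 100L), cat3, "AAAAAA", "up", cfg)
  expect_equal(nrow(res$reads), 200L)
  expect_equal(unname(res$gene_counts["G1"]), 200L)
  lay <- cat3$layout
  bc <- substr(res$reads$sequence, 6 + nchar(lay$upstream_primer) + 1,
               6 + nchar(lay$upstream_primer) + 20)
  expect_true(all(bc == cat3$entries$uptag[1]))
  expect_true(all(nchar(res$reads$sequence) == cfg$read_length))

  cfg0 <- sim_config(reads_per_sample = 0L)
  expect_equal(nrow(amplify_and_sequence(c(G1 = 5L), cat3, "AAAAAA", "up",
                                         cfg0)$reads), 0L)

  expect_error(amplify_and_sequence(c(NOPE = 5L), cat3, "AAAAAA", "up", cfg),
               "absent from catalog")

  # at per-base error 0.01 the fraction of reads with >=1 barcode error
  # approaches 1 - 0.99^20 (binomial closed form)
  cfge <- sim_config(seed = 2L, pcr_noise_sd = 0, per_base_error_rate = 0.01,
                     reads_per_sample = 20000L)
  rese <- amplify_and_sequence(c(G1 = 100L), cat3, "AAAAAA", "up", cfge)
  bce <- substr(rese$reads$sequence, 6 + nchar(lay$upstream_primer) + 1,
                6 + nchar(lay$upstream_primer) + 20)
  frac <- mean(bce != cat3$entries$uptag[1])
  p <- 1 - 0.99^20
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("simulate_screen emits the full sample grid deterministically", {
  s <- small_screen(seed = 21L, n_genes = 25L, classes = c(GFP_NEG = 2L),
                    n_cells = 4000L, reads = 3000L, replicates = 3L)
  # 3 replicates x (5 pools + presorted) x 2 tags = 36 sample streams
  expect_equal(nrow(s$sim$sample_sheet), 36L)
  expect_equal(length(s$sim$read_counts), 36L)

  # reporter-negative mutants are captured far more efficiently than
  # wild type in the uninduced negative gate
  tt <- s$sim$truth
  ratio <- tt$p_Un_Gfp_neg[tt$class == "GFP_NEG"][1] /
    tt$p_Un_Gfp_neg[tt$class == "WT"][1]
  expect_gt(ratio, 10)

  # determinism: identical seed -> identical reads
  s2 <- small_screen(seed = 21L, n_genes = 25L, classes = c(GFP_NEG = 2L),
                     n_cells = 4000L, reads = 3000L, replicates = 3L)
  expect_identical(s$sim$reads, s2$sim$reads)
  expect_identical(s$sim$read_counts, s2$sim$read_counts)

  # multiplex tags are unique within a lane (replicate)
  sheet <- s$sim$sample_sheet
  for (r in unique(sheet$replicate)) {
    expect_false(anyDuplicated(sheet$multiplex_tag[sheet$replicate == r]) > 0)
  }
})
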