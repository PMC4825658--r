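test_that("demultiplex assigns by nearest acceptable tag", {
  sheet <- data.frame(multiplex_tag = c("AAAAAA", "TTTTGG"),
                      sample = c("s1", "s2"), stringsAsFactors = FALSE)
  mk <- function(tags) {
    fastq_records(paste0("r", seq_along(tags)),
                  paste0(tags, strrep("C", 30)),
                  rep(strrep("I", 36), length(tags)))
  }
  # exact, 1-mismatch, and unassignable tags
  reads <- mk(c("AAAAAA", "AAAAAT", "GGGGGG", "TTTTGG"))
  d <- demultiplex(reads, sheet, tag_length = 6L, max_tag_mismatch = 1L)
  expect_equal(nrow(d$samples$s1), 2L)
  expect_equal(nrow(d$samples$s2), 1L)
  expect_equal(d$no_tag, 1L)

  # read at distance 1 from tag A and 3 from tag B goes to A (tags at
  # distance 4); verified against a direct distance computation
  tagA <- "AAAACC"; tagB <- "AAGGGG"
  sheet2 <- data.frame(multiplex_tag = c(tagA, tagB),
                       sample = c("A", "B"), stringsAsFactors = FALSE)
  q <- "AAAACG"
  dA <- sum(strsplit(q, "")[[1]] != strsplit(tagA, "")[[1]])
  dB <- sum(strsplit(q, "")[[1]] != strsplit(tagB, "")[[1]])
  expect_equal(c(dA, dB), c(1, 3))
  d2 <- demultiplex(mk(q), sheet2, 6L, max_tag_mismatch = 1L)
  expect_equal(nrow(d2$samples$A), 1L)

  # tags violating the separation precondition are rejected
  close_sheet <- data.frame(multiplex_tag = c("AAAAAA", "AAAAAT"),
                            sample = c("x", "y"))
  expect_error(demultiplex(mk("AAAAAA"), close_sheet, 6L, 1L),
               "configuration error")
})

test_that("extract_barcode inverts the read generator and tolerates primer noise", {
  cat3 <- tiny_catalog()
  lay <- cat3$layout
  cfg <- sim_config(pcr_noise_sd = 0, per_base_error_rate = 0,
                    reads_per_sample = 50L)
  res <- amplify_and_sequence(c(G2 = 10L), cat3, "ACACAC", "up", cfg, seed = 3L)
  bc <- extract_barcode(res$reads$sequence, lay)
  expect_true(all(bc == cat3$entries$uptag[2]))

  # read shorter than tag + primer + barcode -> NA
  expect_true(is.na(extract_barcode("ACACACGATG", lay)))

  # one substitution in the priming site is tolerated at radius 1
  full <- res$reads$sequence[1]
  broken <- full
  substr(broken, 8, 8) <- if (substr(full, 8, 8) == "A") "C" else "A"
  expect_equal(extract_barcode(broken, lay, primer_max_mismatch = 1L),
               cat3$entries$uptag[2])
  expect_true(is.na(extract_barcode(broken, lay, primer_max_mismatch = 0L)))
})

test_that("match_barcode agrees with the brute-force oracle on random catalogs", {
  set.seed(1234)
  for (trial in 1:20) {
    n <- sample(10:120, 1)
    catalog <- demo_catalog(n, seed = 1000L + trial)
    barcodes <- catalog$entries$uptag
    genes <- catalog$entries$gene
    mm <- sample(0:2, 1)
    queries <- c(
      sample(barcodes, 5),
      vapply(sample(barcodes, 5), mutate_seq, character(1),
             n_sub = sample(1:3, 1)),
      random_dna_for_test(3, 20))
    got <- match_barcode(queries, catalog, "up", max_mismatch = mm)
    for (i in seq_along(queries)) {
      want <- oracle_match(queries[i], barcodes, genes, mm)
      expect_equal(got$outcome[i], want$outcome)
      if (want$outcome == "unique") {
        expect_equal(got$gene[i], want$gene)
        expect_equal(got$distance[i], want$distance)
      }
    }
  }
})

test_that("match_barcode handles exact hits, misses, and shared barcodes", {
  cat3 <- tiny_catalog()
  m <- match_barcode(cat3$entries$uptag[1], cat3, "up")
  expect_equal(m$outcome, "unique")
  expect_equal(m$gene, "G1")
  expect_equal(m$distance, 0L)

  # distance max_mismatch + 1 from everything -> none
  far <- strrep("A", 20)
  expect_equal(match_barcode(far, cat3, "up", max_mismatch = 2L)$outcome, "none")

  # two genes sharing a verbatim barcode: ambiguous, never assigned
  e <- cat3$entries
  e$uptag[2] <- e$uptag[1]
  shared <- barcode_catalog(e)
  expect_equal(match_barcode(e$uptag[1], shared, "up")$outcome, "ambiguous")

  # length mismatch errors
  expect_error(match_barcode("ACGT", cat3, "up"), "length mismatch")
})

test_that("count_barcodes closes the loop on simulated reads with full ledgers", {
  s <- small_screen(seed = 31L, n_genes = 30L, classes = c(GFP_NEG = 2L),
                    n_cells = 5000L, reads = 5000L, replicates = 1L,
                    error_rate = 0)
  sheet <- s$sim$sample_sheet
  up <- sheet[sheet$tag == "up", ]
  samples <- s$sim$reads[paste0(up$sample, ".up")]
  names(samples) <- up$sample
  ct <- count_barcodes(samples, s$catalog, "up",
                       sample_tags = setNames(up$multiplex_tag, up$sample))
  # noise-free counting recovers the simulator's internal read draw exactly
  for (smp in up$sample) {
    expect_identical(ct$counts[, smp],
                     s$sim$read_counts[[paste0(smp, ".up")]])
  }
  # ledger partitions every read
  totals <- vapply(samples, nrow, integer(1))
  expect_equal(unname(colSums(ct$ledger)), unname(totals))
  expect_equal(unname(ct$ledger["assigned", ]), unname(colSums(ct$counts)))
  expect_true(all(ct$ledger[c("ambiguous", "unmatched", "no_tag"), ] == 0))

  # empty sample -> zero column, zero ledger
  ct0 <- count_barcodes(list(empty = fastq_records(character(0), character(0),
                                                   character(0))),
                        s$catalog, "up")
  expect_true(all(ct0$counts == 0L))
  expect_true(all(ct0$ledger == 0L))
})

test_that("counting is monotone in the mismatch radius", {
  catalog <- demo_catalog(40, seed = 77L)
  cfg <- sim_config(seed = 77L, per_base_error_rate = 0.02,
                    reads_per_sample = 3000L)
  comp <- setNames(rep(50L, 40), catalog$entries$gene)
  res <- amplify_and_sequence(comp, catalog, "ACGTCA", "up", cfg)
  samples <- list(s1 = res$reads)
  counts <- lapply(0:3, function(mm) {
    count_barcodes(samples, catalog, "up", max_mismatch = mm)$counts[, 1]
  })
  for (i in 2:4) expect_true(all(counts[[i]] >= counts[[i - 1]]))
})

test_that("minimum-read filter implements the and/or rule at the boundary", {
  genes <- c("g1", "g2", "g3", "g4")
  mk <- function(ctrl) {
    counts <- matrix(ctrl, ncol = 1, dimnames = list(genes, "presorted"))
    ledger <- matrix(c(sum(ctrl), 0L, 0L, 0L), ncol = 1,
                     dimnames = list(c("assigned", "ambiguous", "unmatched",
                                       "no_tag"), "presorted"))
    count_table(counts, ledger, "up")
  }
  up <- mk(c(50L, 49L, 0L, 100L))
  dn <- mk(c(0L, 49L, 50L, 100L))
  inc <- apply_min_read_filter(up, dn, "presorted", threshold = 50L)
  expect_true("g1" %in% inc)            # up = 50, dn = 0: in
  expect_false("g2" %in% inc)           # 49/49: out
  expect_true("g3" %in% inc)            # dn side alone suffices
  expect_equal(apply_min_read_filter(up, dn, "presorted", threshold = 0L),
               genes)
  expect_error(apply_min_read_filter(up, dn, "nope"), "control sample")
})

test_that("merge_tags keeps tags as separate technical columns", {
  genes <- paste0("g", 1:5)
  mk <- function(mat) {
    ledger <- rbind(assigned = colSums(mat), ambiguous = 0L, unmatched = 0L,
                    no_tag = 0L)
    colnames(ledger) <- colnames(mat)
    count_table(mat, ledger, "up")
  }
  set.seed(9)
  m <- matrix(rpois(15, 60), 5, 3, dimnames = list(genes, paste0("s", 1:3)))
  merged <- merge_tags(mk(m), mk(m))
  expect_equal(ncol(merged$counts), 6L)
  expect_identical(unname(merged$counts[, "s1.up"]),
                   unname(merged$counts[, "s1.dn"]))
  # duplicated columns receive identical median-of-ratios size factors
  sf <- estimate_size_factors(merged$counts)
  expect_equal(unname(sf[paste0("s", 1:3, ".up")]),
               unname(sf[paste0("s", 1:3, ".dn")]))

  bad <- mk(m[1:4, ])
  expect_error(merge_tags(mk(m), bad))
})
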