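# Shared fixtures and independent oracles. Fixtures are built in code;
# nothing is read from disk except files the tests write themselves.

tiny_catalog <- function() {
  barcode_catalog(data.frame(
    gene = c("G1", "G2", "G3"),
    uptag = c("ACGTACGTACGTACGTACGT",
              "TTTTGGGGCCCCAAAATTTT",
              "GACTGACTGACTGACTGACT"),
    dntag = c("TGCATGCATGCATGCATGCA",
              "AAAACCCCGGGGTTTTAAAA",
              "CTGACTGACTGACTGACTGA"),
    source = "primary_list", stringsAsFactors = FALSE))
}

write_catalog_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene\tuptag\tdntag",
               apply(df, 1L, paste, collapse = "\t")), path)
  path
}

# Independent brute-force barcode matcher: per query, loop over every
# catalog gene comparing split characters (no shared code with
# match_barcode's vectorized path).
oracle_match <- function(seq, barcodes, genes, max_mismatch) {
  qs <- strsplit(seq, "")[[1]]
  dists <- vapply(barcodes, function(b) {
    sum(strsplit(b, "")[[1]] != qs)
  }, numeric(1), USE.NAMES = FALSE)
  dmin <- min(dists)
  if (dmin > max_mismatch) {
    return(list(outcome = "none", gene = NA_character_, distance = NA_integer_))
  }
  hit <- unique(genes[dists == dmin])
  if (length(hit) == 1L) {
    list(outcome = "unique", gene = hit, distance = dmin)
  } else {
    list(outcome = "ambiguous", gene = NA_character_, distance = NA_integer_)
  }
}

# Location of a (unimodal) class/condition model, read off the raw
# parameter table.
gfp_params_for_test <- function(m, cl, cond) {
  p <- m$params
  p$mean1[p$class == cl & p$condition == cond]
}

random_dna_for_test <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_seq <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Small simulated screen shared by unit tests (kept light; the
# acceptance suite runs the full-size one).
small_screen <- function(seed = 99L, n_genes = 60L,
                         classes = c(GFP_NEG = 4L, NON_INDUCER = 3L,
                                     HIGH_BASAL = 2L),
                         n_cells = 20000L, reads = 20000L, replicates = 2L,
                         error_rate = 0.001) {
  catalog <- demo_catalog(n_genes, seed = seed)
  cls <- rep("WT", n_genes)
  at <- 0L
  for (cl in names(classes)) {
    cls[at + seq_len(classes[[cl]])] <- cl
    at <- at + classes[[cl]]
  }
  pool <- mutant_pool(catalog$entries$gene, cls)
  model <- default_gfp_models()
  gates <- derive_gates(simulate_controls(model, seed = seed + 1L))
  config <- sim_config(seed = seed, n_cells_sorted = n_cells,
                       reads_per_sample = reads, replicates = replicates,
                       per_base_error_rate = error_rate)
  sim <- simulate_screen(pool, model, gates, catalog, config,
                         write_files = FALSE)
  list(catalog = catalog, pool = pool, model = model, gates = gates,
       config = config, sim = sim)
}
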