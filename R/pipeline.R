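# Pipeline wiring: configuration, the simulate and screen stages, and
# helpers used by the command-line entry point (inst/cli/barseqscreen.R).

#' Generate a demo barcode catalog
#'
#' Random unique UPTAG/DNTAG barcodes for `n_genes` synthetic genes —
#' the fixture generator used by tests, demos and the `simulate`
#' subcommand. Barcodes are rejection-sampled to a minimum pairwise
#' Hamming distance so that mismatch-tolerant matching stays unambiguous.
#'
#' @param n_genes Number of genes.
#' @param layout An [amplicon_layout()].
#' @param min_dist Minimum pairwise barcode Hamming distance (default 5).
#' @param seed RNG seed.
#' @return A [barcode_catalog()]; gene names `G0001`, `G0002`, ...
#' @export
demo_catalog <- function(n_genes, layout = amplicon_layout(), min_dist = 5L,
                         seed = 1L) {
  with_seed(seed, {
    len <- layout$barcode_length
    pick <- function(n) {
      # random 20-mers are almost surely >= 5 apart; oversample and prune
      cand <- unique(random_dna(ceiling(n * 1.3) + 10L, len))
      keep <- character(0)
      for (s in cand) {
        if (!length(keep) || min(hamming_matrix(s, keep)) >= min_dist) {
          keep <- c(keep, s)
          if (length(keep) == n) break
        }
      }
      if (length(keep) < n) stop("could not place ", n, " barcodes")
      keep
    }
    bc <- pick(2L * n_genes)
    barcode_catalog(data.frame(
      gene = sprintf("G%04d", seq_len(n_genes)),
      uptag = bc[seq_len(n_genes)],
      dntag = bc[n_genes + seq_len(n_genes)],
      source = "primary_list", stringsAsFactors = FALSE), layout)
  })
}

#' Read or build a pipeline configuration
#'
#' The configuration is a single JSON document (the one human-editable
#' text format this package uses); every key has a default, and CLI flags
#' override config keys. `sim` keys feed [sim_config()].
#'
#' @param path Optional JSON file; `NULL` gives all defaults.
#' @param overrides Named list applied on top of the file values.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L, n_genes = 300L, catalog = NULL,
    sim = list(), threshold = 50L, max_mismatch = 2L,
    primer_max_mismatch = 2L, max_tag_mismatch = 1L,
    padj_max = 0.05, lfc_min = 1, cat_level = 0.999)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg$sim <- do.call(sim_config, c(cfg$sim[setdiff(names(cfg$sim), "seed")],
                                   list(seed = cfg$seed)))
  structure(cfg, class = "pipeline_config")
}

#' Simulate a demo screen to disk
#'
#' Builds (or loads) a catalog, spikes the configured mutant classes into
#' an otherwise wild-type pool, derives gates from simulated control
#' strains, and writes per-sample FASTQ files, the sample sheet, the
#' catalog and the ground-truth table.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param n_mutants Named integer vector: how many mutants of each
#'   non-wild-type class to spike in (default 20 GFP_NEG, 10 NON_INDUCER,
#'   5 HIGH_BASAL).
#' @return The [simulate_screen()] result (invisibly), with `catalog` and
#'   `gates` attached.
#' @export
run_simulate <- function(config = pipeline_config(), outdir,
                         n_mutants = c(GFP_NEG = 20L, NON_INDUCER = 10L,
                                       HIGH_BASAL = 5L)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  catalog <- if (!is.null(config$catalog)) {
    read_catalog(config$catalog)
  } else {
    demo_catalog(config$n_genes, seed = child_seed(config$seed, 11L))
  }
  n <- nrow(catalog$entries)
  if (sum(n_mutants) > n) stop("more mutants than genes in catalog")
  classes <- rep("WT", n)
  at <- 0L
  for (cl in names(n_mutants)) {
    classes[at + seq_len(n_mutants[[cl]])] <- cl
    at <- at + n_mutants[[cl]]
  }
  pool <- mutant_pool(catalog$entries$gene, classes)
  model <- default_gfp_models()
  controls <- simulate_controls(model, seed = child_seed(config$seed, 12L))
  gates <- derive_gates(controls)
  sim <- simulate_screen(pool, model, gates, catalog, config$sim,
                         outdir = outdir)
  write_catalog(catalog, file.path(outdir, "catalog.tsv"))
  write_tsv_meta(gates, file.path(outdir, "gates.tsv"),
                 meta = list(seed = config$seed))
  sim$catalog <- catalog
  sim$gates <- gates
  invisible(sim)
}

#' Run the counting / filtering / testing / classification chain
#'
#' Reads the sample sheet and FASTQ files of a (simulated or real) screen
#' directory, counts UPTAG and DNTAG barcodes with full read ledgers,
#' applies the minimum-read filter against the presorted control, tests
#' each sorted pool against the presorted library, classifies phenotypes,
#' and writes per-pool result tables, phenotype calls, count tables and a
#' machine-readable JSON run report.
#'
#' @param config A [pipeline_config()].
#' @param indir Directory holding `sample_sheet.tsv`, `catalog.tsv`, and
#'   the FASTQ files.
#' @param outdir Results directory.
#' @return List (invisibly): `counts` (per tag), `included`, `results`
#'   (per pool), `calls`, `report`.
#' @export
run_screen <- function(config = pipeline_config(), indir, outdir) {
  sheet_path <- file.path(indir, "sample_sheet.tsv")
  if (!file.exists(sheet_path)) stop("count stage: no sample_sheet.tsv in ", indir)
  sheet <- read_tsv_meta(sheet_path)
  if (!nrow(sheet)) stop("count stage: empty sample sheet")
  catalog <- read_catalog(file.path(indir, "catalog.tsv"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package_version = as.character(utils::packageVersion("barseqscreen")),
               seed = config$seed, threshold = config$threshold,
               padj_max = config$padj_max, lfc_min = config$lfc_min,
               multiple_testing = "BH within pool")
  tables <- list()
  for (tg in c("up", "dn")) {
    sub <- sheet[sheet$tag == tg, ]
    samples <- lapply(file.path(indir, sub$file), read_fastq)
    names(samples) <- sub$sample
    tables[[tg]] <- count_barcodes(
      samples, catalog, tg,
      sample_tags = stats::setNames(sub$multiplex_tag, sub$sample),
      max_mismatch = config$max_mismatch,
      primer_max_mismatch = config$primer_max_mismatch,
      max_tag_mismatch = config$max_tag_mismatch)
    write_count_table(tables[[tg]], file.path(outdir, paste0("counts_", tg, ".tsv")),
                      meta = meta)
  }
  control <- sheet$sample[sheet$pool == "presorted" & sheet$replicate == 1][1]
  if (is.na(control)) stop("filter stage: no presorted replicate-1 sample")
  included <- apply_min_read_filter(tables$up, tables$dn, control,
                                    threshold = config$threshold)
  merged <- merge_tags(tables$up, tables$dn)
  cold <- attr(merged, "col_data")
  pools_present <- intersect(pool_names(), unique(sheet$pool))
  sample_pool <- stats::setNames(sheet$pool[!duplicated(sheet$sample)],
                                 sheet$sample[!duplicated(sheet$sample)])
  presorted_cols <- cold$column[sample_pool[cold$sample] == "presorted"]
  results <- list()
  for (p in pools_present) {
    pool_cols <- cold$column[sample_pool[cold$sample] == p]
    k <- merged$counts[included, c(pool_cols, presorted_cols), drop = FALSE]
    res <- test_enrichment(k, pool_cols, presorted_cols,
                           pseudocount = 0.5)
    results[[p]] <- res
    write_tsv_meta(res, file.path(outdir, paste0("enrichment_", p, ".tsv")),
                   meta = c(meta, list(pool = p,
                                       dispersion_mode = attr(res, "dispersion_mode"))))
  }
  calls <- NULL
  if (all(pool_names() %in% pools_present)) {
    calls <- classify_phenotypes(results, padj_max = config$padj_max,
                                 lfc_min = config$lfc_min)
    write_tsv_meta(calls, file.path(outdir, "phenotype_calls.tsv"), meta = meta)
  }
  report <- list(
    seed = config$seed, threshold = config$threshold,
    genes_in_catalog = nrow(catalog$entries),
    genes_included = length(included),
    ledgers = lapply(tables, function(t) apply(t$ledger, 1L, sum)),
    tested_per_pool = vapply(results, nrow, integer(1)),
    calls = if (!is.null(calls)) as.list(table(calls$call)) else NULL)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts = tables, included = included, results = results,
                 calls = calls, report = report))
}

#' Simulate and analyze a demo screen end to end
#' @inheritParams run_simulate
#' @param dir Working directory; FASTQ go to `dir/sim`, results to
#'   `dir/results`.
#' @return The [run_screen()] result plus `sim` (invisibly).
#' @export
run_all <- function(config = pipeline_config(), dir,
                    n_mutants = c(GFP_NEG = 20L, NON_INDUCER = 10L,
                                  HIGH_BASAL = 5L)) {
  sim <- run_simulate(config, file.path(dir, "sim"), n_mutants = n_mutants)
  out <- run_screen(config, file.path(dir, "sim"), file.path(dir, "results"))
  out$sim <- sim
  invisible(out)
}
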