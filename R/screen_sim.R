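# Simulation of a pooled FACS reporter screen: a barcoded knockout pool
# carrying a pathway-responsive GFP reporter is grown with or without
# inducer, sorted into fluorescence gates defined against control
# strains, regrown, and read out by barcode sequencing.

#' Phenotype classes of reporter mutants
#'
#' The classes a knockout can fall into with respect to a pathway
#' reporter: wild-type behaviour; reporter-negative under both conditions
#' (pathway-null or silencing-defective); normal basal level but no
#' induction (receptor-dead); elevated basal level; hyper-induction;
#' reduced basal level; and a bimodal class whose population switches
#' between a silent and an expressing state.
#'
#' @return Character vector of class names.
#' @export
phenotype_classes <- function() {
  c("WT", "GFP_NEG", "NON_INDUCER", "HIGH_BASAL", "HYPER_INDUCER",
    "LOW_BASAL", "BIMODAL")
}

#' Names of the five sorted pools
#' @return Character vector: two uninduced gates and three induced gates.
#' @export
pool_names <- function() {
  c("Un_Gfp_neg", "Un_Gfp_plus", "In_Gfp_neg", "In_Gfp_basal",
    "In_Gfp_plusplus")
}

#' Default per-class fluorescence models
#'
#' Per class and condition (uninduced/induced), the distribution of
#' log10 reporter fluorescence per cell is a (mixture of) normal(s) on
#' the log10 axis, i.e. log-normal fluorescence. Defaults place the
#' reporter-negative control at `neg_location`, the wild-type basal peak
#' at `wt_basal`, and the wild-type induced peak at `wt_induced`
#' (arbitrary log10 fluorescence units); peak widths `sd` are typical of
#' log-scale flow-cytometry peaks. Class defaults encode: HIGH_BASAL at
#' `high_basal_fold` (default two-fold) the wild-type basal median with
#' normal induction; NON_INDUCER pinned at the wild-type basal level
#' under both conditions; GFP_NEG at the negative control level under
#' both conditions; HYPER_INDUCER inducing `hyper_fold` above wild type;
#' LOW_BASAL at half the wild-type basal level; BIMODAL a mixture of a
#' majority silent subpopulation and a minority subpopulation that
#' behaves like wild type.
#'
#' @param wt_basal,wt_induced,neg_location Peak medians (log10 units).
#' @param sd Peak standard deviation on the log10 axis.
#' @param high_basal_fold Linear fold elevation of the HIGH_BASAL basal median.
#' @param hyper_fold Linear fold elevation of the HYPER_INDUCER induced median.
#' @param low_basal_fold Linear fold reduction of the LOW_BASAL basal median.
#' @param bimodal_weight Mixture weight of the expressing subpopulation
#'   of the BIMODAL class.
#' @return Object of class `gfp_model`.
#' @export
default_gfp_models <- function(wt_basal = 2.0, wt_induced = 3.5,
                               neg_location = 1.0, sd = 0.15,
                               high_basal_fold = 2, hyper_fold = 2,
                               low_basal_fold = 2, bimodal_weight = 0.2) {
  stopifnot(sd > 0, bimodal_weight > 0, bimodal_weight < 1,
            wt_induced > wt_basal)
  row <- function(class, condition, m1, s1 = sd, w2 = 0, m2 = NA, s2 = sd) {
    data.frame(class = class, condition = condition, w1 = 1 - w2, mean1 = m1,
               sd1 = s1, w2 = w2, mean2 = m2, sd2 = s2,
               stringsAsFactors = FALSE)
  }
  hb <- wt_basal + log10(high_basal_fold)
  lb <- wt_basal - log10(low_basal_fold)
  hy <- wt_induced + log10(hyper_fold)
  params <- rbind(
    row("WT", "uninduced", wt_basal), row("WT", "induced", wt_induced),
    row("GFP_NEG", "uninduced", neg_location), row("GFP_NEG", "induced", neg_location),
    row("NON_INDUCER", "uninduced", wt_basal), row("NON_INDUCER", "induced", wt_basal),
    row("HIGH_BASAL", "uninduced", hb), row("HIGH_BASAL", "induced", wt_induced),
    row("HYPER_INDUCER", "uninduced", wt_basal), row("HYPER_INDUCER", "induced", hy),
    row("LOW_BASAL", "uninduced", lb), row("LOW_BASAL", "induced", wt_induced),
    row("BIMODAL", "uninduced", neg_location, w2 = bimodal_weight, m2 = wt_basal),
    row("BIMODAL", "induced", neg_location, w2 = bimodal_weight, m2 = wt_induced))
  structure(list(params = params,
                 controls = list(neg = c(mean = neg_location, sd = sd),
                                 basal = c(mean = wt_basal, sd = sd),
                                 induced = c(mean = wt_induced, sd = sd))),
            class = "gfp_model")
}

#' @noRd
gfp_params <- function(model, class, condition) {
  p <- model$params
  i <- which(p$class == class & p$condition == condition)
  if (!length(i)) stop("unknown class/condition: ", class, "/", condition)
  p[i, ]
}

#' Draw per-cell log10 fluorescence for a class
#' @param n Number of cells.
#' @param model A `gfp_model`.
#' @param class Phenotype class name.
#' @param condition `"uninduced"` or `"induced"`.
#' @return Numeric vector of log10 fluorescence values.
#' @export
rgfp <- function(n, model, class, condition) {
  p <- gfp_params(model, class, condition)
  if (p$w2 > 0) {
    comp <- stats::runif(n) < p$w2
    ifelse(comp, stats::rnorm(n, p$mean2, p$sd2), stats::rnorm(n, p$mean1, p$sd1))
  } else {
    stats::rnorm(n, p$mean1, p$sd1)
  }
}

#' Mixture CDF of log10 fluorescence for a class
#' @param q Quantiles (log10 fluorescence).
#' @inheritParams rgfp
#' @return P(log10 GFP <= q).
#' @export
pgfp <- function(q, model, class, condition) {
  p <- gfp_params(model, class, condition)
  out <- p$w1 * stats::pnorm(q, p$mean1, p$sd1)
  if (p$w2 > 0) out <- out + p$w2 * stats::pnorm(q, p$mean2, p$sd2)
  out
}

#' Draw control-strain fluorescence samples
#'
#' Three control strains are run alongside every sort: the untransformed
#' reporter-negative control, the uninduced reporter strain (basal
#' control), and the induced reporter strain (induced control).
#'
#' @param model A `gfp_model`.
#' @param n Cells per control.
#' @param seed Optional RNG seed.
#' @return List with numeric vectors `neg`, `basal`, `induced`.
#' @export
simulate_controls <- function(model, n = 10000L, seed = NULL) {
  with_seed(seed, {
    lapply(model$controls, function(ct) stats::rnorm(n, ct[["mean"]], ct[["sd"]]))
  })
}

#' Derive sorting gates from control samples
#'
#' Mirrors gating against control strains on the sorter: the negative
#' gates end below the basal control peak, the elevated-basal gate starts
#' above it, and the hyper-induced gate starts above the induced control
#' peak. Percentiles of the control samples set the cut points.
#'
#' @param controls List with `neg`, `basal`, `induced` log10-GFP samples.
#' @param lower_pct,upper_pct Percentiles of a control distribution used
#'   as gate boundaries (defaults 0.01 and 0.99).
#' @return A `gate_set` data.frame with columns `name`, `condition`,
#'   `lower`, `upper`.
#' @export
derive_gates <- function(controls, lower_pct = 0.01, upper_pct = 0.99) {
  stopifnot(all(c("neg", "basal", "induced") %in% names(controls)),
            all(lengths(controls[c("neg", "basal", "induced")]) > 0),
            lower_pct < upper_pct)
  q <- function(x, p) as.numeric(stats::quantile(x, p, names = FALSE))
  basal_lo <- q(controls$basal, lower_pct)
  basal_hi <- q(controls$basal, upper_pct)
  ind_lo <- q(controls$induced, lower_pct)
  ind_hi <- q(controls$induced, upper_pct)
  neg_hi <- q(controls$neg, upper_pct)
  if (!(neg_hi < basal_lo && basal_hi < ind_lo)) {
    stop("configuration error: control distributions overlap at the ",
         "requested percentiles; gates would invert")
  }
  gates <- data.frame(
    name = pool_names(),
    condition = c("uninduced", "uninduced", "induced", "induced", "induced"),
    lower = c(-Inf, basal_hi, -Inf, basal_lo, ind_hi),
    upper = c(basal_lo, Inf, basal_lo, basal_hi, Inf),
    stringsAsFactors = FALSE)
  stopifnot(all(gates$lower < gates$upper))
  class(gates) <- c("gate_set", "data.frame")
  gates
}

#' Define a mutant pool
#'
#' @param gene Gene names (must be a subset of the catalog used downstream).
#' @param class Phenotype class per mutant (see [phenotype_classes()]).
#' @param abundance Positive relative frequencies (normalized to sum 1;
#'   default uniform).
#' @param fitness Per-generation multiplicative growth factor (default 1).
#' @return A `mutant_pool` data.frame.
#' @export
mutant_pool <- function(gene, class = "WT", abundance = NULL, fitness = NULL) {
  n <- length(gene)
  class <- rep_len(class, n)
  if (anyDuplicated(gene)) stop("duplicate genes in pool")
  if (!all(class %in% phenotype_classes())) {
    stop("unknown class(es): ",
         paste(setdiff(unique(class), phenotype_classes()), collapse = ", "))
  }
  abundance <- abundance %||% rep(1 / n, n)
  fitness <- fitness %||% rep(1, n)
  stopifnot(length(abundance) == n, length(fitness) == n,
            all(abundance > 0), all(fitness > 0))
  structure(data.frame(gene = gene, class = class,
                       abundance = abundance / sum(abundance),
                       fitness = fitness, stringsAsFactors = FALSE),
            class = c("mutant_pool", "data.frame"))
}

#' Simulate per-cell fluorescence of a mutant pool
#'
#' Cells are assigned to mutants multinomially in pool abundance and each
#' cell draws a log10-GFP value from its mutant's class/condition model.
#'
#' @param pool A [mutant_pool()].
#' @param model A `gfp_model`.
#' @param condition `"uninduced"` or `"induced"`.
#' @param n_cells Number of cells.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `gene`, `class`, `gfp`.
#' @export
simulate_population <- function(pool, model, condition, n_cells, seed = NULL) {
  stopifnot(n_cells >= 0)
  with_seed(seed, {
    if (n_cells == 0L) {
      return(data.frame(gene = character(0), class = character(0),
                        gfp = numeric(0), stringsAsFactors = FALSE))
    }
    idx <- sample.int(nrow(pool), n_cells, replace = TRUE, prob = pool$abundance)
    gfp <- numeric(n_cells)
    for (cl in unique(pool$class)) {
      sel <- pool$class[idx] == cl
      gfp[sel] <- rgfp(sum(sel), model, cl, condition)
    }
    data.frame(gene = pool$gene[idx], class = pool$class[idx], gfp = gfp,
               stringsAsFactors = FALSE)
  })
}

#' Sort cells through a gate
#'
#' @param cells data.frame from [simulate_population()].
#' @param gate One row of a `gate_set` (or a list with `lower`, `upper`).
#' @return The cells with `lower <= gfp < upper`, order preserved.
#' @export
apply_gate <- function(cells, gate) {
  cells[gate$lower <= cells$gfp & cells$gfp < gate$upper, , drop = FALSE]
}

#' Regrow a sorted pool
#'
#' Expected composition is multiplied by `fitness^generations`,
#' renormalized, and resampled multinomially at the same total cell
#' count, so that neutral pools (all fitness 1) experience only
#' multinomial drift.
#'
#' @param counts Named integer vector of cells per mutant.
#' @param fitness Named (or recycled) per-mutant fitness factors.
#' @param generations Number of regrowth generations.
#' @param seed Optional RNG seed.
#' @return Named integer vector, same names, same total.
#' @export
regrow <- function(counts, fitness = 1, generations = 5L, seed = NULL) {
  stopifnot(all(counts >= 0), generations >= 0)
  total <- sum(counts)
  if (total == 0L) return(counts[0])
  fitness <- rep_len(fitness, length(counts))
  with_seed(seed, {
    w <- counts * fitness^generations
    out <- as.integer(stats::rmultinom(1, total, w / sum(w)))
    names(out) <- names(counts)
    out
  })
}

#' Screen simulation configuration
#'
#' @param seed Master RNG seed; every stage derives its own child seed.
#' @param n_cells_sorted Cells collected into each sorted pool (a sorter
#'   runs until each gate has collected its target cell count).
#' @param n_cells_analyzed Cells run through the sorter per condition per
#'   replicate; `NULL` (default) means `10 * n_cells_sorted`, reflecting
#'   that a genome-scale sort analyzes an order of magnitude more cells
#'   than any one gate collects (about 1e3 cells per strain per condition
#'   at default sizes, the scale of a ~1e7-cell sort of a genome-wide
#'   library).
#' @param regrowth_generations Generations of post-sort growth.
#' @param pcr_noise_sd Log-scale SD of the per-gene PCR efficiency factor.
#' @param per_base_error_rate Per-base substitution probability in reads.
#' @param reads_per_sample Reads generated per sample per tag.
#' @param replicates Biological replicates per pool.
#' @param read_length Read length in nt (50-cycle single-end default).
#' @param sorting_impurity Fraction of each sorted pool drawn from the
#'   ungated parent population (sorting is never perfectly pure).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cells_sorted = 100000L,
                       n_cells_analyzed = NULL,
                       regrowth_generations = 5L, pcr_noise_sd = 0.2,
                       per_base_error_rate = 0.001, reads_per_sample = 100000L,
                       replicates = 3L, read_length = 50L,
                       sorting_impurity = 0.02) {
  stopifnot(per_base_error_rate >= 0, per_base_error_rate <= 1,
            sorting_impurity >= 0, sorting_impurity <= 1,
            n_cells_sorted >= 0, reads_per_sample >= 0, replicates >= 1)
  n_cells_analyzed <- as.integer(n_cells_analyzed %||% (10L * n_cells_sorted))
  stopifnot(n_cells_analyzed >= 0)
  structure(list(seed = as.integer(seed),
                 n_cells_sorted = as.integer(n_cells_sorted),
                 n_cells_analyzed = n_cells_analyzed,
                 regrowth_generations = as.integer(regrowth_generations),
                 pcr_noise_sd = pcr_noise_sd,
                 per_base_error_rate = per_base_error_rate,
                 reads_per_sample = as.integer(reads_per_sample),
                 replicates = as.integer(replicates),
                 read_length = as.integer(read_length),
                 sorting_impurity = sorting_impurity),
            class = "sim_config")
}

#' Generate well-separated multiplex tags
#'
#' Greedy rejection sampling of fixed-length tags with a minimum pairwise
#' Hamming distance, deterministic under a seed.
#'
#' @param n Number of tags.
#' @param length Tag length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed RNG seed.
#' @return Character vector of tags.
#' @export
make_multiplex_tags <- function(n, length = 6L, min_dist = 4L, seed = 1L) {
  with_seed(seed, {
    tags <- character(0)
    tries <- 0L
    while (length(tags) < n) {
      cand <- random_dna(1L, length)
      if (!length(tags) || all(hamming_matrix(cand, tags) >= min_dist)) {
        tags <- c(tags, cand)
      }
      tries <- tries + 1L
      if (tries > 100000L) stop("cannot place ", n, " tags at min_dist ", min_dist)
    }
    tags
  })
}

#' PCR-amplify and sequence a pool composition
#'
#' Per-gene read shares are the composition shares distorted by a
#' per-gene log-normal PCR efficiency factor; each read is laid out as
#' multiplex tag + upstream primer + barcode + downstream primer,
#' truncated or padded (with `A`) to the configured read length, and each
#' base is substituted independently at the configured error rate.
#' Qualities are fabricated constant-high.
#'
#' @param composition Named integer vector of per-gene cell counts.
#' @param catalog A `barcode_catalog`; every composition gene must be present.
#' @param multiplex_tag Tag prefixed to every read.
#' @param tag `"up"` or `"dn"` barcode to sequence.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (defaults to `config$seed`).
#' @param id_prefix Read id prefix.
#' @return List: `reads` ([fastq_records()]), `gene_counts` (named integer
#'   vector of reads drawn per gene, the simulator's internal assignment).
#' @export
amplify_and_sequence <- function(composition, catalog, multiplex_tag,
                                 tag = c("up", "dn"), config = sim_config(),
                                 seed = NULL, id_prefix = "read") {
  tag <- match.arg(tag)
  col <- paste0(tag, "tag")
  missing_genes <- setdiff(names(composition), catalog$entries$gene)
  if (length(missing_genes)) {
    stop("gene(s) absent from catalog: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  composition <- composition[composition > 0]
  n_reads <- config$reads_per_sample
  empty <- fastq_records(character(0), character(0), character(0))
  if (n_reads == 0L || length(composition) == 0L) {
    return(list(reads = empty,
                gene_counts = stats::setNames(integer(length(composition)),
                                              names(composition))))
  }
  barcodes <- catalog$entries[[col]][match(names(composition),
                                           catalog$entries$gene)]
  if (anyNA(barcodes)) {
    stop("gene(s) missing ", col, ": ",
         paste(names(composition)[is.na(barcodes)], collapse = ", "))
  }
  with_seed(seed %||% config$seed, {
    eff <- stats::rlnorm(length(composition), 0, config$pcr_noise_sd)
    share <- composition * eff
    gene_counts <- as.integer(stats::rmultinom(1, n_reads, share / sum(share)))
    names(gene_counts) <- names(composition)
    layout <- catalog$layout
    templates <- paste0(multiplex_tag, layout$upstream_primer, barcodes,
                        layout$downstream_primer)
    templates <- vapply(templates, function(s) {
      if (nchar(s) >= config$read_length) substr(s, 1L, config$read_length)
      else paste0(s, strrep("A", config$read_length - nchar(s)))
    }, character(1), USE.NAMES = FALSE)
    reads <- rep(templates, gene_counts)
    len <- config$read_length
    if (config$per_base_error_rate > 0 && length(reads)) {
      n_bases <- length(reads) * len
      hit <- which(stats::runif(n_bases) < config$per_base_error_rate)
      if (length(hit)) {
        row <- ((hit - 1L) %/% len) + 1L
        pos <- ((hit - 1L) %% len) + 1L
        aff <- unique(row)
        m <- seq_matrix(reads[aff], len)
        rr <- match(row, aff)
        bases <- c("A", "C", "G", "T")
        cur <- m[cbind(rr, pos)]
        shift <- sample.int(3L, length(hit), replace = TRUE)
        m[cbind(rr, pos)] <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
        reads[aff] <- do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
      }
    }
    ids <- sprintf("%s_%06d", id_prefix, seq_along(reads))
    qual <- strrep("I", len)
    list(reads = fastq_records(ids, reads, rep(qual, length(reads))),
         gene_counts = gene_counts)
  })
}

#' Analytic ground truth for a simulated screen
#'
#' For every mutant: its class, the analytic probability that one of its
#' cells falls inside each gate (from the log-normal mixture CDF), and
#' the expected enrichment sign per pool relative to wild type (+1 if its
#' capture probability exceeds twice the wild-type probability, -1 if
#' below half, 0 otherwise).
#'
#' @param pool A [mutant_pool()].
#' @param model A `gfp_model`.
#' @param gates A `gate_set`.
#' @return data.frame of class `truth_table`.
#' @export
truth_table <- function(pool, model, gates) {
  capture <- function(class, gate) {
    pgfp(gate$upper, model, class, gate$condition) -
      pgfp(gate$lower, model, class, gate$condition)
  }
  out <- data.frame(gene = pool$gene, class = pool$class,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gates))) {
    g <- gates[i, ]
    p_class <- vapply(pool$class, capture, numeric(1), gate = g)
    p_wt <- capture("WT", g)
    out[[paste0("p_", g$name)]] <- unname(p_class)
    ratio <- p_class / p_wt
    out[[paste0("sign_", g$name)]] <-
      unname(ifelse(ratio > 2, 1L, ifelse(ratio < 0.5, -1L, 0L)))
  }
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Simulate a full sorted-pool screen to FASTQ
#'
#' Per replicate: the pool is grown uninduced and induced, sorted through
#' the five gates, each sorted pool is contaminated with a small fraction
#' of ungated cells and regrown, and each pool plus the presorted library
#' is sequenced as UPTAG and DNTAG samples carrying distinct multiplex
#' tags (rotated across replicates). Everything is deterministic under
#' `config$seed`.
#'
#' @param pool A [mutant_pool()].
#' @param model A `gfp_model`.
#' @param gates A `gate_set` from [derive_gates()].
#' @param catalog A `barcode_catalog`.
#' @param config A [sim_config()].
#' @param outdir Output directory for FASTQ files and tables (created).
#' @param write_files Write FASTQ/TSV to `outdir`? If `FALSE`, reads are
#'   only returned in memory.
#' @return List: `sample_sheet` (file, sample, pool, replicate, tag,
#'   multiplex_tag), `truth` ([truth_table()]), `read_counts` (per sample
#'   the simulator's internal per-gene read draw), `reads` (per sample
#'   `fastq_records` when `write_files = FALSE`), `dir`.
#' @export
simulate_screen <- function(pool, model, gates, catalog, config = sim_config(),
                            outdir = NULL, write_files = !is.null(outdir)) {
  if (write_files) {
    if (is.null(outdir)) stop("outdir required when write_files = TRUE")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }
  tags12 <- make_multiplex_tags(12L, length = catalog$layout$multiplex_tag_length,
                                min_dist = 4L, seed = child_seed(config$seed, 7L))
  samples <- c("presorted", gates$name)
  sheet <- list(); read_counts <- list(); reads_mem <- list()
  for (r in seq_len(config$replicates)) {
    un <- simulate_population(pool, model, "uninduced", config$n_cells_analyzed,
                              seed = child_seed(config$seed, 100L * r + 1L))
    ind <- simulate_population(pool, model, "induced", config$n_cells_analyzed,
                               seed = child_seed(config$seed, 100L * r + 2L))
    compositions <- list()
    with_seed(child_seed(config$seed, 100L * r + 3L), {
      compositions$presorted <- as.integer(
        stats::rmultinom(1, config$n_cells_analyzed, pool$abundance))
      names(compositions$presorted) <- pool$gene
      for (i in seq_len(nrow(gates))) {
        g <- gates[i, ]
        pop <- if (g$condition == "uninduced") un else ind
        gated <- apply_gate(pop, g)
        n_gated <- nrow(gated)
        p_gated <- if (n_gated > 0L) {
          as.numeric(table(factor(gated$gene, levels = pool$gene))) / n_gated
        } else {
          rep(0, nrow(pool))
        }
        # collected pool = gated composition contaminated with a small
        # fraction of ungated parent cells; fixed collection size
        p_pool <- (1 - config$sorting_impurity) * p_gated +
          config$sorting_impurity * pool$abundance
        if (sum(p_pool) == 0) {
          compositions[[g$name]] <- stats::setNames(integer(nrow(pool)), pool$gene)
          next
        }
        comp <- as.integer(stats::rmultinom(1, config$n_cells_sorted,
                                            p_pool / sum(p_pool)))
        names(comp) <- pool$gene
        compositions[[g$name]] <- regrow(comp, pool$fitness,
                                         config$regrowth_generations)
      }
    })
    for (si in seq_along(samples)) {
      s <- samples[si]
      sample_id <- sprintf("%s_rep%d", s, r)
      for (ti in 1:2) {
        tagname <- c("up", "dn")[ti]
        slot <- (si - 1L) * 2L + ti               # 1..12 within the lane
        mt <- tags12[((slot + r - 2L) %% 12L) + 1L]  # rotate tags by replicate
        res <- amplify_and_sequence(
          compositions[[s]], catalog, mt, tagname, config,
          seed = child_seed(config$seed, 1000L * r + 10L * si + ti),
          id_prefix = paste0(sample_id, "_", tagname))
        fname <- sprintf("%s_%s.fastq", sample_id, tagname)
        if (write_files) {
          write_fastq(res$reads, file.path(outdir, fname))
        } else {
          reads_mem[[paste0(sample_id, ".", tagname)]] <- res$reads
        }
        rc <- stats::setNames(integer(nrow(pool)), pool$gene)
        rc[names(res$gene_counts)] <- res$gene_counts
        read_counts[[paste0(sample_id, ".", tagname)]] <- rc
        sheet[[length(sheet) + 1L]] <- data.frame(
          file = fname, sample = sample_id, pool = s, replicate = r,
          tag = tagname, multiplex_tag = mt, stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, sheet)
  truth <- truth_table(pool, model, gates)
  if (write_files) {
    write_tsv_meta(sheet, file.path(outdir, "sample_sheet.tsv"),
                   meta = list(seed = config$seed))
    write_tsv_meta(truth, file.path(outdir, "truth_table.tsv"),
                   meta = list(seed = config$seed))
  }
  list(sample_sheet = sheet, truth = truth, read_counts = read_counts,
       reads = if (write_files) NULL else reads_mem, dir = outdir)
}
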