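# Demultiplexing and barcode counting: the direct, dependency-free
# replacement for aligning reads against the concatenated N-spacer
# reference with an external aligner. Extraction is anchored on the
# universal priming site; matching is Hamming-distance matching against
# the catalog. For substitution-type sequencing errors this is exactly
# equivalent to the aligner route and testable against a brute-force
# oracle.

#' Construct a count table
#'
#' @param counts Integer matrix, genes x samples.
#' @param ledger Integer matrix with rows `assigned`, `ambiguous`,
#'   `unmatched`, `no_tag`; one column per sample.
#' @param tag `"up"` or `"dn"`.
#' @return Object of class `count_table`.
#' @export
count_table <- function(counts, ledger, tag) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            identical(rownames(ledger),
                      c("assigned", "ambiguous", "unmatched", "no_tag")),
            identical(colnames(counts), colnames(ledger)))
  if (!all(colSums(counts) == ledger["assigned", ])) {
    stop("ledger inconsistency: assigned != column sums")
  }
  structure(list(counts = counts, ledger = ledger, tag = tag),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table (", x$tag, "): ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples; ", sum(x$ledger["assigned", ]),
      " assigned / ", sum(x$ledger), " reads\n", sep = "")
  invisible(x)
}

#' Demultiplex reads by leading multiplex tag
#'
#' Each read is assigned to the sample whose multiplex tag is nearest in
#' Hamming distance over the leading `tag_length` bases, accepted iff
#' that distance is at most `max_tag_mismatch`. Sheet tags must be
#' pairwise separated by more than `2 * max_tag_mismatch` so the nearest
#' acceptable tag is always unique.
#'
#' @param reads A [fastq_records()] data.frame.
#' @param sample_sheet data.frame with columns `multiplex_tag`, `sample`.
#' @param tag_length Tag length in nt.
#' @param max_tag_mismatch Maximum accepted tag Hamming distance.
#' @return List: `samples` (named list of `fastq_records`), `no_tag`
#'   (number of unassignable reads).
#' @export
demultiplex <- function(reads, sample_sheet, tag_length,
                        max_tag_mismatch = 1L) {
  tags <- sample_sheet$multiplex_tag
  stopifnot(all(nchar(tags) == tag_length), !anyDuplicated(sample_sheet$sample))
  if (length(tags) > 1L) {
    d <- hamming_matrix(tags, tags)
    if (min(d[upper.tri(d)]) <= 2L * max_tag_mismatch) {
      stop("configuration error: sample-sheet tags are separated by <= 2 * ",
           "max_tag_mismatch; demultiplexing would be ambiguous")
    }
  }
  lead <- substr(reads$sequence, 1L, tag_length)
  assign <- match(lead, tags)                       # exact matches first
  todo <- which(is.na(assign) & nchar(lead) == tag_length)
  if (length(todo)) {
    d <- hamming_matrix(lead[todo], tags)
    best <- max.col(-d, ties.method = "first")
    ok <- d[cbind(seq_along(todo), best)] <= max_tag_mismatch
    assign[todo[ok]] <- best[ok]
  }
  samples <- lapply(seq_along(tags), function(i) {
    sel <- which(assign == i)
    fastq_records(reads$id[sel], reads$sequence[sel], reads$quality[sel])
  })
  names(samples) <- sample_sheet$sample
  list(samples = samples, no_tag = sum(is.na(assign)))
}

#' Extract the barcode region from reads
#'
#' Locates the upstream universal priming site within a small window
#' around its expected offset (after the multiplex tag), allowing up to
#' `primer_max_mismatch` substitutions, and returns the following
#' `barcode_length` bases. `NA` where the primer is not found or the read
#' is too short.
#'
#' @param sequences Character vector of read sequences.
#' @param layout An [amplicon_layout()].
#' @param primer_max_mismatch Maximum substitutions in the priming site.
#' @param window Offsets around the expected primer start to search.
#' @return Character vector of barcodes (`NA` on failure).
#' @export
extract_barcode <- function(sequences, layout, primer_max_mismatch = 2L,
                            window = 2L) {
  primer <- layout$upstream_primer
  plen <- nchar(primer)
  blen <- layout$barcode_length
  expected <- layout$multiplex_tag_length + 1L
  out <- rep(NA_character_, length(sequences))
  if (!length(sequences)) return(out)
  need <- expected + plen + blen - 1L
  long_enough <- nchar(sequences) >= need
  # exact primer at the expected offset covers the vast majority of reads
  at_expected <- substr(sequences, expected, expected + plen - 1L) == primer
  hit <- long_enough & at_expected
  out[hit] <- substr(sequences[hit], expected + plen,
                     expected + plen + blen - 1L)
  todo <- which(long_enough & !hit)
  if (length(todo)) {
    offsets <- expected + seq(-window, window)
    offsets <- offsets[offsets >= 1L]
    offsets <- offsets[order(abs(offsets - expected))]  # closest offset wins ties
    bestd <- rep(Inf, length(todo))
    bestoff <- rep(NA_integer_, length(todo))
    for (off in offsets) {
      ok <- which(nchar(sequences[todo]) >= off + plen + blen - 1L)
      if (!length(ok)) next
      cand <- substr(sequences[todo[ok]], off, off + plen - 1L)
      d <- as.vector(hamming_matrix(cand, primer))
      upd <- ok[d < bestd[ok]]
      bestd[upd] <- d[d < bestd[ok]]
      bestoff[upd] <- off
    }
    found <- which(bestd <= primer_max_mismatch)
    idx <- todo[found]
    if (length(idx)) {
      out[idx] <- substr(sequences[idx], bestoff[found] + plen,
                         bestoff[found] + plen + blen - 1L)
    }
  }
  out
}

#' Match barcode sequences against a catalog
#'
#' Outcome per query: `unique` iff exactly one catalog gene attains the
#' minimal Hamming distance and that distance is at most `max_mismatch`;
#' `ambiguous` iff two or more genes tie at the minimal acceptable
#' distance (including verbatim barcode collisions between genes);
#' `none` otherwise. Alias barcodes from [merge_catalogs()] count as
#' match candidates for their gene; two candidate sequences of the same
#' gene never make a match ambiguous.
#'
#' @param seqs Character vector of barcode-length sequences.
#' @param catalog A `barcode_catalog`.
#' @param tag `"up"` or `"dn"`.
#' @param max_mismatch Maximum accepted Hamming distance (default 2).
#' @return data.frame with columns `outcome`, `gene` (`NA` unless unique),
#'   `distance` (`NA` unless unique).
#' @export
match_barcode <- function(seqs, catalog, tag = c("up", "dn"), max_mismatch = 2L) {
  tag <- match.arg(tag)
  col <- paste0(tag, "tag")
  blen <- catalog$layout$barcode_length
  if (length(seqs) && any(nchar(seqs) != blen, na.rm = TRUE)) {
    stop("barcode length mismatch: expected ", blen, " nt")
  }
  e <- catalog$entries[!is.na(catalog$entries[[col]]), ]
  ref <- e[[col]]
  ref_gene <- e$gene
  ali <- catalog$aliases[catalog$aliases$tag == tag, , drop = FALSE]
  if (nrow(ali)) {
    ref <- c(ref, ali$sequence)
    ref_gene <- c(ref_gene, ali$gene)
  }
  out <- data.frame(outcome = rep("none", length(seqs)),
                    gene = NA_character_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!length(seqs) || !length(ref)) return(out)
  uq <- unique(seqs[!is.na(seqs)])
  if (!length(uq)) return(out)
  d <- hamming_matrix(uq, ref)
  res_outcome <- character(length(uq))
  res_gene <- rep(NA_character_, length(uq))
  res_dist <- rep(NA_integer_, length(uq))
  mind <- apply(d, 1L, min)
  for (i in seq_along(uq)) {
    if (mind[i] > max_mismatch) {
      res_outcome[i] <- "none"
      next
    }
    genes <- unique(ref_gene[d[i, ] == mind[i]])
    if (length(genes) == 1L) {
      res_outcome[i] <- "unique"
      res_gene[i] <- genes
      res_dist[i] <- mind[i]
    } else {
      res_outcome[i] <- "ambiguous"
    }
  }
  j <- match(seqs, uq)
  filled <- !is.na(j)
  out$outcome[filled] <- res_outcome[j[filled]]
  out$gene[filled] <- res_gene[j[filled]]
  out$distance[filled] <- res_dist[j[filled]]
  out
}

#' Count barcode reads per gene per sample
#'
#' Per sample: reads whose leading multiplex tag does not match the
#' sample's expected tag (when `sample_tags` is supplied) go to the
#' `no_tag` ledger; reads without a locatable priming site or without an
#' acceptable barcode match go to `unmatched`; reads matching two or more
#' genes equally well go to `ambiguous` (never fractionally assigned);
#' the rest are `assigned`. The ledger partitions every read.
#'
#' @param samples Named list of [fastq_records()] (one element per sample).
#' @param catalog A `barcode_catalog`.
#' @param tag `"up"` or `"dn"`.
#' @param sample_tags Optional named character vector: expected multiplex
#'   tag per sample.
#' @param max_mismatch Barcode Hamming radius (default 2).
#' @param primer_max_mismatch Priming-site mismatch allowance (default 2).
#' @param max_tag_mismatch Multiplex-tag mismatch allowance (default 1).
#' @return A [count_table()] over all catalog genes.
#' @export
count_barcodes <- function(samples, catalog, tag = c("up", "dn"),
                           sample_tags = NULL, max_mismatch = 2L,
                           primer_max_mismatch = 2L, max_tag_mismatch = 1L) {
  tag <- match.arg(tag)
  genes <- catalog$entries$gene
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, names(samples)))
  ledger <- matrix(0L, nrow = 4L, ncol = length(samples),
                   dimnames = list(c("assigned", "ambiguous", "unmatched",
                                     "no_tag"), names(samples)))
  for (s in names(samples)) {
    reads <- samples[[s]]
    n <- nrow(reads)
    if (n == 0L) next
    keep <- rep(TRUE, n)
    if (!is.null(sample_tags)) {
      expected <- sample_tags[[s]]
      lead <- substr(reads$sequence, 1L, nchar(expected))
      tag_ok <- lead == expected
      off <- which(!tag_ok)
      if (length(off)) {
        dd <- hamming_matrix(lead[off], expected)
        tag_ok[off] <- dd[, 1L] <= max_tag_mismatch
      }
      keep <- tag_ok
      ledger["no_tag", s] <- sum(!keep)
    }
    bc <- extract_barcode(reads$sequence[keep], catalog$layout,
                          primer_max_mismatch = primer_max_mismatch)
    found <- !is.na(bc)
    m <- match_barcode(bc[found], catalog, tag, max_mismatch = max_mismatch)
    tb <- table(factor(m$gene[m$outcome == "unique"], levels = genes))
    counts[, s] <- as.integer(tb)
    ledger["assigned", s] <- sum(m$outcome == "unique")
    ledger["ambiguous", s] <- sum(m$outcome == "ambiguous")
    ledger["unmatched", s] <- sum(!found) + sum(m$outcome == "none")
  }
  count_table(counts, ledger, tag)
}

#' Minimum-read inclusion filter
#'
#' A mutant enters the analysis iff its UPTAG or its DNTAG count in the
#' presorted control library reaches the threshold (the "and/or" rule,
#' read disjunctively: many knockout strains have one failed tag).
#'
#' @param up,dn `count_table` objects for the two tags.
#' @param control_sample Sample id of the presorted control library.
#' @param threshold Minimum read count (default 50).
#' @return Character vector of included genes.
#' @export
apply_min_read_filter <- function(up, dn, control_sample, threshold = 50L) {
  for (ct in list(up, dn)) {
    if (!control_sample %in% colnames(ct$counts)) {
      stop("control sample not in count table: ", control_sample)
    }
  }
  stopifnot(identical(rownames(up$counts), rownames(dn$counts)))
  ok <- up$counts[, control_sample] >= threshold |
    dn$counts[, control_sample] >= threshold
  rownames(up$counts)[ok]
}

#' Combine UPTAG and DNTAG tables as paired technical measurements
#'
#' The two tags of one biological sample are kept as separate labeled
#' columns (suffixes `.up` / `.dn`) rather than summed: summing would
#' hide tag-specific PCR failure, and the tags are sequenced as separate
#' samples.
#'
#' @param up,dn `count_table` objects over the same gene universe with
#'   identical sample names.
#' @return A `count_table` with `2 *` the columns and `tag = "both"`;
#'   attribute `"col_data"` maps columns to (sample, tag).
#' @export
merge_tags <- function(up, dn) {
  if (!identical(rownames(up$counts), rownames(dn$counts))) {
    stop("gene universe mismatch between up and dn tables")
  }
  stopifnot(identical(colnames(up$counts), colnames(dn$counts)))
  sam <- colnames(up$counts)
  counts <- cbind(up$counts, dn$counts)
  colnames(counts) <- c(paste0(sam, ".up"), paste0(sam, ".dn"))
  ledger <- cbind(up$ledger, dn$ledger)
  colnames(ledger) <- colnames(counts)
  out <- count_table(counts, ledger, "both")
  attr(out, "col_data") <- data.frame(
    column = colnames(counts), sample = rep(sam, 2L),
    tag = rep(c("up", "dn"), each = length(sam)), stringsAsFactors = FALSE)
  out
}

#' Write a count table (and its ledger) to TSV
#' @param ct A `count_table`.
#' @param path Output TSV for counts; ledger goes to `<path>.ledger.tsv`.
#' @param meta Named list of provenance metadata written as `#` headers.
#' @export
write_count_table <- function(ct, path, meta = list()) {
  df <- data.frame(gene = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_meta(df, path, meta = c(list(tag = ct$tag), meta))
  lf <- data.frame(category = rownames(ct$ledger), ct$ledger,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_meta(lf, paste0(path, ".ledger.tsv"), meta = meta)
  invisible(path)
}
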