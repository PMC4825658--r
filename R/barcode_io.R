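#' Amplicon layout of a Bar-Seq read
#'
#' Describes how a sequencing read of a barcode amplicon is laid out:
#' a sample-identifying multiplex tag, the universal upstream priming
#' site, the strain barcode itself, and the downstream priming site.
#' The exact primer and tag sequences differ between amplification
#' designs, so all fields are configurable; the defaults are the common
#' universal priming sites used with the yeast knockout collection and
#' an 18-plex tagging scheme (up to nine UPTAG plus nine DNTAG samples
#' per lane).
#'
#' @param multiplex_tag_length Length in nt of the leading multiplex tag.
#' @param upstream_primer Universal priming site immediately preceding
#'   the barcode.
#' @param barcode_length Barcode length in nt (uniform per catalog).
#' @param downstream_primer Universal priming site following the barcode.
#' @return An object of class `amplicon_layout`.
#' @export
amplicon_layout <- function(multiplex_tag_length = 6L,
                            upstream_primer = "GATGTCCACGAGGTCTCT",
                            barcode_length = 20L,
                            downstream_primer = "CGTACGCTGCAGGTCGAC") {
  stopifnot(multiplex_tag_length > 0L, barcode_length > 0L,
            nzchar(upstream_primer), nzchar(downstream_primer),
            is_dna(upstream_primer), is_dna(downstream_primer))
  structure(list(multiplex_tag_length = as.integer(multiplex_tag_length),
                 upstream_primer = upstream_primer,
                 barcode_length = as.integer(barcode_length),
                 downstream_primer = downstream_primer),
            class = "amplicon_layout")
}

#' Construct a barcode catalog
#'
#' A barcode catalog maps each gene (systematic name) to its UPTAG and/or
#' DNTAG barcode. Catalogs are the reference universe against which
#' sequenced barcodes are matched. Barcodes shared verbatim by two or
#' more genes are flagged ambiguous: reads matching them are ledgered,
#' never assigned.
#'
#' @param entries data.frame with columns `gene`, `uptag`, `dntag`,
#'   `source`; `uptag`/`dntag` may be `NA` (at least one present per row).
#' @param layout An [amplicon_layout()].
#' @return Object of class `barcode_catalog` with elements `entries`,
#'   `layout`, and `aliases` (superseded barcodes still accepted as match
#'   candidates for their gene, see [merge_catalogs()]).
#' @export
barcode_catalog <- function(entries, layout = amplicon_layout()) {
  stopifnot(is.data.frame(entries),
            all(c("gene", "uptag", "dntag", "source") %in% names(entries)))
  entries <- entries[, c("gene", "uptag", "dntag", "source")]
  if (anyDuplicated(entries$gene)) {
    stop("duplicated gene names in catalog: ",
         paste(unique(entries$gene[duplicated(entries$gene)]), collapse = ", "))
  }
  for (tag in c("uptag", "dntag")) {
    bad <- which(!is.na(entries[[tag]]) & !is_dna(entries[[tag]]))
    if (length(bad)) {
      stop("non-DNA ", tag, " at row(s) ", paste(bad, collapse = ", "),
           " (gene ", paste(entries$gene[bad], collapse = ", "), ")")
    }
    lens <- nchar(entries[[tag]][!is.na(entries[[tag]])])
    if (length(lens) && any(lens != layout$barcode_length)) {
      stop(tag, " lengths differ from layout barcode_length (",
           layout$barcode_length, ")")
    }
  }
  if (any(is.na(entries$uptag) & is.na(entries$dntag))) {
    stop("every entry needs at least one of uptag/dntag")
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, layout = layout,
                 aliases = data.frame(gene = character(0), tag = character(0),
                                      sequence = character(0),
                                      stringsAsFactors = FALSE)),
            class = "barcode_catalog")
}

#' @export
print.barcode_catalog <- function(x, ...) {
  cat("barcode_catalog:", nrow(x$entries), "genes;",
      sum(!is.na(x$entries$uptag)), "uptags,",
      sum(!is.na(x$entries$dntag)), "dntags;",
      nrow(x$aliases), "alias barcodes\n")
  invisible(x)
}

#' Look up a catalog entry by gene
#' @param catalog A `barcode_catalog`.
#' @param gene Systematic gene name.
#' @return One-row data.frame.
#' @export
catalog_lookup <- function(catalog, gene) {
  i <- match(gene, catalog$entries$gene)
  if (is.na(i)) stop("gene not in catalog: ", gene)
  catalog$entries[i, ]
}

#' Read a barcode catalog from TSV
#'
#' The catalog dialect is tab-separated with a header line naming columns
#' `gene`, `uptag`, `dntag`; `#` comment lines are allowed; empty fields
#' mean the tag is absent. Public deletion-collection barcode lists in
#' other dialects should be converted to this layout first.
#'
#' @param path TSV file path.
#' @param source_tag `"primary_list"` or `"resequenced"`.
#' @param layout An [amplicon_layout()].
#' @return A [barcode_catalog()].
#' @export
read_catalog <- function(path, source_tag = c("primary_list", "resequenced"),
                         layout = amplicon_layout()) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("catalog file has no header: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene", "uptag", "dntag")
  if (!all(need %in% header)) {
    stop("catalog format error: missing column(s) ",
         paste(setdiff(need, header), collapse = ", "), " in ", path)
  }
  if (length(lines) == 1L) {
    return(barcode_catalog(data.frame(gene = character(0), uptag = character(0),
                                      dntag = character(0), source = character(0),
                                      stringsAsFactors = FALSE), layout))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  get <- function(col) {
    j <- match(col, header)
    v <- vapply(fields, function(f) if (length(f) >= j) f[[j]] else "", character(1))
    v <- trimws(v)
    v[!nzchar(v) | v == "NA"] <- NA_character_
    v
  }
  df <- data.frame(gene = get("gene"), uptag = get("uptag"),
                   dntag = get("dntag"), source = source_tag,
                   stringsAsFactors = FALSE)
  for (tag in c("uptag", "dntag")) {
    bad <- which(!is.na(df[[tag]]) & !is_dna(df[[tag]]))
    if (length(bad)) {
      stop("validation error: non-DNA ", tag, " at line(s) ",
           paste(lineno[-1][bad], collapse = ", "), " of ", path)
    }
  }
  barcode_catalog(df, layout)
}

#' Write a barcode catalog to TSV
#' @param catalog A `barcode_catalog`.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  df <- catalog$entries[, c("gene", "uptag", "dntag")]
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge a primary and a resequenced barcode catalog
#'
#' Where both catalogs carry the same gene with differing sequences the
#' resequenced one wins (resequencing corrected errors in the original
#' lists), but the superseded sequence is retained as an alias match
#' candidate for the same gene so that reads bearing the older barcode
#' are still counted. Conflicts are tallied in attribute `"conflicts"`.
#'
#' @param primary,resequenced `barcode_catalog` objects (layouts must agree).
#' @return Merged `barcode_catalog`.
#' @export
merge_catalogs <- function(primary, resequenced) {
  stopifnot(inherits(primary, "barcode_catalog"),
            inherits(resequenced, "barcode_catalog"),
            identical(primary$layout, resequenced$layout))
  p <- primary$entries
  r <- resequenced$entries
  common <- intersect(p$gene, r$gene)
  conflicts <- 0L
  aliases <- list()
  for (g in common) {
    pe <- p[p$gene == g, ]
    re <- r[r$gene == g, ]
    for (tag in c("uptag", "dntag")) {
      a <- pe[[tag]]; b <- re[[tag]]
      if (!is.na(a) && !is.na(b) && a != b) {
        conflicts <- conflicts + 1L
        aliases[[length(aliases) + 1L]] <-
          data.frame(gene = g, tag = sub("tag$", "", tag), sequence = a,
                     stringsAsFactors = FALSE)
      }
    }
  }
  merged <- rbind(r, p[!(p$gene %in% common), , drop = FALSE])
  merged <- merged[order(match(merged$gene, c(p$gene, r$gene))), , drop = FALSE]
  out <- barcode_catalog(merged, primary$layout)
  prev <- rbind(primary$aliases, resequenced$aliases)
  ali <- if (length(aliases)) rbind(prev, do.call(rbind, aliases)) else prev
  out$aliases <- unique(ali)
  attr(out, "conflicts") <- conflicts
  if (conflicts > 0L) {
    message("merge_catalogs: ", conflicts,
            " sequence conflict(s); resequenced entries kept, ",
            "superseded barcodes retained as aliases")
  }
  out
}

#' Build a concatenated barcode reference
#'
#' All barcodes of one tag are concatenated in catalog order, separated
#' by runs of ambiguous `N` bases, yielding a single reference sequence
#' plus a per-gene interval index (0-based, half-open). This is the
#' reference an external read aligner can be pointed at to cross-validate
#' the package's direct Hamming matching.
#'
#' @param catalog A `barcode_catalog`.
#' @param tag `"up"` or `"dn"`.
#' @param spacer_length Number of `N` bases between consecutive barcodes
#'   (default 20).
#' @return Object of class `concatenated_reference`: list with `sequence`,
#'   `intervals` (data.frame gene/start/end), `spacer_length`, `tag`.
#' @export
build_concatenated_reference <- function(catalog, tag = c("up", "dn"),
                                         spacer_length = 20L) {
  tag <- match.arg(tag)
  stopifnot(spacer_length >= 0L)
  col <- paste0(tag, "tag")
  e <- catalog$entries
  if (!nrow(e)) stop("catalog is empty")
  skip <- is.na(e[[col]])
  if (any(skip)) {
    warning(sum(skip), " entries missing ", col, " skipped: ",
            paste(utils::head(e$gene[skip], 5), collapse = ", "),
            if (sum(skip) > 5) ", ..." else "")
  }
  e <- e[!skip, , drop = FALSE]
  if (!nrow(e)) stop("no entries carry a ", col)
  bc <- e[[col]]
  lbc <- nchar(bc)
  spacer <- strrep("N", spacer_length)
  sequence <- paste(bc, collapse = spacer)
  starts <- cumsum(c(0L, utils::head(lbc, -1) + spacer_length))
  intervals <- data.frame(gene = e$gene, start = starts, end = starts + lbc,
                          stringsAsFactors = FALSE)
  # exhaustive reconstruction check: every interval must read back its barcode
  got <- substring(sequence, intervals$start + 1L, intervals$end)
  stopifnot(identical(got, bc))
  structure(list(sequence = sequence, intervals = intervals,
                 spacer_length = as.integer(spacer_length), tag = tag),
            class = "concatenated_reference")
}

#' Write a concatenated reference as single-record FASTA
#' @param ref A `concatenated_reference`.
#' @param path Output FASTA path.
#' @param name Record name.
#' @export
write_reference_fasta <- function(ref, path, name = paste0("barcode_ref_", ref$tag)) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path, optionally gzipped.
#' @return data.frame of class `fastq_records` with columns `id`,
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L) {
    return(fastq_records(character(0), character(0), character(0)))
  }
  tryCatch({
    # suppressed: Biostrings warns about dropping empty metadata columns
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    fastq_records(names(x), as.character(x),
                  as.character(Biostrings::quality(x)))
  }, error = function(e) {
    stop("FASTQ parse error in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Construct validated FASTQ records
#' @param id,sequence,quality Equal-length character vectors.
#' @return data.frame of class `fastq_records`.
#' @export
fastq_records <- function(id, sequence, quality) {
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad)) {
    stop("sequence/quality length mismatch at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (id ", paste(utils::head(id[bad], 5), collapse = ", "), ")")
  }
  structure(data.frame(id = as.character(id), sequence = as.character(sequence),
                       quality = as.character(quality), stringsAsFactors = FALSE),
            class = c("fastq_records", "data.frame"))
}

#' Write FASTQ records
#' @param records A `fastq_records` data.frame (validated on construction).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(records, path) {
  records <- fastq_records(records$id, records$sequence, records$quality)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  # Biostrings warns about dropping (empty) metadata columns on write
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(records$quality),
                                compress = grepl("\\.gz$", path)))
  invisible(path)
}
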