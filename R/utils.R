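# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

#' @noRd
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Split equal-length strings into an n x len character matrix.
#' @noRd
seq_matrix <- function(x, len) {
  if (length(x) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = len))
  }
  stopifnot(all(nchar(x) == len))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = len, byrow = TRUE)
}

# Full Hamming distance matrix between two sets of equal-length strings.
# Vectorized position-by-position; memory is n_query x n_ref integers.
#' @noRd
hamming_matrix <- function(query, ref) {
  len <- nchar(ref[1])
  qm <- seq_matrix(query, len)
  rm_ <- seq_matrix(ref, len)
  d <- matrix(0L, nrow = length(query), ncol = length(ref))
  for (j in seq_len(len)) {
    d <- d + outer(qm[, j], rm_[, j], "!=")
  }
  d
}

# Pairwise Hamming distance between two equal-length string vectors
# (elementwise, recycled).
#' @noRd
hamming_pair <- function(a, b) {
  am <- strsplit(a, "", fixed = TRUE)
  bm <- strsplit(b, "", fixed = TRUE)
  mapply(function(x, y) sum(x != y), am, bm)
}

# Deterministic child seed derived from a master seed; stays < 2^31.
#' @noRd
child_seed <- function(seed, offset) {
  (as.integer(seed) * 69069L + as.integer(offset)) %% 2147483587L
}

#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

# Write a table with '# key: value' provenance header lines.
#' @noRd
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv_meta <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
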