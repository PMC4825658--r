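# Concordance-at-the-top (CAT) comparison of two ranked gene lists.
# Under the null of no correspondence, the overlap between the top-d
# sets of two independent uniform orderings of G genes is
# hypergeometric(G, d, d); the null band is built from its quantiles.

#' Default depth grid for CAT curves
#' @param G Gene universe size.
#' @return Increasing depths: 10, 20, ... up to min(G, 1000), plus G.
#' @export
default_depth_grid <- function(G) {
  stopifnot(G >= 1)
  if (G < 10L) return(seq_len(G))
  sort(unique(c(seq(10L, min(G, 1000L), by = 10L), G)))
}

#' Concordance-at-the-top curve of two ranked lists
#'
#' Concordance at depth d is the size of the intersection of the two
#' top-d sets divided by d.
#'
#' @param a,b Character vectors: ranked, duplicate-free gene lists over
#'   the same universe.
#' @param depths Depths to evaluate (default [default_depth_grid()]).
#' @return data.frame of class `cat_curve`: `depth`, `concordance`.
#' @export
cat_curve <- function(a, b, depths = default_depth_grid(length(a))) {
  if (!length(a) || !length(b)) stop("ranked lists must be non-empty")
  if (anyDuplicated(a) || anyDuplicated(b)) stop("ranked lists contain duplicates")
  if (!setequal(a, b)) {
    off <- c(setdiff(a, b), setdiff(b, a))
    stop("gene universe mismatch: ",
         paste(utils::head(off, 10), collapse = ", "),
         if (length(off) > 10) ", ..." else "")
  }
  G <- length(a)
  depths <- sort(unique(as.integer(depths)))
  stopifnot(all(depths >= 1), all(depths <= G))
  pos_b <- match(a, b)     # rank in b of the gene at each rank of a
  conc <- vapply(depths, function(d) sum(pos_b[seq_len(d)] <= d) / d,
                 numeric(1))
  structure(data.frame(depth = depths, concordance = conc),
            class = c("cat_curve", "data.frame"))
}

#' Hypergeometric null band for a CAT curve
#'
#' Two-sided `level` band of concordance under the null of two
#' independent uniform orderings: overlap at depth d is
#' hypergeometric(G, d, d); the band is
#' [q_{(1-level)/2}, q_{1-(1-level)/2}] of overlap/d.
#'
#' @param G Universe size.
#' @param depths Depths.
#' @param level Confidence level (default 0.999, i.e. a 99.9% critical
#'   region for no correspondence).
#' @return data.frame: `depth`, `null_lower`, `null_upper`.
#' @export
cat_null_band <- function(G, depths = default_depth_grid(G), level = 0.999) {
  stopifnot(level > 0, level < 1, all(depths >= 1), all(depths <= G))
  depths <- as.integer(depths)
  alpha <- (1 - level) / 2
  lower <- stats::qhyper(alpha, m = depths, n = G - depths, k = depths) / depths
  upper <- stats::qhyper(1 - alpha, m = depths, n = G - depths, k = depths) / depths
  data.frame(depth = depths, null_lower = lower, null_upper = upper)
}

#' Compare two ranked lists with a null critical region
#'
#' Evaluates the CAT curve on a depth grid, attaches the hypergeometric
#' null band, flags depths where the curve exits the band (and in which
#' direction: exiting above at the top indicates correspondence), and
#' returns the verdict `"indistinguishable"` iff no evaluated depth
#' exits. Note that two lists that agree too well also exit (above) a
#' two-sided band wherever its upper bound is below 1.
#'
#' @inheritParams cat_curve
#' @param level Band confidence level (default 0.999).
#' @return List of class `cat_comparison`: `curve` (depth, concordance,
#'   null_lower, null_upper, flag in {"inside", "above", "below"}),
#'   `level`, `verdict`.
#' @export
cat_compare <- function(a, b, depths = default_depth_grid(length(a)),
                        level = 0.999) {
  cc <- cat_curve(a, b, depths)
  band <- cat_null_band(length(a), cc$depth, level)
  curve <- cbind(cc, band[, c("null_lower", "null_upper")])
  curve$flag <- ifelse(curve$concordance > curve$null_upper, "above",
                       ifelse(curve$concordance < curve$null_lower, "below",
                              "inside"))
  structure(list(curve = curve, level = level,
                 verdict = if (all(curve$flag == "inside"))
                   "indistinguishable" else "distinguishable"),
            class = "cat_comparison")
}

#' @export
print.cat_comparison <- function(x, ...) {
  n_out <- sum(x$curve$flag != "inside")
  cat("CAT comparison over", nrow(x$curve), "depths at level", x$level,
      "\n  verdict:", x$verdict,
      sprintf("(%d/%d depths outside the null band)\n", n_out, nrow(x$curve)))
  invisible(x)
}

#' Rank genes by response magnitude
#'
#' Builds the ranked list used for response-concordance comparisons:
#' genes ordered by decreasing absolute log2 fold change (ties broken by
#' gene name for determinism).
#'
#' @param results A [test_enrichment()]-style data.frame with `gene` and
#'   `log2FC` columns.
#' @return Character vector of genes, most-changed first.
#' @export
rank_by_response <- function(results) {
  stopifnot(all(c("gene", "log2FC") %in% colnames(results)))
  results$gene[order(-abs(results$log2FC), results$gene)]
}
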