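#' Ordinal ranks of stability values
#'
#' Ranks values ascending (lowest stability value = rank 1 = most stable).
#' Ties are broken deterministically by position: of two equal values, the
#' one occurring earlier in the input gets the lower rank. The result is
#' always a permutation of 1..k, which is what the geometric-mean consensus
#' requires.
#'
#' @param values numeric vector of stability values, optionally named by
#'   gene; input order is the canonical tie-break order.
#' @return integer vector of ranks, named like `values`.
#' @examples
#' ordinal_ranks(c(A = 0.285, B = 0.285, C = 0.356))  # A 1, B 2, C 3
#' @export
ordinal_ranks <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  r <- rank(values, ties.method = "first")
  storage.mode(r) <- "integer"
  r
}

#' Dense ranks of stability values
#'
#' Tied values share a rank and the next distinct value takes the next
#' integer (1, 1, 2, ...). This is the convention qPCR stability tables
#' typically print for ties; it is informational only — the consensus uses
#' [ordinal_ranks()].
#'
#' @inheritParams ordinal_ranks
#' @return integer vector of dense ranks, named like `values`.
#' @export
dense_ranks <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  r <- match(values, sort(unique(values)))
  storage.mode(r) <- "integer"
  if (!is.null(names(values))) names(r) <- names(values)
  r
}

#' Geometric mean of per-method ranks
#'
#' The comprehensive stability score: the geometric mean of a gene's ranks
#' across the stability methods, `(r1 * ... * rp)^(1/p)`. Output tables
#' round it to 2 decimals; this function returns it unrounded.
#'
#' @param ranks numeric vector of ranks, all >= 1 (typically the four
#'   per-method ordinal ranks of one gene).
#' @return the geometric mean (a single number in `[1, k]`).
#' @examples
#' geometric_mean_rank(c(9, 9, 9, 9))  # 9
#' round(geometric_mean_rank(c(2, 5, 2, 5)), 2)  # 3.16
#' @export
geometric_mean_rank <- function(ranks) {
  if (length(ranks) < 1) stop("need at least one rank")
  if (any(ranks < 1)) stop("ranks must be >= 1")
  exp(mean(log(ranks)))
}

#' RefFinder-style consensus ranking of candidate reference genes
#'
#' Runs the four stability methods (comparative delta-Ct, GeNorm,
#' NormFinder, BestKeeper), converts each method's stability values to
#' ordinal ranks, and scores every gene by the geometric mean of its four
#' ranks. The final comprehensive ranking is ascending in this score (ties
#' broken by input gene order), and the top `n_recommend` genes are the
#' recommendation. By default `n_recommend` is GeNorm's optimal reference
#' count from the pairwise-variation cutoff.
#'
#' @param m a [ct_matrix()] with at least 3 genes and 3 samples.
#' @param efficiency_base amplification base for GeNorm's relative
#'   quantities (default 2).
#' @param use_groups passed to [normfinder()] (default: grouped when 2+
#'   groups are present).
#' @param n_recommend how many genes to recommend; `NULL` (default) uses
#'   GeNorm's optimal reference count.
#' @param ... further arguments passed to [genorm()] (thresholds, report
#'   mode).
#' @return an object of class `rank_consensus`: list with `table` (a
#'   data.frame: gene, geomean, final_rank, then per-method stability,
#'   ordinal and dense rank columns), `recommended` (character vector),
#'   `optimal_n`, `cutoff_met`, and the four method results.
#' @export
consensus <- function(m, efficiency_base = 2, use_groups = NULL,
                      n_recommend = NULL, ...) {
  validate_ct_matrix(m)
  if (nrow(m$ct) < 3) stop("consensus needs at least 3 genes")
  genes <- rownames(m$ct)

  dct <- delta_ct_stability(m)
  gn <- genorm(m, efficiency_base = efficiency_base, ...)
  nf <- normfinder(m, use_groups = use_groups)
  bk <- bestkeeper(m)

  methods <- list(delta_ct = dct, genorm = gn, normfinder = nf,
                  bestkeeper = bk)
  stab <- lapply(methods, function(x) {
    tab <- stability_of(x)
    stats::setNames(tab$stability, tab$gene)[genes]
  })
  ranks <- vapply(stab, ordinal_ranks, integer(length(genes)))
  geomean <- apply(ranks, 1, geometric_mean_rank)
  final_rank <- ordinal_ranks(geomean)

  tab <- data.frame(gene = genes,
                    geomean = unname(geomean),
                    final_rank = unname(final_rank),
                    stringsAsFactors = FALSE)
  for (meth in names(stab)) {
    tab[[paste0(meth, "_stability")]] <- unname(stab[[meth]])
    tab[[paste0(meth, "_rank")]] <- unname(ranks[, meth])
    tab[[paste0(meth, "_dense_rank")]] <- unname(dense_ranks(stab[[meth]]))
  }

  opt <- if (!is.null(gn$pairwise_variation)) optimal_reference_count(gn)
         else list(n = 2L, cutoff_met = NA)
  n_rec <- if (is.null(n_recommend)) opt$n else n_recommend
  n_rec <- min(n_rec, length(genes))
  recommended <- tab$gene[order(tab$final_rank)][seq_len(n_rec)]

  structure(list(table = tab, recommended = recommended,
                 optimal_n = opt$n, cutoff_met = opt$cutoff_met,
                 methods = methods),
            class = "rank_consensus")
}

#' @export
print.rank_consensus <- function(x, ...) {
  cat("Comprehensive reference-gene ranking (geometric mean of ranks)\n")
  tab <- x$table[order(x$table$final_rank),
                 c("gene", "geomean", "final_rank")]
  tab$geomean <- round(tab$geomean, 2)
  print(tab, row.names = FALSE)
  cat("recommended:", paste(x$recommended, collapse = ", "), "\n")
  invisible(x)
}

#' Write a consensus table as TSV
#'
#' One row per gene: comprehensive (geometric-mean) value rounded to 2
#' decimals, comprehensive rank, then per-method stability and both rank
#' conventions; the recommendation is written as a trailing comment line.
#'
#' @param x a `rank_consensus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_table <- function(x, path) {
  tab <- x$table
  tab$geomean <- round(tab$geomean, 2)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("# recommended: %s\n", paste(x$recommended, collapse = ", ")),
      file = path, append = TRUE)
  invisible(path)
}
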