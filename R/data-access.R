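#' Published stability values for D. rybakowi candidate reference genes
#'
#' Per-method stability values (comparative delta-Ct, GeNorm M, NormFinder
#' SV, BestKeeper SD) for ten candidate reference genes of the leaf beetle
#' *Diorhabda rybakowi*, under two experimental conditions (tissue, sex), as
#' published. Row order within each condition follows the published table
#' and is the canonical tie-break order for [ordinal_ranks()]; feeding one
#' condition's columns through [ordinal_ranks()] and
#' [geometric_mean_rank()] reproduces the published comprehensive ranking.
#'
#' @param condition `"tissue"`, `"sex"`, or `NULL` (default) for both.
#' @return data.frame with columns `condition`, `gene`, `delta_ct`,
#'   `genorm`, `normfinder`, `bestkeeper`.
#' @examples
#' tab <- published_stability_values("tissue")
#' ranks <- sapply(tab[, c("delta_ct", "genorm", "normfinder", "bestkeeper")],
#'                 ordinal_ranks)
#' round(apply(ranks, 1, geometric_mean_rank), 2)
#' @export
published_stability_values <- function(condition = NULL) {
  path <- system.file("extdata", "dryb_reference_stability.tsv",
                      package = "refstab", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    condition <- match.arg(condition, unique(df$condition))
    df <- df[df$condition == condition, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
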