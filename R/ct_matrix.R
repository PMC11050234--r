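#' Construct a Ct matrix
#'
#' A `ct_matrix` holds quantification-cycle (Ct) values for a set of candidate
#' genes across a set of samples, together with per-sample metadata: a group
#' label (experimental condition, e.g. tissue or sex) and an optional
#' replicate id. It is the input currency of every stability method in the
#' package.
#'
#' Gene and sample order is meaningful: the order of first occurrence in the
#' input defines the canonical order used for deterministic tie-breaking in
#' ranking and in GeNorm's iterative exclusion.
#'
#' @param ct numeric matrix of Ct values, genes in rows, samples in columns;
#'   must carry unique row and column names. All cells must be finite.
#' @param group character vector of group labels, one per sample (recycled if
#'   length 1). Defaults to a single group `"all"`.
#' @param replicate optional character/integer vector of replicate ids, one
#'   per sample.
#' @return an object of class `ct_matrix`: a list with elements `ct` (the
#'   matrix), `group` (named character vector) and `replicate` (named vector
#'   or `NULL`).
#' @examples
#' ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 26, 27, 28))
#' colnames(ct) <- paste0("s", 1:4)
#' m <- ct_matrix(ct, group = c("t1", "t1", "t2", "t2"))
#' n_genes(m); n_samples(m)
#' @export
ct_matrix <- function(ct, group = "all", replicate = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have row (gene) and column (sample) names")
  group <- rep_len(as.character(group), ncol(ct))
  names(group) <- colnames(ct)
  if (!is.null(replicate)) {
    replicate <- rep_len(as.character(replicate), ncol(ct))
    names(replicate) <- colnames(ct)
  }
  m <- structure(list(ct = ct, group = group, replicate = replicate),
                 class = "ct_matrix")
  validate_ct_matrix(m)
}

#' Validate a Ct matrix
#'
#' Checks the invariants every downstream stability computation relies on:
#' all cells present and finite, unique gene and sample identifiers, at least
#' 2 genes and 3 samples.
#'
#' @param m a `ct_matrix`.
#' @return `m`, invisibly unchanged, or an error.
#' @export
validate_ct_matrix <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  ct <- m$ct
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  bad <- which(!is.finite(ct), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite Ct value for gene '%s', sample '%s'",
                 rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]))
  if (nrow(ct) < 2) stop("at least 2 genes are required (got ", nrow(ct), ")")
  if (ncol(ct) < 3) stop("at least 3 samples are required (got ", ncol(ct), ")")
  m
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d samples, %d group(s)\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$group))))
  cat("genes:  ", paste(utils::head(rownames(x$ct), 8), collapse = ", "),
      if (nrow(x$ct) > 8) ", ..." else "", "\n", sep = "")
  cat("groups: ", paste(unique(x$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname ct_matrix
#' @export
n_genes <- function(m) nrow(m$ct)

#' @rdname ct_matrix
#' @export
n_samples <- function(m) ncol(m$ct)

#' Read a Ct table from a delimited file
#'
#' Two layouts are supported. `"long"` expects columns `sample`, `gene`, `ct`
#' and optionally `group` and `replicate`; when a `replicate` column is
#' present, technical replicates are collapsed to their arithmetic mean Ct per
#' (gene, sample) before analysis. `"wide"` expects genes in the first column
#' and one column per sample (or the transpose with `genes_as = "cols"`);
#' group labels can be supplied separately via `group`.
#'
#' Missing or non-numeric Ct cells are a hard error naming the offending
#' (gene, sample) cell, unless `impute = TRUE`, in which case a missing cell
#' is filled with the mean Ct of that gene over the other samples of the same
#' group, and a message logs each imputation.
#'
#' @param path path to a delimited text file with a header row.
#' @param layout `"long"` or `"wide"`.
#' @param sep field delimiter (default comma; use `"\t"` for TSV).
#' @param genes_as for wide layout: `"rows"` (default) if genes are rows,
#'   `"cols"` if samples are rows.
#' @param group for wide layout: optional character vector of group labels in
#'   sample order, or a named vector keyed by sample.
#' @param impute impute missing Ct cells from same-group gene means
#'   (default `FALSE`: missing cells are an error).
#' @return a validated [ct_matrix()], gene and sample order preserved from the
#'   file (first occurrence).
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), sep = ",",
                          genes_as = c("rows", "cols"), group = NULL,
                          impute = FALSE) {
  layout <- match.arg(layout)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", quote = "\"")
  if (layout == "long") {
    need <- c("sample", "gene", "ct")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("long layout needs columns sample, gene, ct; missing: ",
           paste(miss, collapse = ", "))
    df$sample <- as.character(df$sample)
    df$gene <- as.character(df$gene)
    has_rep <- "replicate" %in% names(df)
    key <- if (has_rep) paste(df$gene, df$sample, df$replicate, sep = "\r")
           else paste(df$gene, df$sample, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate Ct entry for gene '%s', sample '%s'",
                   d$gene, d$sample))
    }
    ctv <- suppressWarnings(as.numeric(df$ct))
    bad <- which(!is.finite(ctv) & !(is.na(df$ct) | df$ct == ""))
    if (length(bad) > 0)
      stop(sprintf("non-numeric Ct value '%s' for gene '%s', sample '%s'",
                   df$ct[bad[1]], df$gene[bad[1]], df$sample[bad[1]]))
    genes <- unique(df$gene)
    samples <- unique(df$sample)
    # collapse technical replicates to the mean per (gene, sample)
    agg <- tapply(ctv, list(factor(df$gene, genes), factor(df$sample, samples)),
                  function(v) mean(v, na.rm = FALSE))
    ct <- matrix(agg, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
    grp <- if ("group" %in% names(df)) {
      g <- tapply(as.character(df$group), factor(df$sample, samples),
                  function(v) v[1])
      as.character(g)
    } else "all"
    m <- structure(list(ct = ct,
                        group = stats::setNames(rep_len(as.character(grp),
                                                        length(samples)),
                                                samples),
                        replicate = NULL),
                   class = "ct_matrix")
  } else {
    if (genes_as == "cols") {
      samples <- as.character(df[[1]])
      genes <- names(df)[-1]
      ct <- t(as.matrix(df[, -1, drop = FALSE]))
      dimnames(ct) <- list(genes, samples)
    } else {
      genes <- as.character(df[[1]])
      samples <- names(df)[-1]
      ct <- as.matrix(df[, -1, drop = FALSE])
      dimnames(ct) <- list(genes, samples)
    }
    storage.mode(ct) <- "double"
    grp <- if (is.null(group)) "all"
           else if (!is.null(names(group))) unname(group[samples])
           else group
    m <- structure(list(ct = ct,
                        group = stats::setNames(rep_len(as.character(grp),
                                                        ncol(ct)), samples),
                        replicate = NULL),
                   class = "ct_matrix")
  }
  if (impute) m <- impute_missing_ct(m)
  validate_ct_matrix(m)
}

impute_missing_ct <- function(m) {
  ct <- m$ct
  bad <- which(!is.finite(ct), arr.ind = TRUE)
  if (nrow(bad) == 0) return(m)
  for (r in seq_len(nrow(bad))) {
    i <- bad[r, 1]; j <- bad[r, 2]
    peers <- setdiff(which(m$group == m$group[j]), j)
    vals <- ct[i, peers]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0)
      stop(sprintf("cannot impute gene '%s', sample '%s': no finite Ct in group '%s'",
                   rownames(ct)[i], colnames(ct)[j], m$group[j]))
    ct[i, j] <- mean(vals)
    message(sprintf("imputed Ct for gene '%s', sample '%s' from group '%s' mean (%.3f)",
                    rownames(ct)[i], colnames(ct)[j], m$group[j], ct[i, j]))
  }
  m$ct <- ct
  m
}

#' Write a Ct table to a delimited file
#'
#' Inverse of [read_ct_table()]: `read_ct_table(write_ct_table(m))` recovers
#' `m` up to float formatting (values are written with enough significant
#' digits for an exact double round-trip in practice).
#'
#' @param m a `ct_matrix`.
#' @param path output path.
#' @param layout `"long"` or `"wide"`.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path, layout = c("long", "wide"), sep = ",") {
  layout <- match.arg(layout)
  validate_ct_matrix(m)
  if (layout == "long") {
    df <- data.frame(
      sample = rep(colnames(m$ct), each = nrow(m$ct)),
      group = rep(unname(m$group), each = nrow(m$ct)),
      gene = rep(rownames(m$ct), times = ncol(m$ct)),
      ct = format(as.vector(m$ct), digits = 15, trim = TRUE,
                  scientific = FALSE),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = rownames(m$ct),
                     apply(m$ct, 2, format, digits = 15, trim = TRUE,
                           scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a Ct matrix to selected sample groups
#'
#' The gene set is unchanged; samples are restricted to those whose group
#' label is in `groups`. The result must still hold at least 3 samples.
#'
#' @param m a `ct_matrix`.
#' @param groups character vector of group labels to keep.
#' @return a `ct_matrix` with the selected samples.
#' @export
subset_by_group <- function(m, groups) {
  validate_ct_matrix(m)
  unknown <- setdiff(groups, unique(m$group))
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  keep <- which(m$group %in% groups)
  out <- structure(list(ct = m$ct[, keep, drop = FALSE],
                        group = m$group[keep],
                        replicate = if (is.null(m$replicate)) NULL
                                    else m$replicate[keep]),
                   class = "ct_matrix")
  validate_ct_matrix(out)
}
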