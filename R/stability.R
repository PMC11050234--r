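#' Relative quantities from Ct values
#'
#' Converts Ct to relative template quantities per gene with
#' `q = E^-(Ct - min Ct)`, the normalization GeNorm expects: the sample with
#' the lowest Ct (most template) of each gene gets q = 1, and every cycle of
#' delay divides q by the amplification base E (2 for perfect doubling).
#'
#' @param m a [ct_matrix()].
#' @param efficiency_base per-cycle amplification factor E, > 1 (default 2).
#' @return a list of class `rq_matrix` with elements `q` (matrix, same
#'   dimnames as the Ct matrix), `efficiency_base` and the sample `group`
#'   labels.
#' @examples
#' ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 26, 27, 28))
#' colnames(ct) <- paste0("s", 1:4)
#' relative_quantities(ct_matrix(ct))$q[1, ]  # 1 0.5 0.25 0.125
#' @export
relative_quantities <- function(m, efficiency_base = 2) {
  validate_ct_matrix(m)
  if (efficiency_base <= 1) stop("`efficiency_base` must be > 1")
  dct <- m$ct - apply(m$ct, 1, min)
  q <- efficiency_base^(-dct)
  structure(list(q = q, efficiency_base = efficiency_base, group = m$group),
            class = "rq_matrix")
}

# log2 relative quantities computed directly on the Ct scale, avoiding the
# exp/log round trip: log2 q = -(Ct - min Ct) * log2(E)
log2_quantities <- function(m, efficiency_base = 2) {
  dct <- m$ct - apply(m$ct, 1, min)
  -dct * log2(efficiency_base)
}

stability_table <- function(method, gene, stability, ranking = "ordinal") {
  rank <- ordinal_ranks(stats::setNames(stability, gene))
  structure(data.frame(gene = gene, stability = unname(stability),
                       rank = unname(rank), stringsAsFactors = FALSE),
            method = method, ranking = ranking,
            class = c("stability_table", "data.frame"))
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("stability_table (%s, %s ranking)\n",
              attr(x, "method"), attr(x, "ranking")))
  NextMethod()
}

#' Comparative delta-Ct stability
#'
#' For each candidate gene, the stability value is the mean over all other
#' genes of the sample standard deviation (n - 1 denominator) of the
#' per-sample Ct difference between the pair. A gene whose Ct tracks every
#' other gene up to an additive constant scores 0; genes that fluctuate
#' relative to the rest score high. Lower is more stable.
#'
#' @param m a [ct_matrix()] with at least 2 genes and 3 samples.
#' @return a `stability_table` with columns `gene`, `stability` (cycles) and
#'   `rank` (1 = most stable, ties broken by input gene order).
#' @export
delta_ct_stability <- function(m) {
  validate_ct_matrix(m)
  ct <- m$ct
  k <- nrow(ct)
  stab <- vapply(seq_len(k), function(i) {
    mean(vapply(setdiff(seq_len(k), i),
                function(j) stats::sd(ct[i, ] - ct[j, ]), numeric(1)))
  }, numeric(1))
  stability_table("delta_ct", rownames(ct), stab)
}

# mean over partners of the SD of pairwise log-ratios, for a gene subset
genorm_m_values <- function(logq) {
  k <- nrow(logq)
  vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(l) stats::sd(logq[j, ] - logq[l, ]), numeric(1)))
  }, numeric(1))
}

#' GeNorm stability analysis
#'
#' Computes GeNorm expression-stability values M and the pairwise-variation
#' series V. For the current gene set, the pairwise variation of genes j and
#' k is the sample SD of the log2 expression ratio `log2(q_j / q_k)`; M_j is
#' the mean pairwise variation of gene j with all other candidates. The gene
#' with the highest M is excluded and M recomputed, until two genes remain;
#' these two can never be separated and share their final M. Each gene's
#' reported stability is its M at the step of its exclusion (option
#' `report = "initial"` returns full-set M instead).
#'
#' Normalization factors NF_n are per-sample geometric means of the relative
#' quantities of the n top-ranked genes; V_n = SD of `log2(NF_n / NF_n+1)`
#' over samples measures what the (n+1)-th gene adds. The smallest n with
#' V_n below `v_threshold` is the optimal number of reference genes.
#'
#' @param m a [ct_matrix()] with at least 3 genes (2 for M values only).
#' @param efficiency_base amplification base E used for `q = E^-dCt`
#'   (default 2).
#' @param m_threshold M value above which a gene is flagged unsuitable as a
#'   reference (default 1.5).
#' @param v_threshold pairwise-variation cutoff (default 0.15).
#' @param report `"exclusion"` (default; M at each gene's exclusion step,
#'   final pair shares one M) or `"initial"` (full-set M for every gene).
#' @return an object of class `genorm_result`: list with `stability`
#'   (a `stability_table`), `exclusion_order` (least to most stable),
#'   `ranking_order` (most to least stable), `final_pair`, `unsuitable`
#'   (genes with M > `m_threshold`), `initial_m`, and `pairwise_variation`
#'   (see [optimal_reference_count()]); `pairwise_variation` is `NULL` when
#'   k < 3.
#' @export
genorm <- function(m, efficiency_base = 2, m_threshold = 1.5,
                   v_threshold = 0.15, report = c("exclusion", "initial")) {
  report <- match.arg(report)
  validate_ct_matrix(m)
  if (efficiency_base <= 1) stop("`efficiency_base` must be > 1")
  logq <- log2_quantities(m, efficiency_base)
  genes <- rownames(logq)
  k <- length(genes)

  initial_m <- stats::setNames(genorm_m_values(logq), genes)
  m_at_exclusion <- stats::setNames(numeric(k), genes)
  exclusion_order <- character(0)
  active <- genes
  while (length(active) > 2) {
    mv <- genorm_m_values(logq[active, , drop = FALSE])
    # tie on the maximum M: drop the gene later in canonical input order
    worst <- active[max(which(mv == max(mv)))]
    m_at_exclusion[worst] <- mv[match(worst, active)]
    exclusion_order <- c(exclusion_order, worst)
    active <- setdiff(active, worst)
  }
  final_pair <- active
  shared_m <- stats::sd(logq[final_pair[1], ] - logq[final_pair[2], ])
  m_at_exclusion[final_pair] <- shared_m

  ranking_order <- c(final_pair, rev(exclusion_order))
  stab_values <- if (report == "exclusion") m_at_exclusion else initial_m
  stab <- stability_table("genorm", genes, unname(stab_values[genes]))
  # unsuitability applies to the reported per-gene M: the full-set M of a
  # sound gene is inflated by every unstable partner still in the set
  unsuitable <- genes[stab_values[genes] > m_threshold]

  pv <- NULL
  if (k >= 3) {
    lognf <- vapply(2:k, function(n) {
      colMeans(logq[ranking_order[seq_len(n)], , drop = FALSE])
    }, numeric(ncol(logq)))  # samples x (k-1), column i is NF_{i+1}
    v <- vapply(seq_len(k - 2), function(i) {
      stats::sd(lognf[, i] - lognf[, i + 1])
    }, numeric(1))
    names(v) <- paste0("V", 2:(k - 1), "/", 3:k)
    pv <- structure(list(v = v, n = 2:(k - 1), v_threshold = v_threshold),
                    class = "pairwise_variation")
  }

  structure(list(stability = stab,
                 exclusion_order = exclusion_order,
                 ranking_order = ranking_order,
                 final_pair = final_pair,
                 unsuitable = unsuitable,
                 m_threshold = m_threshold,
                 initial_m = initial_m,
                 pairwise_variation = pv),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("GeNorm result\n")
  cat("final pair:", paste(x$final_pair, collapse = ", "),
      sprintf("(M = %.3f)\n", x$stability$stability[
        match(x$final_pair[1], x$stability$gene)]))
  if (length(x$unsuitable) > 0)
    cat("unsuitable (M >", x$m_threshold, "):",
        paste(x$unsuitable, collapse = ", "), "\n")
  if (!is.null(x$pairwise_variation)) {
    opt <- optimal_reference_count(x)
    cat(sprintf("optimal number of reference genes: %d%s\n", opt$n,
                if (opt$cutoff_met) "" else " (no V below cutoff)"))
  }
  invisible(x)
}

#' Optimal number of reference genes from GeNorm pairwise variation
#'
#' Returns the smallest n >= 2 whose pairwise variation V_n/n+1 falls
#' strictly below the cutoff; if no n qualifies, returns the total number of
#' candidate genes with `cutoff_met = FALSE`.
#'
#' @param g a `genorm_result` (with pairwise variation present, i.e. k >= 3),
#'   or a bare `pairwise_variation` object.
#' @param v_threshold cutoff; defaults to the one stored at fit time (0.15).
#' @return list with `n` (integer) and `cutoff_met` (logical).
#' @export
optimal_reference_count <- function(g, v_threshold = NULL) {
  pv <- if (inherits(g, "genorm_result")) g$pairwise_variation else g
  if (is.null(pv)) stop("pairwise variation unavailable (needs >= 3 genes)")
  if (is.null(v_threshold)) v_threshold <- pv$v_threshold
  hit <- which(pv$v < v_threshold)
  if (length(hit) > 0) {
    list(n = pv$n[hit[1]], cutoff_met = TRUE)
  } else {
    list(n = max(pv$n) + 1L, cutoff_met = FALSE)
  }
}

# two-way centering residual variances: u_i = sum_j r_ij^2 / (n-1) with
# r = y - rowmean - colmean + grandmean
normfinder_u <- function(y) {
  r <- sweep(sweep(y, 1, rowMeans(y)), 2, colMeans(y)) + mean(y)
  rowSums(r^2) / (ncol(y) - 1)
}

normfinder_sigma2 <- function(y) {
  k <- nrow(y)
  u <- normfinder_u(y)
  pmax((k / (k - 2)) * (u - sum(u) / (k * (k - 1))), 0)
}

#' NormFinder stability analysis
#'
#' Model-based variance decomposition of Ct values (Ct is already log-linear
#' in template amount, so no transformation is applied). In ungrouped mode
#' the stability value of gene i is the square root of its estimated
#' gene-specific variance, obtained from two-way (gene x sample) centered
#' residuals with a bias correction that pools information across genes.
#'
#' In grouped mode the same variance estimate is computed within each sample
#' group, and a per-(gene, group) systematic deviation d measures how much
#' the gene's group mean departs from its overall level relative to the
#' other genes. The deviations are shrunk toward zero in proportion to the
#' estimated between-gene variance of group differences, and the stability
#' value combines the shrunken inter-group deviation with the intra-group
#' variance: `SV_i = mean_g(|d~_ig| + sqrt(gamma2_g * (s2_ig/n_g) /
#' (gamma2_g + s2_ig/n_g)))`. Lower is more stable in both modes.
#'
#' @param m a [ct_matrix()] with at least 3 genes (the bias correction
#'   divides by k - 2).
#' @param use_groups use the sample group labels (default: yes, when the
#'   matrix carries 2 or more groups, each with at least 2 samples required).
#' @return an object of class `normfinder_result`: list with `stability`
#'   (a `stability_table`), `grouped` flag, and, when grouped,
#'   `per_group` — a list of per-group matrices `sigma2` (intra-group
#'   variance), `d` (raw inter-group deviation) and `d_shrunk`.
#' @export
normfinder <- function(m, use_groups = NULL) {
  validate_ct_matrix(m)
  y <- m$ct
  k <- nrow(y)
  if (k < 3) stop("NormFinder needs at least 3 genes (got ", k, ")")
  groups <- unique(m$group)
  if (is.null(use_groups)) use_groups <- length(groups) >= 2

  if (!use_groups) {
    sv <- sqrt(normfinder_sigma2(y))
    return(structure(list(stability = stability_table("normfinder",
                                                      rownames(y), sv),
                          grouped = FALSE, per_group = NULL),
                     class = "normfinder_result"))
  }

  if (length(groups) < 2)
    stop("grouped NormFinder needs >= 2 sample groups")
  ng <- table(m$group)[groups]
  if (any(ng < 2))
    stop("grouped NormFinder needs >= 2 samples per group; singleton group(s): ",
         paste(names(ng)[ng < 2], collapse = ", "))

  grand <- mean(y)
  gene_mean <- rowMeans(y)
  sigma2 <- d_raw <- d_shr <- matrix(
    0, k, length(groups), dimnames = list(rownames(y), groups))
  sv_terms <- matrix(0, k, length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    yg <- y[, m$group == g, drop = FALSE]
    n_g <- ncol(yg)
    s2 <- normfinder_sigma2(yg)
    d <- (rowMeans(yg) - gene_mean) - (mean(yg) - grand)
    gamma2 <- max(0, sum(d^2) / (k - 1) - mean(s2) / n_g)
    dt <- d * gamma2 / (gamma2 + s2 / n_g)
    sigma2[, gi] <- s2
    d_raw[, gi] <- d
    d_shr[, gi] <- dt
    sv_terms[, gi] <- abs(dt) +
      sqrt(gamma2 * (s2 / n_g) / (gamma2 + s2 / n_g))
  }
  sv <- rowMeans(sv_terms)
  structure(list(stability = stability_table("normfinder", rownames(y), sv),
                 grouped = TRUE,
                 per_group = list(sigma2 = sigma2, d = d_raw,
                                  d_shrunk = d_shr)),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder result (%s)\n",
              if (x$grouped) "grouped" else "ungrouped"))
  print(x$stability)
  invisible(x)
}

#' BestKeeper descriptive stability
#'
#' Per-gene descriptive dispersion of raw Ct values: n, arithmetic and
#' geometric mean Ct, min, max, SD and CV. Following the original tool's
#' convention, "SD" is the mean absolute deviation of Ct from the arithmetic
#' mean (in cycles) and CV = 100 * SD / mean (percent); `sd_type = "sd"`
#' switches to the usual n - 1 standard deviation. Genes are ranked by
#' ascending SD (lowest dispersion = most stable).
#'
#' @param m a [ct_matrix()].
#' @param sd_type `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return an object of class `bestkeeper_result`: a data.frame with columns
#'   `gene`, `n`, `mean_ct`, `geo_mean_ct`, `min_ct`, `max_ct`, `sd`, `cv`,
#'   `rank`, plus a `stability` attribute holding the `stability_table`
#'   (stability = SD).
#' @export
bestkeeper <- function(m, sd_type = c("mad", "sd")) {
  sd_type <- match.arg(sd_type)
  validate_ct_matrix(m)
  ct <- m$ct
  mu <- rowMeans(ct)
  disp <- if (sd_type == "mad") rowMeans(abs(ct - mu))
          else apply(ct, 1, stats::sd)
  res <- data.frame(
    gene = rownames(ct),
    n = ncol(ct),
    mean_ct = unname(mu),
    geo_mean_ct = unname(exp(rowMeans(log(ct)))),
    min_ct = unname(apply(ct, 1, min)),
    max_ct = unname(apply(ct, 1, max)),
    sd = unname(disp),
    cv = unname(100 * disp / mu),
    stringsAsFactors = FALSE)
  res$rank <- unname(ordinal_ranks(stats::setNames(res$sd, res$gene)))
  structure(res,
            stability = stability_table("bestkeeper", res$gene, res$sd),
            sd_type = sd_type,
            class = c("bestkeeper_result", "data.frame"))
}

#' Extract the per-gene stability table from a method result
#'
#' @param x a result from [delta_ct_stability()], [genorm()],
#'   [normfinder()] or [bestkeeper()].
#' @return a `stability_table` data.frame (`gene`, `stability`, `rank`).
#' @export
stability_of <- function(x) {
  if (inherits(x, "stability_table")) return(x)
  if (inherits(x, "bestkeeper_result")) return(attr(x, "stability"))
  if (!is.null(x$stability)) return(x$stability)
  stop("no stability table in object of class ", paste(class(x), collapse = "/"))
}

#' Write a stability table as TSV
#'
#' One row per gene with columns `method`, `gene`, `stability`, `rank`.
#'
#' @param x a `stability_table` (or a method result accepted by
#'   [stability_of()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_table <- function(x, path) {
  tab <- stability_of(x)
  out <- data.frame(method = attr(tab, "method"), tab,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
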