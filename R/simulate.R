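#' Specify a Ct-matrix simulation
#'
#' Defines the generative model for a synthetic RT-qPCR experiment:
#' `Ct[i, j] = B_i + s_j + delta[i, g(j)] + eps[i, j]` with per-gene
#' baseline `B_i ~ Uniform(baseline_range)`, per-sample loading offset
#' `s_j ~ Normal(0, loading_sd)` shared by all genes of a sample (RNA
#' input / RT efficiency variation, which a good reference gene must
#' absorb), a condition-dependent shift `delta` for unstable genes, and
#' per-gene replicate noise `eps[i, j] ~ Normal(0, noise_sd[i])`.
#'
#' A gene is "designed stable" when its delta row is all zero and its noise
#' SD is minimal. The true instability score of gene i is
#' `sqrt(Var_g(delta[i, ]) + noise_sd[i]^2)` (population variance across
#' groups), the cycles-scale on which the stability methods operate.
#'
#' @param k number of genes.
#' @param groups number of sample groups, or a character vector of group
#'   labels.
#' @param n_per_group samples per group.
#' @param baseline_range range of per-gene baseline Ct (default 18-30
#'   cycles).
#' @param loading_sd SD of the shared per-sample offset (default 0.5
#'   cycles).
#' @param delta k x G matrix of group shifts in cycles (default all 0).
#' @param noise_sd per-gene replicate noise SD, length k (default 0.2).
#' @param genes gene names (default gene01, gene02, ...).
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(k = 10, groups = 2, n_per_group = 9,
                            baseline_range = c(18, 30), loading_sd = 0.5,
                            delta = NULL, noise_sd = 0.2, genes = NULL) {
  if (length(groups) == 1 && is.numeric(groups))
    groups <- paste0("g", seq_len(groups))
  G <- length(groups)
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(k))
  if (length(genes) != k) stop("`genes` must have length k")
  if (is.null(delta)) delta <- matrix(0, k, G)
  delta <- matrix(delta, k, G, dimnames = list(genes, groups))
  noise_sd <- rep_len(noise_sd, k)
  if (loading_sd < 0) stop("`loading_sd` must be >= 0")
  if (any(noise_sd <= 0)) stop("all `noise_sd` must be > 0")
  if (length(baseline_range) != 2 || diff(baseline_range) < 0)
    stop("`baseline_range` must be c(lo, hi)")
  structure(list(k = k, groups = groups, n_per_group = n_per_group,
                 baseline_range = baseline_range, loading_sd = loading_sd,
                 delta = delta, noise_sd = noise_sd, genes = genes),
            class = "simulation_spec")
}

#' Benchmark simulation preset
#'
#' Ten candidate genes over two conditions with nine samples each: two
#' designed-stable genes (no group shift, noise SD 0.1 cycles), four genes
#' with increasing replicate noise (SD 0.5 to 2.0 cycles) and four genes
#' with increasing condition-dependent shifts (0.5 to 2.0 cycles, on top
#' of 0.3 cycles of noise). This spans the spectrum from "ideal reference"
#' to "clearly regulated" and gives a strict total order of true
#' instability apart from the two stable genes.
#'
#' The `"tissue"` and `"sex"` presets keep the same gene structure but use
#' the sampling designs typical of reference-gene surveys: six tissue
#' groups x three biological replicates, or two sexes x three.
#'
#' @param preset `"benchmark"` (default), `"tissue"` or `"sex"`.
#' @return a [simulation_spec()].
#' @export
preset_simulation_spec <- function(preset = c("benchmark", "tissue", "sex")) {
  preset <- match.arg(preset)
  genes <- c("stable1", "stable2", paste0("noisy", 1:4), paste0("shift", 1:4))
  G <- switch(preset, benchmark = 2, tissue = 6, sex = 2)
  n_per_group <- switch(preset, benchmark = 9, tissue = 3, sex = 3)
  noise_sd <- c(0.1, 0.1, 0.5, 1.0, 1.5, 2.0, rep(0.3, 4))
  delta <- matrix(0, 10, G)
  # regulated genes move in both directions so the panel carries no net
  # shift: a common shift is indistinguishable from a loading offset under
  # relative quantification, and real condition-responsive genes go both ways
  shifts <- c(0.5, -1.0, 1.5, -2.0)
  for (i in 1:4) delta[6 + i, G] <- shifts[i]
  simulation_spec(k = 10, groups = G, n_per_group = n_per_group,
                  loading_sd = 0.5, delta = delta, noise_sd = noise_sd,
                  genes = genes)
}

#' Simulate a Ct matrix with known ground truth
#'
#' Draws from the model in [simulation_spec()] using one seeded stream in
#' a fixed order (baselines, then sample offsets, then per-gene noise), so
#' identical spec + seed reproduces the matrix exactly.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @return list with `ct` (a [ct_matrix()] with group labels) and `truth`
#'   (data.frame: gene, true_score in cycles, true_rank with ties broken
#'   by gene order).
#' @export
simulate_ct <- function(spec, seed = 42) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  G <- length(spec$groups)
  n <- G * spec$n_per_group
  group <- rep(spec$groups, each = spec$n_per_group)
  samples <- paste0(group, "_s", sequence(rep(spec$n_per_group, G)))

  B <- stats::runif(spec$k, spec$baseline_range[1], spec$baseline_range[2])
  s <- stats::rnorm(n, 0, spec$loading_sd)
  eps <- matrix(stats::rnorm(spec$k * n), spec$k, n) * spec$noise_sd
  ct <- B + matrix(s, spec$k, n, byrow = TRUE) +
    spec$delta[, match(group, spec$groups), drop = FALSE] + eps
  dimnames(ct) <- list(spec$genes, samples)

  var_delta <- apply(spec$delta, 1, function(d) mean((d - mean(d))^2))
  score <- sqrt(var_delta + spec$noise_sd^2)
  truth <- data.frame(gene = spec$genes, true_score = unname(score),
                      true_rank = unname(ordinal_ranks(score)),
                      stringsAsFactors = FALSE)
  list(ct = ct_matrix(ct, group = group), truth = truth)
}

#' Simulate a standard-curve dilution series
#'
#' Generates Ct values along a serial dilution under a chosen true
#' amplification base b: `Ct(x) = ct_at_1 - log(x) / log(b)` plus optional
#' Gaussian noise. Fitting the result with [fit_efficiency()] closes the
#' loop: with no noise, `E = (b - 1) * 100` exactly.
#'
#' @param true_base per-cycle amplification factor (> 1); 2 = perfect
#'   doubling.
#' @param ct_at_1 Ct of the undiluted (amount = 1) template.
#' @param steps number of dilution points (default 5, the common fivefold
#'   design 1, 1/5, ..., 1/625).
#' @param fold dilution factor between consecutive points (default 5).
#' @param noise_sd Ct noise SD in cycles (default 0).
#' @param replicates technical replicates per point (default 1).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @return a [dilution_series()].
#' @export
simulate_dilution <- function(true_base = 2, ct_at_1 = 20, steps = 5,
                              fold = 5, noise_sd = 0, replicates = 1,
                              seed = 42) {
  if (true_base <= 1) stop("`true_base` must be > 1")
  if (fold <= 1) stop("`fold` must be > 1")
  if (steps < 3) stop("need at least 3 dilution points")
  set.seed(seed)
  x <- rep(fold^-(0:(steps - 1)), each = replicates)
  ct <- ct_at_1 - log(x) / log(true_base) +
    stats::rnorm(length(x), 0, noise_sd)
  dilution_series(x, ct)
}

#' Simulate a protein sequence with one planted cysteine motif
#'
#' Builds a sequence containing exactly one occurrence of the given
#' pattern: random non-cysteine flanks, conserved cysteines, and gap
#' fillers drawn from the non-cysteine alphabet with gap lengths sampled
#' uniformly inside each window. Because no cysteine appears outside the
#' planted ones, the match is unique and [classify_sequence()] returns the
#' pattern's label (also under `strict` matching).
#'
#' @param pattern a [cys_pattern()].
#' @param flank number of residues before and after the motif (default 10).
#' @param seed integer seed.
#' @return a single amino-acid string.
#' @export
simulate_motif_sequence <- function(pattern, flank = 10, seed = 42) {
  stopifnot(inherits(pattern, "cys_pattern"))
  set.seed(seed)
  non_cys <- setdiff(strsplit(AA_ALPHABET20, "")[[1]], "C")
  draw <- function(n) paste(sample(non_cys, n, replace = TRUE), collapse = "")
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 windows
  gap_len <- apply(pattern$gaps, 1, function(g) pick(g[1]:g[2]))
  paste0(draw(flank), "C",
         paste(vapply(gap_len, function(l) paste0(draw(l), "C"),
                      character(1)), collapse = ""),
         draw(flank))
}
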