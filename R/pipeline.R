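#' Build a run configuration
#'
#' Bundles the inputs and tuning constants of a pipeline run. The two
#' decision thresholds default to the conventions of the field: a GeNorm M
#' value above 1.5 flags a gene as unsuitable, and the smallest n with
#' pairwise variation V below 0.15 is the optimal reference count.
#'
#' @param input path to the Ct table.
#' @param layout `"long"` or `"wide"` (see [read_ct_table()]).
#' @param sep field delimiter of the input file.
#' @param group for wide layout: group labels in sample order.
#' @param efficiency_base amplification base E (> 1, default 2).
#' @param m_threshold GeNorm unsuitability cutoff (default 1.5).
#' @param v_threshold GeNorm pairwise-variation cutoff (default 0.15).
#' @param use_groups grouped NormFinder (`NULL` = auto).
#' @param sd_type BestKeeper dispersion, `"mad"` or `"sd"`.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded with the run.
#' @param target,references,calibrator for [run_quantify()] only.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, layout = "long", sep = ",", group = NULL,
                       efficiency_base = 2, m_threshold = 1.5,
                       v_threshold = 0.15, use_groups = NULL,
                       sd_type = "mad", out_dir = ".", seed = 1,
                       target = NULL, references = NULL, calibrator = NULL) {
  if (efficiency_base <= 1) stop("`efficiency_base` must be > 1")
  if (m_threshold <= 0 || v_threshold <= 0)
    stop("thresholds must be > 0")
  structure(list(input = input, layout = layout, sep = sep, group = group,
                 efficiency_base = efficiency_base,
                 m_threshold = m_threshold, v_threshold = v_threshold,
                 use_groups = use_groups, sd_type = sd_type,
                 out_dir = out_dir, seed = seed, target = target,
                 references = references, calibrator = calibrator),
            class = "run_config")
}

# 32-bit polynomial rolling hash over the deparsed config; enough to tag
# outputs with the configuration that produced them
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

write_with_header <- function(writer, path, config) {
  tmp <- tempfile()
  writer(tmp)
  con <- file(path, "w")
  writeLines(sprintf("# refstab %s | config %s | seed %d",
                     as.character(utils::packageVersion("refstab")),
                     config_hash(config), config$seed), con)
  writeLines(readLines(tmp), con)
  close(con)
  unlink(tmp)
  invisible(path)
}

#' Run the full reference-gene stability pipeline
#'
#' Reads a Ct table, runs the four stability methods and the consensus,
#' and writes six tab-separated tables into `out_dir`: one per method
#' (`delta_ct.tsv`, `genorm.tsv`, `normfinder.tsv`, `bestkeeper.tsv`), the
#' GeNorm pairwise-variation series (`pairwise_variation.tsv`) and the
#' consensus table (`consensus.tsv`), plus a machine-readable
#' `run_summary.json`. Every table carries a header comment with the
#' package version, a config hash and the seed, so a run can be matched to
#' its configuration.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the `consensus` result and the vector
#'   of written `files`.
#' @export
run_stability <- function(config) {
  stopifnot(inherits(config, "run_config"))
  m <- read_ct_table(config$input, layout = config$layout, sep = config$sep,
                     group = config$group)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  cons <- consensus(m, efficiency_base = config$efficiency_base,
                    use_groups = config$use_groups,
                    m_threshold = config$m_threshold,
                    v_threshold = config$v_threshold)
  gn <- cons$methods$genorm

  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  for (meth in c("delta_ct", "genorm", "normfinder", "bestkeeper")) {
    f <- out(paste0(meth, ".tsv"))
    write_with_header(function(p)
      write_stability_table(cons$methods[[meth]], p), f, config)
    files <- c(files, f)
  }
  pv <- gn$pairwise_variation
  f <- out("pairwise_variation.tsv")
  write_with_header(function(p) {
    utils::write.table(data.frame(n = pv$n, v = unname(pv$v)), p,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }, f, config)
  files <- c(files, f)
  f <- out("consensus.tsv")
  write_with_header(function(p) write_consensus_table(cons, p), f, config)
  files <- c(files, f)

  summary <- list(
    n_genes = n_genes(m), n_samples = n_samples(m),
    groups = unique(unname(m$group)),
    recommended = cons$recommended,
    optimal_n = cons$optimal_n, cutoff_met = cons$cutoff_met,
    unsuitable = gn$unsuitable,
    config_hash = config_hash(config), seed = config$seed)
  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, out("run_summary.json"))
  message("recommended reference genes: ",
          paste(cons$recommended, collapse = ", "))
  invisible(list(consensus = cons, files = files))
}

#' Run relative quantification (2^-ddCt)
#'
#' Reads a Ct table and writes `expression.tsv` (per-group mean and SD of
#' fold changes) plus `expression_per_sample.tsv` into `out_dir`. The
#' config must name `target`, `references` and `calibrator`.
#'
#' @param config a [run_config()] with quantification fields set.
#' @return (invisibly) a list with the `relative_expression` result and
#'   the written `files`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$target) || is.null(config$references) ||
      is.null(config$calibrator))
    stop("quantification needs `target`, `references` and `calibrator`")
  m <- read_ct_table(config$input, layout = config$layout, sep = config$sep,
                     group = config$group)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  rx <- delta_delta_ct(m, target = config$target,
                       references = config$references,
                       calibrator = config$calibrator,
                       base = config$efficiency_base)
  out <- function(name) file.path(config$out_dir, name)
  files <- c(out("expression.tsv"), out("expression_per_sample.tsv"))
  write_with_header(function(p)
    utils::write.table(rx$per_group, p, sep = "\t", row.names = FALSE,
                       quote = FALSE), files[1], config)
  write_with_header(function(p)
    utils::write.table(rx$per_sample, p, sep = "\t", row.names = FALSE,
                       quote = FALSE), files[2], config)
  invisible(list(expression = rx, files = files))
}
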