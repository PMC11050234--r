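#' Construct a dilution series
#'
#' Standard-curve input: pairs of relative template amount (1 for the most
#' concentrated point, then e.g. 1/5, 1/25, ... for a fivefold series) and
#' observed Ct. Replicate Ct values at the same amount are kept as
#' individual points and all enter the regression.
#'
#' @param amount numeric vector of relative template amounts, all > 0.
#' @param ct numeric vector of Ct values, same length.
#' @return an object of class `dilution_series` (data.frame with columns
#'   `amount`, `ct`).
#' @export
dilution_series <- function(amount, ct) {
  if (length(amount) != length(ct))
    stop("`amount` and `ct` must have the same length")
  if (any(!is.finite(amount)) || any(amount <= 0))
    stop("all amounts must be finite and > 0")
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  if (length(unique(amount)) < 3)
    stop("at least 3 distinct template amounts are required")
  structure(data.frame(amount = amount, ct = ct),
            class = c("dilution_series", "data.frame"))
}

#' Read a dilution series from CSV
#'
#' Expects a header with columns `amount` and `ct` (extra columns such as a
#' primer id are carried along but ignored by the fit).
#'
#' @param path path to a delimited file.
#' @param sep field delimiter (default comma).
#' @return a [dilution_series()].
#' @export
read_dilution_series <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("amount", "ct") %in% names(df)))
    stop("dilution series needs columns `amount` and `ct`")
  dilution_series(as.numeric(df$amount), as.numeric(df$ct))
}

#' Fit amplification efficiency from a standard curve
#'
#' Ordinary least squares of Ct on log10 of the relative template amount.
#' The amplification efficiency is `E = (10^(-1/slope) - 1) * 100` percent:
#' a perfectly doubling reaction has slope -1/log10(2) = -3.32 cycles per
#' 10-fold dilution and E = 100. R-squared is the coefficient of
#' determination of the fit.
#'
#' By convention E in the 90-110 percent band with R-squared >= 0.90 is
#' considered a well-behaved assay; values outside trigger a warning (never
#' an error — primer sets with E well above 110 occur in practice and may
#' still be usable).
#'
#' @param d a [dilution_series()].
#' @param warn_band numeric length-2: acceptable E band in percent
#'   (default `c(90, 110)`); `NULL` disables the warning.
#' @param warn_r2 warn when R-squared falls below this (default 0.90);
#'   `NULL` disables.
#' @return an object of class `efficiency_fit`: list with `slope`
#'   (cycles per log10 unit), `intercept`, `e_percent`, `r_squared`,
#'   `n_points`.
#' @examples
#' d <- dilution_series(amount = 5^-(0:4), ct = 20 + log2(5) * (0:4))
#' fit_efficiency(d)$e_percent  # 100
#' @export
fit_efficiency <- function(d, warn_band = c(90, 110), warn_r2 = 0.90) {
  stopifnot(inherits(d, "dilution_series"))
  fit <- stats::lm(ct ~ log10(amount), data = d)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8)
    stop("degenerate standard curve: slope is zero or undefined")
  e_percent <- (10^(-1 / slope) - 1) * 100
  # R^2 computed directly (summary.lm warns on exact fits)
  tss <- sum((d$ct - mean(d$ct))^2)
  r2 <- min(max(1 - sum(stats::residuals(fit)^2) / tss, 0), 1)
  if (!is.null(warn_band) &&
      (e_percent < warn_band[1] || e_percent > warn_band[2]))
    warning(sprintf("amplification efficiency %.1f%% outside [%g, %g]%%",
                    e_percent, warn_band[1], warn_band[2]))
  if (!is.null(warn_r2) && r2 < warn_r2)
    warning(sprintf("standard-curve R-squared %.3f below %.2f", r2, warn_r2))
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 e_percent = e_percent,
                 r_squared = r2,
                 n_points = nrow(d)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, intercept %.3f (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("E = %.2f%%, R-squared = %.4f\n", x$e_percent, x$r_squared))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes a target gene to one or more reference genes and expresses
#' each sample as a fold change relative to a calibrator group. The
#' reference signal per sample is the arithmetic mean Ct of the reference
#' genes — on the Ct (log2) scale this is exactly the geometric mean of
#' their relative quantities, the GeNorm normalization-factor convention.
#' Then `dCt_s = Ct_target,s - refsignal_s`, `ddCt_s = dCt_s - mean(dCt)`
#' over the calibrator samples, and `rq_s = base^-ddCt_s`.
#'
#' @param m a [ct_matrix()].
#' @param target target gene name (must not be among `references`).
#' @param references character vector of reference gene names (non-empty).
#' @param calibrator group label whose mean dCt defines fold change 1.
#' @param base amplification base (default 2).
#' @param summarize_on `"rq"` (default: group means and SDs of per-sample
#'   fold changes) or `"ddct"` (mean ddCt per group back-transformed;
#'   SD then reflects log-scale spread).
#' @return an object of class `relative_expression`: list with `per_sample`
#'   (data.frame: sample, group, dct, ddct, rq), `per_group` (data.frame:
#'   group, mean_rq, sd_rq, n), `target`, `references`, `calibrator`.
#' @export
delta_delta_ct <- function(m, target, references, calibrator, base = 2,
                           summarize_on = c("rq", "ddct")) {
  summarize_on <- match.arg(summarize_on)
  validate_ct_matrix(m)
  genes <- rownames(m$ct)
  if (!target %in% genes) stop("unknown target gene: ", target)
  if (length(references) == 0) stop("at least one reference gene is required")
  miss <- setdiff(references, genes)
  if (length(miss) > 0)
    stop("unknown reference gene(s): ", paste(miss, collapse = ", "))
  if (target %in% references)
    stop("target gene must not be among the reference genes")
  if (!calibrator %in% m$group)
    stop("unknown calibrator group: ", calibrator)

  refsignal <- colMeans(m$ct[references, , drop = FALSE])
  dct <- m$ct[target, ] - refsignal
  ddct <- dct - mean(dct[m$group == calibrator])
  rq <- base^(-ddct)

  per_sample <- data.frame(sample = colnames(m$ct), group = unname(m$group),
                           dct = unname(dct), ddct = unname(ddct),
                           rq = unname(rq), stringsAsFactors = FALSE)
  grp <- unique(per_sample$group)
  per_group <- do.call(rbind, lapply(grp, function(g) {
    v <- per_sample[per_sample$group == g, ]
    if (summarize_on == "rq") {
      data.frame(group = g, mean_rq = mean(v$rq),
                 sd_rq = if (nrow(v) > 1) stats::sd(v$rq) else NA_real_,
                 n = nrow(v), stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, mean_rq = base^(-mean(v$ddct)),
                 sd_rq = if (nrow(v) > 1) stats::sd(v$ddct) else NA_real_,
                 n = nrow(v), stringsAsFactors = FALSE)
    }
  }))
  structure(list(per_sample = per_sample, per_group = per_group,
                 target = target, references = references,
                 calibrator = calibrator, base = base,
                 summarize_on = summarize_on),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression of %s vs %s (calibrator: %s)\n",
              x$target, paste(x$references, collapse = "+"), x$calibrator))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
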