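#' Log2-transform a raw intensity matrix
#'
#' Zero intensities are the non-detection convention of LFQ exports and
#' become missing; negative intensities are a data error.
#'
#' @param raw numeric matrix (features x samples) of raw intensities, with
#'   `NA` or 0 marking non-detection. Row/column names become feature and
#'   sample ids.
#' @return a [quant_table()] of log2 intensities.
#' @export
log2_transform <- function(raw) {
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE))
    stop("negative raw intensities are invalid", call. = FALSE)
  m[!is.na(m) & m == 0] <- NA_real_
  quant_table(log2(m))
}

#' Parameters for down-shifted-normal imputation
#'
#' Missing cells are drawn from a normal distribution derived from each
#' sample column's observed statistics: mean `mu - shift * sigma` and
#' standard deviation `width * sigma` (Perseus convention; defaults
#' shift = 1.8, width = 0.3). This emulates the left-censored origin of
#' LFQ missingness by placing imputed values in the lower tail.
#'
#' @param shift nonnegative down-shift in column-sd units (default 1.8).
#' @param width positive width factor in column-sd units (default 0.3).
#' @param seed integer seed; draws are re-seeded per column from
#'   `(seed, sample_id)` so one column's draws do not depend on the others.
#' @param axis `"sample"` (default; columns are samples) or `"feature"`.
#' @return an `imputation_params` list.
#' @export
imputation_params <- function(shift = 1.8, width = 0.3, seed = 1L,
                              axis = c("sample", "feature")) {
  axis <- match.arg(axis)
  if (shift < 0) stop("shift must be >= 0", call. = FALSE)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  structure(list(shift = shift, width = width, seed = as.integer(seed),
                 axis = axis), class = "imputation_params")
}

#' Impute missing values from a down-shifted normal distribution
#'
#' For each sample column with observed mean `mu` and sample (n-1)
#' standard deviation `sigma`, every missing cell is replaced by an
#' independent draw from `Normal(mu - shift * sigma, (width * sigma)^2)`.
#' Observed cells are never altered. Deterministic given
#' `params$seed`.
#'
#' @param table a [quant_table()].
#' @param params an [imputation_params()] (defaults: shift 1.8, width 0.3).
#' @return a complete `quant_table`.
#' @export
impute_downshifted <- function(table, params = imputation_params()) {
  stopifnot(is_quant_table(table), inherits(params, "imputation_params"))
  x <- as_quant_matrix(table)
  if (params$axis == "feature") x <- t(x)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    miss <- is.na(col)
    if (!any(miss)) next
    obs <- col[!miss]
    if (length(obs) < 2L)
      stop(sprintf(
        "column '%s' has %d observed value(s); >= 2 required to impute",
        colnames(x)[j], length(obs)), call. = FALSE)
    mu <- mean(obs)
    sigma <- stats::sd(obs)
    x[miss, j] <- with_seed(
      derive_seed(params$seed, "impute", colnames(x)[j]),
      rnorm(sum(miss), mu - params$shift * sigma, params$width * sigma))
  }
  if (params$axis == "feature") x <- t(x)
  quant_table(x, rownames(table), colnames(table))
}

#' Per-feature detection counts and fractions by group
#'
#' Supports the exclusivity rules: a feature "detected exclusively in one
#' group" has zero observations in the other, and the FDR-level rule
#' additionally requires detection in at least half of that group's
#' samples.
#'
#' @param table a [quant_table()] (un-imputed; `NA` = not detected).
#' @param labels named `"pos"`/`"neg"` vector covering the analyzed samples.
#' @return data.frame with per-feature `n_obs_pos`, `n_obs_neg`,
#'   `frac_pos`, `frac_neg` and a `fully_missing` flag.
#' @export
detection_stats <- function(table, labels) {
  stopifnot(is_quant_table(table))
  labels <- check_group_labels(labels, colnames(table))
  pos <- names(labels)[labels == "pos"]
  neg <- names(labels)[labels == "neg"]
  obs <- !is.na(as_quant_matrix(table))
  n_pos <- rowSums(obs[, pos, drop = FALSE])
  n_neg <- rowSums(obs[, neg, drop = FALSE])
  data.frame(feature_id = rownames(table),
             n_obs_pos = n_pos, n_obs_neg = n_neg,
             frac_pos = n_pos / length(pos), frac_neg = n_neg / length(neg),
             fully_missing = (n_pos + n_neg) == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}
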