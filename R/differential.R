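#' Two-sided pooled-variance (Student) t-test
#'
#' Equal-variance unpaired Student's t with `df = nx + ny - 2` and a
#' two-sided p-value. Zero pooled variance is signaled distinctly (both
#' values `NA`, `degenerate = TRUE`) rather than collapsed to p = 0:
#' such features are routed to the exclusivity/not-tested path by
#' [differential_table()].
#'
#' @param x,y numeric vectors, each of length >= 2 (NAs dropped).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
student_t_two_sided <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("both groups need >= 2 observations", call. = FALSE)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, df = df, degenerate = TRUE))
  }
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Two-group differential abundance with exclusivity rules
#'
#' Implements the discovery-phase comparison between pN+ and pN0 samples:
#' \itemize{
#'   \item features with at least `min_obs_per_group` observations in both
#'     groups get a two-sided pooled Student t-test; significance at
#'     `p <= alpha`, or `q <= alpha` after Benjamini-Hochberg correction
#'     over the tested features when `use_fdr = TRUE`;
#'   \item features detected exclusively in one group are differential by
#'     detection: at the p-level any exclusive detection qualifies, at the
#'     FDR level only when detected in at least `exclusive_min_fraction`
#'     (default 50\%) of that group's samples;
#'   \item everything else is `not_tested`.
#' }
#' Ratio is the difference of log2 group means (log2 pN+/pN0 ratio);
#' significant positive ratios and pN+-exclusive features are `up`,
#' the mirror cases `down`. Run this on the un-imputed table: the
#' exclusivity logic reads the detection mask.
#'
#' @param table a [quant_table()] (un-imputed).
#' @param labels named `"pos"`/`"neg"` vector.
#' @param use_fdr apply BH correction and the 50\%-detection exclusivity
#'   clause (volcano/FDR-level analysis).
#' @param alpha significance level (default 0.05).
#' @param min_obs_per_group minimum per-group observations for testing
#'   (default 2).
#' @param exclusive_min_fraction FDR-level exclusivity detection fraction
#'   (default 0.5).
#' @return data.frame of per-feature records: `feature_id`, `n_obs_pos`,
#'   `n_obs_neg`, `mean_pos`, `mean_neg`, `ratio`, `t_stat`, `p`, `q`,
#'   `exclusivity` (`none`/`exclusive_pos`/`exclusive_neg`) and `status`
#'   (`up`/`down`/`not_significant`/`not_tested`).
#' @export
differential_table <- function(table, labels, use_fdr = FALSE, alpha = 0.05,
                               min_obs_per_group = 2L,
                               exclusive_min_fraction = 0.5) {
  stopifnot(is_quant_table(table))
  labels <- check_group_labels(labels, colnames(table))
  x <- as_quant_matrix(table)
  pos <- names(labels)[labels == "pos"]
  neg <- names(labels)[labels == "neg"]
  det <- detection_stats(table, labels)
  n <- nrow(x)
  rec <- data.frame(feature_id = rownames(table),
                    n_obs_pos = det$n_obs_pos, n_obs_neg = det$n_obs_neg,
                    mean_pos = NA_real_, mean_neg = NA_real_,
                    ratio = NA_real_, t_stat = NA_real_, p = NA_real_,
                    q = NA_real_, exclusivity = "none",
                    status = "not_tested", row.names = NULL,
                    stringsAsFactors = FALSE)
  rec$mean_pos[det$n_obs_pos > 0L] <-
    rowMeans(x[, pos, drop = FALSE], na.rm = TRUE)[det$n_obs_pos > 0L]
  rec$mean_neg[det$n_obs_neg > 0L] <-
    rowMeans(x[, neg, drop = FALSE], na.rm = TRUE)[det$n_obs_neg > 0L]
  rec$ratio <- rec$mean_pos - rec$mean_neg

  testable <- det$n_obs_pos >= min_obs_per_group &
    det$n_obs_neg >= min_obs_per_group
  for (i in which(testable)) {
    tt <- student_t_two_sided(x[i, pos], x[i, neg])
    rec$t_stat[i] <- tt$t
    rec$p[i] <- tt$p
    if (tt$degenerate && is.na(tt$p)) testable[i] <- FALSE  # zero variance
  }
  if (use_fdr) rec$q[testable] <- bh_adjust(rec$p[testable])

  crit <- if (use_fdr) rec$q else rec$p
  sig <- testable & !is.na(crit) & crit <= alpha
  rec$status[testable] <- "not_significant"
  rec$status[sig & rec$ratio > 0] <- "up"
  rec$status[sig & rec$ratio < 0] <- "down"

  excl_pos <- det$n_obs_pos > 0L & det$n_obs_neg == 0L
  excl_neg <- det$n_obs_neg > 0L & det$n_obs_pos == 0L
  if (use_fdr) {
    qual_pos <- excl_pos & det$frac_pos >= exclusive_min_fraction
    qual_neg <- excl_neg & det$frac_neg >= exclusive_min_fraction
    rec$status[(excl_pos & !qual_pos) | (excl_neg & !qual_neg)] <-
      "not_significant"
  } else {
    qual_pos <- excl_pos
    qual_neg <- excl_neg
  }
  rec$exclusivity[qual_pos] <- "exclusive_pos"
  rec$exclusivity[qual_neg] <- "exclusive_neg"
  rec$status[qual_pos] <- "up"
  rec$status[qual_neg] <- "down"
  stopifnot(nrow(rec) == n)
  rec
}

#' Principal-component summary of a feature subset
#'
#' Centered (unscaled) PCA of samples over the given features, as used to
#' summarize how well differential proteins segregate pN+ from pN0.
#'
#' @param table a complete (imputed) [quant_table()].
#' @param feature_subset character vector of feature ids (default: all).
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions summing to 1), `n_components`.
#' @export
pca_summary <- function(table, feature_subset = rownames(table)) {
  stopifnot(is_quant_table(table))
  if (length(feature_subset) == 0L)
    stop("feature subset must be nonempty", call. = FALSE)
  missing_ids <- setdiff(feature_subset, rownames(table))
  if (length(missing_ids))
    stop("unknown feature id(s): ", paste(head(missing_ids, 3L),
                                          collapse = ", "), call. = FALSE)
  x <- t(as_quant_matrix(table)[feature_subset, , drop = FALSE])
  if (anyNA(x))
    stop("PCA requires a complete (imputed) table", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(nrow(x) - 1L, ncol(x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = (ev / sum(ev))[seq_len(k)],
       n_components = k)
}

#' Chi-square comparison of deregulation frequencies
#'
#' Helper comparing counts of deregulated vs non-deregulated features
#' between two datasets (e.g. malignant vs non-malignant populations).
#'
#' @param deregulated,total integer vectors of length 2: deregulated counts
#'   and totals per dataset.
#' @return list with `statistic`, `p`.
#' @export
deregulation_chisq <- function(deregulated, total) {
  stopifnot(length(deregulated) == 2L, length(total) == 2L,
            all(deregulated <= total))
  tab <- rbind(deregulated, total - deregulated)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}
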