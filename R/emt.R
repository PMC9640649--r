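#' Read an Epi/Mes signature from TSV
#'
#' Two-column TSV (`id`, `class`) mapping gene/protein identifiers to the
#' epithelial (`Epi`) or mesenchymal (`Mes`) class. The package ships a
#' 10-gene synthetic toy signature under `inst/extdata/toy_emt_signature.tsv`;
#' full published signatures (e.g. 76-gene EMT panels) are supplied by the
#' user in the same format.
#'
#' @param path file path.
#' @return named character vector gene -> `"Epi"`/`"Mes"`.
#' @export
read_emt_signature <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  sig <- stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
  validate_emt_signature(sig)
  sig
}

validate_emt_signature <- function(signature) {
  if (is.null(names(signature)) || anyDuplicated(names(signature)))
    stop("signature must be uniquely named by gene id", call. = FALSE)
  if (!all(signature %in% c("Epi", "Mes")))
    stop('signature classes must be "Epi" or "Mes"', call. = FALSE)
  if (!any(signature == "Epi") || !any(signature == "Mes"))
    stop("signature needs at least one gene per class", call. = FALSE)
  invisible(signature)
}

#' Per-sample EMT score
#'
#' Score = mean observed abundance of mesenchymal (`Mes`) signature
#' proteins minus mean observed abundance of epithelial (`Epi`) signature
#' proteins; higher scores are more mesenchymal. Missing cells are ignored
#' per sample; a sample with fewer than `min_per_class` observed proteins
#' in either class is flagged invalid (`NA` score).
#'
#' @param table a [quant_table()] (observed values; imputation optional).
#' @param signature named gene -> `"Epi"`/`"Mes"` vector.
#' @param min_per_class minimum observed proteins per class (default 3).
#' @return data.frame with `sample_id`, `score`, `n_mes_used`,
#'   `n_epi_used`, `valid`.
#' @export
emt_score <- function(table, signature, min_per_class = 3L) {
  stopifnot(is_quant_table(table))
  validate_emt_signature(signature)
  mes_ids <- intersect(names(signature)[signature == "Mes"],
                       rownames(table))
  epi_ids <- intersect(names(signature)[signature == "Epi"],
                       rownames(table))
  if (length(mes_ids) + length(epi_ids) == 0L)
    stop("signature has zero overlap with the table", call. = FALSE)
  x <- as_quant_matrix(table)
  n_mes <- colSums(!is.na(x[mes_ids, , drop = FALSE]))
  n_epi <- colSums(!is.na(x[epi_ids, , drop = FALSE]))
  score <- colMeans(x[mes_ids, , drop = FALSE], na.rm = TRUE) -
    colMeans(x[epi_ids, , drop = FALSE], na.rm = TRUE)
  valid <- n_mes >= min_per_class & n_epi >= min_per_class
  score[!valid] <- NA_real_
  data.frame(sample_id = colnames(table), score = unname(score),
             n_mes_used = as.integer(unname(n_mes)),
             n_epi_used = as.integer(unname(n_epi)),
             valid = unname(valid), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Normality-guided paired comparison of two matched score vectors
#'
#' Applies the Shapiro-Wilk test to the paired differences at alpha = 0.05:
#' normal differences get the two-sided paired Student t-test, non-normal
#' ones the two-sided Wilcoxon signed-rank test (zero differences
#' dropped). All-zero differences are degenerate: `p = 1`.
#'
#' @param scores_a,scores_b numeric vectors of equal length, matched order
#'   (`n >= 4` after NA removal - the Shapiro-Wilk minimum plus one).
#' @param alpha normality-test level (default 0.05).
#' @return list with `test` (`"paired_t"`/`"wilcoxon_signed_rank"`/
#'   `"degenerate"`), `statistic`, `p`, `shapiro_p`, `degenerate`.
#' @export
compare_paired <- function(scores_a, scores_b, alpha = 0.05) {
  stopifnot(length(scores_a) == length(scores_b))
  keep <- !is.na(scores_a) & !is.na(scores_b)
  d <- scores_a[keep] - scores_b[keep]
  if (length(d) < 4L)
    stop("need >= 4 complete pairs", call. = FALSE)
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                shapiro_p = NA_real_, degenerate = TRUE))
  sw <- if (stats::sd(d) == 0) list(p.value = 0)  # constant nonzero shift
        else stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    ht <- stats::t.test(d)
    list(test = "paired_t", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro_p = sw$p.value, degenerate = FALSE)
  } else {
    dz <- d[d != 0]
    ht <- suppressWarnings(stats::wilcox.test(dz))
    list(test = "wilcoxon_signed_rank", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro_p = sw$p.value, degenerate = FALSE)
  }
}
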