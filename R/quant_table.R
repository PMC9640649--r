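#' Quantitation table (features x samples)
#'
#' A `quant_table` is a numeric matrix of log2 abundances with features in
#' rows and samples in columns; `NA` marks a missing (non-detected) cell.
#' Row and column names are mandatory and unique. This is the substrate of
#' imputation, differential testing and clustering.
#'
#' @param values numeric matrix (features x samples), `NA` = missing.
#' @param feature_ids,sample_ids optional character vectors overriding
#'   `rownames(values)` / `colnames(values)`.
#' @return an object of class `quant_table` (a named numeric matrix).
#' @export
quant_table <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("quant_table requires feature and sample ids", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("quant_table", class(values))
  values
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d features x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE],
                    6L), ...)
  invisible(x)
}

is_quant_table <- function(x) inherits(x, "quant_table")

as_quant_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Read / write a quantitation table as TSV
#'
#' The on-disk dialect: tab-separated, first column `feature_id`, remaining
#' columns one per sample, empty cell = missing value.
#'
#' @param path file path.
#' @param x a [quant_table()].
#' @return `read_quant_table` returns a `quant_table`;
#'   `write_quant_table` returns `path` invisibly.
#' @export
read_quant_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE)
  if (ncol(dt) < 2L) stop("quant table TSV needs >= 2 columns", call. = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  quant_table(m, feature_ids = as.character(dt[[1L]]),
              sample_ids = colnames(dt)[-1L])
}

#' @rdname read_quant_table
#' @export
write_quant_table <- function(x, path) {
  stopifnot(is_quant_table(x))
  dt <- data.table::data.table(feature_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(as_quant_matrix(x)))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read / write sample group labels
#'
#' Two-column TSV `sample_id`, `group` with groups `pos` (pN+) / `neg` (pN0).
#'
#' @param labels named character vector (names = sample ids, values
#'   `"pos"`/`"neg"`).
#' @param path file path.
#' @export
write_group_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  data.table::fwrite(
    data.table::data.table(sample_id = names(labels), group = unname(labels)),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_group_labels
#' @export
read_group_labels <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  stats::setNames(as.character(dt$group), as.character(dt$sample_id))
}

check_group_labels <- function(labels, sample_ids) {
  if (is.null(names(labels))) stop("labels must be named by sample id",
                                   call. = FALSE)
  unknown <- setdiff(names(labels), sample_ids)
  if (length(unknown))
    stop("unknown sample id(s) in labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  labels <- labels[intersect(sample_ids, names(labels))]
  if (!all(labels %in% c("pos", "neg")))
    stop('group labels must be "pos" or "neg"', call. = FALSE)
  if (!any(labels == "pos") || !any(labels == "neg"))
    stop("both groups must be nonempty", call. = FALSE)
  labels
}

# Deterministic 31-bit seed derivation from a base seed plus arbitrary
# string/integer tokens (polynomial rolling hash; stable across platforms).
derive_seed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647L)
  for (tok in tokens) {
    for (cp in utf8ToInt(tok)) {
      h <- (h * 131 + cp) %% 2147483647
    }
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
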