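#' @keywords internal
cluster_metrics <- c("braycurtis", "canberra", "chebyshev", "cityblock",
                     "correlation", "cosine", "dice", "euclidean", "hamming",
                     "jaccard", "jensenshannon", "kulsinski", "mahalanobis",
                     "yule", "matching", "minkowski", "rogerstanimoto",
                     "russellrao", "seuclidean", "sokalmichener",
                     "sokalsneath", "sqeuclidean")

cluster_binary_metrics <- c("dice", "jaccard", "kulsinski", "matching",
                            "rogerstanimoto", "russellrao", "sokalmichener",
                            "sokalsneath", "yule", "hamming")

cluster_methods <- c("complete", "weighted", "ward")

#' Pairwise distances under the clustering-grid metric vocabulary
#'
#' Computes the distance matrix between the rows of `x` for any of the 22
#' supported metrics (SciPy-compatible definitions). The ten binary/set
#' metrics expect a logical detection-mask matrix; continuous metrics
#' expect numeric data. `minkowski` uses `p = 2` unless given;
#' `seuclidean` standardizes by per-column sample variances of `x`;
#' `jensenshannon` requires nonnegative rows; `mahalanobis` requires a
#' non-singular column covariance.
#'
#' @param x numeric (or logical for binary metrics) matrix, items in rows.
#' @param metric one of `cluster_grid_metrics()`.
#' @param p Minkowski exponent (default 2).
#' @return a `dist` object over rows of `x`.
#' @export
pairwise_distances <- function(x, metric, p = 2) {
  metric <- match.arg(metric, cluster_metrics)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two items", call. = FALSE)
  if (metric %in% cluster_binary_metrics) {
    m <- (x != 0) * 1
    a <- tcrossprod(m)                 # both present
    d <- tcrossprod(1 - m)             # both absent
    b <- tcrossprod(m, 1 - m)          # in i, not in j
    cc <- t(b)
    n <- ncol(m)
    R <- b + cc
    dm <- switch(metric,
      dice = R / (2 * a + R),
      jaccard = ifelse(a + R == 0, 0, R / (a + R)),
      hamming = ,
      matching = R / n,
      kulsinski = (R - a + n) / (R + n),
      rogerstanimoto = 2 * R / (n + R),
      russellrao = (n - a) / n,
      sokalmichener = 2 * R / (n + R),
      sokalsneath = ifelse(a == 0 & R == 0, 0, 2 * R / (a + 2 * R)),
      yule = ifelse(b * cc == 0, 0, 2 * b * cc / (a * d + b * cc)))
    dm[is.nan(dm)] <- 0
    return(stats::as.dist(dm))
  }
  storage.mode(x) <- "double"
  switch(metric,
    braycurtis = {
      n <- nrow(x)
      dm <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dm[j, i] <- dm[i, j] <- sum(abs(x[i, ] - x[j, ])) /
          sum(abs(x[i, ] + x[j, ]))
      }
      stats::as.dist(dm)
    },
    euclidean = stats::dist(x, "euclidean"),
    sqeuclidean = stats::dist(x, "euclidean")^2,
    cityblock = stats::dist(x, "manhattan"),
    chebyshev = stats::dist(x, "maximum"),
    canberra = {
      # SciPy convention: sum |u-v| / (|u|+|v|), 0/0 terms contribute 0
      n <- nrow(x)
      dm <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        num <- abs(x[i, ] - x[j, ])
        den <- abs(x[i, ]) + abs(x[j, ])
        term <- ifelse(den == 0, 0, num / den)
        dm[j, i] <- dm[i, j] <- sum(term)
      }
      stats::as.dist(dm)
    },
    minkowski = stats::dist(x, "minkowski", p = p),
    seuclidean = {
      v <- apply(x, 2L, stats::var)
      if (any(v == 0))
        stop("seuclidean: zero-variance column", call. = FALSE)
      stats::dist(sweep(x, 2L, sqrt(v), "/"), "euclidean")
    },
    correlation = {
      xc <- x - rowMeans(x)
      stats::as.dist(1 - tcrossprod(xc / sqrt(rowSums(xc^2))))
    },
    cosine = stats::as.dist(1 - tcrossprod(x / sqrt(rowSums(x^2)))),
    jensenshannon = {
      if (any(x < 0))
        stop("jensenshannon requires nonnegative data", call. = FALSE)
      pr <- x / rowSums(x)
      n <- nrow(pr)
      kl <- function(a, b) {
        keep <- a > 0
        sum(a[keep] * log(a[keep] / b[keep]))
      }
      dm <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        m <- (pr[i, ] + pr[j, ]) / 2
        dm[j, i] <- dm[i, j] <- sqrt((kl(pr[i, ], m) + kl(pr[j, ], m)) / 2)
      }
      stats::as.dist(dm)
    },
    mahalanobis = {
      vi <- tryCatch(solve(stats::cov(x)), error = function(e)
        stop("mahalanobis: singular covariance", call. = FALSE))
      n <- nrow(x)
      dm <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dd <- x[i, ] - x[j, ]
        dm[j, i] <- dm[i, j] <- sqrt(drop(dd %*% vi %*% dd))
      }
      stats::as.dist(dm)
    })
}

#' @rdname pairwise_distances
#' @export
cluster_grid_metrics <- function() cluster_metrics

#' @rdname pairwise_distances
#' @export
cluster_grid_methods <- function() cluster_methods

hclust_method_of <- c(complete = "complete", weighted = "mcquitty",
                      ward = "ward.D2")

# Metrics whose distances ward (minimum-variance) linkage is defined for.
ward_compatible <- c("euclidean", "seuclidean", "sqeuclidean", "minkowski")

#' Hierarchical clustering for one linkage-method / metric cell
#'
#' @param x items-in-rows matrix (use the detection mask for binary
#'   metrics).
#' @param method one of `"complete"`, `"weighted"` (WPGMA), `"ward"`.
#' @param metric one of [cluster_grid_metrics()].
#' @param k number of flat groups to cut (default 2).
#' @param ward_strict if `TRUE` (default), ward with a non-Euclidean-family
#'   metric is refused as unsupported; set `FALSE` to force the
#'   generic-library behavior of applying ward to any distance matrix.
#' @return a `cluster_assignment` list: `labels` (named `C1`, `C2`, ...,
#'   `C1` = largest group), `k`, `method`, `metric`, `tree` (hclust),
#'   `heights`.
#' @export
linkage_cluster <- function(x, method, metric, k = 2L, ward_strict = TRUE) {
  method <- match.arg(method, cluster_methods)
  metric <- match.arg(metric, cluster_metrics)
  if (method == "ward" && ward_strict && !(metric %in% ward_compatible))
    stop(sprintf("ward linkage unsupported for metric '%s'", metric),
         call. = FALSE)
  d <- pairwise_distances(x, metric)
  tree <- stats::hclust(d, method = hclust_method_of[[method]])
  out <- cut_groups(tree, k)
  out$method <- method
  out$metric <- metric
  out
}

#' Cut a linkage tree into k flat groups
#'
#' Groups are relabeled by decreasing size: `C1` is the largest cluster
#' (ties broken by first item in input order).
#'
#' @param tree an `hclust` object.
#' @param k number of groups, `1 <= k <= n_items`.
#' @return a `cluster_assignment` list.
#' @export
cut_groups <- function(tree, k = 2L) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n)
    stop("k must lie in [1, n_items]", call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first_seen <- vapply(names(sizes),
                       function(g) which(raw == g)[1L], integer(1))
  ord <- order(-as.integer(sizes), first_seen)
  relabel <- stats::setNames(paste0("C", seq_len(k)), names(sizes)[ord])
  structure(list(item_ids = names(raw),
                 labels = stats::setNames(relabel[as.character(raw)],
                                          names(raw)),
                 k = as.integer(k), method = NULL, metric = NULL,
                 tree = tree, heights = tree$height),
            class = "cluster_assignment")
}

#' Run the full linkage-method x metric clustering grid
#'
#' Evaluates every requested (method, metric) combination on the imputed
#' matrix - binary metrics on the supplied detection mask instead - and
#' isolates per-cell failures (singular covariance, unsupported ward
#' cells, ...) without aborting the grid.
#'
#' @param table complete (imputed) [quant_table()].
#' @param axis cluster `"samples"` (default) or `"features"`.
#' @param methods,metrics subsets of the supported grids (defaults: all).
#' @param mask optional logical detection-mask matrix with `table`'s
#'   dimensions (required by the ten binary metrics).
#' @param k number of flat groups (default 2).
#' @param ward_strict see [linkage_cluster()].
#' @param binary_on_values compatibility flag: apply binary metrics to the
#'   continuous values (0 = absent) instead of the mask.
#' @return list with `cells` (named `method:metric` list of
#'   `cluster_assignment` or error record) and `summary` data.frame.
#' @export
linkage_grid <- function(table, axis = c("samples", "features"),
                         methods = cluster_methods,
                         metrics = cluster_metrics, mask = NULL, k = 2L,
                         ward_strict = TRUE, binary_on_values = FALSE) {
  stopifnot(is_quant_table(table))
  axis <- match.arg(axis)
  methods <- match.arg(methods, cluster_methods, several.ok = TRUE)
  metrics <- match.arg(metrics, cluster_metrics, several.ok = TRUE)
  x <- as_quant_matrix(table)
  if (anyNA(x)) stop("grid requires a complete (imputed) table",
                     call. = FALSE)
  if (axis == "samples") x <- t(x)
  if (nrow(x) < 2L) stop("need at least two items to cluster",
                         call. = FALSE)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(as_quant_matrix(table))))
      stop("mask dimensions must match the table", call. = FALSE)
    if (axis == "samples") mask <- t(mask)
  }
  cells <- list()
  rows <- list()
  for (method in methods) for (metric in metrics) {
    key <- paste(method, metric, sep = ":")
    input <- if (metric %in% cluster_binary_metrics && !binary_on_values) {
      if (is.null(mask)) {
        cells[[key]] <- list(error = "binary metric requires a detection mask")
        rows[[key]] <- data.frame(method = method, metric = metric,
                                  ok = FALSE,
                                  note = "no detection mask supplied")
        next
      }
      mask * 1
    } else x
    res <- tryCatch(
      linkage_cluster(input, method, metric, k = k,
                      ward_strict = ward_strict),
      error = function(e) list(error = conditionMessage(e)))
    cells[[key]] <- res
    rows[[key]] <- data.frame(
      method = method, metric = metric,
      ok = inherits(res, "cluster_assignment"),
      note = if (inherits(res, "cluster_assignment")) "" else res$error)
  }
  list(cells = cells,
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's. A table with any zero margin is degenerate:
#' `p = 1` with `degenerate = TRUE`.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(table, alternative = "two.sided")$p.value,
       degenerate = FALSE)
}

#' Associate a 2-group clustering with categorical covariates
#'
#' For each covariate, levels are dichotomized against the modal level
#' (multi-level covariates become modal vs rest) and tested against the
#' `C1`/`C2` assignment with the two-sided Fisher exact test.
#' Single-level (constant) covariates are skipped with a note.
#'
#' @param assignment a `cluster_assignment` with `k = 2`.
#' @param covariates data.frame of categorical covariates, rownames =
#'   item ids (or a `sample_id` column).
#' @param alpha significance flag level (default 0.05).
#' @return data.frame with one row per covariate: `covariate`, `level`
#'   (tested dichotomy), the 2x2 counts `n11`, `n12`, `n21`, `n22`, `p`,
#'   `significant`, `note`.
#' @export
associate_clusters <- function(assignment, covariates, alpha = 0.05) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$k != 2L)
    stop("association requires a 2-group assignment", call. = FALSE)
  if ("sample_id" %in% colnames(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  ids <- intersect(assignment$item_ids, rownames(covariates))
  if (length(ids) == 0L)
    stop("no overlap between assignment items and covariate rows",
         call. = FALSE)
  cl <- assignment$labels[ids]
  out <- lapply(colnames(covariates), function(cv) {
    v <- covariates[ids, cv]
    keep <- !is.na(v)
    v <- as.character(v[keep])
    cls <- cl[keep]
    lev <- unique(v)
    if (length(lev) < 2L)
      return(data.frame(covariate = cv, level = NA_character_,
                        n11 = NA_integer_, n12 = NA_integer_,
                        n21 = NA_integer_, n22 = NA_integer_, p = NA_real_,
                        significant = NA,
                        note = "constant covariate - skipped"))
    modal <- names(sort(table(v), decreasing = TRUE))[1L]
    bin <- ifelse(v == modal, modal, paste0("not_", modal))
    tab <- table(factor(cls, c("C1", "C2")),
                 factor(bin, c(modal, paste0("not_", modal))))
    ft <- fisher_exact_2x2(tab)
    data.frame(covariate = cv, level = modal,
               n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1],
               n22 = tab[2, 2], p = ft$p,
               significant = !ft$degenerate && ft$p <= alpha,
               note = if (ft$degenerate) "degenerate margin" else "")
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Export an hclust tree as Newick text
#'
#' Nested-parenthesis text with merge heights as branch lengths, for
#' external inspection of dendrograms.
#'
#' @param tree an `hclust` object.
#' @return a single Newick string (terminated by `;`).
#' @export
hclust_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  lab <- if (is.null(tree$labels)) as.character(seq_along(tree$order))
         else tree$labels
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_h))
    h <- tree$height[i]
    sprintf("(%s,%s):%g", node(tree$merge[i, 1], h),
            node(tree$merge[i, 2], h), parent_h - h)
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);", node(tree$merge[root, 1], h),
          node(tree$merge[root, 2], h))
}

#' Adjusted Rand index between two flat clusterings
#'
#' @param a,b label vectors of equal length (any label types).
#' @return ARI in `[-1, 1]`; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
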