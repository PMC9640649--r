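#' Classifier families of the signature search
#'
#' The ten supported families, in canonical order (used for top-1
#' tie-breaking). Hyperparameters are fixed per run and recorded in the
#' output; defaults: ridge/lasso regularization 1.0/0.05, linear SVM
#' lambda 0.01 with 200 subgradient epochs, perceptron 100 averaged
#' epochs, decision tree depth 3, GBM 100 stages of depth-2 trees with
#' shrinkage 0.1, random forest 100 trees, RBF SVM (least-squares form)
#' C = 1 with gamma = 1/(V * var).
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("ridge", "linear_svm", "lasso", "linear_discriminant", "perceptron",
    "decision_tree", "naive_bayes", "gbm", "random_forest", "rbf_svm")
}

#' Fixed-hyperparameter classifier specification
#'
#' @param family one of [classifier_families()].
#' @param ... hyperparameter overrides (`lambda`, `epochs`, `max_depth`,
#'   `n_stages`, `shrinkage`, `n_trees`, `C`, `gamma`).
#' @param standardize standardize features within each training fold
#'   (default `FALSE`; the reference pipeline applies no scaling beyond
#'   zero-substitution).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(family, ..., standardize = FALSE) {
  family <- match.arg(family, classifier_families())
  structure(list(family = family, params = list(...),
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Train on one split and score another (single-shot interface)
#'
#' Thin wrapper over the compiled engine, exposed for direct use and for
#' testing the families in isolation. Scores are continuous decision
#' values with `score > 0` predicting the positive class.
#'
#' @param spec a [classifier_spec()].
#' @param x_train,x_test numeric matrices (samples x variables).
#' @param y_train 0/1 integer labels (1 = positive/pN+).
#' @param seed integer seed (consumed by the random forest only).
#' @return numeric score vector for `x_test` rows.
#' @export
train_score <- function(spec, x_train, y_train, x_test, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  if (spec$standardize) {
    mu <- colMeans(x_train)
    sdev <- apply(x_train, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    x_train <- sweep(sweep(x_train, 2L, mu), 2L, sdev, "/")
    x_test <- sweep(sweep(x_test, 2L, mu), 2L, sdev, "/")
  }
  as.numeric(cpp_train_score(x_train, as.integer(y_train), x_test,
                             spec$family, spec$params, as.integer(seed)))
}

#' Cross-validation configuration
#'
#' `R` repetitions of stratified `K`-fold cross-validation. Following the
#' reference design, `K` defaults to the smallest class size (so every
#' fold holds at least one sample of the minority class), giving exactly
#' `R * K` trained models per signature-classifier pair.
#'
#' @param R repetitions (default 10).
#' @param K folds; `NULL` (default) = smallest class size, resolved
#'   against the labels at run time. Must satisfy `2 <= K <= smallest
#'   class size`.
#' @param base_seed integer seed driving all fold partitions.
#' @param n_permutations permutation-test size (default 100).
#' @return a `cv_config` list.
#' @export
cv_config <- function(R = 10L, K = NULL, base_seed = 1L,
                      n_permutations = 100L) {
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  structure(list(R = as.integer(R),
                 K = if (is.null(K)) NULL else as.integer(K),
                 base_seed = as.integer(base_seed),
                 n_permutations = as.integer(n_permutations)),
            class = "cv_config")
}

resolve_k <- function(cv, y) {
  smallest <- min(sum(y == 1L), sum(y == 0L))
  K <- if (is.null(cv$K)) smallest else cv$K
  if (K > smallest)
    stop("K exceeds the smallest class size", call. = FALSE)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  K
}

# R x n matrix of stratified fold ids; repetition r is seeded from
# (seed, r) so partitions are shared across all pairs evaluated under the
# same config.
stratified_folds <- function(y, R, K, seed) {
  n <- length(y)
  folds <- matrix(0L, R, n)
  for (r in seq_len(R)) {
    folds[r, ] <- with_seed(derive_seed(seed, "fold", r), {
      f <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- sample(which(y == cls))
        f[idx] <- rep_len(seq_len(K), length(idx))
      }
      f
    })
  }
  folds
}

#' ROC AUC from continuous scores
#'
#' Rank-based (Mann-Whitney) AUC with ties contributing 0.5; the positive
#' class is scored as label 1.
#'
#' @param scores numeric decision values.
#' @param y 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @param scores,y as in [roc_auc()].
#' @return data.frame with `threshold`, `fpr`, `tpr` (descending
#'   thresholds).
#' @export
roc_curve <- function(scores, y) {
  y <- as.integer(y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  thr <- scores[ord]
  keep <- !duplicated(thr, fromLast = TRUE)
  tpr <- cumsum(ys) / sum(ys)
  fpr <- cumsum(1 - ys) / sum(1 - ys)
  data.frame(threshold = c(Inf, thr[keep]), fpr = c(0, fpr[keep]),
             tpr = c(0, tpr[keep]))
}

#' Prepare a panel table for the signature search
#'
#' Transposes a variables-x-samples [quant_table()] into the samples-x-
#' variables design matrix, replacing missing values with 0 (the reference
#' preprocessing for targeted-panel data) and encoding labels as 1 = pN+.
#'
#' @param table a variables-x-samples [quant_table()].
#' @param labels named `"pos"`/`"neg"` vector.
#' @return list with `x` (samples x variables matrix, no missing values),
#'   `y` (0/1 integer), `variable_ids`, `sample_ids`.
#' @export
prepare_panel <- function(table, labels) {
  stopifnot(is_quant_table(table))
  labels <- check_group_labels(labels, colnames(table))
  ids <- names(labels)
  x <- t(as_quant_matrix(table)[, ids, drop = FALSE])
  x[is.na(x)] <- 0
  list(x = x, y = as.integer(labels == "pos"),
       variable_ids = rownames(table), sample_ids = ids)
}

#' Count and enumerate candidate signatures
#'
#' All nonempty variable subsets of size 1..`max_size`, in deterministic
#' order (by size, then lexicographically by variable position). The count
#' is the binomial-coefficient sum `sum_k C(V, k)`.
#'
#' @param variable_ids character vector of panel variables.
#' @param max_size maximum signature size (default 5).
#' @return `enumerate_signatures`: list of character vectors.
#'   `count_signatures`: the exact count (double).
#' @export
enumerate_signatures <- function(variable_ids, max_size = 5L) {
  n_total <- count_signatures(variable_ids, max_size)
  if (n_total > 5e5)
    stop("refusing to materialize ", n_total,
         " signatures; use iterate_signatures()", call. = FALSE)
  out <- vector("list", n_total)
  pos <- 0L
  iterate_signatures(variable_ids, max_size, function(sig) {
    pos <<- pos + 1L
    out[[pos]] <<- sig
  })
  out
}

#' @rdname enumerate_signatures
#' @export
count_signatures <- function(variable_ids, max_size = 5L) {
  V <- length(variable_ids)
  if (V == 0L) stop("empty variable list", call. = FALSE)
  if (max_size < 1L) stop("max_size must be >= 1", call. = FALSE)
  sum(choose(V, seq_len(min(max_size, V))))
}

#' @rdname enumerate_signatures
#' @param f callback applied to each signature (streaming; nothing is
#'   materialized).
#' @export
iterate_signatures <- function(variable_ids, max_size = 5L, f) {
  V <- length(variable_ids)
  if (V == 0L) stop("empty variable list", call. = FALSE)
  if (max_size < 1L) stop("max_size must be >= 1", call. = FALSE)
  for (k in seq_len(min(max_size, V))) {
    idx <- seq_len(k)
    repeat {
      f(variable_ids[idx])
      # next lexicographic k-combination of 1..V
      j <- k
      while (j >= 1L && idx[j] == V - k + j) j <- j - 1L
      if (j < 1L) break
      idx[j] <- idx[j] + 1L
      if (j < k) idx[(j + 1L):k] <- idx[j] + seq_len(k - j)
    }
  }
  invisible(NULL)
}

signature_key <- function(sig) paste(sig, collapse = "+")

#' Cross-validated AUC distribution for one signature-classifier pair
#'
#' For each repetition, the out-of-fold continuous scores of all K folds
#' are pooled into a single ROC AUC (with K = smallest class size a fold
#' holds one minority sample, so per-fold AUC is ill-defined); the R
#' pooled AUCs form the pair's AUC distribution. Hard predictions
#' (score > 0) pooled over all R*K folds give sensitivity, specificity
#' and precision. Exactly `R * K` models are trained.
#'
#' @param panel a [prepare_panel()] result.
#' @param signature character vector of variable ids.
#' @param classifier a [classifier_spec()] or family name.
#' @param cv a [cv_config()].
#' @param folds optional precomputed fold matrix (shared across pairs).
#' @param per_fold compute one AUC per fold instead of pooling (only
#'   meaningful when folds hold several samples per class).
#' @return a `pair_evaluation` list: `signature`, `classifier`,
#'   `auc_values`, `mean_auc`, `sensitivity`, `specificity`, `precision`,
#'   `models_trained`, plus selection fields filled by later stages.
#' @export
cv_auc_distribution <- function(panel, signature, classifier, cv = cv_config(),
                                folds = NULL, per_fold = FALSE) {
  if (!inherits(classifier, "classifier_spec"))
    classifier <- classifier_spec(classifier)
  missing_vars <- setdiff(signature, panel$variable_ids)
  if (length(missing_vars))
    stop("unknown signature variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  y <- panel$y
  K <- resolve_k(cv, y)
  if (is.null(folds))
    folds <- stratified_folds(y, cv$R, K, cv$base_seed)
  x <- panel$x[, signature, drop = FALSE]
  scores <- if (classifier$standardize) {
    cv_scores_standardized(x, y, folds, classifier)
  } else {
    cpp_cv_scores(x, as.integer(y), folds, classifier$family,
                  classifier$params, cv$base_seed)
  }
  auc <- if (per_fold) {
    unlist(lapply(seq_len(nrow(folds)), function(r) {
      vapply(seq_len(max(folds[r, ])), function(k) {
        sel <- folds[r, ] == k
        if (length(unique(y[sel])) < 2L) return(NA_real_)
        roc_auc(scores[r, sel], y[sel])
      }, numeric(1))
    }))
  } else {
    apply(scores, 1L, roc_auc, y = y)
  }
  pred <- scores > 0
  tp <- sum(pred & rep(y == 1L, each = nrow(folds)))
  fp <- sum(pred & rep(y == 0L, each = nrow(folds)))
  fn <- sum(!pred & rep(y == 1L, each = nrow(folds)))
  tn <- sum(!pred & rep(y == 0L, each = nrow(folds)))
  structure(list(signature = signature, classifier = classifier,
                 auc_values = as.numeric(stats::na.omit(auc)),
                 mean_auc = mean(auc, na.rm = TRUE),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 models_trained = nrow(folds) * K,
                 equivalence_p = NA_real_, permutation_p = NA_real_,
                 is_top1 = FALSE, selected = FALSE,
                 high_performance = FALSE),
            class = "pair_evaluation")
}

# slow path used only when within-fold standardization is requested
cv_scores_standardized <- function(x, y, folds, classifier) {
  scores <- matrix(0, nrow(folds), length(y))
  for (r in seq_len(nrow(folds))) {
    for (k in seq_len(max(folds[r, ]))) {
      te <- folds[r, ] == k
      scores[r, te] <- train_score(classifier, x[!te, , drop = FALSE],
                                   y[!te], x[te, , drop = FALSE],
                                   seed = r * 131L + k)
    }
  }
  scores
}

#' Evaluate every signature x classifier pair
#'
#' Fold partitions are generated once per repetition from the config seed
#' and shared across all pairs, so AUC distributions are comparable
#' between pairs.
#'
#' @param panel a [prepare_panel()] result.
#' @param candidates list of signatures (from [enumerate_signatures()]).
#' @param classifiers list of [classifier_spec()]s or family names.
#' @param cv a [cv_config()].
#' @param on_error `"record"` (default) stores the error message and
#'   continues; `"stop"` aborts.
#' @return list of `pair_evaluation` objects (failed pairs carry
#'   `$error`).
#' @export
evaluate_all_pairs <- function(panel, candidates, classifiers,
                               cv = cv_config(), on_error = "record") {
  classifiers <- lapply(classifiers, function(cl)
    if (inherits(cl, "classifier_spec")) cl else classifier_spec(cl))
  K <- resolve_k(cv, panel$y)
  folds <- stratified_folds(panel$y, cv$R, K, cv$base_seed)
  out <- vector("list", length(candidates) * length(classifiers))
  pos <- 0L
  for (sig in candidates) {
    for (cl in classifiers) {
      pos <- pos + 1L
      out[[pos]] <- tryCatch(
        cv_auc_distribution(panel, sig, cl, cv, folds = folds),
        error = function(e) {
          if (identical(on_error, "stop")) stop(e)
          structure(list(signature = sig, classifier = cl,
                         error = conditionMessage(e)),
                    class = "pair_evaluation")
        })
    }
  }
  out
}

#' Mark the top-1 pair and all statistically equivalent pairs
#'
#' The pair with the highest mean AUC is top-1 (ties: smaller signature,
#' then lexicographic signature, then classifier family order). Every
#' other pair's R AUC values are compared to the top-1's with a two-sided
#' equal-variance t-test; pairs with `p >= 0.05` (cannot be distinguished
#' from the best) are selected alongside top-1. Two identical constant
#' AUC vectors are equivalent by definition (`p = 1`); if either vector
#' has zero variance the test degenerates to exact equality of means.
#'
#' @param evaluations list of `pair_evaluation`s (failed pairs passed
#'   through unselected).
#' @param alpha equivalence threshold (default 0.05).
#' @return the list with `is_top1`, `equivalence_p`, `selected` filled.
#' @export
select_equivalent_to_top1 <- function(evaluations, alpha = 0.05) {
  ok <- which(vapply(evaluations, function(e) is.null(e$error), logical(1)))
  if (length(ok) == 0L) stop("no successful evaluations", call. = FALSE)
  fam_rank <- stats::setNames(seq_along(classifier_families()),
                              classifier_families())
  keys <- vapply(evaluations[ok], function(e) signature_key(e$signature),
                 character(1))
  ordering <- order(
    -vapply(evaluations[ok], `[[`, numeric(1), "mean_auc"),
    vapply(evaluations[ok], function(e) length(e$signature), integer(1)),
    keys,
    fam_rank[vapply(evaluations[ok], function(e) e$classifier$family,
                    character(1))])
  top_idx <- ok[ordering[1L]]
  top <- evaluations[[top_idx]]
  for (i in ok) {
    e <- evaluations[[i]]
    if (i == top_idx) {
      e$is_top1 <- TRUE
      e$equivalence_p <- 1
      e$selected <- TRUE
    } else {
      e$equivalence_p <- auc_equivalence_p(e$auc_values, top$auc_values)
      e$selected <- e$equivalence_p >= alpha
    }
    evaluations[[i]] <- e
  }
  evaluations
}

auc_equivalence_p <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                   error = function(e) NA_real_)
    if (!is.na(tt)) return(tt)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Permutation p-value for one signature-classifier pair
#'
#' Tests independence between the pair's data and the class labels: the
#' observed mean CV AUC is compared against the same full CV pipeline run
#' on label permutations (fold partitions re-stratified per permutation).
#' `p = (1 + #permutations >= observed) / (n_permutations + 1)`, so the
#' smallest achievable value is `1/(n_permutations + 1)`.
#'
#' @param panel a [prepare_panel()] result.
#' @param signature,classifier,cv as in [cv_auc_distribution()].
#' @param n_permutations default from `cv$n_permutations`.
#' @return list with `p`, `observed`, `permuted` (mean AUC per
#'   permutation).
#' @export
permutation_pvalue <- function(panel, signature, classifier,
                               cv = cv_config(),
                               n_permutations = cv$n_permutations) {
  if (n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  observed <- cv_auc_distribution(panel, signature, classifier, cv)$mean_auc
  key <- signature_key(signature)
  permuted <- vapply(seq_len(n_permutations), function(b) {
    yp <- with_seed(derive_seed(cv$base_seed, "perm", key, b),
                    sample(panel$y))
    panel_p <- panel
    panel_p$y <- yp
    cvp <- cv
    cvp$base_seed <- derive_seed(cv$base_seed, "permfold", b)
    cv_auc_distribution(panel_p, signature, classifier, cvp)$mean_auc
  }, numeric(1))
  list(p = (1 + sum(permuted >= observed)) / (n_permutations + 1),
       observed = observed, permuted = permuted)
}

#' Filter selected pairs to high-performance candidates
#'
#' High performance requires selection (top-1 or equivalent), mean AUC at
#' least `auc_min` and permutation p at most `perm_alpha` (both bounds
#' inclusive).
#'
#' @param evaluations list of `pair_evaluation`s with `selected` and
#'   `permutation_p` populated.
#' @param auc_min AUC gate (default 0.85).
#' @param perm_alpha permutation-p gate (default 0.05).
#' @return list of the high-performance `pair_evaluation`s (flag set).
#' @export
high_performance_filter <- function(evaluations, auc_min = 0.85,
                                    perm_alpha = 0.05) {
  kept <- list()
  for (e in evaluations) {
    if (!is.null(e$error) || !isTRUE(e$selected)) next
    if (is.na(e$permutation_p)) next
    if (e$mean_auc >= auc_min && e$permutation_p <= perm_alpha) {
      e$high_performance <- TRUE
      kept[[length(kept) + 1L]] <- e
    }
  }
  kept
}

#' Marker frequency across high-performance signatures
#'
#' Percentage of distinct high-performance signatures containing each
#' variable, sorted decreasingly.
#'
#' @param evaluations list of high-performance `pair_evaluation`s.
#' @return named numeric vector of percentages (empty for empty input).
#' @export
marker_frequency <- function(evaluations) {
  sigs <- unique(lapply(evaluations, `[[`, "signature"))
  if (length(sigs) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(unlist(sigs))
  freq <- stats::setNames(100 * as.vector(tab) / length(sigs), names(tab))
  sort(freq, decreasing = TRUE)
}

#' Run the full signature search
#'
#' Enumerates signatures, evaluates every pair under shared CV folds,
#' selects top-1 and equivalents, computes permutation p-values for the
#' selected pairs that can still reach the AUC gate, applies the
#' high-performance filter and tabulates marker frequencies.
#'
#' @param table variables-x-samples [quant_table()] of the panel.
#' @param labels named `"pos"`/`"neg"` vector.
#' @param max_size maximum signature size (default 5).
#' @param classifiers classifier family names or specs (default: all ten).
#' @param cv a [cv_config()].
#' @param auc_min,perm_alpha high-performance gates (defaults 0.85, 0.05).
#' @return list with `evaluations` (all pairs), `top1`,
#'   `high_performance`, `marker_frequency`, `summary` (data.frame),
#'   `roc_top1` (pooled ROC coordinates of the top-1 pair's first
#'   repetition).
#' @export
run_signature_search <- function(table, labels, max_size = 5L,
                                 classifiers = classifier_families(),
                                 cv = cv_config(), auc_min = 0.85,
                                 perm_alpha = 0.05) {
  panel <- prepare_panel(table, labels)
  candidates <- enumerate_signatures(panel$variable_ids, max_size)
  evals <- evaluate_all_pairs(panel, candidates, classifiers, cv)
  evals <- select_equivalent_to_top1(evals)
  for (i in seq_along(evals)) {
    e <- evals[[i]]
    if (is.null(e$error) && isTRUE(e$selected) && e$mean_auc >= auc_min) {
      evals[[i]]$permutation_p <-
        permutation_pvalue(panel, e$signature, e$classifier, cv)$p
    }
  }
  hp <- high_performance_filter(evals, auc_min, perm_alpha)
  top1 <- evals[[which(vapply(evals, function(e) isTRUE(e$is_top1),
                              logical(1)))[1L]]]
  folds <- stratified_folds(panel$y, cv$R, resolve_k(cv, panel$y),
                            cv$base_seed)
  top_scores <- cpp_cv_scores(
    panel$x[, top1$signature, drop = FALSE], as.integer(panel$y), folds,
    top1$classifier$family, top1$classifier$params, cv$base_seed)
  list(evaluations = evals, top1 = top1, high_performance = hp,
       marker_frequency = marker_frequency(hp),
       summary = evaluation_summary(evals),
       roc_top1 = roc_curve(top_scores[1L, ], panel$y))
}

#' Tabulate pair evaluations
#'
#' @param evaluations list of `pair_evaluation`s.
#' @return data.frame with one row per pair.
#' @export
evaluation_summary <- function(evaluations) {
  rows <- lapply(evaluations, function(e) {
    if (!is.null(e$error))
      return(data.frame(signature = signature_key(e$signature),
                        classifier = e$classifier$family, size =
                          length(e$signature), mean_auc = NA_real_,
                        sd_auc = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, precision = NA_real_,
                        equivalence_p = NA_real_, permutation_p = NA_real_,
                        is_top1 = FALSE, selected = FALSE,
                        high_performance = FALSE, error = e$error))
    data.frame(signature = signature_key(e$signature),
               classifier = e$classifier$family,
               size = length(e$signature), mean_auc = e$mean_auc,
               sd_auc = stats::sd(e$auc_values),
               sensitivity = e$sensitivity, specificity = e$specificity,
               precision = e$precision, equivalence_p = e$equivalence_p,
               permutation_p = e$permutation_p, is_top1 = e$is_top1,
               selected = e$selected,
               high_performance = e$high_performance, error = "")
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
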