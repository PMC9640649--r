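make_panel <- function(n_pos = 10, n_neg = 10, informative = "M1",
                       markers = paste0("M", 1:4), effect = 2, seed = 1) {
  p <- generate_marker_panel(panel_config(
    markers = markers, layers = "protein",
    informative_markers = informative, effect_size = effect,
    n_pos = n_pos, n_neg = n_neg, seed = seed))
  prepare_panel(p$table, p$labels)
}

test_that("prepare_panel zero-substitutes missing values", {
  labels <- make_labels(2, 2)
  m <- matrix(c(1, NA, 2, 3, NA, 4, 5, 6), 2,
              dimnames = list(c("v1", "v2"), names(labels)))
  panel <- prepare_panel(quant_table(m), labels)
  expect_false(anyNA(panel$x))
  expect_identical(panel$x["POS002", "v1"], 2)
  expect_identical(panel$x["POS001", "v2"], 0)
  expect_identical(panel$y, c(1L, 1L, 0L, 0L))
})

test_that("signature enumeration counts and order match the binomial sums", {
  expect_identical(count_signatures(letters[1:6], 5), 62)
  expect_identical(count_signatures(letters[1:3], 5), 7)
  expect_identical(count_signatures(letters[1:3], 1), 3)
  sigs <- enumerate_signatures(letters[1:4], 3)
  expect_identical(length(sigs), 14L)  # 4 + 6 + 4
  expect_identical(sigs[[1]], "a")
  expect_identical(sigs[[5]], c("a", "b"))
  expect_identical(sigs[[length(sigs)]], c("b", "c", "d"))
  expect_identical(anyDuplicated(vapply(sigs, paste, "", collapse = "+")),
                   0L)
  # streaming count agrees with the closed form without materializing
  n <- 0
  iterate_signatures(letters[1:7], 4, function(s) n <<- n + 1)
  expect_identical(n, sum(choose(7, 1:4)))
  expect_error(enumerate_signatures(character(0)), "empty")
})

test_that("CV budget identity: R repetitions x K folds models per pair", {
  panel <- make_panel(n_pos = 7, n_neg = 12, seed = 2)
  cv <- cv_config(R = 10, base_seed = 5)
  expect_identical(resolve_k(cv, panel$y), 7L)
  ev <- cv_auc_distribution(panel, "M1|protein", "ridge", cv)
  expect_identical(ev$models_trained, 70L)
  expect_length(ev$auc_values, 10L)
  expect_error(cv_auc_distribution(panel, "M1|protein", "ridge",
                                   cv_config(R = 2, K = 8)), "smallest")
  expect_error(cv_auc_distribution(panel, "nope", "ridge", cv), "unknown")
})

test_that("roc_auc matches the pairwise oracle and its conventions", {
  set.seed(83)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)  # rounding forces ties
    expect_equal(roc_auc(s, y), auc_oracle(s, y))
    # flipping the labels - or the scores - maps AUC to 1 - AUC;
    # flipping both leaves it invariant (ties stay symmetric at 0.5)
    expect_equal(roc_auc(s, 1 - y), 1 - roc_auc(s, y))
    expect_equal(roc_auc(-s, y), 1 - roc_auc(s, y))
    expect_equal(roc_auc(-s, 1 - y), roc_auc(s, y))
  }
  expect_identical(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
})

test_that("perfect separator and constant variable hit the AUC bounds", {
  labels <- make_labels(6, 6)
  y <- as.integer(labels == "pos")
  set.seed(87)
  m <- rbind(copy = y + rnorm(12, 0, 1e-4), flat = rep(1, 12))
  colnames(m) <- names(labels)
  panel <- prepare_panel(quant_table(m), labels)
  cv <- cv_config(R = 5, base_seed = 3)
  for (fam in c("ridge", "linear_discriminant", "linear_svm")) {
    ev <- cv_auc_distribution(panel, "copy", fam, cv)
    expect_identical(unique(ev$auc_values), 1)
  }
  flat <- cv_auc_distribution(panel, "flat", "ridge", cv)
  expect_identical(unique(flat$auc_values), 0.5)
})

test_that("all ten classifier families learn an easy boundary", {
  panel <- make_panel(n_pos = 25, n_neg = 25, effect = 4, seed = 4)
  cv <- cv_config(R = 3, K = 5, base_seed = 7)
  for (fam in classifier_families()) {
    ev <- cv_auc_distribution(panel, c("M1|protein", "M2|protein"), fam, cv)
    expect_gt(ev$mean_auc, 0.8, label = fam)
    expect_true(is.finite(ev$sensitivity) && is.finite(ev$specificity))
  }
})

test_that("linear families agree with reference implementations", {
  set.seed(91)
  n <- 40
  x <- matrix(rnorm(n * 3), n)
  y <- as.integer(x %*% c(1, -1, 0.5) + rnorm(n, 0, 0.5) > 0)
  xt <- matrix(rnorm(20 * 3), 20)
  # LDA scores are monotone with MASS::lda posterior
  s <- train_score(classifier_spec("linear_discriminant"), x, y, xt)
  fit <- MASS::lda(x, grouping = y)
  post <- predict(fit, xt)$posterior[, "1"]
  expect_gt(cor(s, qlogis(pmin(pmax(post, 1e-12), 1 - 1e-12)),
                method = "spearman"), 0.999)
  # ridge matches the closed form computed independently
  lam <- 1
  xc <- scale(x, scale = FALSE)
  yy <- ifelse(y == 1, 1, -1)
  beta <- solve(crossprod(xc) + lam * diag(3), crossprod(xc, yy - mean(yy)))
  ref <- scale(xt, center = attr(xc, "scaled:center"),
               scale = FALSE) %*% beta + mean(yy)
  expect_equal(train_score(classifier_spec("ridge"), x, y, xt),
               drop(ref), tolerance = 1e-8)
  # lasso shrinks the irrelevant coefficient harder than ridge does
  s_lasso <- train_score(classifier_spec("lasso", lambda = 0.2), x, y, xt)
  expect_true(all(is.finite(s_lasso)))
})

test_that("evaluations share folds and are bitwise reproducible", {
  panel <- make_panel(seed = 5)
  cv <- cv_config(R = 4, K = 4, base_seed = 11)
  sigs <- enumerate_signatures(panel$variable_ids, 1)
  e1 <- evaluate_all_pairs(panel, sigs, c("ridge", "naive_bayes"), cv)
  e2 <- evaluate_all_pairs(panel, sigs, c("ridge", "naive_bayes"), cv)
  expect_identical(length(e1), 8L)
  expect_identical(vapply(e1, `[[`, 0, "mean_auc"),
                   vapply(e2, `[[`, 0, "mean_auc"))
  e3 <- evaluate_all_pairs(panel, sigs, "ridge",
                           cv_config(R = 4, K = 4, base_seed = 12))
  expect_false(identical(vapply(e1[c(1, 3, 5, 7)], `[[`, 0, "mean_auc"),
                         vapply(e3, `[[`, 0, "mean_auc")))
})

test_that("top-1 selection and equivalence follow the stated rules", {
  fake_eval <- function(sig, fam, aucs) {
    structure(list(signature = sig, classifier = classifier_spec(fam),
                   auc_values = aucs, mean_auc = mean(aucs),
                   sensitivity = NA_real_, specificity = NA_real_,
                   precision = NA_real_, models_trained = NA_integer_,
                   equivalence_p = NA_real_, permutation_p = NA_real_,
                   is_top1 = FALSE, selected = FALSE,
                   high_performance = FALSE), class = "pair_evaluation")
  }
  # degenerate-identical rule + obvious inferiority
  evs <- select_equivalent_to_top1(list(
    A = fake_eval("a", "ridge", rep(1, 10)),
    B = fake_eval("b", "lasso", rep(1, 10)),
    C = fake_eval("c", "ridge", rep(0.5, 10))))
  expect_true(evs$A$is_top1)   # tie: lexicographic signature, then family
  expect_true(evs$B$selected)
  expect_identical(evs$B$equivalence_p, 1)
  expect_false(evs$C$selected)
  expect_identical(evs$C$equivalence_p, 0)

  # drawn vectors: clearly different distributions are excluded
  set.seed(97)
  a <- rnorm(10, 0.9, 0.02)
  b <- rnorm(10, 0.6, 0.02)
  evs2 <- select_equivalent_to_top1(list(fake_eval("a", "ridge", a),
                                         fake_eval("b", "ridge", b)))
  expect_true(evs2[[1]]$is_top1)
  expect_false(evs2[[2]]$selected)
  expect_equal(evs2[[2]]$equivalence_p,
               t.test(b, a, var.equal = TRUE)$p.value)

  # single evaluation: top-1 and selected
  single <- select_equivalent_to_top1(list(fake_eval("x", "gbm", c(0.7,
                                                                   0.8))))
  expect_true(single[[1]]$is_top1 && single[[1]]$selected)

  # tie-break prefers the smaller signature
  evs3 <- select_equivalent_to_top1(list(
    fake_eval(c("a", "b"), "ridge", rep(0.9, 5)),
    fake_eval("z", "ridge", rep(0.9, 5))))
  expect_true(evs3[[2]]$is_top1)
})

test_that("permutation p hits its exact bounds", {
  # n chosen so a random permutation virtually never reproduces the
  # labeling (choose(20, 10) partitions)
  labels <- make_labels(10, 10)
  y <- as.integer(labels == "pos")
  set.seed(101)
  m <- rbind(copy = y + rnorm(20, 0, 1e-4))
  colnames(m) <- names(labels)
  panel <- prepare_panel(quant_table(m), labels)
  cv <- cv_config(R = 2, K = 5, base_seed = 13)
  r <- permutation_pvalue(panel, "copy", classifier_spec("ridge"), cv,
                          n_permutations = 99)
  expect_identical(r$p, 0.01)  # 1 / (99 + 1): perfect separation
  expect_identical(r$observed, 1)
  # observed at/below every permutation -> p = 1
  r_flat <- permutation_pvalue(
    prepare_panel(quant_table(matrix(1, 1, 20,
                                     dimnames = list("flat",
                                                     names(labels)))),
                  labels),
    "flat", classifier_spec("ridge"), cv, n_permutations = 19)
  expect_identical(r_flat$p, 1)
  expect_error(permutation_pvalue(panel, "copy",
                                  classifier_spec("ridge"), cv,
                                  n_permutations = 0), ">= 1")
})

test_that("high-performance filter applies inclusive gates", {
  mk <- function(auc, p, selected = TRUE) {
    structure(list(signature = "s", classifier = classifier_spec("ridge"),
                   auc_values = rep(auc, 3), mean_auc = auc,
                   sensitivity = 1, specificity = 1, precision = 1,
                   equivalence_p = 1, permutation_p = p, is_top1 = FALSE,
                   selected = selected, high_performance = FALSE),
              class = "pair_evaluation")
  }
  kept <- high_performance_filter(list(mk(0.90, 0.01), mk(0.90, 0.20),
                                       mk(0.80, 0.01),
                                       mk(0.95, 0.01, selected = FALSE),
                                       mk(0.85, 0.05)))
  expect_identical(length(kept), 2L)   # boundary 0.85/0.05 is kept
  expect_true(all(vapply(kept, `[[`, TRUE, "high_performance")))
  expect_identical(high_performance_filter(list()), list())
})

test_that("marker_frequency tabulates distinct signatures", {
  mk <- function(sig) structure(list(signature = sig), class =
                                  "pair_evaluation")
  f <- marker_frequency(list(mk(c("A", "B")), mk(c("A", "C")),
                             mk(c("A", "B"))))  # duplicate signature
  expect_identical(f[["A"]], 100)
  expect_identical(f[["B"]], 50)
  expect_identical(f[["C"]], 50)
  expect_identical(names(f)[1], "A")
  expect_length(marker_frequency(list()), 0)
})

test_that("training folds never lose a class under stratification", {
  for (seed in 1:5) {
    panel <- make_panel(n_pos = 5, n_neg = 9, seed = seed)
    cv <- cv_config(R = 6, base_seed = seed)
    ev <- cv_auc_distribution(panel, panel$variable_ids[1:2],
                              "naive_bayes", cv)
    expect_length(ev$auc_values, 6L)
  }
})
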