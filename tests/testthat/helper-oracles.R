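# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force BH step-up: q(i) = min_{j >= i} (m * p(j) / j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)  # rank of p[i]
    q[i] <- min(1, min(m * p[ord[j:m]] / (j:m)))
  }
  q
}

# Exhaustive two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, sum hypergeometric probabilities <= observed's.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  amin <- max(0, c1 - (n - r1))
  amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled two-sample t oracle (textbook formulas, no stats::t.test).
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Trapezoid-free AUC oracle by pairwise comparison (O(n^2)).
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

toy_signature <- function(n_per_class = 5L) {
  setNames(rep(c("Epi", "Mes"), each = n_per_class),
           c(sprintf("EPI%02d", seq_len(n_per_class)),
             sprintf("MES%02d", seq_len(n_per_class))))
}

make_labels <- function(n_pos, n_neg) {
  setNames(rep(c("pos", "neg"), c(n_pos, n_neg)),
           c(sprintf("POS%03d", seq_len(n_pos)),
             sprintf("NEG%03d", seq_len(n_neg))))
}

# small deterministic quant table
tiny_table <- function(n_feat = 6L, n_pos = 4L, n_neg = 4L, seed = 1L) {
  set.seed(seed)
  labels <- make_labels(n_pos, n_neg)
  m <- matrix(rnorm(n_feat * (n_pos + n_neg), 25, 2), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                              names(labels)))
  list(table = quant_table(m), labels = labels)
}
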