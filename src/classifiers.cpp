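// Deterministic train-and-score routines for the ten classifier families
// used by the signature x classifier search. Each routine trains on
// (Xtr, ytr) and returns a continuous decision score per test row with the
// convention: score > 0 predicts the positive (pN+) class. All families are
// deterministic given `seed` (only the random forest consumes it).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

vec to_pm1(const ivec &y) {
  vec out(y.n_elem);
  for (uword i = 0; i < y.n_elem; ++i) out[i] = y[i] == 1 ? 1.0 : -1.0;
  return out;
}

// ---- linear families -----------------------------------------------------

vec ridge_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                 double lambda) {
  vec y = to_pm1(ytr);
  rowvec xm = mean(Xtr, 0);
  mat Xc = Xtr.each_row() - xm;
  double ym = mean(y);
  mat A = Xc.t() * Xc;
  A.diag() += lambda;
  vec beta = solve(A, Xc.t() * (y - ym), solve_opts::likely_sympd);
  return (Xte.each_row() - xm) * beta + ym;
}

vec lasso_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                 double lambda) {
  // coordinate descent on 1/(2n)||y - b0 - X b||^2 + lambda ||b||_1
  vec y = to_pm1(ytr);
  const uword n = Xtr.n_rows, p = Xtr.n_cols;
  rowvec xm = mean(Xtr, 0);
  mat Xc = Xtr.each_row() - xm;
  double ym = mean(y);
  vec yc = y - ym;
  vec beta(p, fill::zeros);
  vec resid = yc;
  vec xss(p);
  for (uword j = 0; j < p; ++j) xss[j] = dot(Xc.col(j), Xc.col(j)) / n;
  for (int sweep = 0; sweep < 500; ++sweep) {
    double delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (xss[j] <= 0) continue;
      double rho = dot(Xc.col(j), resid) / n + xss[j] * beta[j];
      double bj = 0.0;
      if (rho > lambda) bj = (rho - lambda) / xss[j];
      else if (rho < -lambda) bj = (rho + lambda) / xss[j];
      double diff = bj - beta[j];
      if (diff != 0.0) {
        resid -= Xc.col(j) * diff;
        beta[j] = bj;
        delta = std::max(delta, std::fabs(diff));
      }
    }
    if (delta < 1e-7) break;
  }
  return (Xte.each_row() - xm) * beta + ym;
}

vec linear_svm_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                      double lambda, int epochs) {
  // full-batch subgradient descent on L2-regularized hinge loss
  vec y = to_pm1(ytr);
  const uword n = Xtr.n_rows, p = Xtr.n_cols;
  vec w(p, fill::zeros);
  double b = 0.0;
  for (int t = 1; t <= epochs; ++t) {
    double eta = 1.0 / (lambda * (t + 1.0));
    vec margin = y % (Xtr * w + b);
    vec gw = lambda * w;
    double gb = 0.0;
    for (uword i = 0; i < n; ++i) {
      if (margin[i] < 1.0) {
        gw -= (y[i] / n) * Xtr.row(i).t();
        gb -= y[i] / n;
      }
    }
    w -= eta * gw;
    b -= eta * gb;
  }
  return Xte * w + b;
}

vec lda_scores(const mat &Xtr, const ivec &ytr, const mat &Xte) {
  uvec pos = find(ytr == 1), neg = find(ytr == 0);
  rowvec mu1 = mean(Xtr.rows(pos), 0), mu0 = mean(Xtr.rows(neg), 0);
  const uword p = Xtr.n_cols;
  mat S(p, p, fill::zeros);
  mat d1 = Xtr.rows(pos); d1.each_row() -= mu1;
  mat d0 = Xtr.rows(neg); d0.each_row() -= mu0;
  S = (d1.t() * d1 + d0.t() * d0) / (Xtr.n_rows - 2.0);
  S.diag() += 1e-8 * (trace(S) / p + 1.0);
  vec w = solve(S, (mu1 - mu0).t(), solve_opts::likely_sympd);
  double thr = dot(w, 0.5 * (mu1 + mu0)) -
    std::log((double)pos.n_elem / neg.n_elem);
  return Xte * w - thr;
}

vec perceptron_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                      int epochs) {
  // averaged perceptron, deterministic cyclic order
  vec y = to_pm1(ytr);
  const uword n = Xtr.n_rows, p = Xtr.n_cols;
  vec w(p, fill::zeros), wsum(p, fill::zeros);
  double b = 0.0, bsum = 0.0;
  long cnt = 0;
  for (int e = 0; e < epochs; ++e) {
    for (uword i = 0; i < n; ++i) {
      if (y[i] * (dot(w, Xtr.row(i)) + b) <= 0.0) {
        w += y[i] * Xtr.row(i).t();
        b += y[i];
      }
      wsum += w;
      bsum += b;
      ++cnt;
    }
  }
  return Xte * (wsum / cnt) + bsum / cnt;
}

vec nb_scores(const mat &Xtr, const ivec &ytr, const mat &Xte) {
  uvec pos = find(ytr == 1), neg = find(ytr == 0);
  rowvec mu1 = mean(Xtr.rows(pos), 0), mu0 = mean(Xtr.rows(neg), 0);
  rowvec v1 = var(Xtr.rows(pos), 0, 0), v0 = var(Xtr.rows(neg), 0, 0);
  double floor_v = 1e-9 * (mean(var(Xtr, 0, 0)) + 1.0);
  v1 = clamp(v1, floor_v, datum::inf);
  v0 = clamp(v0, floor_v, datum::inf);
  double prior = std::log((double)pos.n_elem / neg.n_elem);
  vec out(Xte.n_rows);
  for (uword i = 0; i < Xte.n_rows; ++i) {
    rowvec x = Xte.row(i);
    double l1 = accu(-0.5 * square(x - mu1) / v1 - 0.5 * log(2 * datum::pi * v1));
    double l0 = accu(-0.5 * square(x - mu0) / v0 - 0.5 * log(2 * datum::pi * v0));
    out[i] = l1 - l0 + prior;
  }
  return out;
}

vec rbf_svm_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                   double C, double gamma_in) {
  // least-squares SVM (LS-SVM) with bias; gamma <= 0 means sklearn "scale"
  vec y = to_pm1(ytr);
  const uword n = Xtr.n_rows;
  double gamma = gamma_in;
  if (gamma <= 0) {
    double v = mean(var(Xtr, 0, 0));
    gamma = 1.0 / (Xtr.n_cols * (v > 0 ? v : 1.0));
  }
  mat sq = repmat(sum(square(Xtr), 1), 1, n);
  mat K = exp(-gamma * (sq + sq.t() - 2.0 * Xtr * Xtr.t()));
  mat A(n + 1, n + 1, fill::ones);
  A.submat(0, 0, n - 1, n - 1) = K + eye(n, n) / C;
  A(n, n) = 0.0;
  vec rhs(n + 1, fill::zeros);
  rhs.head(n) = y;
  vec sol = solve(A, rhs);
  mat sqe = repmat(sum(square(Xte), 1), 1, n);
  mat sqt = repmat(sum(square(Xtr), 1), 1, Xte.n_rows);
  mat Ke = exp(-gamma * (sqe + sqt.t() - 2.0 * Xte * Xtr.t()));
  return Ke * sol.head(n) + sol[n];
}

// ---- trees ---------------------------------------------------------------

struct TreeNode {
  int feature = -1;       // -1 = leaf
  double threshold = 0.0;
  double value = 0.0;     // leaf value (prob or regression value)
  int left = -1, right = -1;
};

// greedy CART; classification: minimize gini; regression: minimize SSE
struct Cart {
  std::vector<TreeNode> nodes;
  int max_depth, min_split;
  bool regression;

  int build(const mat &X, const vec &y, const uvec &idx,
            const uvec &features, int depth) {
    TreeNode node;
    double ysum = 0.0;
    for (uword t = 0; t < idx.n_elem; ++t) ysum += y[idx[t]];
    double ymean = ysum / idx.n_elem;
    node.value = ymean;
    bool pure = true;
    for (uword t = 1; t < idx.n_elem; ++t)
      if (y[idx[t]] != y[idx[0]]) { pure = false; break; }
    if (depth >= max_depth || (int)idx.n_elem < min_split || pure) {
      nodes.push_back(node);
      return nodes.size() - 1;
    }
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double parent_imp;
    if (regression) {
      parent_imp = 0.0;
      for (uword t = 0; t < idx.n_elem; ++t)
        parent_imp += (y[idx[t]] - ymean) * (y[idx[t]] - ymean);
    } else {
      parent_imp = idx.n_elem * 2.0 * ymean * (1.0 - ymean);
    }
    for (uword fi = 0; fi < features.n_elem; ++fi) {
      uword f = features[fi];
      std::vector<std::pair<double, double>> xy(idx.n_elem);
      for (uword t = 0; t < idx.n_elem; ++t)
        xy[t] = {X(idx[t], f), y[idx[t]]};
      std::sort(xy.begin(), xy.end());
      double lsum = 0.0, lsq = 0.0;
      double tsum = 0.0, tsq = 0.0;
      for (auto &pr : xy) { tsum += pr.second; tsq += pr.second * pr.second; }
      for (uword t = 0; t + 1 < xy.size(); ++t) {
        lsum += xy[t].second;
        lsq += xy[t].second * xy[t].second;
        if (xy[t].first == xy[t + 1].first) continue;
        double nl = t + 1.0, nr = xy.size() - nl;
        double child_imp;
        if (regression) {
          double limp = lsq - lsum * lsum / nl;
          double rimp = (tsq - lsq) - (tsum - lsum) * (tsum - lsum) / nr;
          child_imp = limp + rimp;
        } else {
          double pl = lsum / nl, prr = (tsum - lsum) / nr;
          child_imp = nl * 2.0 * pl * (1.0 - pl) +
                      nr * 2.0 * prr * (1.0 - prr);
        }
        double gain = parent_imp - child_imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xy[t].first + xy[t + 1].first);
        }
      }
    }
    if (best_f < 0) {
      nodes.push_back(node);
      return nodes.size() - 1;
    }
    std::vector<uword> li, ri;
    for (uword t = 0; t < idx.n_elem; ++t) {
      if (X(idx[t], best_f) <= best_thr) li.push_back(idx[t]);
      else ri.push_back(idx[t]);
    }
    node.feature = best_f;
    node.threshold = best_thr;
    int self = nodes.size();
    nodes.push_back(node);
    nodes[self].left = build(X, y, uvec(li), features, depth + 1);
    nodes[self].right = build(X, y, uvec(ri), features, depth + 1);
    return self;
  }

  double predict_row(const mat &X, uword i) const {
    int cur = 0;
    while (nodes[cur].feature >= 0)
      cur = X(i, nodes[cur].feature) <= nodes[cur].threshold ?
        nodes[cur].left : nodes[cur].right;
    return nodes[cur].value;
  }
};

vec tree_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
                int max_depth) {
  Cart tree{{}, max_depth, 2, false};
  vec y = conv_to<vec>::from(ytr);
  tree.build(Xtr, y, regspace<uvec>(0, Xtr.n_rows - 1),
             regspace<uvec>(0, Xtr.n_cols - 1), 0);
  vec out(Xte.n_rows);
  for (uword i = 0; i < Xte.n_rows; ++i)
    out[i] = tree.predict_row(Xte, i) - 0.5;  // prob - 0.5 -> sign rule
  return out;
}

vec gbm_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
               int n_stages, int max_depth, double shrinkage) {
  // gradient boosting with logistic loss and shallow regression trees;
  // leaf values via one Newton step
  const uword n = Xtr.n_rows;
  vec y01 = conv_to<vec>::from(ytr);
  double pbar = mean(y01);
  pbar = std::min(std::max(pbar, 1e-6), 1.0 - 1e-6);
  double F0 = std::log(pbar / (1.0 - pbar));
  vec Ftr(n, fill::value(F0));
  vec Fte(Xte.n_rows, fill::value(F0));
  uvec all = regspace<uvec>(0, n - 1);
  uvec feats = regspace<uvec>(0, Xtr.n_cols - 1);
  for (int s = 0; s < n_stages; ++s) {
    vec prob = 1.0 / (1.0 + exp(-Ftr));
    vec resid = y01 - prob;
    Cart tree{{}, max_depth, 2, true};
    tree.build(Xtr, resid, all, feats, 0);
    // Newton leaf values: sum(resid) / sum(p(1-p)) per leaf
    std::vector<double> num(tree.nodes.size(), 0.0),
                        den(tree.nodes.size(), 0.0);
    std::vector<int> leaf_of(n);
    for (uword i = 0; i < n; ++i) {
      int cur = 0;
      while (tree.nodes[cur].feature >= 0)
        cur = Xtr(i, tree.nodes[cur].feature) <= tree.nodes[cur].threshold ?
          tree.nodes[cur].left : tree.nodes[cur].right;
      leaf_of[i] = cur;
      num[cur] += resid[i];
      den[cur] += prob[i] * (1.0 - prob[i]);
    }
    for (size_t k = 0; k < tree.nodes.size(); ++k)
      if (tree.nodes[k].feature < 0)
        tree.nodes[k].value = den[k] > 1e-12 ?
          std::min(std::max(num[k] / den[k], -4.0), 4.0) : 0.0;
    for (uword i = 0; i < n; ++i)
      Ftr[i] += shrinkage * tree.nodes[leaf_of[i]].value;
    for (uword i = 0; i < Xte.n_rows; ++i)
      Fte[i] += shrinkage * tree.predict_row(Xte, i);
  }
  return Fte;
}

vec rf_scores(const mat &Xtr, const ivec &ytr, const mat &Xte,
              int n_trees, int max_depth, int seed) {
  const uword n = Xtr.n_rows, p = Xtr.n_cols;
  int mtry = std::max(1, (int)std::floor(std::sqrt((double)p) + 0.5));
  std::mt19937 rng(seed);
  std::uniform_int_distribution<uword> pick_row(0, n - 1);
  vec y = conv_to<vec>::from(ytr);
  vec votes(Xte.n_rows, fill::zeros);
  std::vector<uword> fpool(p);
  for (uword j = 0; j < p; ++j) fpool[j] = j;
  for (int t = 0; t < n_trees; ++t) {
    std::vector<uword> boot(n);
    for (uword i = 0; i < n; ++i) boot[i] = pick_row(rng);
    std::shuffle(fpool.begin(), fpool.end(), rng);
    uvec feats(std::vector<uword>(fpool.begin(), fpool.begin() + mtry));
    Cart tree{{}, max_depth, 2, false};
    tree.build(Xtr, y, uvec(boot), feats, 0);
    for (uword i = 0; i < Xte.n_rows; ++i)
      votes[i] += tree.predict_row(Xte, i);
  }
  return votes / n_trees - 0.5;
}

vec dispatch(const std::string &family, const mat &Xtr, const ivec &ytr,
             const mat &Xte, const Rcpp::List &params, int seed) {
  auto get = [&](const char *nm, double dflt) {
    return params.containsElementNamed(nm) ?
      Rcpp::as<double>(params[nm]) : dflt;
  };
  if (family == "ridge")
    return ridge_scores(Xtr, ytr, Xte, get("lambda", 1.0));
  if (family == "lasso")
    return lasso_scores(Xtr, ytr, Xte, get("lambda", 0.05));
  if (family == "linear_svm")
    return linear_svm_scores(Xtr, ytr, Xte, get("lambda", 0.01),
                             (int)get("epochs", 200));
  if (family == "linear_discriminant")
    return lda_scores(Xtr, ytr, Xte);
  if (family == "perceptron")
    return perceptron_scores(Xtr, ytr, Xte, (int)get("epochs", 100));
  if (family == "naive_bayes")
    return nb_scores(Xtr, ytr, Xte);
  if (family == "decision_tree")
    return tree_scores(Xtr, ytr, Xte, (int)get("max_depth", 3));
  if (family == "gbm")
    return gbm_scores(Xtr, ytr, Xte, (int)get("n_stages", 100),
                      (int)get("max_depth", 2), get("shrinkage", 0.1));
  if (family == "random_forest")
    return rf_scores(Xtr, ytr, Xte, (int)get("n_trees", 100),
                     (int)get("max_depth", 8), seed);
  if (family == "rbf_svm")
    return rbf_svm_scores(Xtr, ytr, Xte, get("C", 1.0), get("gamma", -1.0));
  Rcpp::stop("unknown classifier family: " + family);
}

} // namespace

// [[Rcpp::export(name = "cpp_train_score")]]
Rcpp::NumericVector cpp_train_score(const arma::mat &Xtr,
                                    const arma::ivec &ytr,
                                    const arma::mat &Xte,
                                    const std::string &family,
                                    const Rcpp::List &params, int seed) {
  if (Xtr.n_rows != ytr.n_elem) Rcpp::stop("X/y size mismatch");
  if (Xtr.n_cols != Xte.n_cols) Rcpp::stop("train/test column mismatch");
  vec s = dispatch(family, Xtr, ytr, Xte, params, seed);
  return Rcpp::wrap(s);
}

// Out-of-fold continuous scores for one signature under repeated
// stratified K-fold CV. `folds` is R x n (1-based fold ids); returns an
// R x n score matrix (each row = pooled out-of-fold scores of that
// repetition). score > 0 predicts positive.
// [[Rcpp::export(name = "cpp_cv_scores")]]
arma::mat cpp_cv_scores(const arma::mat &X, const arma::ivec &y,
                        const arma::imat &folds, const std::string &family,
                        const Rcpp::List &params, int seed) {
  const uword n = X.n_rows;
  if (folds.n_cols != n || y.n_elem != n)
    Rcpp::stop("fold matrix / label size mismatch");
  mat scores(folds.n_rows, n, fill::zeros);
  for (uword r = 0; r < folds.n_rows; ++r) {
    int K = folds.row(r).max();
    for (int k = 1; k <= K; ++k) {
      std::vector<uword> tr, te;
      for (uword i = 0; i < n; ++i)
        (folds(r, i) == k ? te : tr).push_back(i);
      if (te.empty()) continue;
      uvec tri(tr), tei(te);
      ivec ytr = y(tri);
      if (ytr.max() == ytr.min())
        Rcpp::stop("training fold lost a class (repetition %d, fold %d)",
                   (int)r + 1, k);
      vec s = dispatch(family, X.rows(tri), ytr, X.rows(tei), params,
                       seed + (int)r * 131 + k);
      for (uword t = 0; t < tei.n_elem; ++t) scores(r, tei[t]) = s[t];
    }
  }
  return scores;
}
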