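#include <Rcpp.h>
#include <R_ext/Applic.h>
using namespace Rcpp;

// Categorical decision-tree learner of the C4.5/C5.0 family.
//
// - multiway splits, one branch per category observed at the node
// - split selection by gain ratio among attributes whose information gain is
//   at least the average gain of all valid candidates
// - a split is valid when at least two branches would receive min_cases cases
// - pessimistic error-based pruning (binomial upper confidence limit), with
//   the error count replaced by expected misclassification cost when a cost
//   matrix is active
// - leaf class = argmin expected cost (ties toward class 0)
// - unseen categories at prediction route to the branch that received the
//   most training cases (the fallback branch)
//
// Categories are passed as 1-based integer codes; 0 marks a category unseen
// in training (prediction only).  Case weights support boosting.

struct Node {
  bool leaf;
  int attr;                 // 0-based attribute index, -1 for leaf
  double n, n0, n1;         // weighted counts reaching the node
  int cls;                  // predicted class at this node if leaf-ified
  std::vector<int> levels;  // category code per branch
  std::vector<Node*> kids;
  int fallback;             // index into kids
  Node() : leaf(true), attr(-1), n(0), n0(0), n1(0), cls(0), fallback(-1) {}
  ~Node() { for (size_t i = 0; i < kids.size(); ++i) delete kids[i]; }
};

static inline double entropy2(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  if (n0 > 0.0) h -= (n0 / n) * std::log2(n0 / n);
  if (n1 > 0.0) h -= (n1 / n) * std::log2(n1 / n);
  return h;
}

// C4.5 upper confidence limit on the error rate of a leaf seeing N cases
// with E errors; returns the pessimistic error (rate * N).
static double pessimistic_errors(double E, double N, double cf) {
  if (N <= 0.0) return 0.0;
  if (E >= N) return N;
  double p = R::qbeta(1.0 - cf, E + 1.0, N - E, 1, 0);
  return N * p;
}

struct FitCtx {
  const int *X;       // n x p, column-major
  const int *y;
  const double *wt;
  int n, p;
  const int *nlev;
  double fn_cost, fp_cost;
  int min_cases;
  double cf;
  bool prune;
  bool cost_in_prune;
};

static void class_counts(const FitCtx &c, const std::vector<int> &idx,
                         double &n0, double &n1) {
  n0 = n1 = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) {
    if (c.y[idx[i]]) n1 += c.wt[idx[i]]; else n0 += c.wt[idx[i]];
  }
}

static int leaf_class(const FitCtx &c, double n0, double n1) {
  // expected cost of predicting 0 is n1 * fn_cost; of predicting 1, n0 * fp_cost
  return (n1 * c.fn_cost > n0 * c.fp_cost) ? 1 : 0;
}

static Node *grow(const FitCtx &c, const std::vector<int> &idx) {
  Node *nd = new Node();
  class_counts(c, idx, nd->n0, nd->n1);
  nd->n = nd->n0 + nd->n1;
  nd->cls = leaf_class(c, nd->n0, nd->n1);

  if (nd->n0 == 0.0 || nd->n1 == 0.0 || (int)idx.size() < 2 * c.min_cases)
    return nd;

  double h_node = entropy2(nd->n0, nd->n1);

  // evaluate candidate attributes
  std::vector<double> gain(c.p, -1.0), ratio(c.p, -1.0);
  int n_valid = 0;
  double gain_sum = 0.0;
  std::vector<double> cnt, cnt0;
  for (int a = 0; a < c.p; ++a) {
    int L = c.nlev[a];
    cnt.assign(L + 1, 0.0);
    cnt0.assign(L + 1, 0.0);
    const int *col = c.X + (size_t)a * c.n;
    for (size_t i = 0; i < idx.size(); ++i) {
      int r = idx[i];
      cnt[col[r]] += c.wt[r];
      if (!c.y[r]) cnt0[col[r]] += c.wt[r];
    }
    int nonempty = 0, big = 0;
    double h_split = 0.0, split_info = 0.0;
    for (int v = 1; v <= L; ++v) {
      if (cnt[v] <= 0.0) continue;
      ++nonempty;
      if (cnt[v] >= (double)c.min_cases) ++big;
      double frac = cnt[v] / nd->n;
      h_split += frac * entropy2(cnt0[v], cnt[v] - cnt0[v]);
      split_info -= frac * std::log2(frac);
    }
    if (nonempty < 2 || big < 2 || split_info <= 0.0) continue;
    double g = h_node - h_split;
    if (g <= 1e-12) continue;
    gain[a] = g;
    ratio[a] = g / split_info;
    gain_sum += g;
    ++n_valid;
  }
  if (n_valid == 0) return nd;
  double avg_gain = gain_sum / n_valid;

  int best = -1;
  for (int a = 0; a < c.p; ++a) {
    if (gain[a] < avg_gain - 1e-9) continue;
    if (best < 0 || ratio[a] > ratio[best] + 1e-12) best = a;
  }
  if (best < 0) return nd;

  // partition by category of the chosen attribute
  int L = c.nlev[best];
  std::vector<std::vector<int> > parts(L + 1);
  const int *col = c.X + (size_t)best * c.n;
  for (size_t i = 0; i < idx.size(); ++i) parts[col[idx[i]]].push_back(idx[i]);

  nd->leaf = false;
  nd->attr = best;
  double best_w = -1.0;
  for (int v = 1; v <= L; ++v) {
    if (parts[v].empty()) continue;
    Node *kid = grow(c, parts[v]);
    nd->levels.push_back(v);
    nd->kids.push_back(kid);
    if (kid->n > best_w) { best_w = kid->n; nd->fallback = (int)nd->kids.size() - 1; }
  }
  if (nd->kids.size() < 2) {  // degenerate; revert to leaf
    for (size_t i = 0; i < nd->kids.size(); ++i) delete nd->kids[i];
    nd->kids.clear(); nd->levels.clear();
    nd->leaf = true; nd->attr = -1; nd->fallback = -1;
  }
  return nd;
}

// pessimistic cost of the subtree rooted at nd; prunes in place
static double prune_rec(const FitCtx &c, Node *nd) {
  double err_as_leaf = (nd->cls == 0) ? nd->n1 : nd->n0;
  double unit_cost = 1.0;
  if (c.cost_in_prune) unit_cost = (nd->cls == 0) ? c.fn_cost : c.fp_cost;
  double leaf_cost = pessimistic_errors(err_as_leaf, nd->n, c.cf) * unit_cost;
  if (nd->leaf) return leaf_cost;

  double sub_cost = 0.0;
  for (size_t i = 0; i < nd->kids.size(); ++i)
    sub_cost += prune_rec(c, nd->kids[i]);

  if (leaf_cost <= sub_cost + 1e-9) {
    for (size_t i = 0; i < nd->kids.size(); ++i) delete nd->kids[i];
    nd->kids.clear(); nd->levels.clear();
    nd->leaf = true; nd->attr = -1; nd->fallback = -1;
    return leaf_cost;
  }
  return sub_cost;
}

static void flatten(Node *nd, std::vector<Node*> &order) {
  order.push_back(nd);
  for (size_t i = 0; i < nd->kids.size(); ++i) flatten(nd->kids[i], order);
}

// [[Rcpp::export]]
List cpp_fit_tree(IntegerMatrix X, IntegerVector y, NumericVector wt,
                  IntegerVector nlev, double fn_cost, double fp_cost,
                  int min_cases, double prune_cf, bool prune,
                  bool cost_in_prune) {
  FitCtx c;
  c.X = X.begin(); c.y = y.begin(); c.wt = wt.begin();
  c.n = X.nrow(); c.p = X.ncol(); c.nlev = nlev.begin();
  c.fn_cost = fn_cost; c.fp_cost = fp_cost;
  c.min_cases = min_cases; c.cf = prune_cf; c.prune = prune;
  c.cost_in_prune = cost_in_prune;

  std::vector<int> idx(c.n);
  for (int i = 0; i < c.n; ++i) idx[i] = i;

  Node *root = grow(c, idx);
  if (prune) prune_rec(c, root);

  std::vector<Node*> order;
  flatten(root, order);
  int nn = (int)order.size();
  std::map<Node*, int> id;
  for (int i = 0; i < nn; ++i) id[order[i]] = i + 1;  // 1-based node ids

  IntegerVector is_leaf(nn), attr(nn), cls(nn), fallback(nn);
  NumericVector n_w(nn), n0_w(nn), n1_w(nn);
  std::vector<int> b_node, b_level, b_child;
  for (int i = 0; i < nn; ++i) {
    Node *nd = order[i];
    is_leaf[i] = nd->leaf ? 1 : 0;
    attr[i] = nd->leaf ? NA_INTEGER : nd->attr + 1;
    cls[i] = nd->cls;
    n_w[i] = nd->n; n0_w[i] = nd->n0; n1_w[i] = nd->n1;
    fallback[i] = nd->leaf ? NA_INTEGER : id[nd->kids[nd->fallback]];
    for (size_t k = 0; k < nd->kids.size(); ++k) {
      b_node.push_back(i + 1);
      b_level.push_back(nd->levels[k]);
      b_child.push_back(id[nd->kids[k]]);
    }
  }

  // usage importance: share of training weight passing a split on each
  // attribute (each root-leaf path splits on an attribute at most once)
  NumericVector usage(c.p);
  double total = n_w[0] > 0 ? n_w[0] : 1.0;
  for (int i = 0; i < nn; ++i)
    if (!is_leaf[i]) usage[attr[i] - 1] += n_w[i];
  for (int a = 0; a < c.p; ++a) usage[a] = 100.0 * usage[a] / total;

  delete root;
  return List::create(
    _["is_leaf"] = is_leaf, _["attr"] = attr, _["cls"] = cls,
    _["n"] = n_w, _["n0"] = n0_w, _["n1"] = n1_w, _["fallback"] = fallback,
    _["branch_node"] = wrap(b_node), _["branch_level"] = wrap(b_level),
    _["branch_child"] = wrap(b_child), _["usage"] = usage);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(IntegerMatrix X,
                               IntegerVector is_leaf, IntegerVector attr,
                               IntegerVector cls, IntegerVector fallback,
                               IntegerVector branch_node,
                               IntegerVector branch_level,
                               IntegerVector branch_child) {
  int n = X.nrow(), nn = is_leaf.size(), nb = branch_node.size();
  // branch lookup: first branch row per node (branches are grouped by node)
  std::vector<int> first(nn + 2, nb);
  for (int j = nb - 1; j >= 0; --j) first[branch_node[j]] = j;
  for (int i = nn; i >= 1; --i) if (first[i] > first[i + 1]) first[i] = first[i + 1];

  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    int node = 1;
    while (!is_leaf[node - 1]) {
      int a = attr[node - 1];
      int val = X(r, a - 1);
      int nxt = -1;
      for (int j = first[node]; j < nb && branch_node[j] == node; ++j) {
        if (branch_level[j] == val) { nxt = branch_child[j]; break; }
      }
      if (nxt < 0) nxt = fallback[node - 1];
      node = nxt;
    }
    out[r] = cls[node - 1];
  }
  return out;
}
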