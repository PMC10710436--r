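#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

// Three-state (Gotoh) global alignment minimizing total penalty.
// Penalties: m per matched base, x per substituted base, gaps cost o + n*e
// (first gap base costs o + e). States: M diagonal, D consumes a (deletion
// from the query's point of view), I consumes b (insertion).
//
// Tie-break during traceback: diagonal > deletion > insertion at the end
// cell and at M-state predecessors; within a gap state, continuing the gap
// is preferred over opening a new one so that runs stay contiguous.
// [[Rcpp::export]]
List cpp_align_affine(std::string a, std::string b,
                      double m, double x, double o, double e) {
  const int n = (int)a.size(), q = (int)b.size();
  std::vector<double> M((size_t)(n + 1) * (q + 1), INF);
  std::vector<double> D((size_t)(n + 1) * (q + 1), INF);
  std::vector<double> I((size_t)(n + 1) * (q + 1), INF);
  auto ix = [&](int i, int j) { return (size_t)i * (q + 1) + j; };

  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) D[ix(i, 0)] = o + i * e;
  for (int j = 1; j <= q; ++j) I[ix(0, j)] = o + j * e;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= q; ++j) {
      double sub = (a[i - 1] == b[j - 1]) ? m : x;
      double prev = std::min(M[ix(i - 1, j - 1)],
                    std::min(D[ix(i - 1, j - 1)], I[ix(i - 1, j - 1)]));
      if (prev < INF) M[ix(i, j)] = prev + sub;
      D[ix(i, j)] = std::min(D[ix(i - 1, j)] + e,
                    std::min(M[ix(i - 1, j)] + o + e, I[ix(i - 1, j)] + o + e));
      I[ix(i, j)] = std::min(I[ix(i, j - 1)] + e,
                    std::min(M[ix(i, j - 1)] + o + e, D[ix(i, j - 1)] + o + e));
    }
  }

  // end state selection: diagonal > deletion > insertion
  double mv = M[ix(n, q)], dv = D[ix(n, q)], iv = I[ix(n, q)];
  double best = std::min(mv, std::min(dv, iv));
  int state = (mv <= best + EPS) ? 0 : (dv <= best + EPS ? 1 : 2);

  std::string ops;
  ops.reserve(n + q);
  int i = n, j = q;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double sub = (a[i - 1] == b[j - 1]) ? m : x;
      ops.push_back(a[i - 1] == b[j - 1] ? '=' : 'X');
      double tgt = M[ix(i, j)] - sub;
      --i; --j;
      if (std::fabs(M[ix(i, j)] - tgt) < EPS) state = 0;
      else if (std::fabs(D[ix(i, j)] - tgt) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      double v = D[ix(i, j)];
      --i;
      if (std::fabs(D[ix(i, j)] + e - v) < EPS) state = 1;
      else if (std::fabs(M[ix(i, j)] + o + e - v) < EPS) state = 0;
      else state = 2;
    } else {
      ops.push_back('I');
      double v = I[ix(i, j)];
      --j;
      if (std::fabs(I[ix(i, j)] + e - v) < EPS) state = 2;
      else if (std::fabs(M[ix(i, j)] + o + e - v) < EPS) state = 0;
      else state = 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["penalty"] = best, _["ops"] = ops);
}

// ---------------------------------------------------------------------------
// Exhaustive-path oracles. These deliberately avoid the Gotoh recurrence:
// they enumerate every monotone alignment path by depth-first search (with
// branch-and-bound pruning on the running cost, which cannot decrease) and
// are used to validate the DP on short sequences.

struct EnumCtx {
  const char *a, *b;
  int la, lb;
  double m, x, o, e;
  double best;
};

static void enum_affine_rec(EnumCtx &c, int i, int j, int last, double cost) {
  if (cost >= c.best) return;
  if (i == c.la && j == c.lb) { c.best = cost; return; }
  if (i < c.la && j < c.lb)
    enum_affine_rec(c, i + 1, j + 1, 0,
                    cost + (c.a[i] == c.b[j] ? c.m : c.x));
  if (i < c.la)
    enum_affine_rec(c, i + 1, j, 1, cost + (last == 1 ? c.e : c.o + c.e));
  if (j < c.lb)
    enum_affine_rec(c, i, j + 1, 2, cost + (last == 2 ? c.e : c.o + c.e));
}

// [[Rcpp::export]]
double cpp_enum_affine(std::string a, std::string b,
                       double m, double x, double o, double e) {
  EnumCtx c{a.c_str(), b.c_str(), (int)a.size(), (int)b.size(), m, x, o, e, INF};
  enum_affine_rec(c, 0, 0, -1, 0.0);
  return c.best;
}

struct EdDeCtx {
  const char *a, *b;
  int la, lb;
  double best;
};

// minimize 2*DE + ED where each substituted base is one distinct edit and
// one edited base, and each gap is one distinct edit with one edited base
// per gap position; tracked directly, not via an affine cost formula
static void enum_edde_rec(EdDeCtx &c, int i, int j, int last, int ed, int de) {
  if (2.0 * de + ed >= c.best) return;
  if (i == c.la && j == c.lb) { c.best = 2.0 * de + ed; return; }
  if (i < c.la && j < c.lb) {
    bool match = (c.a[i] == c.b[j]);
    enum_edde_rec(c, i + 1, j + 1, 0, ed + (match ? 0 : 1), de + (match ? 0 : 1));
  }
  if (i < c.la) enum_edde_rec(c, i + 1, j, 1, ed + 1, de + (last == 1 ? 0 : 1));
  if (j < c.lb) enum_edde_rec(c, i, j + 1, 2, ed + 1, de + (last == 2 ? 0 : 1));
}

// [[Rcpp::export]]
double cpp_enum_2de_ed(std::string a, std::string b) {
  EdDeCtx c{a.c_str(), b.c_str(), (int)a.size(), (int)b.size(), INF};
  enum_edde_rec(c, 0, 0, -1, 0, 0);
  return c.best;
}

// ---------------------------------------------------------------------------
// Budgeted reach extension used by dependence testing during clustering.
//
// a: reference-side sequence from the cluster's begin to the window limit.
// b: the cluster's alternate sequence followed by the reference sequence
//    from the cluster's end to the same limit.
// cl_ref / cl_alt: lengths of the cluster's reference span and alternate
//    sequence (prefixes of a and b respectively).
//
// Beyond the cluster the query equals the reference, so a cell with
// i - cl_ref == j - cl_alt (both positive) lies on the main diagonal and a
// diagonal step into it is a match of a reference base to its own copy;
// such steps are forbidden, so every counted path stays off the diagonal in
// the inter-cluster region. Returns the largest number of reference bases
// consumable by any path whose penalty stays within the budget.
// [[Rcpp::export]]
int cpp_reach_extend(std::string a, std::string b, int cl_ref, int cl_alt,
                     double budget, double m, double x, double o, double e) {
  const int n = (int)a.size(), q = (int)b.size();
  std::vector<double> M((size_t)(n + 1) * (q + 1), INF);
  std::vector<double> D((size_t)(n + 1) * (q + 1), INF);
  std::vector<double> I((size_t)(n + 1) * (q + 1), INF);
  auto ix = [&](int i, int j) { return (size_t)i * (q + 1) + j; };

  M[ix(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) D[ix(i, 0)] = o + i * e;
  for (int j = 1; j <= q; ++j) I[ix(0, j)] = o + j * e;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= q; ++j) {
      bool on_diag = (i > cl_ref) && (j > cl_alt) && (i - cl_ref == j - cl_alt);
      if (!on_diag) {
        double sub = (a[i - 1] == b[j - 1]) ? m : x;
        double prev = std::min(M[ix(i - 1, j - 1)],
                      std::min(D[ix(i - 1, j - 1)], I[ix(i - 1, j - 1)]));
        if (prev < INF) M[ix(i, j)] = prev + sub;
      }
      D[ix(i, j)] = std::min(D[ix(i - 1, j)] + e,
                    std::min(M[ix(i - 1, j)] + o + e, I[ix(i - 1, j)] + o + e));
      I[ix(i, j)] = std::min(I[ix(i, j - 1)] + e,
                    std::min(M[ix(i, j - 1)] + o + e, D[ix(i, j - 1)] + o + e));
    }
  }

  int reach = 0;
  for (int i = 0; i <= n; ++i) {
    bool ok = false;
    for (int j = 0; j <= q && !ok; ++j) {
      if (M[ix(i, j)] <= budget + EPS || D[ix(i, j)] <= budget + EPS ||
          I[ix(i, j)] <= budget + EPS)
        ok = true;
    }
    if (ok) reach = i;
  }
  return reach;
}

struct ReachCtx {
  const char *a, *b;
  int la, lb, cl_ref, cl_alt;
  double budget, m, x, o, e;
  int best;
};

static void reach_rec(ReachCtx &c, int i, int j, int last, double cost) {
  if (cost > c.budget + EPS) return;
  if (i > c.best) c.best = i;
  if (i < c.la && j < c.lb) {
    bool on_diag = (i + 1 > c.cl_ref) && (j + 1 > c.cl_alt) &&
                   (i + 1 - c.cl_ref == j + 1 - c.cl_alt);
    if (!on_diag)
      reach_rec(c, i + 1, j + 1, 0, cost + (c.a[i] == c.b[j] ? c.m : c.x));
  }
  if (i < c.la) reach_rec(c, i + 1, j, 1, cost + (last == 1 ? c.e : c.o + c.e));
  if (j < c.lb) reach_rec(c, i, j + 1, 2, cost + (last == 2 ? c.e : c.o + c.e));
}

// exhaustive counterpart of cpp_reach_extend for short windows
// [[Rcpp::export]]
int cpp_reach_enum(std::string a, std::string b, int cl_ref, int cl_alt,
                   double budget, double m, double x, double o, double e) {
  ReachCtx c{a.c_str(), b.c_str(), (int)a.size(), (int)b.size(),
             cl_ref, cl_alt, budget, m, x, o, e, 0};
  reach_rec(c, 0, 0, -1, 0.0);
  return c.best;
}
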