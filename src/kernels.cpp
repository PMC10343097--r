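#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without overflow; -Inf-safe
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Global affine-gap DP (Gotoh) over a precomputed column-pair score matrix.
//
// States: M (columns aligned), X (gap inserted into B, consumes A),
// Y (gap inserted into A, consumes B).  A gap run of length g costs
// open * mult + (g - 1) * extend, where mult is the position-specific
// open multiplier of the profile receiving the gap, indexed by the
// column of the *other* profile after which the gap opens (0..L).
// free_ends = true leaves terminal gap runs uncharged.
//
// Tie-break during traceback: M over X over Y; within a state, prefer
// continuing the same state over re-opening.
//
// Returns list(score, a, b): a and b are 1-based column indices into the
// two profiles, 0 marking a gap, one entry per output column.
// [[Rcpp::export]]
List affine_dp_cpp(NumericMatrix match, double gap_open, double gap_extend,
                   NumericVector open_mult_a, NumericVector open_mult_b,
                   bool free_ends) {
  const int la = match.nrow(), lb = match.ncol();
  if ((int)open_mult_a.size() != la + 1 || (int)open_mult_b.size() != lb + 1)
    stop("open multiplier vectors must have length L+1");

  // DP tables, (la+1) x (lb+1)
  std::vector<double> M((la + 1) * (lb + 1), NEG_INF);
  std::vector<double> X((la + 1) * (lb + 1), NEG_INF);
  std::vector<double> Y((la + 1) * (lb + 1), NEG_INF);
  // predecessor state for traceback: 0=M, 1=X, 2=Y, 3=origin
  std::vector<signed char> pM((la + 1) * (lb + 1), -1);
  std::vector<signed char> pX((la + 1) * (lb + 1), -1);
  std::vector<signed char> pY((la + 1) * (lb + 1), -1);
  const int W = lb + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0; pM[IDX(0, 0)] = 3;
  for (int i = 1; i <= la; ++i) {
    double open = free_ends ? 0.0 : gap_open * open_mult_b[0];
    double ext  = free_ends ? 0.0 : gap_extend;
    X[IDX(i, 0)] = -(open + (i - 1) * ext);
    pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    double open = free_ends ? 0.0 : gap_open * open_mult_a[0];
    double ext  = free_ends ? 0.0 : gap_extend;
    Y[IDX(0, j)] = -(open + (j - 1) * ext);
    pY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M from diagonal
      double dm = M[IDX(i - 1, j - 1)], dx = X[IDX(i - 1, j - 1)],
             dy = Y[IDX(i - 1, j - 1)];
      double best = dm; signed char bp = 0;
      if (dx > best) { best = dx; bp = 1; }
      if (dy > best) { best = dy; bp = 2; }
      M[IDX(i, j)] = best + match(i - 1, j - 1);
      pM[IDX(i, j)] = bp;

      // X: consume A row i, gap in B after its column j
      bool term = free_ends && (j == lb);
      double openx = term ? 0.0 : gap_open * open_mult_b[j];
      double extx  = term ? 0.0 : gap_extend;
      double xm = M[IDX(i - 1, j)] - openx;
      double xx = X[IDX(i - 1, j)] - extx;
      double xy = Y[IDX(i - 1, j)] - openx;
      best = xx; bp = 1;                   // prefer continuation
      if (xm > best) { best = xm; bp = 0; }
      if (xy > best) { best = xy; bp = 2; }
      X[IDX(i, j)] = best; pX[IDX(i, j)] = bp;

      // Y: consume B column j, gap in A after row i
      term = free_ends && (i == la);
      double openy = term ? 0.0 : gap_open * open_mult_a[i];
      double exty  = term ? 0.0 : gap_extend;
      double ym = M[IDX(i, j - 1)] - openy;
      double yy = Y[IDX(i, j - 1)] - exty;
      double yx = X[IDX(i, j - 1)] - openy;
      best = yy; bp = 2;
      if (ym > best) { best = ym; bp = 0; }
      if (yx > best) { best = yx; bp = 1; }
      Y[IDX(i, j)] = best; pY[IDX(i, j)] = bp;
    }
  }

  double vm = M[IDX(la, lb)], vx = X[IDX(la, lb)], vy = Y[IDX(la, lb)];
  double score = vm; int state = 0;
  if (vx > score) { score = vx; state = 1; }
  if (vy > score) { score = vy; state = 2; }

  // traceback
  std::vector<int> ra, rb;
  int i = la, j = lb;
  while (!(i == 0 && j == 0)) {
    signed char prev;
    if (state == 0) {
      prev = pM[IDX(i, j)];
      ra.push_back(i); rb.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = pX[IDX(i, j)];
      ra.push_back(i); rb.push_back(0);
      --i;
    } else {
      prev = pY[IDX(i, j)];
      ra.push_back(0); rb.push_back(j);
      --j;
    }
    if (prev == 3) break;
    state = prev;
  }
  const int n = ra.size();
  IntegerVector a(n), b(n);
  for (int k = 0; k < n; ++k) { a[k] = ra[n - 1 - k]; b[k] = rb[n - 1 - k]; }
  return List::create(_["score"] = score, _["a"] = a, _["b"] = b);
#undef IDX
}

// Score-only Gotoh with two rolling rows (linear space in the shorter
// dimension); charged terminal gaps, uniform open penalty.  Used to
// cross-check the full-table DP.
// [[Rcpp::export]]
double affine_score_linear_cpp(NumericMatrix match, double gap_open,
                               double gap_extend) {
  const int la = match.nrow(), lb = match.ncol();
  std::vector<double> m0(lb + 1), m1(lb + 1), x0(lb + 1), x1(lb + 1),
      y0(lb + 1), y1(lb + 1);
  m0[0] = 0.0; x0[0] = y0[0] = NEG_INF;
  for (int j = 1; j <= lb; ++j) {
    y0[j] = -(gap_open + (j - 1) * gap_extend);
    m0[j] = x0[j] = NEG_INF;
  }
  for (int i = 1; i <= la; ++i) {
    m1[0] = NEG_INF; y1[0] = NEG_INF;
    x1[0] = -(gap_open + (i - 1) * gap_extend);
    for (int j = 1; j <= lb; ++j) {
      double diag = std::max(m0[j - 1], std::max(x0[j - 1], y0[j - 1]));
      m1[j] = diag + match(i - 1, j - 1);
      x1[j] = std::max(std::max(m0[j], y0[j]) - gap_open, x0[j] - gap_extend);
      y1[j] = std::max(std::max(m1[j - 1], x1[j - 1]) - gap_open,
                       y1[j - 1] - gap_extend);
    }
    std::swap(m0, m1); std::swap(x0, x1); std::swap(y0, y1);
  }
  return std::max(m0[lb], std::max(x0[lb], y0[lb]));
}

// Longest common subsequence length, two-row DP.
// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector a, IntegerVector b) {
  const int la = a.size(), lb = b.size();
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Pair-HMM forward-backward posterior match probabilities.
//
// Three emitting states: M (emits a residue pair), X (emits in sequence 1
// only), Y (emits in sequence 2 only).  Transitions: M->X = M->Y = delta,
// M->M = 1-2*delta, X->X = Y->Y = eps, X->M = Y->M = 1-eps, no X<->Y.
// The virtual start behaves like an M state (start->M = 1-2*delta,
// start->X = start->Y = delta); no end transition, i.e. every complete
// monotone path through both sequences is weighted by its product of
// start/transition/emission probabilities.
//
// x, y: 0-based residue indices into the emission tables.
// lem: log joint match emissions (A x A); lbx, lby: log background
// emissions for X and Y.
// [[Rcpp::export]]
NumericMatrix pairhmm_posterior_cpp(IntegerVector x, IntegerVector y,
                                    NumericMatrix lem, NumericVector lbx,
                                    NumericVector lby, double delta,
                                    double eps) {
  const int lx = x.size(), ly = y.size();
  const double ld = std::log(delta), le = std::log(eps),
               lmm = std::log(1.0 - 2.0 * delta),
               lgm = std::log(1.0 - eps);
  const int W = ly + 1;
#define IDX(i, j) ((i) * W + (j))
  std::vector<double> fm((lx + 1) * W, NEG_INF), fx((lx + 1) * W, NEG_INF),
      fy((lx + 1) * W, NEG_INF);
  fm[IDX(0, 0)] = 0.0;  // virtual start, treated as M for transitions
  for (int i = 0; i <= lx; ++i) {
    for (int j = 0; j <= ly; ++j) {
      if (i == 0 && j == 0) continue;
      if (i > 0 && j > 0) {
        double t = lse3(fm[IDX(i - 1, j - 1)] + lmm,
                        fx[IDX(i - 1, j - 1)] + lgm,
                        fy[IDX(i - 1, j - 1)] + lgm);
        fm[IDX(i, j)] = t + lem(x[i - 1], y[j - 1]);
      }
      if (i > 0) {
        double t = lse2(fm[IDX(i - 1, j)] + ld, fx[IDX(i - 1, j)] + le);
        fx[IDX(i, j)] = t + lbx[x[i - 1]];
      }
      if (j > 0) {
        double t = lse2(fm[IDX(i, j - 1)] + ld, fy[IDX(i, j - 1)] + le);
        fy[IDX(i, j)] = t + lby[y[j - 1]];
      }
    }
  }
  double logz = lse3(fm[IDX(lx, ly)], fx[IDX(lx, ly)], fy[IDX(lx, ly)]);

  std::vector<double> bm((lx + 1) * W, NEG_INF), bx((lx + 1) * W, NEG_INF),
      by((lx + 1) * W, NEG_INF);
  bm[IDX(lx, ly)] = bx[IDX(lx, ly)] = by[IDX(lx, ly)] = 0.0;
  for (int i = lx; i >= 0; --i) {
    for (int j = ly; j >= 0; --j) {
      if (i == lx && j == ly) continue;
      double vm = NEG_INF, vx = NEG_INF, vy = NEG_INF;
      if (i < lx && j < ly) {
        double e = lem(x[i], y[j]) + bm[IDX(i + 1, j + 1)];
        vm = lse2(vm, lmm + e);
        vx = lse2(vx, lgm + e);
        vy = lse2(vy, lgm + e);
      }
      if (i < lx) {
        double e = lbx[x[i]] + bx[IDX(i + 1, j)];
        vm = lse2(vm, ld + e);
        vx = lse2(vx, le + e);
      }
      if (j < ly) {
        double e = lby[y[j]] + by[IDX(i, j + 1)];
        vm = lse2(vm, ld + e);
        vy = lse2(vy, le + e);
      }
      bm[IDX(i, j)] = vm; bx[IDX(i, j)] = vx; by[IDX(i, j)] = vy;
    }
  }

  NumericMatrix post(lx, ly);
  for (int i = 1; i <= lx; ++i)
    for (int j = 1; j <= ly; ++j) {
      double lp = fm[IDX(i, j)] + bm[IDX(i, j)] - logz;
      post(i - 1, j - 1) = (lp == NEG_INF) ? 0.0 : std::exp(lp);
    }
  return post;
#undef IDX
}

// Maximum-expected-accuracy value over a posterior matrix: best monotone
// path sum of matched-cell posteriors (gaps cost nothing).
// [[Rcpp::export]]
double mea_score_cpp(NumericMatrix post) {
  const int la = post.nrow(), lb = post.ncol();
  std::vector<double> prev(lb + 1, 0.0), cur(lb + 1, 0.0);
  for (int i = 1; i <= la; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= lb; ++j) {
      double d = prev[j - 1] + post(i - 1, j - 1);
      cur[j] = std::max(d, std::max(prev[j], cur[j - 1]));
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Triplet relaxation for the consistency transformation:
// C[x, y] = sum_k min(A[x, k], B[k, y]) for A = W(i,z), B = W(z,j).
// [[Rcpp::export]]
NumericMatrix minplus_relax_cpp(NumericMatrix A, NumericMatrix B) {
  const int li = A.nrow(), lz = A.ncol(), lj = B.ncol();
  if (B.nrow() != lz) stop("inner dimensions disagree");
  NumericMatrix C(li, lj);
  for (int x = 0; x < li; ++x) {
    for (int k = 0; k < lz; ++k) {
      double a = A(x, k);
      if (a <= 0.0) continue;
      for (int y = 0; y < lj; ++y) {
        double b = B(k, y);
        if (b <= 0.0) continue;
        C(x, y) += (a < b) ? a : b;
      }
    }
  }
  return C;
}
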