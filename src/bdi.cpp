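// Birth-death-innovation (BDI) transition probabilities on a truncated state
// space 0..n_max and the pruning likelihood of one orthogroup's tip counts.
//
// The chain has up-rate n*beta + iota and down-rate n*delta.  The generator is
// truncated at n_max with a leaking boundary: from state n_max the up-rate
// still leaves the state space, so rows of P sum to 1 minus the leaked mass.
//
// All matrix exponentials use uniformization (Poisson-weighted powers of
// M = I + Q/q), which is unconditionally stable and nonnegative.  The
// generator is tridiagonal, so the likelihood only ever applies it to
// vectors at O(3n) per term; full matrices are built just for the exported
// transition-matrix function, with scaling-and-squaring for long intervals.
#include <RcppArmadillo.h>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// The uniformization vectors span hundreds of orders of magnitude, and
// denormal operands cost ~100 cycles each on x86.  Mass below ~1e-300 is
// irrelevant here (partials are rescaled), so flush denormals to zero
// inside the hot routines and restore the FP environment on exit.
struct FlushDenormals {
#if defined(__SSE2__)
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

static void bdi_updown(double b, double d, double i, int nmax,
                       vec &up, vec &down) {
  up.set_size(nmax + 1);
  down.set_size(nmax + 1);
  for (int k = 0; k <= nmax; ++k) {
    up[k] = k * b + i;
    down[k] = k * d;
  }
}

// Uniformization: P(t) = sum_m Pois(m; q t) M^m with M = I + Q/q.
// For q t > 64 the interval is halved s times and the result squared back.
static mat pmat_unif(double b, double d, double i, double t, int nmax) {
  int n = nmax + 1;
  if (t <= 0.0) return eye(n, n);
  vec up, down;
  bdi_updown(b, d, i, nmax, up, down);
  double q = 0.0;
  for (int k = 0; k <= nmax; ++k) q = std::max(q, up[k] + down[k]);
  if (q <= 0.0) return eye(n, n);

  mat Q(n, n, fill::zeros);
  for (int k = 0; k <= nmax; ++k) {
    Q(k, k) = -(up[k] + down[k]);
    if (k < nmax) Q(k, k + 1) = up[k];
    if (k > 0) Q(k, k - 1) = down[k];
  }
  double qt = q * t;
  int s = 0;
  while (qt > 64.0) { qt /= 2.0; ++s; }

  mat M = eye(n, n) + Q / q;
  mat A = eye(n, n);
  double w = std::exp(-qt), cum = w;
  mat P = w * A;
  int m = 0;
  // stop once the Poisson tail is exhausted; the weight test guards against
  // floating-point stalls where cum rounds just below 1
  while (1.0 - cum > 1e-15 && !(m > qt && w < 1e-18) && m < 100000) {
    ++m;
    A = A * M;
    w *= qt / m;
    P += w * A;
    cum += w;
  }
  for (int k = 0; k < s; ++k) P = P * P;
  return P;
}

// [[Rcpp::export]]
arma::mat bdi_pmat_cpp(double birth, double death, double innovation,
                       double t, int n_max) {
  FlushDenormals ftz;
  return pmat_unif(birth, death, innovation, t, n_max);
}

// e^{Qt} v (or e^{Q^T t} v) by segmented uniformization on the tridiagonal
// generator.  Long intervals are split so each segment has q*t <= 500; the
// vector is rescaled between segments and the log of the applied scale is
// accumulated into *logscale.  Inner loops run on raw buffers: the term
// count is O(q t), so per-term cost must stay at a few flops per state.
static vec expmv_unif(double b, double d, double i, double t, int nmax,
                      vec v, bool transpose, double *logscale) {
  int n = nmax + 1;
  if (t <= 0.0) return v;

  // uniformized jump chain M = I + Q/q, precomputed as raw arrays
  std::vector<double> upq(n), dnq(n), diag(n);
  double q = 0.0;
  for (int k = 0; k < n; ++k) {
    double up = k * b + i, dn = k * d;
    q = std::max(q, up + dn);
  }
  if (q <= 0.0) return v;
  for (int k = 0; k < n; ++k) {
    double up = k * b + i, dn = k * d;
    upq[k] = up / q;
    dnq[k] = dn / q;
    diag[k] = 1.0 - (up + dn) / q;
  }

  double qt_total = q * t;
  int n_seg = (int)std::ceil(qt_total / 500.0);
  double qt = qt_total / n_seg;

  std::vector<double> a(n), tmp(n), acc(n);
  for (int seg = 0; seg < n_seg; ++seg) {
    for (int k = 0; k < n; ++k) a[k] = v[k];
    double w = std::exp(-qt), cum = w;
    for (int k = 0; k < n; ++k) acc[k] = w * a[k];
    int m = 0;
    // weight test as in pmat_unif: avoids spinning when cum rounds below 1
    while (1.0 - cum > 1e-15 && !(m > qt && w < 1e-18) && m < 100000) {
      ++m;
      w *= qt / m;
      cum += w;
      const double *__restrict ap = a.data();
      const double *__restrict dg = diag.data();
      const double *__restrict uq = upq.data();
      const double *__restrict dq = dnq.data();
      double *__restrict tp = tmp.data();
      if (!transpose) {
        // tmp_j = diag_j a_j + dnq_j a_{j-1} + upq_j a_{j+1}
        tp[0] = dg[0] * ap[0] + uq[0] * ap[1];
        for (int k = 1; k < n - 1; ++k) {
          tp[k] = dg[k] * ap[k] + dq[k] * ap[k - 1] + uq[k] * ap[k + 1];
        }
        tp[n - 1] = dg[n - 1] * ap[n - 1] + dq[n - 1] * ap[n - 2];
      } else {
        // tmp_k = diag_k a_k + upq_{k-1} a_{k-1} + dnq_{k+1} a_{k+1}
        tp[0] = dg[0] * ap[0] + dq[1] * ap[1];
        for (int k = 1; k < n - 1; ++k) {
          tp[k] = dg[k] * ap[k] + uq[k - 1] * ap[k - 1] + dq[k + 1] * ap[k + 1];
        }
        tp[n - 1] = dg[n - 1] * ap[n - 1] + uq[n - 2] * ap[n - 2];
      }
      a.swap(tmp);
      const double *an = a.data();
      double *cp = acc.data();
      for (int k = 0; k < n; ++k) cp[k] += w * an[k];
    }
    double mx = 0.0;
    for (int k = 0; k < n; ++k) {
      v[k] = acc[k];
      mx = std::max(mx, acc[k]);
    }
    if (mx > 0.0 && (mx < 1e-100 || mx > 1e100)) {
      for (int k = 0; k < n; ++k) v[k] /= mx;
      if (logscale) *logscale += std::log(mx);
    }
  }
  return v;
}

// [[Rcpp::export]]
Rcpp::List bdi_expmv_cpp(double birth, double death, double innovation,
                         double t, int n_max, const arma::vec &v,
                         bool transpose = false) {
  FlushDenormals ftz;
  double logscale = 0.0;
  vec out = expmv_unif(birth, death, innovation, t, n_max, v, transpose,
                       &logscale);
  return Rcpp::List::create(Rcpp::Named("v") = out,
                            Rcpp::Named("logscale") = logscale);
}

// Pruning log-likelihood of tip counts for one orthogroup.
//   edge:      n_edge x 2 (parent, child), 1-based node indices, ordered so
//              every child's subtree is processed before its parent edge
//              (ape postorder).
//   elen:      branch lengths per edge (Myr).
//   eclass:    1-based rate-class index per edge.
//   rates:     n_class x 3 (birth, death, innovation).
//   tipstate:  per node, observed count for tips, -1 for internal nodes.
//   prior:     root prior over 0..n_max.
// [[Rcpp::export]]
double bdi_loglik_cpp(const arma::imat &edge, const arma::vec &elen,
                      const arma::ivec &eclass, const arma::mat &rates,
                      const arma::ivec &tipstate, int root,
                      const arma::vec &prior, int n_max) {
  FlushDenormals ftz;
  int n = n_max + 1;
  int n_node = tipstate.n_elem;
  int n_edge = edge.n_rows;

  mat L(n, n_node);
  for (int v = 0; v < n_node; ++v) {
    if (tipstate[v] >= 0) {
      L.col(v).zeros();
      if (tipstate[v] > n_max) Rcpp::stop("tip count exceeds n_max");
      L(tipstate[v], v) = 1.0;
    } else {
      L.col(v).ones();
    }
  }

  double logscale = 0.0;
  for (int e = 0; e < n_edge; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    int cl = eclass[e] - 1;
    // rates implying > ~1000 uniformization terms on one branch mean tens
    // of expected events per gene: astronomically unlikely for count data
    // of this kind, and disproportionately expensive -- treat as -Inf so
    // the optimizer's penalty wall keeps the search in the feasible region
    double q_edge = (n_max * (rates(cl, 0) + rates(cl, 1)) + rates(cl, 2));
    if (q_edge * elen[e] > 1000.0) return -datum::inf;
    vec v = expmv_unif(rates(cl, 0), rates(cl, 1), rates(cl, 2), elen[e],
                       n_max, L.col(c), false, &logscale);
    double m = v.max();
    if (!(m > 0.0)) return -datum::inf;
    logscale += std::log(m);
    L.col(p) %= v / m;
  }
  double lik = dot(prior, L.col(root - 1));
  if (!(lik > 0.0)) return -datum::inf;
  return std::log(lik) + logscale;
}
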