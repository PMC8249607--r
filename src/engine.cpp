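// Fixed-step RK4 integrator for delay-coupled quotient networks, with
// co-integrated transverse variational blocks and Benettin renormalization.
// Delayed values come from a ring buffer of past states with linear
// interpolation between grid points; pre-history is constant.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// node models (dispatch on integer id)
//   1 linear:   n=1, pars (a)                f = a*x
//   2 kuramoto: n=1, pars (omega)            f = omega
//   3 neuron:   n=3, pars (a, alpha, b, c, e)
// ---------------------------------------------------------------------------
static inline void node_f(int id, const double* p, const double* x, double* dx) {
  switch (id) {
  case 1: dx[0] = p[0] * x[0]; break;
  case 2: dx[0] = p[0]; break;
  case 3: {
    const double a = p[0], al = p[1], b = p[2], c = p[3], e = p[4];
    const double x0 = x[0];
    dx[0] = a * x0 * x0 - x0 * x0 * x0 - x[1] - x[2];
    dx[1] = (a + al) * x0 * x0 - x[1];
    dx[2] = c * (b * x0 - x[2] + e);
    break;
  }
  default: stop("unknown node model id");
  }
}

// Jacobian, row-major n x n
static inline void node_Df(int id, const double* p, const double* x, double* J, int n) {
  std::memset(J, 0, sizeof(double) * n * n);
  switch (id) {
  case 1: J[0] = p[0]; break;
  case 2: J[0] = 0.0; break;
  case 3: {
    const double a = p[0], al = p[1], b = p[2], c = p[3];
    const double x0 = x[0];
    J[0] = 2.0 * a * x0 - 3.0 * x0 * x0; J[1] = -1.0; J[2] = -1.0;
    J[3] = 2.0 * (a + al) * x0;          J[4] = -1.0; J[5] = 0.0;
    J[6] = c * b;                        J[7] = 0.0;  J[8] = -c;
    break;
  }
  default: stop("unknown node model id");
  }
}

// ---------------------------------------------------------------------------
// coupling models (per layer)
//   1 diffusive first component: h = (xj0 - xi0, 0, ...)
//   2 sigmoid chemical, pars (d, lambda, theta): h = ((d - xi0) g(xj0), 0, ...)
//   3 kuramoto sine: h = sin(xj0 - xi0)          (n = 1)
// ---------------------------------------------------------------------------
static inline double sigmoid(double u, double lambda, double theta) {
  return 1.0 / (1.0 + std::exp(-lambda * (u - theta)));
}

static inline void coup_h(int id, const double* p, const double* xi,
                          const double* xj, double* out, int n) {
  std::memset(out, 0, sizeof(double) * n);
  switch (id) {
  case 1: out[0] = xj[0] - xi[0]; break;
  case 2: out[0] = (p[0] - xi[0]) * sigmoid(xj[0], p[1], p[2]); break;
  case 3: out[0] = std::sin(xj[0] - xi[0]); break;
  default: stop("unknown coupling id");
  }
}

// partial derivatives w.r.t. receiver (D1) and delayed sender (D2);
// all three couplings act on the first state component only, so we return
// the scalar (0,0) entry.
static inline double coup_D1(int id, const double* p, const double* xi, const double* xj) {
  switch (id) {
  case 1: return -1.0;
  case 2: return -sigmoid(xj[0], p[1], p[2]);
  case 3: return -std::cos(xj[0] - xi[0]);
  default: stop("unknown coupling id");
  }
}

static inline double coup_D2(int id, const double* p, const double* xi, const double* xj) {
  switch (id) {
  case 1: return 1.0;
  case 2: {
    const double s = sigmoid(xj[0], p[1], p[2]);
    return (p[0] - xi[0]) * p[1] * s * (1.0 - s);
  }
  case 3: return std::cos(xj[0] - xi[0]);
  default: stop("unknown coupling id");
  }
}

// ---------------------------------------------------------------------------
// system container
// ---------------------------------------------------------------------------
struct QuotientSys {
  int Q, n, L;
  std::vector<int> model_id;          // per quotient node
  std::vector<std::vector<double>> model_pars;
  std::vector<double> sigma, delay;
  std::vector<int> coup_id;
  std::vector<std::vector<double>> coup_pars;
  std::vector<NumericMatrix> R;       // Q x Q per layer
  // variational block (optional)
  int m = 0;                          // block rows
  std::vector<int> rowq;              // quotient node per block row (0-based)
  std::vector<NumericMatrix> Bb;      // m x m per layer
  int sdim() const { return Q * n; }
  int dim() const { return Q * n + m * n; }
};

static QuotientSys make_sys(const List& sys) {
  QuotientSys S;
  S.Q = as<int>(sys["Q"]);
  S.n = as<int>(sys["n"]);
  IntegerVector mid = sys["model_id"];
  List mp = sys["model_pars"];
  for (int q = 0; q < S.Q; ++q) {
    S.model_id.push_back(mid[q]);
    S.model_pars.push_back(as<std::vector<double>>(mp[q]));
  }
  S.sigma = as<std::vector<double>>(sys["sigma"]);
  S.delay = as<std::vector<double>>(sys["delay"]);
  IntegerVector cid = sys["coupling_id"];
  List cp = sys["coupling_pars"];
  List Rl = sys["R"];
  S.L = Rl.size();
  for (int k = 0; k < S.L; ++k) {
    S.coup_id.push_back(cid[k]);
    S.coup_pars.push_back(as<std::vector<double>>(cp[k]));
    S.R.push_back(as<NumericMatrix>(Rl[k]));
  }
  return S;
}

// history ring buffer over the combined state
struct History {
  int dim, nslot;
  double dt;
  long step0 = 0;                 // step index of slot cursor start
  long count = 0;                 // number of stored steps so far
  std::vector<double> buf;        // nslot * dim
  std::vector<double> pre;        // constant pre-history state
  History(int dim_, int nslot_, double dt_, const double* y0)
    : dim(dim_), nslot(nslot_), dt(dt_), buf((size_t)nslot_ * dim_),
      pre(y0, y0 + dim_) {}
  double* slot(long step) { return buf.data() + (size_t)(step % nslot) * dim; }
  void push(long step, const double* y) {
    std::memcpy(slot(step), y, sizeof(double) * dim);
    count = step + 1;
  }
  // state component j at time t (t <= current time); linear interpolation
  double at(double t, int j) {
    double sq = t / dt;
    long i0 = (long)std::floor(sq);
    double frac = sq - i0;
    const double* a = (i0 < 0) ? pre.data() : slot(i0);
    const double* b = (i0 + 1 < 0) ? pre.data() : slot(i0 + 1);
    if (i0 >= count) a = slot(count - 1);
    if (i0 + 1 >= count) b = (count > 0) ? slot(count - 1) : pre.data();
    return (1.0 - frac) * a[j] + frac * b[j];
  }
  void scale_eta(int offset, double fac) {
    long lo = count - nslot; if (lo < 0) lo = 0;
    for (long s = lo; s < count; ++s) {
      double* y = slot(s);
      for (int j = offset; j < dim; ++j) y[j] *= fac;
    }
    for (int j = offset; j < dim; ++j) pre[j] *= fac;
  }
};

// combined derivative: quotient + (optionally) variational block
static void deriv(const QuotientSys& S, History& H, double t,
                  const double* y, double* dy) {
  const int n = S.n, Q = S.Q, sd = Q * n;
  std::vector<double> xd(n), hout(n), J(n * n);
  // quotient nodes
  for (int q = 0; q < Q; ++q) {
    const double* xq = y + q * n;
    node_f(S.model_id[q], S.model_pars[q].data(), xq, dy + q * n);
    for (int k = 0; k < S.L; ++k) {
      const NumericMatrix& R = S.R[k];
      const double dl = S.delay[k];
      for (int q2 = 0; q2 < Q; ++q2) {
        const double r = R(q, q2);
        if (r == 0.0) continue;
        const double* xj;
        if (dl == 0.0) {
          xj = y + q2 * n;
        } else {
          for (int c = 0; c < n; ++c) xd[c] = H.at(t - dl, q2 * n + c);
          xj = xd.data();
        }
        coup_h(S.coup_id[k], S.coup_pars[k].data(), xq, xj, hout.data(), n);
        const double s = S.sigma[k] * r;
        for (int c = 0; c < n; ++c) dy[q * n + c] += s * hout[c];
      }
    }
  }
  if (S.m == 0) return;
  // variational block rows
  std::vector<double> sq_now(n), sq2(n), ed(n);
  for (int r = 0; r < S.m; ++r) {
    const int q = S.rowq[r];
    const double* sqv = y + q * n;           // synchronous state of this row's cluster
    const double* eta = y + sd + r * n;
    double* de = dy + sd + r * n;
    // Psi1 block: Df + sum_k sigma_k sum_q2 R_{q q2} D1h
    node_Df(S.model_id[q], S.model_pars[q].data(), sqv, J.data(), n);
    for (int k = 0; k < S.L; ++k) {
      const NumericMatrix& R = S.R[k];
      const double dl = S.delay[k];
      for (int q2 = 0; q2 < Q; ++q2) {
        const double rr = R(q, q2);
        if (rr == 0.0) continue;
        const double* xj;
        if (dl == 0.0) xj = y + q2 * n;
        else {
          for (int c = 0; c < n; ++c) sq2[c] = H.at(t - dl, q2 * n + c);
          xj = sq2.data();
        }
        J[0] += S.sigma[k] * rr * coup_D1(S.coup_id[k], S.coup_pars[k].data(), sqv, xj);
      }
    }
    for (int a = 0; a < n; ++a) {
      double acc = 0.0;
      for (int b = 0; b < n; ++b) acc += J[a * n + b] * eta[b];
      de[a] = acc;
    }
    // Psi2 terms: sum_k sigma_k B^k_{r l} D2h(s_{q_r}(t), s_{q_l}(t-d)) eta_l(t-d)
    for (int k = 0; k < S.L; ++k) {
      const NumericMatrix& B = S.Bb[k];
      const double dl = S.delay[k];
      for (int l = 0; l < S.m; ++l) {
        const double bb = B(r, l);
        if (bb == 0.0) continue;
        const int ql = S.rowq[l];
        const double* xj;
        const double* etal;
        if (dl == 0.0) {
          xj = y + ql * n;
          etal = y + sd + l * n;
        } else {
          for (int c = 0; c < n; ++c) sq2[c] = H.at(t - dl, ql * n + c);
          xj = sq2.data();
          for (int c = 0; c < n; ++c) ed[c] = H.at(t - dl, sd + l * n + c);
          etal = ed.data();
        }
        const double d2 = coup_D2(S.coup_id[k], S.coup_pars[k].data(), sqv, xj);
        de[0] += S.sigma[k] * bb * d2 * etal[0];
      }
    }
  }
}

static bool rk4_step(const QuotientSys& S, History& H, long step, double dt,
                     std::vector<double>& y, std::vector<double>& k1,
                     std::vector<double>& k2, std::vector<double>& k3,
                     std::vector<double>& k4, std::vector<double>& tmp) {
  const int D = (int)y.size();
  const double t = step * dt;
  deriv(S, H, t, y.data(), k1.data());
  for (int j = 0; j < D; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
  deriv(S, H, t + 0.5 * dt, tmp.data(), k2.data());
  for (int j = 0; j < D; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
  deriv(S, H, t + 0.5 * dt, tmp.data(), k3.data());
  for (int j = 0; j < D; ++j) tmp[j] = y[j] + dt * k3[j];
  deriv(S, H, t + dt, tmp.data(), k4.data());
  for (int j = 0; j < D; ++j) {
    y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    if (!std::isfinite(y[j])) return false;
  }
  return true;
}

static int hist_slots(const QuotientSys& S, double dt) {
  double dmax = 0.0;
  for (double d : S.delay) if (d > dmax) dmax = d;
  int ns = (int)std::ceil(dmax / dt) + 4;
  return ns < 8 ? 8 : ns;
}

// [[Rcpp::export]]
List cpp_integrate(List sys, NumericVector y0, double t_transient,
                   double t_record, double dt, int record_every) {
  QuotientSys S = make_sys(sys);
  const int D = S.sdim();
  if ((int)y0.size() != D) stop("y0 has wrong length");
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(D), k2(D), k3(D), k4(D), tmp(D);
  History H(D, hist_slots(S, dt), dt, y.data());
  long nt = (long)std::llround(t_transient / dt);
  long nr = (long)std::llround(t_record / dt);
  long nrec = nr / record_every + 1;
  NumericMatrix out(nrec, D);
  NumericVector times(nrec);
  long irec = 0;
  H.push(0, y.data());
  for (long step = 0; step < nt + nr; ++step) {
    if (step >= nt && (step - nt) % record_every == 0) {
      times[irec] = step * dt;
      for (int j = 0; j < D; ++j) out(irec, j) = y[j];
      ++irec;
    }
    if (!rk4_step(S, H, step, dt, y, k1, k2, k3, k4, tmp))
      stop("state diverged (non-finite) at t = %f", step * dt);
    H.push(step + 1, y.data());
  }
  if (irec < nrec) {
    times[irec] = (nt + nr) * dt;
    for (int j = 0; j < D; ++j) out(irec, j) = y[j];
    ++irec;
  }
  return List::create(_["times"] = times[Range(0, irec - 1)],
                      _["states"] = out(Range(0, irec - 1), _));
}

// [[Rcpp::export]]
List cpp_mle(List sys, NumericVector y0, IntegerVector rowq, List Bblock,
             NumericVector eta0, double dt, double t_transient,
             double t_total, double renorm_interval) {
  QuotientSys S = make_sys(sys);
  S.m = rowq.size();
  for (int r = 0; r < S.m; ++r) S.rowq.push_back(rowq[r]);
  for (int k = 0; k < S.L; ++k) S.Bb.push_back(as<NumericMatrix>(Bblock[k]));
  const int sd = S.sdim(), D = S.sdim() + S.m * S.n;
  if ((int)y0.size() != sd) stop("y0 has wrong length");
  if ((int)eta0.size() != S.m * S.n) stop("eta0 has wrong length");

  // Co-integrate quotient and perturbation from the start; renormalize
  // throughout (this also aligns eta with the leading direction during the
  // transient) but accumulate log-norms only after the transient.
  std::vector<double> y(D);
  for (int j = 0; j < sd; ++j) y[j] = y0[j];
  double nrm0 = 0.0;
  for (int j = 0; j < S.m * S.n; ++j) nrm0 += eta0[j] * eta0[j];
  nrm0 = std::sqrt(nrm0);
  if (nrm0 <= 0) stop("eta0 must be nonzero");
  for (int j = 0; j < S.m * S.n; ++j) y[sd + j] = eta0[j] / nrm0;
  std::vector<double> k1(D), k2(D), k3(D), k4(D), tmp(D);
  History H(D, hist_slots(S, dt), dt, y.data());
  H.push(0, y.data());
  long nt = (long)std::llround(t_transient / dt);
  long ntot = (long)std::llround(t_total / dt);
  long K = (long)std::llround(renorm_interval / dt);
  if (K < 1) K = 1;
  std::vector<double> logs;
  bool unstable = false;
  for (long step = 0; step < nt + ntot; ++step) {
    if (!rk4_step(S, H, step, dt, y, k1, k2, k3, k4, tmp)) { unstable = true; break; }
    H.push(step + 1, y.data());
    if ((step + 1) % K == 0) {
      double nrm = 0.0;
      for (int j = sd; j < D; ++j) nrm += y[j] * y[j];
      nrm = std::sqrt(nrm);
      if (!std::isfinite(nrm) || nrm == 0.0) { unstable = !std::isfinite(nrm); break; }
      if (step + 1 > nt) logs.push_back(std::log(nrm));
      const double fac = 1.0 / nrm;
      for (int j = sd; j < D; ++j) y[j] *= fac;
      H.scale_eta(sd, fac);
    }
  }
  double mle, se = NA_REAL;
  if (unstable) {
    mle = R_PosInf;
  } else if (logs.empty()) {
    mle = NA_REAL;
  } else {
    double sum = 0.0;
    for (double v : logs) sum += v;
    mle = sum / ((double)logs.size() * K * dt);
    size_t half = logs.size() / 2;
    if (logs.size() - half > 1) {
      double mu = 0.0; size_t cnt = logs.size() - half;
      for (size_t i = half; i < logs.size(); ++i) mu += logs[i] / (K * dt);
      mu /= cnt;
      double ss = 0.0;
      for (size_t i = half; i < logs.size(); ++i) {
        double d = logs[i] / (K * dt) - mu; ss += d * d;
      }
      se = std::sqrt(ss / (cnt - 1) / cnt);
    }
  }
  return List::create(_["mle"] = mle, _["se"] = se,
                      _["n_renorm"] = (int)logs.size(),
                      _["final_state"] = NumericVector(y.begin(), y.begin() + sd));
}

// ---------------------------------------------------------------------------
// brute-force balanced-partition enumeration over restricted growth strings
// ---------------------------------------------------------------------------
static bool balanced_cpp(const std::vector<NumericMatrix>& A, int N,
                         const std::vector<int>& col, int Q, double tol) {
  std::vector<double> Sm((size_t)N * Q);
  for (const NumericMatrix& Ak : A) {
    std::fill(Sm.begin(), Sm.end(), 0.0);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) {
        double a = Ak(i, j);
        if (a != 0.0) Sm[(size_t)i * Q + col[j]] += a;
      }
    // rows within a block must agree
    std::vector<int> rep(Q, -1);
    for (int i = 0; i < N; ++i) {
      int b = col[i];
      if (rep[b] < 0) { rep[b] = i; continue; }
      const double* ri = Sm.data() + (size_t)i * Q;
      const double* rr = Sm.data() + (size_t)rep[b] * Q;
      for (int qq = 0; qq < Q; ++qq) {
        double scale = std::max(1.0, std::fabs(rr[qq]));
        if (std::fabs(ri[qq] - rr[qq]) > tol * scale) return false;
      }
    }
  }
  return true;
}

static void rgs_rec(const std::vector<NumericMatrix>& A, int N,
                    const std::vector<int>& types, std::vector<int>& col,
                    std::vector<int>& btype, int i, int used, double tol,
                    List& out) {
  if (i == N) {
    if (balanced_cpp(A, N, col, used, tol)) {
      IntegerVector v(N);
      for (int j = 0; j < N; ++j) v[j] = col[j] + 1;
      out.push_back(v);
    }
    return;
  }
  for (int b = 0; b <= used && b < N; ++b) {
    if (b < used && btype[b] != types[i]) continue;
    col[i] = b;
    int nu = (b == used) ? used + 1 : used;
    if (b == used) btype[b] = types[i];
    rgs_rec(A, N, types, col, btype, i + 1, nu, tol, out);
  }
}

// iterated refinement to the coarsest balanced coloring below color0:
// split colors on the signature (old color, per-layer per-color input sums
// printed to 9 significant digits) until stable; colors renumbered by first
// appearance.
// [[Rcpp::export]]
IntegerVector cpp_refine_coloring(List Alist, IntegerVector color0) {
  const int N = color0.size();
  std::vector<NumericMatrix> A;
  for (int k = 0; k < Alist.size(); ++k) A.push_back(as<NumericMatrix>(Alist[k]));
  std::vector<int> color(N);
  for (int i = 0; i < N; ++i) color[i] = color0[i] - 1;
  int ncol = 0;
  for (int i = 0; i < N; ++i) ncol = std::max(ncol, color[i] + 1);
  char buf[40];
  std::vector<double> S;
  for (;;) {
    std::vector<std::string> sig(N);
    for (int i = 0; i < N; ++i) {
      snprintf(buf, sizeof(buf), "c%d", color[i]);
      sig[i] = buf;
    }
    for (const NumericMatrix& Ak : A) {
      S.assign((size_t)N * ncol, 0.0);
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j) {
          double a = Ak(i, j);
          if (a != 0.0) S[(size_t)i * ncol + color[j]] += a;
        }
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < ncol; ++c) {
          snprintf(buf, sizeof(buf), " %.9g", S[(size_t)i * ncol + c]);
          sig[i] += buf;
        }
    }
    std::map<std::string, int> seen;
    std::vector<int> newc(N);
    int nn = 0;
    for (int i = 0; i < N; ++i) {
      auto it = seen.find(sig[i]);
      if (it == seen.end()) { seen.emplace(sig[i], nn); newc[i] = nn++; }
      else newc[i] = it->second;
    }
    if (nn == ncol) break;
    color = newc;
    ncol = nn;
  }
  // renumber by first appearance
  std::vector<int> remap(ncol, -1);
  int nn = 0;
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) {
    if (remap[color[i]] < 0) remap[color[i]] = nn++;
    out[i] = remap[color[i]] + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_enumerate_balanced(List Alist, IntegerVector types, double tol) {
  std::vector<NumericMatrix> A;
  for (int k = 0; k < Alist.size(); ++k) A.push_back(as<NumericMatrix>(Alist[k]));
  const int N = types.size();
  std::vector<int> col(N, 0), btype(N, 0);
  List out;
  std::vector<int> ty(types.begin(), types.end());
  rgs_rec(A, N, ty, col, btype, 0, 0, tol, out);
  return out;
}
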