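#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// MuSSE ordinary differential equations, integrated tipward -> rootward.
// State vector y = (E_1..E_k, D_1..D_k):
//   dE_i/dt = mu_i - (lambda_i + mu_i + qrow_i) E_i + lambda_i E_i^2
//             + sum_{j != i} q_ij E_j
//   dD_i/dt = -(lambda_i + mu_i + qrow_i) D_i + 2 lambda_i E_i D_i
//             + sum_{j != i} q_ij D_j
// qrow_i = sum_{j != i} q_ij.

struct MusseSystem {
  int k;
  std::vector<double> lambda, mu, qrow, q; // q row-major k*k, zero diagonal

  MusseSystem(const NumericVector &lam, const NumericVector &m,
              const NumericMatrix &Q) {
    k = lam.size();
    lambda.assign(lam.begin(), lam.end());
    mu.assign(m.begin(), m.end());
    q.assign((size_t)k * k, 0.0);
    qrow.assign(k, 0.0);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (i != j) {
          q[(size_t)i * k + j] = Q(i, j);
          qrow[i] += Q(i, j);
        }
  }

  void rhs(const double *y, double *dy) const {
    const double *E = y;
    const double *D = y + k;
    double *dE = dy;
    double *dD = dy + k;
    for (int i = 0; i < k; ++i) {
      double sqE = 0.0, sqD = 0.0;
      const double *qi = &q[(size_t)i * k];
      for (int j = 0; j < k; ++j) {
        sqE += qi[j] * E[j];
        sqD += qi[j] * D[j];
      }
      const double tot = lambda[i] + mu[i] + qrow[i];
      dE[i] = mu[i] - tot * E[i] + lambda[i] * E[i] * E[i] + sqE;
      dD[i] = -tot * D[i] + 2.0 * lambda[i] * E[i] * D[i] + sqD;
    }
  }
};

// Reusable scratch space so per-branch calls do not allocate.
struct RkWorkspace {
  std::vector<double> k1, k2, k3, k4, k5, k6, ytmp, ynew, yerr;
  explicit RkWorkspace(int n)
      : k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), ytmp(n), ynew(n), yerr(n) {}
};

// Cash-Karp embedded Runge-Kutta 4(5) with adaptive step size.
// Integrates y over duration t; rescales the D block if it threatens to
// underflow, accumulating the log factor in *logcomp.  Throws on failure.
static void integrate_branch(const MusseSystem &sys, std::vector<double> &y,
                             double t, double rtol, double atol,
                             double *logcomp, RkWorkspace &ws) {
  if (t < 0) stop("negative branch duration");
  if (t == 0) return;
  const int n = 2 * sys.k;
  const int k = sys.k;

  static const double b21 = 0.2;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                      d6 = c6 - 0.25;

  std::vector<double> &k1 = ws.k1, &k2 = ws.k2, &k3 = ws.k3, &k4 = ws.k4,
                      &k5 = ws.k5, &k6 = ws.k6, &ytmp = ws.ytmp,
                      &ynew = ws.ynew, &yerr = ws.yerr;

  double tcur = 0.0;
  double h = t; // first trial step: whole branch (short branches are common)
  long nsteps = 0;
  const long max_steps = 2000000;

  while (tcur < t) {
    if (++nsteps > max_steps)
      stop("ODE solver failed: step limit reached on a branch of length %g", t);
    if (h > t - tcur) h = t - tcur;

    sys.rhs(y.data(), k1.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    sys.rhs(ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    sys.rhs(ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    sys.rhs(ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                            b54 * k4[i]);
    sys.rhs(ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    sys.rhs(ytmp.data(), k6.data());

    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                     d6 * k6[i]);
      const double sc = atol + rtol * std::fabs(ynew[i]);
      const double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }

    if (errmax <= 1.0) { // accept
      tcur += h;
      y = ynew;
      // guard against D underflow mid-branch
      double dmax = 0.0;
      for (int i = 0; i < k; ++i)
        if (y[k + i] > dmax) dmax = y[k + i];
      if (dmax > 0.0 && dmax < 1e-150) {
        for (int i = 0; i < k; ++i) y[k + i] /= dmax;
        *logcomp += std::log(dmax);
      }
      double fac = (errmax < 1e-12) ? 5.0 : 0.9 * std::pow(errmax, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14 * t)
        stop("ODE solver failed: tolerance not met (step underflow)");
    }
  }
}

// [[Rcpp::export]]
List musse_branch_cpp(NumericVector E0, NumericVector D0, double t,
                      NumericVector lambda, NumericVector mu, NumericMatrix Q,
                      double rtol, double atol) {
  const int k = lambda.size();
  if (E0.size() != k || D0.size() != k) stop("state length must equal k");
  MusseSystem sys(lambda, mu, Q);
  std::vector<double> y(2 * k);
  for (int i = 0; i < k; ++i) {
    y[i] = E0[i];
    y[k + i] = D0[i];
  }
  double logcomp = 0.0;
  RkWorkspace ws(2 * k);
  integrate_branch(sys, y, t, rtol, atol, &logcomp, ws);
  NumericVector E(k), D(k);
  for (int i = 0; i < k; ++i) {
    E[i] = y[i];
    D[i] = y[k + i];
  }
  return List::create(_["E"] = E, _["D"] = D, _["logcomp"] = logcomp);
}

// Full-tree pruning likelihood.
// edge: 2-column matrix in postorder (ape node ids, 1-based), edge_len
// matching.  tip_state: 0-based state per tip id 1..ntip, NA for unknown.
// root_mode: 0 = weighted-by-data (FitzJohn), 1 = equal, 2 = given vector.
// Conditioning on survival divides D_i by lambda_i (1 - E_i)^2 element-wise
// before the weights are formed.
// [[Rcpp::export]]
double musse_loglik_cpp(IntegerMatrix edge, NumericVector edge_len, int ntip,
                        IntegerVector tip_state, NumericVector lambda,
                        NumericVector mu, NumericMatrix Q, NumericVector f,
                        int root_mode, bool condition_surv,
                        NumericVector root_prior, double rtol, double atol) {
  const int k = lambda.size();
  const int nedge = edge.nrow();
  const int nnode_total = ntip + (nedge / 2); // binary rooted: nedge = 2*(n-1)

  MusseSystem sys(lambda, mu, Q);

  std::vector<double> Dn((size_t)(nnode_total + 1) * k, 0.0);
  std::vector<double> En((size_t)(nnode_total + 1) * k, 0.0);
  std::vector<double> logc(nnode_total + 1, 0.0);
  std::vector<int> nseen(nnode_total + 1, 0);

  std::vector<double> y(2 * k);
  RkWorkspace ws(2 * k);

  for (int e = 0; e < nedge; ++e) {
    const int child = edge(e, 1);
    const int parent = edge(e, 0);
    double acc = 0.0;

    if (child <= ntip) {
      const int st = tip_state[child - 1];
      for (int i = 0; i < k; ++i) {
        y[i] = 1.0 - f[i];
        if (st == NA_INTEGER || st < 0)
          y[k + i] = f[i];
        else
          y[k + i] = (i == st) ? f[i] : 0.0;
      }
    } else {
      if (nseen[child] != 2) stop("internal node %d is not binary", child);
      for (int i = 0; i < k; ++i) {
        y[i] = En[(size_t)child * k + i];
        y[k + i] = Dn[(size_t)child * k + i];
      }
      acc = logc[child];
    }

    integrate_branch(sys, y, edge_len[e], rtol, atol, &acc, ws);

    if (nseen[parent] == 0) {
      for (int i = 0; i < k; ++i) {
        En[(size_t)parent * k + i] = y[i];
        Dn[(size_t)parent * k + i] = y[k + i];
      }
      logc[parent] = acc;
      nseen[parent] = 1;
    } else if (nseen[parent] == 1) {
      double dmax = 0.0;
      for (int i = 0; i < k; ++i) {
        double d = lambda[i] * Dn[(size_t)parent * k + i] * y[k + i];
        Dn[(size_t)parent * k + i] = d;
        if (d > dmax) dmax = d;
      }
      logc[parent] += acc;
      if (dmax > 0.0) {
        for (int i = 0; i < k; ++i) Dn[(size_t)parent * k + i] /= dmax;
        logc[parent] += std::log(dmax);
      }
      nseen[parent] = 2;
    } else {
      stop("node %d has more than two children (polytomy)", parent);
    }
  }

  const int root = ntip + 1;
  if (nseen[root] != 2) stop("root was not visited exactly twice");

  std::vector<double> Dr(k), w(k);
  double dsum = 0.0;
  for (int i = 0; i < k; ++i) {
    double d = Dn[(size_t)root * k + i];
    if (condition_surv) {
      const double e = En[(size_t)root * k + i];
      const double denom = lambda[i] * (1.0 - e) * (1.0 - e);
      d = (denom > 0.0) ? d / denom : 0.0;
    }
    Dr[i] = d;
    dsum += d;
  }

  double lik = 0.0;
  if (root_mode == 0) {
    if (dsum <= 0.0) return R_NegInf;
    for (int i = 0; i < k; ++i) lik += Dr[i] * (Dr[i] / dsum);
  } else if (root_mode == 1) {
    for (int i = 0; i < k; ++i) lik += Dr[i] / k;
  } else {
    for (int i = 0; i < k; ++i) lik += Dr[i] * root_prior[i];
  }
  if (!(lik > 0.0) || !std::isfinite(lik)) return R_NegInf;
  return std::log(lik) + logc[root];
}

// Gillespie simulation of a k-state trait-dependent birth-death tree from a
// single stem lineage.  Stops either at the moment the (stop_taxa + 1)-th
// birth would occur, or at stop_time.  Uses R's RNG.
// Returns per-lineage records; type: 0 split, 1 extinct tip, 2 extant tip.
// [[Rcpp::export]]
List gillespie_musse_cpp(NumericVector lambda, NumericVector mu,
                         NumericMatrix Q, int root_state, int stop_taxa,
                         double stop_time, double max_events) {
  const int k = lambda.size();
  std::vector<double> qrow(k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) qrow[i] += Q(i, j);

  std::vector<int> parent(1, 0), state(1, root_state), type(1, -1);
  std::vector<double> tstart(1, 0.0), tend(1, NA_REAL);

  // living lineages bucketed by state for O(k) event selection
  std::vector<std::vector<int> > living(k);
  std::vector<int> slot(1, 0); // index of lineage within its bucket
  living[root_state].push_back(0);
  int nliving = 1;

  double tcur = 0.0;
  double nev = 0.0;

  auto remove_living = [&](int lin) {
    const int s = state[lin];
    const int pos = slot[lin];
    const int last = living[s].back();
    living[s][pos] = last;
    slot[last] = pos;
    living[s].pop_back();
  };

  while (nliving > 0) {
    if (++nev > max_events) stop("event cap exceeded");
    double total = 0.0;
    for (int s = 0; s < k; ++s)
      total += living[s].size() * (lambda[s] + mu[s] + qrow[s]);
    if (total <= 0.0) { tcur = stop_time; break; } // frozen: nothing can happen
    const double dt = R::exp_rand() / total;
    if (tcur + dt >= stop_time) { tcur = stop_time; break; }
    tcur += dt;

    // choose state bucket, then event type, then lineage
    double u = unif_rand() * total;
    int s = k - 1;
    for (int i = 0; i < k; ++i) {
      const double r = living[i].size() * (lambda[i] + mu[i] + qrow[i]);
      if (u < r) { s = i; break; }
      u -= r;
    }
    const int lin =
        living[s][(int)std::floor(unif_rand() * living[s].size())];
    double v = unif_rand() * (lambda[s] + mu[s] + qrow[s]);

    if (v < lambda[s]) {
      // birth: if we already hold the target number of tips, sample here
      if (stop_taxa > 0 && nliving == stop_taxa) break;
      type[lin] = 0;
      tend[lin] = tcur;
      remove_living(lin);
      for (int c = 0; c < 2; ++c) {
        parent.push_back(lin + 1); // 1-based parent id
        state.push_back(s);
        type.push_back(-1);
        tstart.push_back(tcur);
        tend.push_back(NA_REAL);
        slot.push_back((int)living[s].size());
        living[s].push_back((int)parent.size() - 1);
      }
      ++nliving;
    } else if (v < lambda[s] + mu[s]) {
      type[lin] = 1;
      tend[lin] = tcur;
      remove_living(lin);
      --nliving;
    } else {
      // state change
      v -= lambda[s] + mu[s];
      int s2 = -1;
      for (int j = 0; j < k; ++j) {
        if (j == s) continue;
        if (v < Q(s, j)) { s2 = j; break; }
        v -= Q(s, j);
      }
      if (s2 < 0) s2 = (s == k - 1) ? k - 2 : k - 1; // numerical edge
      remove_living(lin);
      state[lin] = s2;
      slot[lin] = (int)living[s2].size();
      living[s2].push_back(lin);
    }
  }

  // close survivors at tcur
  const int m = (int)parent.size();
  for (int i = 0; i < m; ++i) {
    if (type[i] == -1) {
      type[i] = 2;
      tend[i] = tcur;
    }
  }

  return List::create(
      _["parent"] = IntegerVector(parent.begin(), parent.end()),
      _["state"] = IntegerVector(state.begin(), state.end()),
      _["type"] = IntegerVector(type.begin(), type.end()),
      _["tstart"] = NumericVector(tstart.begin(), tstart.end()),
      _["tend"] = NumericVector(tend.begin(), tend.end()),
      _["t_stop"] = tcur);
}

// Eigenvector in-centrality of a non-negative weight matrix by power
// iteration on the transpose, uniform start, sup-norm normalisation so the
// maximum is exactly 1.  Period-2 oscillation is resolved by averaging the
// last two iterates; anything else past max_iter is an error.
// [[Rcpp::export]]
NumericVector power_centrality_cpp(NumericMatrix W, double tol, int max_iter) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  std::vector<double> x(n, 1.0), xnew(n), xprev(n, 1.0);
  bool any_pos = false;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (W(i, j) < 0) stop("negative weight");
      if (W(i, j) > 0) any_pos = true;
    }
  if (!any_pos) stop("weight matrix has no positive entry");

  for (int it = 0; it < max_iter; ++it) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += W(i, j) * x[i]; // in-centrality
      xnew[j] = s;
      if (s > mx) mx = s;
    }
    if (mx <= 0.0) stop("power iteration collapsed to zero vector");
    double dlast = 0.0, dprev = 0.0;
    for (int j = 0; j < n; ++j) {
      xnew[j] /= mx;
      double a = std::fabs(xnew[j] - x[j]);
      double b = std::fabs(xnew[j] - xprev[j]);
      if (a > dlast) dlast = a;
      if (b > dprev) dprev = b;
    }
    if (dlast < tol) return NumericVector(xnew.begin(), xnew.end());
    if (dprev < tol) { // period-2 oscillation: average the two iterates
      double mx2 = 0.0;
      for (int j = 0; j < n; ++j) {
        xnew[j] = 0.5 * (xnew[j] + x[j]);
        if (xnew[j] > mx2) mx2 = xnew[j];
      }
      for (int j = 0; j < n; ++j) xnew[j] /= mx2;
      return NumericVector(xnew.begin(), xnew.end());
    }
    xprev = x;
    x = xnew;
  }
  stop("eigenvector centrality did not converge in %d iterations", max_iter);
}
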