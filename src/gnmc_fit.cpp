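// Cyclic coordinate-descent engine for the joint network + multinomial
// classifier objective:
//
//   -loglik(B, Theta, theta0) + 0.5 * ||Y - XB||_F^2
//     + l1 * sum_j ||beta_j||_1 + (l2/2) * sum_j ||beta_j||_2^2
//     + l3 * sum_g ||theta_g||_1 + (l4/2) * sum_g theta_g' Ls_g theta_g
//
// Each outer cycle linearises the likelihood (Fisher scoring working
// responses), sweeps beta then theta coordinates with soft-thresholding,
// updates the intercepts, and ends with a step-halving acceptance check on
// the exact objective so the recorded trace is non-increasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double a, double b) {
  if (a > 0.0 && b < std::fabs(a)) return a - b;
  if (a < 0.0 && b < std::fabs(a)) return a + b;
  return 0.0;
}

// Edge weights, degrees and normalised Laplacian from a square B.
// w_ij = (|b_ij| + |b_ji|)/2 off-diagonal, zero self-weights.
static void graph_from_B(const mat& B, mat& W, vec& d, mat& L) {
  const uword k = B.n_cols;
  W = (abs(B) + abs(B.t())) / 2.0;
  W.diag().zeros();
  d = sum(W, 1);
  L.zeros(k, k);
  for (uword i = 0; i < k; ++i) {
    if (d(i) > 0.0) L(i, i) = 1.0;
    for (uword j = 0; j < k; ++j) {
      if (i != j && W(i, j) != 0.0 && d(i) > 0.0 && d(j) > 0.0)
        L(i, j) = -W(i, j) / std::sqrt(d(i) * d(j));
    }
  }
}

// Exact objective. The Laplacian term is evaluated as |theta|' L |theta|,
// identical to theta' (S L S) theta with S = diag(sgn(theta)), sgn(0) := +1,
// and continuous in (B, Theta).
static double objective_full(const mat& X, const mat& Y, const mat& Z,
                             const mat& B, const mat& Th, const vec& th0,
                             double l1, double l2, double l3, double l4,
                             bool graph) {
  mat F = X * B;
  mat eta = F * Th.t();
  eta.each_row() += th0.t();
  vec m = max(eta, 1);
  vec lse = m + log(sum(exp(eta.each_col() - m), 1));
  double ll = accu(Z % eta) - accu(lse);
  double rss = 0.5 * accu(square(Y - F));
  double pen = l1 * accu(abs(B)) + 0.5 * l2 * accu(square(B)) +
               l3 * accu(abs(Th));
  if (graph && l4 > 0.0) {
    mat W, L;
    vec d;
    graph_from_B(B, W, d, L);
    for (uword g = 0; g < Th.n_rows; ++g) {
      rowvec a = abs(Th.row(g));
      pen += 0.5 * l4 * as_scalar(a * L * a.t());
    }
  }
  return -ll + rss + pen;
}

// [[Rcpp::export]]
Rcpp::List gnmc_fit_cpp(const arma::mat& X, const arma::mat& Y,
                        const arma::mat& Z, double l1, double l2, double l3,
                        double l4, arma::mat B, arma::mat Th, arma::vec th0,
                        int max_cycles, double tol, double clip,
                        bool update_B, bool update_theta,
                        bool update_intercept, bool graph, bool no_self) {
  const uword n = X.n_rows, p = X.n_cols, k = Y.n_cols, G = Z.n_cols;
  (void)n;
  const vec a = sum(square(X), 0).t();  // column sums of squares, length p
  const mat X2 = square(X);

  double obj = objective_full(X, Y, Z, B, Th, th0, l1, l2, l3, l4, graph);
  std::vector<double> trace;
  bool converged = false;
  std::string status = "max_cycles";
  int cycles_done = 0;

  for (int cycle = 1; cycle <= max_cycles; ++cycle) {
    cycles_done = cycle;

    // refresh working quantities at current parameters
    mat F = X * B;
    mat eta = F * Th.t();
    eta.each_row() += th0.t();
    mat E = Y - F;
    vec m = max(eta, 1);
    mat P = exp(eta.each_col() - m);
    P.each_col() /= sum(P, 1);
    P = clamp(P, clip, 1.0 - clip);
    mat zeta = P % (1.0 - P);
    // R = zeta .* (k_work - eta), which equals Z - P at the expansion point;
    // maintained incrementally as coordinates move within the cycle.
    mat R = Z - P;
    mat C = X2.t() * zeta;  // p x G: sum_i zeta_ig x_il^2

    // graph penalty matrices frozen for the cycle
    mat W, Lcur;
    vec dg;
    const bool use_graph = graph && l4 > 0.0;
    if (use_graph) graph_from_B(B, W, dg, Lcur);

    const mat B_old = B;
    const mat Th_old = Th;
    const vec th0_old = th0;

    if (update_B) {
      for (uword j = 0; j < k; ++j) {
        for (uword l = 0; l < p; ++l) {
          if (no_self && l == j) continue;
          double tc = 0.0, cross = 0.0;
          for (uword g = 0; g < G; ++g) {
            const double t = Th(g, j);
            if (t != 0.0) {
              tc += t * t * C(l, g);
              cross += t * dot(X.col(l), R.col(g));
            }
          }
          const double old = B(l, j);
          const double num =
              cross + old * tc + dot(X.col(l), E.col(j)) + old * a(l);
          const double den = a(l) + tc + l2;
          const double nb = (den > 0.0) ? soft(num, l1) / den : 0.0;
          const double delta = nb - old;
          if (delta != 0.0) {
            B(l, j) = nb;
            E.col(j) -= delta * X.col(l);
            F.col(j) += delta * X.col(l);
            for (uword g = 0; g < G; ++g) {
              const double t = Th(g, j);
              if (t != 0.0)
                R.col(g) -= (t * delta) * (zeta.col(g) % X.col(l));
            }
          }
        }
      }
    }

    if (update_theta) {
      for (uword g = 0; g < G; ++g) {
        mat Ls;
        vec lth;
        if (use_graph) {
          vec s(k);
          for (uword j = 0; j < k; ++j) s(j) = (Th(g, j) < 0.0) ? -1.0 : 1.0;
          Ls = Lcur % (s * s.t());
          lth = Ls * Th.row(g).t();
        }
        for (uword j = 0; j < k; ++j) {
          const double dgj = dot(zeta.col(g), square(F.col(j)));
          const double old = Th(g, j);
          double lap_num = 0.0, lap_den = 0.0;
          if (use_graph) {
            lap_num = l4 * (lth(j) - Ls(j, j) * old);
            lap_den = l4 * Ls(j, j);
          }
          const double num = dot(F.col(j), R.col(g)) + old * dgj - lap_num;
          const double den = dgj + lap_den;
          const double nt = (den > 0.0) ? soft(num, l3) / den : 0.0;
          const double delta = nt - old;
          if (delta != 0.0) {
            Th(g, j) = nt;
            R.col(g) -= delta * (zeta.col(g) % F.col(j));
            if (use_graph) lth += delta * Ls.col(j);
          }
        }
      }
    }

    if (update_intercept) {
      for (uword g = 0; g < G; ++g) {
        const double delta = accu(R.col(g)) / accu(zeta.col(g));
        th0(g) += delta;
        R.col(g) -= delta * zeta.col(g);
      }
    }

    // step-halving acceptance on the exact objective
    double obj_new =
        objective_full(X, Y, Z, B, Th, th0, l1, l2, l3, l4, graph);
    const double slack = 1e-10 * (std::fabs(obj) + 1.0);
    if (obj_new > obj + slack) {
      const mat Bc = B;
      const mat Thc = Th;
      const vec th0c = th0;
      double s = 1.0;
      bool ok = false;
      for (int h = 0; h < 20; ++h) {
        s *= 0.5;
        B = B_old + s * (Bc - B_old);
        Th = Th_old + s * (Thc - Th_old);
        th0 = th0_old + s * (th0c - th0_old);
        obj_new = objective_full(X, Y, Z, B, Th, th0, l1, l2, l3, l4, graph);
        if (obj_new <= obj + slack) {
          ok = true;
          break;
        }
      }
      if (!ok) {
        B = B_old;
        Th = Th_old;
        th0 = th0_old;
        status = "no_descent";
        trace.push_back(obj);
        break;
      }
    }

    trace.push_back(obj_new);
    if (std::fabs(obj - obj_new) <= tol * (std::fabs(obj) + 1e-10)) {
      converged = true;
      status = "converged";
      obj = obj_new;
      break;
    }
    obj = obj_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("B") = B, Rcpp::Named("Theta") = Th,
      Rcpp::Named("theta0") = th0, Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("converged") = converged, Rcpp::Named("status") = status,
      Rcpp::Named("n_cycles") = cycles_done,
      Rcpp::Named("objective") = obj);
}
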