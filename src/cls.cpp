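// Batched exact constrained least squares and the alternating sweep loop.
//
// Mirrors the face-enumeration scheme documented in R/solvers.R: the global
// minimizer of a convex quadratic under non-negativity / box / simplex
// constraints lies on one of the faces obtained by fixing variables at
// bounds; each face is solved once for all right-hand sides and the feasible
// candidate with the smallest objective wins. K (cell types) is small, so
// 2^K .. 3^K faces are cheap when batched.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FEAS_TOL = 1e-9;

// solve M x = rhs, falling back to pseudo-inverse (min-norm, covers tie
// faces with duplicate design columns)
static mat solve_face(const mat& M, const mat& rhs) {
  mat out;
  if (!solve(out, M, rhs, solve_opts::no_approx)) {
    out = pinv(M) * rhs;
  }
  return out;
}

// core: min_x x'AtA x - 2 x'atb  s.t. lower <= x (<= upper), optionally
// sum(x) = sum_to (upper must be +inf in that case)
static mat cls_core(mat AtA, mat AtB, double lower, double upper,
                    bool has_sum, double sum_to) {
  const uword K = AtA.n_rows, r = AtB.n_cols;

  double sc = AtA.diag().max();
  if (sc > 0 && std::isfinite(sc)) { AtA /= sc; AtB /= sc; }

  mat X(K, r, fill::value(datum::nan));

  // pre-pass: unconstrained / equality-only solution
  mat x0;
  if (!has_sum) {
    x0 = solve_face(AtA, AtB);
  } else {
    mat M(K + 1, K + 1, fill::ones);
    M(K, K) = 0;
    M.submat(0, 0, K - 1, K - 1) = 2 * AtA;
    mat rhs(K + 1, r);
    rhs.rows(0, K - 1) = 2 * AtB;
    rhs.row(K).fill(sum_to);
    x0 = solve_face(M, rhs).rows(0, K - 1);
  }
  std::vector<uword> todo;
  for (uword c = 0; c < r; ++c) {
    bool ok = x0.col(c).min() >= lower - FEAS_TOL &&
              x0.col(c).max() <= upper + FEAS_TOL;
    if (ok) X.col(c) = x0.col(c); else todo.push_back(c);
  }
  if (todo.empty()) return X;

  const uword nt = todo.size();
  mat AtBt(K, nt);
  for (uword j = 0; j < nt; ++j) AtBt.col(j) = AtB.col(todo[j]);

  vec best_obj(nt, fill::value(datum::inf));
  vec best_nrm(nt, fill::value(datum::inf));
  mat Xt(K, nt, fill::value(datum::nan));

  const int states = std::isfinite(upper) ? 3 : 2;
  uword n_faces = 1;
  for (uword k = 0; k < K; ++k) n_faces *= states;

  std::vector<int> st(K);
  for (uword g = 0; g < n_faces; ++g) {
    uword code = g;
    uvec freeIdx(K), fixIdx(K);
    uword nf = 0, nx = 0;
    double fixsum = 0;
    for (uword k = 0; k < K; ++k) {
      st[k] = code % states;
      code /= states;
      if (st[k] == 0) freeIdx(nf++) = k;
      else { fixIdx(nx++) = k; if (st[k] == 2) fixsum += upper; }
    }
    if (has_sum && nf == 0) continue;
    if (has_sum && fixsum > sum_to + FEAS_TOL) continue;
    freeIdx.resize(nf);
    fixIdx.resize(nx);

    vec fixval(nx);
    for (uword j = 0; j < nx; ++j) fixval(j) = (st[fixIdx(j)] == 2) ? upper : 0.0;

    mat cand(K, nt, fill::zeros);
    for (uword j = 0; j < nx; ++j) cand.row(fixIdx(j)).fill(fixval(j));

    if (nf > 0) {
      mat rhs = AtBt.rows(freeIdx);
      if (nx > 0) {
        vec shift = AtA.submat(freeIdx, fixIdx) * fixval;
        rhs.each_col() -= shift;
      }
      mat sol;
      if (!has_sum) {
        sol = solve_face(AtA.submat(freeIdx, freeIdx), rhs);
      } else {
        mat M(nf + 1, nf + 1, fill::ones);
        M(nf, nf) = 0;
        M.submat(0, 0, nf - 1, nf - 1) = 2 * AtA.submat(freeIdx, freeIdx);
        mat rhs2(nf + 1, nt);
        rhs2.rows(0, nf - 1) = 2 * rhs;
        rhs2.row(nf).fill(sum_to - fixsum);
        sol = solve_face(M, rhs2).rows(0, nf - 1);
      }
      cand.rows(freeIdx) = sol;
    }

    // feasibility + objective, column-wise
    rowvec obj = sum(cand % (AtA * cand), 0) - 2 * sum(cand % AtBt, 0);
    rowvec nrm = sum(square(cand), 0);
    for (uword j = 0; j < nt; ++j) {
      const vec& cj = cand.col(j);
      if (cj.min() < lower - FEAS_TOL || cj.max() > upper + FEAS_TOL) continue;
      if (obj(j) < best_obj(j) - 1e-12 ||
          (std::abs(obj(j) - best_obj(j)) <= 1e-12 && nrm(j) < best_nrm(j))) {
        Xt.col(j) = cj;
        best_obj(j) = obj(j);
        best_nrm(j) = nrm(j);
      }
    }
  }
  if (Xt.has_nan()) Rcpp::stop("constrained solver found no feasible face (internal)");
  for (uword j = 0; j < nt; ++j) X.col(todo[j]) = Xt.col(j);
  return X;
}

// snap round-off onto bounds; renormalize simplex columns
static void cls_clamp(mat& X, double lower, double upper, bool has_sum,
                      double sum_to) {
  if (X.min() < lower - 1e-8 || X.max() > upper + 1e-8) {
    Rcpp::stop("constrained solver produced an infeasible solution (internal)");
  }
  X.clamp(lower, std::isfinite(upper) ? upper : datum::inf);
  if (has_sum) {
    rowvec cs = sum(X, 0) / sum_to;
    X.each_row() /= cs;
  }
}

// [[Rcpp::export(name = ".cls_solve_cpp")]]
arma::mat cls_solve_cpp(const arma::mat& AtA, const arma::mat& AtB,
                        double lower, double upper, bool has_sum,
                        double sum_to) {
  mat X = cls_core(AtA, AtB, lower, upper, has_sum, sum_to);
  cls_clamp(X, lower, upper, has_sum, sum_to);
  return X;
}

// W update for all features: design is t(H), one box/nnls solve per feature
static mat profiles_step(const mat& Y, const mat& H, bool methylation) {
  mat AtA = H * H.t();
  mat AtB = H * Y.t();
  double upper = methylation ? 1.0 : datum::inf;
  mat Wt = cls_core(AtA, AtB, 0.0, upper, false, 0.0);
  cls_clamp(Wt, 0.0, upper, false, 0.0);
  return Wt.t();
}

// H update for all samples: simplex solve per sample
static mat proportions_step(const mat& Y, const mat& W) {
  mat AtA = W.t() * W;
  mat AtB = W.t() * Y;
  mat H = cls_core(AtA, AtB, 0.0, datum::inf, true, 1.0);
  cls_clamp(H, 0.0, datum::inf, true, 1.0);
  return H;
}

// [[Rcpp::export(name = ".rf_alternate_cpp")]]
Rcpp::List rf_alternate_cpp(const arma::mat& Y, const arma::mat& H0,
                            bool methylation, double tol, int max_iter) {
  mat H = H0;
  mat W = profiles_step(Y, H, methylation);
  double prev = std::sqrt(accu(square(Y - W * H)) / Y.n_elem);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    H = proportions_step(Y, W);
    W = profiles_step(Y, H, methylation);
    double cur = std::sqrt(accu(square(Y - W * H)) / Y.n_elem);
    // relative change: scale-invariant across expression / methylation
    if (std::abs(prev - cur) < tol * std::max(cur, 1e-12)) {
      prev = cur;
      converged = true;
      break;
    }
    prev = cur;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("rmse") = prev,
                            Rcpp::Named("inner_iterations") = it,
                            Rcpp::Named("converged") = converged);
}
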