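// Per-voxel projected gradient descent for the bi-tensor free-water model.
//
// Objective (data term): sum_i (a_i - f*exp(-b q_i' D q_i) - (1-f)*exp(-b d))^2
// optionally plus a quadratic coupling to fixed neighbour fractions,
//   reg_w * sum_j (f - f_nb_j)^2,
// used by the block-coordinate sweeps of the spatially regularized fit.
//
// The tensor is parameterized by its matrix logarithm L (symmetric), so
// D = expm(L) is positive definite for any symmetric L. The fraction f is
// kept inside [fmin, fmax] by projection after every trial step. Steps use
// backtracking halving on the joint direction (gradient normalized by its
// max-norm), which enforces a monotone non-increasing objective.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sym_from6(const vec &v) {
  mat D(3, 3);
  D(0, 0) = v(0); D(1, 0) = D(0, 1) = v(1); D(1, 1) = v(2);
  D(2, 0) = D(0, 2) = v(3); D(2, 1) = D(1, 2) = v(4); D(2, 2) = v(5);
  return D;
}

static vec six_from_sym(const mat &D) {
  vec v(6);
  v(0) = D(0, 0); v(1) = D(1, 0); v(2) = D(1, 1);
  v(3) = D(2, 0); v(4) = D(2, 1); v(5) = D(2, 2);
  return v;
}

// matrix log of an SPD-ish matrix, eigenvalues floored at ev_floor
static mat logm_spd(const mat &D, double ev_floor) {
  vec ev; mat V;
  eig_sym(ev, V, symmatu(D));
  ev = clamp(ev, ev_floor, datum::inf);
  return V * diagmat(log(ev)) * V.t();
}

static mat expm_sym(const mat &L, vec &ev, mat &V) {
  eig_sym(ev, V, symmatu(L));
  return V * diagmat(exp(ev)) * V.t();
}

struct VoxelData {
  const vec &a;       // observed attenuations (n_dwi)
  const mat &Q;       // n_dwi x 3 directions
  double b, w;        // shell b, exp(-b d)
  double reg_w;       // neighbour coupling weight
  const vec &f_nb;    // fixed neighbour fractions (may be empty)
};

static double objective(const VoxelData &vd, double f, const mat &L) {
  vec ev; mat V;
  mat D = expm_sym(L, ev, V);
  vec c = sum((vd.Q * D) % vd.Q, 1);
  vec m = f * exp(-vd.b * c) + (1.0 - f) * vd.w;
  vec r = vd.a - m;
  double obj = dot(r, r);
  if (vd.reg_w > 0 && vd.f_nb.n_elem > 0)
    obj += vd.reg_w * accu(square(f - vd.f_nb));
  return obj;
}

// objective with gradient wrt f and L
static double obj_grad(const VoxelData &vd, double f, const mat &L,
                       double &gf, mat &gL) {
  vec ev; mat V;
  mat D = expm_sym(L, ev, V);
  vec c = sum((vd.Q * D) % vd.Q, 1);
  vec e = exp(-vd.b * c);
  vec r = vd.a - (f * e + (1.0 - f) * vd.w);
  double obj = dot(r, r);
  gf = -2.0 * dot(r, e - vd.w);
  // dObj/dD = sum_i 2 r_i f b e_i q_i q_i'
  mat gD = 2.0 * f * vd.b * (vd.Q.t() * diagmat(r % e) * vd.Q);
  // chain through D = expm(L): gL = V (Vt gD V % Phi) Vt with the Loewner
  // matrix Phi of divided differences of exp at the eigenvalues of L
  mat Phi(3, 3);
  for (int k = 0; k < 3; ++k)
    for (int l = 0; l < 3; ++l) {
      double dl = ev(k) - ev(l);
      Phi(k, l) = (std::abs(dl) < 1e-12)
                    ? std::exp(ev(k))
                    : (std::exp(ev(k)) - std::exp(ev(l))) / dl;
    }
  gL = V * ((V.t() * gD * V) % Phi) * V.t();
  gL = symmatu(0.5 * (gL + gL.t()));
  if (vd.reg_w > 0 && vd.f_nb.n_elem > 0) {
    obj += vd.reg_w * accu(square(f - vd.f_nb));
    gf += 2.0 * vd.reg_w * accu(f - vd.f_nb);
  }
  return obj;
}

struct FitResult {
  double f;
  mat D;
  double obj0, obj;
  int iters;
  bool converged, flagged;
  std::vector<double> trace;
};

static FitResult fit_one(const VoxelData &vd, double f0, const mat &D0,
                         double fmin, double fmax,
                         int max_iters, double tol, double step0,
                         int max_halvings, double ev_floor, bool keep_trace) {
  FitResult res;
  res.flagged = false;
  double f = std::min(std::max(f0, fmin), fmax);
  mat L = logm_spd(D0, ev_floor);
  double obj = objective(vd, f, L);
  res.obj0 = obj;
  if (keep_trace) res.trace.push_back(obj);
  res.converged = false;
  int it = 0;
  if (!std::isfinite(obj)) {
    res.flagged = true;
    res.f = f; res.D = sym_from6(six_from_sym(D0)); res.obj = obj;
    res.iters = 0;
    return res;
  }
  double t_rel = step0;  // last accepted step in normalized units
  for (it = 0; it < max_iters; ++it) {
    double gf; mat gL;
    double cur = obj_grad(vd, f, L, gf, gL);
    if (!std::isfinite(cur) || !std::isfinite(gf) || !gL.is_finite()) {
      res.flagged = true;
      break;
    }
    double gnorm = std::max(std::abs(gf), abs(gL).max());
    if (gnorm < 1e-15) { res.converged = true; break; }
    // warm-start the line search from twice the last accepted step so the
    // backtracking budget is spent near the useful scale, not re-halving
    // from step0 every iteration
    t_rel = std::min(2.0 * t_rel, step0);
    double t = t_rel / gnorm;
    bool accepted = false;
    double f_new = f, obj_new = obj;
    mat L_new = L;
    for (int h = 0; h <= max_halvings; ++h) {
      f_new = std::min(std::max(f - t * gf, fmin), fmax);
      L_new = L - t * gL;
      obj_new = objective(vd, f_new, L_new);
      if (std::isfinite(obj_new) && obj_new < obj) { accepted = true; break; }
      t *= 0.5;
      t_rel *= 0.5;
    }
    if (!accepted) { res.converged = true; break; }  // local stationarity
    double rel = (obj - obj_new) / std::max(obj, 1e-300);
    f = f_new; L = L_new; obj = obj_new;
    if (keep_trace) res.trace.push_back(obj);
    if (rel < tol) { res.converged = true; ++it; break; }
  }
  vec ev; mat V;
  res.D = expm_sym(L, ev, V);
  res.f = f;
  res.obj = obj;
  res.iters = it;
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_voxel(const arma::vec &att, const arma::mat &Q, double b,
                         double d, double f0, const arma::vec &D0_six,
                         double fmin, double fmax, int max_iters, double tol,
                         double step0, int max_halvings, double reg_w,
                         const arma::vec &f_nb, double ev_floor) {
  VoxelData vd{att, Q, b, std::exp(-b * d), reg_w, f_nb};
  FitResult r = fit_one(vd, f0, sym_from6(D0_six), fmin, fmax, max_iters,
                        tol, step0, max_halvings, ev_floor, true);
  vec six = six_from_sym(r.D);
  return Rcpp::List::create(
      Rcpp::Named("f") = r.f,
      Rcpp::Named("tensor") = Rcpp::NumericVector(six.begin(), six.end()),
      Rcpp::Named("objective") = Rcpp::NumericVector(r.trace.begin(),
                                                     r.trace.end()),
      Rcpp::Named("initial_objective") = r.obj0,
      Rcpp::Named("final_objective") = r.obj,
      Rcpp::Named("iterations") = r.iters,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("flagged") = r.flagged);
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_voxels(const arma::mat &att, const arma::mat &Q, double b,
                          double d, const arma::vec &f0,
                          const arma::mat &D0_six, const arma::vec &fmin,
                          const arma::vec &fmax, int max_iters, double tol,
                          double step0, int max_halvings,
                          const arma::vec &reg_w, const arma::mat &f_nb_mat,
                          const arma::imat &nb_count, double ev_floor) {
  // att: n_dwi x nvox; D0_six: 6 x nvox; f_nb_mat: max_nb x nvox with
  // nb_count(v) valid entries per voxel (empty when unregularized)
  const uword nvox = att.n_cols;
  vec f(nvox), obj0(nvox), obj(nvox);
  mat tensor(6, nvox);
  ivec iters(nvox);
  uvec converged(nvox), flagged(nvox);
  vec empty;
  for (uword v = 0; v < nvox; ++v) {
    vec a = att.col(v);
    double rw = reg_w.n_elem == 1 ? reg_w(0) : reg_w(v);
    vec fnb;
    if (rw > 0 && f_nb_mat.n_elem > 0 && nb_count(v) > 0)
      fnb = f_nb_mat.col(v).head(nb_count(v));
    VoxelData vd{a, Q, b, std::exp(-b * d), rw, fnb};
    FitResult r = fit_one(vd, f0(v), sym_from6(D0_six.col(v)), fmin(v),
                          fmax(v), max_iters, tol, step0, max_halvings,
                          ev_floor, false);
    f(v) = r.f;
    tensor.col(v) = six_from_sym(r.D);
    obj0(v) = r.obj0;
    obj(v) = r.obj;
    iters(v) = r.iters;
    converged(v) = r.converged ? 1 : 0;
    flagged(v) = r.flagged ? 1 : 0;
  }
  return Rcpp::List::create(
      Rcpp::Named("f") = f, Rcpp::Named("tensor") = tensor,
      Rcpp::Named("initial_objective") = obj0,
      Rcpp::Named("final_objective") = obj,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = Rcpp::LogicalVector(converged.begin(),
                                                     converged.end()),
      Rcpp::Named("flagged") = Rcpp::LogicalVector(flagged.begin(),
                                                   flagged.end()));
}
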