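// Numerical kernels for multi-exponential T2 relaxometry:
//  - extended phase graph (EPG) echo amplitudes for CPMG trains with
//    imperfect refocusing pulses (source of stimulated echoes),
//  - Lawson-Hanson non-negative least squares (column and Gram variants),
//  - chi-squared-inflation regularized NNLS (Tikhonov weight by bisection),
//  - batch voxelwise MWF fitting with flip-angle estimation,
//  - sparsity-promoting iterative joint NNLS (SPIJN) over all voxels.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// EPG recursion. States F+(k), F-(k), Z(k) tracked to order n_echoes.
// CPMG convention: 90deg excitation, refocusing about the orthogonal axis;
// all echo amplitudes are real and non-negative. Longitudinal recovery is
// neglected (echo train short relative to TR); T1 still damps stored Z
// states, which is what makes stimulated-echo correction T1-dependent.
// ---------------------------------------------------------------------------
static void epg_shift(vec &Fp, vec &Fm) {
  const uword K = Fp.n_elem - 1;
  double fm1 = Fm(1);
  for (uword k = K; k >= 1; --k) Fp(k) = Fp(k - 1);
  Fp(0) = fm1; // F(-1) refocuses into F(0)
  for (uword k = 0; k < K; ++k) Fm(k) = Fm(k + 1);
  Fm(K) = 0.0;
  Fm(0) = Fp(0); // k = 0 state shared (real-valued CPMG)
}

static vec epg_curve(double t2, double t1, double esp, double alpha_deg,
                     int n_echoes) {
  const double a = alpha_deg * datum::pi / 180.0;
  const double E2 = std::exp(-esp / (2.0 * t2));
  const double E1 = std::exp(-esp / (2.0 * t1));
  const double c2 = std::cos(a / 2.0) * std::cos(a / 2.0);
  const double s2 = std::sin(a / 2.0) * std::sin(a / 2.0);
  const double sa = std::sin(a);
  const double ca = std::cos(a);
  const uword K = (uword)n_echoes + 1;
  vec Fp(K + 1, fill::zeros), Fm(K + 1, fill::zeros), Z(K + 1, fill::zeros);
  Fp(0) = 1.0;
  Fm(0) = 1.0;
  vec out((uword)n_echoes);
  for (int e = 0; e < n_echoes; ++e) {
    Fp *= E2; Fm *= E2; Z *= E1;
    epg_shift(Fp, Fm);
    for (uword k = 0; k <= K; ++k) {
      double fp = Fp(k), fm = Fm(k), z = Z(k);
      Fp(k) = c2 * fp + s2 * fm + sa * z;
      Fm(k) = s2 * fp + c2 * fm - sa * z;
      Z(k) = -0.5 * sa * fp + 0.5 * sa * fm + ca * z;
    }
    Fp *= E2; Fm *= E2; Z *= E1;
    epg_shift(Fp, Fm);
    // magnitude acquisition: deep stimulated-echo pathways can invert the
    // echo sign; the measured amplitude is its modulus
    out((uword)e) = std::abs(Fp(0));
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_epg_curve(double t2, double t1, double esp, double alpha_deg,
                        int n_echoes) {
  return epg_curve(t2, t1, esp, alpha_deg, n_echoes);
}

// [[Rcpp::export]]
arma::mat cpp_epg_basis(const arma::vec &t2_values, double t1, double esp,
                        double alpha_deg, int n_echoes) {
  mat A((uword)n_echoes, t2_values.n_elem);
  for (uword j = 0; j < t2_values.n_elem; ++j)
    A.col(j) = epg_curve(t2_values(j), t1, esp, alpha_deg, n_echoes);
  return A;
}

// ---------------------------------------------------------------------------
// Lawson-Hanson NNLS, column-space variant. Returns x >= 0 minimizing
// ||A x - b||^2. chi2 receives the squared residual norm.
// ---------------------------------------------------------------------------
static vec nnls_lh(const mat &A, const vec &b, double &chi2) {
  const uword n = A.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> P(n, false);
  vec w = A.t() * b; // gradient at x = 0
  const double tol = 10.0 * datum::eps * norm(A, "fro") * norm(A, "fro");
  uword nP = 0;
  int outer = 0, outer_max = (int)(3 * n + 30);
  while (outer++ < outer_max) {
    // pick most positive gradient among the zero set
    int jmax = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!P[j] && w(j) > wmax) { wmax = w(j); jmax = (int)j; }
    if (jmax < 0 || nP == std::min(A.n_rows, n)) break;
    P[(uword)jmax] = true; ++nP;
    int inner = 0;
    while (inner++ < (int)(3 * n + 30)) {
      uvec idx(nP); uword c = 0;
      for (uword j = 0; j < n; ++j) if (P[j]) idx(c++) = j;
      vec z;
      bool ok = solve(z, A.cols(idx), b, solve_opts::no_approx);
      if (!ok) { // rank deficiency: fall back to pinv solve
        z = pinv(A.cols(idx)) * b;
      }
      if (z.min() > 0.0) {
        x.zeros();
        for (uword k = 0; k < nP; ++k) x(idx(k)) = z(k);
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < nP; ++k)
        if (z(k) <= 0.0) {
          double xi = x(idx(k));
          double step = xi / (xi - z(k));
          if (step < alpha) alpha = step;
        }
      for (uword k = 0; k < nP; ++k)
        x(idx(k)) += alpha * (z(k) - x(idx(k)));
      for (uword k = 0; k < nP; ++k)
        if (x(idx(k)) <= tol) x(idx(k)) = 0.0;
      // rebuild passive set
      nP = 0;
      for (uword j = 0; j < n; ++j) {
        P[j] = x(j) > 0.0;
        if (P[j]) ++nP;
      }
      if (nP == 0) break;
    }
    vec r = b - A * x;
    w = A.t() * r;
  }
  vec r = b - A * x;
  chi2 = dot(r, r);
  return x;
}

// [[Rcpp::export]]
Rcpp::List cpp_nnls(const arma::mat &A, const arma::vec &b) {
  double chi2;
  vec x = nnls_lh(A, b, chi2);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("chi2") = chi2);
}

// Gram-matrix Lawson-Hanson: minimize x'Gx - 2 c'x subject to x >= 0,
// where G = A'A (+ diagonal penalty) and c = A'b. Used by SPIJN where one
// dictionary is shared by tens of thousands of voxels.
static vec nnls_gram(const mat &G, const vec &c, double scale) {
  const uword n = G.n_cols;
  vec x(n, fill::zeros);
  std::vector<bool> P(n, false);
  vec w = c; // gradient of -0.5 objective at 0
  const double tol = 10.0 * datum::eps * (scale > 0 ? scale : 1.0);
  uword nP = 0;
  int outer = 0, outer_max = (int)(3 * n + 30);
  while (outer++ < outer_max) {
    int jmax = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!P[j] && w(j) > wmax) { wmax = w(j); jmax = (int)j; }
    if (jmax < 0) break;
    P[(uword)jmax] = true; ++nP;
    int inner = 0;
    while (inner++ < (int)(3 * n + 30)) {
      uvec idx(nP); uword cc = 0;
      for (uword j = 0; j < n; ++j) if (P[j]) idx(cc++) = j;
      mat Gpp = G.submat(idx, idx);
      vec z;
      bool ok = solve(z, Gpp, c.elem(idx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) z = pinv(Gpp) * c.elem(idx);
      if (z.min() > 0.0) {
        x.zeros();
        for (uword k = 0; k < nP; ++k) x(idx(k)) = z(k);
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < nP; ++k)
        if (z(k) <= 0.0) {
          double xi = x(idx(k));
          double step = xi / (xi - z(k));
          if (step < alpha) alpha = step;
        }
      for (uword k = 0; k < nP; ++k)
        x(idx(k)) += alpha * (z(k) - x(idx(k)));
      for (uword k = 0; k < nP; ++k)
        if (x(idx(k)) <= 0.0) x(idx(k)) = 0.0;
      nP = 0;
      for (uword j = 0; j < n; ++j) {
        P[j] = x(j) > 0.0;
        if (P[j]) ++nP;
      }
      if (nP == 0) break;
    }
    w = c - G * x;
  }
  return x;
}

// ---------------------------------------------------------------------------
// Regularized NNLS: find Tikhonov weight mu such that the data misfit
// chi2(mu) = ||A x_mu - b||^2 equals reg_factor * chi2_min, where x_mu
// solves min ||A x - b||^2 + mu ||x||^2 with x >= 0. Bisection on mu;
// contract: |chi2 - target| <= 1e-3 * target.
// ---------------------------------------------------------------------------
static vec nnls_reg(const mat &A, const vec &b, double reg_factor,
                    double &chi2_out, double &mu_out) {
  double chi2_min;
  vec x0 = nnls_lh(A, b, chi2_min);
  mu_out = 0.0;
  chi2_out = chi2_min;
  double b2 = dot(b, b);
  if (reg_factor <= 1.0 || chi2_min <= 1e-12 * b2 || b2 <= 0.0) return x0;
  const double target = reg_factor * chi2_min;
  const uword n = A.n_cols, m = A.n_rows;
  mat Aug(m + n, n, fill::zeros);
  Aug.rows(0, m - 1) = A;
  vec baug(m + n, fill::zeros);
  baug.subvec(0, m - 1) = b;
  auto chi2_at = [&](double mu, vec &x) {
    double smu = std::sqrt(mu);
    for (uword j = 0; j < n; ++j) Aug(m + j, j) = smu;
    double dummy;
    x = nnls_lh(Aug, baug, dummy);
    vec r = b - A * x;
    return dot(r, r);
  };
  // bracket
  double mu_hi = 1e-6 * trace(A.t() * A) / n;
  vec xh;
  double chi_hi = chi2_at(mu_hi, xh);
  int grow = 0;
  while (chi_hi < target && grow++ < 60) {
    mu_hi *= 10.0;
    chi_hi = chi2_at(mu_hi, xh);
  }
  double mu_lo = 0.0;
  vec xbest = xh;
  double chi_best = chi_hi;
  for (int it = 0; it < 100; ++it) {
    if (std::abs(chi_best - target) <= 1e-3 * target) break;
    double mu_mid = 0.5 * (mu_lo + mu_hi);
    vec xm;
    double chi_mid = chi2_at(mu_mid, xm);
    if (chi_mid < target) mu_lo = mu_mid; else mu_hi = mu_mid;
    xbest = xm; chi_best = chi_mid; mu_out = mu_mid;
    // keep the iterate on the admissible side of the bracket
    if (chi_mid >= target || std::abs(chi_mid - target) <= 1e-3 * target)
      continue;
  }
  chi2_out = chi_best;
  return xbest;
}

// [[Rcpp::export]]
Rcpp::List cpp_nnls_reg(const arma::mat &A, const arma::vec &b,
                        double reg_factor) {
  double chi2, mu;
  vec x = nnls_reg(A, b, reg_factor, chi2, mu);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("chi2") = chi2,
                            Rcpp::Named("mu") = mu);
}

// [[Rcpp::export]]
arma::vec cpp_nnls_chi2_batch(const arma::mat &A, const arma::mat &B) {
  vec out(B.n_cols);
  double chi2;
  for (uword v = 0; v < B.n_cols; ++v) {
    nnls_lh(A, B.col(v), chi2);
    out(v) = chi2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batch voxelwise MWF fit: per voxel, (optionally) estimate the refocusing
// flip angle by scanning candidate EPG bases for the minimum unregularized
// NNLS misfit with parabolic refinement, rebuild the basis at the estimate,
// then run chi-squared-inflation regularized NNLS.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_fit_mwf_batch(const arma::mat &B, const arma::vec &t2_values,
                             double t1, double esp,
                             const arma::vec &angle_grid, double reg_factor,
                             bool flip_correction, double fixed_flip) {
  const uword n_echo = B.n_rows, n_vox = B.n_cols, n_t2 = t2_values.n_elem;
  const int ne = (int)n_echo;
  const uword n_ang = angle_grid.n_elem;
  std::vector<mat> bases(n_ang);
  if (flip_correction)
    for (uword a = 0; a < n_ang; ++a)
      bases[a] = cpp_epg_basis(t2_values, t1, esp, angle_grid(a), ne);
  mat fixed_basis;
  if (!flip_correction)
    fixed_basis = cpp_epg_basis(t2_values, t1, esp, fixed_flip, ne);

  mat X(n_t2, n_vox, fill::zeros);
  vec flips(n_vox, fill::value(datum::nan));
  vec chi2s(n_vox, fill::value(datum::nan));
  Rcpp::LogicalVector invalid(n_vox), flat(n_vox);
  double amin = flip_correction ? angle_grid.min() : fixed_flip;
  double amax = flip_correction ? angle_grid.max() : fixed_flip;

  for (uword v = 0; v < n_vox; ++v) {
    vec b = B.col(v);
    double b2 = dot(b, b);
    if (!b.is_finite() || b2 <= 0.0) { invalid[v] = true; continue; }
    double alpha_hat = fixed_flip;
    if (flip_correction) {
      vec chi(n_ang);
      double c2;
      for (uword a = 0; a < n_ang; ++a) {
        nnls_lh(bases[a], b, c2);
        chi(a) = c2;
      }
      uword m = chi.index_min();
      if (chi.max() - chi.min() <= 1e-12 * std::max(chi.max(), b2)) {
        flat[v] = true;
        alpha_hat = angle_grid(m);
      } else if (m == 0 || m == n_ang - 1) {
        alpha_hat = angle_grid(m);
      } else {
        // parabola through (m-1, m, m+1)
        double y0 = chi(m - 1), y1 = chi(m), y2 = chi(m + 1);
        double x0 = angle_grid(m - 1), x1 = angle_grid(m),
               x2 = angle_grid(m + 1);
        double denom = (y0 - 2.0 * y1 + y2);
        if (std::abs(denom) < 1e-300) alpha_hat = x1;
        else {
          double h = 0.5 * (x2 - x0) / 2.0 * 0.0; // unused; uniform grid assumed
          (void)h;
          alpha_hat = x1 + 0.5 * (x2 - x1) * (y0 - y2) / denom;
        }
        if (alpha_hat < amin) alpha_hat = amin;
        if (alpha_hat > amax) alpha_hat = amax;
      }
    }
    mat A = flip_correction
                ? cpp_epg_basis(t2_values, t1, esp, alpha_hat, ne)
                : fixed_basis;
    double chi2, mu;
    vec x = nnls_reg(A, b, reg_factor, chi2, mu);
    X.col(v) = x;
    flips(v) = alpha_hat;
    chi2s(v) = chi2;
    if (accu(x) <= 0.0) invalid[v] = true;
  }
  return Rcpp::List::create(
      Rcpp::Named("amplitudes") = X, Rcpp::Named("flip") = flips,
      Rcpp::Named("chi2") = chi2s, Rcpp::Named("invalid") = invalid,
      Rcpp::Named("flat_profile") = flat);
}

// ---------------------------------------------------------------------------
// SPIJN: sparsity-promoting iterative joint NNLS. Solves
//   min sum_v ||A x_v - b_v||^2 + lambda * sum_j w_j ||x_j.||
// by iterative reweighting (w_j from inverse row norms), one shared
// dictionary A for all voxels, via Gram-based Lawson-Hanson per voxel.
// On convergence the global support is restricted to <= max_components and
// the voxels are re-fit unregularized on the restricted dictionary.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_spijn(const arma::mat &B, const arma::mat &A, double lambda,
                     int max_components, int max_iter, double tol) {
  const uword n_t2 = A.n_cols, n_vox = B.n_cols;
  // normalize dictionary columns so the row-sparsity penalty treats short
  // and long T2 components evenly; amplitudes are rescaled on exit
  vec colnorm(n_t2);
  mat An = A;
  for (uword j = 0; j < n_t2; ++j) {
    colnorm(j) = norm(A.col(j), 2);
    if (colnorm(j) > 0) An.col(j) /= colnorm(j);
  }
  mat AtA = An.t() * An;
  mat AtB = An.t() * B;
  double scale = trace(AtA);
  // The row-sparsity penalty is applied in its greedy hard-threshold
  // limit (backward elimination): the joint NNLS is re-solved on the
  // active dictionary, candidate components are ranked by their
  // inverse-row-norm weights (largest weight = weakest row first), and a
  // candidate is eliminated only if re-solving without it increases the
  // joint misfit by at most `lambda` (relative). Elimination is forced
  // while the support exceeds max_components. A quadratic (ridge)
  // surrogate is deliberately not used: it collapses genuine two-pool
  // mixtures onto intermediate single-T2 atoms before the joint
  // information can act (see vignette).
  mat X(n_t2, n_vox, fill::zeros);
  std::vector<bool> active(n_t2, true);
  bool converged = false;
  int iter = 0;
  double e_tot = accu(square(B));

  // joint NNLS restricted to the currently active dictionary rows
  auto solve_active = [&](const std::vector<bool> &act_flags, mat &Xout) {
    uvec act(n_t2);
    uword na = 0;
    for (uword j = 0; j < n_t2; ++j) if (act_flags[j]) act(na++) = j;
    act.resize(na);
    mat G = AtA.submat(act, act);
    mat C = AtB.rows(act);
    mat Xa(na, n_vox);
    for (uword v = 0; v < n_vox; ++v)
      Xa.col(v) = nnls_gram(G, C.col(v), scale);
    Xout.zeros();
    Xout.rows(act) = Xa;
    return accu(square(B - An * Xout));
  };

  double misfit = solve_active(active, X);
  if (lambda > 0.0) {
    // drop numerically dead rows outright
    for (uword j = 0; j < n_t2; ++j)
      if (active[j] && norm(X.row(j), 2) <= 0.0) active[j] = false;
    std::vector<bool> rejected(n_t2, false);
    mat Xt(n_t2, n_vox);
    for (iter = 1; iter <= max_iter; ++iter) {
      int n_active = 0;
      for (uword j = 0; j < n_t2; ++j) if (active[j]) ++n_active;
      if (n_active <= 1) { converged = true; break; }
      // candidate order: largest inverse-row-norm weight first
      vec rownorm(n_t2, fill::value(datum::inf));
      for (uword j = 0; j < n_t2; ++j)
        if (active[j] && !rejected[j]) rownorm(j) = norm(X.row(j), 2);
      uvec ord = sort_index(rownorm, "ascend");
      bool accepted = false;
      bool force = n_active > max_components;
      double budget = lambda * std::max(misfit, 1e-9 * e_tot);
      double best_dm = datum::inf;
      int best_j = -1;
      mat Xbest;
      double mbest = 0.0;
      for (uword i = 0; i < n_t2; ++i) {
        uword j = ord(i);
        if (!active[j] || rejected[j]) continue;
        std::vector<bool> trial = active;
        trial[j] = false;
        double mt = solve_active(trial, Xt);
        if (mt - misfit <= budget) {
          active = trial;
          X = Xt;
          misfit = mt;
          std::fill(rejected.begin(), rejected.end(), false);
          accepted = true;
          break;
        }
        if (mt - misfit < best_dm) {
          best_dm = mt - misfit;
          best_j = (int)j;
          Xbest = Xt;
          mbest = mt;
        }
        rejected[j] = true;
      }
      if (!accepted && force && best_j >= 0) {
        // over the component budget and no removal is cheap: drop the one
        // that degrades the joint fit least
        active[(uword)best_j] = false;
        X = Xbest;
        misfit = mbest;
        std::fill(rejected.begin(), rejected.end(), false);
        accepted = true;
      }
      if (!accepted) {
        int n_testable = 0;
        for (uword j = 0; j < n_t2; ++j)
          if (active[j] && !rejected[j]) ++n_testable;
        if (n_testable == 0 || n_active <= max_components) {
          converged = n_active <= max_components;
          break;
        }
      }
    }
  } else {
    converged = true;
  }
  // restrict the global support (cap at max_components by row norm) and
  // refit unregularized on the restricted dictionary
  vec rownorm(n_t2);
  for (uword j = 0; j < n_t2; ++j) rownorm(j) = norm(X.row(j), 2);
  uvec keep;
  if (lambda > 0.0) {
    uvec act = find(rownorm > 0);
    std::vector<uword> kv;
    for (uword i = 0; i < act.n_elem; ++i)
      if (active[act(i)]) kv.push_back(act(i));
    if ((int)kv.size() > max_components) {
      uvec ord = sort_index(rownorm, "descend");
      kv.clear();
      int k = 0;
      for (uword i = 0; i < n_t2 && k < max_components; ++i)
        if (active[ord(i)] && rownorm(ord(i)) > 0) {
          kv.push_back(ord(i));
          ++k;
        }
    }
    if (kv.empty()) kv.push_back(rownorm.index_max());
    std::sort(kv.begin(), kv.end());
    keep = uvec(kv);
    mat As = An.cols(keep);
    mat Gs = As.t() * As;
    mat AtBs = As.t() * B;
    mat Xs(keep.n_elem, n_vox);
    for (uword v = 0; v < n_vox; ++v)
      Xs.col(v) = nnls_gram(Gs, AtBs.col(v), trace(Gs));
    X.zeros();
    X.rows(keep) = Xs;
  } else {
    keep = find(rownorm > 0);
  }
  // back to the unnormalized dictionary's amplitude scale
  for (uword j = 0; j < n_t2; ++j)
    if (colnorm(j) > 0) X.row(j) /= colnorm(j);
  return Rcpp::List::create(
      Rcpp::Named("amplitudes") = X,
      Rcpp::Named("support") = Rcpp::IntegerVector(keep.begin(), keep.end()),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iter);
}
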