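// Compiled core: batch forward kinematics of the constrained chain and a
// per-frame bounded Levenberg-Marquardt inverse-kinematics solver with
// warm starts and an analytic chain-rule Jacobian. Mirrors the R reference
// implementation (R/kinematics.R).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct FlatModel {
  int nseg, nq, nmark;
  arma::ivec parent;
  arma::mat origin;        // 3 x nseg
  arma::ivec naxes;
  arma::mat axes;          // 3 x 3*nseg
  arma::imat qidx;         // 3 x nseg
  arma::ivec presc;
  arma::vec sx, ap_y, ap_ypp, si_y, si_ypp;
  arma::ivec marker_seg;
  arma::mat marker_local;  // 3 x nmark
};

FlatModel parse_flat(const List& flat) {
  FlatModel m;
  m.nseg = as<int>(flat["nseg"]);
  m.nq = as<int>(flat["nq"]);
  m.nmark = as<int>(flat["nmark"]);
  m.parent = as<arma::ivec>(flat["parent"]);
  m.origin = as<arma::mat>(flat["origin"]);
  m.naxes = as<arma::ivec>(flat["naxes"]);
  m.axes = as<arma::mat>(flat["axes"]);
  m.qidx = as<arma::imat>(flat["qidx"]);
  m.presc = as<arma::ivec>(flat["presc"]);
  List sp = flat["spline"];
  m.sx = as<arma::vec>(sp["x"]);
  m.ap_y = as<arma::vec>(sp["ap_y"]);
  m.ap_ypp = as<arma::vec>(sp["ap_ypp"]);
  m.si_y = as<arma::vec>(sp["si_y"]);
  m.si_ypp = as<arma::vec>(sp["si_ypp"]);
  m.marker_seg = as<arma::ivec>(flat["marker_seg"]);
  m.marker_local = as<arma::mat>(flat["marker_local"]);
  return m;
}

const double DEG = M_PI / 180.0;

inline arma::mat33 rot_axis(const arma::vec3& a, double deg) {
  double th = deg * DEG, c = std::cos(th), s = std::sin(th);
  arma::mat33 K = {{0, -a[2], a[1]}, {a[2], 0, -a[0]}, {-a[1], a[0], 0}};
  arma::mat33 I(arma::fill::eye);
  return I + s * K + (1 - c) * (K * K);
}

// natural cubic spline (precomputed second derivatives); clamped to the
// knot range (the coordinate bounds keep the solver inside it). Optionally
// returns the first derivative.
inline double sp_eval(const arma::vec& x, const arma::vec& y,
                      const arma::vec& ypp, double xv, double* dy = nullptr) {
  int n = x.n_elem;
  if (xv <= x[0]) xv = x[0];
  if (xv >= x[n - 1]) xv = x[n - 1];
  int i = 0;
  while (i < n - 2 && xv > x[i + 1]) ++i;
  double h = x[i + 1] - x[i];
  double A = (x[i + 1] - xv) / h, B = 1 - A;
  if (dy)
    *dy = (y[i + 1] - y[i]) / h +
          h / 6.0 * (-(3 * A * A - 1) * ypp[i] + (3 * B * B - 1) * ypp[i + 1]);
  return A * y[i] + B * y[i + 1] +
         ((A * A * A - A) * ypp[i] + (B * B * B - B) * ypp[i + 1]) * h * h / 6.0;
}

// Per-frame kinematic state, including the quantities needed for the
// analytic Jacobian: world joint pivots, world axis directions and the
// world-frame derivative of the prescribed translation w.r.t. its driver.
struct FkState {
  std::vector<arma::mat33> Rw;
  arma::mat tw;        // 3 x nseg segment origins
  arma::mat mk;        // 3 x nmark markers
  arma::mat pivot;     // 3 x nseg joint center (pre-prescribed-offset)
  arma::mat axw;       // 3 x 3*nseg world axis directions
  arma::mat dpresc;    // 3 x nseg world d(prescribed translation)/d(driver)
  explicit FkState(const FlatModel& m)
      : Rw(m.nseg), tw(3, m.nseg), mk(3, m.nmark), pivot(3, m.nseg),
        axw(3, 3 * m.nseg), dpresc(3, m.nseg, arma::fill::zeros) {}
};

void fk_one(const FlatModel& m, const arma::vec& q, FkState& st,
            bool want_jac) {
  for (int s = 0; s < m.nseg; ++s) {
    arma::mat33 Rj(arma::fill::eye);
    arma::mat33 Rpar;
    if (m.parent[s] < 0)
      Rpar.eye();
    else
      Rpar = st.Rw[m.parent[s]];
    for (int k = 0; k < m.naxes[s]; ++k) {
      arma::vec3 ax = m.axes.col(3 * s + k);
      if (want_jac) st.axw.col(3 * s + k) = Rpar * (Rj * ax);
      Rj = Rj * rot_axis(ax, q[m.qidx(k, s)]);
    }
    if (m.parent[s] < 0) {
      st.Rw[s] = Rj;
      st.tw.col(s) = q.subvec(0, 2);
      st.pivot.col(s) = st.tw.col(s);
    } else {
      int p = m.parent[s];
      st.Rw[s] = Rpar * Rj;
      arma::vec3 piv = st.tw.col(p) + Rpar * m.origin.col(s);
      st.pivot.col(s) = piv;
      if (m.presc[s]) {
        double fl = q[m.qidx(0, s)];
        double dap, dsi;
        arma::vec3 tp;
        tp[0] = sp_eval(m.sx, m.ap_y, m.ap_ypp, fl, &dap);
        tp[1] = sp_eval(m.sx, m.si_y, m.si_ypp, fl, &dsi);
        tp[2] = 0;
        st.tw.col(s) = piv + st.Rw[s] * tp;
        if (want_jac) {
          arma::vec3 dtp = {dap, dsi, 0};
          st.dpresc.col(s) = st.Rw[s] * dtp;
        }
      } else {
        st.tw.col(s) = piv;
      }
    }
  }
  for (int j = 0; j < m.nmark; ++j) {
    int s = m.marker_seg[j];
    st.mk.col(j) = st.Rw[s] * m.marker_local.col(j) + st.tw.col(s);
  }
}

}  // namespace

// [[Rcpp::export]]
List fk_batch_cpp(List flat, const arma::mat& qmat) {
  FlatModel m = parse_flat(flat);
  int nf = qmat.n_rows;
  arma::cube markers(3, m.nmark, nf);
  arma::cube seg_t(3, m.nseg, nf);
  arma::cube seg_R(3, 3 * m.nseg, nf);
  FkState st(m);
  for (int f = 0; f < nf; ++f) {
    arma::vec q = qmat.row(f).t();
    fk_one(m, q, st, false);
    markers.slice(f) = st.mk;
    seg_t.slice(f) = st.tw;
    for (int s = 0; s < m.nseg; ++s)
      seg_R.slice(f).cols(3 * s, 3 * s + 2) = st.Rw[s];
  }
  return List::create(_["markers"] = markers, _["seg_t"] = seg_t,
                      _["seg_R"] = seg_R);
}

// Analytic Jacobian of the active-marker residual stack w.r.t. q (degrees
// and mm). A marker depends only on the joints on its ancestor chain: the
// derivative w.r.t. a rotation is (pi/180) * axis_world x (x - pivot),
// plus the prescribed-translation derivative for the knee driver; pelvis
// translations contribute the identity.
static void fill_jacobian(const FlatModel& m, const FkState& st,
                          const std::vector<int>& act, const arma::vec& sw,
                          arma::mat& J) {
  J.zeros();
  for (size_t i = 0; i < act.size(); ++i) {
    int j = act[i];
    arma::vec3 x = st.mk.col(j);
    int r0 = 3 * i;
    for (int k = 0; k < 3; ++k) J(r0 + k, k) = sw[i];  // pelvis translation
    int s = m.marker_seg[j];
    while (s >= 0) {
      arma::vec3 lever = x - st.pivot.col(s);
      for (int k = 0; k < m.naxes[s]; ++k) {
        int qi = m.qidx(k, s);
        arma::vec3 a = st.axw.col(3 * s + k);
        arma::vec3 d = DEG * arma::cross(a, lever);
        if (m.presc[s] && k == 0) d += st.dpresc.col(s);
        J(r0, qi) += sw[i] * d[0];
        J(r0 + 1, qi) += sw[i] * d[1];
        J(r0 + 2, qi) += sw[i] * d[2];
      }
      s = m.parent[s];
    }
  }
}

// [[Rcpp::export]]
arma::mat ik_jacobian_cpp(List flat, const arma::vec& q, const arma::vec& w) {
  FlatModel m = parse_flat(flat);
  FkState st(m);
  fk_one(m, q, st, true);
  std::vector<int> act;
  for (int j = 0; j < m.nmark; ++j)
    if (w[j] > 0) act.push_back(j);
  arma::vec sw(act.size());
  for (size_t i = 0; i < act.size(); ++i) sw[i] = std::sqrt(w[act[i]]);
  arma::mat J(3 * act.size(), m.nq);
  fill_jacobian(m, st, act, sw, J);
  return J;
}

// [[Rcpp::export]]
List ik_solve_cpp(List flat, const arma::cube& exp_markers, const arma::vec& w,
                  const arma::vec& q0, const arma::mat& bounds, double xtol,
                  double gtol, double ftol, int max_iter) {
  FlatModel m = parse_flat(flat);
  int nf = exp_markers.n_slices;
  arma::mat qout(nf, m.nq);
  arma::mat resid(nf, m.nmark);
  resid.fill(arma::datum::nan);
  arma::ivec iters(nf, arma::fill::zeros);
  arma::ivec conv(nf, arma::fill::zeros);

  FkState st(m), stTrial(m);
  arma::vec q = q0;

  for (int f = 0; f < nf; ++f) {
    const arma::mat& obs = exp_markers.slice(f);
    std::vector<int> act;
    for (int j = 0; j < m.nmark; ++j)
      if (w[j] > 0 && obs.col(j).is_finite()) act.push_back(j);
    int na = act.size();
    if (na == 0) { qout.row(f) = q.t(); continue; }

    arma::vec sw(na);
    for (int i = 0; i < na; ++i) sw[i] = std::sqrt(w[act[i]]);

    auto residual = [&](FkState& state, arma::vec& r) {
      for (int i = 0; i < na; ++i) {
        int j = act[i];
        r.subvec(3 * i, 3 * i + 2) = sw[i] * (state.mk.col(j) - obs.col(j));
      }
    };

    for (int k = 0; k < m.nq; ++k)
      q[k] = std::min(std::max(q[k], bounds(k, 0)), bounds(k, 1));

    arma::vec r(3 * na), rn(3 * na);
    fk_one(m, q, st, true);
    residual(st, r);
    double cost = arma::dot(r, r);
    double lambda = 1e-5;
    bool converged = false;
    int it = 0;
    arma::mat J(3 * na, m.nq);
    arma::vec qn(m.nq);

    for (it = 0; it < max_iter; ++it) {
      fill_jacobian(m, st, act, sw, J);
      arma::vec g = J.t() * r;
      if (arma::norm(g, "inf") < gtol) { converged = true; break; }
      arma::mat H = J.t() * J;
      arma::vec dH = H.diag();

      bool accepted = false;
      double step = 0;
      for (int tries = 0; tries < 40; ++tries) {
        arma::mat Hl = H;
        Hl.diag() += lambda * dH + 1e-12;
        arma::vec d;
        if (!arma::solve(d, Hl, -g,
                         arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
          lambda *= 10;
          continue;
        }
        qn = q + d;
        for (int k = 0; k < m.nq; ++k)
          qn[k] = std::min(std::max(qn[k], bounds(k, 0)), bounds(k, 1));
        fk_one(m, qn, stTrial, true);
        residual(stTrial, rn);
        double cn = arma::dot(rn, rn);
        if (cn < cost) {
          step = arma::norm(qn - q, "inf");
          double drop = cost - cn;
          q = qn;
          r = rn;
          cost = cn;
          std::swap(st, stTrial);
          lambda = std::max(lambda / 3.0, 1e-12);
          accepted = true;
          if (drop < ftol * std::max(cost, 1e-300)) converged = true;
          break;
        }
        lambda *= 5;
        if (lambda > 1e12) break;
      }
      if (!accepted) { converged = true; break; }  // at a minimum to fp precision
      if (converged || step < xtol) { converged = true; break; }
    }

    qout.row(f) = q.t();
    iters[f] = it + 1;
    conv[f] = converged ? 1 : 0;
    for (int i = 0; i < na; ++i) {
      int j = act[i];
      resid(f, j) = arma::norm(st.mk.col(j) - obs.col(j), 2);
    }
  }

  return List::create(_["q"] = qout, _["resid"] = resid,
                      _["iterations"] = iters, _["converged"] = conv);
}
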