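#include <Rcpp.h>
using namespace Rcpp;

// One exact step of the constant-coefficient two-compartment system with a
// constant zero-order input, via the spectral decomposition of the 2x2
// rate matrix (see the R-level twocpt_step(), which this mirrors).
static inline void step2(double &ac, double &ap, double rate, double h,
                         double k10, double k12, double k21) {
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  if (disc < 0.0) disc = 0.0;
  double rt = std::sqrt(disc);
  double l1 = 0.5 * (-s + rt);
  double l2 = 0.5 * (-s - rt);
  double d = rt > 1e-12 ? rt : 1e-12;   // repeated-eigenvalue guard
  double a = k10 + k12;
  double p11 = (-a - l2) / d;
  double p12 = k21 / d;
  double p21 = k12 / d;
  double p22 = (-k21 - l2) / d;
  double e1 = std::exp(l1 * h);
  double e2 = std::exp(l2 * h);
  double f1 = std::fabs(l1) > 1e-12 ? std::expm1(l1 * h) / l1 : h;
  double f2 = std::fabs(l2) > 1e-12 ? std::expm1(l2 * h) / l2 : h;
  double nac = (e1 * p11 + e2 * (1.0 - p11)) * ac + (e1 - e2) * p12 * ap +
               (f1 * p11 + f2 * (1.0 - p11)) * rate;
  double nap = (e1 - e2) * p21 * ac + (e1 * p22 + e2 * (1.0 - p22)) * ap +
               (f1 - f2) * p21 * rate;
  ac = nac;
  ap = nap;
}

// Piecewise-constant propagation of a batch of parameter vectors through a
// shared segment schedule; growing peripheral volumes are handled by
// midpoint-frozen substeps of length <= dt_max.
// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(NumericVector times, NumericVector seg_start,
                   NumericVector seg_end, NumericVector seg_rate,
                   NumericVector seg_clkrt, NumericVector cl_body,
                   NumericVector v_c, NumericVector v_p0,
                   NumericVector vp_slope, double q, double dt_max) {
  int m = cl_body.size();
  int nt = times.size();
  int ns = seg_start.size();
  NumericMatrix Ac(m, nt), Ap(m, nt);
  std::vector<double> ac(m, 0.0), ap(m, 0.0);
  bool varying = false;
  for (int i = 0; i < m; ++i) if (vp_slope[i] > 0.0) varying = true;
  double t_cur = seg_start[0];
  int next_out = 0;
  while (next_out < nt && times[next_out] < t_cur + 1e-9) {
    for (int i = 0; i < m; ++i) { Ac(i, next_out) = ac[i]; Ap(i, next_out) = ap[i]; }
    ++next_out;
  }
  for (int sgi = 0; sgi < ns; ++sgi) {
    double s1 = seg_end[sgi];
    double rate = seg_rate[sgi];
    // stop points: output times inside the segment, then the segment end
    while (true) {
      double tn;
      bool is_out = (next_out < nt && times[next_out] <= s1 + 1e-9);
      tn = is_out ? times[next_out] : s1;
      if (tn > t_cur + 1e-12) {
        int nsub = 1;
        if (varying && tn - t_cur > dt_max)
          nsub = (int)std::ceil((tn - t_cur) / dt_max);
        double h = (tn - t_cur) / nsub;
        for (int kk = 0; kk < nsub; ++kk) {
          double tmid = t_cur + (kk + 0.5) * h;
          for (int i = 0; i < m; ++i) {
            double vp = v_p0[i] * (1.0 + vp_slope[i] * tmid);
            step2(ac[i], ap[i], rate, h,
                  (cl_body[i] + seg_clkrt[sgi]) / v_c[i],
                  q / v_c[i], q / vp);
          }
        }
        t_cur = tn;
      }
      if (is_out) {
        for (int i = 0; i < m; ++i) { Ac(i, next_out) = ac[i]; Ap(i, next_out) = ap[i]; }
        ++next_out;
        // duplicate output times
        while (next_out < nt && times[next_out] <= t_cur + 1e-9) {
          for (int i = 0; i < m; ++i) { Ac(i, next_out) = ac[i]; Ap(i, next_out) = ap[i]; }
          ++next_out;
        }
      } else {
        break;  // segment end reached
      }
      if (std::fabs(t_cur - s1) < 1e-12 &&
          !(next_out < nt && times[next_out] <= s1 + 1e-9)) break;
    }
  }
  NumericMatrix conc(m, nt);
  for (int j = 0; j < nt; ++j)
    for (int i = 0; i < m; ++i) conc(i, j) = Ac(i, j) / v_c[i];
  return List::create(_["conc"] = conc, _["Ac"] = Ac, _["Ap"] = Ap);
}
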