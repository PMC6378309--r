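#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-trial sampling loop. Uses R's RNG so that, given the same seed,
// the draw sequence is identical to the pure-R engine (step_trial):
// per step rnorm(fixated), rnorm(non-fixated), runif(duration), then
// either a tie coin (decision) or a switch draw.
// [[Rcpp::export(.sim_trial_cpp)]]
List sim_trial_cpp(double v_left, double v_right,
                   double sigma0, double delta, double gamma_, double kappa,
                   double lam, double omega, double omega0,
                   double t_min, double t_max,
                   int first_left, int max_samples, bool trace) {
  const double s0sq = sigma0 * sigma0;   // fixated sampling variance
  const double snsq = kappa * s0sq;      // non-fixated sampling variance
  const double sd_n = std::sqrt(snsq);

  double muL = 0.0, muR = 0.0, varL = s0sq, varR = s0sq;
  bool fix_left = first_left != 0;

  std::vector<int> fix_item, fix_n;
  std::vector<double> fix_dur;
  int cur_n = 0;
  double cur_dur = 0.0, rt = 0.0;
  int t = 0, choice = 0;
  bool forced = false;

  NumericMatrix tr;
  if (trace) tr = NumericMatrix(max_samples, 10);

  for (;;) {
    const double vf = fix_left ? v_left : v_right;
    const double vn = fix_left ? v_right : v_left;
    const double xf = R::rnorm(vf, sigma0);
    const double xn = R::rnorm(gamma_ * vn, sd_n);
    const double xL = fix_left ? xf : xn;
    const double xR = fix_left ? xn : xf;

    // mean updates use the pre-update belief variances
    const double svL = fix_left ? s0sq : snsq;
    const double svR = fix_left ? snsq : s0sq;
    muL = (varL * xL + svL * muL) / (varL + svL);
    muR = (varR * xR + svR * muR) / (varR + svR);
    if (fix_left) {
      varL = varL * s0sq / (varL + s0sq);
      varR = lam * varR * snsq / (varR + snsq);
    } else {
      varR = varR * s0sq / (varR + s0sq);
      varL = lam * varL * snsq / (varL + snsq);
    }
    ++t;
    const double dur = R::runif(t_min, t_max);
    ++cur_n;
    cur_dur += dur;
    rt += dur;

    const double conf = R::pnorm(std::fabs(muL - muR) / std::sqrt(varL + varR),
                                 0.0, 1.0, 1, 0);
    const double theta = 1.0 - delta * t;

    if (trace && t <= tr.nrow()) {
      tr(t - 1, 0) = t;
      tr(t - 1, 1) = fix_left ? 1 : 2;
      tr(t - 1, 2) = xL;
      tr(t - 1, 3) = xR;
      tr(t - 1, 4) = muL;
      tr(t - 1, 5) = muR;
      tr(t - 1, 6) = varL;
      tr(t - 1, 7) = varR;
      tr(t - 1, 8) = theta;
      tr(t - 1, 9) = conf;
    }

    bool stop_now = false;
    if (conf > theta) {
      stop_now = true;
    } else if (t >= max_samples) {
      stop_now = true;
      forced = true;
    }
    if (stop_now) {
      if (muL > muR) choice = 1;
      else if (muR > muL) choice = 2;
      else choice = (R::unif_rand() < 0.5) ? 1 : 2;
      fix_item.push_back(fix_left ? 1 : 2);
      fix_n.push_back(cur_n);
      fix_dur.push_back(cur_dur);
      break;
    }

    const double sdf = fix_left ? std::sqrt(varL) : std::sqrt(varR);
    const double sdn = fix_left ? std::sqrt(varR) : std::sqrt(varL);
    const double p_sw = 1.0 / (1.0 + std::exp(-(omega * sdn / sdf + omega0)));
    if (R::unif_rand() < p_sw) {
      fix_item.push_back(fix_left ? 1 : 2);
      fix_n.push_back(cur_n);
      fix_dur.push_back(cur_dur);
      cur_n = 0;
      cur_dur = 0.0;
      fix_left = !fix_left;
    }
  }

  List out = List::create(
    _["choice"] = choice,
    _["rt_ms"] = rt,
    _["n_samples_total"] = t,
    _["forced"] = forced,
    _["fix_item"] = wrap(fix_item),
    _["fix_n"] = wrap(fix_n),
    _["fix_dur"] = wrap(fix_dur),
    _["mu_left"] = muL, _["mu_right"] = muR,
    _["var_left"] = varL, _["var_right"] = varR);
  if (trace) out["trace"] = tr;
  return out;
}
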