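// Compiled engine for the individual-based partnering-and-conception
// simulator.  Mirrors the reference R engine in R/population.R and
// R/reproduction.R: per step (clock t) each woman, in one pass --
//   1. dies at hazard d(age) (closing her open episodes in the log);
//   2. if married, divorces at hazard mu_marital, else (age > min) marries
//      at hazard alpha;
//   3. forms a new nonmarital partnership at her individual rate
//      (lam_p unmarried / lam_e married) * h(t) * age multiplier;
//   4. if non-gestating and of reproductive age, may conceive.
// Open nonmarital episodes dissolve at mu_casual; registered boys are
// subject to the same mortality; after the clock advances, due
// gestations deliver (birth dated at the exact due day) and newborn
// girls join the population.
//
// All per-step event probabilities are 1 - exp(-rate * dt).  The
// conception block uses the exact marginal of the act-allocation model:
// with total acts N ~ Poisson(mu) and a fraction s of acts to a partner
// whose per-act conception probability is p, the step conception
// probability with that partner is 1 - E[(1-p)^Binomial-split] =
// 1 - exp(-mu * s * p), and splits to distinct partners are independent
// Poisson thinnings.  The first success in random partner order sets the
// biological father, as in the reference engine's explicit allocation.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static const double YEAR = 365.25;

struct StepFun {
  std::vector<double> br, val;
  double at(double x) const {
    if (x < br[0]) return 0.0;
    size_t lo = 0, hi = br.size();
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (br[mid] <= x) lo = mid; else hi = mid;
    }
    return val[lo];
  }
};

static StepFun make_stepfun(List tab) {
  StepFun f;
  NumericVector a = tab["age"], v = tab["value"];
  f.br.assign(a.begin(), a.end());
  f.val.assign(v.begin(), v.end());
  return f;
}

struct LinFun {
  std::vector<double> ts, vs;
  double at(double x) const {
    if (ts.size() == 1 || x <= ts.front()) return vs.front();
    if (x >= ts.back()) return vs.back();
    size_t i = 1;
    while (ts[i] < x) ++i;
    double w = (x - ts[i - 1]) / (ts[i] - ts[i - 1]);
    return vs[i - 1] + w * (vs[i] - vs[i - 1]);
  }
};

// [[Rcpp::export]]
List sim_core(List par, NumericVector init_birth_day, LogicalVector init_married,
              IntegerVector init_husband, NumericVector init_lam_p,
              NumericVector init_lam_e, int next_male_start) {
  const double dt = as<double>(par["time_step_days"]);
  const double dtY = dt / YEAR;
  const double horizon_days = as<double>(par["horizon_years"]) * YEAR;
  const double alpha = as<double>(par["alpha"]);
  const double mu_m = as<double>(par["mu_marital"]);
  const double mu_c = as<double>(par["mu_casual"]);
  const double gest_mean = as<double>(par["gest_mean"]);
  const double gest_sd = as<double>(par["gest_sd"]);
  const double phi_m = as<double>(par["phi_m"]);
  const double eff = as<double>(par["eff"]);
  const double cv_unmar = as<double>(par["cv_unmarried"]);
  const double cv_mar = as<double>(par["cv_marital"]);
  const double cv_em = as<double>(par["cv_extramarital"]);
  const double min_age = as<double>(par["min_partner_age"]);
  const double max_fert = as<double>(par["max_conception_age"]);
  const double lp_mean = as<double>(par["lam_p_mean"]);
  const double lp_var = as<double>(par["lam_p_var"]);
  const double le_mean = as<double>(par["lam_e_mean"]);
  const double le_var = as<double>(par["lam_e_var"]);

  StepFun fec = make_stepfun(par["fecundability"]);
  StepFun coit = make_stepfun(par["coital_frequency"]);
  StepFun mort = make_stepfun(par["mortality"]);
  StepFun mult = make_stepfun(par["age_multiplier"]);
  LinFun h;
  {
    List ht = par["h_of_t"];
    NumericVector ts = ht["time"], vs = ht["value"];
    h.ts.assign(ts.begin(), ts.end());
    h.vs.assign(vs.begin(), vs.end());
  }

  // age bands on the union of all schedule breakpoints, with per-band
  // step probabilities precomputed once
  std::vector<double> bands(1, 0.0);
  for (size_t j = 0; j < fec.br.size(); ++j) bands.push_back(fec.br[j]);
  for (size_t j = 0; j < coit.br.size(); ++j) bands.push_back(coit.br[j]);
  for (size_t j = 0; j < mort.br.size(); ++j) bands.push_back(mort.br[j]);
  for (size_t j = 0; j < mult.br.size(); ++j) bands.push_back(mult.br[j]);
  std::sort(bands.begin(), bands.end());
  bands.erase(std::unique(bands.begin(), bands.end()), bands.end());
  size_t nb = bands.size();
  std::vector<double> b_pdie(nb), b_mult(nb), b_mu(nb), b_f(nb),
      b_pc_mar(nb), b_pc_pm1(nb);
  for (size_t j = 0; j < nb; ++j) {
    double a = bands[j];
    b_pdie[j] = 1.0 - std::exp(-mort.at(a) * dtY);
    b_mult[j] = mult.at(a);
    b_mu[j] = coit.at(a) * dt / 30.4375;       // expected acts per step
    b_f[j] = fec.at(a);
    b_pc_mar[j] = 1.0 - std::exp(-b_mu[j] * b_f[j] * (1.0 - eff * cv_mar));
    b_pc_pm1[j] = 1.0 - std::exp(-b_mu[j] * b_f[j] * (1.0 - eff * cv_unmar));
  }
  const double pr_em_scale = 1.0 - eff * cv_em;
  const double pr_pm_scale = 1.0 - eff * cv_unmar;
  const double pr_mar_scale = 1.0 - eff * cv_mar;

  // women
  std::vector<double> wb(init_birth_day.begin(), init_birth_day.end());
  size_t n0 = wb.size();
  std::vector<double> wd(n0, NA_REAL), wdue(n0, NA_REAL), wgs(n0, NA_REAL);
  std::vector<char> wm(n0, 0), wg(n0, 0);
  std::vector<int> wh(n0, NA_INTEGER), wmrow(n0, -1), wgf(n0, NA_INTEGER),
      wgfh(n0, NA_INTEGER), wreg(n0, -1);
  std::vector<double> wlp(init_lam_p.begin(), init_lam_p.end());
  std::vector<double> wle(init_lam_e.begin(), init_lam_e.end());
  std::vector<double> wqp(n0), wqe(n0);        // exp(-lam * dtY) per woman
  for (size_t i = 0; i < n0; ++i) {
    wqp[i] = std::exp(-wlp[i] * dtY);
    wqe[i] = std::exp(-wle[i] * dtY);
  }

  // partnership log (class 1 marital, 2 premarital, 3 extramarital)
  std::vector<int> lw, lp_, lc;
  std::vector<double> ls, le;

  // registry
  std::vector<int> rm, rbf, rpf, rwidx;
  std::vector<double> rbd, rgd, rdd;
  std::vector<char> rnp, rsexF;

  std::vector<int> act_row, act_w, act_p;      // open nonmarital episodes
  std::vector<int> boys;                       // alive boys' registry rows

  int next_male = next_male_start;
  for (size_t i = 0; i < n0; ++i) {
    if (init_married[i]) {
      wm[i] = 1;
      wh[i] = init_husband[i];
      wmrow[i] = (int)lw.size();
      lw.push_back((int)i + 1); lp_.push_back(wh[i]); lc.push_back(1);
      ls.push_back(0.0); le.push_back(NA_REAL);
    }
  }

  RNGScope rngscope;
  double t = 0.0;

  auto close_marriage = [&](size_t w, double when) {
    le[wmrow[w]] = when;
    wm[w] = 0; wh[w] = NA_INTEGER; wmrow[w] = -1;
  };
  auto drop_active = [&](size_t k) {
    act_row[k] = act_row.back(); act_row.pop_back();
    act_w[k] = act_w.back(); act_w.pop_back();
    act_p[k] = act_p.back(); act_p.pop_back();
  };

  const double p_div = 1.0 - std::exp(-mu_m * dtY);
  const double p_wed = 1.0 - std::exp(-alpha * dtY);
  const double p_cas = 1.0 - std::exp(-mu_c * dtY);

  std::unordered_map<int, std::vector<int> > partners;
  std::vector<int> pid; std::vector<double> ppr; std::vector<int> ord;

  while (t < horizon_days) {
    // open nonmarital episodes dissolve
    for (size_t k = 0; k < act_row.size();) {
      if (R::runif(0.0, 1.0) < p_cas) {
        le[act_row[k]] = t;
        drop_active(k);
      } else ++k;
    }
    // registered boys die
    for (size_t k = 0; k < boys.size();) {
      int r = boys[k];
      double age = (t - rbd[r]) / YEAR;
      size_t b = (size_t)(std::upper_bound(bands.begin(), bands.end(), age) -
                          bands.begin()) - 1;
      if (R::runif(0.0, 1.0) < b_pdie[b]) {
        rdd[r] = t;
        boys[k] = boys.back(); boys.pop_back();
      } else ++k;
    }

    double ht = h.at(t / YEAR);
    partners.clear();
    for (size_t k = 0; k < act_w.size(); ++k)
      partners[act_w[k]].push_back(act_p[k]);

    size_t n_now = wb.size();                  // newborns wait a step
    for (size_t i = 0; i < n_now; ++i) {
      if (!ISNA(wd[i])) continue;
      double age = (t - wb[i]) / YEAR;
      size_t b = (size_t)(std::upper_bound(bands.begin(), bands.end(), age) -
                          bands.begin()) - 1;
      // death
      if (R::runif(0.0, 1.0) < b_pdie[b]) {
        wd[i] = t;
        if (wm[i]) close_marriage(i, t);
        for (size_t k = 0; k < act_row.size();) {
          if (act_w[k] == (int)i + 1) { le[act_row[k]] = t; drop_active(k); }
          else ++k;
        }
        wg[i] = 0;
        if (wreg[i] >= 0) rdd[wreg[i]] = t;
        continue;
      }
      // marriage dynamics
      if (wm[i]) {
        if (R::runif(0.0, 1.0) < p_div) close_marriage(i, t);
      } else if (age > min_age && R::runif(0.0, 1.0) < p_wed) {
        wm[i] = 1; wh[i] = next_male++;
        wmrow[i] = (int)lw.size();
        lw.push_back((int)i + 1); lp_.push_back(wh[i]); lc.push_back(1);
        ls.push_back(t); le.push_back(NA_REAL);
        // marriage closes her open nonmarital partnerships
        for (size_t k = 0; k < act_row.size();) {
          if (act_w[k] == (int)i + 1) { le[act_row[k]] = t; drop_active(k); }
          else ++k;
        }
        partners.erase((int)i + 1);
      }
      // new nonmarital partnership
      if (ht > 0 && age > min_age) {
        double s = ht * b_mult[b];
        double q = wm[i] ? wqe[i] : wqp[i];
        if (q < 1.0 && s > 0) {
          double pform = (s == 1.0) ? 1.0 - q : 1.0 - std::pow(q, s);
          if (R::runif(0.0, 1.0) < pform) {
            int ptok = next_male++;
            int row = (int)lw.size();
            lw.push_back((int)i + 1); lp_.push_back(ptok);
            lc.push_back(wm[i] ? 3 : 2);
            ls.push_back(t); le.push_back(NA_REAL);
            act_row.push_back(row); act_w.push_back((int)i + 1);
            act_p.push_back(ptok);
            partners[(int)i + 1].push_back(ptok);
          }
        }
      }
      // conception
      if (wg[i] || age < min_age || age >= max_fert || b_f[b] <= 0) continue;
      std::vector<int>* pp = NULL;
      std::unordered_map<int, std::vector<int> >::iterator it =
          partners.find((int)i + 1);
      if (it != partners.end() && !it->second.empty()) pp = &it->second;
      int father = NA_INTEGER;
      if (wm[i] && pp == NULL) {               // spouse only: fast path
        if (R::runif(0.0, 1.0) < b_pc_mar[b]) father = wh[i];
      } else if (!wm[i] && pp != NULL && pp->size() == 1) {
        if (R::runif(0.0, 1.0) < b_pc_pm1[b]) father = (*pp)[0];
      } else if (pp != NULL) {                 // multiple partners
        int k = (int)pp->size();
        pid.clear(); ppr.clear();
        if (wm[i]) {
          pid.push_back(wh[i]);
          ppr.push_back(1.0 - std::exp(-b_mu[b] * phi_m * b_f[b] * pr_mar_scale));
          double sh = (1.0 - phi_m) / (double)k;
          for (int j = 0; j < k; ++j) {
            pid.push_back((*pp)[j]);
            ppr.push_back(1.0 - std::exp(-b_mu[b] * sh * b_f[b] * pr_em_scale));
          }
        } else {
          double sh = 1.0 / (double)k;
          for (int j = 0; j < k; ++j) {
            pid.push_back((*pp)[j]);
            ppr.push_back(1.0 - std::exp(-b_mu[b] * sh * b_f[b] * pr_pm_scale));
          }
        }
        int m = (int)pid.size();
        ord.resize(m);
        for (int j = 0; j < m; ++j) ord[j] = j;
        for (int j = m - 1; j > 0; --j) {
          int u = (int)std::floor(R::runif(0.0, 1.0) * (j + 1));
          if (u > j) u = j;
          std::swap(ord[j], ord[u]);
        }
        for (int j = 0; j < m; ++j) {
          if (R::runif(0.0, 1.0) < ppr[ord[j]]) { father = pid[ord[j]]; break; }
        }
      }
      if (father != NA_INTEGER) {
        double g = std::max(1.0, std::floor(R::rnorm(gest_mean, gest_sd) + 0.5));
        wg[i] = 1; wgs[i] = t; wdue[i] = t + g;
        wgf[i] = father;
        wgfh[i] = wm[i] ? wh[i] : NA_INTEGER;
      }
    }

    t += dt;

    // deliveries
    for (size_t i = 0; i < n_now; ++i) {
      if (!ISNA(wd[i]) || !wg[i] || wdue[i] > t) continue;
      double bday = wdue[i];
      int bio = wgf[i], put = wgfh[i];
      bool nonpat = (put != NA_INTEGER) && (bio != put);
      bool female = R::runif(0.0, 1.0) < 0.5;
      int r = (int)rm.size();
      rm.push_back((int)i + 1); rbf.push_back(bio); rpf.push_back(put);
      rbd.push_back(bday); rgd.push_back(bday - wgs[i]);
      rnp.push_back(nonpat ? 1 : 0); rsexF.push_back(female ? 1 : 0);
      rdd.push_back(NA_REAL); rwidx.push_back(NA_INTEGER);
      if (female) {
        wb.push_back(bday); wd.push_back(NA_REAL);
        wm.push_back(0); wh.push_back(NA_INTEGER); wmrow.push_back(-1);
        wg.push_back(0); wdue.push_back(NA_REAL); wgs.push_back(NA_REAL);
        wgf.push_back(NA_INTEGER); wgfh.push_back(NA_INTEGER);
        double lp = (lp_mean == 0 || lp_var == 0)
                        ? lp_mean
                        : R::rgamma(lp_mean * lp_mean / lp_var, lp_var / lp_mean);
        double lev = (le_mean == 0 || le_var == 0)
                         ? le_mean
                         : R::rgamma(le_mean * le_mean / le_var, le_var / le_mean);
        wlp.push_back(lp); wle.push_back(lev);
        wqp.push_back(std::exp(-lp * dtY));
        wqe.push_back(std::exp(-lev * dtY));
        wreg.push_back(r);
        rwidx[r] = (int)wb.size();
      } else {
        boys.push_back(r);
      }
      wg[i] = 0; wdue[i] = NA_REAL; wgs[i] = NA_REAL;
      wgf[i] = NA_INTEGER; wgfh[i] = NA_INTEGER;
    }
  }

  return List::create(
      _["registry"] = List::create(
          _["mother_id"] = wrap(rm), _["bio_father_id"] = wrap(rbf),
          _["putative_father_id"] = wrap(rpf), _["birth_day"] = wrap(rbd),
          _["gestation_days"] = wrap(rgd),
          _["nonpaternity"] = LogicalVector(rnp.begin(), rnp.end()),
          _["female"] = LogicalVector(rsexF.begin(), rsexF.end()),
          _["death_day"] = wrap(rdd), _["woman_idx"] = wrap(rwidx)),
      _["plog"] = List::create(
          _["woman_id"] = wrap(lw), _["partner_id"] = wrap(lp_),
          _["class"] = wrap(lc), _["start_day"] = wrap(ls),
          _["end_day"] = wrap(le)),
      _["women"] = List::create(
          _["birth_day"] = wrap(wb), _["death_day"] = wrap(wd),
          _["married"] = LogicalVector(wm.begin(), wm.end()),
          _["lam_p"] = wrap(wlp), _["lam_e"] = wrap(wle)),
      _["final_day"] = t);
}
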