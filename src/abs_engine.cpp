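// Hourly agent scheduler. Stage coding matches the R side:
// 1 egg, 2 larva, 3 pupa, 4 immature adult, 5 mature adult.
// Per agent, per hour, in order: develop/transition -> reproduce (daily, with
// the daily sterilization test after laying) -> natural death -> human-induced
// death. Dead agents are removed at the end of the hour; newly laid eggs are
// appended after the survivors and first processed the following hour.
// All randomness comes from R's RNG so set.seed() governs results.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double hourly_p(double daily, bool literal) {
  if (daily <= 0.0) return 0.0;
  if (daily >= 1.0) return 1.0;
  return literal ? std::pow(daily, 1.0 / 24.0)
                 : 1.0 - std::pow(1.0 - daily, 1.0 / 24.0);
}

static inline double draw_threshold_c(double K, double gamma) {
  for (;;) {
    double v = 24.0 * K * (1.0 + gamma * norm_rand());
    if (v > 0.0) return v;
  }
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export(name = ".abs_advance")]]
List abs_advance(List state, NumericVector temps, List par, bool record_daily) {
  // --- unpack state ------------------------------------------------------
  IntegerVector st0 = state["stage"];
  NumericVector ac0 = state["acc"];
  NumericVector th0 = state["thr"];
  LogicalVector fe0 = state["fertile"];
  IntegerVector bh0 = state["birth_hour"];
  int hour = as<int>(state["hour"]);
  double cum_eggs = as<double>(state["cum_eggs"]);
  double cum_births = as<double>(state["cum_births"]);
  double deaths_nat = as<double>(state["deaths_natural"]);
  double deaths_hum = as<double>(state["deaths_human"]);
  double adult_deaths = as<double>(state["adult_deaths"]);
  bool cap_flag = as<bool>(state["cap_exceeded"]);

  std::vector<int> stage(st0.begin(), st0.end());
  std::vector<double> acc(ac0.begin(), ac0.end());
  std::vector<double> thr(th0.begin(), th0.end());
  std::vector<char> fert(fe0.size());
  for (int i = 0; i < fe0.size(); ++i) fert[i] = fe0[i] ? 1 : 0;
  std::vector<int> birth(bh0.begin(), bh0.end());

  // --- unpack parameters -------------------------------------------------
  NumericVector tmin = par["T_min"];   // length 4: e, l, p, a
  NumericVector Kv = par["K"];         // length 4
  double tmax = as<double>(par["T_max"]);
  double gamma = as<double>(par["gamma"]);
  int mort_mode = as<int>(par["mort_mode"]);   // 0 fixed, 1 temperature
  NumericVector M = par["M_star"];     // length 4
  NumericMatrix quad = par["quadratics"]; // rows el, p, a; cols a2, a1, a0
  double r = as<double>(par["r"]);
  double r_var = as<double>(par["r_var"]);
  double ff = as<double>(par["female_fraction"]);
  double t_S = as<double>(par["t_S"]);
  double S = as<double>(par["S"]);
  double r_red = as<double>(par["r_red"]);
  bool sterile_off = as<bool>(par["sterile_offspring"]);
  int dm = as<int>(par["D_m"]);        // 0 thermal_unit, 1 hourly_probability
  double Nm = as<double>(par["N_m"]);
  int repro_hour = as<int>(par["reproduction_hour"]);
  bool literal = as<bool>(par["literal_exponent"]);
  double sd_eggs = std::sqrt(r_var);

  static const int par_idx[6] = {0, 0, 1, 2, 3, 3};   // stage -> e/l/p/a index
  static const int quad_idx[6] = {0, 0, 0, 1, 2, 2};  // stage -> quadratic row

  int n_hours = temps.size();
  int max_days = n_hours / 24 + 2;
  NumericMatrix day_counts(record_daily ? max_days : 0, 5);
  NumericMatrix day_temps(record_daily ? max_days : 0, 3);
  int days_rec = 0;
  double cur_tmin = R_PosInf, cur_tmax = R_NegInf, cur_tsum = 0.0;
  int cur_tn = 0;

  int live = 0;
  for (size_t i = 0; i < stage.size(); ++i) if (stage[i] > 0) ++live;

  int status = 0;            // 0 running, 1 extirpated
  double te_hour = NA_REAL;

  if (live == 0) {           // empty initial population: extirpated at once
    status = 1;
    te_hour = 0.0;
  }

  int t = 0;
  for (; t < n_hours && status == 0; ++t) {
    double T = temps[t];
    bool interv = (double)hour >= 24.0 * t_S;
    bool repro_now = ((hour % 24) + 24) % 24 == repro_hour;

    // per-stage rates for this hour
    double inc[6], hp[6];
    for (int s = 1; s <= 5; ++s) {
      int pi = par_idx[s];
      double ic = (s == 5) ? 0.0
                 : (T > tmax ? 0.0 : (T > tmin[pi] ? T - tmin[pi] : 0.0));
      inc[s] = ic;
      double daily = M[pi];
      if (mort_mode == 1) {
        int q = quad_idx[s];
        double mu = clamp01(quad(q, 0) * T * T + quad(q, 1) * T + quad(q, 2));
        daily = clamp01(daily + mu);
      }
      hp[s] = hourly_p(daily, literal);
    }
    double hpS = hourly_p(S, literal);

    cur_tmin = std::min(cur_tmin, T);
    cur_tmax = std::max(cur_tmax, T);
    cur_tsum += T; ++cur_tn;

    size_t n0 = stage.size();
    std::vector<int> nw_stage; std::vector<double> nw_acc, nw_thr;
    std::vector<char> nw_fert; std::vector<int> nw_birth;

    for (size_t i = 0; i < n0; ++i) {
      int s = stage[i];
      if (s <= 0) continue;                         // died earlier this hour? (never: compacted)

      // (1) development
      if (s < 5) {
        if (dm == 0) {
          acc[i] += inc[s];
          while (s < 5 && acc[i] >= thr[i]) {
            double carry = acc[i] - thr[i];
            ++s;
            thr[i] = (s < 5) ? draw_threshold_c(Kv[par_idx[s]], gamma) : R_PosInf;
            acc[i] = carry;
          }
          stage[i] = s;
        } else {
          double p = inc[s] / (24.0 * Kv[par_idx[s]]);
          if (p > 1.0) p = 1.0;
          if (p > 0.0 && unif_rand() < p) stage[i] = ++s;
        }
      }

      // (2) reproduction (daily) + sterilization test after laying
      if (repro_now && s == 5 && fert[i]) {
        double ne = std::round(r + (r_var > 0.0 ? sd_eggs * norm_rand() : 0.0));
        if (ne < 0.0) ne = 0.0;
        int n_eggs = (int)ne;
        cum_eggs += n_eggs;
        int n_fem = (ff >= 1.0) ? n_eggs
                  : (ff <= 0.0) ? 0
                  : (int)R::rbinom(n_eggs, ff);
        char off_fert = (interv && sterile_off) ? 0 : 1;
        for (int e = 0; e < n_fem; ++e) {
          if (live + (double)nw_stage.size() >= Nm) { cap_flag = true; break; }
          nw_stage.push_back(1);
          nw_acc.push_back(0.0);
          nw_thr.push_back(dm == 0 ? draw_threshold_c(Kv[0], gamma) : 0.0);
          nw_fert.push_back(off_fert);
          nw_birth.push_back(hour);
          cum_births += 1.0;
        }
        if (interv && r_red > 0.0 && unif_rand() < r_red) fert[i] = 0;
      }

      // (3) natural death
      if (hp[s] > 0.0 && unif_rand() < hp[s]) {
        deaths_nat += 1.0;
        if (s >= 4) adult_deaths += 1.0;
        stage[i] = 0; --live;
        continue;
      }

      // (4) human-induced death (adults, after countermeasures begin)
      if (interv && s >= 4 && hpS > 0.0 && unif_rand() < hpS) {
        deaths_hum += 1.0;
        adult_deaths += 1.0;
        stage[i] = 0; --live;
      }
    }

    // compact survivors in insertion order, then append this hour's eggs
    size_t w = 0;
    for (size_t i = 0; i < stage.size(); ++i) {
      if (stage[i] > 0) {
        if (w != i) {
          stage[w] = stage[i]; acc[w] = acc[i]; thr[w] = thr[i];
          fert[w] = fert[i]; birth[w] = birth[i];
        }
        ++w;
      }
    }
    stage.resize(w); acc.resize(w); thr.resize(w); fert.resize(w); birth.resize(w);
    stage.insert(stage.end(), nw_stage.begin(), nw_stage.end());
    acc.insert(acc.end(), nw_acc.begin(), nw_acc.end());
    thr.insert(thr.end(), nw_thr.begin(), nw_thr.end());
    fert.insert(fert.end(), nw_fert.begin(), nw_fert.end());
    birth.insert(birth.end(), nw_birth.begin(), nw_birth.end());
    live = (int)stage.size();

    ++hour;

    bool day_end = (hour % 24) == 0;
    if (live == 0) {
      status = 1;
      te_hour = (double)hour;
    }
    if (record_daily && (day_end || status == 1) && cur_tn > 0 && days_rec < max_days) {
      for (size_t i = 0; i < stage.size(); ++i) day_counts(days_rec, stage[i] - 1) += 1.0;
      day_temps(days_rec, 0) = cur_tmin;
      day_temps(days_rec, 1) = cur_tsum / cur_tn;
      day_temps(days_rec, 2) = cur_tmax;
      ++days_rec;
      cur_tmin = R_PosInf; cur_tmax = R_NegInf; cur_tsum = 0.0; cur_tn = 0;
    }
  }

  // partial final day (temps exhausted mid-day)
  if (record_daily && status == 0 && cur_tn > 0 && days_rec < max_days) {
    for (size_t i = 0; i < stage.size(); ++i) day_counts(days_rec, stage[i] - 1) += 1.0;
    day_temps(days_rec, 0) = cur_tmin;
    day_temps(days_rec, 1) = cur_tsum / cur_tn;
    day_temps(days_rec, 2) = cur_tmax;
    ++days_rec;
  }

  List out_state = List::create(
    _["stage"] = IntegerVector(stage.begin(), stage.end()),
    _["acc"] = NumericVector(acc.begin(), acc.end()),
    _["thr"] = NumericVector(thr.begin(), thr.end()),
    _["fertile"] = LogicalVector(fert.begin(), fert.end()),
    _["birth_hour"] = IntegerVector(birth.begin(), birth.end()),
    _["hour"] = hour,
    _["cum_eggs"] = cum_eggs,
    _["cum_births"] = cum_births,
    _["deaths_natural"] = deaths_nat,
    _["deaths_human"] = deaths_hum,
    _["adult_deaths"] = adult_deaths,
    _["cap_exceeded"] = cap_flag);

  List res = List::create(
    _["state"] = out_state,
    _["status"] = status,
    _["te_hour"] = te_hour,
    _["hours_run"] = t,
    _["days_recorded"] = days_rec);
  if (record_daily) {
    res["day_counts"] = day_counts;
    res["day_temps"] = day_temps;
  }
  return res;
}
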