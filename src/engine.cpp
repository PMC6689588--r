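// Fast round-update engine for the foraging / social-learning simulator.
//
// Semantics are identical to the pure-R reference engine (see R/dynamics.R,
// R/reproduction.R): per round (1) action draw, (2) exploiters commit to the
// best remembered patch, (3) occupancy and scramble payoffs resolved
// simultaneously, (4) learners observe with current payoffs and occupancy,
// (5) payoff histories and ages advance, (6) environmental turnover,
// (7) mortality and replacement.  All randomness comes from R's RNG so runs
// are reproducible with set.seed(); the two engines do not consume random
// numbers in the same order and are compared statistically, not bitwise.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// Per-individual patch memories, stored in one contiguous arena for cache
// locality (scans dominate the round update).  An individual gains at most
// one new patch entry per round lived (learners add one patch, exploiters
// only revisit known patches), so min(n_patches, max_age) + 1 slots per
// individual is a hard capacity bound, not a heuristic.
struct MemoryArena {
  int cap;
  std::vector<int> patch;
  std::vector<double> value;
  std::vector<int> size;
  MemoryArena(int n, int cap_) : cap(cap_),
      patch((std::size_t)n * cap_), value((std::size_t)n * cap_),
      size(n, 0) {}
  bool empty(int i) const { return size[i] == 0; }
  void clear(int i) { size[i] = 0; }
  void set(int i, int m, double v) {
    const std::size_t o = (std::size_t)i * cap;
    const int n = size[i];
    for (int k = 0; k < n; ++k)
      if (patch[o + k] == m) { value[o + k] = v; return; }
    if (n < cap) {
      patch[o + n] = m;
      value[o + n] = v;
      size[i] = n + 1;
    } else { // unreachable by the capacity argument; replace the worst entry
      int worst = 0;
      for (int k = 1; k < n; ++k)
        if (value[o + k] < value[o + worst]) worst = k;
      patch[o + worst] = m;
      value[o + worst] = v;
    }
  }
  // Patch with the highest remembered payoff; ties broken uniformly at
  // random (reservoir scheme).  -1 when the memory is empty.
  int best(int i) const {
    const int n = size[i];
    if (n == 0) return -1;
    const std::size_t o = (std::size_t)i * cap;
    double bv = value[o];
    int bp = patch[o];
    int ties = 1;
    for (int k = 1; k < n; ++k) {
      if (value[o + k] > bv) {
        bv = value[o + k]; bp = patch[o + k]; ties = 1;
      } else if (value[o + k] == bv) {
        ++ties;
        if (unif_rand() * ties < 1.0) bp = patch[o + k];
      }
    }
    return bp;
  }
};

struct ParentPool {
  std::vector<int> idx;    // population indices, top-ranked first
  std::vector<double> cum; // unnormalised cumulative sampling weights
  double total = 0.0;
  bool empty() const { return idx.empty(); }
  int sample() const {
    double u = unif_rand() * total;
    std::size_t k = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (k >= idx.size()) k = idx.size() - 1;
    return idx[k];
  }
};

// Rank candidates by fitness (descending, ties shuffled uniformly) and keep
// the top ceil(beta * n).  criterion 0: equal weights (minimum income);
// criterion 1: weights proportional to fitness (relative income).
ParentPool build_pool(const std::vector<int>& cand,
                      const std::vector<double>& fit,
                      double beta, int criterion) {
  ParentPool pool;
  const std::size_t n = cand.size();
  if (n == 0) return pool;
  std::vector<std::size_t> ord(n);
  for (std::size_t k = 0; k < n; ++k) ord[k] = k;
  std::vector<double> key(n);
  for (std::size_t k = 0; k < n; ++k) key[k] = unif_rand();
  std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
    if (fit[a] != fit[b]) return fit[a] > fit[b];
    return key[a] < key[b];
  });
  std::size_t k = (std::size_t)std::ceil(beta * (double)n);
  if (k < 1) k = 1;
  if (k > n) k = n;
  pool.idx.reserve(k);
  pool.cum.reserve(k);
  double tot = 0.0;
  bool relative = (criterion == 1);
  double fitsum = 0.0;
  if (relative)
    for (std::size_t j = 0; j < k; ++j) fitsum += fit[ord[j]];
  for (std::size_t j = 0; j < k; ++j) {
    double w = (relative && fitsum > 0.0) ? fit[ord[j]] : 1.0;
    tot += w;
    pool.idx.push_back(cand[ord[j]]);
    pool.cum.push_back(tot);
  }
  pool.total = tot;
  return pool;
}

inline int unif_index(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

} // namespace

// Modes: 0 fixed_proportion, 1 asexual, 2 sexual.
// Criterion: 0 minimum_income, 1 relative_income.
// Fitness mode: 0 windowed, 1 single_round.
// Sex codes: 0 female, 1 male, 2 none.
// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(int n_individuals, int n_patches,
                    double mean_payoff, double payoff_variance,
                    double turnover, double learn_prob,
                    int window, double discount, int fitness_mode,
                    int mode, int criterion,
                    double beta, double beta_f, double beta_m,
                    double mutation_rate, double death_prob, int max_age,
                    int max_rounds,
                    NumericVector alpha_init, IntegerVector sex_init,
                    IntegerVector age_init,
                    bool force_individual, bool strict_sex_ratio,
                    bool naive_alpha, bool log_individuals) {
  const int N = n_individuals, M = n_patches;
  const double shape = mean_payoff * mean_payoff / payoff_variance;
  const double scale = payoff_variance / mean_payoff;
  const int maturity = (fitness_mode == 0) ? window : 1;

  // --- state -------------------------------------------------------------
  std::vector<double> payoffs(M);
  for (int m = 0; m < M; ++m) payoffs[m] = R::rgamma(shape, scale);

  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<int> sex(sex_init.begin(), sex_init.end());
  std::vector<int> age(age_init.begin(), age_init.end());
  std::vector<int> ident(N);
  for (int i = 0; i < N; ++i) ident[i] = i + 1;
  int next_ident = N + 1;

  MemoryArena mem(N, std::min(M, max_age) + 1);
  // payoff histories as per-individual ring buffers of length `window`
  std::vector<double> hist((std::size_t)N * window, 0.0);
  std::vector<int> hpos(N, 0);
  std::vector<double> w(window);
  for (int j = 0; j < window; ++j) w[j] = std::exp(-discount * j);

  std::vector<int> prev_patch(N, -1); // patch exploited last round, -1 if none
  std::vector<int> chosen(N, -1);
  std::vector<char> learner(N, 0), forced(N, 0), dead(N, 0);
  std::vector<double> collected(N, 0.0);
  std::vector<int> occ(M, 0);
  std::vector<int> demo;
  demo.reserve(N);

  const bool binary = mode != 0; // evolutionary runs use binary alpha

  // --- per-round summaries ----------------------------------------------
  std::vector<double> rec_freq, rec_freq_f, rec_freq_m,
      rec_mean_s, rec_mean_i, rec_var_s, rec_var_i, rec_total;
  std::vector<int> rec_nexp_s, rec_nexp_i, rec_nlearn, rec_deaths;
  rec_freq.reserve(max_rounds);

  // final-round (pre-mortality) snapshot
  std::vector<int> fin_ident(N), fin_sex(N), fin_age(N), fin_patch(N),
      fin_action(N);
  std::vector<double> fin_alpha(N), fin_collected(N);

  // optional long-format per-individual log
  std::vector<int> log_round, log_ident, log_sexv, log_action, log_patch;
  std::vector<double> log_alpha, log_coll;

  double max_cons_err = 0.0;
  int n_pool_fallback = 0;
  int term_round = 0;
  std::string term_cause = "max_rounds";

  for (int t = 1; t <= max_rounds; ++t) {
    // (1) action draw; exploiters with empty memories become individual
    // learners for the round (they have nowhere to go)
    for (int i = 0; i < N; ++i) {
      bool L = unif_rand() < learn_prob;
      bool F = false;
      if (!L && mem.empty(i)) { L = true; F = true; }
      learner[i] = L;
      forced[i] = F;
      chosen[i] = -1;
    }
    // (2) exploiters commit to their best remembered patch
    for (int i = 0; i < N; ++i)
      if (!learner[i]) chosen[i] = mem.best(i);
    // (3) occupancy and scramble shares, resolved simultaneously
    std::fill(occ.begin(), occ.end(), 0);
    for (int i = 0; i < N; ++i)
      if (chosen[i] >= 0) ++occ[chosen[i]];
    double tot_collected = 0.0;
    for (int i = 0; i < N; ++i) {
      if (chosen[i] >= 0) {
        double c = payoffs[chosen[i]] / occ[chosen[i]];
        collected[i] = c;
        mem.set(i, chosen[i], c);
        tot_collected += c;
      } else {
        collected[i] = 0.0;
      }
    }
    double tot_occupied = 0.0;
    for (int m = 0; m < M; ++m)
      if (occ[m] > 0) tot_occupied += payoffs[m];
    double err = std::fabs(tot_collected - tot_occupied);
    if (err > max_cons_err) max_cons_err = err;

    // (4) learners observe: socially (copy a previous-round exploiter's
    // patch) with probability alpha, otherwise a uniformly random patch;
    // expected payoff uses current payoffs and current occupancy
    demo.clear();
    for (int i = 0; i < N; ++i)
      if (prev_patch[i] >= 0) demo.push_back(i);
    for (int i = 0; i < N; ++i) {
      if (!learner[i]) continue;
      bool social = false;
      if ((naive_alpha || !forced[i]) && !force_individual && alpha[i] > 0.0) {
        social = (alpha[i] >= 1.0) ? true : (unif_rand() < alpha[i]);
      }
      int m;
      int act; // 1 exploit, 2 individual learn, 3 social learn
      if (social && !demo.empty()) {
        m = prev_patch[demo[unif_index((int)demo.size())]];
        act = 3;
      } else {
        m = unif_index(M); // includes social learners with no demonstrators
        act = 2;
      }
      double ph = occ[m] > 0 ? payoffs[m] / occ[m] : payoffs[m];
      mem.set(i, m, ph);
      chosen[i] = m; // observed patch, for the logs
      learner[i] = (act == 3) ? 3 : 2;
    }

    // (5) histories and ages advance
    for (int i = 0; i < N; ++i) {
      hpos[i] = (hpos[i] + 1) % window;
      hist[(std::size_t)i * window + hpos[i]] = collected[i];
      ++age[i];
    }
    for (int i = 0; i < N; ++i)
      prev_patch[i] = (learner[i] == 0) ? chosen[i] : -1;

    // summaries over exploiters by strategy (social: alpha >= 0.5)
    {
      double sum_s = 0, ss_s = 0, sum_i = 0, ss_i = 0;
      int ns = 0, ni = 0, nl = 0;
      for (int i = 0; i < N; ++i) {
        if (learner[i] != 0) { ++nl; continue; }
        if (alpha[i] >= 0.5) {
          sum_s += collected[i]; ss_s += collected[i] * collected[i]; ++ns;
        } else {
          sum_i += collected[i]; ss_i += collected[i] * collected[i]; ++ni;
        }
      }
      rec_nexp_s.push_back(ns);
      rec_nexp_i.push_back(ni);
      rec_nlearn.push_back(nl);
      rec_mean_s.push_back(ns > 0 ? sum_s / ns : NA_REAL);
      rec_mean_i.push_back(ni > 0 ? sum_i / ni : NA_REAL);
      rec_var_s.push_back(ns > 1 ? (ss_s - sum_s * sum_s / ns) / (ns - 1)
                                 : NA_REAL);
      rec_var_i.push_back(ni > 1 ? (ss_i - sum_i * sum_i / ni) / (ni - 1)
                                 : NA_REAL);
      rec_total.push_back(tot_collected);
    }

    // snapshot of the round (overwritten until the last executed round)
    for (int i = 0; i < N; ++i) {
      fin_ident[i] = ident[i];
      fin_alpha[i] = alpha[i];
      fin_sex[i] = sex[i];
      fin_age[i] = age[i];
      fin_action[i] = learner[i] == 0 ? 1 : (learner[i] == 3 ? 3 : 2);
      fin_patch[i] = chosen[i];
      fin_collected[i] = collected[i];
    }
    if (log_individuals) {
      for (int i = 0; i < N; ++i) {
        log_round.push_back(t);
        log_ident.push_back(ident[i]);
        log_alpha.push_back(alpha[i]);
        log_sexv.push_back(sex[i]);
        log_action.push_back(fin_action[i]);
        log_patch.push_back(chosen[i] + 1);
        log_coll.push_back(collected[i]);
      }
    }

    // (6) turnover: payoffs redraw independently with probability tau
    if (turnover > 0.0)
      for (int m = 0; m < M; ++m)
        if (unif_rand() < turnover) payoffs[m] = R::rgamma(shape, scale);

    // (7) mortality and replacement
    int n_dead = 0;
    for (int i = 0; i < N; ++i) {
      dead[i] = (age[i] >= max_age) || (unif_rand() < death_prob);
      if (dead[i]) ++n_dead;
    }
    rec_deaths.push_back(n_dead);

    if (n_dead > 0) {
      if (mode == 0) {
        // fixed composition: dead replaced by naive copies of themselves
        for (int i = 0; i < N; ++i)
          if (dead[i]) {
            mem.clear(i);
            for (int j = 0; j < window; ++j)
              hist[(std::size_t)i * window + j] = 0.0;
            hpos[i] = 0;
            age[i] = 0;
            prev_patch[i] = -1;
            ident[i] = next_ident++;
          }
      } else {
        // selection: mature survivors ranked by the fitness proxy
        std::vector<int> cand_f, cand_m, cand_a;
        std::vector<double> fit_f, fit_m, fit_a;
        for (int i = 0; i < N; ++i) {
          if (dead[i] || age[i] < maturity) continue;
          double F;
          if (fitness_mode == 0) {
            F = 0.0;
            for (int j = 0; j < window; ++j)
              F += w[j] *
                   hist[(std::size_t)i * window + ((hpos[i] - j + window * 2) % window)];
          } else {
            F = hist[(std::size_t)i * window + hpos[i]];
          }
          if (mode == 2) {
            if (sex[i] == 0) { cand_f.push_back(i); fit_f.push_back(F); }
            else             { cand_m.push_back(i); fit_m.push_back(F); }
          } else {
            cand_a.push_back(i);
            fit_a.push_back(F);
          }
        }
        // fallback when no mature survivor exists: draw uniformly from all
        // survivors (flagged; unreachable under realistic configurations)
        std::vector<int> surv;
        auto fallback_pool = [&]() {
          ParentPool p;
          surv.clear();
          for (int i = 0; i < N; ++i)
            if (!dead[i]) surv.push_back(i);
          double tot = 0.0;
          for (std::size_t k = 0; k < surv.size(); ++k) {
            tot += 1.0;
            p.idx.push_back(surv[k]);
            p.cum.push_back(tot);
          }
          p.total = tot;
          return p;
        };

        if (mode == 1) {
          ParentPool pool = build_pool(cand_a, fit_a, beta, criterion);
          if (pool.empty()) { pool = fallback_pool(); ++n_pool_fallback; }
          for (int i = 0; i < N; ++i) {
            if (!dead[i]) continue;
            double a, s;
            if (!pool.empty()) {
              int p = pool.sample();
              a = alpha[p];
              s = sex[p];
            } else { // nobody left alive at all: naive copy
              a = alpha[i];
              s = sex[i];
            }
            if (binary && mutation_rate > 0.0 && unif_rand() < mutation_rate)
              a = 1.0 - a;
            alpha[i] = a;
            sex[i] = (int)s;
            mem.clear(i);
            for (int j = 0; j < window; ++j)
              hist[(std::size_t)i * window + j] = 0.0;
            hpos[i] = 0;
            age[i] = 0;
            prev_patch[i] = -1;
            ident[i] = next_ident++;
          }
        } else { // sexual
          ParentPool pf = build_pool(cand_f, fit_f, beta_f, criterion);
          ParentPool pm = build_pool(cand_m, fit_m, beta_m, criterion);
          bool fell = false;
          if (pf.empty()) { pf = fallback_pool(); fell = true; }
          if (pm.empty()) { pm = fallback_pool(); fell = true; }
          if (fell) ++n_pool_fallback;
          for (int i = 0; i < N; ++i) {
            if (!dead[i]) continue;
            int s = strict_sex_ratio ? sex[i] : (unif_rand() < 0.5 ? 0 : 1);
            double a;
            if (!pf.empty() && !pm.empty()) {
              int mother = pf.sample();
              int father = pm.sample();
              a = (s == 0) ? alpha[mother] : alpha[father];
            } else {
              a = alpha[i];
              s = sex[i];
            }
            if (binary && mutation_rate > 0.0 && unif_rand() < mutation_rate)
              a = 1.0 - a;
            alpha[i] = a;
            sex[i] = s;
            mem.clear(i);
            for (int j = 0; j < window; ++j)
              hist[(std::size_t)i * window + j] = 0.0;
            hpos[i] = 0;
            age[i] = 0;
            prev_patch[i] = -1;
            ident[i] = next_ident++;
          }
        }
      }
    }

    // composition entering the next round
    {
      double s_all = 0, s_f = 0, s_m = 0;
      int n_f = 0, n_m = 0;
      for (int i = 0; i < N; ++i) {
        s_all += alpha[i];
        if (sex[i] == 0) { s_f += alpha[i]; ++n_f; }
        else if (sex[i] == 1) { s_m += alpha[i]; ++n_m; }
      }
      rec_freq.push_back(s_all / N);
      rec_freq_f.push_back(n_f > 0 ? s_f / n_f : NA_REAL);
      rec_freq_m.push_back(n_m > 0 ? s_m / n_m : NA_REAL);
    }

    term_round = t;
    if (binary) { // fixation check, evolutionary modes only
      bool fixed = true;
      for (int i = 1; i < N; ++i)
        if (alpha[i] != alpha[0]) { fixed = false; break; }
      if (fixed) { term_cause = "fixation"; break; }
    }
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
  }

  const int T = term_round;
  IntegerVector rnd(T);
  for (int t = 0; t < T; ++t) rnd[t] = t + 1;
  DataFrame rounds = DataFrame::create(
      _["round"] = rnd,
      _["freq_social"] = NumericVector(rec_freq.begin(), rec_freq.end()),
      _["freq_social_f"] = NumericVector(rec_freq_f.begin(), rec_freq_f.end()),
      _["freq_social_m"] = NumericVector(rec_freq_m.begin(), rec_freq_m.end()),
      _["n_learners"] = IntegerVector(rec_nlearn.begin(), rec_nlearn.end()),
      _["n_exploit_social"] = IntegerVector(rec_nexp_s.begin(), rec_nexp_s.end()),
      _["n_exploit_individual"] = IntegerVector(rec_nexp_i.begin(), rec_nexp_i.end()),
      _["mean_collected_social"] = NumericVector(rec_mean_s.begin(), rec_mean_s.end()),
      _["mean_collected_individual"] = NumericVector(rec_mean_i.begin(), rec_mean_i.end()),
      _["var_collected_social"] = NumericVector(rec_var_s.begin(), rec_var_s.end()),
      _["var_collected_individual"] = NumericVector(rec_var_i.begin(), rec_var_i.end()),
      _["total_collected"] = NumericVector(rec_total.begin(), rec_total.end()),
      _["deaths"] = IntegerVector(rec_deaths.begin(), rec_deaths.end()));

  CharacterVector act_lab = CharacterVector::create(
      "exploit", "learn_individual", "learn_social");
  CharacterVector sex_lab = CharacterVector::create("female", "male", "none");
  CharacterVector fin_act(N), fin_sx(N);
  IntegerVector fin_p(N);
  for (int i = 0; i < N; ++i) {
    fin_act[i] = act_lab[fin_action[i] - 1];
    fin_sx[i] = sex_lab[fin_sex[i]];
    fin_p[i] = fin_patch[i] >= 0 ? fin_patch[i] + 1 : NA_INTEGER;
  }
  DataFrame final = DataFrame::create(
      _["ident"] = IntegerVector(fin_ident.begin(), fin_ident.end()),
      _["alpha"] = NumericVector(fin_alpha.begin(), fin_alpha.end()),
      _["sex"] = fin_sx,
      _["age"] = IntegerVector(fin_age.begin(), fin_age.end()),
      _["action"] = fin_act,
      _["patch"] = fin_p,
      _["collected"] = NumericVector(fin_collected.begin(), fin_collected.end()),
      _["stringsAsFactors"] = false);

  List out = List::create(
      _["rounds"] = rounds,
      _["final"] = final,
      _["termination_round"] = term_round,
      _["termination_cause"] = term_cause,
      _["max_conservation_error"] = max_cons_err,
      _["n_pool_fallback"] = n_pool_fallback);

  if (log_individuals) {
    int L = (int)log_round.size();
    CharacterVector la(L), ls(L);
    IntegerVector lp(L);
    for (int k = 0; k < L; ++k) {
      la[k] = act_lab[log_action[k] - 1];
      ls[k] = sex_lab[log_sexv[k]];
      lp[k] = log_patch[k] > 0 ? log_patch[k] : NA_INTEGER;
    }
    out["log"] = DataFrame::create(
        _["round"] = IntegerVector(log_round.begin(), log_round.end()),
        _["ident"] = IntegerVector(log_ident.begin(), log_ident.end()),
        _["alpha"] = NumericVector(log_alpha.begin(), log_alpha.end()),
        _["sex"] = ls,
        _["action"] = la,
        _["patch"] = lp,
        _["collected"] = NumericVector(log_coll.begin(), log_coll.end()),
        _["stringsAsFactors"] = false);
  }
  return out;
}
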