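#include <Rcpp.h>
using namespace Rcpp;

// Agent-based simulator of five linked biallelic loci (focal locus at index
// 2) plus one binary cultural trait per individual. Haploid individuals,
// biparental reproduction: two parents drawn with probability proportional
// to fitness (random union with replacement), offspring genome formed by
// independent crossovers in the four adjacent intervals, symmetric allele
// flips at rate mu at the non-focal loci, and the cultural trait assigned by
// the vertical-transmission rule evaluated on the offspring's focal-locus
// allele and the parents' traits.

static const int L = 5;
static const int FOCAL = 2;

// sweep_type: 0 = genetic (selection s on derived focal allele),
//             1 = cultural (selection s on trait C),
//             2 = none (neutral).
struct SimParams {
  int N;
  double mu;
  double radj[4];    // adjacent-interval recombination probabilities
  int variant;       // 0 affinity, 1 trait bias
  double p1, p2;     // beta1/beta2 or gamma1/gamma2
  int sweep_type;
  double s;
};

static inline int weighted_parent(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  // binary search for first cum[i] >= u
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

static void generation(const SimParams& P, bool selected,
                       std::vector<int>& gen, std::vector<int>& tr,
                       std::vector<int>& gen2, std::vector<int>& tr2) {
  const int N = P.N;
  std::vector<double> cum(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (selected) {
      if (P.sweep_type == 0 && gen[i * L + FOCAL] == 1) w = 1.0 + P.s;
      if (P.sweep_type == 1 && tr[i] == 1) w = 1.0 + P.s;
    }
    tot += w;
    cum[i] = tot;
  }
  for (int i = 0; i < N; ++i) {
    int a = weighted_parent(cum);
    int b = weighted_parent(cum);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    for (int l = 0; l < L; ++l) {
      if (l > 0 && unif_rand() < P.radj[l - 1]) cur ^= 1;
      int allele = (cur == 0) ? gen[a * L + l] : gen[b * L + l];
      if (l != FOCAL && P.mu > 0 && unif_rand() < P.mu) allele ^= 1;
      gen2[i * L + l] = allele;
    }
    int ta = tr[a], tb = tr[b], t;
    if (ta == tb) {
      t = ta;
    } else {
      int off = gen2[i * L + FOCAL];
      if (P.variant == 0) {
        int fa = gen[a * L + FOCAL], fb = gen[b * L + FOCAL];
        if (fa == fb) {
          // parents equally similar: copy a random parent
          t = (unif_rand() < 0.5) ? ta : tb;
        } else {
          double beta = (off == 1) ? P.p1 : P.p2;
          int simtrait = (fa == off) ? ta : tb;
          int othtrait = (fa == off) ? tb : ta;
          t = (unif_rand() < beta) ? othtrait : simtrait;
        }
      } else {
        double gma = (off == 1) ? P.p1 : P.p2;
        t = (unif_rand() < gma) ? 1 : 0;
      }
    }
    tr2[i] = t;
  }
}

static void het_of(const std::vector<int>& gen, int N, double het[L]) {
  for (int l = 0; l < L; ++l) {
    double p = 0.0;
    for (int i = 0; i < N; ++i) p += gen[i * L + l];
    p /= N;
    het[l] = 2.0 * p * (1.0 - p);
  }
}

static void hap_counts(const std::vector<int>& gen, int N, int hc[32]) {
  for (int h = 0; h < 32; ++h) hc[h] = 0;
  for (int i = 0; i < N; ++i) {
    int code = 0;
    for (int l = 0; l < L; ++l) code = (code << 1) | gen[i * L + l];
    hc[code] += 1;
  }
}

// Neutral burn-in from a monomorphic start; optionally records per-locus
// heterozygosity every record_every generations (0 = no recording).
// [[Rcpp::export]]
List cpp_burn_in(int N, double mu, NumericVector r_adj, int variant,
                 double p1, double p2, int generations, int record_every) {
  SimParams P;
  P.N = N; P.mu = mu;
  for (int k = 0; k < 4; ++k) P.radj[k] = r_adj[k];
  P.variant = variant; P.p1 = p1; P.p2 = p2;
  P.sweep_type = 2; P.s = 0.0;
  std::vector<int> gen(N * L, 0), tr(N, 0), gen2(N * L), tr2(N);
  int nrec = (record_every > 0) ? generations / record_every : 0;
  NumericMatrix het_series(nrec, L);
  double het[L];
  int rec = 0;
  for (int g = 0; g < generations; ++g) {
    generation(P, false, gen, tr, gen2, tr2);
    gen.swap(gen2); tr.swap(tr2);
    if (record_every > 0 && (g + 1) % record_every == 0 && rec < nrec) {
      het_of(gen, N, het);
      for (int l = 0; l < L; ++l) het_series(rec, l) = het[l];
      ++rec;
    }
  }
  IntegerMatrix genome(N, L);
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < L; ++l) genome(i, l) = gen[i * L + l];
  het_of(gen, N, het);
  NumericVector hfin(L);
  for (int l = 0; l < L; ++l) hfin[l] = het[l];
  return List::create(_["genome"] = genome, _["het"] = hfin,
                      _["het_series"] = het_series);
}

// Repeated sweep experiment. Burn in once (or per attempt when
// independent_burnins is true), then repeatedly introduce the favoured
// element and keep only attempts where it fixed, until min_sweeps successes
// (or max_attempts). Between attempts in shared mode, the neutral reservoir
// population drifts for perturb_gens generations.
// A genetic sweep introduces one copy of a beneficial allele at the focal
// locus. A cultural sweep introduces, in one random individual, the
// favoured trait C together with a single new neutral marker allele at the
// focal locus: the trait arises once on a unique genetic background
// (x0 = Q0-convention of the single-locus model) and stays associated with
// that background only through the transmission rule.
// [[Rcpp::export]]
List cpp_chromosome_experiment(int N, double mu, NumericVector r_adj,
                               int variant, double p1, double p2,
                               int sweep_type, double s, int burn_in,
                               int min_sweeps, int perturb_gens,
                               bool independent_burnins,
                               int max_gen, int max_attempts) {
  SimParams P;
  P.N = N; P.mu = mu;
  for (int k = 0; k < 4; ++k) P.radj[k] = r_adj[k];
  P.variant = variant; P.p1 = p1; P.p2 = p2;
  P.sweep_type = sweep_type; P.s = s;

  std::vector<int> res_gen(N * L, 0), res_tr(N, 0);
  std::vector<int> gen(N * L), tr(N), gen2(N * L), tr2(N);
  SimParams Pn = P; Pn.sweep_type = 2;  // neutral dynamics for burn-in/drift

  if (!independent_burnins) {
    for (int g = 0; g < burn_in; ++g) {
      generation(Pn, false, res_gen, res_tr, gen2, tr2);
      res_gen.swap(gen2); res_tr.swap(tr2);
    }
  }

  NumericMatrix het_out(min_sweeps, L);
  IntegerMatrix hap_out(min_sweeps, 32);
  IntegerVector duration(min_sweeps);
  int successes = 0, attempts = 0;
  double het[L];
  int hc[32];

  while (successes < min_sweeps && attempts < max_attempts) {
    ++attempts;
    if (independent_burnins) {
      std::fill(res_gen.begin(), res_gen.end(), 0);
      std::fill(res_tr.begin(), res_tr.end(), 0);
      for (int g = 0; g < burn_in; ++g) {
        generation(Pn, false, res_gen, res_tr, gen2, tr2);
        res_gen.swap(gen2); res_tr.swap(tr2);
      }
    } else {
      for (int g = 0; g < perturb_gens; ++g) {
        generation(Pn, false, res_gen, res_tr, gen2, tr2);
        res_gen.swap(gen2); res_tr.swap(tr2);
      }
    }
    gen = res_gen; tr = res_tr;

    if (sweep_type == 2) {
      // neutral condition: record the standing variation directly
      het_of(gen, N, het);
      hap_counts(gen, N, hc);
      for (int l = 0; l < L; ++l) het_out(successes, l) = het[l];
      for (int h = 0; h < 32; ++h) hap_out(successes, h) = hc[h];
      duration[successes] = 0;
      ++successes;
      continue;
    }

    int who = (int)std::floor(unif_rand() * N);
    gen[who * L + FOCAL] = 1;
    if (sweep_type == 1) tr[who] = 1;

    int g = 0, fixed = -1;
    while (g < max_gen) {
      int count = 0;
      if (sweep_type == 0)
        for (int i = 0; i < N; ++i) count += gen[i * L + FOCAL];
      else
        for (int i = 0; i < N; ++i) count += tr[i];
      if (count == 0) { fixed = 0; break; }
      if (count == N) { fixed = 1; break; }
      generation(P, true, gen, tr, gen2, tr2);
      gen.swap(gen2); tr.swap(tr2);
      ++g;
    }
    if (fixed == 1) {
      het_of(gen, N, het);
      hap_counts(gen, N, hc);
      for (int l = 0; l < L; ++l) het_out(successes, l) = het[l];
      for (int h = 0; h < 32; ++h) hap_out(successes, h) = hc[h];
      duration[successes] = g;
      ++successes;
    }
  }

  return List::create(_["het"] = het_out, _["hap"] = hap_out,
                      _["duration"] = duration,
                      _["successes"] = successes, _["attempts"] = attempts);
}
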