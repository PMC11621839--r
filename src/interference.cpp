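#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// Phenogenotype order throughout: 0 = AC, 1 = aC, 2 = Ac, 3 = ac.
// Mating classes follow the canonical order of the R engine.
static const int PI_[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int PJ_[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

// Fill the 10 x 4 offspring matrix. variant: 0 = affinity (p1 = beta1,
// p2 = beta2), 1 = cultural trait bias (p1 = gamma1, p2 = gamma2).
static void offspring_matrix(int variant, double p1, double p2,
                             double O[10][4]) {
  for (int m = 0; m < 10; ++m)
    for (int k = 0; k < 4; ++k) O[m][k] = 0.0;
  O[0][0] = 1.0;                       // AC x AC
  O[1][0] = 0.5; O[1][1] = 0.5;        // AC x aC
  O[4][1] = 1.0;                       // aC x aC
  O[6][1] = 0.0;                       // aC x ac (set below)
  O[7][2] = 1.0;                       // Ac x Ac
  O[8][2] = 0.5; O[8][3] = 0.5;        // Ac x ac
  O[9][3] = 1.0;                       // ac x ac
  if (variant == 0) {
    double b1 = p1, b2 = p2;
    O[2][0] = 0.5; O[2][2] = 0.5;                                  // AC x Ac
    O[3][0] = (1 - b1) / 2; O[3][1] = b2 / 2;                      // AC x ac
    O[3][2] = b1 / 2;       O[3][3] = (1 - b2) / 2;
    O[5][0] = b1 / 2;       O[5][1] = (1 - b2) / 2;                // aC x Ac
    O[5][2] = (1 - b1) / 2; O[5][3] = b2 / 2;
    O[6][1] = 0.5; O[6][3] = 0.5;                                  // aC x ac
  } else {
    double g1 = p1, g2 = p2;
    O[2][0] = g1; O[2][2] = 1 - g1;                                // AC x Ac
    O[3][0] = g1 / 2; O[3][1] = g2 / 2;                            // AC x ac
    O[3][2] = (1 - g1) / 2; O[3][3] = (1 - g2) / 2;
    O[5][0] = g1 / 2; O[5][1] = g2 / 2;                            // aC x Ac
    O[5][2] = (1 - g1) / 2; O[5][3] = (1 - g2) / 2;
    O[6][1] = g2; O[6][3] = 1 - g2;                                // aC x ac
  }
}

// Exact expected next-generation phenogenotype frequencies (the
// transmission-table engine), mirroring next_generation_exact() in R.
static void next_gen_expected(const double f[4], double sA, double sC,
                              const double O[10][4], double out[4]) {
  double W[4] = {(1 + sC) * (1 + sA), 1 + sC, 1 + sA, 1.0};
  double g[4], wbar = 0.0;
  for (int k = 0; k < 4; ++k) { g[k] = f[k] * W[k]; wbar += g[k]; }
  double acc[4] = {0, 0, 0, 0};
  for (int m = 0; m < 10; ++m) {
    double mf = g[PI_[m]] * g[PJ_[m]];
    if (PI_[m] != PJ_[m]) mf *= 2.0;
    for (int k = 0; k < 4; ++k) acc[k] += mf * O[m][k];
  }
  double s2 = wbar * wbar;
  for (int k = 0; k < 4; ++k) out[k] = acc[k] / s2;
}

// [[Rcpp::export]]
NumericVector cpp_next_gen_expected(NumericVector f, double sA, double sC,
                                    int variant, double p1, double p2) {
  double O[10][4];
  offspring_matrix(variant, p1, p2, O);
  double fin[4] = {f[0], f[1], f[2], f[3]};
  double out[4];
  next_gen_expected(fin, sA, sC, O, out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// Wright-Fisher replicates of a single new A copy invading a population of
// size N with a segregating cultural trait. Returns the fate of allele A per
// replicate. init_background: -1 = mutant starts on C with probability x0,
// 0 = forced c, 1 = forced C. Resident cultural backgrounds are set
// deterministically to round(x0 * (N - 1)) copies of C.
// outcome codes: 1 = A fixed, 0 = A lost, -1 = still segregating at max_gen.
// [[Rcpp::export]]
List cpp_interference_replicates(int N, double sA, double sC, int variant,
                                 double p1, double p2, double x0,
                                 int replicates, int max_gen,
                                 int init_background) {
  double O[10][4];
  offspring_matrix(variant, p1, p2, O);
  IntegerVector outcome(replicates), t_fix(replicates), origin(replicates);
  int nC_res = (int)std::floor(x0 * (N - 1) + 0.5);
  double f[4], ef[4];
  std::vector<int> cnt(4);
  for (int rep = 0; rep < replicates; ++rep) {
    int onC;
    if (init_background < 0) onC = (unif_rand() < x0) ? 1 : 0;
    else onC = init_background;
    // counts (AC, aC, Ac, ac)
    cnt[0] = onC;            // mutant on C background
    cnt[1] = nC_res;
    cnt[2] = 1 - onC;        // mutant on c background
    cnt[3] = (N - 1) - nC_res;
    origin[rep] = onC;
    int gen = 0, res = -1;
    while (gen < max_gen) {
      int nA = cnt[0] + cnt[2];
      if (nA == 0) { res = 0; break; }
      if (nA == N) { res = 1; break; }
      for (int k = 0; k < 4; ++k) f[k] = (double)cnt[k] / N;
      next_gen_expected(f, sA, sC, O, ef);
      int draw[4];
      rmultinom(N, ef, 4, draw);
      for (int k = 0; k < 4; ++k) cnt[k] = draw[k];
      ++gen;
    }
    outcome[rep] = res;
    t_fix[rep] = gen;
  }
  return List::create(_["outcome"] = outcome, _["t_fix"] = t_fix,
                      _["origin"] = origin);
}
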