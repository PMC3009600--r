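// Wright-Fisher forward core: binary {A,G} genomes, fitness by G-count,
// multinomial resampling, per-site mutation, reference-genome substitution
// counting. Uses R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
List wf_core(int N, int L, double mu_to_AT, double mu_to_GC,
             NumericVector fitness_table, int generations, int burn_in,
             double fix_thr, int thin, int init_n) {
  // identical starting sequences with init_n G's; reference genome matches
  std::vector<unsigned char> pop((size_t)N * L, 0), newpop((size_t)N * L);
  std::vector<int> gcount(N, init_n), newgcount(N);
  std::vector<unsigned char> ref(L, 0);
  for (int l = 0; l < init_n && l < L; ++l) ref[l] = 1;
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < init_n && l < L; ++l) pop[(size_t)i * L + l] = 1;
  std::vector<double> cumw(N);
  std::vector<int> colG(L);

  long double N_A = 0.0L, N_G = 0.0L;
  double N_A_to_G = 0.0, N_G_to_A = 0.0;

  int n_rec = generations / thin + 1;
  NumericVector traj(n_rec);
  int rec = 0;

  for (int gen = 0; gen < generations; ++gen) {
    // --- resample proportional to fitness ---
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      tot += fitness_table[gcount[i]];
      cumw[i] = tot;
    }
    for (int i = 0; i < N; ++i) {
      double u = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumw[mid] < u) lo = mid + 1; else hi = mid;
      }
      std::memcpy(&newpop[(size_t)i * L], &pop[(size_t)lo * L], L);
      newgcount[i] = gcount[lo];
    }
    pop.swap(newpop);
    gcount.swap(newgcount);

    // --- mutation ---
    long long nG = 0;
    for (int i = 0; i < N; ++i) nG += gcount[i];
    long long nA = (long long)N * L - nG;
    int kGA = (nG > 0) ? (int)R::rbinom((double)nG, mu_to_AT) : 0;
    int kAG = (nA > 0) ? (int)R::rbinom((double)nA, mu_to_GC) : 0;
    for (int m = 0; m < kGA; ++m) {   // G -> A flips at random G sites
      for (int tries = 0; tries < 10000; ++tries) {
        int i = (int)(unif_rand() * N);
        int l = (int)(unif_rand() * L);
        size_t idx = (size_t)i * L + l;
        if (pop[idx] == 1) { pop[idx] = 0; --gcount[i]; break; }
      }
    }
    for (int m = 0; m < kAG; ++m) {   // A -> G flips at random A sites
      for (int tries = 0; tries < 10000; ++tries) {
        int i = (int)(unif_rand() * N);
        int l = (int)(unif_rand() * L);
        size_t idx = (size_t)i * L + l;
        if (pop[idx] == 0) { pop[idx] = 1; ++gcount[i]; break; }
      }
    }

    // --- exposure counters (after burn-in) ---
    bool counting = gen >= burn_in;
    if (counting) {
      long long g2 = 0;
      for (int i = 0; i < N; ++i) g2 += gcount[i];
      N_G += (long double)g2;
      N_A += (long double)((long long)N * L - g2);
    }

    // --- reference-genome update / substitution counting ---
    std::fill(colG.begin(), colG.end(), 0);
    for (int i = 0; i < N; ++i) {
      const unsigned char* row = &pop[(size_t)i * L];
      for (int l = 0; l < L; ++l) colG[l] += row[l];
    }
    for (int l = 0; l < L; ++l) {
      double fG = (double)colG[l] / N;
      if (fG > fix_thr && ref[l] == 0) {
        ref[l] = 1;
        if (counting) N_A_to_G += 1.0;
      } else if ((1.0 - fG) > fix_thr && ref[l] == 1) {
        ref[l] = 0;
        if (counting) N_G_to_A += 1.0;
      }
    }

    if (gen % thin == 0 && rec < n_rec) {
      long long g3 = 0;
      for (int i = 0; i < N; ++i) g3 += gcount[i];
      traj[rec++] = (double)g3 / ((double)N * L);
    }
    if (gen % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["N_A"] = (double)N_A, _["N_G"] = (double)N_G,
    _["N_A_to_G"] = N_A_to_G, _["N_G_to_A"] = N_G_to_A,
    _["trajectory"] = traj[Range(0, std::max(0, rec - 1))]);
}
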