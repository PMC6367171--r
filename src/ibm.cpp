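// Individual-based simulator of the tribe-splitting sleep model.
//
// Life cycle per generation (identical to the analytic kernel):
//   1. night phase: patch brood survives with probability S = 1 - a(1 - V)
//      (Bernoulli; selective mode only)
//   2. reproduction: female i bears Poisson(brood_mean * fec_i * Phi_m)
//      offspring, fathers drawn per contest-weight x viability shares
//   3. inheritance: Mendelian, per-component mutation (Gaussian step,
//      clipped to [m, 1])
//   4. dispersal: per-offspring sex-specific Bernoulli(d_x); with
//      probability d_B a patch's dispersers leave together as a bud that
//      takes over the entire immigration of one destination patch
//      (derangement routing via a random cyclic shift); otherwise they
//      scatter among the patches not fed by a bud
//   5. regulation: n_f / n_m adults sampled uniformly from each patch's
//      candidates; patches short of candidates refill from the global
//      juvenile pool
//
// The neutral mode replaces steps 1-3 by fixed-size broods with iid
// uniform parent draws and unique founder allele labels; it estimates the
// stationary identity-by-descent probabilities the analytic recursion
// predicts.
//
// All randomness comes from one xoshiro256++ stream seeded via splitmix64,
// so runs are bit-identical for a given seed on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline bool bern(double p) { return runif() < p; }
  // unbiased bounded integer in [0, n)
  inline uint32_t below(uint32_t n) {
    uint64_t m = (uint64_t)(uint32_t)next() * n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (0u - n) % n;
      while (l < t) {
        m = (uint64_t)(uint32_t)next() * n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }
  int rpois(double lambda) {  // Knuth; lambda is always modest (< ~30)
    double L = std::exp(-lambda);
    int k = 0;
    double p = 1.0;
    do { ++k; p *= runif(); } while (p > L);
    return k - 1;
  }
  bool have_spare; double spare;
  double rnorm() {  // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, ss;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      ss = u * u + v * v;
    } while (ss >= 1.0 || ss == 0.0);
    double f = std::sqrt(-2.0 * std::log(ss) / ss);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// ------------------------------------------------------------- helpers ----
struct Params {
  double d_f, d_m, d_B, m, b_f, b_m, a, c_f, c_m;
  int n_f, n_m;
};

static Params read_params(const List& p) {
  Params q;
  q.d_f = as<double>(p["d_f"]); q.d_m = as<double>(p["d_m"]);
  q.d_B = as<double>(p["d_B"]); q.m = as<double>(p["m"]);
  q.b_f = as<double>(p["b_f"]); q.b_m = as<double>(p["b_m"]);
  q.a = as<double>(p["a"]); q.c_f = as<double>(p["c_f"]);
  q.c_m = as<double>(p["c_m"]);
  q.n_f = as<int>(p["n_f"]); q.n_m = as<int>(p["n_m"]);
  return q;
}

enum Mode { MONO = 0, SEXSP = 1, PO_UNIMPRINTED = 2, PO_MAT = 3, PO_PAT = 4 };

// components per allele: monomorphic 1; sex-specific and parent-of-origin 2
static int n_comp(int mode) { return mode == MONO ? 1 : 2; }

// expressed phenotype of an adult given its two alleles (mat slot, pat slot)
static inline double phenotype(int mode, bool female, const double* mat,
                               const double* pat) {
  switch (mode) {
    case MONO:  return 0.5 * (mat[0] + pat[0]);
    case SEXSP: return female ? 0.5 * (mat[0] + pat[0])
                              : 0.5 * (mat[1] + pat[1]);
    case PO_UNIMPRINTED: return 0.5 * (mat[0] + pat[1]);
    case PO_MAT: return mat[0];
    default:     return pat[1];  // PO_PAT
  }
}

// -------------------------------------------------------- selective IBM ----
// Adults stored as flat arrays: patch-major, individual, slot (mat=0,
// pat=1), component.

// [[Rcpp::export]]
List ibm_run_cpp(List params_, int n_patches, int generations,
                 double mutation_rate, double mutation_sd,
                 int mode_, NumericVector init_values,
                 double brood_mean, int record_every, double seed_) {
  const Params P = read_params(params_);
  const int K = n_comp(mode_);
  const int NF = P.n_f, NM = P.n_m, N = n_patches;
  const int strideF = NF * 2 * K, strideM = NM * 2 * K;
  Rng rng((uint64_t)seed_);

  // effective viability/contest coefficient handling: b = 0 means no
  // viability differences
  const bool via_f = P.b_f > 0, via_m = P.b_m > 0;

  std::vector<double> fem(N * strideF), mal(N * strideM);
  // initial monomorphic population at init_values (one value per component)
  for (int p = 0; p < N; ++p) {
    for (int i = 0; i < NF * 2; ++i)
      for (int k = 0; k < K; ++k)
        fem[p * strideF + i * K + k] = init_values[k];
    for (int i = 0; i < NM * 2; ++i)
      for (int k = 0; k < K; ++k)
        mal[p * strideM + i * K + k] = init_values[k];
  }

  // juvenile buffers per destination patch and sex
  std::vector<std::vector<double>> juvF(N), juvM(N);
  const int JS = 2 * K;  // doubles per juvenile
  for (int p = 0; p < N; ++p) { juvF[p].reserve(64 * JS); juvM[p].reserve(64 * JS); }
  std::vector<double> scatterF, scatterM;          // juvenile genomes
  std::vector<int> scatterF_home, scatterM_home;   // natal patches
  std::vector<int> scatter_dest;                   // patches fed by scatter
  std::vector<uint8_t> bud_fed(N);

  std::vector<double> zf(NF), zm(NM), fec(NF), cwM(NM);

  const int n_rec = generations / record_every;
  // records: per-class mean allelic values (K columns for slot-relevant
  // class means), mean phenotype f, mean phenotype m
  NumericMatrix traj(n_rec, K + 2);
  int rec = 0;

  auto mutate = [&](double* g) {
    for (int k = 0; k < K; ++k) {
      if (rng.bern(mutation_rate)) {
        double v = g[k] + mutation_sd * rng.rnorm();
        // reflect into [m, 1]
        for (int it = 0; it < 8 && (v < P.m || v > 1.0); ++it) {
          if (v < P.m) v = 2 * P.m - v;
          if (v > 1.0) v = 2.0 - v;
        }
        if (v < P.m) v = P.m;
        if (v > 1.0) v = 1.0;
        g[k] = v;
      }
    }
  };

  for (int gen = 0; gen < generations; ++gen) {
    for (int p = 0; p < N; ++p) { juvF[p].clear(); juvM[p].clear(); }
    scatterF.clear(); scatterM.clear();
    scatterF_home.clear(); scatterM_home.clear();
    scatter_dest.clear();
    std::fill(bud_fed.begin(), bud_fed.end(), 0);

    // dispersal routing for this generation
    int shift = 1 + (int)rng.below((uint32_t)(N - 1));  // cyclic derangement
    std::vector<uint8_t> bud_mode(N);
    for (int p = 0; p < N; ++p) bud_mode[p] = rng.bern(P.d_B) ? 1 : 0;
    for (int p = 0; p < N; ++p) {
      int dest = p + shift; if (dest >= N) dest -= N;
      if (bud_mode[p]) bud_fed[dest] = 1;
    }
    for (int p = 0; p < N; ++p) {
      int dest = p + shift; if (dest >= N) dest -= N;
      if (!bud_mode[p]) scatter_dest.push_back(dest);
    }

    // reproduction
    for (int p = 0; p < N; ++p) {
      double wake = 0.0;
      for (int i = 0; i < NF; ++i) {
        const double* a0 = &fem[p * strideF + (i * 2) * K];
        zf[i] = phenotype(mode_, true, a0, a0 + K);
        wake += 1.0 - zf[i];
      }
      for (int j = 0; j < NM; ++j) {
        const double* a0 = &mal[p * strideM + (j * 2) * K];
        zm[j] = phenotype(mode_, false, a0, a0 + K);
        wake += 1.0 - zm[j];
      }
      double V = wake / (NF + NM);
      double S = 1.0 - P.a * (1.0 - V);
      if (S <= 0.0 || !rng.bern(S)) continue;  // brood destroyed

      // female fecundities and male cumulative weights
      double sum_wf = 0.0;
      for (int i = 0; i < NF; ++i) sum_wf += 1.0 - P.c_f * zf[i];
      if (sum_wf <= 0.0) sum_wf = -1.0;  // flag: uniform shares
      double sum_wm = 0.0, phi_m = 0.0, cum = 0.0;
      for (int j = 0; j < NM; ++j) sum_wm += 1.0 - P.c_m * zm[j];
      bool uni_m = sum_wm <= 0.0;
      for (int j = 0; j < NM; ++j) {
        double w = uni_m ? 1.0 : 1.0 - P.c_m * zm[j];
        double v = via_m ? P.b_m * zm[j] : 1.0;
        phi_m += w * v;
        cum += w * v;
        cwM[j] = cum;
      }
      phi_m /= (uni_m ? NM : sum_wm);
      if (cum <= 0.0) continue;  // no viable fathers (all z = 0)
      double inv_cum = 1.0 / cum;

      int dest_bud = p + shift; if (dest_bud >= N) dest_bud -= N;
      bool buds = bud_mode[p] != 0;

      for (int i = 0; i < NF; ++i) {
        double wf = sum_wf < 0 ? 1.0 : 1.0 - P.c_f * zf[i];
        double share = sum_wf < 0 ? (1.0 / NF) : wf / sum_wf;
        double fec_i = (via_f ? P.b_f * zf[i] : 1.0) * NF * share;
        double lambda = brood_mean * fec_i * phi_m;
        if (lambda <= 0.0) continue;
        int kids = rng.rpois(lambda);
        const double* mom = &fem[p * strideF + (i * 2) * K];
        for (int c = 0; c < kids; ++c) {
          // father: cumulative search (n_m is small)
          double u = rng.runif() / inv_cum;
          int j = 0;
          while (cwM[j] < u && j < NM - 1) ++j;
          const double* dad = &mal[p * strideM + (j * 2) * K];
          double child[8];  // 2K <= 4 used
          const double* mg = mom + (rng.bern(0.5) ? K : 0);
          const double* pg = dad + (rng.bern(0.5) ? K : 0);
          for (int k = 0; k < K; ++k) { child[k] = mg[k]; child[K + k] = pg[k]; }
          mutate(child);
          mutate(child + K);
          bool female = rng.bern(0.5);
          double d_x = female ? P.d_f : P.d_m;
          bool leave = d_x > 0.0 && rng.bern(d_x);
          if (!leave) {
            auto& buf = female ? juvF[p] : juvM[p];
            buf.insert(buf.end(), child, child + JS);
          } else if (buds) {
            auto& buf = female ? juvF[dest_bud] : juvM[dest_bud];
            buf.insert(buf.end(), child, child + JS);
          } else {
            if (female) {
              scatterF.insert(scatterF.end(), child, child + JS);
              scatterF_home.push_back(p);
            } else {
              scatterM.insert(scatterM.end(), child, child + JS);
              scatterM_home.push_back(p);
            }
          }
        }
      }
    }

    // distribute scattered dispersers among scatter-fed patches
    const int n_sd = (int)scatter_dest.size();
    auto place_scatter = [&](std::vector<double>& pool,
                             std::vector<int>& home,
                             std::vector<std::vector<double>>& juv) {
      int n = (int)home.size();
      for (int i = 0; i < n; ++i) {
        int dest = -1;
        if (n_sd > 0) {
          for (int t = 0; t < 8; ++t) {
            dest = scatter_dest[rng.below((uint32_t)n_sd)];
            if (dest != home[i]) break;
          }
        } else {
          dest = (int)rng.below((uint32_t)N);  // no scatter-fed patch: anywhere
        }
        juv[dest].insert(juv[dest].end(), pool.begin() + (size_t)i * JS,
                         pool.begin() + (size_t)(i + 1) * JS);
      }
    };
    place_scatter(scatterF, scatterF_home, juvF);
    place_scatter(scatterM, scatterM_home, juvM);

    // global refill pools (flat index over all juveniles of a sex)
    std::vector<std::pair<int, int>> poolF, poolM;
    for (int p = 0; p < N; ++p) {
      int nf = (int)juvF[p].size() / JS, nm = (int)juvM[p].size() / JS;
      for (int i = 0; i < nf; ++i) poolF.push_back({p, i});
      for (int i = 0; i < nm; ++i) poolM.push_back({p, i});
    }
    if (poolF.empty() || poolM.empty()) {
      stop("population extinct at generation %d (no juveniles of one sex)",
           gen);
    }

    // regulation: sample adults for every patch
    auto regulate = [&](int p, std::vector<std::vector<double>>& juv,
                        std::vector<std::pair<int, int>>& pool,
                        std::vector<double>& adults, int n_x, int stride) {
      std::vector<double>& cand = juv[p];
      int nc = (int)cand.size() / JS;
      double* A = &adults[(size_t)p * stride];
      if (nc >= n_x) {
        // partial Fisher-Yates over candidate indices
        for (int i = 0; i < n_x; ++i) {
          int j = i + (int)rng.below((uint32_t)(nc - i));
          for (int t = 0; t < JS; ++t)
            std::swap(cand[(size_t)i * JS + t], cand[(size_t)j * JS + t]);
          for (int t = 0; t < JS; ++t)
            A[i * JS + t] = cand[(size_t)i * JS + t];
        }
      } else {
        for (int i = 0; i < nc; ++i)
          for (int t = 0; t < JS; ++t)
            A[i * JS + t] = cand[(size_t)i * JS + t];
        for (int i = nc; i < n_x; ++i) {
          auto pick = pool[rng.below((uint32_t)pool.size())];
          const double* src = &juv[pick.first][(size_t)pick.second * JS];
          for (int t = 0; t < JS; ++t) A[i * JS + t] = src[t];
        }
      }
    };
    // adults are overwritten in place: juveniles were already copied out
    std::vector<double> newF(N * strideF), newM(N * strideM);
    for (int p = 0; p < N; ++p) {
      regulate(p, juvF, poolF, newF, NF, strideF);
      regulate(p, juvM, poolM, newM, NM, strideM);
    }
    fem.swap(newF); mal.swap(newM);

    if ((gen + 1) % record_every == 0) {
      // class means: component k averaged over the slot where it is
      // expressed (mat slot for component 0 in PO modes, pat slot for
      // component 1); for MONO/SEXSP average both slots
      double cm[2] = {0.0, 0.0};
      double phf = 0.0, phm = 0.0;
      long ncf = (long)N * NF, ncm = (long)N * NM;
      for (int p = 0; p < N; ++p) {
        for (int i = 0; i < NF; ++i) {
          const double* a0 = &fem[p * strideF + (i * 2) * K];
          phf += phenotype(mode_, true, a0, a0 + K);
          if (mode_ >= PO_UNIMPRINTED) {
            cm[0] += a0[0]; cm[1] += a0[K + 1];
          } else {
            for (int k = 0; k < K; ++k) cm[k] += 0.5 * (a0[k] + a0[K + k]);
          }
        }
        for (int j = 0; j < NM; ++j) {
          const double* a0 = &mal[p * strideM + (j * 2) * K];
          phm += phenotype(mode_, false, a0, a0 + K);
          if (mode_ >= PO_UNIMPRINTED) {
            cm[0] += a0[0]; cm[1] += a0[K + 1];
          } else {
            for (int k = 0; k < K; ++k) cm[k] += 0.5 * (a0[k] + a0[K + k]);
          }
        }
      }
      long ntot = ncf + ncm;
      for (int k = 0; k < K; ++k) traj(rec, k) = cm[k] / ntot;
      traj(rec, K) = phf / ncf;
      traj(rec, K + 1) = phm / ncm;
      ++rec;
    }
  }

  return List::create(_["trajectory"] = traj);
}

// ---------------------------------------------------------- neutral IBM ----
// Allele labels, unique at founding; estimates stationary IBD within
// patches (by pair sex and by slot combination) and the between-patch
// background.

// [[Rcpp::export]]
List ibm_neutral_cpp(List params_, int n_patches, int generations,
                     int burn_in, int sample_every, int brood_per_sex,
                     double seed_) {
  const Params P = read_params(params_);
  const int NF = P.n_f, NM = P.n_m, N = n_patches;
  const int strideF = NF * 2, strideM = NM * 2;
  Rng rng((uint64_t)seed_);

  std::vector<int64_t> fem(N * strideF), mal(N * strideM);
  int64_t next_label = 0;
  for (auto& x : fem) x = next_label++;
  for (auto& x : mal) x = next_label++;

  std::vector<std::vector<int64_t>> juvF(N), juvM(N);
  std::vector<int64_t> scatterF, scatterM;
  std::vector<int> scatterF_home, scatterM_home;
  std::vector<int> scatter_dest;
  std::vector<uint8_t> bud_fed(N), bud_mode(N);

  // accumulators per sample generation: 12 slot categories + F + between
  // category order: ff(mm,mp,pm,pp), mm(...), fm(...)
  std::vector<std::array<double, 14>> samples;

  for (int gen = 0; gen < generations; ++gen) {
    for (int p = 0; p < N; ++p) { juvF[p].clear(); juvM[p].clear(); }
    scatterF.clear(); scatterM.clear();
    scatterF_home.clear(); scatterM_home.clear();
    scatter_dest.clear();
    std::fill(bud_fed.begin(), bud_fed.end(), 0);

    int shift = 1 + (int)rng.below((uint32_t)(N - 1));
    for (int p = 0; p < N; ++p) bud_mode[p] = rng.bern(P.d_B) ? 1 : 0;
    for (int p = 0; p < N; ++p) {
      int dest = p + shift; if (dest >= N) dest -= N;
      if (bud_mode[p]) bud_fed[dest] = 1;
      else scatter_dest.push_back(dest);
    }

    for (int p = 0; p < N; ++p) {
      int dest_bud = p + shift; if (dest_bud >= N) dest_bud -= N;
      bool buds = bud_mode[p] != 0;
      for (int sex = 0; sex < 2; ++sex) {
        bool female = sex == 0;
        for (int c = 0; c < brood_per_sex; ++c) {
          int i = (int)rng.below((uint32_t)NF);
          int j = (int)rng.below((uint32_t)NM);
          int64_t mg = fem[p * strideF + i * 2 + (rng.bern(0.5) ? 1 : 0)];
          int64_t pg = mal[p * strideM + j * 2 + (rng.bern(0.5) ? 1 : 0)];
          double d_x = female ? P.d_f : P.d_m;
          bool leave = d_x > 0.0 && rng.bern(d_x);
          if (!leave) {
            auto& buf = female ? juvF[p] : juvM[p];
            buf.push_back(mg); buf.push_back(pg);
          } else if (buds) {
            auto& buf = female ? juvF[dest_bud] : juvM[dest_bud];
            buf.push_back(mg); buf.push_back(pg);
          } else if (female) {
            scatterF.push_back(mg); scatterF.push_back(pg);
            scatterF_home.push_back(p);
          } else {
            scatterM.push_back(mg); scatterM.push_back(pg);
            scatterM_home.push_back(p);
          }
        }
      }
    }

    const int n_sd = (int)scatter_dest.size();
    auto place_scatter = [&](std::vector<int64_t>& pool,
                             std::vector<int>& home,
                             std::vector<std::vector<int64_t>>& juv) {
      int n = (int)home.size();
      for (int i = 0; i < n; ++i) {
        int dest = -1;
        if (n_sd > 0) {
          for (int t = 0; t < 8; ++t) {
            dest = scatter_dest[rng.below((uint32_t)n_sd)];
            if (dest != home[i]) break;
          }
        } else {
          dest = (int)rng.below((uint32_t)N);
        }
        juv[dest].push_back(pool[2 * i]);
        juv[dest].push_back(pool[2 * i + 1]);
      }
    };
    place_scatter(scatterF, scatterF_home, juvF);
    place_scatter(scatterM, scatterM_home, juvM);

    std::vector<std::pair<int, int>> poolF, poolM;
    for (int p = 0; p < N; ++p) {
      for (int i = 0; i < (int)juvF[p].size() / 2; ++i) poolF.push_back({p, i});
      for (int i = 0; i < (int)juvM[p].size() / 2; ++i) poolM.push_back({p, i});
    }
    if (poolF.empty() || poolM.empty()) stop("neutral population extinct");

    auto regulate = [&](int p, std::vector<std::vector<int64_t>>& juv,
                        std::vector<std::pair<int, int>>& pool,
                        std::vector<int64_t>& adults, int n_x, int stride) {
      std::vector<int64_t>& cand = juv[p];
      int nc = (int)cand.size() / 2;
      int64_t* A = &adults[(size_t)p * stride];
      if (nc >= n_x) {
        for (int i = 0; i < n_x; ++i) {
          int j = i + (int)rng.below((uint32_t)(nc - i));
          std::swap(cand[2 * i], cand[2 * j]);
          std::swap(cand[2 * i + 1], cand[2 * j + 1]);
          A[i * 2] = cand[2 * i]; A[i * 2 + 1] = cand[2 * i + 1];
        }
      } else {
        for (int i = 0; i < nc; ++i) {
          A[i * 2] = cand[2 * i]; A[i * 2 + 1] = cand[2 * i + 1];
        }
        for (int i = nc; i < n_x; ++i) {
          auto pick = pool[rng.below((uint32_t)pool.size())];
          A[i * 2] = juv[pick.first][2 * pick.second];
          A[i * 2 + 1] = juv[pick.first][2 * pick.second + 1];
        }
      }
    };
    std::vector<int64_t> newF(N * strideF), newM(N * strideM);
    for (int p = 0; p < N; ++p) {
      regulate(p, juvF, poolF, newF, NF, strideF);
      regulate(p, juvM, poolM, newM, NM, strideM);
    }
    fem.swap(newF); mal.swap(newM);

    // sample IBD
    if (gen >= burn_in && (gen - burn_in) % sample_every == 0) {
      std::array<double, 14> acc{};
      std::array<long, 14> cnt{};
      auto pair_cats = [&](const int64_t* x, const int64_t* y, int base) {
        // focal slot (mat, pat) x partner slot (mat, pat); accumulate both
        // directions so the estimate is symmetric
        for (int s = 0; s < 2; ++s)
          for (int t = 0; t < 2; ++t) {
            acc[base + 2 * s + t] += (x[s] == y[t]) + (y[s] == x[t]);
            cnt[base + 2 * s + t] += 2;
          }
      };
      for (int p = 0; p < N; ++p) {
        const int64_t* Fp = &fem[(size_t)p * strideF];
        const int64_t* Mp = &mal[(size_t)p * strideM];
        for (int i = 0; i < NF; ++i)
          for (int j = i + 1; j < NF; ++j)
            pair_cats(Fp + 2 * i, Fp + 2 * j, 0);
        for (int i = 0; i < NM; ++i)
          for (int j = i + 1; j < NM; ++j)
            pair_cats(Mp + 2 * i, Mp + 2 * j, 4);
        for (int i = 0; i < NF; ++i)
          for (int j = 0; j < NM; ++j)
            pair_cats(Fp + 2 * i, Mp + 2 * j, 8);
        for (int i = 0; i < NF; ++i) {
          acc[12] += Fp[2 * i] == Fp[2 * i + 1]; cnt[12] += 1;
        }
        for (int j = 0; j < NM; ++j) {
          acc[12] += Mp[2 * j] == Mp[2 * j + 1]; cnt[12] += 1;
        }
      }
      // between-patch background: random cross-patch gene pairs
      for (int t = 0; t < 4 * N; ++t) {
        int p1 = (int)rng.below((uint32_t)N);
        int p2 = (int)rng.below((uint32_t)N);
        if (p2 == p1) { if (++p2 >= N) p2 = 0; }
        int64_t g1 = fem[(size_t)p1 * strideF +
                         rng.below((uint32_t)strideF)];
        int64_t g2 = fem[(size_t)p2 * strideF +
                         rng.below((uint32_t)strideF)];
        acc[13] += g1 == g2; cnt[13] += 1;
      }
      for (int c = 0; c < 14; ++c) acc[c] /= cnt[c];
      samples.push_back(acc);
    }
  }

  NumericMatrix out((int)samples.size(), 14);
  for (int i = 0; i < (int)samples.size(); ++i)
    for (int c = 0; c < 14; ++c) out(i, c) = samples[i][c];
  colnames(out) = CharacterVector::create(
    "ff_mm", "ff_mp", "ff_pm", "ff_pp",
    "mm_mm", "mm_mp", "mm_pm", "mm_pp",
    "fm_mm", "fm_mp", "fm_pm", "fm_pp",
    "F", "between");
  return List::create(_["samples"] = out);
}
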