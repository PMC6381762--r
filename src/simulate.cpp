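#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent Gillespie simulation for the (2,2) sample.
//
// Time runs backwards in units of 2*Ne_ref generations; a pair of lineages
// in deme d coalesces at rate 1/c_d. Branch lengths are accumulated into
// the four folded mutation classes as the genealogy is built, so the
// output of each replicate is the class-resolved total branch length
// vector (het_b, het_v, shared_het, fixed_diff).
//
// Uses R's RNG (RNGScope via Rcpp attributes): set.seed() on the R side
// makes replicates reproducible.

static inline int popcount4(int m) {
  return ((m >> 0) & 1) + ((m >> 1) & 1) + ((m >> 2) & 1) + ((m >> 3) & 1);
}

// folded class of a branch mask, 0-based: 0 het_b, 1 het_v, 2 shared, 3 fixed
static inline int class_of_mask(int mask) {
  int n = popcount4(mask);
  if (n == 3) { mask = (~mask) & 15; n = 1; }
  int nv = ((mask >> 0) & 1) + ((mask >> 1) & 1);
  if (n == 1) return nv == 1 ? 1 : 0;
  return (nv == 2 || nv == 0) ? 3 : 2;
}

struct SimState {
  int mask[4];
  int deme[4];  // 0 = V, 1 = B, irrelevant after the split
  int n;
};

static void accumulate(const SimState& st, double dt, double* tau) {
  for (int i = 0; i < st.n; ++i)
    if (st.mask[i] != 15) tau[class_of_mask(st.mask[i])] += dt;
}

static void coalesce(SimState& st, int a, int b) {
  st.mask[a] |= st.mask[b];
  st.mask[b] = st.mask[st.n - 1];
  st.deme[b] = st.deme[st.n - 1];
  st.n--;
}

// [[Rcpp::export(name = ".sim_class_lengths_cpp")]]
NumericMatrix sim_class_lengths_cpp(int n_rep,
                                    double T_split, double c_V, double c_B,
                                    double c_anc,
                                    double m, int mig_from_deme,
                                    double T_adm, double f, int adm_from_deme) {
  NumericMatrix out(n_rep, 4);
  const double cd[2] = {c_V, c_B};

  for (int rep = 0; rep < n_rep; ++rep) {
    SimState st;
    st.n = 4;
    for (int i = 0; i < 4; ++i) { st.mask[i] = 1 << i; st.deme[i] = i < 2 ? 0 : 1; }
    double tau[4] = {0, 0, 0, 0};
    double t = 0.0;
    bool adm_done = (adm_from_deme < 0);

    // pre-split epoch: two demes
    while (st.n > 1 && t < T_split) {
      int nd[2] = {0, 0};
      for (int i = 0; i < st.n; ++i) nd[st.deme[i]]++;
      double rate_coal[2], rate_mig = 0.0;
      for (int d = 0; d < 2; ++d)
        rate_coal[d] = nd[d] * (nd[d] - 1) / 2.0 / cd[d];
      if (mig_from_deme >= 0) rate_mig = m * nd[mig_from_deme];
      double total = rate_coal[0] + rate_coal[1] + rate_mig;

      double dt = total > 0 ? R::rexp(1.0 / total) : R_PosInf;
      double t_next = t + dt;
      double boundary = (!adm_done && T_adm < T_split) ? T_adm : T_split;
      if (t_next >= boundary) {
        accumulate(st, boundary - t, tau);
        t = boundary;
        if (!adm_done && boundary == T_adm) {
          for (int i = 0; i < st.n; ++i)
            if (st.deme[i] == adm_from_deme && unif_rand() < f)
              st.deme[i] = 1 - adm_from_deme;
          adm_done = true;
        }
        continue;
      }
      accumulate(st, dt, tau);
      t = t_next;

      double u = unif_rand() * total;
      if (u < rate_coal[0] + rate_coal[1]) {
        int d = (u < rate_coal[0]) ? 0 : 1;
        // pick an unordered pair uniformly among lineages in deme d
        int idx[4], k = 0;
        for (int i = 0; i < st.n; ++i) if (st.deme[i] == d) idx[k++] = i;
        int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
        int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
        if (b >= a) b++;
        coalesce(st, idx[a], idx[b]);
      } else {
        int idx[4], k = 0;
        for (int i = 0; i < st.n; ++i) if (st.deme[i] == mig_from_deme) idx[k++] = i;
        int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
        st.deme[idx[a]] = 1 - mig_from_deme;
      }
    }

    // ancestral epoch: one deme of relative size c_anc
    while (st.n > 1) {
      double total = st.n * (st.n - 1) / 2.0 / c_anc;
      double dt = R::rexp(1.0 / total);
      accumulate(st, dt, tau);
      int a = (int)(unif_rand() * st.n); if (a >= st.n) a = st.n - 1;
      int b = (int)(unif_rand() * (st.n - 1)); if (b >= st.n - 1) b = st.n - 2;
      if (b >= a) b++;
      coalesce(st, a, b);
    }

    for (int j = 0; j < 4; ++j) out(rep, j) = tau[j];
  }
  return out;
}
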