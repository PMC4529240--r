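#include <Rcpp.h>
using namespace Rcpp;

// Exact race probabilities for a display of up to 6 elements processed by
// independent exponential clocks with rates v_x. An element is encoded iff it
// finishes by tau AND is among the first K finishers. The probability that
// exactly the set T is encoded splits into two k-independent pieces:
//   free(T): all of T finish by tau and nothing else does (store never full)
//   fill(T): the elements of T are the first |T| finishers and the |T|-th
//            finish time is <= tau (store exactly full)
// so that P_k(T) = free(T) * P(K > |T|) + fill(T) * P(K = |T|).
//
// fill(T) = P(max_{x in T} X_x <= tau and max_T X < min_{T^c} X); with
// Q = sum of rates outside T, inclusion-exclusion over B subseteq T gives
//   fill(T) = sum_{B != 0} (-1)^{|B|+1} V_B/(V_B+Q) (1 - e^{-(V_B+Q) tau}),
// algebraically identical to the ordering-sum of hypoexponential CDFs but
// O(2^|T|) instead of O(|T|! |T|). Zero-rate elements cancel exactly.

static inline int popcount6(int m) {
  int c = 0;
  while (m) { m &= m - 1; ++c; }
  return c;
}

static void set_probs(const double *v, const double *E,
                      const int *occ, int nocc, int Tmask,
                      double *outFree, double *outFill) {
  double pfree = 1.0, Q = 0.0, EQ = 1.0;
  int members[6];
  int t = 0;
  for (int j = 0; j < nocc; ++j) {
    int x = occ[j];
    if (Tmask & (1 << x)) {
      members[t++] = x;
      pfree *= (1.0 - E[x]);
    } else {
      pfree *= E[x];
      Q += v[x];
      EQ *= E[x];
    }
  }
  *outFree = pfree;
  if (t == 0) { *outFill = 0.0; return; }
  double Vb[64], Eb[64];
  Vb[0] = 0.0; Eb[0] = 1.0;
  double fill = 0.0;
  for (int m = 1; m < (1 << t); ++m) {
    int low = m & (-m);
    int j = 0;
    while (!(low & (1 << j))) ++j;
    int x = members[j];
    Vb[m] = Vb[m ^ low] + v[x];
    Eb[m] = Eb[m ^ low] * E[x];
    double denom = Vb[m] + Q;
    double term = (denom > 0.0) ? (Vb[m] / denom) * (1.0 - Eb[m] * EQ) : 0.0;
    fill += (popcount6(m) & 1) ? term : -term;
  }
  *outFill = fill;
}

// P(report = A) at one tau node: marginalize over encoded distractor subsets.
// pK indexed 1..6 (pK[0] unused); pKtail[s] = P(K > s).
static double report_prob_node(const double *v, const double *E,
                               const int *occ, int nocc,
                               const int *dist, int nd,
                               const double *pK, const double *pKtail,
                               int Amask) {
  double p = 0.0;
  for (int dm = 0; dm < (1 << nd); ++dm) {
    int Tmask = Amask;
    for (int j = 0; j < nd; ++j)
      if (dm & (1 << j)) Tmask |= (1 << dist[j]);
    int s = popcount6(Tmask);
    double pfree, pfill;
    set_probs(v, E, occ, nocc, Tmask, &pfree, &pfill);
    double w = pfree * pKtail[s];
    if (s >= 1 && s <= 6) w += pK[s] * pfill;
    p += w;
  }
  return p;
}

static void unpack_roles(const int *roles, int *occ, int *nocc,
                         int *tgt, int *ntgt, int *dist, int *nd) {
  *nocc = *ntgt = *nd = 0;
  for (int x = 0; x < 6; ++x) {
    if (roles[x] == 1) { tgt[(*ntgt)++] = x; occ[(*nocc)++] = x; }
    else if (roles[x] == 2) { dist[(*nd)++] = x; occ[(*nocc)++] = x; }
  }
}

static void pk_tails(const NumericVector &pK, double *pk, double *tail) {
  pk[0] = 0.0;
  for (int k = 1; k <= 6; ++k) pk[k] = pK[k - 1];
  tail[6] = 0.0;
  for (int s = 5; s >= 0; --s) tail[s] = tail[s + 1] + pk[s + 1];
}

// Distribution over reported target subsets (conditional on no lapse),
// indexed by bitmask over the target locations in increasing location order.
// [[Rcpp::export]]
NumericVector cpp_report_dist(NumericVector v, IntegerVector roles,
                              NumericVector tau, NumericVector tw,
                              NumericVector pK) {
  int occ[6], tgt[6], dist[6], nocc, ntgt, nd;
  unpack_roles(INTEGER(roles), occ, &nocc, tgt, &ntgt, dist, &nd);
  double pk[7], tail[7];
  pk_tails(pK, pk, tail);
  int nA = 1 << ntgt;
  NumericVector out(nA);
  int nq = tau.size();
  double E[6];
  const double *vp = REAL(v);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nocc; ++j) {
      int x = occ[j];
      E[x] = std::exp(-v[x] * tau[i]);
    }
    for (int a = 0; a < nA; ++a) {
      int Amask = 0;
      for (int j = 0; j < ntgt; ++j)
        if (a & (1 << j)) Amask |= (1 << tgt[j]);
      out[a] += tw[i] * report_prob_node(vp, E, occ, nocc, dist, nd,
                                         pk, tail, Amask);
    }
  }
  return out;
}

// Total negative log-likelihood over grouped trials. Each row g of the inputs
// describes one unique (layout, exposure, report) combination observed
// count[g] times. repmask is a bitmask over locations 0..5 of the reported
// target set. taumat[g, i] is the effective exposure (s) at quadrature node i.
// [[Rcpp::export]]
List cpp_nll(NumericMatrix vmat, IntegerMatrix rolesmat, IntegerVector repmask,
             NumericMatrix taumat, NumericVector tw, NumericVector pK,
             double plapse, double lik_floor, IntegerVector counts) {
  int g = vmat.nrow(), nq = tw.size();
  double pk[7], tail[7];
  pk_tails(pK, pk, tail);
  double nll = 0.0;
  int nfloor = 0;
  int occ[6], tgt[6], dist[6], nocc, ntgt, nd, roles[6];
  double v[6], E[6];
  for (int r = 0; r < g; ++r) {
    for (int x = 0; x < 6; ++x) { roles[x] = rolesmat(r, x); v[x] = vmat(r, x); }
    unpack_roles(roles, occ, &nocc, tgt, &ntgt, dist, &nd);
    int A = repmask[r];
    double p = 0.0;
    for (int i = 0; i < nq; ++i) {
      for (int j = 0; j < nocc; ++j) {
        int x = occ[j];
        E[x] = std::exp(-v[x] * taumat(r, i));
      }
      p += tw[i] * report_prob_node(v, E, occ, nocc, dist, nd, pk, tail, A);
    }
    p = (1.0 - plapse) * p + (A == 0 ? plapse : 0.0);
    if (p < lik_floor) { p = lik_floor; ++nfloor; }
    nll -= counts[r] * std::log(p);
  }
  return List::create(_["nll"] = nll, _["n_floored"] = nfloor);
}

// Generative simulator: one reported target-location bitmask per trial.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_simulate_reports(NumericMatrix vmat, IntegerMatrix rolesmat,
                                   NumericVector exposure_ms, double mu_t0,
                                   double sigma_t0, NumericVector pK,
                                   double plapse) {
  RNGScope scope;
  int n = vmat.nrow();
  IntegerVector out(n);
  double cumK[6];
  double acc = 0.0;
  for (int k = 0; k < 6; ++k) { acc += pK[k]; cumK[k] = acc; }
  for (int r = 0; r < n; ++r) {
    if (unif_rand() < plapse) { out[r] = 0; continue; }
    double t0 = norm_rand() * sigma_t0 + mu_t0;
    double tau = (exposure_ms[r] - t0) / 1000.0;
    if (tau < 0.0) tau = 0.0;
    double u = unif_rand();
    int K = 6;
    for (int k = 0; k < 6; ++k)
      if (u <= cumK[k]) { K = k + 1; break; }
    double t[6];
    int idx[6], m = 0;
    for (int x = 0; x < 6; ++x) {
      if (rolesmat(r, x) == 0) continue;
      double vx = vmat(r, x);
      // exponential finish time; zero-rate elements never finish
      double ft = (vx > 0.0) ? exp_rand() / vx : R_PosInf;
      t[m] = ft; idx[m] = x; ++m;
    }
    // encoded = finish <= tau and among the first K finishers
    int ord[6];
    for (int j = 0; j < m; ++j) ord[j] = j;
    for (int a = 1; a < m; ++a) {          // insertion sort by finish time
      int ja = ord[a];
      int b = a - 1;
      while (b >= 0 && t[ord[b]] > t[ja]) { ord[b + 1] = ord[b]; --b; }
      ord[b + 1] = ja;
    }
    int rep = 0;
    int taken = 0;
    for (int j = 0; j < m && taken < K; ++j) {
      int e = ord[j];
      if (t[e] <= tau) {
        ++taken;
        if (rolesmat(r, idx[e]) == 1) rep |= (1 << idx[e]);
      } else break;
    }
    out[r] = rep;
  }
  return out;
}
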