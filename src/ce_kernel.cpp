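#include <Rcpp.h>
using namespace Rcpp;

// Batch objective: Phi for each candidate permutation against the ensemble.
// perms: n_samples x n, perms(s, pos) = 1-based universe item index at
// position pos+1. R: n x m ranks of each universe item in each list (k+1 for
// items missing from a top-k list). Mcand / Mlist: (n+1) x m importance
// curves indexed by rank (all zero when weighted = false).
// [[Rcpp::export]]
NumericVector phi_batch_cpp(const IntegerMatrix& perms, const IntegerMatrix& R,
                            const NumericMatrix& Mcand,
                            const NumericMatrix& Mlist,
                            const NumericVector& w, const bool weighted) {
  const int ns = perms.nrow(), n = perms.ncol(), m = R.ncol();
  NumericVector phi(ns);
  std::vector<int> rcand(n);
  for (int s = 0; s < ns; ++s) {
    for (int pos = 0; pos < n; ++pos) rcand[perms(s, pos) - 1] = pos + 1;
    double total = 0.0;
    for (int i = 0; i < m; ++i) {
      double d = 0.0;
      if (weighted) {
        for (int t = 0; t < n; ++t) {
          const int r1 = rcand[t], r2 = R(t, i);
          d += std::abs(Mcand(r1 - 1, i) - Mlist(r2 - 1, i)) *
               std::abs(r1 - r2);
        }
      } else {
        for (int t = 0; t < n; ++t) d += std::abs(rcand[t] - R(t, i));
      }
      total += w[i] * d;
    }
    phi[s] = total;
  }
  return phi;
}

// Sample permutations from an item-by-position probability matrix P (n x n):
// positions are filled left to right, drawing each item from column pos of P
// renormalised over the items not yet used. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sample_permutations_cpp(const NumericMatrix& P,
                                      const int n_samples) {
  const int n = P.nrow();
  IntegerMatrix perms(n_samples, n);
  std::vector<int> unused(n);
  std::vector<double> buf(n);
  const double* p = REAL(P);
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < n; ++t) unused[t] = t;
    int k = n;
    for (int pos = 0; pos < n; ++pos, --k) {
      const double* col = p + (R_xlen_t)pos * n;
      double tot = 0.0;
      for (int i = 0; i < k; ++i) {
        tot += col[unused[i]];
        buf[i] = tot;
      }
      const double u = unif_rand() * tot;
      int pick = k - 1;
      for (int i = 0; i < k; ++i) {
        if (buf[i] >= u) { pick = i; break; }
      }
      perms(s, pos) = unused[pick] + 1;
      unused[pick] = unused[k - 1];
    }
  }
  return perms;
}

// Empirical item-by-position frequency matrix of the elite permutations.
// [[Rcpp::export]]
NumericMatrix elite_frequency_cpp(const IntegerMatrix& perms,
                                  const IntegerVector& elite_rows,
                                  const int n) {
  NumericMatrix F(n, n);
  const int k = elite_rows.size();
  for (int e = 0; e < k; ++e) {
    const int s = elite_rows[e] - 1;
    for (int pos = 0; pos < n; ++pos) F(perms(s, pos) - 1, pos) += 1.0 / k;
  }
  return F;
}
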