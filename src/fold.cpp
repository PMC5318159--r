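#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Base-pair-counting secondary-structure engine: every Watson-Crick or GU
// pair scores -1, hairpin loops span at least `min_loop` unpaired bases, and
// positions listed in `unpaired` are hard-constrained to stay single-stranded.
// Sequences are encoded A=0, C=1, G=2, U/T=3.

static inline bool can_pair(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

// [[Rcpp::export]]
IntegerVector nussinov_pairs(IntegerVector seq, LogicalVector unpaired,
                             int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, -1);
  if (n == 0) return partner;
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (unpaired[k] || unpaired[j] || !can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) +
                (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // deterministic traceback: prefer pairing j when it attains the optimum,
  // and among co-optimal partners prefer the smallest opening index k
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = M[i][j];
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (unpaired[k] || unpaired[j] || !can_pair(seq[k], seq[j])) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0) +
              (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == target) {
        partner[k] = j;
        partner[j] = k;
        if (k > i) stack.push_back({i, k - 1});
        if (k + 1 <= j - 1) stack.push_back({k + 1, j - 1});
        done = true;
      }
    }
    if (!done) stack.push_back({i, j - 1});
  }
  return partner;
}

// Inside-outside over the unambiguous grammar
//   S(i,j) -> S(i,j-1) | S(i,k-1) P(k,j);  P(k,j) -> '(' S(k+1,j-1) ')'
// with pair weight w = exp(beta) and per-base rescaling s to keep doubles in
// range (the scale cancels exactly in the probability ratio).
// [[Rcpp::export]]
NumericMatrix pair_prob_matrix(IntegerVector seq, LogicalVector unpaired,
                               double beta, int min_loop) {
  int n = seq.size();
  NumericMatrix P(n, n);
  if (n < min_loop + 2) return P;
  double w = std::exp(beta);

  // rescale so the MFE structure has weight ~1
  IntegerVector mfe = nussinov_pairs(seq, unpaired, min_loop);
  int npairs = 0;
  for (int i = 0; i < n; ++i) if (mfe[i] > i) ++npairs;
  double s = std::exp(-beta * (double)npairs / (double)n);
  double ws2 = w * s * s;

  // inside: Q over [i,j], Qb for pair (i,j); index helper with empty = 1*scale^0
  std::vector<std::vector<double>> Q(n + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double>> Qb(n, std::vector<double>(n, 0.0));
  // Q stored as Q[i][j] for 0-based i..j inclusive; empty intervals via helper
  auto Qget = [&](int i, int j) -> double {
    if (i > j) return 1.0;
    return Q[i][j];
  };
  for (int i = 0; i < n; ++i) Q[i][i] = s;
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double q = s * Qget(i, j - 1);
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (unpaired[k] || unpaired[j] || !can_pair(seq[k], seq[j])) continue;
        double qb = ws2 * Qget(k + 1, j - 1);
        Qb[k][j] = qb;
        q += Qget(i, k - 1) * qb;
      }
      Q[i][j] = q;
    }
  }
  double Ztot = Qget(0, n - 1);
  if (Ztot <= 0.0) return P;

  // outside
  std::vector<std::vector<double>> Qh(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> Qbh(n, std::vector<double>(n, 0.0));
  Qh[0][n - 1] = 1.0;
  for (int span = n - 1; span >= 1; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double qh = Qh[i][j];
      if (qh != 0.0) {
        // rule: j unpaired
        Qh[i][j - 1] += s * qh;
        // rule: k pairs j
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (Qb[k][j] == 0.0) continue;
          if (k > i) Qh[i][k - 1] += qh * Qb[k][j];
          Qbh[k][j] += qh * Qget(i, k - 1);
        }
      }
      // pair node (i,j) of this span hands its interior down
      if (Qbh[i][j] != 0.0 && i + 1 <= j - 1) {
        Qh[i + 1][j - 1] += Qbh[i][j] * ws2;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      if (Qb[i][j] == 0.0) continue;
      double p = Qbh[i][j] * Qb[i][j] / Ztot;
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return P;
}
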