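#include <Rcpp.h>
using namespace Rcpp;

// Exact explicit-duration (semi-Markov) Viterbi over a small state set.
//
// Scoring semantics (shared with the pure-R enumeration oracle used in the
// test suite):
//   path = [(s1,d1),...,(sm,dm)], sum(d) = L
//   score = init[s1]
//         + sum_i emission(s_i, segment_i)
//         + sum_{i<m} durInternal(s_i,d_i) + exit(s_i) + trans(s_i,s_{i+1})
//         + durFinal(s_m,d_m) + final[s_m]
// with, per duration kind:
//   geometric: durInternal(d) = (d-1)*log q,  exit = log(1-q),
//              durFinal(d)    = (d-1)*log q
//   explicit:  durInternal(d) = log pmf(d) (mod-3 congruence enforced on
//              internal segments), exit = 0, durFinal(d) = log P(D >= d)
//              (right-censored final segment)
//   fixed:     d must equal fixedLen; duration factor 0; exit = 0
//
// Emissions are passed as phase-threaded cumulative arrays: cum[s] is an
// (L+1) x 3 matrix with C_r[i] = sum_{j<i} M[(r+j) mod 3][j] over the
// finite per-position scores, so a segment [u,t) whose first base has
// codon phase f scores C_r[t] - C_r[u] with r = (f - u) mod 3.  Positions
// with -Inf emission (hard constraints such as in-frame stop codons) are
// counted in the parallel cumulative matrix cumMask[s]; a segment is
// admissible only when its mask count difference is zero, keeping the
// finite sums exact.  Fixed (anchored) states instead use anchor[s][u] =
// full window score for a segment starting at u (-Inf when the hard codon
// constraint fails).

static const double NEG_TH = -1e25;

// [[Rcpp::export]]
List viterbi_ghmm_cpp(int L,
                      IntegerVector kind,
                      List cum,
                      List cumMask,
                      List anchor,
                      IntegerVector fixedLen,
                      NumericVector selfLogQ,
                      NumericVector exitLog,
                      List dlog,
                      List surv,
                      IntegerVector congR,
                      IntegerVector inPhase,
                      NumericMatrix transLog,
                      NumericVector initLog,
                      NumericVector finalLog) {
  const int S = kind.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<NumericMatrix> C(S), MK(S);
  std::vector<NumericVector> A(S), DL(S), SV(S);
  for (int s = 0; s < S; ++s) {
    C[s] = as<NumericMatrix>(cum[s]);
    MK[s] = as<NumericMatrix>(cumMask[s]);
    A[s] = as<NumericVector>(anchor[s]);
    DL[s] = as<NumericVector>(dlog[s]);
    SV[s] = as<NumericVector>(surv[s]);
  }

  std::vector<std::vector<double>> B(S, std::vector<double>(L + 1, NEG));
  std::vector<std::vector<double>> In(S, std::vector<double>(L + 1, NEG));
  std::vector<std::vector<int>> ptrFrom(S, std::vector<int>(L + 1, -1));
  std::vector<std::vector<int>> inPred(S, std::vector<int>(L + 1, -2));

  for (int s = 0; s < S; ++s) {
    In[s][0] = initLog[s];
    inPred[s][0] = -1;
  }

  for (int t = 1; t <= L; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = NEG;
      int bestFrom = -1;
      if (kind[s] == 0) {                       // geometric
        bool masked = MK[s](t, 0) - MK[s](t - 1, 0) > 0.5;
        double e = C[s](t, 0) - C[s](t - 1, 0);
        double enter = In[s][t - 1];
        double cont = (t >= 2) ? B[s][t - 1] + selfLogQ[s] : NEG;
        if (masked) {
          // position t-1 is inadmissible for this state
        } else if (enter >= cont && enter > NEG_TH) {
          best = enter + e; bestFrom = t - 1;
        } else if (cont > NEG_TH) {
          best = cont + e; bestFrom = ptrFrom[s][t - 1];
        }
      } else if (kind[s] == 2) {                // fixed
        int d = fixedLen[s];
        if (t >= d) {
          int u = t - d;
          double a = A[s][u];
          double v = In[s][u];
          if (a > NEG_TH && v > NEG_TH) { best = v + a; bestFrom = u; }
        }
      } else {                                  // explicit
        int Dmax = DL[s].size();
        if (Dmax > t) Dmax = t;
        int ph = inPhase[s];
        for (int d = 1; d <= Dmax; ++d) {
          double dp = DL[s][d - 1];
          if (dp <= NEG_TH) continue;
          if (congR[s] >= 0 && (d % 3) != congR[s]) continue;
          int u = t - d;
          double v = In[s][u];
          if (v <= NEG_TH) continue;
          int r = ((ph - u) % 3 + 3) % 3;
          if (MK[s](t, r) - MK[s](u, r) > 0.5) continue;
          double sc = v + (C[s](t, r) - C[s](u, r)) + dp;
          if (sc > best) { best = sc; bestFrom = u; }
        }
      }
      B[s][t] = best;
      ptrFrom[s][t] = bestFrom;
    }
    for (int s2 = 0; s2 < S; ++s2) {
      double best = NEG;
      int bestPred = -2;
      for (int s1 = 0; s1 < S; ++s1) {
        double b = B[s1][t];
        if (b <= NEG_TH) continue;
        double v = b + exitLog[s1] + transLog(s1, s2);
        if (v > best) { best = v; bestPred = s1; }
      }
      In[s2][t] = best;
      inPred[s2][t] = bestPred;
    }
  }

  // final segment: explicit states are re-scored with censored durations
  double bestScore = NEG;
  int bestState = -1, bestFrom = -1;
  for (int s = 0; s < S; ++s) {
    if (!(finalLog[s] > NEG_TH)) continue;
    double v = NEG;
    int from = -1;
    if (kind[s] == 1) {
      int Dmax = SV[s].size();
      if (Dmax > L) Dmax = L;
      int ph = inPhase[s];
      for (int d = 1; d <= Dmax; ++d) {
        double sp = SV[s][d - 1];
        if (sp <= NEG_TH) continue;
        int u = L - d;
        double iv = In[s][u];
        if (iv <= NEG_TH) continue;
        int r = ((ph - u) % 3 + 3) % 3;
        if (MK[s](L, r) - MK[s](u, r) > 0.5) continue;
        double sc = iv + (C[s](L, r) - C[s](u, r)) + sp;
        if (sc > v) { v = sc; from = u; }
      }
    } else {
      v = B[s][L];
      from = ptrFrom[s][L];
    }
    if (v <= NEG_TH) continue;
    double tot = v + finalLog[s];
    if (tot > bestScore) { bestScore = tot; bestState = s; bestFrom = from; }
  }

  if (!(bestScore > NEG_TH) || bestState < 0)
    return List::create(_["score"] = R_NegInf,
                        _["state"] = IntegerVector(0),
                        _["from"] = IntegerVector(0),
                        _["to"] = IntegerVector(0));

  std::vector<int> st, fr, to;
  int s = bestState, t = L, from = bestFrom;
  while (true) {
    st.push_back(s); fr.push_back(from); to.push_back(t);
    if (from == 0) break;
    int pred = inPred[s][from];
    if (pred < 0) break;   // defensive; should not occur with from > 0
    t = from;
    s = pred;
    from = ptrFrom[s][t];
  }
  std::reverse(st.begin(), st.end());
  std::reverse(fr.begin(), fr.end());
  std::reverse(to.begin(), to.end());
  return List::create(_["score"] = bestScore,
                      _["state"] = wrap(st),
                      _["from"] = wrap(fr),
                      _["to"] = wrap(to));
}
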