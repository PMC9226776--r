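#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Plan7-style local alignment DP in log2 (bit) space.
//
// States: M_1..M_L (emit), I_1..I_{L-1} (emit), D_2..D_L (silent).
// Local mode: entry B -> M_k with probability 1/L for any k, exit M_k -> E
// free (probability 1). Unaligned flanking residues score 0 under the null,
// so a path score is entry + sum(emission log-odds) + sum(transition log2 p).
//
// Transition vectors are indexed by source node k = 1..L-1 (0-based k-1):
// tmm, tmi, tmd out of M_k; tim, tii out of I_k; tdm, tdd out of D_k.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log2_add(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp((b - a) * M_LN2)) / M_LN2;
}

struct DPResult {
  double viterbi;
  double forward;
  int end_k;   // 1-based match node where the viterbi path exits
  int end_i;   // 1-based sequence position emitted by that node
};

// seq: 0-based residue column indices into the emission matrices
static DPResult run_dp(const NumericMatrix& mlo, const NumericMatrix& ilo,
                       const NumericVector& tmm, const NumericVector& tmi,
                       const NumericVector& tmd, const NumericVector& tim,
                       const NumericVector& tii, const NumericVector& tdm,
                       const NumericVector& tdd, const IntegerVector& seq,
                       std::vector<signed char>* ptrM = nullptr,
                       std::vector<signed char>* ptrI = nullptr,
                       std::vector<signed char>* ptrD = nullptr) {
  const int L = mlo.nrow();
  const int n = seq.size();
  const double entry = -std::log2((double)L);

  // column-major [k + L*i], i = 0..n (i residues consumed)
  std::vector<double> VM((size_t)L * (n + 1), NEG_INF);
  std::vector<double> VI((size_t)L * (n + 1), NEG_INF);
  std::vector<double> VD((size_t)L * (n + 1), NEG_INF);
  std::vector<double> FM, FI, FD;
  const bool want_fwd = ptrM == nullptr;  // traceback pass skips forward
  if (want_fwd) {
    FM.assign((size_t)L * (n + 1), NEG_INF);
    FI.assign((size_t)L * (n + 1), NEG_INF);
    FD.assign((size_t)L * (n + 1), NEG_INF);
  }
  if (ptrM) {
    ptrM->assign((size_t)L * (n + 1), -1);
    ptrI->assign((size_t)L * (n + 1), -1);
    ptrD->assign((size_t)L * (n + 1), -1);
  }

  double best = NEG_INF, fwd = NEG_INF;
  int best_k = 0, best_i = 0;

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1];
    const size_t c = (size_t)L * i, p = (size_t)L * (i - 1);
    for (int k = 1; k <= L; ++k) {
      // ---- M_k emits x_i ----
      double e = mlo(k - 1, x);
      double v = entry;       // ptr code 0 = begin
      signed char who = 0;
      if (k >= 2) {
        double a = VM[p + k - 2] + tmm[k - 2];
        if (a > v) { v = a; who = 1; }
        a = VI[p + k - 2] + tim[k - 2];
        if (a > v) { v = a; who = 2; }
        a = VD[p + k - 2] + tdm[k - 2];
        if (a > v) { v = a; who = 3; }
      }
      VM[c + k - 1] = e + v;
      if (ptrM) (*ptrM)[c + k - 1] = who;
      if (want_fwd) {
        double f = entry;
        if (k >= 2) {
          f = log2_add(f, FM[p + k - 2] + tmm[k - 2]);
          f = log2_add(f, FI[p + k - 2] + tim[k - 2]);
          f = log2_add(f, FD[p + k - 2] + tdm[k - 2]);
        }
        FM[c + k - 1] = e + f;
        fwd = log2_add(fwd, FM[c + k - 1]);  // free exit from every M
      }
      if (VM[c + k - 1] > best) { best = VM[c + k - 1]; best_k = k; best_i = i; }
      // ---- I_k emits x_i (k <= L-1) ----
      if (k <= L - 1) {
        double ei = ilo(k - 1, x);
        double vm = VM[p + k - 1] + tmi[k - 1];
        double vi = VI[p + k - 1] + tii[k - 1];
        if (vm >= vi) { VI[c + k - 1] = ei + vm; if (ptrI) (*ptrI)[c + k - 1] = 1; }
        else          { VI[c + k - 1] = ei + vi; if (ptrI) (*ptrI)[c + k - 1] = 2; }
        if (want_fwd)
          FI[c + k - 1] = ei + log2_add(FM[p + k - 1] + tmi[k - 1],
                                        FI[p + k - 1] + tii[k - 1]);
      }
    }
    // ---- D_k silent, same column, increasing k ----
    for (int k = 2; k <= L; ++k) {
      double vm = VM[c + k - 2] + tmd[k - 2];
      double vd = VD[c + k - 2] + tdd[k - 2];
      if (vm >= vd) { VD[c + k - 1] = vm; if (ptrD) (*ptrD)[c + k - 1] = 1; }
      else          { VD[c + k - 1] = vd; if (ptrD) (*ptrD)[c + k - 1] = 3; }
      if (want_fwd)
        FD[c + k - 1] = log2_add(FM[c + k - 2] + tmd[k - 2],
                                 FD[c + k - 2] + tdd[k - 2]);
    }
  }

  DPResult r;
  r.viterbi = best;
  r.forward = fwd;
  r.end_k = best_k;
  r.end_i = best_i;
  if (ptrM) {  // keep VM/VI/VD alive for traceback through the stored copies
    // nothing extra: traceback uses pointer codes only
  }
  return r;
}

// [[Rcpp::export(name = ".hmm_dp_scores")]]
NumericVector hmm_dp_scores(NumericMatrix mlo, NumericMatrix ilo,
                            NumericVector tmm, NumericVector tmi, NumericVector tmd,
                            NumericVector tim, NumericVector tii,
                            NumericVector tdm, NumericVector tdd,
                            IntegerVector seq) {
  DPResult r = run_dp(mlo, ilo, tmm, tmi, tmd, tim, tii, tdm, tdd, seq);
  return NumericVector::create(_["viterbi"] = r.viterbi, _["forward"] = r.forward);
}

// Viterbi bits for many sequences against one model (scan / calibration).
// [[Rcpp::export(name = ".hmm_viterbi_many")]]
NumericVector hmm_viterbi_many(NumericMatrix mlo, NumericMatrix ilo,
                               NumericVector tmm, NumericVector tmi, NumericVector tmd,
                               NumericVector tim, NumericVector tii,
                               NumericVector tdm, NumericVector tdd,
                               List seqs) {
  const int m = seqs.size();
  NumericVector out(m);
  std::vector<signed char> pm, pi, pd;
  for (int j = 0; j < m; ++j) {
    IntegerVector s = seqs[j];
    // viterbi-only pass (pointer buffers suppress the forward recursion)
    DPResult r = run_dp(mlo, ilo, tmm, tmi, tmd, tim, tii, tdm, tdd, s,
                        &pm, &pi, &pd);
    out[j] = r.viterbi;
  }
  return out;
}

// Full DP with traceback. Returns viterbi/forward bits and the best path as a
// 3-column matrix: state (1=M, 2=I, 3=D), node, seq position (0 for D).
// [[Rcpp::export(name = ".hmm_dp_path")]]
List hmm_dp_path(NumericMatrix mlo, NumericMatrix ilo,
                 NumericVector tmm, NumericVector tmi, NumericVector tmd,
                 NumericVector tim, NumericVector tii,
                 NumericVector tdm, NumericVector tdd,
                 IntegerVector seq) {
  const int L = mlo.nrow();
  std::vector<signed char> pm, pi, pd;
  DPResult rv = run_dp(mlo, ilo, tmm, tmi, tmd, tim, tii, tdm, tdd, seq,
                       &pm, &pi, &pd);
  DPResult rf = run_dp(mlo, ilo, tmm, tmi, tmd, tim, tii, tdm, tdd, seq);

  // traceback from (M, end_k, end_i)
  std::vector<std::array<int, 3>> rev;
  int state = 1, k = rv.end_k, i = rv.end_i;
  while (true) {
    rev.push_back({state, k, state == 3 ? 0 : i});
    signed char who;
    size_t idx = (size_t)L * i + (k - 1);
    if (state == 1) who = pm[idx];
    else if (state == 2) who = pi[idx];
    else who = pd[idx];
    if (state == 1) {
      if (who == 0) break;          // entry
      k -= 1; i -= 1;
      state = (who == 1) ? 1 : (who == 2) ? 2 : 3;
    } else if (state == 2) {        // came from M_k or I_k at i-1
      i -= 1;
      state = (who == 1) ? 1 : 2;
    } else {                        // D_k from M_{k-1} or D_{k-1}, same i
      k -= 1;
      state = (who == 1) ? 1 : 3;
    }
  }
  IntegerMatrix path(rev.size(), 3);
  for (size_t j = 0; j < rev.size(); ++j) {
    size_t r = rev.size() - 1 - j;
    path(j, 0) = rev[r][0];
    path(j, 1) = rev[r][1];
    path(j, 2) = rev[r][2];
  }
  colnames(path) = CharacterVector::create("state", "node", "pos");
  return List::create(_["viterbi"] = rv.viterbi, _["forward"] = rf.forward,
                      _["path"] = path);
}
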