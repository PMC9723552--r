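#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Affine-gap pairwise DNA alignment with deterministic tie-breaking.
//
// Two modes:
//   semiglobal: the probe (pattern) is aligned end-to-end, the target
//               (subject) contributes a consecutive subsequence (free end
//               gaps on the subject). This mirrors how a polynucleotide
//               probe hybridizes somewhere inside a longer gene.
//   global:     both sequences aligned end-to-end (used for homolog
//               nucleotide identities between locus genes).
//
// Gap convention: a gap of length L costs gap_open + L * gap_extend
// (both passed as positive penalties). 'N' never matches anything,
// including another 'N'.
//
// Tie-breaks (fixed so that results are reproducible and independently
// re-derivable): when scores tie, prefer state M (diagonal) over P
// (probe char vs gap) over Q (target char vs gap); the semiglobal end
// column is the smallest subject index achieving the optimum.
//
// Score matrices are kept as two rolling rows; tracebacks are full byte
// matrices so memory stays at ~3 bytes per DP cell.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_core")]]
List align_core(std::string probe, std::string target,
                double match, double mismatch,
                double gap_open, double gap_extend,
                bool global_subject) {
  const int m = probe.size(), n = target.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const double oe = gap_open + gap_extend, e = gap_extend;
  const int W = n + 1;

  std::vector<double> Mprev(W), Mcur(W), Pprev(W), Pcur(W), Qprev(W), Qcur(W);
  std::vector<unsigned char> tbM((m + 1) * W), tbP((m + 1) * W), tbQ((m + 1) * W);

  // row 0
  if (global_subject) {
    Mprev[0] = 0.0; Pprev[0] = Qprev[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      Mprev[j] = Pprev[j] = NEG_INF;
      Qprev[j] = -(gap_open + j * e);
      tbQ[j] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int j = 0; j <= n; ++j) { Mprev[j] = 0.0; Pprev[j] = Qprev[j] = NEG_INF; }
  }

  for (int i = 1; i <= m; ++i) {
    const char pc = probe[i - 1];
    unsigned char *rM = &tbM[i * W], *rP = &tbP[i * W], *rQ = &tbQ[i * W];
    // column 0: only a probe-vs-gap run can reach here
    Mcur[0] = Qcur[0] = NEG_INF;
    Pcur[0] = -(gap_open + i * e);
    rP[0] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= n; ++j) {
      // M: consume both (diagonal from row i-1, col j-1)
      double best = Mprev[j - 1]; unsigned char bs = 0;
      if (Pprev[j - 1] > best) { best = Pprev[j - 1]; bs = 1; }
      if (Qprev[j - 1] > best) { best = Qprev[j - 1]; bs = 2; }
      const char tc = target[j - 1];
      Mcur[j] = (best == NEG_INF) ? NEG_INF
                : best + ((pc == tc && pc != 'N') ? match : mismatch);
      rM[j] = bs;
      // P: probe char vs gap (from row i-1, col j)
      best = Mprev[j] - oe; bs = 0;
      if (Pprev[j] - e > best) { best = Pprev[j] - e; bs = 1; }
      if (Qprev[j] - oe > best) { best = Qprev[j] - oe; bs = 2; }
      Pcur[j] = best; rP[j] = bs;
      // Q: target char vs gap (from row i, col j-1)
      best = Mcur[j - 1] - oe; bs = 0;
      if (Pcur[j - 1] - oe > best) { best = Pcur[j - 1] - oe; bs = 1; }
      if (Qcur[j - 1] - e > best) { best = Qcur[j - 1] - e; bs = 2; }
      Qcur[j] = best; rQ[j] = bs;
    }
    std::swap(Mprev, Mcur); std::swap(Pprev, Pcur); std::swap(Qprev, Qcur);
  }
  // final row now lives in the *prev buffers

  int end_j = n; unsigned char end_state = 0; double score;
  if (global_subject) {
    score = Mprev[n]; end_state = 0;
    if (Pprev[n] > score) { score = Pprev[n]; end_state = 1; }
    if (Qprev[n] > score) { score = Qprev[n]; end_state = 2; }
  } else {
    score = NEG_INF;
    for (int j = 0; j <= n; ++j) {
      // alignments never end in a target-consuming gap column (Q); such
      // endings are dominated because trailing target is free anyway
      if (Mprev[j] > score) { score = Mprev[j]; end_j = j; end_state = 0; }
      if (Pprev[j] > score) { score = Pprev[j]; end_j = j; end_state = 1; }
    }
  }

  std::string trace;
  trace.reserve(m + n);
  int i = m, j = end_j; unsigned char s = end_state;
  while (i > 0 || (global_subject && j > 0)) {
    if (s == 0) {
      const char pc = probe[i - 1], tc = target[j - 1];
      trace.push_back((pc == tc && pc != 'N') ? '=' : 'X');
      s = tbM[i * W + j]; --i; --j;
    } else if (s == 1) {
      trace.push_back('I');
      s = tbP[i * W + j]; --i;
    } else {
      trace.push_back('D');
      s = tbQ[i * W + j]; --j;
    }
    if (!global_subject && i == 0) break;
  }
  std::reverse(trace.begin(), trace.end());

  return List::create(_["score"] = score,
                      _["trace"] = trace,
                      _["target_start"] = j,   // 0-based, half-open span
                      _["target_end"] = end_j);
}
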