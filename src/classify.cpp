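#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fragment-to-feature classification.
//
// Coordinates are 1-based inclusive. Transcript exon chains are given as
// concatenated genomic (estart, eend) arrays with 0-based offsets per
// transcript (offset has length nTx + 1). Flattened exons are concatenated
// per gene with fgOffset (length nGenes + 1). Junction candidate ids per
// transcript gap are in jid with jOffset (length nTx + 1); gap k of a
// transcript (between exon k and k+1, genomic order) has candidate id
// jid[jOffset[t] + k - 1].
//
// A mate covering transcript interval [a, b] bridges gap k (cumulative
// exon length C_k) iff a <= C_k and C_k + 1 <= b; its overhang for that
// gap is min(C_k - a + 1, b - C_k).

// DEJU rule: if either mate bridges a junction, assign the fragment to the
// bridged junction with the longest minimum overhang (max over mates per
// junction; ties -> leftmost gap); encode as -(junction id). Otherwise
// assign to the flattened exon of the fragment's gene with the largest
// total overlap across both mates (ties -> leftmost); encode as the flat
// exon index. 0 = unassigned.
// [[Rcpp::export]]
List classify_deju_cpp(IntegerVector tx, IntegerVector tstart,
                       IntegerVector flen, int readLen,
                       IntegerVector estart, IntegerVector eend,
                       IntegerVector offset, IntegerVector txGene,
                       IntegerVector jid, IntegerVector jOffset,
                       int nJunctions,
                       IntegerVector fstart, IntegerVector fend,
                       IntegerVector fgOffset) {
  int n = tx.size();
  IntegerVector assign(n);
  IntegerVector maxOver(nJunctions);
  std::vector<int> cum; cum.reserve(64);
  std::vector<int> ovl; ovl.reserve(64);
  for (int i = 0; i < n; i++) {
    int t = tx[i] - 1;
    int lo = offset[t], hi = offset[t + 1];
    int nE = hi - lo;
    cum.clear();
    int acc = 0;
    for (int k = 0; k < nE; k++) {
      acc += eend[lo + k] - estart[lo + k] + 1;
      cum.push_back(acc);
    }
    int s = tstart[i], L = flen[i];
    int a1 = s, b1 = std::min(s + readLen - 1, s + L - 1);
    int a2 = std::max(s, s + L - readLen), b2 = s + L - 1;
    // junction scan
    int bestGap = -1, bestOver = 0;
    for (int k = 0; k < nE - 1; k++) {
      int C = cum[k];
      int over = 0;
      if (a1 <= C && C + 1 <= b1) {
        int o = std::min(C - a1 + 1, b1 - C);
        if (o > over) over = o;
      }
      if (a2 <= C && C + 1 <= b2) {
        int o = std::min(C - a2 + 1, b2 - C);
        if (o > over) over = o;
      }
      if (over > bestOver) { bestOver = over; bestGap = k; }
    }
    if (bestGap >= 0) {
      int j = jid[jOffset[t] + bestGap];
      assign[i] = -j;
      if (bestOver > maxOver[j - 1]) maxOver[j - 1] = bestOver;
      continue;
    }
    // exon assignment: largest total overlap with the gene's flat exons.
    // Compute the genomic blocks of both mates once, then accumulate
    // per-flat-exon overlap over those few blocks.
    int g = txGene[t] - 1;
    int flo = fgOffset[g], fhi = fgOffset[g + 1];
    int nF = fhi - flo;
    ovl.assign(nF, 0);
    for (int mate = 0; mate < 2; mate++) {
      int a = mate == 0 ? a1 : a2, b = mate == 0 ? b1 : b2;
      int prev = 0;
      for (int k = 0; k < nE; k++) {
        int clo = prev + 1, chi = cum[k];
        prev = cum[k];
        if (chi < a) continue;
        if (clo > b) break;
        int ta = std::max(a, clo), tb = std::min(b, chi);
        int gs = estart[lo + k] + (ta - clo);
        int ge = estart[lo + k] + (tb - clo);
        for (int f = 0; f < nF; f++) {
          int fs = fstart[flo + f], fe = fend[flo + f];
          if (fe < gs) continue;
          if (fs > ge) break;
          ovl[f] += std::min(ge, fe) - std::max(gs, fs) + 1;
        }
      }
    }
    int bestF = 0, bestOv = 0;
    for (int f = 0; f < nF; f++)
      if (ovl[f] > bestOv) { bestOv = ovl[f]; bestF = flo + f + 1; }
    assign[i] = bestF; // 0 when no overlap at all; ties -> leftmost
  }
  return List::create(_["assign"] = assign, _["max_overhang"] = maxOver);
}

// Legacy DEU rule: the fragment contributes one count to EVERY flattened
// exon either mate overlaps by >= 1 bp (set semantics per fragment), and
// junction features do not exist. Returns counts per flat exon.
// [[Rcpp::export]]
IntegerVector count_deu_cpp(IntegerVector tx, IntegerVector tstart,
                            IntegerVector flen, int readLen,
                            IntegerVector estart, IntegerVector eend,
                            IntegerVector offset, IntegerVector txGene,
                            IntegerVector fstart, IntegerVector fend,
                            IntegerVector fgOffset) {
  int n = tx.size();
  int nFlat = fstart.size();
  IntegerVector counts(nFlat);
  std::vector<int> cum; cum.reserve(64);
  std::vector<int> hit; hit.reserve(64);
  for (int i = 0; i < n; i++) {
    int t = tx[i] - 1;
    int lo = offset[t], hi = offset[t + 1];
    int nE = hi - lo;
    cum.clear();
    int acc = 0;
    for (int k = 0; k < nE; k++) {
      acc += eend[lo + k] - estart[lo + k] + 1;
      cum.push_back(acc);
    }
    int s = tstart[i], L = flen[i];
    int a1 = s, b1 = std::min(s + readLen - 1, s + L - 1);
    int a2 = std::max(s, s + L - readLen), b2 = s + L - 1;
    int g = txGene[t] - 1;
    int flo = fgOffset[g], fhi = fgOffset[g + 1];
    int nF = fhi - flo;
    hit.assign(nF, 0);
    for (int mate = 0; mate < 2; mate++) {
      int a = mate == 0 ? a1 : a2, b = mate == 0 ? b1 : b2;
      int prev = 0;
      for (int k = 0; k < nE; k++) {
        int clo = prev + 1, chi = cum[k];
        prev = cum[k];
        if (chi < a) continue;
        if (clo > b) break;
        int ta = std::max(a, clo), tb = std::min(b, chi);
        int gs = estart[lo + k] + (ta - clo);
        int ge = estart[lo + k] + (tb - clo);
        for (int f = 0; f < nF; f++) {
          if (fend[flo + f] < gs) continue;
          if (fstart[flo + f] > ge) break;
          hit[f] = 1;
        }
      }
    }
    for (int f = 0; f < nF; f++) if (hit[f]) counts[flo + f]++;
  }
  return counts;
}
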