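#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman style) alignment of an amino-acid sequence against
// the columns of a position-specific scoring matrix with affine gap costs.
//
// scores : ncol(profile) x nalpha matrix; scores(i, a) is the score (half-bit
//          log-odds) for residue code a aligned to profile column i.
// seq    : 0-based residue codes into the columns of `scores`.
// Gap of length k costs gap_open + k * gap_extend on either side.
// Local alignments start and end in the match state.
//
// Non-overlapping suboptimal hits are recovered greedily: after each
// traceback the covered sequence positions are masked and the DP is rerun.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Hit {
  double score;
  int pstart, pend, sstart, send;      // 1-based inclusive
  std::vector<int> path_p, path_s;     // NA encoded as 0
};

static bool run_dp(const NumericMatrix& S, const IntegerVector& seq,
                   double go, double ge, double min_score,
                   const std::vector<bool>& mask, Hit& out) {
  const int L = S.nrow();        // profile columns
  const int n = seq.size();      // sequence length
  // state matrices, (L+1) x (n+1); index [i][j] = profile col i, seq pos j
  std::vector<double> M((L + 1) * (n + 1), NEG_INF);
  std::vector<double> X((L + 1) * (n + 1), NEG_INF);  // gap in sequence
  std::vector<double> Y((L + 1) * (n + 1), NEG_INF);  // gap in profile
  // traceback: 0 = local start, 1 = from M, 2 = from X, 3 = from Y
  std::vector<unsigned char> tbM((L + 1) * (n + 1), 0);
  std::vector<unsigned char> tbX((L + 1) * (n + 1), 0);
  std::vector<unsigned char> tbY((L + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = at(i, j);
      if (mask[j - 1]) continue;  // all states at masked positions stay -Inf
      // match state
      double prevM = M[at(i - 1, j - 1)], prevX = X[at(i - 1, j - 1)],
             prevY = Y[at(i - 1, j - 1)];
      double cont = 0.0; unsigned char tb = 0;
      if (prevM > cont) { cont = prevM; tb = 1; }
      if (prevX > cont) { cont = prevX; tb = 2; }
      if (prevY > cont) { cont = prevY; tb = 3; }
      double sc = S(i - 1, seq[j - 1]) + cont;
      M[idx] = sc; tbM[idx] = tb;
      if (sc > best) { best = sc; bi = i; bj = j; }
      // gap in sequence (consume profile column i)
      double xo = M[at(i - 1, j)] - go - ge;
      double xe = X[at(i - 1, j)] - ge;
      if (xo >= xe) { X[idx] = xo; tbX[idx] = 1; }
      else          { X[idx] = xe; tbX[idx] = 2; }
      // gap in profile (consume sequence position j)
      double yo = M[at(i, j - 1)] - go - ge;
      double ye = Y[at(i, j - 1)] - ge;
      if (yo >= ye) { Y[idx] = yo; tbY[idx] = 1; }
      else          { Y[idx] = ye; tbY[idx] = 3; }
    }
  }
  if (bi < 0 || best < min_score) return false;

  // traceback from (bi, bj) in match state
  std::vector<int> pp, ps;
  int i = bi, j = bj, state = 1;
  while (state != 0) {
    int idx = at(i, j);
    if (state == 1) {
      pp.push_back(i); ps.push_back(j);
      int nxt = tbM[idx]; --i; --j; state = nxt;
    } else if (state == 2) {
      pp.push_back(i); ps.push_back(0);   // profile col vs gap
      int nxt = tbX[idx]; --i; state = nxt;
    } else {
      pp.push_back(0); ps.push_back(j);   // gap vs sequence residue
      int nxt = tbY[idx]; --j; state = nxt;
    }
  }
  std::reverse(pp.begin(), pp.end());
  std::reverse(ps.begin(), ps.end());
  out.score = best;
  out.pend = bi; out.send = bj;
  out.pstart = i + 1; out.sstart = j + 1;
  out.path_p = pp; out.path_s = ps;
  return true;
}

// [[Rcpp::export(name = ".profile_scan_cpp")]]
List profile_scan_cpp(NumericMatrix scores, IntegerVector seq,
                      double gap_open, double gap_extend,
                      double min_score, int max_hits) {
  const int n = seq.size();
  std::vector<bool> mask(n, false);
  List hits;
  for (int h = 0; h < max_hits; ++h) {
    Hit hit;
    if (!run_dp(scores, seq, gap_open, gap_extend, min_score, mask, hit))
      break;
    for (int j = hit.sstart; j <= hit.send; ++j) mask[j - 1] = true;
    IntegerVector pp(hit.path_p.size()), ps(hit.path_s.size());
    for (size_t k = 0; k < hit.path_p.size(); ++k) {
      pp[k] = hit.path_p[k] == 0 ? NA_INTEGER : hit.path_p[k];
      ps[k] = hit.path_s[k] == 0 ? NA_INTEGER : hit.path_s[k];
    }
    hits.push_back(List::create(
        _["score"] = hit.score,
        _["profile_start"] = hit.pstart, _["profile_end"] = hit.pend,
        _["seq_start"] = hit.sstart, _["seq_end"] = hit.send,
        _["path_profile"] = pp, _["path_seq"] = ps));
  }
  return hits;
}
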