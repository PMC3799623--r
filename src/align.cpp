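#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment of two frequency profiles (Gotoh three-state DP).
//
// Profiles are 4 x L matrices of base frequencies (A,C,G,T); column mass may be
// < 1 when a profile column contains gaps or N, which contribute a score of 0
// against anything. A gap of length l costs gap_open + (l - 1) * gap_extend.
// Ties are broken deterministically: diagonal, then up (gap in b), then left.
//
// Returns moves (1 = diagonal, 2 = up / consume a, 3 = left / consume b) and
// the optimal score.
// [[Rcpp::export(name = ".nw_profiles_cpp")]]
List nw_profiles_cpp(NumericMatrix pa, NumericMatrix pb,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = pa.ncol(), m = pb.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  // column-column substitution score
  // s(i,j) = sum_x sum_y pa(x,i) pb(y,j) * (x==y ? match : mismatch)
  // = mismatch * massA*massB + (match-mismatch) * sum_x pa(x,i)pb(x,j)
  std::vector<double> fa(4 * n), fb(4 * m);
  std::vector<double> massA(n), massB(m);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int x = 0; x < 4; ++x) { fa[4 * i + x] = pa(x, i); s += pa(x, i); }
    massA[i] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0;
    for (int x = 0; x < 4; ++x) { fb[4 * j + x] = pb(x, j); s += pb(x, j); }
    massB[j] = s;
  }

  // traceback: per state, predecessor state at each cell (0=M,1=Ix,2=Iy)
  const size_t W = (size_t)(m + 1);
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);

  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = gap_open + (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    Xcur[0] = gap_open + (i - 1) * gap_extend;
    tbX[i * W] = (i == 1) ? 0 : 1;

    const double* ai = &fa[4 * (i - 1)];
    const double ma = massA[i - 1];
    unsigned char* rM = &tbM[i * W];
    unsigned char* rX = &tbX[i * W];
    unsigned char* rY = &tbY[i * W];
    for (int j = 1; j <= m; ++j) {
      const double* bj = &fb[4 * (j - 1)];
      double dot = ai[0] * bj[0] + ai[1] * bj[1] + ai[2] * bj[2] +
                   ai[3] * bj[3];
      double sub = mismatch * ma * massB[j - 1] + (match - mismatch) * dot;

      // M: from any state at (i-1, j-1); prefer M, then Ix, then Iy
      double best = Mprev[j - 1]; int from = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; from = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; from = 2; }
      Mcur[j] = (best == NEG) ? NEG : best + sub;
      rM[j] = (unsigned char)from;

      // Ix (up, consume a): open from M/Iy, extend from Ix
      best = Mprev[j] + gap_open; from = 0;
      if (Xprev[j] + gap_extend > best) { best = Xprev[j] + gap_extend; from = 1; }
      if (Yprev[j] + gap_open > best)   { best = Yprev[j] + gap_open;   from = 2; }
      Xcur[j] = best;
      rX[j] = (unsigned char)from;

      // Iy (left, consume b)
      best = Mcur[j - 1] + gap_open; from = 0;
      if (Xcur[j - 1] + gap_open > best)   { best = Xcur[j - 1] + gap_open;   from = 1; }
      if (Ycur[j - 1] + gap_extend > best) { best = Ycur[j - 1] + gap_extend; from = 2; }
      Ycur[j] = best;
      rY[j] = (unsigned char)from;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  double score = Mprev[m]; int state = 0;
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }

  // traceback needs full matrices only for the predecessor states, which we
  // stored; the path is reconstructed from (n, m) backwards
  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0)      { prev = tbM[i * W + j]; moves.push_back(1); --i; --j; }
    else if (state == 1) { prev = tbX[i * W + j]; moves.push_back(2); --i; }
    else                 { prev = tbY[i * W + j]; moves.push_back(3); --j; }
    state = prev;
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["moves"] = wrap(moves), _["score"] = score);
}
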