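#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Gotoh three-state affine-gap alignment with full traceback.
// States: M (match/mismatch), X (gap in b, consumes a), Y (gap in a,
// consumes b). A gap of length L costs open + (L-1)*extend.
// Traceback ties are broken diagonal (M) > up (X) > left (Y).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_cpp(std::string a, std::string b, NumericMatrix smat,
               std::string chars, double gap_open, double gap_extend,
               bool local) {
  int n = a.size(), m = b.size();
  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < chars.size(); ++k)
    lut[(unsigned char)chars[k]] = (int)k;
  std::vector<int> ai(n), bj(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character not in substitution alphabet");
  }
  for (int j = 0; j < m; ++j) {
    bj[j] = lut[(unsigned char)b[j]];
    if (bj[j] < 0) stop("character not in substitution alphabet");
  }

  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // predecessor state of each cell: 0=M, 1=X, 2=Y, 3=fresh start
  std::vector<unsigned char> tbM((n + 1) * W, 3), tbX((n + 1) * W, 3),
      tbY((n + 1) * W, 3);

  M[0] = 0.0;
  if (local) {
    for (int i = 1; i <= n; ++i) M[i * W] = 0.0;
    for (int j = 1; j <= m; ++j) M[j] = 0.0;
  } else {
    for (int i = 1; i <= n; ++i) {
      X[i * W] = -(gap_open + (i - 1) * gap_extend);
      tbX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = -(gap_open + (j - 1) * gap_extend);
      tbY[j] = (j == 1) ? 0 : 2;
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1,
          dg = (i - 1) * W + j - 1;
      double s = smat(ai[i - 1], bj[j - 1]);
      double mm = M[dg], mx = X[dg], my = Y[dg];
      double md = std::max(mm, std::max(mx, my));
      double mval = md + s;
      unsigned char mtb = (md == mm) ? 0 : ((md == mx) ? 1 : 2);
      if (local && mval < 0.0) { mval = 0.0; mtb = 3; }
      M[c] = mval; tbM[c] = mtb;
      double xo = M[up] - gap_open, xe = X[up] - gap_extend,
             xy = Y[up] - gap_open;
      double xv = std::max(xo, std::max(xe, xy));
      X[c] = xv;
      tbX[c] = (xv == xo) ? 0 : ((xv == xe) ? 1 : 2);
      double yo = M[lf] - gap_open, ye = Y[lf] - gap_extend,
             yx = X[lf] - gap_open;
      double yv = std::max(yo, std::max(ye, yx));
      Y[c] = yv;
      tbY[c] = (yv == yo) ? 0 : ((yv == ye) ? 2 : 1);
      if (local && M[c] > best) { best = M[c]; best_i = i; best_j = j; }
    }
  }

  double score;
  int i, j, state = 0;
  std::string ra, rb;

  if (local) {
    score = best;
    i = best_i; j = best_j;
    while (i > 0 && j > 0) {
      int c = i * W + j;
      if (state == 0) {
        if (M[c] <= 0.0) break;
        unsigned char prev = tbM[c];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        if (prev == 3) break;
        state = prev;
      } else if (state == 1) {
        unsigned char prev = tbX[c];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        state = prev;
      } else {
        unsigned char prev = tbY[c];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        state = prev;
      }
    }
  } else {
    int c = n * W + m;
    double fm = M[c], fx = X[c], fy = Y[c];
    score = std::max(fm, std::max(fx, fy));
    state = (score == fm) ? 0 : ((score == fx) ? 1 : 2);
    i = n; j = m;
    while (i > 0 || j > 0) {
      c = i * W + j;
      if (state == 0) {
        unsigned char prev = tbM[c];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        state = prev;
      } else if (state == 1) {
        unsigned char prev = tbX[c];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        state = prev;
      } else {
        unsigned char prev = tbY[c];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        state = prev;
      }
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
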