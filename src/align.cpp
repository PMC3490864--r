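#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh), end gaps penalised.
// Gap cost convention: a gap of length L costs open + (L-1) * extend,
// i.e. `open` is charged at the first gapped column and `extend` per
// additional column.
//
// Deterministic tie-breaking: on equal score prefer substitution (M) over
// gap in sequence a (consuming b) over gap in sequence b (consuming a),
// both when choosing the final state and at every traceback step.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, NumericMatrix sub,
                 CharacterVector alphabet, double open_pen, double extend_pen) {
  const int n = a.size(), m = b.size();
  // residue -> matrix index
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)(as<std::string>(alphabet[i])[0])] = i;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue not in substitution alphabet: %c", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue not in substitution alphabet: %c", b[j]);
  }

  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), Ia((n + 1) * W, NEG_INF),
      Ib((n + 1) * W, NEG_INF);
  // traceback pointers: previous state 0=M, 1=Ia, 2=Ib
  std::vector<signed char> pM((n + 1) * W, -1), pIa((n + 1) * W, -1),
      pIb((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {  // leading gap in a (consumes b)
    Ia[j] = -(open_pen + (j - 1) * extend_pen);
    pIa[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {  // leading gap in b (consumes a)
    Ib[i * W] = -(open_pen + (i - 1) * extend_pen);
    pIb[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: align a[i-1] with b[j-1]
      double best = M[d];
      signed char arg = 0;
      if (Ia[d] > best) { best = Ia[d]; arg = 1; }
      if (Ib[d] > best) { best = Ib[d]; arg = 2; }
      if (best > NEG_INF / 2) {
        M[c] = best + sub(ai[i - 1], bi[j - 1]);
        pM[c] = arg;
      }
      // Ia: gap in a at this column (consumes b[j-1])
      best = (M[l] > NEG_INF / 2) ? M[l] - open_pen : NEG_INF;
      arg = 0;
      if (Ia[l] - extend_pen > best) { best = Ia[l] - extend_pen; arg = 1; }
      if (Ib[l] - open_pen > best) { best = Ib[l] - open_pen; arg = 2; }
      if (best > NEG_INF / 2) { Ia[c] = best; pIa[c] = arg; }
      // Ib: gap in b at this column (consumes a[i-1])
      best = (M[u] > NEG_INF / 2) ? M[u] - open_pen : NEG_INF;
      arg = 0;
      if (Ia[u] - open_pen > best) { best = Ia[u] - open_pen; arg = 1; }
      if (Ib[u] - extend_pen > best) { best = Ib[u] - extend_pen; arg = 2; }
      if (best > NEG_INF / 2) { Ib[c] = best; pIb[c] = arg; }
    }
  }

  const size_t end = n * W + m;
  double score = M[end];
  int state = 0;
  if (Ia[end] > score) { score = Ia[end]; state = 1; }
  if (Ib[end] > score) { score = Ib[end]; state = 2; }

  // traceback
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (state == 0) {
      int prev = pM[c];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = pIa[c];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = prev;
    } else {
      int prev = pIb[c];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
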