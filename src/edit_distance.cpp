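#include <Rcpp.h>

using namespace Rcpp;

// Decode a UTF-8 byte string into code points so that distances are
// per-character, not per-byte (unit strings may carry e.g. micro signs).
static std::vector<int> utf8_codepoints(const char *s) {
  std::vector<int> out;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(s);
  while (*p) {
    int cp, extra;
    if (*p < 0x80)      { cp = *p;         extra = 0; }
    else if (*p < 0xE0) { cp = *p & 0x1F;  extra = 1; }
    else if (*p < 0xF0) { cp = *p & 0x0F;  extra = 2; }
    else                { cp = *p & 0x07;  extra = 3; }
    ++p;
    for (int k = 0; k < extra && *p; ++k, ++p) cp = (cp << 6) | (*p & 0x3F);
    out.push_back(cp);
  }
  return out;
}

static int edit_distance_one(const std::vector<int> &a, const std::vector<int> &b,
                             int sub_cost) {
  const int n = static_cast<int>(a.size());
  const int m = static_cast<int>(b.size());
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      const int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : sub_cost);
      cur[j] = std::min(del, std::min(ins, sub));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Pairwise (recycled) edit distance between two character vectors.
// sub_cost = 1 gives the plain Levenshtein distance; sub_cost = 2 makes a
// substitution as expensive as a deletion plus an insertion, which is the
// distance underlying the matching-blocks similarity ratio.
// [[Rcpp::export]]
IntegerVector edit_distance_cpp(CharacterVector a, CharacterVector b, int sub_cost) {
  const R_xlen_t na = a.size(), nb = b.size();
  const R_xlen_t n = std::max(na, nb);
  IntegerVector out(n);
  if (na == 0 || nb == 0) return IntegerVector(0);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[i % na], sb = b[i % nb];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::vector<int> va = utf8_codepoints(Rf_translateCharUTF8(sa.get_sexp()));
    std::vector<int> vb = utf8_codepoints(Rf_translateCharUTF8(sb.get_sexp()));
    out[i] = edit_distance_one(va, vb, sub_cost);
  }
  return out;
}

// Number of code points, matching the distance's notion of length.
// [[Rcpp::export]]
IntegerVector utf8_length_cpp(CharacterVector a) {
  const R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String s = a[i];
    if (s == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = static_cast<int>(utf8_codepoints(Rf_translateCharUTF8(s.get_sexp())).size());
  }
  return out;
}
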