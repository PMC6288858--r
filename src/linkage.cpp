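#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Jaro similarity of two C strings. Matching window is
// floor(max(la, lb) / 2) - 1, never negative. Returns 0 when either
// string is empty or no characters match.
static double jaro_sim(const char *a, int la, const char *b, int lb) {
  if (la == 0 || lb == 0) return 0.0;
  int win = std::max(la, lb) / 2 - 1;
  if (win < 0) win = 0;

  std::vector<char> a_match(la, 0), b_match(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    int lo = std::max(0, i - win), hi = std::min(lb - 1, i + win);
    for (int j = lo; j <= hi; ++j) {
      if (!b_match[j] && a[i] == b[j]) {
        a_match[i] = 1; b_match[j] = 1; ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;

  // transpositions: matched characters out of order, counted half each
  int t2 = 0, k = 0;
  for (int i = 0; i < la; ++i) {
    if (!a_match[i]) continue;
    while (!b_match[k]) ++k;
    if (a[i] != b[k]) ++t2;
    ++k;
  }
  double t = t2 / 2.0;
  return (m / (double)la + m / (double)lb + (m - t) / m) / 3.0;
}

static double jw_sim(const char *a, int la, const char *b, int lb,
                     double prefix_scale, int max_prefix) {
  double j = jaro_sim(a, la, b, lb);
  if (j <= 0.0) return j;
  int lim = std::min(std::min(la, lb), max_prefix);
  int p = 0;
  while (p < lim && a[p] == b[p]) ++p;
  return j + p * prefix_scale * (1.0 - j);
}

// [[Rcpp::export(name = ".jw_cpp")]]
NumericVector jw_cpp(CharacterVector a, CharacterVector b,
                     double prefix_scale, int max_prefix) {
  R_xlen_t n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = a[i % a.size()], sb = b[i % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_REAL; continue; }
    const char *ca = CHAR(sa), *cb = CHAR(sb);
    out[i] = jw_sim(ca, std::strlen(ca), cb, std::strlen(cb),
                    prefix_scale, max_prefix);
  }
  return out;
}

// Best cross-pair Jaro-Winkler between two name lists (one row of a
// CharacterMatrix each). Returns -1 if either side has no name.
static double best_name_sim(const CharacterMatrix &A, int ia,
                            const CharacterMatrix &B, int ib,
                            double prefix_scale, int max_prefix) {
  double best = -1.0;
  for (int i = 0; i < A.ncol(); ++i) {
    SEXP sa = A(ia, i);
    if (sa == NA_STRING) continue;
    const char *ca = CHAR(sa);
    int la = std::strlen(ca);
    if (la == 0) continue;
    for (int j = 0; j < B.ncol(); ++j) {
      SEXP sb = B(ib, j);
      if (sb == NA_STRING) continue;
      const char *cb = CHAR(sb);
      int lb = std::strlen(cb);
      if (lb == 0) continue;
      double s = jw_sim(ca, la, cb, lb, prefix_scale, max_prefix);
      if (s > best) best = s;
    }
  }
  return best;
}

// Score aligned pairs: row i of the encounter matrices against row i of the
// person matrices. Same field schema as link_best_cpp below.
// [[Rcpp::export(name = ".score_aligned_cpp")]]
NumericVector score_aligned_cpp(CharacterMatrix enc_name, CharacterMatrix enc_hh,
                                CharacterMatrix enc_tcl, CharacterMatrix enc_exact,
                                CharacterMatrix per_name, CharacterMatrix per_hh,
                                CharacterMatrix per_tcl, CharacterMatrix per_exact,
                                NumericVector m, NumericVector u,
                                double jw_threshold, double prefix_scale,
                                int max_prefix) {
  const int n = enc_name.nrow(), nf = 9;
  if (per_name.nrow() != n) stop("row mismatch");
  std::vector<double> wa(nf), wd(nf);
  for (int f = 0; f < nf; ++f) {
    wa[f] = std::log2(m[f] / u[f]);
    wd[f] = std::log2((1.0 - m[f]) / (1.0 - u[f]));
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double score = 0.0;
    const CharacterMatrix *EA[3] = {&enc_name, &enc_hh, &enc_tcl};
    const CharacterMatrix *PA[3] = {&per_name, &per_hh, &per_tcl};
    const int fidx[3] = {0, 7, 8};
    for (int k = 0; k < 3; ++k) {
      double s = best_name_sim(*EA[k], i, *PA[k], i, prefix_scale, max_prefix);
      if (s < 0) continue;
      score += (s >= jw_threshold) ? wa[fidx[k]] : wd[fidx[k]];
    }
    for (int c = 0; c < 6; ++c) {
      SEXP se = enc_exact(i, c), sp = per_exact(i, c);
      if (se == NA_STRING || sp == NA_STRING) continue;
      score += (std::strcmp(CHAR(se), CHAR(sp)) == 0) ? wa[c + 1] : wd[c + 1];
    }
    out[i] = score;
  }
  return out;
}

// Fellegi-Sunter scoring of every encounter against every registry person,
// keeping the best-scoring person per encounter.
//
// Field order (9): name, sex, birth_year, birth_month, birth_day, village,
// sub_village, hh_member_name, tcl_name. Name-type fields (1, 8, 9) use the
// permutation-invariant max-Jaro-Winkler rule; the rest exact equality.
// enc_exact / per_exact hold the six exact fields as character columns in
// the order above (NA = absent).
//
// Tie-break among equal best scores: fewest disagreeing fields, then lowest
// row index (caller passes the registry sorted by person_id). `tie` is TRUE
// when >= 2 persons attain the final best score.
// [[Rcpp::export(name = ".link_best_cpp")]]
List link_best_cpp(CharacterMatrix enc_name, CharacterMatrix enc_hh,
                   CharacterMatrix enc_tcl, CharacterMatrix enc_exact,
                   CharacterMatrix per_name, CharacterMatrix per_hh,
                   CharacterMatrix per_tcl, CharacterMatrix per_exact,
                   NumericVector m, NumericVector u,
                   double jw_threshold, double prefix_scale, int max_prefix) {
  const int ne = enc_name.nrow(), np = per_name.nrow(), nf = 9;
  if (m.size() != nf || u.size() != nf)
    stop("m and u must have length 9");
  std::vector<double> wa(nf), wd(nf);
  for (int f = 0; f < nf; ++f) {
    if (!(u[f] > 0 && m[f] > u[f] && m[f] < 1))
      stop("require 0 < u < m < 1 for every field");
    wa[f] = std::log2(m[f] / u[f]);
    wd[f] = std::log2((1.0 - m[f]) / (1.0 - u[f]));
  }
  const double eps = 1e-9;

  IntegerVector best_idx(ne), best_dis(ne);
  NumericVector best_score(ne);
  LogicalVector tie(ne);

  for (int e = 0; e < ne; ++e) {
    double bs = R_NegInf;
    int bi = -1, bd = 0;
    bool btie = false;
    for (int p = 0; p < np; ++p) {
      double score = 0.0;
      int dis = 0;
      // name-type fields: (matrix pair, field index)
      const CharacterMatrix *EA[3] = {&enc_name, &enc_hh, &enc_tcl};
      const CharacterMatrix *PA[3] = {&per_name, &per_hh, &per_tcl};
      const int fidx[3] = {0, 7, 8};
      for (int k = 0; k < 3; ++k) {
        double s = best_name_sim(*EA[k], e, *PA[k], p, prefix_scale, max_prefix);
        if (s < 0) continue;            // missing on one side
        if (s >= jw_threshold) score += wa[fidx[k]];
        else { score += wd[fidx[k]]; ++dis; }
      }
      // exact fields 2..7 -> columns 0..5 of *_exact
      for (int c = 0; c < 6; ++c) {
        SEXP se = enc_exact(e, c), sp = per_exact(p, c);
        if (se == NA_STRING || sp == NA_STRING) continue;
        if (std::strcmp(CHAR(se), CHAR(sp)) == 0) score += wa[c + 1];
        else { score += wd[c + 1]; ++dis; }
      }
      if (score > bs + eps) {
        bs = score; bi = p; bd = dis; btie = false;
      } else if (score > bs - eps) {
        btie = true;
        if (dis < bd) { bi = p; bd = dis; }
      }
    }
    best_idx[e] = bi + 1;  // 1-based
    best_score[e] = bs;
    best_dis[e] = bd;
    tie[e] = btie;
  }
  return List::create(_["person_idx"] = best_idx,
                      _["match_score"] = best_score,
                      _["n_disagree"] = best_dis,
                      _["tie"] = tie);
}
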