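#include <Rcpp.h>
using namespace Rcpp;

// Two-dimensional Pareto-front kernels.
//
// All kernels operate on an n x 2 matrix of score pairs. Orientation is
// handled by sign factors sa, sb in {+1,-1} (+1 = maximize), so stored
// scores keep their original scale. `eps` is an optional absolute
// tolerance: |u - v| <= eps counts as equal (default 0 = exact).
//
// Every oriented scalar comparison bumps a counter, giving a
// hardware-independent cost measure for the complexity checks.

namespace {

struct Cmp {
  double sa, sb, eps;
  long long count;
  Cmp(double sa_, double sb_, double eps_) : sa(sa_), sb(sb_), eps(eps_), count(0) {}
  // oriented three-way comparison in dimension A (resp. B)
  int a(double u, double v) {
    ++count;
    double d = sa * (u - v);
    if (d > eps) return 1;
    if (d < -eps) return -1;
    return 0;
  }
  int b(double u, double v) {
    ++count;
    double d = sb * (u - v);
    if (d > eps) return 1;
    if (d < -eps) return -1;
    return 0;
  }
};

inline bool dominates_cc(int ca, int cb) {
  // first pair dominates second given three-way results
  return (ca > 0 && cb >= 0) || (ca >= 0 && cb > 0);
}

void check_sorted_front(const NumericMatrix& m, Cmp& cmp, const char* who) {
  const int n = m.nrow();
  for (int i = 1; i < n; ++i) {
    int ca = cmp.a(m(i - 1, 0), m(i, 0));
    int cb = cmp.b(m(i - 1, 1), m(i, 1));
    if (!(ca > 0 && cb < 0))
      stop("%s: input is not a sorted Pareto list (row %d)", who, i + 1);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_pf_lex(NumericMatrix m, double sa, double sb, double eps, bool check) {
  Cmp cmp(sa, sb, eps);
  const int n = m.nrow();
  if (check) {
    for (int i = 1; i < n; ++i) {
      int ca = cmp.a(m(i - 1, 0), m(i, 0));
      if (ca < 0 || (ca == 0 && cmp.b(m(i - 1, 1), m(i, 1)) < 0))
        stop("pf_lex: input is not sorted in decreasing lexicographic order (row %d)", i + 1);
    }
  }
  std::vector<int> out;
  out.reserve(64);
  for (int i = 0; i < n; ++i) {
    if (out.empty()) {
      out.push_back(i);
      continue;
    }
    // last kept element (x, y); keep (a, b) only if it improves dimension B
    double y = m(out.back(), 1);
    if (cmp.b(y, m(i, 1)) >= 0) continue;
    out.push_back(i);
  }
  return List::create(_["idx"] = wrap(out), _["comparisons"] = (double)cmp.count);
}

// [[Rcpp::export]]
List cpp_pf_isort(NumericMatrix m, double sa, double sb, double eps) {
  Cmp cmp(sa, sb, eps);
  const int n = m.nrow();
  std::vector<int> out;
  out.reserve(64);
  // rewrite system processes list head against pf of the remainder,
  // hence elements are inserted from the last to the first
  for (int i = n - 1; i >= 0; --i) {
    const double a = m(i, 0), b = m(i, 1);
    size_t p = 0;
    for (;;) {
      if (p == out.size()) {
        out.push_back(i);
        break;
      }
      const double x = m(out[p], 0), y = m(out[p], 1);
      const int ca = cmp.a(a, x);
      if (ca > 0) {
        // insert before (x,y); then remove following elements with b >= y'
        out.insert(out.begin() + p, i);
        size_t q = p + 1;
        while (q < out.size() && cmp.b(b, m(out[q], 1)) >= 0)
          out.erase(out.begin() + q);
        break;
      } else if (ca == 0) {
        if (cmp.b(b, y) > 0) {
          out[p] = i; // (a,b) supersedes (x,y)
          size_t q = p + 1;
          while (q < out.size() && cmp.b(b, m(out[q], 1)) >= 0)
            out.erase(out.begin() + q);
        }
        break; // b <= y: new element dominated (or duplicate)
      } else {
        if (cmp.b(b, y) > 0) {
          ++p; // incomparable, keep scanning
          continue;
        }
        break; // a < x, b <= y: dominated
      }
    }
  }
  return List::create(_["idx"] = wrap(out), _["comparisons"] = (double)cmp.count);
}

// [[Rcpp::export]]
List cpp_pf_nosort(NumericMatrix m, double sa, double sb, double eps) {
  Cmp cmp(sa, sb, eps);
  const int n = m.nrow();
  std::vector<int> out;
  out.reserve(64);
  for (int i = n - 1; i >= 0; --i) {
    const double a = m(i, 0), b = m(i, 1);
    bool keep = true;
    size_t j = 0;
    while (j < out.size()) {
      const int ca = cmp.a(a, m(out[j], 0));
      const int cb = cmp.b(b, m(out[j], 1));
      if (ca == 0 && cb == 0) { keep = false; break; }   // duplicate
      if (dominates_cc(ca, cb)) {                        // new dominates old
        out.erase(out.begin() + j);
        continue;
      }
      if (dominates_cc(-ca, -cb)) { keep = false; break; } // old dominates new
      ++j;
    }
    if (keep) out.push_back(i);
  }
  return List::create(_["idx"] = wrap(out), _["comparisons"] = (double)cmp.count);
}

// [[Rcpp::export]]
List cpp_pf_smooth(NumericMatrix m, double sa, double sb, double eps) {
  Cmp cmp(sa, sb, eps);
  const int n = m.nrow();
  std::vector<int> out;
  out.reserve(64);
  long long repairs = 0; // firings of the out-of-order rules
  int t = 0;
  while (t < n) {
    const double a = m(t, 0), b = m(t, 1);
    if (out.empty()) {
      out.push_back(t);
      ++t;
      continue;
    }
    const double x = m(out.back(), 0), y = m(out.back(), 1);
    const int ca = cmp.a(a, x);
    if (ca > 0 || (ca == 0 && cmp.b(b, y) > 0)) {
      // out of order (or the new pair dominates the last kept one)
      if (cmp.b(b, y) >= 0) {
        out.pop_back(); // last kept element is dominated; re-examine (a,b)
        ++repairs;
        continue;
      }
      // a > x, b < y: insert into the prefix from the low end, keep (x,y)
      ++repairs;
      int p = (int)out.size() - 1; // pinned last element
      int k = p - 1;
      bool placed = false;
      while (!placed) {
        if (k < 0) {
          out.insert(out.begin(), t);
          placed = true;
          break;
        }
        const int ca2 = cmp.a(a, m(out[k], 0));
        const int cb2 = cmp.b(b, m(out[k], 1));
        if (ca2 == 0 && cb2 == 0) { placed = true; break; } // duplicate vanishes
        if (dominates_cc(ca2, cb2)) {
          out.erase(out.begin() + k);
          --k;
          continue;
        }
        if (dominates_cc(-ca2, -cb2)) { placed = true; break; } // new vanishes
        if (ca2 > 0) { --k; continue; }
        out.insert(out.begin() + k + 1, t);
        placed = true;
      }
      ++t;
      continue;
    }
    // in order: plain single-pass rules
    if (cmp.b(y, b) >= 0) {
      ++t; // dominated by last kept element
    } else {
      out.push_back(t);
      ++t;
    }
  }
  return List::create(_["idx"] = wrap(out), _["comparisons"] = (double)cmp.count,
                      _["repairs"] = (double)repairs);
}

// [[Rcpp::export]]
List cpp_pareto_merge(NumericMatrix mx, NumericMatrix my, double sa, double sb,
                      double eps, bool check) {
  Cmp cmp(sa, sb, eps);
  if (check) {
    check_sorted_front(mx, cmp, "pareto_merge");
    check_sorted_front(my, cmp, "pareto_merge");
  }
  const int nx = mx.nrow(), ny = my.nrow();
  std::vector<int> src, idx;
  src.reserve(nx + ny);
  idx.reserve(nx + ny);
  int ix = 0, iy = 0;
  while (ix < nx && iy < ny) {
    const double a = mx(ix, 0), b = mx(ix, 1);
    const double c = my(iy, 0), d = my(iy, 1);
    const int ca = cmp.a(a, c);
    const int cb = cmp.b(b, d);
    if (ca > 0) {
      src.push_back(1); idx.push_back(ix); ++ix;
      if (cb > 0) {
        while (iy < ny && cmp.b(my(iy, 1), b) <= 0) ++iy; // dropWhile on y
      } else if (cb == 0) {
        ++iy;
      } // cb < 0: keep y head
    } else if (ca == 0) {
      if (cb > 0) {
        src.push_back(1); idx.push_back(ix); ++ix;
        while (iy < ny && cmp.b(my(iy, 1), b) <= 0) ++iy;
      } else if (cb == 0) {
        src.push_back(1); idx.push_back(ix); ++ix; ++iy; // duplicates collapse
      } else {
        src.push_back(2); idx.push_back(iy); ++iy;
        while (ix < nx && cmp.b(mx(ix, 1), d) <= 0) ++ix; // dropWhile on x
      }
    } else {
      src.push_back(2); idx.push_back(iy); ++iy;
      if (cb > 0) {
        // keep x head
      } else if (cb == 0) {
        ++ix;
      } else {
        while (ix < nx && cmp.b(mx(ix, 1), d) <= 0) ++ix;
      }
    }
  }
  for (; ix < nx; ++ix) { src.push_back(1); idx.push_back(ix); }
  for (; iy < ny; ++iy) { src.push_back(2); idx.push_back(iy); }
  return List::create(_["src"] = wrap(src), _["idx"] = wrap(idx),
                      _["comparisons"] = (double)cmp.count);
}

// [[Rcpp::export]]
bool cpp_is_sorted_front(NumericMatrix m, double sa, double sb, double eps) {
  Cmp cmp(sa, sb, eps);
  const int n = m.nrow();
  for (int i = 1; i < n; ++i) {
    int ca = cmp.a(m(i - 1, 0), m(i, 0));
    int cb = cmp.b(m(i - 1, 1), m(i, 1));
    if (!(ca > 0 && cb < 0)) return false;
  }
  return true;
}
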