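#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Pedigree kinship by memoised recursion. Animals are 1..n in topological
// order (parents precede offspring), 0 = unknown parent. Keys pack the
// ordered pair into a 64-bit integer; depth is bounded by pedigree depth.
namespace {

struct KinshipCache {
  const int *sire;
  const int *dam;
  long long n;
  std::unordered_map<long long, double> memo;

  KinshipCache(const int *s, const int *d, int n_) : sire(s), dam(d), n(n_) {}

  double kin(int i, int j) {
    if (i == 0 || j == 0) return 0.0;
    if (i > j) std::swap(i, j);
    long long key = (long long)(i - 1) * n + (j - 1);
    auto hit = memo.find(key);
    if (hit != memo.end()) return hit->second;
    double v;
    if (i == j) {
      v = 0.5 * (1.0 + kin(sire[i - 1], dam[i - 1]));
    } else {
      // j is the younger animal (topological order), recurse on its parents
      v = 0.5 * (kin(i, sire[j - 1]) + kin(i, dam[j - 1]));
    }
    memo[key] = v;
    return v;
  }
};

} // namespace

// Inbreeding coefficients F_i = kinship(sire_i, dam_i), exact for any
// topologically ordered pedigree.
// [[Rcpp::export(name = ".cpp_inbreeding")]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  KinshipCache kc(INTEGER(sire), INTEGER(dam), n);
  NumericVector F(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s < 0 || s > i || d < 0 || d > i)
      stop("pedigree is not topologically ordered at animal %d", i + 1);
    F[i] = kc.kin(s, d);
  }
  return F;
}

// Henderson's rules with inbreeding: triplet contributions to A^{-1}.
// d_i is the Mendelian-sampling variance given parental inbreeding.
// [[Rcpp::export(name = ".cpp_ainv_triplets")]]
List cpp_ainv_triplets(IntegerVector sire, IntegerVector dam, NumericVector F) {
  int n = sire.size();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(9 * n); tj.reserve(9 * n); tx.reserve(9 * n);
  auto push = [&](int i, int j, double x) {
    ti.push_back(i); tj.push_back(j); tx.push_back(x);
  };
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    double ds;
    if (s > 0 && d > 0) {
      ds = 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
    } else if (s > 0) {
      ds = 0.75 - 0.25 * F[s - 1];
    } else if (d > 0) {
      ds = 0.75 - 0.25 * F[d - 1];
    } else {
      ds = 1.0;
    }
    double b = 1.0 / ds;
    push(i, i, b);
    if (s > 0) {
      push(s, s, 0.25 * b);
      push(i, s, -0.5 * b);
      push(s, i, -0.5 * b);
    }
    if (d > 0) {
      push(d, d, 0.25 * b);
      push(i, d, -0.5 * b);
      push(d, i, -0.5 * b);
    }
    if (s > 0 && d > 0) {
      push(s, d, 0.25 * b);
      push(d, s, 0.25 * b);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
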