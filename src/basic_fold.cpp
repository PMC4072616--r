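#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Simplified base-pair scoring used by the built-in "basic" backend.
// Energies are coarse stand-ins on the kcal/mol scale: 3 H-bonds for G-C,
// 2 for A-U, 1 for the G.U wobble.  INF marks a forbidden pair.
static const double INF = std::numeric_limits<double>::infinity();

static double pair_e(int a, int b) {
  // encoding: A=0, C=1, G=2, U=3
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0;
  return INF;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'U': v[i] = 3; break;
      default: stop("non-ACGU character '%s' in sequence", std::string(1, s[i]));
    }
  }
  return v;
}

// Minimum hairpin loop size (unpaired bases enclosed by a pair).
static const int MIN_LOOP = 3;
// Bonus when a pair stacks directly on the enclosed pair.
static const double STACK_BONUS = -1.0;

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq) {
  std::vector<int> x = encode(seq);
  int n = (int)x.size();
  std::string db(n, '.');
  if (n < MIN_LOOP + 2) {
    return List::create(_["structure"] = db, _["dg"] = 0.0);
  }
  // V(i,j): best energy with (i,j) paired; W(i,j): best energy on [i,j].
  NumericMatrix V(n, n), W(n, n);
  std::fill(V.begin(), V.end(), INF);
  std::fill(W.begin(), W.end(), 0.0);

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double pe = pair_e(x[i], x[j]);
      if (pe < INF) {
        double best = 0.0; // hairpin closing (i,j), loop >= MIN_LOOP
        if (j - i - 1 > MIN_LOOP) {
          if (V(i + 1, j - 1) < INF)
            best = std::min(best, V(i + 1, j - 1) + STACK_BONUS);
          best = std::min(best, W(i + 1, j - 1));
        }
        V(i, j) = pe + best;
      }
      double w = W(i, j - 1); // j unpaired
      for (int k = i; k + MIN_LOOP + 1 <= j; ++k) {
        if (V(k, j) == INF) continue;
        double left = (k > i) ? W(i, k - 1) : 0.0;
        w = std::min(w, left + V(k, j));
      }
      W(i, j) = std::min(w, 0.0);
    }
  }

  // traceback
  std::vector<std::pair<int, int>> stack;
  std::vector<std::pair<int, int>> vstack;
  stack.push_back({0, n - 1});
  const double EPS = 1e-9;
  while (!stack.empty() || !vstack.empty()) {
    if (!vstack.empty()) {
      int i = vstack.back().first, j = vstack.back().second;
      vstack.pop_back();
      db[i] = '(';
      db[j] = ')';
      double pe = pair_e(x[i], x[j]);
      double inner = V(i, j) - pe;
      if (std::abs(inner) < EPS) continue; // hairpin
      if (j - i - 1 > MIN_LOOP && V(i + 1, j - 1) < INF &&
          std::abs(inner - (V(i + 1, j - 1) + STACK_BONUS)) < EPS) {
        vstack.push_back({i + 1, j - 1});
      } else {
        stack.push_back({i + 1, j - 1});
      }
      continue;
    }
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < MIN_LOOP + 1) continue;
    double w = W(i, j);
    if (std::abs(w) < EPS) continue;
    if (std::abs(w - W(i, j - 1)) < EPS) {
      stack.push_back({i, j - 1});
      continue;
    }
    bool done = false;
    for (int k = i; k + MIN_LOOP + 1 <= j && !done; ++k) {
      if (V(k, j) == INF) continue;
      double left = (k > i) ? W(i, k - 1) : 0.0;
      if (std::abs(w - (left + V(k, j))) < EPS) {
        if (k > i) stack.push_back({i, k - 1});
        vstack.push_back({k, j});
        done = true;
      }
    }
  }

  double dg = W(0, n - 1);
  if (dg >= 0.0) { // open-chain floor
    return List::create(_["structure"] = std::string(n, '.'), _["dg"] = 0.0);
  }
  return List::create(_["structure"] = db, _["dg"] = dg);
}

// Intermolecular-only duplex MFE (RNAhybrid-style model): the short
// sequence pairs antiparallel against any site of the long one; bulges and
// interior loops up to 3 nt per side are allowed, no intramolecular pairs.
// [[Rcpp::export]]
double duplex_mfe_cpp(std::string short_seq, std::string long_seq) {
  std::vector<int> s = encode(short_seq), u = encode(long_seq);
  int m = (int)s.size(), n = (int)u.size();
  const double LOOP_COST = 0.7; // per unpaired bulge/interior base
  // E(a,b): best duplex energy with s[a] paired to u[b] as the 5'-most
  // (on s) pair; extension moves a forward and b backward.
  std::vector<std::vector<double>> E(m, std::vector<double>(n, INF));
  double best = 0.0;
  for (int a = m - 1; a >= 0; --a) {
    for (int b = 0; b < n; ++b) {
      double pe = pair_e(s[a], u[b]);
      if (pe == INF) continue;
      double e = pe;
      double ext = 0.0;
      for (int da = 1; da <= 4; ++da) {
        for (int db_ = 1; db_ <= 4; ++db_) {
          if (da > 1 && db_ > 1 && da + db_ > 5) continue;
          int a2 = a + da, b2 = b - db_;
          if (a2 >= m || b2 < 0) continue;
          if (E[a2][b2] == INF) continue;
          double cost = (da == 1 && db_ == 1)
                          ? STACK_BONUS
                          : LOOP_COST * ((da - 1) + (db_ - 1));
          ext = std::min(ext, E[a2][b2] + cost);
        }
      }
      E[a][b] = e + ext;
      best = std::min(best, E[a][b]);
    }
  }
  return best;
}
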