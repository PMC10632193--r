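#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Functional-pruning optimal partitioning for the Gaussian mean-shift model.
//
// Minimises  sum_j sum_{i in seg j} (y_i - mu_j)^2 + D * beta  over all
// segmentations (D = number of changepoints) by maintaining the optimal
// penalised cost of y[1..t] as a function of the last segment's mean:
// a piecewise-quadratic envelope updated with the Viterbi-style recursion
//   Cost_{t+1}(mu) = min(Cost_t(mu), F_t + beta) + (y_{t+1} - mu)^2,
// where F_t = min_mu Cost_t(mu).  The min with a constant is applied piece
// by piece (interval pruning); adding the new point's cost shifts every
// piece identically, so interval boundaries only move at truncation time.
//
// Tie-breaking: where a piece equals the truncation level the incumbent
// piece is kept (a changepoint needs a strict improvement), and among
// pieces attaining F_t the one with the earliest candidate changepoint
// wins. This yields parsimony-first, deterministic output.

namespace {

struct Piece {
  int s;        // candidate last changepoint (0 = no changepoint yet)
  double a, b, c; // quadratic a*mu^2 + b*mu + c
  double l, u;    // interval of mu on which this piece is the envelope
};

inline double piece_min(const Piece &p) {
  // a >= 1 always holds when this is called (after a data point is added)
  double v = -p.b / (2.0 * p.a);
  if (v < p.l) v = p.l;
  else if (v > p.u) v = p.u;
  return (p.a * v + p.b) * v + p.c;
}

} // namespace

// [[Rcpp::export(name = ".fpop_cpp")]]
List fpop_cpp(NumericVector y, double beta) {
  const int n = y.size();
  if (n == 0) stop("empty input");
  const double INF = std::numeric_limits<double>::infinity();
  const double WIDTH_TOL = 1e-12;

  std::vector<int> lastchange(n + 1, 0);
  std::vector<double> Fval(n + 1, 0.0);

  std::vector<Piece> env;
  env.push_back(Piece{0, 1.0, -2.0 * y[0], y[0] * y[0], -INF, INF});
  Fval[1] = piece_min(env[0]);
  lastchange[1] = 0;

  std::vector<Piece> nxt;
  for (int t = 2; t <= n; ++t) {
    const double m = Fval[t - 1] + beta;
    const int cand = t - 1;

    // min(Cost, m): keep each quadratic where it is <= m, cover the rest
    // with the constant piece of the new candidate.
    nxt.clear();
    bool last_is_const = false;
    for (size_t k = 0; k < env.size(); ++k) {
      const Piece &p = env[k];
      // roots of a*mu^2 + b*mu + (c - m) = 0
      const double disc = p.b * p.b - 4.0 * p.a * (p.c - m);
      double r1 = INF, r2 = -INF;
      if (disc > 0.0) {
        const double sq = std::sqrt(disc);
        r1 = (-p.b - sq) / (2.0 * p.a);
        r2 = (-p.b + sq) / (2.0 * p.a);
      }
      const double kl = std::max(p.l, r1);
      const double ku = std::min(p.u, r2);
      if (kl >= ku - WIDTH_TOL) {
        // piece everywhere above m on its interval: constant takes over
        if (last_is_const) {
          nxt.back().u = p.u;
        } else {
          nxt.push_back(Piece{cand, 0.0, 0.0, m, p.l, p.u});
          last_is_const = true;
        }
        continue;
      }
      if (kl > p.l + WIDTH_TOL) {
        if (last_is_const) nxt.back().u = kl;
        else nxt.push_back(Piece{cand, 0.0, 0.0, m, p.l, kl});
      }
      Piece kept = p;
      kept.l = (kl > p.l + WIDTH_TOL) ? kl : p.l;
      kept.u = (ku < p.u - WIDTH_TOL) ? ku : p.u;
      nxt.push_back(kept);
      last_is_const = false;
      if (ku < p.u - WIDTH_TOL) {
        nxt.push_back(Piece{cand, 0.0, 0.0, m, ku, p.u});
        last_is_const = true;
      }
    }
    env.swap(nxt);

    // add (y_t - mu)^2 to every piece
    const double yt = y[t - 1];
    for (size_t k = 0; k < env.size(); ++k) {
      env[k].a += 1.0;
      env[k].b += -2.0 * yt;
      env[k].c += yt * yt;
    }

    // global minimum and its candidate (ties: earliest candidate)
    double best = INF;
    int bs = 0;
    for (size_t k = 0; k < env.size(); ++k) {
      const double v = piece_min(env[k]);
      if (v < best || (v == best && env[k].s < bs)) {
        best = v;
        bs = env[k].s;
      }
    }
    Fval[t] = best;
    lastchange[t] = bs;
  }

  // backtrack
  std::vector<int> cps;
  for (int cp = lastchange[n]; cp > 0; cp = lastchange[cp]) cps.push_back(cp);
  std::reverse(cps.begin(), cps.end());

  return List::create(_["changepoints"] = wrap(cps),
                      _["cost"] = Fval[n]);
}
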