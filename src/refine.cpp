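// Stochastic constraint-projection refinement of a C-alpha trace against a
// ternary contact map. Hot loop of the reconstructor: O(L^2) per sweep over
// all known residue pairs, so it lives in C++.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Fraction of known (non -1, off-diagonal) pairs whose distance relation
// matches the map label. Bond pairs are not special-cased here; they are
// ordinary map entries plus the separate bond reset in the refiner.
static double satisfaction_core(const NumericMatrix &X, const IntegerMatrix &M,
                                double thr2) {
  const int L = X.nrow();
  long known = 0, ok = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      const int lab = M(i, j);
      if (lab == -1) continue;
      ++known;
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (lab == 1 ? (d2 <= thr2) : (d2 > thr2)) ++ok;
    }
  }
  if (known == 0) return 1.0; // vacuous
  return double(ok) / double(known);
}

// [[Rcpp::export(name = ".satisfaction_cpp")]]
double satisfaction_cpp(NumericMatrix X, IntegerMatrix M, double threshold) {
  return satisfaction_core(X, M, threshold * threshold);
}

// [[Rcpp::export(name = ".refine_cpp")]]
List refine_cpp(NumericMatrix X0, IntegerMatrix M, LogicalVector bonded_after,
                double threshold, double bond_length, int max_sweeps,
                double satisfaction_target, double move_fraction,
                double push_margin, double perturb_sigma, int stagnation_window,
                int seed, double soft_margin, double soft_weight,
                int polish_sweeps) {
  const int L = X0.nrow();
  NumericMatrix X = clone(X0);
  const double thr2 = threshold * threshold;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  NumericMatrix best = clone(X);
  double best_sat = satisfaction_core(X, M, thr2);
  double prev_sat = best_sat;
  int since_improve = 0;
  int sweeps_used = 0;
  std::vector<int> nviol(L, 0);

  for (int sweep = 0; sweep < max_sweeps && best_sat < satisfaction_target;
       ++sweep) {
    sweeps_used = sweep + 1;
    std::fill(nviol.begin(), nviol.end(), 0);
    // contact / non-contact projection over all known pairs
    for (int i = 0; i < L; ++i) {
      for (int j = i + 1; j < L; ++j) {
        const int lab = M(i, j);
        if (lab == -1) continue;
        double dx = X(j, 0) - X(i, 0);
        double dy = X(j, 1) - X(i, 1);
        double dz = X(j, 2) - X(i, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (lab == 1 && d2 > thr2) {
          ++nviol[i]; ++nviol[j];
          const double d = std::sqrt(d2);
          const double shift = move_fraction * (d - threshold) / d / 2.0;
          X(i, 0) += shift * dx; X(i, 1) += shift * dy; X(i, 2) += shift * dz;
          X(j, 0) -= shift * dx; X(j, 1) -= shift * dy; X(j, 2) -= shift * dz;
        } else if (lab == 0 && d2 <= thr2) {
          ++nviol[i]; ++nviol[j];
          double d = std::sqrt(d2);
          if (d < 1e-6) { // coincident points: pick a random direction
            dx = gauss(rng); dy = gauss(rng); dz = gauss(rng);
            d = std::sqrt(dx * dx + dy * dy + dz * dz);
          }
          const double target = threshold + push_margin;
          const double shift = (target - d) / d / 2.0;
          X(i, 0) -= shift * dx; X(i, 1) -= shift * dy; X(i, 2) -= shift * dz;
          X(j, 0) += shift * dx; X(j, 1) += shift * dy; X(j, 2) += shift * dz;
        } else if (soft_weight > 0 && lab == 1 &&
                   d2 > (threshold - soft_margin) * (threshold - soft_margin)) {
          // soft hinge buffer: satisfied but close to the threshold; nudge
          // toward the constraint interior (max-margin regularization that
          // lifts the degeneracy of near-threshold-only maps)
          const double d = std::sqrt(d2);
          const double shift =
              soft_weight * (d - (threshold - soft_margin)) / d / 2.0;
          X(i, 0) += shift * dx; X(i, 1) += shift * dy; X(i, 2) += shift * dz;
          X(j, 0) -= shift * dx; X(j, 1) -= shift * dy; X(j, 2) -= shift * dz;
        } else if (soft_weight > 0 && lab == 0 &&
                   d2 <= (threshold + soft_margin) * (threshold + soft_margin)) {
          const double d = std::sqrt(d2);
          const double shift =
              soft_weight * ((threshold + soft_margin) - d) / d / 2.0;
          X(i, 0) -= shift * dx; X(i, 1) -= shift * dy; X(i, 2) -= shift * dz;
          X(j, 0) += shift * dx; X(j, 1) += shift * dy; X(j, 2) += shift * dz;
        }
      }
    }
    // bond reset: consecutive points (unless a chain break separates them)
    for (int i = 0; i + 1 < L; ++i) {
      if (!bonded_after[i]) continue;
      double dx = X(i + 1, 0) - X(i, 0);
      double dy = X(i + 1, 1) - X(i, 1);
      double dz = X(i + 1, 2) - X(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-6) {
        dx = gauss(rng); dy = gauss(rng); dz = gauss(rng);
        d = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      const double shift = (bond_length - d) / d / 2.0;
      X(i, 0) -= shift * dx; X(i, 1) -= shift * dy; X(i, 2) -= shift * dz;
      X(i + 1, 0) += shift * dx; X(i + 1, 1) += shift * dy; X(i + 1, 2) += shift * dz;
    }

    const double sat = satisfaction_core(X, M, thr2);
    if (sat > best_sat) {
      best_sat = sat;
      best = clone(X);
      since_improve = 0;
    } else {
      ++since_improve;
    }
    // stagnation: kick only the residues still violating constraints (plus
    // their bonded neighbours, mildly), keeping the best-ever snapshot safe
    if (since_improve >= stagnation_window && sat <= prev_sat + 1e-9) {
      for (int i = 0; i < L; ++i) {
        double s_i = 0.0;
        if (nviol[i] > 0) s_i = perturb_sigma * std::min(3, nviol[i]);
        else if ((i > 0 && nviol[i - 1] > 0) || (i + 1 < L && nviol[i + 1] > 0))
          s_i = 0.3 * perturb_sigma;
        if (s_i > 0)
          for (int k = 0; k < 3; ++k) X(i, k) += s_i * gauss(rng);
      }
      since_improve = 0;
    }
    prev_sat = sat;
  }

  // polish phase: anneal the converged structure toward the interior of the
  // feasible set (max-margin) with the soft hinge forces; no kicks. Kept only
  // if it does not lose satisfaction.
  if (polish_sweeps > 0 && soft_weight > 0 && sweeps_used > 0) {
    NumericMatrix P = clone(best);
    for (int sweep = 0; sweep < polish_sweeps; ++sweep) {
      for (int i = 0; i < L; ++i) {
        for (int j = i + 1; j < L; ++j) {
          const int lab = M(i, j);
          if (lab == -1) continue;
          double dx = P(j, 0) - P(i, 0);
          double dy = P(j, 1) - P(i, 1);
          double dz = P(j, 2) - P(i, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          const double d = std::sqrt(d2);
          double shift = 0.0;
          if (lab == 1 && d2 > thr2)
            shift = move_fraction * (d - threshold) / d / 2.0;
          else if (lab == 1 && d > threshold - soft_margin)
            shift = soft_weight * (d - (threshold - soft_margin)) / d / 2.0;
          else if (lab == 0 && d2 <= thr2)
            shift = -((threshold + push_margin) - d) / d / 2.0;
          else if (lab == 0 && d <= threshold + soft_margin)
            shift = -soft_weight * ((threshold + soft_margin) - d) / d / 2.0;
          if (shift != 0.0) {
            P(i, 0) += shift * dx; P(i, 1) += shift * dy; P(i, 2) += shift * dz;
            P(j, 0) -= shift * dx; P(j, 1) -= shift * dy; P(j, 2) -= shift * dz;
          }
        }
      }
      for (int i = 0; i + 1 < L; ++i) {
        if (!bonded_after[i]) continue;
        double dx = P(i + 1, 0) - P(i, 0);
        double dy = P(i + 1, 1) - P(i, 1);
        double dz = P(i + 1, 2) - P(i, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < 1e-6) continue;
        const double shift = (bond_length - d) / d / 2.0;
        P(i, 0) -= shift * dx; P(i, 1) -= shift * dy; P(i, 2) -= shift * dz;
        P(i + 1, 0) += shift * dx; P(i + 1, 1) += shift * dy;
        P(i + 1, 2) += shift * dz;
      }
    }
    const double polished_sat = satisfaction_core(P, M, thr2);
    if (polished_sat >= best_sat) {
      best = P;
      best_sat = polished_sat;
    }
  }

  // bond regularization: the returned trace must be chain-like (bonded
  // distances near bond_length) even when the map's constraints were
  // unsatisfiable; pure bond projection converges fast and is local
  for (int sweep = 0; sweep < 300; ++sweep) {
    double maxdev = 0.0;
    for (int i = 0; i + 1 < L; ++i) {
      if (!bonded_after[i]) continue;
      double dx = best(i + 1, 0) - best(i, 0);
      double dy = best(i + 1, 1) - best(i, 1);
      double dz = best(i + 1, 2) - best(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-6) {
        dx = gauss(rng); dy = gauss(rng); dz = gauss(rng);
        d = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      maxdev = std::max(maxdev, std::fabs(d - bond_length));
      const double shift = (bond_length - d) / d / 2.0;
      best(i, 0) -= shift * dx; best(i, 1) -= shift * dy; best(i, 2) -= shift * dz;
      best(i + 1, 0) += shift * dx; best(i + 1, 1) += shift * dy;
      best(i + 1, 2) += shift * dz;
    }
    if (maxdev < 0.3) break;
  }
  best_sat = satisfaction_core(best, M, thr2);

  return List::create(_["xyz"] = best, _["satisfaction"] = best_sat,
                      _["sweeps"] = sweeps_used);
}
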