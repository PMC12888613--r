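#include <Rcpp.h>
using namespace Rcpp;

// Teacher-forced prediction trajectory for one participant's trial sequence.
//
// family: 0 = no_learning, 1 = coarse (Big Five factor-level), 2 = fine
// (per-trait with similarity generalization). State resets to V0 at every
// change of `block` (a new profile is a new person to learn about). All
// values are on the favorability scale.
//
// trait:  0-based trait index per trial
// block:  integer block id per trial (state resets when it changes)
// feedback: profile self-rating per trial (favorability scale)
// trait_factor: 0-based factor index per trait (length n_traits)
// v0: initial expectations per trait (length n_traits)
// rp: reference point per trait (length n_traits, ignored if use_rp = false)
// S:  n_traits x n_traits similarity (used only by family 2)
//
// Returns the model's expected rating for each trial, computed before the
// trial's own feedback is applied.
// [[Rcpp::export]]
NumericVector tl_trajectory(IntegerVector trait, IntegerVector block,
                            NumericVector feedback,
                            int family, bool use_rp,
                            double alpha, double w,
                            NumericVector v0, NumericVector rp,
                            IntegerVector trait_factor, NumericMatrix S,
                            int n_factors) {
  const int n = trait.size();
  const int nt = v0.size();
  NumericVector pred(n);
  std::vector<double> Vfine(nt);
  std::vector<double> Vcoarse(n_factors);
  std::vector<int> fcount(n_factors);

  if (family == 2 && (S.nrow() != nt || S.ncol() != nt))
    stop("similarity matrix dimension does not match lexicon size");
  if (use_rp && rp.size() != nt)
    stop("reference-point vector length does not match lexicon size");

  int cur_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != cur_block) {
      cur_block = block[t];
      if (family == 2) {
        for (int i = 0; i < nt; ++i) Vfine[i] = v0[i];
      } else if (family == 1) {
        std::fill(Vcoarse.begin(), Vcoarse.end(), 0.0);
        std::fill(fcount.begin(), fcount.end(), 0);
        for (int i = 0; i < nt; ++i) {
          Vcoarse[trait_factor[i]] += v0[i];
          fcount[trait_factor[i]] += 1;
        }
        for (int f = 0; f < n_factors; ++f)
          if (fcount[f] > 0) Vcoarse[f] /= fcount[f];
      }
    }
    const int j = trait[t];
    if (j < 0 || j >= nt) stop("trait index out of range at trial %d", t + 1);

    double base;
    if (family == 0) {
      base = rp[j];
      pred[t] = base;
    } else {
      base = (family == 1) ? Vcoarse[trait_factor[j]] : Vfine[j];
      pred[t] = use_rp ? w * rp[j] + (1.0 - w) * base : base;
    }

    if (family == 1) {
      const int f = trait_factor[j];
      Vcoarse[f] += alpha * (feedback[t] - Vcoarse[f]);
    } else if (family == 2) {
      const double delta = feedback[t] - Vfine[j];
      for (int i = 0; i < nt; ++i)
        Vfine[i] += alpha * S(i, j) * delta;
    }
  }
  return pred;
}

// Gaussian log-likelihood of observed predictions around the trajectory,
// summed over valid trials only.
// [[Rcpp::export]]
double tl_gauss_loglik(NumericVector observed, NumericVector predicted,
                       LogicalVector valid, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  const int n = observed.size();
  double ll = 0.0;
  const double c = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  for (int t = 0; t < n; ++t) {
    if (!valid[t]) continue;
    const double z = (observed[t] - predicted[t]) / sigma;
    ll += c - 0.5 * z * z;
  }
  return ll;
}

// Per-participant log-likelihoods for a whole condition in one call:
// sequences are concatenated, with subject s occupying rows
// [start[s], start[s+1]). Participant-level parameters are vectors; v0 and
// S are shared. rp is an n_traits x n_subjects matrix (0 x 0 when unused).
// [[Rcpp::export]]
NumericVector tl_subject_logliks(IntegerVector trait, IntegerVector block,
                                 NumericVector feedback,
                                 NumericVector observed, LogicalVector valid,
                                 IntegerVector start,
                                 int family, bool use_rp,
                                 NumericVector alpha, NumericVector w,
                                 NumericVector sigma,
                                 NumericVector v0, NumericMatrix rp,
                                 IntegerVector trait_factor, NumericMatrix S,
                                 int n_factors) {
  const int n_s = start.size() - 1;
  const int nt = v0.size();
  NumericVector out(n_s);
  std::vector<double> Vfine(nt);
  std::vector<double> Vcoarse(n_factors);
  std::vector<int> fcount(n_factors);

  for (int s = 0; s < n_s; ++s) {
    const double a = alpha[s], ws = w[s], sg = sigma[s];
    const double c = -0.5 * std::log(2.0 * M_PI) - std::log(sg);
    double ll = 0.0;
    int cur_block = NA_INTEGER;
    bool first = true;
    for (int t = start[s]; t < start[s + 1]; ++t) {
      if (first || block[t] != cur_block) {
        cur_block = block[t];
        first = false;
        if (family == 2) {
          for (int i = 0; i < nt; ++i) Vfine[i] = v0[i];
        } else if (family == 1) {
          std::fill(Vcoarse.begin(), Vcoarse.end(), 0.0);
          std::fill(fcount.begin(), fcount.end(), 0);
          for (int i = 0; i < nt; ++i) {
            Vcoarse[trait_factor[i]] += v0[i];
            fcount[trait_factor[i]] += 1;
          }
          for (int f = 0; f < n_factors; ++f)
            if (fcount[f] > 0) Vcoarse[f] /= fcount[f];
        }
      }
      const int j = trait[t];
      double base, pred;
      if (family == 0) {
        pred = rp(j, s);
      } else {
        base = (family == 1) ? Vcoarse[trait_factor[j]] : Vfine[j];
        pred = use_rp ? ws * rp(j, s) + (1.0 - ws) * base : base;
      }
      if (valid[t]) {
        const double zres = (observed[t] - pred) / sg;
        ll += c - 0.5 * zres * zres;
      }
      if (family == 1) {
        const int f = trait_factor[j];
        Vcoarse[f] += a * (feedback[t] - Vcoarse[f]);
      } else if (family == 2) {
        const double delta = feedback[t] - Vfine[j];
        for (int i = 0; i < nt; ++i)
          Vfine[i] += a * S(i, j) * delta;
      }
    }
    out[s] = ll;
  }
  return out;
}
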