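#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid haplotype-copying HMM (Li & Stephens style), forward-backward.
//
// Hidden state: ordered pair (k1, k2) of template haplotypes from a panel of
// K references. Each chromosome switches templates independently between
// adjacent informative sites with probability s = 1 - exp(-rho * delta),
// delta in Morgan; after a switch the new template is uniform on the K
// references. Emission at an observed (panel) genotype compares the implied
// genotype H[k1] + H[k2] with the observation under a per-allele error rate.
// Posterior genotype probabilities at unobserved sites are obtained by
// transporting the flanking forward/backward messages to the site's map
// position (the state path is piecewise constant between informative sites).
//
// The transition kernel factorises per haplotype, so applying it to a K x K
// message costs O(K^2):
//   A' = u^2 A + u*v*(rowMarg + colMarg) + v^2 * tot,  u = 1-s, v = s/K.

static void apply_kernel(const std::vector<double>& A, std::vector<double>& out,
                         int K, double s) {
  const double u = 1.0 - s, v = s / K;
  std::vector<double> m1(K, 0.0), m2(K, 0.0); // m1[j] = sum_i A[i,j]; m2[i] = sum_j A[i,j]
  double tot = 0.0;
  for (int j = 0; j < K; ++j) {
    for (int i = 0; i < K; ++i) {
      const double a = A[i + K * j];
      m1[j] += a;
      m2[i] += a;
      tot += a;
    }
  }
  const double uv = u * v, vv = v * v * tot;
  for (int j = 0; j < K; ++j) {
    for (int i = 0; i < K; ++i) {
      out[i + K * j] = u * u * A[i + K * j] + uv * (m1[j] + m2[i]) + vv;
    }
  }
}

static void normalize(std::vector<double>& A) {
  double s = 0.0;
  for (double a : A) s += a;
  if (s <= 0.0) {
    const double f = 1.0 / A.size();
    for (double& a : A) a = f;
  } else {
    const double f = 1.0 / s;
    for (double& a : A) a *= f;
  }
}

// emission probability table P(obs g | implied g) for per-allele error e
static void emission_table(double e, double E[3][3]) {
  const double c = 1.0 - e;
  // implied 0: obs ~ Binom(2, e); implied 2: Binom(2, 1-e)
  E[0][0] = c * c;       E[0][1] = 2 * c * e;       E[0][2] = e * e;
  E[2][0] = e * e;       E[2][1] = 2 * c * e;       E[2][2] = c * c;
  // implied 1: one allele of each; obs count = Bern(c) + Bern(e)
  E[1][0] = c * e;       E[1][1] = c * c + e * e;   E[1][2] = c * e;
}

// [[Rcpp::export(name = ".hmm_posterior_cpp")]]
NumericVector hmm_posterior_cpp(IntegerMatrix H, IntegerMatrix G,
                                NumericVector pos, double rho, double err) {
  const int K = H.nrow();
  const int m = H.ncol();
  const int n = G.nrow();
  if (G.ncol() != m || (int)pos.size() != m)
    stop("dimension mismatch between H, G and pos");
  double E[3][3];
  emission_table(err, E);

  NumericVector out(Dimension(n, m, 3));
  const int KK = K * K;
  std::vector<double> tmp(KK), msg(KK);

  for (int s = 0; s < n; ++s) {
    // informative sites for this sample
    std::vector<int> inf;
    inf.reserve(m);
    for (int j = 0; j < m; ++j) {
      const int g = G(s, j);
      if (g >= 0 && g <= 2) inf.push_back(j);
    }
    const int ni = (int)inf.size();
    if (ni == 0) stop("sample with no observed genotypes; handle in caller");

    // forward pass (alpha includes emission at its site), stored per inf site
    std::vector<std::vector<double> > alpha(ni, std::vector<double>(KK));
    std::vector<std::vector<double> > betaE(ni, std::vector<double>(KK));
    for (int t = 0; t < ni; ++t) {
      const int j = inf[t];
      if (t == 0) {
        const double f = 1.0 / KK;
        for (int q = 0; q < KK; ++q) tmp[q] = f;
      } else {
        const double delta = pos[j] - pos[inf[t - 1]];
        const double sw = 1.0 - std::exp(-rho * delta);
        apply_kernel(alpha[t - 1], tmp, K, sw);
      }
      const int g = G(s, j);
      for (int k2 = 0; k2 < K; ++k2) {
        const int h2 = H(k2, j);
        for (int k1 = 0; k1 < K; ++k1) {
          const int imp = H(k1, j) + h2;
          alpha[t][k1 + K * k2] = tmp[k1 + K * k2] * E[imp][g];
        }
      }
      normalize(alpha[t]);
    }
    // backward pass: betaN[t] = transported future (no emission at t),
    // betaE[t] = E_t .* betaN[t] (ready to be transported further left)
    std::vector<std::vector<double> > betaN(ni, std::vector<double>(KK));
    for (int t = ni - 1; t >= 0; --t) {
      const int j = inf[t];
      if (t == ni - 1) {
        std::fill(betaN[t].begin(), betaN[t].end(), 1.0);
      } else {
        const double delta = pos[inf[t + 1]] - pos[j];
        const double sw = 1.0 - std::exp(-rho * delta);
        apply_kernel(betaE[t + 1], betaN[t], K, sw);
        normalize(betaN[t]);
      }
      const int g = G(s, j);
      for (int k2 = 0; k2 < K; ++k2) {
        const int h2 = H(k2, j);
        for (int k1 = 0; k1 < K; ++k1) {
          const int imp = H(k1, j) + h2;
          betaE[t][k1 + K * k2] = betaN[t][k1 + K * k2] * E[imp][g];
        }
      }
      normalize(betaE[t]);
    }

    // posterior genotype probabilities at every site
    int t_left = -1; // index into inf of last informative site <= j
    for (int j = 0; j < m; ++j) {
      while (t_left + 1 < ni && inf[t_left + 1] <= j) ++t_left;
      if (t_left >= 0 && inf[t_left] == j) {
        // at an informative site: alpha carries the emission, betaN does not
        for (int q = 0; q < KK; ++q)
          msg[q] = alpha[t_left][q] * betaN[t_left][q];
      } else {
        // between informative sites: transport both flanks to this position
        if (t_left < 0) {
          // before the first informative site: backward side only
          const double deltaR = pos[inf[0]] - pos[j];
          const double swR = 1.0 - std::exp(-rho * deltaR);
          apply_kernel(betaE[0], msg, K, swR);
        } else if (t_left == ni - 1) {
          const double deltaL = pos[j] - pos[inf[t_left]];
          const double swL = 1.0 - std::exp(-rho * deltaL);
          apply_kernel(alpha[t_left], msg, K, swL);
        } else {
          const double deltaL = pos[j] - pos[inf[t_left]];
          const double swL = 1.0 - std::exp(-rho * deltaL);
          apply_kernel(alpha[t_left], tmp, K, swL);
          const double deltaR = pos[inf[t_left + 1]] - pos[j];
          const double swR = 1.0 - std::exp(-rho * deltaR);
          apply_kernel(betaE[t_left + 1], msg, K, swR);
          for (int q = 0; q < KK; ++q) msg[q] *= tmp[q];
        }
      }
      normalize(msg);
      // genotype posterior: error-free copy of the template alleles
      double p0 = 0.0, p1 = 0.0, p2 = 0.0;
      for (int k2 = 0; k2 < K; ++k2) {
        const int h2 = H(k2, j);
        for (int k1 = 0; k1 < K; ++k1) {
          const double w = msg[k1 + K * k2];
          const int imp = H(k1, j) + h2;
          if (imp == 0) p0 += w;
          else if (imp == 1) p1 += w;
          else p2 += w;
        }
      }
      const double psum = p0 + p1 + p2;
      out[s + (size_t)n * j] = p0 / psum;
      out[s + (size_t)n * j + (size_t)n * m] = p1 / psum;
      out[s + (size_t)n * j + 2 * (size_t)n * m] = p2 / psum;
    }
  }
  return out;
}
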