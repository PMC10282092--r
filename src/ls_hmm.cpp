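#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying HMM over genotype likelihoods.
//
// Hidden state at site l: ordered pair (j, k) of panel haplotypes.
// Haploid transition between adjacent sites: with switch mass
// lambda_l = 1 - exp(-rho_scale * dM_l / K) (dM in Morgans) spread uniformly
// over the K haplotypes, i.e. stay prob (1 - lambda) + lambda/K, move prob
// lambda/K to each specific haplotype. Diploid transition factorises as the
// product of the two haploid transitions, which keeps every update O(K^2)
// via row/column sums.
//
// Emission at (j, k): sum over copied allele pairs (a, b) of
// P(a | H[j, l]) * P(b | H[k, l]) * exp(loggl[l, a + b]), with
// P(a | h) = 1 - mu if a == h else mu (miscopying).

static inline void interval_lambdas(const NumericVector& cm, int K,
                                    double rho_scale, std::vector<double>& lambda) {
  int M = cm.size();
  lambda.assign(M, 0.0);
  for (int l = 1; l < M; ++l) {
    double dM = (cm[l] - cm[l - 1]) / 100.0;  // cM -> Morgans
    if (dM < 0) stop("genetic positions must be non-decreasing");
    lambda[l] = 1.0 - std::exp(-rho_scale * dM / (double)K);
  }
}

// [[Rcpp::export]]
List ls_forward_backward_cpp(const IntegerMatrix& H, const NumericMatrix& loggl,
                             const NumericVector& cm, double rho_scale, double mu) {
  const int K = H.nrow();
  const int M = H.ncol();
  if (K < 2) stop("reference panel must contain at least 2 haplotypes");
  if (loggl.nrow() != M || cm.size() != M)
    stop("genotype likelihoods, panel and map must cover the same sites");
  if (mu <= 0 || mu >= 0.5) stop("mu must be in (0, 0.5)");

  const size_t KK = (size_t)K * (size_t)K;
  std::vector<double> lambda;
  interval_lambdas(cm, K, rho_scale, lambda);

  std::vector<double> alpha(KK * (size_t)M);
  std::vector<double> q(K), rs(K), cs(K);
  NumericMatrix gp(M, 3);
  double loglik = 0.0;

  // forward pass, scaled so each site's alpha sums to 1
  for (int l = 0; l < M; ++l) {
    const double e0 = std::exp(loggl(l, 0));
    const double e1 = std::exp(loggl(l, 1));
    const double e2 = std::exp(loggl(l, 2));
    for (int j = 0; j < K; ++j) q[j] = mu + (1.0 - 2.0 * mu) * (double)H(j, l);
    double* a = &alpha[KK * (size_t)l];
    if (l == 0) {
      const double init = 1.0 / (double)KK;
      for (int j = 0; j < K; ++j) {
        const double qj = q[j];
        for (int k = 0; k < K; ++k) {
          const double qk = q[k];
          const double em = e0 * (1 - qj) * (1 - qk)
                          + e1 * ((1 - qj) * qk + qj * (1 - qk))
                          + e2 * qj * qk;
          a[(size_t)j * K + k] = init * em;
        }
      }
    } else {
      const double* ap = &alpha[KK * (size_t)(l - 1)];
      const double lam = lambda[l];
      const double stay = 1.0 - lam, sw = lam / (double)K;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += ap[(size_t)j * K + k];
        rs[j] = s;
        tot += s;
      }
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += ap[(size_t)j * K + k];
        cs[k] = s;
      }
      const double s2 = stay * stay, ssw = stay * sw, sw2 = sw * sw * tot;
      for (int j = 0; j < K; ++j) {
        const double qj = q[j];
        const double rj = rs[j];
        for (int k = 0; k < K; ++k) {
          const double qk = q[k];
          const double em = e0 * (1 - qj) * (1 - qk)
                          + e1 * ((1 - qj) * qk + qj * (1 - qk))
                          + e2 * qj * qk;
          const size_t jk = (size_t)j * K + k;
          a[jk] = em * (s2 * ap[jk] + ssw * (rj + cs[k]) + sw2);
        }
      }
    }
    double sc = 0.0;
    for (size_t i = 0; i < KK; ++i) sc += a[i];
    if (sc <= 0) stop("numerical underflow in forward pass at site %d", l + 1);
    const double inv = 1.0 / sc;
    for (size_t i = 0; i < KK; ++i) a[i] *= inv;
    loglik += std::log(sc);
  }

  // backward pass streamed against the stored forward quantities;
  // posterior state weights are alpha_l * beta_l and the genotype posterior
  // redistributes each state's weight over copied-allele pairs.
  std::vector<double> beta(KK, 1.0), G(KK);
  for (int l = M - 1; l >= 0; --l) {
    const double e0 = std::exp(loggl(l, 0));
    const double e1 = std::exp(loggl(l, 1));
    const double e2 = std::exp(loggl(l, 2));
    for (int j = 0; j < K; ++j) q[j] = mu + (1.0 - 2.0 * mu) * (double)H(j, l);
    const double* a = &alpha[KK * (size_t)l];
    double g0 = 0.0, g1 = 0.0, g2 = 0.0, z = 0.0;
    for (int j = 0; j < K; ++j) {
      const double qj = q[j];
      for (int k = 0; k < K; ++k) {
        const double qk = q[k];
        const double w0 = e0 * (1 - qj) * (1 - qk);
        const double w1 = e1 * ((1 - qj) * qk + qj * (1 - qk));
        const double w2 = e2 * qj * qk;
        const double em = w0 + w1 + w2;
        const size_t jk = (size_t)j * K + k;
        const double post = a[jk] * beta[jk];
        z += post;
        const double u = post / em;
        g0 += u * w0;
        g1 += u * w1;
        g2 += u * w2;
        G[jk] = em * beta[jk];  // for the next (leftward) beta update
      }
    }
    if (z <= 0) stop("numerical underflow in backward pass at site %d", l + 1);
    gp(l, 0) = g0 / z;
    gp(l, 1) = g1 / z;
    gp(l, 2) = g2 / z;
    if (l > 0) {
      const double lam = lambda[l];
      const double stay = 1.0 - lam, sw = lam / (double)K;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += G[(size_t)j * K + k];
        rs[j] = s;
        tot += s;
      }
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += G[(size_t)j * K + k];
        cs[k] = s;
      }
      const double s2 = stay * stay, ssw = stay * sw, sw2 = sw * sw * tot;
      double sc = 0.0;
      for (int j = 0; j < K; ++j) {
        for (int k = 0; k < K; ++k) {
          const size_t jk = (size_t)j * K + k;
          beta[jk] = s2 * G[jk] + ssw * (rs[j] + cs[k]) + sw2;
          sc += beta[jk];
        }
      }
      const double inv = 1.0 / sc;  // rescale; constants cancel in posteriors
      for (size_t i = 0; i < KK; ++i) beta[i] *= inv;
    }
  }

  return List::create(_["gp"] = gp, _["loglik"] = loglik);
}

// Viterbi decoding over the same state space, with per-site copied-allele
// maximisation to emit a phased haplotype pair. Backpointers are stored as
// bytes, so K is limited to 256 haplotypes (plenty for the K^2 state space
// this exact implementation is meant for).
// [[Rcpp::export]]
List ls_viterbi_cpp(const IntegerMatrix& H, const NumericMatrix& loggl,
                    const NumericVector& cm, double rho_scale, double mu) {
  const int K = H.nrow();
  const int M = H.ncol();
  if (K < 2) stop("reference panel must contain at least 2 haplotypes");
  if (K > 256) stop("Viterbi phasing supports at most 256 panel haplotypes");
  if (loggl.nrow() != M || cm.size() != M)
    stop("genotype likelihoods, panel and map must cover the same sites");

  const size_t KK = (size_t)K * (size_t)K;
  std::vector<double> lambda;
  interval_lambdas(cm, K, rho_scale, lambda);

  std::vector<double> delta(KK), A(KK), ndelta(KK), q(K), colmax(K), logem(KK);
  std::vector<unsigned char> bpj(KK * (size_t)M), bpk(KK * (size_t)M);

  for (int l = 0; l < M; ++l) {
    const double e0 = std::exp(loggl(l, 0));
    const double e1 = std::exp(loggl(l, 1));
    const double e2 = std::exp(loggl(l, 2));
    for (int j = 0; j < K; ++j) q[j] = mu + (1.0 - 2.0 * mu) * (double)H(j, l);
    for (int j = 0; j < K; ++j) {
      const double qj = q[j];
      for (int k = 0; k < K; ++k) {
        const double qk = q[k];
        const double em = e0 * (1 - qj) * (1 - qk)
                        + e1 * ((1 - qj) * qk + qj * (1 - qk))
                        + e2 * qj * qk;
        logem[(size_t)j * K + k] = std::log(em);
      }
    }
    if (l == 0) {
      const double linit = -std::log((double)KK);
      for (size_t i = 0; i < KK; ++i) delta[i] = linit + logem[i];
      continue;
    }
    const double lam = lambda[l];
    const double lstay = std::log(1.0 - lam + lam / (double)K);
    const double lsw = std::log(lam / (double)K);  // -Inf when lam == 0 is fine
    // stage 1: maximise over the first haplotype index
    for (int kp = 0; kp < K; ++kp) {
      double cm1 = -INFINITY;
      int arg = 0;
      for (int jp = 0; jp < K; ++jp) {
        const double v = delta[(size_t)jp * K + kp];
        if (v > cm1) { cm1 = v; arg = jp; }
      }
      colmax[kp] = cm1;
      // A[j, kp]: best over predecessors j' for each target j
      for (int j = 0; j < K; ++j) {
        const double staying = delta[(size_t)j * K + kp] + lstay;
        const double moving = cm1 + lsw;
        const size_t idx = (size_t)j * K + kp;
        if (staying >= moving) {
          A[idx] = staying;
          bpj[KK * (size_t)l + idx] = (unsigned char)j;
        } else {
          A[idx] = moving;
          bpj[KK * (size_t)l + idx] = (unsigned char)arg;
        }
      }
    }
    // stage 2: maximise over the second haplotype index
    for (int j = 0; j < K; ++j) {
      double rm = -INFINITY;
      int arg = 0;
      for (int kp = 0; kp < K; ++kp) {
        const double v = A[(size_t)j * K + kp];
        if (v > rm) { rm = v; arg = kp; }
      }
      for (int k = 0; k < K; ++k) {
        const double staying = A[(size_t)j * K + k] + lstay;
        const double moving = rm + lsw;
        const size_t idx = (size_t)j * K + k;
        if (staying >= moving) {
          ndelta[idx] = staying + logem[idx];
          bpk[KK * (size_t)l + idx] = (unsigned char)k;
        } else {
          ndelta[idx] = moving + logem[idx];
          bpk[KK * (size_t)l + idx] = (unsigned char)arg;
        }
      }
    }
    std::swap(delta, ndelta);
  }

  // backtrack
  IntegerMatrix path(M, 2);
  size_t best = 0;
  for (size_t i = 1; i < KK; ++i)
    if (delta[i] > delta[best]) best = i;
  int j = (int)(best / K), k = (int)(best % K);
  double best_logprob = delta[best];
  for (int l = M - 1; l >= 0; --l) {
    path(l, 0) = j + 1;
    path(l, 1) = k + 1;
    if (l > 0) {
      const int kp = bpk[KK * (size_t)l + (size_t)j * K + k];
      const int jp = bpj[KK * (size_t)l + (size_t)j * K + kp];
      j = jp;
      k = kp;
    }
  }

  // phased alleles: per site, argmax over copied-allele pairs given the state
  IntegerMatrix haps(M, 2);
  for (int l = 0; l < M; ++l) {
    const double e0 = std::exp(loggl(l, 0));
    const double e1 = std::exp(loggl(l, 1));
    const double e2 = std::exp(loggl(l, 2));
    const int sj = path(l, 0) - 1, sk = path(l, 1) - 1;
    const double qj = mu + (1.0 - 2.0 * mu) * (double)H(sj, l);
    const double qk = mu + (1.0 - 2.0 * mu) * (double)H(sk, l);
    const double w[4] = { e0 * (1 - qj) * (1 - qk),   // (0,0)
                          e1 * (1 - qj) * qk,         // (0,1)
                          e1 * qj * (1 - qk),         // (1,0)
                          e2 * qj * qk };             // (1,1)
    int arg = 0;
    for (int i = 1; i < 4; ++i)
      if (w[i] > w[arg]) arg = i;
    haps(l, 0) = arg >> 1;
    haps(l, 1) = arg & 1;
  }

  return List::create(_["path"] = path, _["haps"] = haps,
                      _["logprob"] = best_logprob);
}
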