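#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Li-Stephens haplotype-copying HMM kernels.
//
// States are reference haplotypes (haploid) or ordered haplotype pairs
// (diploid). Between adjacent sites a gamete switches with probability p,
// landing uniformly on one of the H haplotypes, so the per-haplotype
// transition kernel is (1 - p) * delta + p / H. Emissions allow an
// emission-mismatch probability eps of copying the opposite allele.
//
// Implementation notes shared by both kernels:
//  * the forward and backward passes keep their vectors normalized to sum 1;
//    at sites with uniform emissions the transition preserves that total
//    exactly, so rescaling (and any emission work) is skipped there;
//  * the forward log-likelihood is the sum of the log scaling factors
//    collected at the non-uniform sites.

// ---------------------------------------------------------------------------
// haploid kernel
// ---------------------------------------------------------------------------

// Site evidence enters as per-site products over the observations:
// m1[l] = prod P(obs | allele 1), m0[l] = prod P(obs | allele 0), so the
// state emission is em(h, l) = w1(h, l) * m1[l] + (1 - w1(h, l)) * m0[l],
// where w1 = P(emit allele 1 | copying h) = hap == 1 ? 1 - eps : eps.
// has_ev[l] == 0 marks m1 = m0 = 1 (uniform emission).
//
// Outputs: alpha (H x L, normalized forward probabilities), a_out[l] =
// posterior alternate-allele probability, and the log-likelihood.
// d1_out/d0_out (optional): the unnormalized posterior masses of the
// emitted allele being 1/0, used for leave-one-read-out adjustment.
static void haploid_posterior(const double* w1, int H, int L,
                              const double* pswitch,
                              const double* m1, const double* m0,
                              const unsigned char* has_ev,
                              double* alpha, double* beta_buf, double* a_out,
                              double* loglik_out,
                              double* d1_out = nullptr,
                              double* d0_out = nullptr) {
  double loglik = 0.0;
  const double invH = 1.0 / H;

  // forward
  {
    double* a0 = alpha;
    if (has_ev[0]) {
      double c = 0.0;
      const double e1 = m1[0], e0 = m0[0];
      for (int h = 0; h < H; ++h) {
        const double w = w1[h];
        a0[h] = (w * e1 + (1.0 - w) * e0) * invH;
        c += a0[h];
      }
      loglik += std::log(c);
      const double ic = 1.0 / c;
      for (int h = 0; h < H; ++h) a0[h] *= ic;
    } else {
      for (int h = 0; h < H; ++h) a0[h] = invH;
    }
  }
  for (int l = 1; l < L; ++l) {
    const double p = pswitch[l - 1];
    const double stay = 1.0 - p, jump = p * invH;
    const double* prev = alpha + static_cast<size_t>(l - 1) * H;
    double* cur = alpha + static_cast<size_t>(l) * H;
    if (has_ev[l]) {
      const double e1 = m1[l], e0 = m0[l];
      const double* w = w1 + static_cast<size_t>(l) * H;
      double c = 0.0;
      for (int h = 0; h < H; ++h) {
        const double em = w[h] * e1 + (1.0 - w[h]) * e0;
        const double v = (stay * prev[h] + jump) * em;
        cur[h] = v;
        c += v;
      }
      loglik += std::log(c);
      const double ic = 1.0 / c;
      for (int h = 0; h < H; ++h) cur[h] *= ic;
    } else {
      for (int h = 0; h < H; ++h) cur[h] = stay * prev[h] + jump;
    }
  }

  // backward, emitting the allele posterior on the fly
  double* beta = beta_buf;
  for (int h = 0; h < H; ++h) beta[h] = invH;
  for (int l = L - 1; l >= 0; --l) {
    const double* al = alpha + static_cast<size_t>(l) * H;
    const double* w = w1 + static_cast<size_t>(l) * H;
    if (has_ev[l]) {
      // the emitted allele is conditioned on the site's own evidence:
      // within state h the allele splits w1*m1 : w0*m0, and the stored
      // alpha carries em(h,l) = w1*m1 + w0*m0, so divide it back out
      const double e1 = m1[l], e0 = m0[l];
      double d1 = 0.0, d0 = 0.0;
      for (int h = 0; h < H; ++h) {
        const double wh = w[h];
        const double g = al[h] * beta[h] / (wh * e1 + (1.0 - wh) * e0);
        d1 += g * wh * e1;
        d0 += g * (1.0 - wh) * e0;
      }
      a_out[l] = d1 / (d1 + d0);
      if (d1_out) { d1_out[l] = d1; d0_out[l] = d0; }
    } else {
      double tot = 0.0, dose = 0.0;
      for (int h = 0; h < H; ++h) {
        const double g = al[h] * beta[h];
        tot += g;
        dose += g * w[h];
      }
      a_out[l] = dose / tot;
      if (d1_out) { d1_out[l] = dose; d0_out[l] = tot - dose; }
    }
    if (l > 0) {
      const double p = pswitch[l - 1];
      const double stay = 1.0 - p, jump = p * invH;
      if (has_ev[l]) {
        const double e1 = m1[l], e0 = m0[l];
        double s = 0.0;
        for (int h = 0; h < H; ++h) {
          const double em = w[h] * e1 + (1.0 - w[h]) * e0;
          beta[h] *= em;
          s += beta[h];
        }
        double c = 0.0;
        for (int h = 0; h < H; ++h) {
          beta[h] = stay * beta[h] + jump * s;
          c += beta[h];
        }
        const double ic = 1.0 / c;
        for (int h = 0; h < H; ++h) beta[h] *= ic;
      } else {
        for (int h = 0; h < H; ++h) beta[h] = stay * beta[h] + jump;
      }
    }
  }
  *loglik_out = loglik;
}


// Forward-pass log-likelihood only (no posterior), for collapsed
// Metropolis moves on read labels.
static double haploid_forward_ll(const double* w1, int H, int L,
                                 const double* pswitch,
                                 const double* m1, const double* m0,
                                 const unsigned char* has_ev,
                                 double* work) {
  double loglik = 0.0;
  const double invH = 1.0 / H;
  if (has_ev[0]) {
    double c = 0.0;
    for (int h = 0; h < H; ++h) {
      const double w = w1[h];
      work[h] = (w * m1[0] + (1.0 - w) * m0[0]) * invH;
      c += work[h];
    }
    loglik += std::log(c);
    for (int h = 0; h < H; ++h) work[h] /= c;
  } else {
    for (int h = 0; h < H; ++h) work[h] = invH;
  }
  for (int l = 1; l < L; ++l) {
    const double p = pswitch[l - 1];
    const double stay = 1.0 - p, jump = p * invH;
    if (has_ev[l]) {
      const double e1 = m1[l], e0 = m0[l];
      const double* w = w1 + static_cast<size_t>(l) * H;
      double c = 0.0;
      for (int h = 0; h < H; ++h) {
        const double em = w[h] * e1 + (1.0 - w[h]) * e0;
        work[h] = (stay * work[h] + jump) * em;
        c += work[h];
      }
      loglik += std::log(c);
      for (int h = 0; h < H; ++h) work[h] /= c;
    } else {
      for (int h = 0; h < H; ++h) work[h] = stay * work[h] + jump;
    }
  }
  return loglik;
}

static std::vector<double> emission_w1(const IntegerMatrix& hap, double eps) {
  const int H = hap.nrow(), L = hap.ncol();
  std::vector<double> w1(static_cast<size_t>(H) * L);
  for (int l = 0; l < L; ++l)
    for (int h = 0; h < H; ++h)
      w1[static_cast<size_t>(l) * H + h] = hap(h, l) == 1 ? 1.0 - eps : eps;
  return w1;
}

// Haploid Li-Stephens posterior for one gamete given per-site evidence
// products; exposed for direct use and testing against path enumeration.
// [[Rcpp::export]]
List cpp_haploid_posterior(IntegerMatrix hap, NumericVector pswitch,
                           double eps, NumericVector m1, NumericVector m0) {
  const int H = hap.nrow(), L = hap.ncol();
  if (m1.size() != L || m0.size() != L) stop("evidence must have one entry per site");
  std::vector<double> w1 = emission_w1(hap, eps);
  std::vector<unsigned char> has_ev(L);
  for (int l = 0; l < L; ++l) has_ev[l] = (m1[l] != 1.0 || m0[l] != 1.0);
  std::vector<double> alpha(static_cast<size_t>(H) * L), beta(H), a(L);
  double ll = 0.0;
  haploid_posterior(w1.data(), H, L, REAL(pswitch), REAL(m1), REAL(m0),
                    has_ev.data(), alpha.data(), beta.data(), a.data(), &ll);
  return List::create(_["allele_prob"] = NumericVector(a.begin(), a.end()),
                      _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// diploid kernel
// ---------------------------------------------------------------------------

// Scratch for the diploid pass: row/column sums of the current (unnormalized)
// alpha are accumulated while it is written, and its total is folded into the
// next step's transition constants instead of a rescaling sweep.
struct DipState {
  std::vector<double> mat, rs, cs;
  double total;
};

// One diploid forward step from `prev` (site l-1) into `out` (site l).
// When `pre` is non-null the pre-emission (transition-only, normalized)
// probabilities are stored there. Returns log of the site's scaling factor.
static double dip_forward_step(const DipState& prev, int l,
                               const double* w1, const double* gl,
                               double p, int H, DipState& out, double* pre) {
  const double invH = 1.0 / H;
  const double invS = 1.0 / prev.total;
  const double stay = 1.0 - p, jump = p * invH;
  const double s2 = stay * stay * invS, sj = stay * jump * invS,
               jj = jump * jump;
  const double g0 = gl[0], g1 = gl[1], g2 = gl[2];
  const bool uniform = (g0 == g1 && g1 == g2);
  const double* w = w1 + static_cast<size_t>(l) * H;

  std::fill(out.rs.begin(), out.rs.end(), 0.0);
  double total = 0.0;
  for (int k = 0; k < H; ++k) {
    const double wk1 = w[k], wk0 = 1.0 - wk1;
    // em(j,k) = uk + w1j * (vk - uk)
    const double uk = g0 * wk0 + g1 * wk1;
    const double dk = (g1 * wk0 + g2 * wk1) - uk;
    const double base_k = sj * prev.cs[k] + jj;
    const double* pc = prev.mat.data() + static_cast<size_t>(k) * H;
    double* oc = out.mat.data() + static_cast<size_t>(k) * H;
    double* prc = pre ? pre + static_cast<size_t>(k) * H : nullptr;
    double cs = 0.0;
    if (uniform) {
      for (int j = 0; j < H; ++j) {
        const double a = s2 * pc[j] + sj * prev.rs[j] + base_k;
        if (prc) prc[j] = a;
        oc[j] = a;
        cs += a;
        out.rs[j] += a;
      }
    } else {
      for (int j = 0; j < H; ++j) {
        const double a = s2 * pc[j] + sj * prev.rs[j] + base_k;
        if (prc) prc[j] = a;
        const double val = a * (uk + w[j] * dk);
        oc[j] = val;
        cs += val;
        out.rs[j] += val;
      }
    }
    out.cs[k] = cs;
    total += cs;
  }
  out.total = total;
  // `pre` is a normalized propagation, so the emitted mass is the scaling
  // factor; at uniform sites the constant emission factor is not multiplied
  // into the stored matrix and enters the likelihood directly
  return uniform ? std::log(total) + std::log(g0) : std::log(total);
}

// Diploid forward-backward over ordered haplotype pairs with genotype-
// likelihood emissions. gl is L x 3 (linear scale). Memory is kept at
// O(H^2 sqrt(L)) by checkpointing the forward pass and recomputing it
// blockwise during the backward pass.
// [[Rcpp::export]]
List cpp_diploid_fb(NumericMatrix gl, IntegerMatrix hap,
                    NumericVector pswitch, double eps) {
  const int H = hap.nrow(), L = hap.ncol();
  if (H < 2) stop("diploid imputation needs a panel with at least 2 haplotypes");
  if (gl.nrow() != L || gl.ncol() != 3) stop("gl must be L x 3");
  const size_t HH = static_cast<size_t>(H) * H;
  std::vector<double> w1 = emission_w1(hap, eps);

  // per-site likelihood rows, contiguous
  std::vector<double> glv(3 * static_cast<size_t>(L));
  for (int l = 0; l < L; ++l) {
    glv[3 * l] = gl(l, 0);
    glv[3 * l + 1] = gl(l, 1);
    glv[3 * l + 2] = gl(l, 2);
  }

  auto make_state = [&]() {
    DipState s;
    s.mat.resize(HH);
    s.rs.resize(H);
    s.cs.resize(H);
    s.total = 1.0;
    return s;
  };

  auto init_state = [&](DipState& s) {
    const double invHH = 1.0 / static_cast<double>(HH);
    const double g0 = glv[0], g1 = glv[1], g2 = glv[2];
    const double* w = w1.data();
    std::fill(s.rs.begin(), s.rs.end(), 0.0);
    double total = 0.0;
    for (int k = 0; k < H; ++k) {
      const double wk1 = w[k], wk0 = 1.0 - wk1;
      const double uk = g0 * wk0 + g1 * wk1;
      const double dk = (g1 * wk0 + g2 * wk1) - uk;
      double* oc = s.mat.data() + static_cast<size_t>(k) * H;
      double cs = 0.0;
      for (int j = 0; j < H; ++j) {
        const double val = invHH * (uk + w[j] * dk);
        oc[j] = val;
        cs += val;
        s.rs[j] += val;
      }
      s.cs[k] = cs;
      total += cs;
    }
    s.total = total;
    return std::log(total);
  };

  // forward with checkpoints at block starts (post- and pre-emission)
  const int B = std::max(1, (int)std::ceil(std::sqrt((double)L)));
  const int n_ck = (L + B - 1) / B;
  std::vector<DipState> ck(n_ck);
  std::vector<std::vector<double>> ck_pre(n_ck);
  DipState cur = make_state(), nxt = make_state();
  double loglik = init_state(cur);
  ck[0] = cur;
  ck_pre[0].assign(HH, 1.0 / (double)HH);
  std::vector<double> pre_buf(HH);
  for (int l = 1; l < L; ++l) {
    const bool at_ck = (l % B == 0);
    loglik += dip_forward_step(cur, l, w1.data(), &glv[3 * l], pswitch[l - 1],
                               H, nxt, at_ck ? pre_buf.data() : nullptr);
    std::swap(cur, nxt);
    if (at_ck) {
      ck[l / B] = cur;
      ck_pre[l / B] = pre_buf;
    }
  }

  // backward with blockwise forward recomputation
  NumericMatrix post_g(L, 3);
  NumericVector dosage(L);
  // beta kept normalized to total 1; its row/col sums are refreshed on use
  std::vector<double> beta(HH, 1.0 / (double)HH), work(HH);
  std::vector<double> b_rs(H), b_cs(H), s0(H), s1(H);
  std::vector<double> blk_pre(static_cast<size_t>(B) * HH);
  std::vector<DipState> blk(2);
  blk[0] = make_state();
  blk[1] = make_state();

  auto emit_posterior = [&](int l, const double* pre_l) {
    const double* w = w1.data() + static_cast<size_t>(l) * H;
    double t0 = 0.0, t1 = 0.0, t2 = 0.0;
    for (int k = 0; k < H; ++k) {
      const double wk1 = w[k], wk0 = 1.0 - wk1;
      const double* prc = pre_l + static_cast<size_t>(k) * H;
      const double* bc = beta.data() + static_cast<size_t>(k) * H;
      double a0 = 0.0, a1 = 0.0;
      for (int j = 0; j < H; ++j) {
        const double q = prc[j] * bc[j];
        a0 += q * (1.0 - w[j]);
        a1 += q * w[j];
      }
      t0 += a0 * wk0;
      t1 += a0 * wk1 + a1 * wk0;
      t2 += a1 * wk1;
    }
    const double g0 = glv[3 * l] * t0, g1 = glv[3 * l + 1] * t1,
                 g2 = glv[3 * l + 2] * t2;
    const double tot = g0 + g1 + g2;
    post_g(l, 0) = g0 / tot;
    post_g(l, 1) = g1 / tot;
    post_g(l, 2) = g2 / tot;
    dosage[l] = (g1 + 2.0 * g2) / tot;
  };

  // backward step: beta at site l -> beta at site l-1 through emission at l
  auto backward_step = [&](int l) {
    const double p = pswitch[l - 1];
    const double invH = 1.0 / H;
    const double stay = 1.0 - p, jump = p * invH;
    const double g0 = glv[3 * l], g1 = glv[3 * l + 1], g2 = glv[3 * l + 2];
    const bool uniform = (g0 == g1 && g1 == g2);
    const double* w = w1.data() + static_cast<size_t>(l) * H;

    const double* C;
    double tot;
    if (uniform) {
      // C = g0 * beta: scalar factors cancel in the final normalization,
      // so use beta directly
      std::fill(s0.begin(), s0.end(), 0.0);
      tot = 0.0;
      for (int k = 0; k < H; ++k) {
        const double* bc = beta.data() + static_cast<size_t>(k) * H;
        double cs = 0.0;
        for (int j = 0; j < H; ++j) {
          cs += bc[j];
          s0[j] += bc[j];
        }
        s1[k] = cs;
        tot += cs;
      }
      C = beta.data();
    } else {
      std::fill(s0.begin(), s0.end(), 0.0);
      tot = 0.0;
      for (int k = 0; k < H; ++k) {
        const double wk1 = w[k], wk0 = 1.0 - wk1;
        const double uk = g0 * wk0 + g1 * wk1;
        const double dk = (g1 * wk0 + g2 * wk1) - uk;
        const double* bc = beta.data() + static_cast<size_t>(k) * H;
        double* wc = work.data() + static_cast<size_t>(k) * H;
        double cs = 0.0;
        for (int j = 0; j < H; ++j) {
          const double cval = bc[j] * (uk + w[j] * dk);
          wc[j] = cval;
          cs += cval;
          s0[j] += cval;
        }
        s1[k] = cs;
        tot += cs;
      }
      C = work.data();
    }
    const double s2 = stay * stay, sj = stay * jump, jj = jump * jump;
    const double inv_tot_scale = 1.0 / tot;  // renormalize in the same sweep
    for (int k = 0; k < H; ++k) {
      const double base_k = sj * s1[k] + jj * tot;
      const double* cc = C + static_cast<size_t>(k) * H;
      double* bc = beta.data() + static_cast<size_t>(k) * H;
      for (int j = 0; j < H; ++j) {
        bc[j] = (s2 * cc[j] + sj * s0[j] + base_k) * inv_tot_scale;
      }
    }
  };

  for (int c = n_ck - 1; c >= 0; --c) {
    const int start = c * B;
    const int end = std::min(L, start + B) - 1;  // inclusive
    // recompute pre-emission alphas within the block
    blk[0] = ck[c];
    std::copy(ck_pre[c].begin(), ck_pre[c].end(), blk_pre.begin());
    DipState* prev = &blk[0];
    DipState* scratch = &blk[1];
    for (int l = start + 1; l <= end; ++l) {
      dip_forward_step(*prev, l, w1.data(), &glv[3 * l], pswitch[l - 1], H,
                       *scratch, &blk_pre[static_cast<size_t>(l - start) * HH]);
      std::swap(prev, scratch);
    }
    for (int l = end; l >= start; --l) {
      emit_posterior(l, &blk_pre[static_cast<size_t>(l - start) * HH]);
      if (l > 0) backward_step(l);
    }
  }

  return List::create(_["posterior"] = post_g, _["dosage"] = dosage,
                      _["loglik"] = loglik);
}

// ---------------------------------------------------------------------------
// read-aware Gibbs engine
// ---------------------------------------------------------------------------

// Two-block Gibbs sampler over (gamete haplotype paths, read labels), the
// structure that makes read co-localization usable: given the current
// labels, each gamete's reference-copying path is sampled exactly by
// forward-filtering backward-sampling (FFBS); given the two sampled paths,
// the reads are conditionally independent, so every read's gamete label is
// resampled from its exact conditional. A global label-swap move (accepted
// with probability 1/2 by symmetry) keeps the two gamete identities
// exchangeable. Genotype posteriors are accumulated Rao-Blackwellized, from
// the per-gamete marginal forward-backward allele posteriors rather than
// the sampled paths.
//
// Read evidence is CSR: obs_site (0-based site index), obs_p1 / obs_p0
// (probability of the observed base given the underlying allele), read_ptr
// (offsets, length n_reads + 1). Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List cpp_read_aware(IntegerMatrix hap, NumericVector pswitch, double eps,
                    IntegerVector obs_site, NumericVector obs_p1,
                    NumericVector obs_p0, IntegerVector read_ptr,
                    int n_iter, int burn_in, bool keep_trace) {
  const int H = hap.nrow(), L = hap.ncol();
  const int n_reads = read_ptr.size() - 1;
  const int n_keep = n_iter - burn_in;
  if (n_keep <= 0) stop("burn_in must be smaller than gibbs_iterations");

  std::vector<double> w1 = emission_w1(hap, eps);
  std::vector<int> labels(n_reads);
  for (int r = 0; r < n_reads; ++r) labels[r] = unif_rand() < 0.5 ? 1 : 2;

  std::vector<double> m1(L), m0(L);
  std::vector<unsigned char> has_ev(L);
  std::vector<double> alpha(static_cast<size_t>(H) * L), beta(H);
  std::vector<double> a1(L, 0.0), a2(L, 0.0);
  std::vector<int> path1(L), path2(L);
  std::vector<double> acc0(L, 0.0), acc1(L, 0.0), acc2(L, 0.0);
  std::vector<int> touched(obs_site.begin(), obs_site.end());
  std::sort(touched.begin(), touched.end());
  touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
  IntegerMatrix trace(keep_trace ? n_reads : 0, keep_trace ? n_keep : 0);
  double ll = 0.0;
  std::vector<double> fwd_work(H);
  // first covered site of each read, for breakpoint proposals
  std::vector<int> first_site(n_reads, -1);
  for (int r = 0; r < n_reads; ++r) {
    if (read_ptr[r + 1] > read_ptr[r]) {
      int mn = obs_site[read_ptr[r]];
      for (int o = read_ptr[r]; o < read_ptr[r + 1]; ++o)
        mn = std::min(mn, (int)obs_site[o]);
      first_site[r] = mn;
    }
  }

  // sample a state index from the (normalized) column alpha[, l]
  auto sample_state = [&](const double* col) {
    double u = unif_rand();
    double cum = 0.0;
    for (int h = 0; h < H; ++h) {
      cum += col[h];
      if (u <= cum) return h;
    }
    return H - 1;
  };

  auto build_evidence = [&](const std::vector<int>& lab, int g) {
    for (int l : touched) {
      m1[l] = 1.0;
      m0[l] = 1.0;
      has_ev[l] = 0;
    }
    for (int r = 0; r < n_reads; ++r) {
      if (lab[r] != g) continue;
      for (int o = read_ptr[r]; o < read_ptr[r + 1]; ++o) {
        const int s = obs_site[o];
        m1[s] *= obs_p1[o];
        m0[s] *= obs_p0[o];
        has_ev[s] = 1;
      }
    }
  };

  // marginal label log-likelihood (paths integrated out) of a labelling
  auto label_loglik = [&](const std::vector<int>& lab) {
    build_evidence(lab, 1);
    double out = haploid_forward_ll(w1.data(), H, L, REAL(pswitch), m1.data(),
                                    m0.data(), has_ev.data(), fwd_work.data());
    build_evidence(lab, 2);
    out += haploid_forward_ll(w1.data(), H, L, REAL(pswitch), m1.data(),
                              m0.data(), has_ev.data(), fwd_work.data());
    return out;
  };

  // forward-backward marginal a_out plus an FFBS path draw for one gamete
  auto gamete_update = [&](int g, std::vector<double>& a_out,
                           std::vector<int>& path) {
    build_evidence(labels, g);
    haploid_posterior(w1.data(), H, L, REAL(pswitch), m1.data(), m0.data(),
                      has_ev.data(), alpha.data(), beta.data(), a_out.data(),
                      &ll);
    // backward path sampling from the stored forward probabilities
    path[L - 1] = sample_state(alpha.data() + static_cast<size_t>(L - 1) * H);
    for (int l = L - 2; l >= 0; --l) {
      const double p = pswitch[l];
      const double stay = 1.0 - p, jump = p / H;
      const double* col = alpha.data() + static_cast<size_t>(l) * H;
      const double a_next = col[path[l + 1]];
      const double p_stay = stay * a_next / (stay * a_next + jump);
      path[l] = (unif_rand() < p_stay) ? path[l + 1] : sample_state(col);
    }
  };

  for (int it = 0; it < n_iter; ++it) {
    gamete_update(1, a1, path1);
    gamete_update(2, a2, path2);

    if (it >= burn_in) {
      for (int l = 0; l < L; ++l) {
        acc0[l] += (1.0 - a1[l]) * (1.0 - a2[l]);
        acc1[l] += a1[l] * (1.0 - a2[l]) + a2[l] * (1.0 - a1[l]);
        acc2[l] += a1[l] * a2[l];
      }
    }

    // resample labels given the two sampled paths (exact conditional)
    for (int r = 0; r < n_reads; ++r) {
      double lo1 = 0.0, lo2 = 0.0;
      for (int o = read_ptr[r]; o < read_ptr[r + 1]; ++o) {
        const int s = obs_site[o];
        const double wp1 = w1[static_cast<size_t>(s) * H + path1[s]];
        const double wp2 = w1[static_cast<size_t>(s) * H + path2[s]];
        lo1 += std::log(wp1 * obs_p1[o] + (1.0 - wp1) * obs_p0[o]);
        lo2 += std::log(wp2 * obs_p1[o] + (1.0 - wp2) * obs_p0[o]);
      }
      const double p1 = 1.0 / (1.0 + std::exp(lo2 - lo1));
      labels[r] = unif_rand() < p1 ? 1 : 2;
    }
    // collapsed Metropolis breakpoint moves: flip the labels of every read
    // starting at or beyond a random site, to let whole phase blocks swap
    // (single-read Gibbs cannot cross between the symmetric modes)
    if (n_reads > 1) {
      double ll_cur = label_loglik(labels);
      for (int prop_i = 0; prop_i < 3; ++prop_i) {
        const int b = (int)std::floor(unif_rand() * L);
        std::vector<int> prop(labels);
        bool any = false;
        for (int r = 0; r < n_reads; ++r) {
          if (first_site[r] >= b) {
            prop[r] = 3 - prop[r];
            any = true;
          }
        }
        if (!any) continue;
        const double ll_prop = label_loglik(prop);
        if (std::log(unif_rand()) < ll_prop - ll_cur) {
          labels.swap(prop);
          ll_cur = ll_prop;
        }
      }
    }
    // global gamete-identity swap, accepted with probability 1/2
    if (unif_rand() < 0.5) {
      for (int r = 0; r < n_reads; ++r) labels[r] = 3 - labels[r];
    }
    if (keep_trace && it >= burn_in) {
      for (int r = 0; r < n_reads; ++r) trace(r, it - burn_in) = labels[r];
    }
    if ((it & 7) == 0) Rcpp::checkUserInterrupt();
  }

  // finalize the reported labels as the per-read argmax given the last
  // sampled gamete paths (the trace keeps the raw posterior samples)
  for (int r = 0; r < n_reads; ++r) {
    double lo1 = 0.0, lo2 = 0.0;
    for (int o = read_ptr[r]; o < read_ptr[r + 1]; ++o) {
      const int s = obs_site[o];
      const double wp1 = w1[static_cast<size_t>(s) * H + path1[s]];
      const double wp2 = w1[static_cast<size_t>(s) * H + path2[s]];
      lo1 += std::log(wp1 * obs_p1[o] + (1.0 - wp1) * obs_p0[o]);
      lo2 += std::log(wp2 * obs_p1[o] + (1.0 - wp2) * obs_p0[o]);
    }
    if (lo1 != lo2) labels[r] = lo1 > lo2 ? 1 : 2;
  }

  NumericMatrix post(L, 3);
  NumericVector dosage(L);
  for (int l = 0; l < L; ++l) {
    post(l, 0) = acc0[l] / n_keep;
    post(l, 1) = acc1[l] / n_keep;
    post(l, 2) = acc2[l] / n_keep;
    dosage[l] = post(l, 1) + 2.0 * post(l, 2);
  }
  List out = List::create(
    _["posterior"] = post, _["dosage"] = dosage,
    _["labels"] = IntegerVector(labels.begin(), labels.end()),
    _["allele_prob_1"] = NumericVector(a1.begin(), a1.end()),
    _["allele_prob_2"] = NumericVector(a2.begin(), a2.end()));
  if (keep_trace) out["trace"] = trace;
  return out;
}
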