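// Monte Carlo kernels for the confined phantom lattice ring polymer.
//
// Site geometry is passed in as a neighbor table (M x 6, 0-based site ids,
// -1 = no accessible neighbor in that direction), so the kernels are
// agnostic of the actual confinement shape. All randomness comes from R's
// RNG (unif_rand) so results are reproducible through set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int rint_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline bool is_neighbor(const IntegerMatrix& nb, int a, int b) {
  for (int s = 0; s < 6; ++s) if (nb(a, s) == b) return true;
  return false;
}

// energy of region `reg` (0-based) against all co-occupants of site `site`,
// skipping regions flagged in `skip` (moving set). Returns +Inf on a
// hard-core (infinite-coupling) contact.
static inline double site_energy(const std::vector<std::vector<int> >& occ,
                                 const NumericMatrix& eps,
                                 const LogicalMatrix& inf_mask,
                                 int site, int reg,
                                 const int* skip, int nskip) {
  double e = 0.0;
  const std::vector<int>& v = occ[site];
  for (size_t t = 0; t < v.size(); ++t) {
    int k = v[t];
    bool sk = false;
    for (int q = 0; q < nskip; ++q) if (skip[q] == k) { sk = true; break; }
    if (sk) continue;
    if (inf_mask(reg, k)) return R_PosInf;
    e += eps(reg, k);
  }
  return e;
}

static inline void occ_remove(std::vector<std::vector<int> >& occ, int site, int reg) {
  std::vector<int>& v = occ[site];
  for (size_t t = 0; t < v.size(); ++t)
    if (v[t] == reg) { v[t] = v.back(); v.pop_back(); return; }
}

// Metropolis sampler.
//   nb          M x 6 neighbor table
//   init        length-N 0-based site ids (legal ring)
//   monomer_reg length-N map monomer -> 0-based region index, -1 if not a center
//   centers     region -> monomer index (0-based)
//   eps/inf_mask n x n couplings
//   tether_ok   length-M logical; monomer `tether_mono` restricted to TRUE
//               sites (tether_mono = -1 disables)
// Snapshot schedule: burn_sweeps, then n_samples snapshots thin_sweeps apart.
// [[Rcpp::export]]
List mc_sample_cpp(const IntegerMatrix& nb, const IntegerVector& init,
                   const IntegerVector& monomer_reg, const IntegerVector& centers,
                   const NumericMatrix& eps, const LogicalMatrix& inf_mask,
                   int burn_sweeps, int n_samples, int thin_sweeps,
                   bool keep_monomers,
                   double p_translate, double p_pair,
                   const LogicalVector& tether_ok, int tether_mono) {
  const int M = nb.nrow(), N = init.size(), nreg = eps.nrow();
  RNGScope scope;

  std::vector<int> pos(init.begin(), init.end());
  std::vector<std::vector<int> > occ(M);
  for (int r = 0; r < nreg; ++r) occ[pos[centers[r]]].push_back(r);

  IntegerMatrix out_centers(n_samples, nreg);
  IntegerMatrix out_mono = keep_monomers ? IntegerMatrix(n_samples, N)
                                         : IntegerMatrix(0, 0);
  double n_prop = 0.0, n_acc = 0.0;
  std::vector<int> cand(6);
  std::vector<int> newpos(N);

  long total_sweeps = (long)burn_sweeps + (long)n_samples * thin_sweeps;
  int sample_idx = 0;
  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int att = 0; att < N; ++att) {
      double u = unif_rand();
      n_prop += 1.0;
      if (u < p_translate) {
        // rigid translation of the whole ring; co-occupancy pattern (and
        // hence energy) is preserved, so acceptance = legality
        int d = rint_below(6);
        bool ok = true;
        for (int i = 0; i < N; ++i) {
          int np = nb(pos[i], d);
          if (np < 0) { ok = false; break; }
          newpos[i] = np;
        }
        if (ok && tether_mono >= 0 && !tether_ok[newpos[tether_mono]]) ok = false;
        if (ok) {
          for (int r = 0; r < nreg; ++r) occ[pos[centers[r]]].clear();
          for (int i = 0; i < N; ++i) pos[i] = newpos[i];
          for (int r = 0; r < nreg; ++r) occ[pos[centers[r]]].push_back(r);
          n_acc += 1.0;
        }
      } else if (u < p_translate + p_pair) {
        // translate a bonded monomer pair (i, i+1) by one lattice step
        int i = rint_below(N), j = (i + 1) % N;
        int ip = (i - 1 + N) % N, jn = (j + 1) % N;
        int d = rint_below(6);
        int ni = nb(pos[i], d), njp = nb(pos[j], d);
        if (ni < 0 || njp < 0) continue;
        if (!is_neighbor(nb, pos[ip], ni) || !is_neighbor(nb, njp, pos[jn])) continue;
        if (tether_mono == i && !tether_ok[ni]) continue;
        if (tether_mono == j && !tether_ok[njp]) continue;
        int regs[2] = { monomer_reg[i], monomer_reg[j] };
        int news[2] = { ni, njp };
        int olds[2] = { pos[i], pos[j] };
        int skip[2]; int nskip = 0;
        for (int q = 0; q < 2; ++q) if (regs[q] >= 0) skip[nskip++] = regs[q];
        double dE = 0.0; bool inf_hit = false;
        for (int q = 0; q < 2; ++q) {
          if (regs[q] < 0) continue;
          double e_new = site_energy(occ, eps, inf_mask, news[q], regs[q], skip, nskip);
          if (!R_finite(e_new)) { inf_hit = true; break; }
          double e_old = site_energy(occ, eps, inf_mask, olds[q], regs[q], skip, nskip);
          dE += e_new - e_old;
        }
        if (inf_hit) continue;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          for (int q = 0; q < 2; ++q) if (regs[q] >= 0) occ_remove(occ, olds[q], regs[q]);
          pos[i] = ni; pos[j] = njp;
          for (int q = 0; q < 2; ++q) if (regs[q] >= 0) occ[news[q]].push_back(regs[q]);
          n_acc += 1.0;
        }
      } else {
        // single-monomer kink move: resite monomer i among the common
        // neighbors of its two ring neighbors (a symmetric proposal set
        // that does not depend on the current position of i)
        int i = rint_below(N);
        int a = pos[(i - 1 + N) % N], b = pos[(i + 1) % N];
        int nc = 0;
        if (a == b) {
          for (int s = 0; s < 6; ++s) { int v = nb(a, s); if (v >= 0) cand[nc++] = v; }
        } else {
          for (int s = 0; s < 6; ++s) {
            int v = nb(a, s);
            if (v >= 0 && is_neighbor(nb, b, v)) cand[nc++] = v;
          }
        }
        if (nc == 0) continue;
        int np = cand[rint_below(nc)];
        if (np == pos[i]) { n_acc += 1.0; continue; }  // null move
        if (tether_mono == i && !tether_ok[np]) continue;
        int reg = monomer_reg[i];
        double dE = 0.0;
        if (reg >= 0) {
          int skip1 = reg;
          double e_new = site_energy(occ, eps, inf_mask, np, reg, &skip1, 1);
          if (!R_finite(e_new)) continue;
          double e_old = site_energy(occ, eps, inf_mask, pos[i], reg, &skip1, 1);
          dE = e_new - e_old;
        }
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          if (reg >= 0) { occ_remove(occ, pos[i], reg); occ[np].push_back(reg); }
          pos[i] = np;
          n_acc += 1.0;
        }
      }
    }
    if (sweep >= burn_sweeps && ((sweep - burn_sweeps + 1) % thin_sweeps == 0)) {
      if (sample_idx < n_samples) {
        for (int r = 0; r < nreg; ++r) out_centers(sample_idx, r) = pos[centers[r]];
        if (keep_monomers)
          for (int i = 0; i < N; ++i) out_mono(sample_idx, i) = pos[i];
        ++sample_idx;
      }
    }
  }

  return List::create(_["centers"] = out_centers,
                      _["monomers"] = out_mono,
                      _["acceptance"] = n_acc / n_prop,
                      _["n_samples"] = sample_idx);
}

// ---- exact sampling of the non-interacting confined closed walk --------
//
// With eps == 0 every legal ring configuration has equal weight, so rings
// can be drawn exactly (i.i.d.) by conditioning each lattice step on the
// number of walks that still close the ring, i.e. on powers of the
// confinement adjacency operator A.

// one application of A (counts of walks extended by one step)
static inline void adj_apply(const IntegerMatrix& nb, const std::vector<double>& v,
                             std::vector<double>& w) {
  const int M = nb.nrow();
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < M; ++i) {
    double vi = v[i];
    if (vi == 0.0) continue;
    for (int d = 0; d < 6; ++d) { int q = nb(i, d); if (q >= 0) w[q] += vi; }
  }
}

// log closed-walk counts log (A^N)_{ss} for the requested start sites
// (0-based); the caller may exploit confinement symmetries to query only
// orbit representatives. -Inf if no closed walk exists.
// [[Rcpp::export]]
NumericVector ring_logcounts_cpp(const IntegerMatrix& nb, int N,
                                 const IntegerVector& starts) {
  const int M = nb.nrow();
  std::vector<double> v(M), w(M);
  NumericVector out(starts.size());
  for (int t = 0; t < starts.size(); ++t) {
    int s = starts[t];
    std::fill(v.begin(), v.end(), 0.0); v[s] = 1.0;
    double logscale = 0.0, tot = 0.0;
    for (int step = 0; step < N; ++step) {
      adj_apply(nb, v, w);
      tot = 0.0;
      for (int i = 0; i < M; ++i) tot += w[i];
      if (tot == 0.0) { logscale = R_NegInf; break; }
      for (int i = 0; i < M; ++i) v[i] = w[i] / tot;
      logscale += std::log(tot);
    }
    out[t] = (R_finite(logscale) && v[s] > 0.0) ? logscale + std::log(v[s]) : R_NegInf;
  }
  return out;
}

// Draw one ring per element of start_sites (0-based site id of monomer 0,
// pre-drawn by the caller proportionally to the closed-walk counts). The
// backward weight table B_j = A^j e_{r0} is built once per distinct start
// site and reused; rows keep the caller's order, so results are i.i.d.
// conditioned on the starts.
// [[Rcpp::export]]
IntegerMatrix ring_exact_sample_cpp(const IntegerMatrix& nb, int N,
                                    const IntegerVector& start_sites) {
  const int M = nb.nrow();
  const int S = start_sites.size();
  RNGScope scope;

  // group sample indices by start site
  std::vector<std::vector<int> > by_start(M);
  for (int s = 0; s < S; ++s) by_start[start_sites[s]].push_back(s);

  std::vector<double> v(M), w(M);
  std::vector<double> B((size_t)M * N, 0.0);
  IntegerMatrix out(S, N);

  for (int r0 = 0; r0 < M; ++r0) {
    if (by_start[r0].empty()) continue;
    // columns of B normalized to sum 1: only within-column ratios are used
    std::fill(v.begin(), v.end(), 0.0); v[r0] = 1.0;
    for (int i = 0; i < M; ++i) B[i] = v[i];
    for (int j = 1; j < N; ++j) {
      adj_apply(nb, v, w);
      double tot = 0.0;
      for (int i = 0; i < M; ++i) tot += w[i];
      if (tot == 0.0) stop("no closed walk of length N from a requested start site");
      for (int i = 0; i < M; ++i) { v[i] = w[i] / tot; B[(size_t)j * M + i] = v[i]; }
    }
    if (B[(size_t)0 * M + r0] <= 0.0) stop("internal error: empty start weight");

    for (size_t t = 0; t < by_start[r0].size(); ++t) {
      int smp = by_start[r0][t];
      out(smp, 0) = r0;
      int cur = r0;
      for (int k = 0; k + 1 < N; ++k) {
        // weight of candidate u: number of (N-k-1)-step walks u -> r0,
        // which by symmetry of A is B_{N-k-1}(u)
        int rem = N - k - 1;
        double wts[6]; int ids[6]; int nc = 0; double tot = 0.0;
        for (int d = 0; d < 6; ++d) {
          int q = nb(cur, d);
          if (q < 0) continue;
          double wq = B[(size_t)rem * M + q];
          if (wq <= 0.0) continue;
          ids[nc] = q; wts[nc] = wq; tot += wq; ++nc;
        }
        if (nc == 0) stop("ring cannot be closed from a sampled prefix");  // unreachable
        double uu = unif_rand() * tot, a2 = 0.0;
        int pick = nc - 1;
        for (int c = 0; c < nc; ++c) { a2 += wts[c]; if (uu <= a2) { pick = c; break; } }
        cur = ids[pick];
        out(smp, k + 1) = cur;
      }
    }
  }
  return out;
}

// co-occupancy frequency matrix from an S x n matrix of center site ids
// [[Rcpp::export]]
NumericMatrix cooccupancy_cpp(const IntegerMatrix& center_sites) {
  const int S = center_sites.nrow(), n = center_sites.ncol();
  NumericMatrix f(n, n);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) {
      int ci = center_sites(s, i);
      for (int j = i + 1; j < n; ++j)
        if (ci == center_sites(s, j)) { f(i, j) += 1.0; }
    }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      f(i, j) /= S; f(j, i) = f(i, j);
    }
  return f;
}
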