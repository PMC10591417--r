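// Asynchronous birth/death Monte Carlo engine for the senescence lattice model.
//
// State is passed in from R (one column of `alleles` per site) and returned in
// the same layout, so runs can be stopped, inspected, modified and resumed
// from R.  All randomness is drawn from R's RNG stream: a run is reproducible
// from set.seed() alone.
//
// Individuals are stored in slot-indexed arrays with a site -> slot
// indirection so that a diffusion swap exchanges two integers instead of
// copying genomes.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <climits>

using namespace Rcpp;

static inline int rint_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// failures before first success at probability p, p in (0,1)
static inline int geom_gap(double p) {
  return (int)std::floor(std::log(unif_rand()) / std::log1p(-p));
}

// independent per-position bit flips at probability p, via geometric skipping
static inline void mutate_positions(Rbyte* g, const std::vector<int>& pos, double p) {
  const int m = (int)pos.size();
  if (p <= 0.0) return;
  if (p >= 1.0) {
    for (int i = 0; i < m; ++i) g[pos[i]] ^= 1;
    return;
  }
  int i = geom_gap(p);
  while (i < m) {
    g[pos[i]] ^= 1;
    i += 1 + geom_gap(p);
  }
}

// [[Rcpp::export]]
List engine_run(IntegerVector occ_in, IntegerVector age_in, IntegerVector tag_in,
                RawMatrix alleles_in, IntegerVector fec_pos0, IntegerVector sen_pos0,
                IntegerVector target_in, int phase_in, int t0, int ngen, List par) {
  const int N       = as<int>(par["N"]);
  const int Lf      = (int)fec_pos0.size();
  const int La      = (int)sen_pos0.size();
  const int L       = Lf + La;
  const int N2      = N * N;
  const double delta0 = as<double>(par["delta0"]);
  const double b      = as<double>(par["b"]);
  const int    nrad   = as<int>(par["n"]);
  const int    T      = as<int>(par["T"]);
  const double prec   = as<double>(par["prec"]);
  const double pf     = as<double>(par["pf"]);
  const double pa     = as<double>(par["pa"]);
  const double D      = as<double>(par["D"]);
  const bool sexual       = as<bool>(par["sexual"]);
  const bool directional  = as<bool>(par["directional"]);
  const bool config_field = as<bool>(par["config_field"]);
  const bool evb          = as<bool>(par["evolvable_baseline"]);
  // immediate refill: a site vacated by death is contested in the same
  // elementary step; otherwise death and birth are mutually exclusive and
  // an emptied site can only be refilled when drawn again later
  const bool imm = par.containsElementNamed("immediate_refill") ?
    as<bool>(par["immediate_refill"]) : true;
  // site visiting order within a generation: a fresh random permutation
  // (every site exactly once, one death trial per occupant at exactly
  // delta_i) or i.i.d. uniform draws with replacement
  const bool perm_order = par.containsElementNamed("site_order") ?
    (as<std::string>(par["site_order"]) == "permutation") : false;

  if (alleles_in.nrow() != L || alleles_in.ncol() != N2)
    stop("allele matrix must be (L_f + L_a) x N^2");
  if (occ_in.size() != N2 || age_in.size() != N2 || tag_in.size() != N2)
    stop("state vectors must have length N^2");
  if (target_in.size() != Lf) stop("target length must equal L_f");

  // slot-indexed individual state (slot i initially holds site i)
  std::vector<unsigned char> occ(N2), tag(N2);
  std::vector<int> age(N2), s(N2), na(N2), tmax(N2), slot_of(N2);
  RawMatrix alleles = clone(alleles_in);
  Rbyte* AL = alleles.begin();  // column-major, one column of L bytes per slot
  std::vector<unsigned char> targ(Lf);
  IntegerVector target = clone(target_in);
  int phase = phase_in;

  std::vector<int> fpos(Lf), spos(La);
  for (int k = 0; k < Lf; ++k) fpos[k] = fec_pos0[k];
  for (int j = 0; j < La; ++j) spos[j] = sen_pos0[j];
  for (int k = 0; k < Lf; ++k) targ[k] = (unsigned char)target[k];
  int ones = 0;
  for (int k = 0; k < Lf; ++k) ones += targ[k];

  std::vector<double> powb(Lf + 1);
  powb[0] = 1.0;
  for (int k = 1; k <= Lf; ++k) powb[k] = powb[k - 1] * b;
  const double powb_max = powb[Lf];

  // derived per-individual quantities
  for (int i = 0; i < N2; ++i) {
    slot_of[i] = i;
    occ[i] = (unsigned char)occ_in[i];
    age[i] = age_in[i];
    tag[i] = (unsigned char)tag_in[i];
    int si = 0, ni = 0;
    if (occ[i]) {
      const Rbyte* gi = AL + (size_t)i * L;
      for (int k = 0; k < Lf; ++k) si += (gi[fpos[k]] == targ[k]);
      for (int j = 0; j < La; ++j) ni += gi[spos[j]];
    }
    s[i] = si;
    na[i] = ni;
    tmax[i] = ni > 0 ? (int)std::floor((1.0 - delta0) / (0.01 * ni)) : INT_MAX;
  }

  // neighbourhood offsets: reproduction radius nrad, diffusion radius 1
  std::vector<int> ndx, ndy;
  for (int dx = -nrad; dx <= nrad; ++dx)
    for (int dy = -nrad; dy <= nrad; ++dy)
      if (dx != 0 || dy != 0) { ndx.push_back(dx); ndy.push_back(dy); }
  const int K = (int)ndx.size();
  static const int d8x[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int d8y[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  const int Dint = (int)std::floor(D);
  const double Dfrac = D - Dint;

  const int NMET = 14;
  NumericMatrix metrics(ngen, NMET);
  CharacterVector metnames = CharacterVector::create(
      "t", "occupancy", "mean_alpha", "mean_age", "mean_mortality",
      "mean_baseline", "mean_fecundity", "corr_alpha_fec", "mean_match",
      "mean_hamming", "invader_freq", "deaths", "births", "swaps");
  colnames(metrics) = metnames;

  std::vector<int> order;
  if (perm_order) {
    order.resize(N2);
    for (int i = 0; i < N2; ++i) order[i] = i;
  }

  std::vector<int> cand(K > 8 ? K : 8);
  std::vector<double> w(K > 8 ? K : 8);
  std::vector<Rbyte> child(L);
  std::vector<int> picked(8);

  for (int g = 1; g <= ngen; ++g) {
    const int t = t0 + g;  // absolute generation index being produced

    // directional target drift: one locus flips every T generations,
    // before the generation's updates
    if (directional && (t - 1) > 0 && ((t - 1) % T) == 0) {
      int kflip = -1;
      if (phase > 0) {  // ascending: flip a random 0 to 1
        int nz = Lf - ones, pick = rint_below(nz), seen = 0;
        for (int k = 0; k < Lf; ++k)
          if (!targ[k] && seen++ == pick) { kflip = k; break; }
        targ[kflip] = 1; ++ones;
        if (ones == Lf) phase = -1;
      } else {          // descending: flip a random 1 to 0
        int pick = rint_below(ones), seen = 0;
        for (int k = 0; k < Lf; ++k)
          if (targ[k] && seen++ == pick) { kflip = k; break; }
        targ[kflip] = 0; --ones;
        if (ones == 0) phase = 1;
      }
      const int pos = fpos[kflip];
      const unsigned char v = targ[kflip];
      for (int sl = 0; sl < N2; ++sl)
        if (occ[sl]) s[sl] += (AL[(size_t)sl * L + pos] == v) ? 1 : -1;
    }

    long deaths = 0, births = 0, swaps = 0;

    if (perm_order) {  // Fisher-Yates reshuffle each generation
      for (int i = N2 - 1; i > 0; --i)
        std::swap(order[i], order[rint_below(i + 1)]);
    }

    for (int step = 0; step < N2; ++step) {
      const int idx = perm_order ? order[step] : rint_below(N2);
      const int sl = slot_of[idx];

      const bool was_occ = occ[sl];
      if (was_occ) {
        double dp;
        if (evb) dp = 0.002 + 0.01 * na[sl];
        else if (na[sl] == 0) dp = delta0;
        else if (age[sl] > tmax[sl]) dp = 1.0;
        else dp = delta0 + 0.01 * na[sl] * age[sl];
        if (unif_rand() < dp) { occ[sl] = 0; ++deaths; }
      }

      if (!occ[sl] && (imm || !was_occ)) {
        // the vacated (or already empty) site is contested immediately
        int nc = 0;
        if (config_field) {
          int npick = 0;
          while (npick < 8) {
            int site = rint_below(N2);
            if (site == idx) continue;
            bool dup = false;
            for (int q = 0; q < npick; ++q)
              if (picked[q] == site) { dup = true; break; }
            if (!dup) picked[npick++] = site;
          }
          for (int q = 0; q < 8; ++q) {
            int cs = slot_of[picked[q]];
            if (occ[cs]) { cand[nc] = cs; w[nc] = powb[s[cs]]; ++nc; }
          }
        } else {
          const int r = idx / N, c = idx % N;
          for (int q = 0; q < K; ++q) {
            int rr = r + ndx[q]; if (rr < 0) rr += N; else if (rr >= N) rr -= N;
            int cc = c + ndy[q]; if (cc < 0) cc += N; else if (cc >= N) cc -= N;
            int cs = slot_of[rr * N + cc];
            if (occ[cs]) { cand[nc] = cs; w[nc] = powb[s[cs]]; ++nc; }
          }
        }

        bool born = false;
        unsigned char ctag = 0;
        if (!sexual && nc >= 1) {
          double tot = 0; for (int q = 0; q < nc; ++q) tot += w[q];
          double u = unif_rand() * tot; int q1 = 0;
          for (; q1 < nc - 1; ++q1) { u -= w[q1]; if (u <= 0) break; }
          const int p1 = cand[q1];
          std::memcpy(child.data(), AL + (size_t)p1 * L, L);
          ctag = tag[p1];
          born = true;
        } else if (sexual && nc >= 2) {
          double tot = 0; for (int q = 0; q < nc; ++q) tot += w[q];
          double u = unif_rand() * tot; int q1 = 0;
          for (; q1 < nc - 1; ++q1) { u -= w[q1]; if (u <= 0) break; }
          const int p1 = cand[q1];
          // second parent without replacement (dioecy)
          cand[q1] = cand[nc - 1]; w[q1] = w[nc - 1];
          tot = 0; for (int q = 0; q < nc - 1; ++q) tot += w[q];
          u = unif_rand() * tot; int q2 = 0;
          for (; q2 < nc - 2; ++q2) { u -= w[q2]; if (u <= 0) break; }
          const int p2 = cand[q2];

          const Rbyte* A = AL + (size_t)p1 * L;
          const Rbyte* B = AL + (size_t)p2 * L;
          if (prec > 0 && (prec >= 1.0 || unif_rand() < prec)) {
            const int cut = 1 + rint_below(L - 1);  // internal inter-locus point
            if (unif_rand() < 0.5) std::swap(A, B);
            std::memcpy(child.data(), A, cut);
            std::memcpy(child.data() + cut, B + cut, L - cut);
          } else {
            std::memcpy(child.data(), unif_rand() < 0.5 ? A : B, L);
          }
          ctag = tag[p1] | tag[p2];
          born = true;
        }

        if (born) {
          mutate_positions(child.data(), fpos, pf);
          mutate_positions(child.data(), spos, pa);
          std::memcpy(AL + (size_t)sl * L, child.data(), L);
          int si = 0, ni = 0;
          for (int k = 0; k < Lf; ++k) si += (child[fpos[k]] == targ[k]);
          for (int j = 0; j < La; ++j) ni += child[spos[j]];
          s[sl] = si; na[sl] = ni;
          tmax[sl] = ni > 0 ? (int)std::floor((1.0 - delta0) / (0.01 * ni)) : INT_MAX;
          occ[sl] = 1; age[sl] = 0; tag[sl] = ctag;
          ++births;
        }
      }

      // spatial mixing: D swap trials appended to every elementary update
      if (D > 0) {
        int m = Dint;
        if (Dfrac > 0 && unif_rand() < Dfrac) ++m;
        for (int q = 0; q < m; ++q) {
          const int u1 = rint_below(N2);
          const int d = rint_below(8);
          int rr = u1 / N + d8x[d]; if (rr < 0) rr += N; else if (rr >= N) rr -= N;
          int cc = u1 % N + d8y[d]; if (cc < 0) cc += N; else if (cc >= N) cc -= N;
          const int u2 = rr * N + cc;
          std::swap(slot_of[u1], slot_of[u2]);
        }
        swaps += m;
      }
    }

    // synchronous age update at the end of the generation
    for (int sl = 0; sl < N2; ++sl)
      if (occ[sl]) ++age[sl];

    // lattice summaries over occupied sites
    long nocc = 0, ninv = 0;
    double sa = 0, sage = 0, smort = 0, sbase = 0, sfec = 0, smatch = 0;
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int sl = 0; sl < N2; ++sl) {
      if (!occ[sl]) continue;
      ++nocc;
      const double a = evb ? 0.0 : 0.01 * na[sl];
      const double base = evb ? 0.002 + 0.01 * na[sl] : delta0;
      double dp;
      if (evb) dp = base;
      else if (na[sl] == 0) dp = delta0;
      else if (age[sl] > tmax[sl]) dp = 1.0;
      else dp = delta0 + a * age[sl];
      const double fec = powb[s[sl]] / powb_max;
      sa += a; sage += age[sl]; smort += dp; sbase += base;
      sfec += fec; smatch += s[sl];
      sx += a; sy += fec; sxx += a * a; syy += fec * fec; sxy += a * fec;
      if (tag[sl]) ++ninv;
    }
    const int row = g - 1;
    metrics(row, 0) = t;
    metrics(row, 1) = (double)nocc / N2;
    if (nocc > 0) {
      metrics(row, 2) = sa / nocc;
      metrics(row, 3) = sage / nocc;
      metrics(row, 4) = smort / nocc;
      metrics(row, 5) = sbase / nocc;
      metrics(row, 6) = sfec / nocc;
      const double vx = sxx / nocc - (sx / nocc) * (sx / nocc);
      const double vy = syy / nocc - (sy / nocc) * (sy / nocc);
      if (vx > 1e-16 && vy > 1e-16)
        metrics(row, 7) = (sxy / nocc - (sx / nocc) * (sy / nocc)) / std::sqrt(vx * vy);
      else
        metrics(row, 7) = NA_REAL;
      metrics(row, 8) = smatch / nocc;
      metrics(row, 9) = Lf - smatch / nocc;
      metrics(row, 10) = (double)ninv / nocc;
    } else {
      for (int q = 2; q <= 10; ++q) metrics(row, q) = NA_REAL;
    }
    metrics(row, 11) = (double)deaths;
    metrics(row, 12) = (double)births;
    metrics(row, 13) = (double)swaps;
  }

  // write final state back in site order
  IntegerVector occ_out(N2), age_out(N2), tag_out(N2);
  RawMatrix alleles_out(L, N2);
  for (int i = 0; i < N2; ++i) {
    const int sl = slot_of[i];
    occ_out[i] = occ[sl];
    age_out[i] = age[sl];
    tag_out[i] = tag[sl];
    std::memcpy(alleles_out.begin() + (size_t)i * L, AL + (size_t)sl * L, L);
  }
  for (int k = 0; k < Lf; ++k) target[k] = targ[k];

  return List::create(
      _["metrics"] = metrics, _["occ"] = occ_out, _["age"] = age_out,
      _["tag"] = tag_out, _["alleles"] = alleles_out, _["target"] = target,
      _["phase"] = phase, _["t"] = t0 + ngen);
}
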