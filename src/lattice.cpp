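#include <Rcpp.h>
using namespace Rcpp;

// Explicit one-step update of a scalar lattice field:
//   out(P) = [ f(P)*(1-lambda) + (lambda/6) * sum_{6 face neighbors} f
//              + chi(P)*influx ] * (1 - decay)
// Under the no-flux boundary rule a boundary site keeps the lambda/6
// share of each missing neighbor itself (mass conserving); under the
// absorbing rule that share is lost.
//
// Sources are given either as 1-based linear indices (srcIdx) or, for a
// spatially uniform influx (vascular drug delivery), via uniformInflux.
// [[Rcpp::export(name = ".latticeStepC")]]
NumericVector latticeStepC(NumericVector field, IntegerVector dims,
                           double lambda, IntegerVector srcIdx,
                           double influx, double uniformInflux,
                           double decay, bool noflux) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (field.size() != n) stop("field length does not match dims");
  NumericVector out(n);
  const double keep = 1.0 - lambda, w = lambda / 6.0, surv = 1.0 - decay;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double f = field[idx];
        double nb = 0.0;
        int miss = 0;
        if (i > 0)      nb += field[idx - sx]; else ++miss;
        if (i < nx - 1) nb += field[idx + sx]; else ++miss;
        if (j > 0)      nb += field[idx - sy]; else ++miss;
        if (j < ny - 1) nb += field[idx + sy]; else ++miss;
        if (k > 0)      nb += field[idx - sz]; else ++miss;
        if (k < nz - 1) nb += field[idx + sz]; else ++miss;
        double v = f * keep + w * nb + uniformInflux;
        if (noflux && miss > 0) v += w * miss * f;
        out[idx] = v * surv;
      }
    }
  }
  if (influx != 0.0) {
    for (R_xlen_t s = 0; s < srcIdx.size(); ++s) {
      R_xlen_t p = srcIdx[s] - 1;
      if (p < 0 || p >= n) stop("source index out of bounds");
      out[p] += influx * surv;
    }
  }
  return out;
}

// In-place write into the engine's privately owned occupancy array,
// avoiding R's copy-on-write for single-site updates in the agent
// sweep.  `x` must never be shared with user-visible objects.
// [[Rcpp::export(name = ".setIntInPlace")]]
void setIntInPlace(IntegerVector x, R_xlen_t idx, int value) {
  if (idx < 1 || idx > x.size()) stop("index out of bounds");
  x[idx - 1] = value;
}

// ---- full agent sweep ---------------------------------------------------
// C++ version of the per-step agent loop (phenotype switching, migration,
// division, apoptosis bookkeeping).  Mirrors the R reference path used by
// advanceCell(); all vectors are the engine's private working copies and
// are updated in place.  Parameter vector layout (see .sweepParams in R):
//  0 dt, 1 K_L_mm, 2 lambda0_mm, 3 K_GC_1, 4 lambda0_1, 5 beta1_GC,
//  6 K_GC_2, 7 lambda0_2, 8 beta2_GC, 9 K_T_mm, 10 P0_mm, 11 E0,
//  12 beta_w, 13 K_D, 14 K_W, 15 P0_ob, 16 beta_ob, 17 K_O_RL,
//  18 P0_oc, 19 P_pathway_oc, 20 epsilon_ratio, 21 ampApop, 22 ampProl
// [[Rcpp::export(name = ".sweepAgentsC")]]
int sweepAgentsC(IntegerVector order, int nAgents,
                 IntegerVector type, IntegerVector ai, IntegerVector aj,
                 IntegerVector ak, IntegerVector phen, IntegerVector phase,
                 IntegerVector phaseStep, IntegerVector cd,
                 IntegerVector rest, LogicalVector alive,
                 IntegerVector occ, IntegerVector dims,
                 NumericVector fDKK1, NumericVector fRANKL,
                 NumericVector fOPG, NumericVector fTNFa,
                 NumericVector fBHQ, NumericVector fGC, NumericVector fLDM,
                 NumericVector par, IntegerMatrix cyclen,
                 IntegerVector restlen) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const double VTAB[7] = {1.0 / 16, 1, 1, 1.0 / 4, 1.0 / 4, 1.0 / 8,
                          1.0 / 8};
  int n = nAgents;

  auto lin = [&](int i, int j, int k) -> R_xlen_t {
    return (i - 1) + (R_xlen_t)(j - 1) * sy + (R_xlen_t)(k - 1) * sz;
  };
  auto countOcc = [&](int i, int j, int k) -> int {
    int c = 0;
    if (i < nx && occ[lin(i + 1, j, k)]) ++c;
    if (i > 1 && occ[lin(i - 1, j, k)]) ++c;
    if (j < ny && occ[lin(i, j + 1, k)]) ++c;
    if (j > 1 && occ[lin(i, j - 1, k)]) ++c;
    if (k < nz && occ[lin(i, j, k + 1)]) ++c;
    if (k > 1 && occ[lin(i, j, k - 1)]) ++c;
    return c;
  };
  // roulette over empty face neighbors; returns linear index or -1 and
  // fills (ci, cj, ck)
  auto pickEmpty = [&](int i, int j, int k, int &ci, int &cj,
                       int &ck) -> R_xlen_t {
    R_xlen_t cand[6]; int cii[6], cjj[6], ckk[6]; int m = 0;
    R_xlen_t li;
    if (i < nx && !occ[li = lin(i + 1, j, k)]) { cand[m] = li;
      cii[m] = i + 1; cjj[m] = j; ckk[m] = k; ++m; }
    if (i > 1 && !occ[li = lin(i - 1, j, k)]) { cand[m] = li;
      cii[m] = i - 1; cjj[m] = j; ckk[m] = k; ++m; }
    if (j < ny && !occ[li = lin(i, j + 1, k)]) { cand[m] = li;
      cii[m] = i; cjj[m] = j + 1; ckk[m] = k; ++m; }
    if (j > 1 && !occ[li = lin(i, j - 1, k)]) { cand[m] = li;
      cii[m] = i; cjj[m] = j - 1; ckk[m] = k; ++m; }
    if (k < nz && !occ[li = lin(i, j, k + 1)]) { cand[m] = li;
      cii[m] = i; cjj[m] = j; ckk[m] = k + 1; ++m; }
    if (k > 1 && !occ[li = lin(i, j, k - 1)]) { cand[m] = li;
      cii[m] = i; cjj[m] = j; ckk[m] = k - 1; ++m; }
    if (!m) return -1;
    double w[6], tot = 0;
    for (int l = 0; l < m; ++l) {
      w[l] = VTAB[countOcc(cii[l], cjj[l], ckk[l])];
      tot += w[l];
    }
    double u = R::unif_rand() * tot, acc = 0;
    int pickIdx = m - 1;
    for (int l = 0; l < m; ++l) { acc += w[l]; if (u < acc) { pickIdx = l;
        break; } }
    ci = cii[pickIdx]; cj = cjj[pickIdx]; ck = ckk[pickIdx];
    return cand[pickIdx];
  };
  auto migrate = [&](int id0) -> bool {  // id0 is 0-based
    int ci, cj, ck;
    R_xlen_t to = pickEmpty(ai[id0], aj[id0], ak[id0], ci, cj, ck);
    if (to < 0) return false;
    occ[lin(ai[id0], aj[id0], ak[id0])] = 0;
    occ[to] = id0 + 1;
    ai[id0] = ci; aj[id0] = cj; ak[id0] = ck;
    if (phase[id0] == 0) phen[id0] = 1;
    return true;
  };

  const double dt = par[0], eps = par[20], ampApop = par[21],
               ampProl = par[22];

  for (R_xlen_t oi = 0; oi < order.size(); ++oi) {
    const int id = order[oi] - 1;
    if (!alive[id]) continue;

    if (phen[id] == 4) {                 // completing apoptosis
      if (--cd[id] <= 0) {
        occ[lin(ai[id], aj[id], ak[id])] = 0;
        alive[id] = FALSE;
      }
      continue;
    }

    const R_xlen_t li = lin(ai[id], aj[id], ak[id]);
    const int ty = type[id];

    // (1) apoptosis draw against the drug-modulated hazard
    double lam;
    if (ty == 1) {
      double h = fLDM[li] / par[1]; h *= h;
      lam = par[2] + ampApop * h / (1 + h);
    } else if (ty == 2) {
      double h = fGC[li] / par[3]; h *= h;
      lam = par[4] + par[5] * h / (1 + h);
    } else {
      double h = fGC[li] / par[6]; h *= h;
      lam = par[7] + par[8] * h / (1 + h);
    }
    if (lam > 0 && R::unif_rand() < 1 - std::exp(-lam * dt)) {
      phen[id] = 4; phase[id] = 0; cd[id] = 10;
      continue;
    }

    // (2) cycle gate (with rest period after a failed draw)
    if (phase[id] == 0 && rest[id] > 0) {
      --rest[id];
    } else if (phase[id] == 0) {
      double p;
      if (ty == 1) {
        double h = fTNFa[li] / par[9]; h *= h;
        p = par[10] + ampProl * h / (1 + h);
      } else if (ty == 2) {
        double D = fDKK1[li], B = fBHQ[li];
        double De = D > 0 ? D * D / (D + B) : 0.0;
        double x = De / par[13];
        double EW = par[11] + par[12] / (1 + x * x);
        double h = EW / par[14]; h *= h;
        p = par[15] + par[16] * h / (1 + h);
      } else {
        double orl = fOPG[li] / std::max(fRANKL[li], eps);
        double x = orl / par[17];
        p = par[18] + par[19] / (1 + x * x);
      }
      p = std::min(std::max(p, 0.0), 1.0);
      if (R::unif_rand() < p) {
        phase[id] = 1; phaseStep[id] = 0; phen[id] = 2;
      } else {
        rest[id] = restlen[ty - 1] - 1;
      }
    }

    // (3) cycle progression; M phase divides
    if (phase[id] > 0) {
      ++phaseStep[id];
      if (phase[id] < 4) {               // G0/G1, S, G2: migrate
        if (phaseStep[id] >= cyclen(ty - 1, phase[id] - 1)) {
          ++phase[id]; phaseStep[id] = 0;
        }
        migrate(id);
        continue;
      }
      int ci, cj, ck;
      R_xlen_t to = pickEmpty(ai[id], aj[id], ak[id], ci, cj, ck);
      if (to < 0) continue;              // reversibly quiescent
      if (n >= type.size()) stop("agent storage exhausted");
      const int nid = n++;               // 0-based daughter slot
      type[nid] = ty; ai[nid] = ci; aj[nid] = cj; ak[nid] = ck;
      phen[nid] = 3; phase[nid] = 0; phaseStep[nid] = 0; cd[nid] = 0;
      rest[nid] = restlen[ty - 1];
      alive[nid] = TRUE;
      occ[to] = nid + 1;
      phase[id] = 0; phaseStep[id] = 0; phen[id] = 3;
      continue;
    }

    // (4) non-cycling cells migrate (or quiesce in place)
    migrate(id);
  }
  return n;
}
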