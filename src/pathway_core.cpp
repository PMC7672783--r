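#include <Rcpp.h>
using namespace Rcpp;

// Cohort cycle loop over the expanded (treatment stage x health state) space.
//
// Per cycle, in order: record start-of-cycle occupancy; apply death; apply
// the stage-specific health-state transition; force treatment stop for mass
// above the EDSS stop level (to the stage's forced destination); apply
// voluntary discontinuation to alive on-treatment mass and route it across
// destination stages. Routed mass becomes occupancy (and "entrant" mass, used
// for first-year cost accrual) at the start of the next cycle.
//
// init_occ:   S x H start occupancy (mass over stages and health states)
// P_list:     list of S H x H row-stochastic matrices (no mortality)
// death_prob: T x H per-cycle, per-state annual death probability
// disc_rate:  length-S voluntary annual discontinuation probability
// route:      S x S routing of voluntary discontinuation mass (rows sum to 1
//             for stages with disc_rate > 0)
// forced_mask: S x H, 1 where the forced stop applies (on-DMD, EDSS > stop)
// forced_dest: length-S 0-based destination stage of the forced stop (-1 if
//             not applicable)
// [[Rcpp::export]]
List run_pathway_core(NumericMatrix init_occ, List P_list,
                      NumericMatrix death_prob, NumericVector disc_rate,
                      NumericMatrix route, IntegerMatrix forced_mask,
                      IntegerVector forced_dest, int n_cycles,
                      int dead_state) {
  const int S = init_occ.nrow();
  const int H = init_occ.ncol();
  const int T = n_cycles;
  const int D = dead_state - 1;  // 0-based index of DEAD

  // sparse (CSR) form of each stage's transition matrix; rows are ~75%
  // zeros, so iterating nonzeros only speeds the cycle loop up considerably
  std::vector<std::vector<int>> Pptr(S);
  std::vector<std::vector<int>> Pcol(S);
  std::vector<std::vector<double>> Pval(S);
  for (int s = 0; s < S; ++s) {
    NumericMatrix Ps = as<NumericMatrix>(P_list[s]);
    Pptr[s].assign(H + 1, 0);
    for (int h = 0; h < H; ++h) {
      for (int j = 0; j < H; ++j) {
        double p = Ps(h, j);
        if (p != 0.0) {
          Pcol[s].push_back(j);
          Pval[s].push_back(p);
        }
      }
      Pptr[s][h + 1] = (int)Pcol[s].size();
    }
  }

  NumericVector trace(T * S * H);       // [t + T*s + T*S*h]
  trace.attr("dim") = IntegerVector::create(T, S, H);
  NumericMatrix entrants(T, S), vol_disc(T, S), forced(T, S);
  NumericVector deaths(T);

  NumericMatrix occ(clone(init_occ));
  NumericMatrix nxt(S, H);
  NumericMatrix inflow(S, H);
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int h = 0; h < H; ++h) if (h != D) tot += occ(s, h);
    entrants(0, s) = tot;
  }

  for (int t = 0; t < T; ++t) {
    // record start-of-cycle occupancy
    for (int s = 0; s < S; ++s)
      for (int h = 0; h < H; ++h)
        trace[t + T * s + T * S * h] = occ(s, h);

    // (1) death
    for (int s = 0; s < S; ++s) {
      double moved = 0.0;
      for (int h = 0; h < H; ++h) {
        if (h == D) continue;
        double m = occ(s, h) * death_prob(t, h);
        occ(s, h) -= m;
        moved += m;
      }
      occ(s, D) += moved;
      deaths[t] += moved;
    }

    // (2) health-state transition (sparse rows)
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& ptr = Pptr[s];
      const std::vector<int>& col = Pcol[s];
      const std::vector<double>& val = Pval[s];
      for (int h = 0; h < H; ++h) {
        double m = occ(s, h);
        if (m <= 0.0) continue;
        for (int k = ptr[h]; k < ptr[h + 1]; ++k) {
          nxt(s, col[k]) += m * val[k];
        }
      }
    }
    std::copy(nxt.begin(), nxt.end(), occ.begin());

    // (3) forced stop above the EDSS stop level
    for (int s = 0; s < S; ++s) {
      int fd = forced_dest[s];
      if (fd < 0) continue;
      double tot = 0.0;
      for (int h = 0; h < H; ++h) {
        if (forced_mask(s, h) && occ(s, h) > 0.0) {
          double m = occ(s, h);
          occ(s, h) = 0.0;
          occ(fd, h) += m;
          tot += m;
        }
      }
      forced(t, s) = tot;
      if (t + 1 < T) entrants(t + 1, fd) += tot;
    }

    // (4) voluntary discontinuation, routed; effective next cycle start.
    // Removals are computed on pre-routing occupancy and inflows buffered,
    // so mass switching into another treatment stage this cycle is not
    // exposed to that stage's discontinuation until the next cycle.
    std::fill(inflow.begin(), inflow.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      double q = disc_rate[s];
      if (q <= 0.0) continue;
      double tot = 0.0;
      for (int h = 0; h < H; ++h) {
        if (h == D) continue;
        double m = occ(s, h) * q;
        if (m <= 0.0) continue;
        occ(s, h) -= m;
        tot += m;
        for (int d2 = 0; d2 < S; ++d2) {
          double r = route(s, d2);
          if (r > 0.0) inflow(d2, h) += m * r;
        }
      }
      vol_disc(t, s) = tot;
      if (t + 1 < T) {
        for (int d2 = 0; d2 < S; ++d2) {
          double r = route(s, d2);
          if (r > 0.0) entrants(t + 1, d2) += tot * r;
        }
      }
    }
    for (int s = 0; s < S; ++s)
      for (int h = 0; h < H; ++h) occ(s, h) += inflow(s, h);
  }

  return List::create(_["trace"] = trace, _["entrants"] = entrants,
                      _["vol_disc"] = vol_disc, _["forced"] = forced,
                      _["deaths"] = deaths);
}
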