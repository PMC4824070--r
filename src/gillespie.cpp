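#include <Rcpp.h>
using namespace Rcpp;

// Embedded-jump-chain simulation of one RNAP and the pioneer ribosome on a
// nascent transcript. All positions are 1-based nt. RNAP advances 1 nt per
// step; the ribosome advances 3 nt (one codon) per step; waiting times are
// exponential, so event selection by propensity (the jump chain) fully
// determines the recorded quantities and no clock is kept.
//
// Exclusion: the ribosome may only occupy A-site positions a with
//   a + down_protect <= rnap_pos - rnap_protect.
// Initiation gate: the ribosome loads at A-site start_codon + 3 once the
// RNAP has cleared both the RBS (rnap_pos >= rbs_end + rnap_protect) and the
// exclusion zone of the freshly placed ribosome.
//
// Draws come from R's RNG (unif_rand) so set.seed() in R gives bit-identical
// trajectory sets.

// [[Rcpp::export]]
DataFrame simulate_trajectories_cpp(int n_traj,
                                    int rbs_end,
                                    int start_codon,
                                    int stop_last,
                                    int hairpin_start,
                                    int decision_point,
                                    double k_rnap,
                                    IntegerVector pause_pos,
                                    NumericVector pause_rate,
                                    double k_ribosome,
                                    IntegerVector ribo_pause_pos,
                                    NumericVector ribo_pause_rate,
                                    double k_init,
                                    int down_protect,
                                    int rnap_protect,
                                    bool translation_enabled,
                                    double te0,
                                    double readthrough_floor,
                                    int k_repress,
                                    bool check_invariants) {
  RNGScope scope;

  const int a_init = start_codon + 3;              // A site on the second codon
  const int a_stop = stop_last - 2;                // stop codon in the A site
  const int init_gate = std::max(rbs_end + rnap_protect,
                                 a_init + down_protect + rnap_protect);

  NumericVector x_out(n_traj);
  LogicalVector term_out(n_traj);
  IntegerVector head_out(n_traj);
  IntegerVector catch_out(n_traj);

  // dense lookups for pause rates: RNAP keyed by transcript position,
  // ribosome keyed by A-site position
  std::vector<double> step_rate(decision_point + 1, k_rnap);
  for (int i = 0; i < pause_pos.size(); ++i) {
    int p = pause_pos[i];
    if (p >= 1 && p <= decision_point) step_rate[p] = pause_rate[i];
  }
  std::vector<double> ribo_rate(stop_last + 1, k_ribosome);
  for (int i = 0; i < ribo_pause_pos.size(); ++i) {
    int p = ribo_pause_pos[i];
    if (p >= 1 && p <= stop_last) ribo_rate[p] = ribo_pause_rate[i];
  }

  for (int tr = 0; tr < n_traj; ++tr) {
    int rnap = 1;
    int ribo = NA_INTEGER;
    bool initiated = false;
    int head_start = NA_INTEGER;
    int catch_up = NA_INTEGER;

    while (rnap < decision_point) {
      double r_rnap = step_rate[rnap];
      double r_init = (!initiated && translation_enabled && rnap >= init_gate)
                        ? k_init : 0.0;
      bool at_stop = initiated && (ribo + 3 > a_stop);
      bool excluded = initiated && !at_stop &&
                      (ribo + 3 + down_protect > rnap - rnap_protect);
      double r_ribo = (initiated && !at_stop && !excluded) ? ribo_rate[ribo] : 0.0;

      // catching up means the ribosome, having advanced past initiation,
      // runs into the RNAP; contact at the initiation instant is the gate,
      // not a catch-up
      if (excluded && ribo > a_init && catch_up == NA_INTEGER) catch_up = ribo;

      double total = r_rnap + r_init + r_ribo;
      double u = unif_rand() * total;
      if (u < r_rnap) {
        ++rnap;
      } else if (u < r_rnap + r_init) {
        initiated = true;
        ribo = a_init;
        head_start = rnap - rbs_end;
      } else {
        ribo += 3;
      }

      if (check_invariants && initiated &&
          ribo + down_protect > rnap - rnap_protect) {
        stop("exclusion invariant violated: A-site %d, RNAP %d", ribo, rnap);
      }
      if (check_invariants && initiated &&
          hairpin_start - ribo < hairpin_start - stop_last) {
        stop("stop-codon bound violated: A-site %d beyond stop at %d",
             ribo, stop_last);
      }
    }

    double x = initiated ? (double)(hairpin_start - ribo) : R_PosInf;
    bool repressed = initiated && (x <= (double)k_repress);
    double p_term = repressed ? readthrough_floor : te0;
    bool terminated = unif_rand() < p_term;

    x_out[tr] = x;
    term_out[tr] = terminated;
    head_out[tr] = head_start;
    catch_out[tr] = catch_up;
  }

  return DataFrame::create(_["trajectory"] = seq_len(n_traj),
                           _["x"] = x_out,
                           _["terminated"] = term_out,
                           _["head_start"] = head_out,
                           _["catch_up_pos"] = catch_out);
}
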