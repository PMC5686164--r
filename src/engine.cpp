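#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Strategy codes: keep in sync with strategy_ids() on the R side.
enum Strat {
  S_AC = 0, S_AD = 1, S_RANDOM = 2, S_TFT = 3, S_GTFT = 4, S_WSLS = 5,
  S_ZDE = 6, S_ZDG = 7, S_HARD_JOSS = 8, S_TF2T = 9, S_GRIM = 10,
  S_HARD_TFT = 11, S_HARD_MAJO = 12, S_HARD_TF2T = 13
};

// Per-edge, per-player sufficient statistics.  Windows are padded with C (=1)
// so that the blanket cooperate-first rule falls out of the decision rules for
// the deterministic strategies (HARD_MAJO's 0 >= 0 tie yields its first-move
// defection).
struct Side {
  int own1;              // own last move, 1 = C
  int opp1, opp2, opp3;  // opponent's last three moves, most recent first
  int coop, def;         // opponent cooperation / defection counts
  int round;             // rounds played on this edge
};

static inline void side_init(Side &s) {
  s.own1 = 1; s.opp1 = s.opp2 = s.opp3 = 1;
  s.coop = 0; s.def = 0; s.round = 0;
}

// Cooperation probability of a memory-one strategy given (own, opp) last moves.
static inline double mem1_prob(int st, int own, int opp) {
  switch (st) {
  case S_RANDOM: return 0.5;
  case S_GTFT:   return opp ? 1.0 : (1.0 / 3.0);
  case S_ZDE:
    if (own &&  opp) return 11.0 / 13.0;
    if (own && !opp) return 0.5;
    if (!own && opp) return 7.0 / 26.0;
    return 0.0;
  case S_ZDG:
    if (own &&  opp) return 1.0;
    if (own && !opp) return 2.0 / 11.0;
    if (!own && opp) return 1.0;
    return 4.0 / 11.0;
  case S_HARD_JOSS: return opp ? 0.9 : 0.0;
  }
  return 0.5; // not reached
}

// One move decision.  Stochastic strategies consume exactly one uniform draw
// per decision; RANDOM also draws for its first move, the other stochastic
// strategies open with C without drawing.
static inline int strat_move(int st, const Side &s) {
  switch (st) {
  case S_AC:     return 1;
  case S_AD:     return 0;
  case S_RANDOM: return unif_rand() < 0.5 ? 1 : 0;
  case S_TFT:    return s.opp1;
  case S_GTFT: case S_ZDE: case S_ZDG: case S_HARD_JOSS:
    if (s.round == 0) return 1;
    return unif_rand() < mem1_prob(st, s.own1, s.opp1) ? 1 : 0;
  case S_WSLS:      return s.own1 == s.opp1 ? 1 : 0;
  case S_TF2T:      return (s.opp1 == 0 && s.opp2 == 0) ? 0 : 1;
  case S_GRIM:      return s.def == 0 ? 1 : 0;
  case S_HARD_TFT:  return (s.opp1 && s.opp2 && s.opp3) ? 1 : 0;
  case S_HARD_MAJO: return s.coop > s.def ? 1 : 0;
  case S_HARD_TF2T:
    return ((s.opp1 == 0 && s.opp2 == 0) || (s.opp2 == 0 && s.opp3 == 0)) ? 0 : 1;
  }
  return 1; // not reached
}

static inline void side_update(Side &s, int own, int opp) {
  s.own1 = own;
  s.opp3 = s.opp2; s.opp2 = s.opp1; s.opp1 = opp;
  if (opp) s.coop++; else s.def++;
  s.round++;
}

struct Pay {
  double m[2][2]; // m[my][their]
  explicit Pay(const NumericVector &p) {
    // p = (R, S, T, P)
    m[1][1] = p[0]; m[1][0] = p[1]; m[0][1] = p[2]; m[0][0] = p[3];
  }
};

// Iterated match between strategies a and b.  Each repeat restarts the game
// from the defined first moves.  Returns a repeats x 2 matrix of summed
// payoffs (column 1: player a).  Draw order: a then b, each round.
// [[Rcpp::export]]
NumericMatrix rr_match_cpp(int a, int b, int rounds, int repeats,
                           NumericVector pay) {
  Pay P(pay);
  NumericMatrix out(repeats, 2);
  for (int rep = 0; rep < repeats; rep++) {
    Side sa, sb;
    side_init(sa); side_init(sb);
    double ta = 0.0, tb = 0.0;
    for (int r = 0; r < rounds; r++) {
      int ma = strat_move(a, sa);
      int mb = strat_move(b, sb);
      ta += P.m[ma][mb];
      tb += P.m[mb][ma];
      side_update(sa, ma, mb);
      side_update(sb, mb, ma);
    }
    out(rep, 0) = ta;
    out(rep, 1) = tb;
  }
  return out;
}

// Long-run payoff estimate from one continuous trajectory: burn-in rounds are
// discarded, then `blocks` consecutive blocks of `rounds` rounds each yield
// per-round block means (for a standard error).  Returns blocks x 2.
// [[Rcpp::export]]
NumericMatrix sim_pair_cpp(int a, int b, int rounds, int burn, int blocks,
                           NumericVector pay) {
  Pay P(pay);
  Side sa, sb;
  side_init(sa); side_init(sb);
  NumericMatrix out(blocks, 2);
  for (int r = 0; r < burn; r++) {
    int ma = strat_move(a, sa);
    int mb = strat_move(b, sb);
    side_update(sa, ma, mb);
    side_update(sb, mb, ma);
  }
  for (int blk = 0; blk < blocks; blk++) {
    double ta = 0.0, tb = 0.0;
    for (int r = 0; r < rounds; r++) {
      int ma = strat_move(a, sa);
      int mb = strat_move(b, sb);
      ta += P.m[ma][mb];
      tb += P.m[mb][ma];
      side_update(sa, ma, mb);
      side_update(sb, mb, ma);
    }
    out(blk, 0) = ta / rounds;
    out(blk, 1) = tb / rounds;
  }
  return out;
}

// Fitness comparison without division: with psi (= phi/k) fitness, compare
// phi_i * k_j vs phi_j * k_i so exact ties stay exact (phi is an integer-
// valued sum of payoffs, representable exactly in doubles here).
static inline int fit_cmp(double phi_i, int k_i, double phi_j, int k_j,
                          bool psi) {
  double a = psi ? phi_i * k_j : phi_i;
  double b = psi ? phi_j * k_i : phi_j;
  if (a < b) return -1;
  if (a > b) return 1;
  return 0;
}

// Divide-and-conquer tournament run on a fixed network.
//
// edges: m x 2 matrix of 0-based node ids; strat: length-N strategy codes.
// Every edge holds an independent iterated game; after each epoch of
// `epoch_len` rounds, nodes synchronously copy the strategy of the strictly
// fittest neighbour (self keeps on ties with the neighbourhood maximum; ties
// among strictly better neighbours are broken uniformly, one draw per tied
// node).  Per-edge histories persist across strategy updates.
//
// Draw order per round: edges in storage order, first-column player first;
// update draws: nodes in ascending id order.
// [[Rcpp::export]]
List dnc_run_cpp(IntegerMatrix edges, IntegerVector strat0, int weak_code,
                 bool psi, int epoch_len, int max_rounds, int tail,
                 NumericVector pay) {
  const int m = edges.nrow();
  const int n = strat0.size();
  Pay P(pay);

  std::vector<int> ef(m), et(m), strat(n), deg(n, 0);
  for (int i = 0; i < m; i++) {
    ef[i] = edges(i, 0);
    et[i] = edges(i, 1);
    deg[ef[i]]++; deg[et[i]]++;
  }
  for (int i = 0; i < n; i++) strat[i] = strat0[i];

  // CSR adjacency
  std::vector<int> off(n + 1, 0), adj(2 * m);
  for (int i = 0; i < m; i++) { off[ef[i] + 1]++; off[et[i] + 1]++; }
  for (int i = 0; i < n; i++) off[i + 1] += off[i];
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int i = 0; i < m; i++) {
      adj[cur[ef[i]]++] = et[i];
      adj[cur[et[i]]++] = ef[i];
    }
  }

  std::vector<Side> su(m), sv(m);
  for (int i = 0; i < m; i++) { side_init(su[i]); side_init(sv[i]); }

  std::vector<double> phi(n, 0.0), last_phi(n, 0.0);
  std::vector<int> newstrat(n), cand;

  int wc = 0;
  for (int i = 0; i < n; i++) if (strat[i] == weak_code) wc++;

  const int n_epochs = max_rounds / epoch_len;
  std::vector<int> comp; // weak count during each played epoch
  comp.reserve(n_epochs);

  double f_w = (double)wc / n;
  int term_round = 0;
  std::string reason = "extinction";

  if (wc != 0 && wc != n) {
    for (int e = 1; e <= n_epochs; e++) {
      comp.push_back(wc);
      std::fill(phi.begin(), phi.end(), 0.0);
      for (int r = 0; r < epoch_len; r++) {
        for (int i = 0; i < m; i++) {
          int ma = strat_move(strat[ef[i]], su[i]);
          int mb = strat_move(strat[et[i]], sv[i]);
          phi[ef[i]] += P.m[ma][mb];
          phi[et[i]] += P.m[mb][ma];
          side_update(su[i], ma, mb);
          side_update(sv[i], mb, ma);
        }
      }
      last_phi = phi;
      // synchronous best-takes-over update
      for (int i = 0; i < n; i++) {
        int best = -1; // best neighbour index, -1 while none strictly known
        cand.clear();
        for (int a = off[i]; a < off[i + 1]; a++) {
          int j = adj[a];
          if (best < 0) { best = j; cand.assign(1, j); continue; }
          int c = fit_cmp(phi[j], deg[j], phi[best], deg[best], psi);
          if (c > 0) { best = j; cand.assign(1, j); }
          else if (c == 0) cand.push_back(j);
        }
        if (best >= 0 &&
            fit_cmp(phi[best], deg[best], phi[i], deg[i], psi) > 0) {
          int pick = 0;
          if ((int)cand.size() > 1) {
            pick = (int)(unif_rand() * cand.size());
            if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
          }
          newstrat[i] = strat[cand[pick]];
        } else {
          newstrat[i] = strat[i];
        }
      }
      strat = newstrat;
      wc = 0;
      for (int i = 0; i < n; i++) if (strat[i] == weak_code) wc++;
      if (wc == 0 || wc == n) {
        term_round = e * epoch_len;
        f_w = (double)wc / n;
        break;
      }
      if (e == n_epochs) {
        term_round = max_rounds;
        reason = "cap";
        // average weak fraction over the last `tail` rounds
        double acc = 0.0;
        for (int ee = 1; ee <= n_epochs; ee++) {
          double lo = std::max((double)(ee - 1) * epoch_len,
                               (double)(max_rounds - tail));
          double hi = (double)ee * epoch_len;
          if (hi > lo) acc += (hi - lo) * comp[ee - 1] / (double)n;
        }
        f_w = acc / tail;
      }
    }
  }

  return List::create(
    _["weak_count"] = IntegerVector(comp.begin(), comp.end()),
    _["f_w"] = f_w,
    _["termination_round"] = term_round,
    _["reason"] = reason,
    _["strategies"] = IntegerVector(strat.begin(), strat.end()),
    _["epochs"] = (int)comp.size(),
    _["phi"] = NumericVector(last_phi.begin(), last_phi.end()));
}
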