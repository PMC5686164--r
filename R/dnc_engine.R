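#' Epoch configuration for the networked tournament
#'
#' @param measure Fitness measure: `"phi"` (payoff accumulated over the
#'   epoch) or `"psi"` (`phi` divided by degree).
#' @param epoch_len Rounds between strategy updates (the published protocol
#'   uses 200).
#' @param max_rounds Round cap (20,000), a multiple of `epoch_len`.
#' @param tail Trailing window, in rounds, over which the final weak
#'   frequency is averaged when the cap is reached (2,000).
#' @return An object of class `dnc_config`.
#' @export
dnc_config <- function(measure = c("phi", "psi"), epoch_len = 200L,
                       max_rounds = 20000L, tail = 2000L) {
  measure <- match.arg(measure)
  stopifnot(epoch_len >= 1, max_rounds %% epoch_len == 0,
            tail >= 1, tail <= max_rounds)
  structure(list(measure = measure, epoch_len = as.integer(epoch_len),
                 max_rounds = as.integer(max_rounds),
                 tail = as.integer(tail)),
            class = "dnc_config")
}

#' Run a divide-and-conquer tournament on a network
#'
#' Every edge hosts an independent iterated Prisoner's Dilemma: each round,
#' both endpoints move simultaneously on each of their edges, applying
#' their current strategy to that edge's private history.  After each epoch
#' of `epoch_len` rounds, node fitness is the accumulated epoch payoff
#' `phi` (or the degree-averaged `psi`), and all nodes synchronously adopt
#' the strategy of the strictly fittest member of their closed
#' neighbourhood (self wins ties with the neighbourhood maximum; ties among
#' strictly better neighbours are broken uniformly at random).  Per-edge
#' histories persist across strategy changes, so a convert's next move is
#' its new policy applied to the old history, never a fresh first move.
#'
#' The run stops at the extinction of either strategy (final weak frequency
#' 0 or 1) or at `max_rounds`, in which case the weak frequency is averaged
#' over the last `tail` rounds.
#'
#' @param net An [ipd_network()].
#' @param assignment An [assign_strategies()] result.
#' @param config A [dnc_config()].
#' @param params A [pd_payoffs()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation; identical RNG draw order, practical only for small
#'   networks).
#' @return An object of class `dnc_trajectory`: list with `weak_count`
#'   (weak-strategy nodes during each played epoch), `f_w` (final weak
#'   frequency), `termination_round`, `reason` (`"extinction"` or
#'   `"cap"`), `strategies` (final per-node ids), `epochs`, and `phi` (the
#'   accumulated fitness of the last evaluated epoch).
#' @export
dnc_run <- function(net, assignment, config = dnc_config(),
                    params = pd_payoffs(), engine = c("cpp", "r")) {
  stopifnot(inherits(net, "ipd_network"), inherits(assignment, "ipd_assignment"),
            inherits(config, "dnc_config"))
  engine <- match.arg(engine)
  codes <- strategy_code(assignment$strategies)
  weak_code <- strategy_code(assignment$weak)
  res <- if (engine == "cpp") {
    dnc_run_cpp(net$edges - 1L, codes, weak_code,
                config$measure == "psi", config$epoch_len,
                config$max_rounds, config$tail, pay_vector(params))
  } else {
    dnc_run_r(net, codes, weak_code, config, params)
  }
  structure(list(weak_count = res$weak_count, f_w = res$f_w,
                 termination_round = res$termination_round,
                 reason = res$reason,
                 strategies = strategy_ids()[res$strategies + 1L],
                 epochs = res$epochs, phi = res$phi, n = net$n,
                 config = config,
                 weak = assignment$weak, strong = assignment$strong),
            class = "dnc_trajectory")
}

#' @export
print.dnc_trajectory <- function(x, ...) {
  cat(sprintf(
    "dnc_trajectory: %s (weak) vs %s (strong), %d epochs, %s at round %d, f_w = %.4f\n",
    x$weak, x$strong, x$epochs, x$reason, x$termination_round, x$f_w))
  invisible(x)
}

#' Epoch fitness records
#'
#' Turns accumulated per-node epoch payoffs into fitness records: `phi_i`
#' is the payoff summed over all of node i's edges and all rounds of the
#' epoch, `psi_i = phi_i / k_i` its degree average.
#'
#' @param phi Numeric vector of accumulated epoch payoffs.
#' @param degree Integer vector of node degrees.
#' @return Data frame with columns `node`, `k`, `phi`, `psi`.
#' @export
epoch_fitness <- function(phi, degree) {
  stopifnot(length(phi) == length(degree), all(degree >= 1))
  data.frame(node = seq_along(phi), k = degree, phi = phi,
             psi = phi / degree)
}

#' Best-takes-over strategy update
#'
#' Synchronous local learning: every node compares its fitness with the
#' maximum in its neighbourhood and copies the strictly fittest
#' neighbour's strategy, keeping its own on ties with the maximum.  Ties
#' among strictly better neighbours are broken uniformly (one RNG draw per
#' tied node, in ascending node order).  Fitness comparisons under `psi`
#' are done by cross-multiplication (`phi_i k_j` vs `phi_j k_i`) so exact
#' ties are decided exactly.
#'
#' @param strategies Character vector of current per-node strategy ids.
#' @param phi Accumulated epoch payoffs.
#' @param net An [ipd_network()].
#' @param measure `"phi"` or `"psi"`.
#' @return The new strategy vector.
#' @export
local_update <- function(strategies, phi, net, measure = c("phi", "psi")) {
  measure <- match.arg(measure)
  stopifnot(length(strategies) == net$n, length(phi) == net$n)
  adj <- adjacency_list(net)
  deg <- net$degree
  psi <- measure == "psi"
  cmp <- function(i, j) { # sign of f_i - f_j
    a <- if (psi) phi[i] * deg[j] else phi[i]
    b <- if (psi) phi[j] * deg[i] else phi[j]
    sign(a - b)
  }
  out <- strategies
  for (i in seq_len(net$n)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    best <- nb[1]; cand <- nb[1]
    for (j in nb[-1]) {
      s <- cmp(j, best)
      if (s > 0) { best <- j; cand <- j }
      else if (s == 0) cand <- c(cand, j)
    }
    if (cmp(best, i) > 0) {
      pick <- if (length(cand) > 1) {
        cand[floor(stats::runif(1) * length(cand)) + 1]
      } else cand
      out[i] <- strategies[pick]
    }
  }
  out
}

# Pure-R reference engine.  Mirrors the compiled engine decision for
# decision and draw for draw, so trajectories under a fixed seed are
# identical; used to validate the compiled path on small fixtures.
dnc_run_r <- function(net, codes, weak_code, config, params) {
  ids <- strategy_ids()
  m <- nrow(net$edges)
  n <- net$n
  paym <- matrix(pay_vector(params)[c(4, 2, 3, 1)], 2, 2)
  # side state: own1, o1, o2, o3, coop, def, round
  su <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L), nrow = m, ncol = 7,
               byrow = TRUE)
  sv <- su
  strategies <- ids[codes + 1L]
  wc <- sum(codes == weak_code)
  n_epochs <- config$max_rounds %/% config$epoch_len
  comp <- integer(0)
  f_w <- wc / n
  term <- 0L; reason <- "extinction"
  move1 <- function(strat, s) { # mirrors the compiled strat_move
    switch(strat,
      ac = 1L, ad = 0L,
      random = if (stats::runif(1) < 0.5) 1L else 0L,
      tft = s[2],
      gtft = , zde = , zdg = , hard_joss = {
        if (s[7] == 0L) return(1L)
        v <- memory_one_vector(strat)
        state <- paste0(if (s[1]) "C" else "D", if (s[2]) "C" else "D")
        if (stats::runif(1) < v[[state]]) 1L else 0L
      },
      wsls = as.integer(s[1] == s[2]),
      tf2t = if (!s[2] && !s[3]) 0L else 1L,
      grim = if (s[6] > 0L) 0L else 1L,
      hard_tft = if (s[2] && s[3] && s[4]) 1L else 0L,
      hard_majo = if (s[5] > s[6]) 1L else 0L,
      hard_tf2t = if ((!s[2] && !s[3]) || (!s[3] && !s[4])) 0L else 1L)
  }
  upd <- function(s, own, opp) {
    c(own, opp, s[2], s[3], s[5] + (opp == 1L), s[6] + (opp == 0L),
      s[7] + 1L)
  }
  last_phi <- numeric(n)
  if (wc != 0 && wc != n) {
    for (e in seq_len(n_epochs)) {
      comp <- c(comp, wc)
      phi <- numeric(n)
      for (r in seq_len(config$epoch_len)) {
        for (i in seq_len(m)) {
          u <- net$edges[i, 1]; v <- net$edges[i, 2]
          ma <- move1(strategies[u], su[i, ])
          mb <- move1(strategies[v], sv[i, ])
          phi[u] <- phi[u] + paym[ma + 1L, mb + 1L]
          phi[v] <- phi[v] + paym[mb + 1L, ma + 1L]
          su[i, ] <- upd(su[i, ], ma, mb)
          sv[i, ] <- upd(sv[i, ], mb, ma)
        }
      }
      last_phi <- phi
      strategies <- local_update(strategies, phi, net, config$measure)
      wc <- sum(strategies == ids[weak_code + 1L])
      if (wc == 0 || wc == n) {
        term <- e * config$epoch_len
        f_w <- wc / n
        break
      }
      if (e == n_epochs) {
        term <- config$max_rounds
        reason <- "cap"
        acc <- 0
        for (ee in seq_len(n_epochs)) {
          lo <- max((ee - 1) * config$epoch_len,
                    config$max_rounds - config$tail)
          hi <- ee * config$epoch_len
          if (hi > lo) acc <- acc + (hi - lo) * comp[ee] / n
        }
        f_w <- acc / config$tail
      }
    }
  }
  list(weak_count = comp, f_w = f_w, termination_round = term,
       reason = reason, strategies = match(strategies, ids) - 1L,
       epochs = length(comp), phi = last_phi)
}

#' Single-round fitness diagnostic for uniform-move nodes
#'
#' When node `i` plays the same move `X` with all of its neighbours in a
#' round, its summed payoff over its edges has the closed form
#' `G_i = k_i * (Delta_i X + T W_i + P (1 - W_i))` with
#' `Delta_i = S - P + (R - T + P - S) W_i`, where `W_i` is the fraction of
#' `i`'s neighbours that cooperated with `i` this round.  The diagnostic is
#' undefined (returns `NULL`) when `i`'s moves differ across edges, which
#' is the typical divide-and-conquer regime.
#'
#' @param own_moves Character vector of node `i`'s moves on its edges this
#'   round.
#' @param opp_moves The corresponding neighbour moves toward `i`.
#' @param params A [pd_payoffs()] object.
#' @return List with `X`, `W`, `Delta` and `G`, or `NULL` if the node's
#'   moves are not uniform.
#' @export
eq4_diagnostic <- function(own_moves, opp_moves, params = pd_payoffs()) {
  stopifnot(length(own_moves) == length(opp_moves), length(own_moves) >= 1,
            all(own_moves %in% c("C", "D")), all(opp_moves %in% c("C", "D")))
  if (length(unique(own_moves)) != 1L) return(NULL)
  k <- length(own_moves)
  X <- move_indicator(own_moves[1])
  W <- mean(opp_moves == "C")
  R <- params[["R"]]; S <- params[["S"]]; T <- params[["T"]]; P <- params[["P"]]
  Delta <- S - P + (R - T + P - S) * W
  list(X = X, W = W, Delta = Delta,
       G = k * (Delta * X + T * W + P * (1 - W)))
}
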