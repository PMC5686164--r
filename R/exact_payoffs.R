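#' Markov transition matrix of a memory-one pair
#'
#' For players A and B with memory-one vectors `p` and `s`, the joint play
#' is a Markov chain on the four outcomes (CC, CD, DC, DD), written from
#' A's perspective.  Rows index the previous outcome; note that in the
#' second and third rows B's relevant entries are `s[DC]` and `s[CD]`
#' respectively, because an outcome that is CD for A is DC for B.
#'
#' @param p,s Memory-one vectors (see [memory_one_vector()]), in the order
#'   (CC, CD, DC, DD).
#' @return A 4x4 row-stochastic matrix with dimnames
#'   `c("CC","CD","DC","DD")`.
#' @export
transition_matrix <- function(p, s) {
  stopifnot(length(p) == 4, length(s) == 4,
            all(p >= 0 & p <= 1), all(s >= 0 & s <= 1))
  # B's cooperation probability seen from A's state ordering
  sb <- c(s[1], s[3], s[2], s[4])
  M <- matrix(0, 4, 4, dimnames = list(c("CC", "CD", "DC", "DD"),
                                       c("CC", "CD", "DC", "DD")))
  for (i in 1:4) {
    M[i, ] <- c(p[i] * sb[i],       p[i] * (1 - sb[i]),
                (1 - p[i]) * sb[i], (1 - p[i]) * (1 - sb[i]))
  }
  M
}

#' Evolve a state vector one step
#'
#' @param phi Length-4 probability vector over (CC, CD, DC, DD).
#' @param M A 4x4 row-stochastic matrix (see [transition_matrix()]).
#' @return `phi %*% M`, a probability vector.
#' @export
evolve_state <- function(phi, M) {
  stopifnot(length(phi) == 4, all(phi >= -1e-12),
            abs(sum(phi) - 1) < 1e-9)
  if (!is.matrix(M) || any(dim(M) != 4) ||
      any(abs(rowSums(M) - 1) > 1e-9) || any(M < -1e-12)) {
    stop("M must be a 4x4 row-stochastic matrix", call. = FALSE)
  }
  drop(phi %*% M)
}

# Press-Dyson determinant D(p, s, f).  With f = (1,1,1,1) this is the
# normalising determinant; with f = S_x it yields the stationary payoff
# numerator.  Rows use B's entries cross-indexed as in transition_matrix().
press_dyson_D <- function(p, s, f) {
  D <- matrix(c(
    -1 + p[1] * s[1], -1 + p[1], -1 + s[1], f[1],
    p[2] * s[3],      -1 + p[2], s[3],      f[2],
    p[3] * s[2],      p[3],      -1 + s[2], f[3],
    p[4] * s[4],      p[4],      s[4],      f[4]), 4, 4, byrow = TRUE)
  det(D)
}

# ---------------------------------------------------------------------------
# Exact finite-state chain for pairs of bounded-memory strategies.
# State: (a1, a2, a3, b1, b2, b3, gA, gB) where a1 is A's most recent move
# (1 = C), windows are padded with C, and gA records whether B has ever
# defected.  Every strategy except hard_majo is a function of this state.
# The Cesaro limit from the defined first moves is obtained by repeatedly
# squaring the lazy chain (M + I)/2, which converges for periodic and
# absorbing chains alike.
# ---------------------------------------------------------------------------

chain_coop_prob <- function(strategy, own1, opp1, opp2, opp3, grim) {
  v <- memory_one_vector(strategy)
  if (!is.null(v) && strategy != "grim") {
    state <- paste0(if (own1) "C" else "D", if (opp1) "C" else "D")
    return(v[[state]])
  }
  switch(strategy,
    grim = if (grim) 0 else 1,
    tf2t = if (!opp1 && !opp2) 0 else 1,
    hard_tft = if (opp1 && opp2 && opp3) 1 else 0,
    hard_tf2t = if ((!opp1 && !opp2) || (!opp2 && !opp3)) 0 else 1,
    stop("no finite-window representation for ", strategy, call. = FALSE))
}

first_move_prob <- function(strategy) {
  # probability of cooperating on the first move
  switch(strategy, ad = 0, hard_majo = 0, random = 0.5, 1)
}

chain_pair_payoffs <- function(a, b, params) {
  bits <- expand.grid(gB = 0:1, gA = 0:1, b3 = 0:1, b2 = 0:1, b1 = 0:1,
                      a3 = 0:1, a2 = 0:1, a1 = 0:1)
  n <- nrow(bits) # 256
  key <- function(a1, a2, a3, b1, b2, b3, gA, gB) {
    1L + gB + 2L * gA + 4L * b3 + 8L * b2 + 16L * b1 +
      32L * a3 + 64L * a2 + 128L * a1
  }
  # paym[my+1, their+1] with 0 = D: [D,D]=P, [D,C]=T, [C,D]=S, [C,C]=R
  paym <- matrix(pay_vector(params)[c(4, 2, 3, 1)], 2, 2)
  M <- matrix(0, n, n)
  ea <- numeric(n); eb <- numeric(n)
  for (i in seq_len(n)) {
    st <- bits[i, ]
    pa <- chain_coop_prob(a, st$a1, st$b1, st$b2, st$b3, st$gA)
    pb <- chain_coop_prob(b, st$b1, st$a1, st$a2, st$a3, st$gB)
    for (ma in 0:1) {
      for (mb in 0:1) {
        pr <- (if (ma) pa else 1 - pa) * (if (mb) pb else 1 - pb)
        if (pr == 0) next
        j <- key(ma, st$a1, st$a2, mb, st$b1, st$b2,
                 st$gA | !mb, st$gB | !ma)
        M[i, j] <- M[i, j] + pr
        ea[i] <- ea[i] + pr * paym[ma + 1, mb + 1]
        eb[i] <- eb[i] + pr * paym[mb + 1, ma + 1]
      }
    }
  }
  phi0 <- numeric(n)
  fa <- first_move_prob(a); fb <- first_move_prob(b)
  for (ma in 0:1) {
    for (mb in 0:1) {
      w <- (if (ma) fa else 1 - fa) * (if (mb) fb else 1 - fb)
      if (w == 0) next
      j <- key(ma, 1L, 1L, mb, 1L, 1L, as.integer(!mb), as.integer(!ma))
      phi0[j] <- phi0[j] + w
    }
  }
  L <- (M + diag(n)) / 2
  for (k in 1:60) {
    L <- L %*% L
    L <- L / rowSums(L) # keep rows stochastic against roundoff drift
  }
  pinf <- drop(phi0 %*% L)
  list(value_a = sum(pinf * ea), value_b = sum(pinf * eb))
}

# ---------------------------------------------------------------------------
# Exact cycle detection for deterministic pairs.  Joint state: both sides'
# (own last, opponent window, trigger flag) plus the exact count difference
# d = coop - def for any hard_majo side.  For drifting hard_majo counters the
# reduced state (without d) is checked for recurrence with a frozen majority
# sign, which makes the continuation provably periodic.
# ---------------------------------------------------------------------------

det_move <- function(strategy, own1, o1, o2, o3, def, d) {
  switch(strategy,
    ac = 1L, ad = 0L,
    tft = o1,
    wsls = as.integer(own1 == o1),
    tf2t = if (!o1 && !o2) 0L else 1L,
    grim = if (def > 0L) 0L else 1L,
    hard_tft = if (o1 && o2 && o3) 1L else 0L,
    hard_majo = if (d > 0L) 1L else 0L,
    hard_tf2t = if ((!o1 && !o2) || (!o2 && !o3)) 0L else 1L,
    stop("not a deterministic strategy: ", strategy, call. = FALSE))
}

det_cycle_payoffs <- function(a, b, params, max_steps = 20000L) {
  paym <- matrix(pay_vector(params)[c(4, 2, 3, 1)], 2, 2)
  hmA <- a == "hard_majo"; hmB <- b == "hard_majo"
  # side state vectors: own1, o1, o2, o3, def count, d = coop - def
  A <- c(1L, 1L, 1L, 1L, 0L, 0L)
  B <- c(1L, 1L, 1L, 1L, 0L, 0L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  reduced <- new.env(hash = TRUE, parent = emptyenv())
  cumA <- numeric(max_steps + 1L); cumB <- numeric(max_steps + 1L)
  dA <- integer(max_steps + 1L); dB <- integer(max_steps + 1L)
  for (t in seq_len(max_steps)) {
    rkey <- paste(A[1:4], B[1:4], min(A[5], 1L), min(B[5], 1L),
                  collapse = " ")
    full <- paste(rkey, if (hmA) A[6] else 0L, if (hmB) B[6] else 0L)
    prev <- seen[[full]]
    if (!is.null(prev)) {
      len <- t - prev$t
      return(list(value_a = (cumA[t] - prev$cumA) / len,
                  value_b = (cumB[t] - prev$cumB) / len))
    }
    seen[[full]] <- list(t = t, cumA = cumA[t], cumB = cumB[t])
    if (hmA || hmB) {
      occ <- reduced[[rkey]]
      if (!is.null(occ)) {
        seg <- occ$t:(t - 1L)
        ok <- TRUE
        if (hmA) {
          dd <- A[6] - occ$dA
          dseg <- c(occ$dA, dA[seg])
          ok <- ok && ((dd > 0 && min(dseg) >= 1L) ||
                       (dd < 0 && max(dseg) <= 0L))
        }
        if (hmB) {
          dd <- B[6] - occ$dB
          dseg <- c(occ$dB, dB[seg])
          ok <- ok && ((dd > 0 && min(dseg) >= 1L) ||
                       (dd < 0 && max(dseg) <= 0L))
        }
        if (ok) {
          len <- t - occ$t
          return(list(value_a = (cumA[t] - occ$cumA) / len,
                      value_b = (cumB[t] - occ$cumB) / len))
        }
      }
      reduced[[rkey]] <- list(t = t, dA = A[6], dB = B[6],
                              cumA = cumA[t], cumB = cumB[t])
    }
    ma <- det_move(a, A[1], A[2], A[3], A[4], A[5], A[6])
    mb <- det_move(b, B[1], B[2], B[3], B[4], B[5], B[6])
    cumA[t + 1L] <- cumA[t] + paym[ma + 1L, mb + 1L]
    cumB[t + 1L] <- cumB[t] + paym[mb + 1L, ma + 1L]
    A <- c(ma, mb, A[2], A[3], A[5] + (mb == 0L), A[6] + if (mb == 1L) 1L else -1L)
    B <- c(mb, ma, B[2], B[3], B[5] + (ma == 0L), B[6] + if (ma == 1L) 1L else -1L)
    dA[t] <- A[6]; dB[t] <- B[6]
  }
  NULL # no provable cycle (falls back to simulation)
}

# ---------------------------------------------------------------------------

# Ensemble simulation: independent matches of `rounds` rounds each, averaged
# across repeats (the published match protocol).  An ensemble is used rather
# than one long trajectory because for hard_majo against a stochastic
# opponent the majority counter performs a random walk, so time averages are
# not self-averaging; the tabulated quantity is the ensemble mean.
sim_pair_payoffs <- function(a, b, params, rounds = 1e4, repeats = 100L) {
  m <- rr_match_cpp(strategy_code(a), strategy_code(b), as.integer(rounds),
                    as.integer(repeats), pay_vector(params)) / rounds
  list(value_a = mean(m[, 1]), value_b = mean(m[, 2]),
       se_a = stats::sd(m[, 1]) / sqrt(repeats),
       se_b = stats::sd(m[, 2]) / sqrt(repeats))
}

# Both directions of a pair, with the branch logic shared by
# expected_payoff() and payoff_table().
pair_payoffs <- function(a, b, params = pd_payoffs(), sim_rounds = 1e4,
                         sim_repeats = 100L) {
  pa <- memory_one_vector(a)
  pb <- memory_one_vector(b)
  RSTP <- pay_vector(params)
  if (!is.null(pa) && !is.null(pb)) {
    D1 <- press_dyson_D(pa, pb, rep(1, 4))
    if (abs(D1) > 1e-9) {
      Sx <- RSTP                 # A receives (R, S, T, P) over (CC,CD,DC,DD)
      Sy <- RSTP[c(1, 3, 2, 4)]  # B receives (R, T, S, P)
      return(list(value_a = press_dyson_D(pa, pb, Sx) / D1,
                  value_b = press_dyson_D(pa, pb, Sy) / D1,
                  method = "determinant", se_a = 0, se_b = 0))
    }
  }
  if (!is_stochastic(a) && !is_stochastic(b)) {
    cyc <- det_cycle_payoffs(a, b, params)
    if (!is.null(cyc)) {
      return(c(cyc, list(method = "cycle", se_a = 0, se_b = 0)))
    }
  } else if (a != "hard_majo" && b != "hard_majo") {
    ch <- chain_pair_payoffs(a, b, params)
    return(c(ch, list(method = "chain", se_a = 0, se_b = 0)))
  }
  sim <- sim_pair_payoffs(a, b, params, rounds = sim_rounds,
                          repeats = sim_repeats)
  c(sim[c("value_a", "value_b")], list(method = "simulated"),
    sim[c("se_a", "se_b")])
}

#' Long-run expected payoff of a strategy pair
#'
#' Computes the expected per-round payoff `E(a, b)` of strategy `a` against
#' strategy `b` in the stationary state of their iterated game, choosing the
#' strongest available method:
#'
#' 1. `"determinant"` — both strategies memory-one and the joint chain
#'    ergodic: the Press-Dyson determinant ratio, exact.
#' 2. `"cycle"` — both strategies deterministic: exact play from the
#'    defined first moves until the bounded joint state recurs; the cycle
#'    average is returned.  `hard_majo`'s unbounded majority counter is
#'    handled by recurrence with a provably frozen majority sign.
#' 3. `"chain"` — any other pair not involving `hard_majo`: exact
#'    finite-state Markov chain over the joint three-round window.
#' 4. `"simulated"` — `hard_majo` against a stochastic opponent: an
#'    ensemble of independent matches (default 10,000 rounds x 100
#'    repeats, i.e. 1e6 simulated rounds) averaged across repeats, with a
#'    standard error over repeats.  An ensemble is used because
#'    `hard_majo`'s majority counter performs a random walk against a
#'    stochastic opponent, so a single trajectory's time average does not
#'    self-average.
#'
#' @param a,b Strategy ids.
#' @param params A [pd_payoffs()] object.
#' @param sim_rounds,sim_repeats Rounds per repeat and number of repeats
#'   for the simulation fallback.
#' @return An object of class `payoff_expectation`: list with elements
#'   `a`, `b`, `value`, `method`, `se` (0 for exact methods).
#' @examples
#' expected_payoff("gtft", "ad")$value  # 2/3
#' @export
expected_payoff <- function(a, b, params = pd_payoffs(), sim_rounds = 1e4,
                            sim_repeats = 100L) {
  strategy_code(a); strategy_code(b)
  r <- pair_payoffs(a, b, params, sim_rounds = sim_rounds,
                    sim_repeats = sim_repeats)
  structure(list(a = a, b = b, value = r$value_a, method = r$method,
                 se = r$se_a),
            class = "payoff_expectation")
}

#' @export
print.payoff_expectation <- function(x, ...) {
  cat(sprintf("E(%s, %s) = %.6g  [%s%s]\n", x$a, x$b, x$value, x$method,
              if (x$se > 0) sprintf(", se %.2g", x$se) else ""))
  invisible(x)
}

#' Self-play minus invader payoff gap
#'
#' The statistic `delta(a, b) = E(a, a) - E(b, a)`: how much better `a`
#' does against itself than `b` does against `a`.  A negative value means
#' `b` invades a resident `a` population in expectation.
#'
#' @inheritParams expected_payoff
#' @return A single number.
#' @examples
#' payoff_delta("random", "ad")  # -0.75
#' @export
payoff_delta <- function(a, b, params = pd_payoffs(), sim_rounds = 1e4,
                         sim_repeats = 100L) {
  expected_payoff(a, a, params, sim_rounds, sim_repeats)$value -
    expected_payoff(b, a, params, sim_rounds, sim_repeats)$value
}

#' Expected payoff table of the fourteen strategies
#'
#' All 196 ordered-pair expectations `E(row, col)`, computed once per
#' unordered pair with the method selection of [expected_payoff()].
#'
#' @inheritParams expected_payoff
#' @return A list of class `ipd_payoff_table` with 14x14 matrices `value`,
#'   `method` and `se` (rows: focal strategy).
#' @export
payoff_table <- function(params = pd_payoffs(), sim_rounds = 1e4,
                         sim_repeats = 100L) {
  ids <- strategy_ids()
  k <- length(ids)
  value <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  method <- matrix(NA_character_, k, k, dimnames = list(ids, ids))
  se <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      r <- pair_payoffs(ids[i], ids[j], params, sim_rounds = sim_rounds,
                        sim_repeats = sim_repeats)
      value[i, j] <- r$value_a; value[j, i] <- r$value_b
      method[i, j] <- method[j, i] <- r$method
      se[i, j] <- r$se_a; se[j, i] <- r$se_b
    }
  }
  structure(list(value = value, method = method, se = se, params = params),
            class = "ipd_payoff_table")
}

#' @export
print.ipd_payoff_table <- function(x, digits = 3, ...) {
  cat("Expected payoff table E(row, col), per round\n")
  print(round(x$value, digits))
  invisible(x)
}
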