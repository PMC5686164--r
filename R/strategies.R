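#' The fourteen tournament strategies
#'
#' Returns the closed set of strategy identifiers, in canonical order.  The
#' lower-case tokens are used throughout the package (function arguments,
#' CSV output, the command-line interface).
#'
#' * `ac` / `ad` — unconditional cooperation / defection.
#' * `random` — cooperates with probability 0.5 every round.
#' * `tft` — tit-for-tat: copies the opponent's previous move.
#' * `gtft` — generous tit-for-tat: forgives a defection with probability 1/3.
#' * `wsls` — win-stay-lose-shift (Pavlov).
#' * `zde` — extortionate zero-determinant strategy with extortion factor 3.
#' * `zdg` — generous zero-determinant strategy (factor 3 about `R`).
#' * `hard_joss` — tit-for-tat that cooperates only with probability 0.9
#'   after opponent cooperation.
#' * `tf2t` — tit-for-two-tats: defects only after two consecutive
#'   opponent defections.
#' * `grim` — cooperates until the opponent's first defection, then defects
#'   forever.
#' * `hard_tft` — defects if the opponent defected in any of the last three
#'   rounds.
#' * `hard_majo` — hard majority: opens with defection, then defects
#'   whenever the opponent's defections to date are at least as many as its
#'   cooperations.
#' * `hard_tf2t` — defects if the opponent defected twice in a row within
#'   the last three rounds.
#'
#' @return Character vector of the 14 identifiers.
#' @export
strategy_ids <- function() {
  c("ac", "ad", "random", "tft", "gtft", "wsls", "zde", "zdg",
    "hard_joss", "tf2t", "grim", "hard_tft", "hard_majo", "hard_tf2t")
}

# 0-based integer code used by the compiled engine.
strategy_code <- function(strategy) {
  i <- match(strategy, strategy_ids())
  if (anyNA(i)) {
    stop("unknown strategy id: ", paste(strategy[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i - 1L
}

STOCHASTIC <- c("random", "gtft", "zde", "zdg", "hard_joss")
DETERMINISTIC <- setdiff(
  c("ac", "ad", "tft", "wsls", "tf2t", "grim", "hard_tft", "hard_majo",
    "hard_tf2t"), character())

is_stochastic <- function(strategy) strategy %in% STOCHASTIC

#' Memory-one representation of a strategy
#'
#' Ten of the fourteen strategies are memory-one: their play is fully
#' described by the four probabilities of cooperating after the previous
#' joint outcomes CC, CD, DC and DD (own move listed first).  The remaining
#' four (`tf2t`, `hard_tft`, `hard_majo`, `hard_tf2t`) condition on more
#' than one round of history and have no such vector.
#'
#' @param strategy A strategy id (see [strategy_ids()]).
#' @return Named numeric vector `c(CC =, CD =, DC =, DD =)`, or `NULL` if
#'   the strategy is not memory-one.
#' @examples
#' memory_one_vector("tft")   # (1, 0, 1, 0)
#' memory_one_vector("tf2t")  # NULL
#' @export
memory_one_vector <- function(strategy) {
  strategy_code(strategy) # validates
  v <- switch(strategy,
    ac        = c(1, 1, 1, 1),
    ad        = c(0, 0, 0, 0),
    random    = c(.5, .5, .5, .5),
    tft       = c(1, 0, 1, 0),
    gtft      = c(1, 1 / 3, 1, 1 / 3),
    wsls      = c(1, 0, 0, 1),
    zde       = c(11 / 13, 1 / 2, 7 / 26, 0),
    zdg       = c(1, 2 / 11, 1, 4 / 11),
    hard_joss = c(0.9, 0, 0.9, 0),
    grim      = c(1, 0, 0, 0),
    NULL)
  if (!is.null(v)) names(v) <- c("CC", "CD", "DC", "DD")
  v
}

#' Per-opponent game history
#'
#' The sufficient statistics a player keeps about one opponent: the last
#' three opponent moves (most recent first, padded with `"C"` before round
#' three), the player's own last move, the opponent's cooperation and
#' defection counts, the grim trigger flag, and the number of rounds played.
#' These statistics drive all fourteen policies, so no unbounded history is
#' ever stored.
#'
#' @param own_last Own previous move.
#' @param opp_window Character vector (length 3) of opponent moves, most
#'   recent first.
#' @param coop,def Opponent cooperation / defection counts.
#' @param round Rounds already played.
#' @return An object of class `pair_history`.
#' @export
pair_history <- function(own_last = "C", opp_window = c("C", "C", "C"),
                         coop = 0L, def = 0L, round = 0L) {
  assert_move(own_last)
  stopifnot(length(opp_window) == 3L, all(opp_window %in% c("C", "D")),
            coop >= 0L, def >= 0L, round >= 0L)
  if (coop + def != round) {
    stop("inconsistent history: coop + def must equal round", call. = FALSE)
  }
  structure(list(own_last = own_last, opp_window = opp_window,
                 coop = as.integer(coop), def = as.integer(def),
                 grim = def > 0L, round = as.integer(round)),
            class = "pair_history")
}

#' Advance a pair history by one observed round
#'
#' @param h A [pair_history()].
#' @param own,opp The two moves just played.
#' @return The updated `pair_history`.
#' @export
update_history <- function(h, own, opp) {
  stopifnot(inherits(h, "pair_history"))
  assert_move(own); assert_move(opp)
  pair_history(own_last = own,
               opp_window = c(opp, h$opp_window[1:2]),
               coop = h$coop + (opp == "C"),
               def = h$def + (opp == "D"),
               round = h$round + 1L)
}

#' First move of a strategy
#'
#' Every strategy opens cooperatively unless it specifies otherwise:
#' `hard_majo` opens with defection, `ad` always defects, and `random`
#' flips its coin (consuming one uniform draw).
#'
#' @param strategy A strategy id.
#' @return `"C"` or `"D"`.
#' @export
first_move <- function(strategy) {
  strategy_code(strategy)
  switch(strategy,
         ad = "D",
         hard_majo = "D",
         random = if (stats::runif(1) < 0.5) "C" else "D",
         "C")
}

#' Next move of a strategy given a pair history
#'
#' Implements all fourteen policies on the [pair_history()] sufficient
#' statistics.  Stochastic strategies (`random`, `gtft`, `zde`, `zdg`,
#' `hard_joss`) consume exactly one uniform draw per decision from R's RNG
#' stream; the deterministic strategies consume none, so trajectories are
#' bit-reproducible under a fixed seed.
#'
#' This is the reference implementation; the compiled engine in the match
#' and network simulators follows the identical decision rules and draw
#' order, which the test-suite checks by trajectory equality.
#'
#' @param strategy A strategy id.
#' @param h A [pair_history()] with `round >= 1` (use [first_move()] for
#'   round one).
#' @return `"C"` or `"D"`.
#' @examples
#' h <- update_history(pair_history(), "C", "D")
#' next_move("tft", h)  # "D"
#' @export
next_move <- function(strategy, h) {
  strategy_code(strategy)
  stopifnot(inherits(h, "pair_history"))
  if (h$round < 1L) {
    stop("next_move needs round >= 1; use first_move for the opening round",
         call. = FALSE)
  }
  own <- h$own_last == "C"
  opp <- h$opp_window == "C" # logical length 3, most recent first
  cd <- function(p) if (stats::runif(1) < p) "C" else "D"
  switch(strategy,
    ac = "C",
    ad = "D",
    random = cd(0.5),
    tft = if (opp[1]) "C" else "D",
    gtft = , zde = , zdg = , hard_joss = {
      v <- memory_one_vector(strategy)
      state <- paste0(if (own) "C" else "D", if (opp[1]) "C" else "D")
      cd(v[[state]])
    },
    wsls = if (own == opp[1]) "C" else "D",
    tf2t = if (!opp[1] && !opp[2]) "D" else "C",
    grim = if (h$def > 0L) "D" else "C",
    hard_tft = if (all(opp)) "C" else "D",
    hard_majo = if (h$coop > h$def) "C" else "D",
    hard_tf2t = if ((!opp[1] && !opp[2]) || (!opp[2] && !opp[3])) "D" else "C")
}
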