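#' Play an iterated match between two strategies
#'
#' Both players move simultaneously each round, each applying its policy to
#' the shared per-pair history; the round count is never visible to the
#' policies, so no end-game inference is possible.  Repeats restart the game
#' and are aggregated by summation.  Uses R's RNG stream (seed with
#' [set.seed()]); per round the first-listed player draws first.
#'
#' @param a,b Strategy ids.
#' @param rounds Rounds per repeat.
#' @param repeats Independent repeats.
#' @param params A [pd_payoffs()] object.
#' @return List with `a_total`, `b_total` (summed over all rounds and
#'   repeats) and `per_repeat`, a `repeats` x 2 matrix.
#' @examples
#' play_iterated("ac", "ad", rounds = 10)  # (0, 50)
#' @export
play_iterated <- function(a, b, rounds, repeats = 1L, params = pd_payoffs()) {
  stopifnot(rounds >= 1, repeats >= 1)
  m <- rr_match_cpp(strategy_code(a), strategy_code(b), as.integer(rounds),
                    as.integer(repeats), pay_vector(params))
  list(a_total = sum(m[, 1]), b_total = sum(m[, 2]), per_repeat = m)
}

#' Decide a round-robin match
#'
#' The strategy with the higher head-to-head aggregate wins; on an exact
#' tie, the strategy with the higher self-play aggregate wins; if both are
#' tied the match is a draw.  Equality is exact (no epsilon band):
#' deterministic pairs can and do tie exactly, stochastic pairs are almost
#' surely strictly ordered.
#'
#' @param a_total,b_total Head-to-head aggregate payoffs.
#' @param a_self,b_self Self-play aggregate payoffs under the same
#'   rounds-times-repeats protocol.
#' @return `"a"`, `"b"` or `"draw"`.
#' @export
decide_match <- function(a_total, b_total, a_self, b_self) {
  if (a_total > b_total) return("a")
  if (b_total > a_total) return("b")
  if (a_self > b_self) return("a")
  if (b_self > a_self) return("b")
  "draw"
}

#' Round-robin tournament of the fourteen strategies
#'
#' Plays all 91 unordered pairs of distinct strategies (each a
#' `rounds`-round iterated game repeated `repeats` times) plus the fourteen
#' self-matches, and applies [decide_match()].  A strategy's self-play
#' aggregate is the mean of the two seats of its self-match, computed once
#' and reused across all matches.  The loser of a match is the *weak*
#' strategy, the winner the *strong* one; draws carry no labels.
#'
#' The published protocol is 10,000 rounds repeated 100 times.
#'
#' @param rounds,repeats Match protocol.
#' @param params A [pd_payoffs()] object.
#' @return A list of class `ipd_scoreboard`: `matches` (data frame with one
#'   row per unordered pair: totals, self totals, verdict, weak, strong),
#'   `self_totals` (named vector), `n_nondraw`, and the protocol.
#' @export
round_robin <- function(rounds = 10000L, repeats = 100L,
                        params = pd_payoffs()) {
  ids <- strategy_ids()
  self_totals <- vapply(ids, function(s) {
    r <- play_iterated(s, s, rounds, repeats, params)
    (r$a_total + r$b_total) / 2
  }, numeric(1))
  pairs <- utils::combn(ids, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- play_iterated(a, b, rounds, repeats, params)
    v <- decide_match(r$a_total, r$b_total, self_totals[[a]],
                      self_totals[[b]])
    data.frame(strategy_a = a, strategy_b = b,
               total_a = r$a_total, total_b = r$b_total,
               self_a = self_totals[[a]], self_b = self_totals[[b]],
               verdict = v,
               weak = switch(v, a = b, b = a, draw = NA_character_),
               strong = switch(v, a = a, b = b, draw = NA_character_),
               stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, res)
  structure(list(matches = matches, self_totals = self_totals,
                 n_nondraw = sum(matches$verdict != "draw"),
                 rounds = rounds, repeats = repeats, params = params),
            class = "ipd_scoreboard")
}

#' @export
print.ipd_scoreboard <- function(x, ...) {
  cat(sprintf("Round-robin scoreboard: %d rounds x %d repeats\n",
              x$rounds, x$repeats))
  cat(sprintf("%d of %d matches decided (non-draw)\n",
              x$n_nondraw, nrow(x$matches)))
  invisible(x)
}

#' Weak/strong map of a scoreboard
#'
#' @param sb An `ipd_scoreboard` from [round_robin()].
#' @return Data frame with columns `weak`, `strong`, one row per non-draw
#'   match, the weak strategy listed first.
#' @export
weak_strong_map <- function(sb) {
  stopifnot(inherits(sb, "ipd_scoreboard"))
  m <- sb$matches[sb$matches$verdict != "draw", c("weak", "strong")]
  rownames(m) <- NULL
  m
}
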