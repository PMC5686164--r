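#' Prisoner's Dilemma payoff parameters
#'
#' Creates the value object carrying the four payoffs of a two-player
#' two-move game: the reward `R` for mutual cooperation, the sucker's payoff
#' `S` for cooperating with a defector, the temptation `T` for defecting a
#' cooperator and the punishment `P` for mutual defection.  The object is
#' passed explicitly to every function that scores games; there is no global
#' payoff state.
#'
#' A Prisoner's Dilemma requires `T > R > P >= S`, and `2R > T + S` so that
#' mutual cooperation beats alternating exploitation.  The default instance
#' is `(R, S, T, P) = (3, 0, 5, 1)`.
#'
#' @param R,S,T,P Numeric payoffs (dimensionless).
#' @return An object of class `pd_payoffs`: a named numeric vector
#'   `c(R =, S =, T =, P =)`.
#' @examples
#' pd_payoffs()
#' game_payoff("D", "C", pd_payoffs())  # temptation, 5
#' @export
pd_payoffs <- function(R = 3, S = 0, T = 5, P = 1) {
  stopifnot(is.numeric(R), is.numeric(S), is.numeric(T), is.numeric(P))
  p <- c(R = R, S = S, T = T, P = P)
  if (!(T > R && R > P && P >= S)) {
    stop("invalid payoff parameters: need T > R > P >= S", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("invalid payoff parameters: need 2R > T + S", call. = FALSE)
  }
  structure(p, class = "pd_payoffs")
}

#' @export
print.pd_payoffs <- function(x, ...) {
  cat(sprintf("PD payoffs: R = %g, S = %g, T = %g, P = %g\n",
              x[["R"]], x[["S"]], x[["T"]], x[["P"]]))
  invisible(x)
}

# Moves are the characters "C" and "D"; X = 1 for C, 0 for D.
assert_move <- function(m) {
  if (!(is.character(m) && length(m) == 1L && m %in% c("C", "D"))) {
    stop("a move must be \"C\" or \"D\"", call. = FALSE)
  }
  invisible(m)
}

#' Move indicator
#'
#' Maps a move to its indicator `X`: 1 for cooperation, 0 for defection.
#' The player's move vector is then `(X, 1 - X)`.
#'
#' @param m `"C"` or `"D"`.
#' @return 0 or 1.
#' @export
move_indicator <- function(m) {
  assert_move(m)
  if (m == "C") 1L else 0L
}

#' Single-game payoff
#'
#' The focal ("row") player's payoff from one simultaneous game: with move
#' vectors \eqn{\Omega_i = (X_i, 1-X_i)} the payoff is the bilinear form
#' \eqn{\Omega_i^T M \Omega_j} with \eqn{M = [[R, S], [T, P]]}.
#'
#' @param my,their Moves (`"C"` or `"D"`), `my` being the focal player's.
#' @param params A [pd_payoffs()] object.
#' @return The focal player's payoff, one of `R`, `S`, `T`, `P`.
#' @examples
#' game_payoff("C", "D")  # sucker's payoff, 0
#' @export
game_payoff <- function(my, their, params = pd_payoffs()) {
  stopifnot(inherits(params, "pd_payoffs"))
  oi <- c(move_indicator(my), 1L - move_indicator(my))
  oj <- c(move_indicator(their), 1L - move_indicator(their))
  M <- matrix(c(params[["R"]], params[["T"]], params[["S"]], params[["P"]]),
              nrow = 2)
  drop(oi %*% M %*% oj)
}

# (R, S, T, P) in the order the C++ engine expects.
pay_vector <- function(params) {
  stopifnot(inherits(params, "pd_payoffs"))
  unname(params[c("R", "S", "T", "P")])
}
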