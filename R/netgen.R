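#' Construct a network from an edge matrix
#'
#' @param n Node count.
#' @param edges Two-column integer matrix of 1-based node ids.
#' @return An object of class `ipd_network`: list with `n`, `edges` (each
#'   row `from < to`, rows sorted), and `degree`.
#' @export
ipd_network <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoint out of range", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (anyDuplicated(edges)) {
      stop("duplicate edges are not allowed", call. = FALSE)
    }
  }
  degree <- tabulate(edges, nbins = n)
  structure(list(n = as.integer(n), edges = edges, degree = degree),
            class = "ipd_network")
}

#' @export
print.ipd_network <- function(x, ...) {
  cat(sprintf("ipd_network: %d nodes, %d edges, mean degree %.2f\n",
              x$n, nrow(x$edges), mean(x$degree)))
  invisible(x)
}

#' Is the network connected?
#'
#' Breadth-first search from node 1.
#'
#' @param net An [ipd_network()].
#' @return Logical.
#' @export
is_connected <- function(net) {
  stopifnot(inherits(net, "ipd_network"))
  if (net$n <= 1L) return(TRUE)
  adj <- adjacency_list(net)
  seen <- logical(net$n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# Neighbour lists in edge-storage order (the same order the compiled engine
# uses, so tie-breaking draws coincide between the two engines).
adjacency_list <- function(net) {
  adj <- rep(list(integer(0)), net$n)
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges[i, 1]; v <- net$edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

#' Watts-Strogatz small-world network
#'
#' Classic construction: a ring lattice in which every node is linked to
#' its `k/2` nearest neighbours on each side, then each lattice edge's far
#' endpoint is rewired independently with probability `p` to a uniformly
#' drawn node, resampling on self-loops and duplicates.  The edge count is
#' therefore exactly `n * k / 2`.
#'
#' Uses R's RNG: one uniform per edge for the rewire decision plus one per
#' resampling attempt.
#'
#' @param n Nodes (`n > k`).
#' @param k Even lattice degree.
#' @param p Rewiring probability in `[0, 1]`.
#' @return An [ipd_network()].
#' @export
generate_ws <- function(n, k, p) {
  if (!(n > k && k >= 2 && k %% 2 == 0 && p >= 0 && p <= 1)) {
    stop("need n > k >= 2, k even, 0 <= p <= 1", call. = FALSE)
  }
  half <- k %/% 2
  has <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste0(min(i, j), "-", max(i, j))
  from <- integer(n * half); to <- integer(n * half)
  idx <- 0L
  for (off in seq_len(half)) {
    for (i in seq_len(n)) {
      j <- (i - 1L + off) %% n + 1L
      idx <- idx + 1L
      from[idx] <- i; to[idx] <- j
      assign(ekey(i, j), TRUE, envir = has)
    }
  }
  for (e in seq_len(idx)) {
    if (stats::runif(1) < p) {
      i <- from[e]; j <- to[e]
      repeat {
        t <- sample.int(n, 1L)
        if (t != i && is.null(has[[ekey(i, t)]])) break
      }
      rm(list = ekey(i, j), envir = has)
      assign(ekey(i, t), TRUE, envir = has)
      to[e] <- t
    }
  }
  ipd_network(n, cbind(from, to))
}

#' Barabasi-Albert scale-free network
#'
#' Starts from a complete graph on `m0` seed nodes; every subsequent node
#' attaches `m` edges to distinct existing nodes drawn proportionally to
#' degree (repeated-node sampling with rejection of duplicates).  The edge
#' count is exactly `choose(m0, 2) + (n - m0) * m`.
#'
#' @param n Nodes.
#' @param m Edges added per new node.
#' @param m0 Seed nodes (`n >= m0 >= m >= 1`).
#' @return An [ipd_network()].
#' @export
generate_ba <- function(n, m, m0 = m) {
  if (!(n >= m0 && m0 >= m && m >= 1)) {
    stop("need n >= m0 >= m >= 1", call. = FALSE)
  }
  seed <- utils::combn(seq_len(m0), 2)
  from <- seed[1, ]; to <- seed[2, ]
  # multiset of edge endpoints: sampling from it is degree-proportional
  bag <- c(from, to)
  if (n > m0) {
    for (v in (m0 + 1L):n) {
      targets <- integer(0)
      while (length(targets) < m) {
        t <- bag[sample.int(length(bag), 1L)]
        if (!(t %in% targets)) targets <- c(targets, t)
      }
      from <- c(from, rep.int(v, m)); to <- c(to, targets)
      bag <- c(bag, targets, rep.int(v, m))
    }
  }
  ipd_network(n, cbind(from, to))
}

#' Network presets of the tournament
#'
#' The four study networks: `wssn1`/`wssn2` are Watts-Strogatz networks
#' with `N = 1024`, `k = 6` and rewiring `p = 0.1` / `p = 0.2` (3,072 edges
#' each); `basn1`/`basn2` are Barabasi-Albert networks with `m = m0 = 3`
#' and `N = 1024` / `N = 2048` (3,066 and 6,138 edges with the
#' complete-triangle seed).  Presets are regenerated until connected
#' (disconnection is extremely rare at these parameters).
#'
#' @param name One of `"wssn1"`, `"wssn2"`, `"basn1"`, `"basn2"`.
#' @param max_tries Regeneration attempts before giving up.
#' @return An [ipd_network()].
#' @export
network_preset <- function(name, max_tries = 100L) {
  gen <- switch(name,
    wssn1 = function() generate_ws(1024L, 6L, 0.1),
    wssn2 = function() generate_ws(1024L, 6L, 0.2),
    basn1 = function() generate_ba(1024L, 3L, 3L),
    basn2 = function() generate_ba(2048L, 3L, 3L),
    stop("unknown preset: ", name, call. = FALSE))
  for (i in seq_len(max_tries)) {
    net <- gen()
    if (is_connected(net)) return(net)
  }
  stop("failed to generate a connected preset in ", max_tries, " tries",
       call. = FALSE)
}

#' Degree-ranked assignment of the weak strategy
#'
#' Splits an even-sized population half-and-half between a weak and a
#' strong strategy.  Of the `N/2` weak players, `epsilon = floor(alpha *
#' N/2)` are placed on the top-degree nodes (descending degree, ties broken
#' by a seeded shuffle) and the rest uniformly at random among the
#' remaining nodes; all other nodes receive the strong strategy.
#'
#' @param net An [ipd_network()] with an even node count.
#' @param weak,strong Strategy ids.
#' @param alpha Fraction in `[0, 1]` of weak players forced onto top
#'   degrees.
#' @return An object of class `ipd_assignment`: list with `strategies`
#'   (character vector, one id per node), `weak`, `strong`, `alpha`,
#'   `epsilon`.
#' @export
assign_strategies <- function(net, weak, strong, alpha) {
  stopifnot(inherits(net, "ipd_network"), alpha >= 0, alpha <= 1)
  strategy_code(weak); strategy_code(strong)
  n <- net$n
  if (n %% 2L != 0L) stop("node count must be even", call. = FALSE)
  mu <- n %/% 2L
  eps <- floor(alpha * mu)
  shuffle <- sample.int(n) # seeded tie-break for near-regular degree sequences
  ranking <- order(-net$degree, shuffle)
  top <- ranking[seq_len(eps)]
  rest <- setdiff(seq_len(n), top)
  others <- if (mu - eps > 0) {
    rest[sample.int(length(rest), mu - eps)]
  } else integer(0)
  strategies <- rep(strong, n)
  strategies[c(top, others)] <- weak
  structure(list(strategies = strategies, weak = weak, strong = strong,
                 alpha = alpha, epsilon = as.integer(eps), top = top),
            class = "ipd_assignment")
}

#' @export
print.ipd_assignment <- function(x, ...) {
  cat(sprintf(
    "ipd_assignment: %s (weak) vs %s (strong), alpha = %g, epsilon = %d\n",
    x$weak, x$strong, x$alpha, x$epsilon))
  invisible(x)
}
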