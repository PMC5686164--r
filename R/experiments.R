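#' Plan an alpha-sweep experiment
#'
#' The published grid tests 101 values of alpha (0 to 1, step 0.01), each
#' run ten times, on each network preset and fitness measure, for every
#' non-draw match of the round-robin scoreboard.
#'
#' @param network Preset name (see [network_preset()]).
#' @param measure `"phi"` or `"psi"`.
#' @param matches Data frame with columns `weak`, `strong` (e.g. from
#'   [weak_strong_map()]), the weak strategy listed first.
#' @param alpha Increasing numeric grid in `[0, 1]`.
#' @param replicates Replicates per alpha value.
#' @param config A [dnc_config()]; its `measure` is overridden by
#'   `measure`.
#' @param regenerate_network If `TRUE` (default) every replicate generates
#'   a fresh network from its own substream; if `FALSE` one network per
#'   plan is generated from the root seed and reused.
#' @return An object of class `sweep_plan`.
#' @export
sweep_plan <- function(network, measure = c("phi", "psi"), matches,
                       alpha = seq(0, 1, by = 0.01), replicates = 10L,
                       config = dnc_config(), regenerate_network = TRUE) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(matches), all(c("weak", "strong") %in% names(matches)),
            all(diff(alpha) > 0), all(alpha >= 0 & alpha <= 1),
            replicates >= 1)
  config$measure <- measure
  structure(list(network = network, measure = measure,
                 matches = matches[, c("weak", "strong")],
                 alpha = alpha, replicates = as.integer(replicates),
                 config = config,
                 regenerate_network = isTRUE(regenerate_network)),
            class = "sweep_plan")
}

# One deterministic sub-seed per (match, alpha, replicate), derived from the
# root seed so individual runs are re-executable in isolation.
substream_seeds <- function(root_seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an alpha sweep
#'
#' Executes [assign_strategies()] + [dnc_run()] for every (match, alpha,
#' replicate) cell of the plan, each from its own deterministic substream
#' of `seed`, and returns tidy rows.
#'
#' @param plan A [sweep_plan()].
#' @param seed Root seed; every cell derives its own sub-seed from it.
#' @param params A [pd_payoffs()] object.
#' @param verbose Print one line per completed cell.
#' @return A data frame of class `sweep_result`: one row per cell with
#'   columns `network`, `measure`, `weak`, `strong`, `alpha`, `replicate`,
#'   `seed`, `f_w`, `termination_round`, `reason`.
#' @export
run_sweep <- function(plan, seed, params = pd_payoffs(), verbose = FALSE) {
  stopifnot(inherits(plan, "sweep_plan"))
  cells <- expand.grid(replicate = seq_len(plan$replicates),
                       alpha_i = seq_along(plan$alpha),
                       match_i = seq_len(nrow(plan$matches)))
  seeds <- substream_seeds(seed, nrow(cells))
  fixed_net <- NULL
  if (!plan$regenerate_network) {
    set.seed(seed)
    fixed_net <- network_preset(plan$network)
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    a <- plan$alpha[cell$alpha_i]
    weak <- plan$matches$weak[cell$match_i]
    strong <- plan$matches$strong[cell$match_i]
    set.seed(seeds[i])
    net <- if (is.null(fixed_net)) network_preset(plan$network) else fixed_net
    asg <- assign_strategies(net, weak, strong, a)
    tr <- dnc_run(net, asg, plan$config, params)
    rows[[i]] <- data.frame(
      network = plan$network, measure = plan$measure,
      weak = weak, strong = strong, alpha = a,
      replicate = cell$replicate, seed = seeds[i], f_w = tr$f_w,
      termination_round = tr$termination_round, reason = tr$reason,
      stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("%s vs %s alpha=%.2f rep %d: f_w = %.4f (%s)",
                      weak, strong, a, cell$replicate, tr$f_w, tr$reason))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Per-alpha mean weak frequency
#'
#' @param result A [run_sweep()] result.
#' @return Data frame with one row per (match, alpha): mean `f_w` over
#'   replicates.
#' @export
sweep_summary <- function(result) {
  agg <- stats::aggregate(f_w ~ weak + strong + alpha, data = result, FUN = mean)
  agg[order(agg$weak, agg$strong, agg$alpha), ]
}

#' Protocol accounting
#'
#' Pure arithmetic on a plan: rounds per match equals `|alpha grid| *
#' replicates * max_rounds` (the cap; early extinction only shortens actual
#' runs), games per round equals the preset's edge count, and the grand
#' total multiplies by the number of matches and of (network, measure)
#' configurations.  The published protocol gives 20,200,000 rounds per
#' match and 8,726,400,000 rounds over 54 matches and 8 configurations.
#'
#' @param plan A [sweep_plan()].
#' @param n_matches Matches per configuration (54 in the published
#'   tournament; defaults to the plan's match list).
#' @param n_configurations Number of (network, measure) configurations.
#' @return List with `rounds_per_match`, `runs_per_match`,
#'   `total_rounds`.
#' @export
sweep_accounting <- function(plan, n_matches = nrow(plan$matches),
                             n_configurations = 1L) {
  rpm <- as.numeric(length(plan$alpha)) * plan$replicates *
    plan$config$max_rounds
  list(rounds_per_match = rpm,
       runs_per_match = length(plan$alpha) * plan$replicates,
       total_rounds = rpm * n_matches * n_configurations)
}
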