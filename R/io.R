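#' Read a network from a two-column edge list
#'
#' The file format is one undirected edge per line, two whitespace-
#' separated 0-based node ids, lower id first.  Self-loops and duplicate
#' edges are rejected with the offending line number.
#'
#' @param path File path.
#' @param n Node count; defaults to `max(id) + 1`.
#' @return An [ipd_network()].
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 2L || anyNA(suppressWarnings(as.integer(p)))) {
      stop(sprintf("malformed edge list line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    if (p[1] == p[2]) {
      stop(sprintf("self-loop at line %d: '%s'", i, lines[i]), call. = FALSE)
    }
  }
  e <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE) + 1L
  if (is.null(n)) n <- max(e)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate edge at line %d", anyDuplicated(key)),
         call. = FALSE)
  }
  ipd_network(n, e)
}

#' Write a network as a two-column edge list
#'
#' @param net An [ipd_network()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ipd_network"))
  writeLines(paste(net$edges[, 1] - 1L, net$edges[, 2] - 1L), path)
  invisible(path)
}

#' Small deterministic test networks
#'
#' * `ring4` — a 4-cycle, degrees (2,2,2,2).
#' * `star5` — a hub with four leaves.
#' * `two_triangles` — two triangles joined by one bridge edge.
#' * `tiny_ba` — a Barabasi-Albert graph with `N = 8`, `m = m0 = 3`
#'   (18 edges), generated from the current RNG state.
#'
#' @param name Fixture name.
#' @return An [ipd_network()].
#' @export
make_fixture <- function(name) {
  switch(name,
    ring4 = ipd_network(4, cbind(c(1, 2, 3, 1), c(2, 3, 4, 4))),
    star5 = ipd_network(5, cbind(1, 2:5)),
    two_triangles = ipd_network(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                                         c(4, 5), c(4, 6), c(5, 6),
                                         c(3, 4))),
    tiny_ba = generate_ba(8, 3, 3),
    stop("unknown fixture: ", name, call. = FALSE))
}

#' Run manifest for a sweep
#'
#' Records what is needed to re-execute any single run of a sweep: the
#' package version, the root seed, a hash of the plan, and the per-cell
#' sub-seeds.  The plan hash changes whenever any plan field changes.
#'
#' @param plan A [sweep_plan()].
#' @param seed Root seed.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(plan, seed) {
  stopifnot(inherits(plan, "sweep_plan"))
  n <- nrow(plan$matches) * length(plan$alpha) * plan$replicates
  list(structure = "ipdnet run manifest",
       version = as.character(utils::packageVersion("ipdnet")),
       seed = seed,
       plan_hash = plan_hash(plan),
       substreams = substream_seeds(seed, n),
       created = format(Sys.time(), tz = "UTC")) |>
    structure(class = "run_manifest")
}

# md5 of the serialized plan (written to a temp file; base R's only digest)
plan_hash <- function(plan) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(plan, f, version = 2)
  unname(tools::md5sum(f))
}
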