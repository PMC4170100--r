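# MCODE module detection (Bader-Hogue style): vertex weighting by the
# density x core number of the highest k-core of the closed neighborhood,
# greedy seeded growth with a weight admission threshold, optional haircut
# and fluff post-processing. Fully deterministic given the documented
# tie-break (weight descending, then lexicographic node ID).

#' MCODE parameters
#'
#' Canonical MCODE defaults, recorded explicitly so module reports carry
#' their provenance.
#'
#' @param node_score_cutoff admission band below the seed weight, in
#'   `[0, 1)`: a neighbor joins a growing module if its weight is at least
#'   `seed_weight * (1 - node_score_cutoff)` (default 0.2).
#' @param k_core a finished module must contain a k-core of at least this
#'   order (default 2), discarding trivial pairs.
#' @param haircut remove singly-connected members (keep the module's 2-core;
#'   default `TRUE`).
#' @param fluff add unassigned neighbors whose closed-neighborhood density
#'   exceeds `fluff_density` (default `FALSE`).
#' @param fluff_density density threshold used when `fluff = TRUE`.
#' @param max_depth maximum growth distance from the seed (default 100).
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, k_core = 2L, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.1, max_depth = 100L) {
  if (!is.numeric(node_score_cutoff) || node_score_cutoff < 0 ||
      node_score_cutoff >= 1)
    stop("`node_score_cutoff` must lie in [0, 1)", call. = FALSE)
  stop_if_not_count(k_core, "k_core")
  stop_if_not_count(max_depth, "max_depth")
  structure(list(node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core), haircut = isTRUE(haircut),
                 fluff = isTRUE(fluff), fluff_density = fluff_density,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

# density of a simple undirected graph; 0 for < 2 vertices
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE vertex weight: k x density of the highest k-core of the closed
# neighborhood of v.
mcode_vertex_weights <- function(g) {
  vn <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  w <- numeric(length(vn))
  for (i in seq_along(vn)) {
    nb <- c(i, as.integer(adj[[i]]))
    if (length(nb) < 2) { w[i] <- 0; next }
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) { w[i] <- 0; next }
    ksub <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[i] <- kmax * graph_density(ksub)
  }
  names(w) <- vn
  w
}

#' MCODE module detection
#'
#' Finds densely interconnected modules ("a group of densely connected
#' nodes with a sparsely connected periphery"). Vertices are weighted by
#' the core-clustering coefficient of their closed neighborhood; modules
#' grow greedily from unassigned highest-weight seeds, admitting neighbors
#' whose weight is within the `node_score_cutoff` band of the seed weight;
#' the haircut step then prunes singly-connected periphery. Module score is
#' density x size; modules are ranked by descending score with a
#' deterministic tie-break.
#'
#' @param net a simple undirected [igraph::graph].
#' @param params an [mcode_params()].
#' @return Data-frame-like list of class `ssr_mcode`: one element per module
#'   with `members` (character), `seed`, `score`, `density`, `size`; ordered
#'   by descending score. Empty list for an edgeless graph.
#' @export
mcode <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  if (igraph::vcount(net) == 0 || igraph::ecount(net) == 0)
    return(structure(list(), class = "ssr_mcode", params = params))
  if (igraph::any_multiple(net) || any(igraph::which_loop(net)))
    stop("`net` must be a simple graph", call. = FALSE)

  w <- mcode_vertex_weights(net)
  vn <- names(w)
  order_idx <- order(-w, vn)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  assigned <- rep(FALSE, length(vn))
  names(assigned) <- vn
  modules <- list()

  for (s in order_idx) {
    if (assigned[s] || w[s] <= 0) next
    threshold <- w[s] * (1 - params$node_score_cutoff)
    members <- s
    seen <- rep(FALSE, length(vn)); seen[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (seen[u] || assigned[u]) next
          seen[u] <- TRUE
          if (w[u] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(net, members)
    if (params$haircut && igraph::vcount(sub) > 0) {
      core <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(core >= 2))
    }
    if (igraph::vcount(sub) == 0) next
    if (max(igraph::coreness(sub)) < params$k_core) next
    core_members <- sort(igraph::V(sub)$name)
    mem_names <- core_members
    if (params$fluff) {
      extra <- character(0)
      for (v in core_members) {
        for (u in as.integer(adj[[match(v, vn)]])) {
          un <- vn[u]
          if (un %in% mem_names || assigned[u] || un %in% extra) next
          nb <- c(u, as.integer(adj[[u]]))
          if (graph_density(igraph::induced_subgraph(net, nb)) >=
              params$fluff_density)
            extra <- c(extra, un)
        }
      }
      mem_names <- sort(c(core_members, extra))
    }
    # fluffed periphery may be shared between modules; only the dense core
    # is claimed
    assigned[match(core_members, vn)] <- TRUE
    msub <- igraph::induced_subgraph(net, mem_names)
    dens <- graph_density(msub)
    modules[[length(modules) + 1L]] <-
      list(members = mem_names, seed = vn[s],
           density = dens, size = length(mem_names),
           score = dens * length(mem_names))
  }
  if (length(modules)) {
    first <- vapply(modules, function(m) m$members[1], character(1))
    scr <- vapply(modules, `[[`, numeric(1), "score")
    sz <- vapply(modules, `[[`, numeric(1), "size")
    modules <- modules[order(-scr, -sz, first)]
  }
  structure(modules, class = "ssr_mcode", params = params)
}

#' @export
print.ssr_mcode <- function(x, ...) {
  cat("MCODE modules:", length(x), "\n")
  for (i in seq_along(x))
    cat(sprintf("  #%d size %d, density %.3f, score %.3f (seed %s)\n",
                i, x[[i]]$size, x[[i]]$density, x[[i]]$score, x[[i]]$seed))
  invisible(x)
}

#' Tabulate MCODE modules
#'
#' @param modules an `ssr_mcode` result.
#' @return Data frame `module_id`, `score`, `size`, `members`
#'   (comma-separated).
#' @export
mcode_table <- function(modules) {
  if (!length(modules))
    return(data.frame(module_id = integer(), score = numeric(),
                      size = integer(), members = character()))
  data.frame(module_id = seq_along(modules),
             score = vapply(modules, `[[`, numeric(1), "score"),
             size = vapply(modules, `[[`, numeric(1), "size"),
             members = vapply(modules, function(m)
               paste(m$members, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}
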