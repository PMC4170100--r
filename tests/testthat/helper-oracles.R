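# Independent oracles used across the suite. These are deliberately naive
# re-implementations kept separate from the package code paths they check.

# sliding-window occurrence count (overlapping)
naive_count <- function(s, p) {
  n <- nchar(s); m <- nchar(p)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(s, i, i + m - 1L) == p, logical(1)))
}

# two-pass Pearson correlation from the covariance formula
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force degree counts from an edge data frame
naive_degrees <- function(edges, nodes) {
  d <- setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    d[edges$from[i]] <- d[edges$from[i]] + 1L
    d[edges$to[i]] <- d[edges$to[i]] + 1L
  }
  d
}

# Venn region counts by explicit membership bitmask enumeration
bitmask_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  masks <- vapply(universe, function(g)
    sum(2^(which(vapply(sets, function(s) g %in% s, logical(1))) - 1L)),
    numeric(1))
  out <- integer(2^length(sets) - 1L)
  names(out) <- vapply(seq_along(out), function(m)
    paste(names(sets)[bitwAnd(m, 2^(seq_along(sets) - 1L)) > 0],
          collapse = "&"), character(1))
  for (m in masks) out[m] <- out[m] + 1L
  out
}

# density x size of a node set in a graph, from first principles
naive_module_score <- function(net, members) {
  v <- length(members)
  if (v < 2) return(0)
  el <- igraph::as_data_frame(net, what = "edges")
  e <- sum(el$from %in% members & el$to %in% members)
  (2 * e / (v * (v - 1))) * v
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small random ACGT string
rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# planted one-module compendium used by several network tests
module_fixture <- function(n_noise = 500, module_size = 50, latent_r = 0.95,
                           n_samples = 60, seed = 3) {
  gen_compendium(compendium_spec(
    n_noise + module_size, n_samples,
    modules = list(list(size = module_size, latent_r = latent_r)),
    rng_seed = seed))
}
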