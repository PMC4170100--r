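# Degree structure, scale-free summary and MCODE module detection.

star_graph <- function() {
  igraph::graph_from_data_frame(
    data.frame(from = "hub", to = paste0("leaf", 1:5)), directed = FALSE)
}

test_that("degree_summary bins a star graph correctly", {
  ds <- degree_summary(star_graph())
  expect_identical(unname(ds$bins), c(6L, 0L, 0L))
  expect_identical(ds$degrees$gene[1], "hub")
  expect_identical(ds$degrees$degree[1], 5L)
  expect_length(ds$hubs, 0)
})

test_that("degree bins match a brute-force count and partition the nodes", {
  set.seed(71)
  g <- igraph::sample_gnp(200, 0.05)
  igraph::V(g)$name <- sprintf("n%03d", 1:200)
  ds <- degree_summary(g)
  el <- igraph::as_data_frame(g, what = "edges")
  d <- naive_degrees(el, igraph::V(g)$name)
  expect_identical(unname(ds$bins),
                   c(sum(d < 10), sum(d >= 10 & d < 100), sum(d >= 100)))
  expect_identical(sum(ds$bins), 200L)
  # per-node degrees agree with the oracle
  expect_identical(setNames(ds$degrees$degree, ds$degrees$gene)[names(d)], d)
})

test_that("hub and structural lists are nested and degree-sorted", {
  edges <- do.call(rbind, lapply(1:120, function(i)
    data.frame(from = "big", to = sprintf("x%03d", i))))
  edges <- rbind(edges, do.call(rbind, lapply(1:30, function(i)
    data.frame(from = "mid", to = sprintf("x%03d", i)))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  ds <- degree_summary(g)
  expect_identical(ds$hubs, "big")
  expect_setequal(ds$structural, c("big", "mid"))
  expect_true(all(ds$hubs %in% ds$structural))
  expect_true(all(diff(ds$degrees$degree) <= 0))
})

test_that("scale_free_summary flags degenerate distributions, fits real ones", {
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- paste0("r", 1:20)
  sf <- scale_free_summary(ring)
  expect_false(sf$slope_defined)
  expect_identical(sf$histogram$degree, 2L)

  two <- igraph::graph_from_data_frame(data.frame(from = "a", to = "b"),
                                       directed = FALSE)
  h <- scale_free_summary(two)$histogram
  expect_identical(h$degree, 1L)
  expect_identical(h$count, 2L)

  set.seed(72)
  ba <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  igraph::V(ba)$name <- sprintf("v%04d", 1:2000)
  sfb <- scale_free_summary(ba)
  expect_true(sfb$slope_defined)
  expect_lt(sfb$slope, 0)  # heavy-tailed preferential attachment
})

test_that("mcode isolates a clique from trivial pairs", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("k", 1:5)
  for (i in 1:10) {
    h <- igraph::make_graph(c(1, 2), n = 2, directed = FALSE)
    igraph::V(h)$name <- paste0("p", i, c("a", "b"))
    g <- igraph::disjoint_union(g, h)
  }
  mods <- mcode(g)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$members, paste0("k", 1:5))
  expect_equal(mods[[1]]$score, 5.0)
  expect_equal(mods[[1]]$density, 1.0)
})

test_that("mcode finds both cliques behind a sparse background", {
  edges <- rbind(
    t(combn(paste0("a", 1:4), 2)),
    t(combn(paste0("b", 1:4), 2)),
    cbind(paste0("c", 1:5), paste0("c", 2:6)),
    c("c1", "a1"), c("c4", "b1"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE)
  mods <- mcode(g)
  expect_length(mods, 2)
  mem <- lapply(mods, `[[`, "members")
  expect_setequal(mem[[1]], paste0("a", 1:4))  # lexicographic tie-break
  expect_setequal(mem[[2]], paste0("b", 1:4))
  expect_equal(vapply(mods, `[[`, numeric(1), "score"), c(4, 4))
})

test_that("mcode scores equal an independent density recomputation", {
  set.seed(73)
  g <- igraph::sample_gnp(60, 0.12)
  igraph::V(g)$name <- sprintf("v%02d", 1:60)
  # implant one dense subgraph
  dense <- sprintf("v%02d", 1:8)
  for (p in combn(dense, 2, simplify = FALSE))
    if (!igraph::are_adjacent(g, p[1], p[2]))
      g <- igraph::add_edges(g, p)
  mods <- mcode(g)
  expect_gt(length(mods), 0)
  for (m in mods)
    expect_equal(m$score, naive_module_score(g, m$members), tolerance = 1e-12)
})

test_that("mcode output is invariant under node relabeling", {
  set.seed(74)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  dense <- sprintf("v%02d", 5:10)
  for (p in combn(dense, 2, simplify = FALSE))
    if (!igraph::are_adjacent(g, p[1], p[2]))
      g <- igraph::add_edges(g, p)
  perm <- setNames(sprintf("w%02d", sample(40)), sprintf("v%02d", 1:40))
  g2 <- g
  igraph::V(g2)$name <- unname(perm[igraph::V(g)$name])
  m1 <- mcode(g)
  m2 <- mcode(g2)
  expect_identical(length(m1), length(m2))
  sets1 <- lapply(m1, function(m) sort(unname(perm[m$members])))
  sets2 <- lapply(m2, function(m) sort(m$members))
  expect_setequal(vapply(sets1, paste, character(1), collapse = ","),
                  vapply(sets2, paste, character(1), collapse = ","))
})

test_that("mcode handles edgeless graphs and rejects multigraphs", {
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(empty)$name <- letters[1:5]
  expect_length(mcode(empty), 0)
  multi <- igraph::make_graph(c(1, 2, 1, 2), n = 2, directed = FALSE)
  igraph::V(multi)$name <- c("a", "b")
  expect_error(mcode(multi), "simple")
})

test_that("top-2 mcode modules recover two planted co-expression modules", {
  sim <- gen_compendium(compendium_spec(
    400, 60, modules = list(list(size = 40, latent_r = 0.95),
                            list(size = 40, latent_r = 0.95)),
    rng_seed = 75))
  truth <- split(sim$truth$gene_id, sim$truth$module)
  seeds <- c(head(truth$M1, 6), head(truth$M2, 6))
  ex <- expand_seeds(sim$values, seeds)
  mods <- mcode(ex$network)
  expect_gte(length(mods), 2)
  got <- lapply(mods[1:2], `[[`, "members")
  j <- outer(seq_along(got), 1:2, Vectorize(function(i, k)
    jaccard(got[[i]], truth[[k]])))
  expect_gte(max(j[1, ]), 0.9)
  expect_gte(max(j[2, ]), 0.9)
})
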