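# Venn partitions, network/DE cross-examination and the pipeline surface.

test_that("percentages round half away from zero", {
  expect_identical(percent_round(220, 820), 27L)
  expect_identical(percent_round(783, 3332), 23L)
  expect_identical(percent_round(2549, 3332), 77L)
  expect_identical(percent_round(15, 820), 2L)
  expect_identical(percent_round(89, 820), 11L)
  expect_identical(percent_round(1, 8), 13L)    # 12.5 -> 13
  expect_identical(percent_round(-1, 8), -13L)  # -12.5 -> -13
})

test_that("venn partition covers the degenerate layouts", {
  s <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  v <- venn_partition(s)
  expect_identical(unname(v$counts["A&B&C"]), 5L)
  expect_identical(sum(v$counts), v$union_size)
  expect_true(all(v$counts[names(v$counts) != "A&B&C"] == 0))

  d <- venn_partition(list(A = c("a", "b"), B = c("c"), C = c("d", "e")))
  expect_identical(unname(d$counts[c("A", "B", "C")]), c(2L, 1L, 2L))
  expect_true(all(d$counts[grepl("&", names(d$counts))] == 0))

  expect_error(venn_partition(list(A = "a", B = "b", C = "c", D = "d")),
               "2 or 3")
})

test_that("venn regions equal the bitmask enumeration oracle", {
  set.seed(61)
  genes <- sprintf("g%04d", 1:1000)
  for (rep in 1:5) {
    sets <- list(A = sample(genes, 300), B = sample(genes, 250),
                 C = sample(genes, 350))
    v <- venn_partition(sets)
    oracle <- bitmask_venn_counts(sets)
    expect_identical(v$counts[names(oracle)], oracle[names(oracle)])
    # regions are disjoint and exhaustive
    expect_identical(sum(v$counts), length(unique(unlist(sets))))
    expect_identical(anyDuplicated(unlist(v$regions)), 0L)
  }
})

small_net <- function(genes) {
  edges <- data.frame(from = genes[1], to = genes[-1])
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

test_that("cross_examine on all-unchanged calls reports zero overlap", {
  genes <- paste0("g", 1:6)
  net <- small_net(genes)
  degs <- degree_summary(net)
  cs <- lapply(c("m1", "m2"), function(m)
    de_call_set(paste0(m, "_dawn"), m, "dawn",
                setNames(rep("unchanged", 6), genes)))
  rep <- cross_examine(net, degs, cs)
  expect_identical(unname(rep$counts["up_dawn_any"]), 0L)
  expect_identical(unname(rep$percent["up_dawn_any"]), 0L)
  expect_identical(unname(rep$counts["stable"]), 6L)
})

test_that("planted module genes up in all lines are counted as such", {
  sim <- module_fixture(n_noise = 150, module_size = 30, seed = 62)
  mod <- sim$truth$gene_id[!is.na(sim$truth$module)]
  ex <- expand_seeds(sim$values, mod[1:6])
  net <- ex$network
  degs <- degree_summary(net)
  all_genes <- sim$truth$gene_id
  calls <- lapply(c("adg1", "be2_be3", "adg1_be2_be3"), function(m) {
    v <- setNames(rep("unchanged", length(all_genes)), all_genes)
    v[mod] <- "up"
    de_call_set(paste0(m, "_dawn"), m, "dawn", v)
  })
  rep <- cross_examine(net, degs, calls)
  in_net_mod <- intersect(mod, igraph::V(net)$name)
  expect_identical(unname(rep$counts["up_dawn_all"]), length(in_net_mod))
  expect_identical(unname(rep$counts["up_dawn_any"]), length(in_net_mod))
  # every printed percentage is reproducible from the stored sets
  expect_identical(unname(rep$percent["up_dawn_any"]),
                   percent_round(length(rep$sets$up_dawn_any),
                                 unname(rep$counts["network_size"])))
  expect_identical(unname(rep$percent["stable"]),
                   percent_round(length(rep$sets$stable),
                                 unname(rep$counts["network_size"])))
})

test_that("disjoint namespaces are a hard error", {
  net <- small_net(paste0("g", 1:4))
  degs <- degree_summary(net)
  cs <- list(de_call_set("x_dawn", "x", "dawn",
                         setNames("up", "other_gene")))
  expect_error(cross_examine(net, degs, cs), "namespace")
})

test_that("call sets validate their inputs", {
  expect_error(de_call_set("a", "m", "noon", setNames("up", "g")), "dawn")
  expect_error(de_call_set("a", "m", "dawn", setNames("sideways", "g")),
               "up/down")
  expect_error(de_call_set("a", "m", "dawn", c("up", "down")), "named")
})

test_that("pipeline configs validate before any computation", {
  expect_error(run_pipeline(list()), "out_dir")
  bad <- tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(read_pipeline_config(bad), "not_a_key")
  expect_error(read_pipeline_config("/nonexistent/x.yaml"), "not found")
})

test_that("a small end-to-end run produces consistent artifacts", {
  out <- tempfile("ssr_run_")
  cfg <- list(seed = 7L, n_genes = 150L, n_samples = 30L,
              module_sizes = "20,20", module_r = "0.95,0.95",
              seeds_per_module = 6L, de_extra = 5L,
              promoter_length = 300L, kmer_B = 99L)
  res <- suppressMessages(run_pipeline(cfg, out))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "network.graphml")))
  expect_true(file.exists(file.path(out, "overlap_report.json")))

  # manifest digests match the files on disk
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  for (f in names(man$files))
    expect_identical(unname(tools::md5sum(file.path(out, f))),
                     man$files[[f]])

  # the planted modules dominate the network and the report
  net_genes <- igraph::V(res$expansion$network)$name
  mod <- res$compendium$truth$gene_id[!is.na(res$compendium$truth$module)]
  expect_gte(jaccard(net_genes, mod), 0.8)
  # planted dawn response: all-lines intersection is the module core, up to
  # the handful of genes the extreme-variance step may drop per comparison
  n_mod_net <- length(intersect(mod, net_genes))
  expect_lte(unname(res$report$counts["up_dawn_all"]), n_mod_net)
  expect_gte(unname(res$report$counts["up_dawn_all"]), n_mod_net - 6L)
  # round-trip of the written network preserves the edge set
  rt <- read_edges_tsv(file.path(out, "network_edges.tsv"))
  expect_identical(nrow(rt), as.integer(igraph::ecount(res$expansion$network)))
  unlink(out, recursive = TRUE)
})

test_that("matrix, FASTA and seed-list round trips preserve content", {
  m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3),
                                               paste0("s", 1:4)))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m, tolerance = 1e-12)

  seqs <- c(p1 = "ACGTACGT", p2 = "GGGCCCAA")
  fa <- tempfile(fileext = ".fasta")
  write_promoters_fasta(seqs, fa)
  expect_identical(read_promoters_fasta(fa), seqs)

  sl <- tempfile(fileext = ".txt")
  writeLines(c("# seeds", "At3g47340", "", "At2g18700"), sl)
  expect_identical(read_seed_list(sl), c("At3g47340", "At2g18700"))
})
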