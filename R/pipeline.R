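# End-to-end synthetic demonstration pipeline: simulate -> coexpress ->
# network -> mcode -> de -> motifs -> integrate, with a machine-readable
# run manifest. All stages are deterministic given the config seed.

pipeline_defaults <- function() list(
  seed = 42L,
  # compendium
  n_genes = 600L, n_samples = 60L,
  module_sizes = "40,40", module_r = "0.95,0.95", noise_sd = 1,
  seeds_per_module = 6L,
  # expansion
  r2_cutoff = 0.36, expand_min_neighbors = 5L, rounds = 3L,
  final_min_degree = 2L,
  # differential expression (three lines x dawn/dusk)
  mutants = "adg1,be2_be3,adg1_be2_be3",
  de_pairs = 3L, de_sigma = 0.25, de_effect = 1, de_extra = 20L,
  de_alpha = 0.05,
  # promoters / motifs
  promoter_length = 500L, promoter_gc = 0.5,
  planted_kmer = "GATAA", planted_prob = 0.77,
  kmer_k = 5L, kmer_B = 199L,
  motif_table = system.file("extdata", "known_motifs.tsv", package = "ssrnet"))

#' Read a flat key-value pipeline configuration file
#'
#' The file is flat YAML (`key: value` per line); unknown keys are an
#' error, omitted keys take the documented defaults (see
#' [run_pipeline()]).
#'
#' @param path configuration file path.
#' @return Named configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), c(names(defs), "out_dir"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  modifyList(defs, user)
}

parse_csv_num <- function(x) as.numeric(strsplit(as.character(x), ",")[[1]])
parse_csv_chr <- function(x) trimws(strsplit(as.character(x), ",")[[1]])

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage \"%s\" failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a compendium with planted co-expression modules, expands a
#' seed set into the network, summarises degree structure and MCODE
#' modules, simulates dye-swap comparisons for three mutant lines at dawn
#' and dusk (dawn up-regulation planted on the module genes), tests
#' promoter motif enrichment on the dawn-responsive subset, cross-examines
#' network membership with the DE calls, and writes all artifacts plus a
#' run manifest to `out_dir`. Byte-identical across runs with the same
#' config.
#'
#' @param config a config list (e.g. from [read_pipeline_config()]) or the
#'   path of a config file; missing keys take documented defaults.
#' @param out_dir output directory (created if needed); overrides any
#'   `out_dir` key in the config.
#' @return (Invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  cfg <- modifyList(pipeline_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, paste0(...))
  msg <- function(...) message("[ssrnet] ", sprintf(...))

  sizes <- as.integer(parse_csv_num(cfg$module_sizes))
  rs <- parse_csv_num(cfg$module_r)
  stopifnot(length(sizes) == length(rs))
  mutants <- parse_csv_chr(cfg$mutants)

  msg("simulate: compendium %d genes x %d samples, %d planted modules",
      cfg$n_genes, cfg$n_samples, length(sizes))
  sim <- pipeline_stage("simulate", {
    spec <- compendium_spec(cfg$n_genes, cfg$n_samples,
                            modules = Map(function(s, r)
                              list(size = s, latent_r = r), sizes, rs),
                            noise_sd = cfg$noise_sd, rng_seed = cfg$seed)
    gen_compendium(spec)
  })
  write_matrix_tsv(sim$values, p("compendium.tsv"))
  write.table(sim$truth, p("compendium_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  module_genes <- sim$truth$gene_id[!is.na(sim$truth$module)]
  seeds <- unlist(lapply(split(module_genes,
                               sim$truth$module[!is.na(sim$truth$module)]),
                         head, cfg$seeds_per_module), use.names = FALSE)

  msg("coexpress: %d seeds, r2 cutoff %g", length(seeds), cfg$r2_cutoff)
  exp <- pipeline_stage("coexpress", expand_seeds(
    sim$values, seeds,
    expansion_config(cfg$r2_cutoff, cfg$expand_min_neighbors, cfg$rounds,
                     cfg$final_min_degree)))
  net <- exp$network
  write_edges_tsv(net, p("network_edges.tsv"))
  write_sif(net, p("network.sif"))
  write_graphml(net, p("network.graphml"))
  write.table(exp$rounds, p("expansion_rounds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  msg("network: %d nodes, %d edges", igraph::vcount(net), igraph::ecount(net))
  degs <- pipeline_stage("network", degree_summary(net))
  sf <- pipeline_stage("network", scale_free_summary(net))
  write.table(degs$degrees, p("degree_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  mods <- pipeline_stage("mcode", mcode(net))
  msg("mcode: %d modules", length(mods))
  write.table(mcode_table(mods), p("modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  msg("de: %d lines x dawn/dusk, %d dye-swap pairs", length(mutants),
      cfg$de_pairs)
  call_sets <- pipeline_stage("de", {
    out <- list()
    for (i in seq_along(mutants)) {
      for (tp in c("dawn", "dusk")) {
        # dawn comparisons carry the planted sugar-starvation response on
        # the module genes plus a small line-private gene set; dusk is null
        de_genes <- if (tp == "dawn") {
          extra_seed <- cfg$seed + 100L * i
          extra <- with_seed(extra_seed,
            sample(setdiff(sim$truth$gene_id, module_genes), cfg$de_extra))
          c(module_genes, extra)
        } else character(0)
        tc <- gen_two_color(two_color_spec(
          cfg$n_genes, cfg$de_pairs, effect = cfg$de_effect,
          sigma = cfg$de_sigma, rng_seed = cfg$seed + 10L * i +
            (tp == "dusk"), de_genes = de_genes))
        rownames(tc$ratios) <- sim$truth$gene_id  # shared gene namespace
        tab <- de_test(tc$ratios, tc$arrays, de_config(alpha = cfg$de_alpha))
        lab <- paste(mutants[i], tp, sep = "_")
        write.table(tab, p("de_", lab, ".tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        out[[lab]] <- de_call_set(lab, mutants[i], tp, tab)
      }
    }
    out
  })

  msg("motifs: %s planted in module-gene promoters", cfg$planted_kmer)
  motif_res <- pipeline_stage("motifs", {
    n_mod <- length(module_genes)
    prom_sub <- gen_promoters(promoter_spec(
      n_mod, length = cfg$promoter_length, gc_fraction = cfg$promoter_gc,
      planted = list(list(pattern = cfg$planted_kmer,
                          insertion_prob = cfg$planted_prob)),
      rng_seed = cfg$seed + 7L))
    n_bg <- cfg$n_genes - n_mod
    prom_bg <- gen_promoters(promoter_spec(
      n_bg, length = cfg$promoter_length, gc_fraction = cfg$promoter_gc,
      rng_seed = cfg$seed + 8L))
    subset_seqs <- setNames(prom_sub$sequences, module_genes)
    bg_ids <- setdiff(sim$truth$gene_id, module_genes)
    all_seqs <- c(subset_seqs, setNames(prom_bg$sequences, bg_ids))
    all_seqs <- all_seqs[sim$truth$gene_id]
    write_promoters_fasta(all_seqs, p("promoters.fasta"))
    motifs <- read_motif_table(cfg$motif_table)
    enr <- known_motif_enrichment(subset_seqs, motifs, all_seqs)
    kmers <- kmer_overrepresentation(subset_seqs, all_seqs, k = cfg$kmer_k,
                                     B = cfg$kmer_B, rng_seed = cfg$seed + 9L)
    write.table(enr, p("motif_enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(head(kmers, 50L), p("kmer_top50.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(enrichment = enr, kmers = kmers)
  })

  msg("integrate: cross-examining network with %d call sets", length(call_sets))
  report <- pipeline_stage("integrate", cross_examine(net, degs, call_sets))
  write.table(report$per_comparison, p("overlap_per_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$venn_dawn_up)) {
    venn_df <- data.frame(region = names(report$venn_dawn_up$counts),
                          count = as.integer(report$venn_dawn_up$counts))
    write.table(venn_df, p("venn_dawn_up.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(
    list(counts = as.list(report$counts), percent = as.list(report$percent),
         structural = report$structural_table,
         scale_free_slope = if (sf$slope_defined) sf$slope else NULL),
    p("overlap_report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  artifacts <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  cfg_rec <- cfg[setdiff(names(cfg), "out_dir")]  # path-free, so manifests
  manifest <- list(                               # from identical configs match
    package = "ssrnet",
    version = as.character(packageVersion("ssrnet")),
    seed = cfg$seed,
    config = cfg_rec[order(names(cfg_rec))],
    files = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, artifacts))), artifacts)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  msg("done: %d artifacts in %s", length(artifacts) + 1L, cfg$out_dir)

  invisible(list(compendium = sim, expansion = exp, degrees = degs,
                 scale_free = sf, modules = mods, call_sets = call_sets,
                 motifs = motif_res, report = report, manifest = manifest))
}
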