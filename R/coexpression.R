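# Query-vs-genome squared correlation and recursive seed-guided expansion.

#' Squared Pearson correlation between query genes and the whole compendium
#'
#' Computes, for every (query, other-gene) pair, the squared Pearson
#' correlation of expression profiles across samples (the guided-gene edge
#' statistic). Pairs involving a zero-variance profile, or with fewer than 3
#' complete samples, are omitted and reported in the `"omitted"` attribute.
#'
#' @param values numeric genes x samples matrix with gene IDs as rownames.
#' @param queries character vector of query gene IDs; must intersect the
#'   compendium (queries absent from it raise a warning, or an error when
#'   all are absent).
#' @return Data frame `query`, `target`, `r2` (no self pairs), with
#'   attributes `omitted` (genes dropped for zero variance) and
#'   `missing_queries`.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8.5), c = c(4, 3, 2, 1))
#' colnames(m) <- paste0("s", 1:4)
#' pairwise_r2(m, "a")
#' @export
pairwise_r2 <- function(values, queries) {
  stopifnot(is.matrix(values), is.numeric(values), !is.null(rownames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in the compendium", call. = FALSE)
  if (ncol(values) < 3)
    stop("at least 3 samples are required to compute correlations", call. = FALSE)
  queries <- unique(as.character(queries))
  missing <- setdiff(queries, rownames(values))
  if (length(missing) == length(queries))
    stop("all query genes are missing from the compendium: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing)) {
    warning("dropping query genes absent from the compendium: ",
            paste(missing, collapse = ", "), call. = FALSE)
    queries <- setdiff(queries, missing)
  }

  n_ok <- rowSums(is.finite(values))
  sds <- apply(values, 1, function(x) stats::sd(x, na.rm = TRUE))
  usable <- n_ok >= 3 & is.finite(sds) & sds > 0
  omitted <- rownames(values)[!usable]
  queries_use <- queries[usable[queries]]
  if (!length(queries_use))
    stop("all query genes have zero variance or too few finite samples",
         call. = FALSE)
  targets <- rownames(values)[usable]

  use <- if (anyNA(values)) "pairwise.complete.obs" else "everything"
  r <- cor(t(values[queries_use, , drop = FALSE]),
           t(values[targets, , drop = FALSE]), use = use)
  if (anyNA(values)) {
    ok <- !is.na(values[targets, , drop = FALSE])
    okq <- !is.na(values[queries_use, , drop = FALSE])
    n_pair <- okq %*% t(ok)  # complete samples per pair
    r[n_pair < 3] <- NA
  }
  out <- data.frame(query = rep(queries_use, times = length(targets)),
                    target = rep(targets, each = length(queries_use)),
                    r2 = as.vector(r)^2, stringsAsFactors = FALSE)
  out <- out[out$query != out$target & !is.na(out$r2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  attr(out, "missing_queries") <- missing
  out
}

#' Threshold a correlation table into an undirected edge set
#'
#' @param table data frame `query`, `target`, `r2` (as from [pairwise_r2()]).
#' @param r2_cutoff significance cutoff on r-squared, strictly inside (0, 1);
#'   pairs with `r2 >= r2_cutoff` become edges.
#' @return Data frame `from`, `to`, `r2` with `from < to`, deduplicated.
#' @export
threshold_edges <- function(table, r2_cutoff) {
  stopifnot(is.data.frame(table), all(c("query", "target", "r2") %in% names(table)))
  if (!is.numeric(r2_cutoff) || length(r2_cutoff) != 1L ||
      r2_cutoff <= 0 || r2_cutoff >= 1)
    stop("`r2_cutoff` must lie strictly in (0, 1)", call. = FALSE)
  keep <- !is.na(table$r2) & table$r2 >= r2_cutoff &
    table$query != table$target
  tb <- table[keep, , drop = FALSE]
  from <- pmin(tb$query, tb$target)
  to <- pmax(tb$query, tb$target)
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(from = from[!dup], to = to[!dup], r2 = tb$r2[!dup],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Configuration of the recursive guided-gene expansion
#'
#' @param r2_cutoff r-squared cutoff defining "significantly co-expressed"
#'   (default 0.36, i.e. |r| >= 0.6); recorded in all outputs since the
#'   choice is a first-class analysis parameter.
#' @param expand_min_neighbors minimum neighbor count for a gene found in
#'   one round to become a query of the next (default 5).
#' @param rounds number of correlation rounds: the initial seed pass plus
#'   recursive passes (default 3 = initial + two more).
#' @param final_min_degree minimum degree for membership of the final
#'   network (default 2: "at least two neighbors"); enforced as the
#'   `final_min_degree`-core so that every retained node satisfies it.
#' @return An `expansion_config` list.
#' @export
expansion_config <- function(r2_cutoff = 0.36, expand_min_neighbors = 5L,
                             rounds = 3L, final_min_degree = 2L) {
  if (!is.numeric(r2_cutoff) || r2_cutoff <= 0 || r2_cutoff >= 1)
    stop("`r2_cutoff` must lie strictly in (0, 1)", call. = FALSE)
  stop_if_not_count(expand_min_neighbors, "expand_min_neighbors")
  stop_if_not_count(rounds, "rounds")
  stop_if_not_count(final_min_degree, "final_min_degree")
  structure(list(r2_cutoff = r2_cutoff,
                 expand_min_neighbors = as.integer(expand_min_neighbors),
                 rounds = as.integer(rounds),
                 final_min_degree = as.integer(final_min_degree)),
            class = "expansion_config")
}

#' Recursive seed-guided co-expression network expansion
#'
#' Round 1 uses the seed genes as queries; each round computes query-versus-
#' genome squared correlations, thresholds them into edges, and promotes
#' genes with at least `expand_min_neighbors` neighbors in that round's
#' graph into the next round's query set (queries are never dropped). After
#' the last round the accumulated edge set is restricted to its
#' `final_min_degree`-core, so every node of the final network has at least
#' that many neighbors.
#'
#' @param values numeric genes x samples expression matrix.
#' @param seeds character vector of seed gene IDs (seeds absent from the
#'   compendium are reported, not silently dropped).
#' @param cfg an [expansion_config()].
#' @return An object of class `ssr_expansion`: list with
#'   * `network`: [igraph::graph] with `r2` edge weights and the config
#'     stamped as graph attributes (empty graph, with a warning, when round
#'     1 finds nothing),
#'   * `rounds`: per-round log (`round`, `n_queries`, `n_edges`, `n_new`),
#'   * `queries_by_round`: list of query sets entering each round.
#' @export
expand_seeds <- function(values, seeds, cfg = expansion_config()) {
  stopifnot(inherits(cfg, "expansion_config"))
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("empty seed set", call. = FALSE)
  missing <- setdiff(seeds, rownames(values))
  if (length(missing) == length(seeds))
    stop("no seed gene is present in the compendium: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing))
    warning("seeds absent from the compendium: ",
            paste(missing, collapse = ", "), call. = FALSE)
  queries <- sort(intersect(seeds, rownames(values)))

  edges <- data.frame(from = character(), to = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  log <- vector("list", cfg$rounds)
  queries_by_round <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    queries_by_round[[r]] <- queries
    tbl <- pairwise_r2(values, queries)
    ed <- threshold_edges(tbl, cfg$r2_cutoff)
    edges <- rbind(edges, ed)
    key <- paste(edges$from, edges$to, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    deg <- table(c(ed$from, ed$to))
    promoted <- names(deg)[deg >= cfg$expand_min_neighbors]
    added <- setdiff(promoted, queries)
    log[[r]] <- data.frame(round = r, n_queries = length(queries),
                           n_edges = nrow(ed), n_new = length(added))
    queries <- sort(union(queries, promoted))
  }
  log <- do.call(rbind, log)

  if (!nrow(edges)) {
    warning("no edge reached the r2 cutoff in any round; returning an empty network",
            call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$weight <- edges$r2
    core <- igraph::coreness(g)
    g <- igraph::induced_subgraph(g, names(core)[core >= cfg$final_min_degree])
  }
  g <- igraph::set_graph_attr(g, "r2_cutoff", cfg$r2_cutoff)
  g <- igraph::set_graph_attr(g, "expand_min_neighbors", cfg$expand_min_neighbors)
  g <- igraph::set_graph_attr(g, "rounds", cfg$rounds)
  g <- igraph::set_graph_attr(g, "final_min_degree", cfg$final_min_degree)
  structure(list(network = g, rounds = log,
                 queries_by_round = queries_by_round, config = cfg),
            class = "ssr_expansion")
}

#' @export
print.ssr_expansion <- function(x, ...) {
  cat("Seed-guided co-expression expansion\n")
  cat(sprintf("  rounds: %d, r2 cutoff: %g, expansion threshold: %d neighbors\n",
              x$config$rounds, x$config$r2_cutoff, x$config$expand_min_neighbors))
  print(x$rounds, row.names = FALSE)
  cat(sprintf("  final network: %d nodes, %d edges (min degree %d)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$config$final_min_degree))
  invisible(x)
}
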