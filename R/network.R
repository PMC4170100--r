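# Degree structure, hub classification and scale-free summary of the
# co-expression network.

#' Build a co-expression network from an edge table
#'
#' @param edges data frame `from`, `to`, `r2`.
#' @return A simple undirected [igraph::graph] with `r2` edge weights.
#' @export
coexpression_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  g <- igraph::graph_from_data_frame(edges[edges$from != edges$to, , drop = FALSE],
                                     directed = FALSE)
  if ("r2" %in% names(edges)) igraph::E(g)$weight <- edges$r2[edges$from != edges$to]
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Degree summary with hub and structural-gene classification
#'
#' Bins node degrees into the three classes used to describe the network:
#' fewer than 10 neighbors, 10-99 neighbors, and 100 or more. Genes with
#' more than 100 neighbors are listed as hub (candidate master-regulator)
#' genes; genes with more than 25 neighbors as the structural class.
#'
#' @param net an [igraph::graph].
#' @return An `ssr_degree_summary` list: `degrees` (data frame `gene`,
#'   `degree`, sorted by descending degree then gene ID), `bins` (named
#'   counts `lt10`, `d10_99`, `ge100`), `hubs` (degree > 100),
#'   `structural` (degree > 25).
#' @export
degree_summary <- function(net) {
  if (igraph::vcount(net) == 0) {
    warning("empty network: empty degree summary", call. = FALSE)
    return(structure(list(
      degrees = data.frame(gene = character(), degree = integer()),
      bins = c(lt10 = 0L, d10_99 = 0L, ge100 = 0L),
      hubs = character(), structural = character()),
      class = "ssr_degree_summary"))
  }
  d <- igraph::degree(net)
  ord <- order(-d, names(d))
  degrees <- data.frame(gene = names(d)[ord], degree = as.integer(d[ord]),
                        stringsAsFactors = FALSE)
  bins <- c(lt10 = sum(d < 10), d10_99 = sum(d >= 10 & d < 100),
            ge100 = sum(d >= 100))
  structure(list(degrees = degrees, bins = bins,
                 hubs = degrees$gene[degrees$degree > 100],
                 structural = degrees$gene[degrees$degree > 25]),
            class = "ssr_degree_summary")
}

#' @export
print.ssr_degree_summary <- function(x, ...) {
  cat("Degree summary:", nrow(x$degrees), "nodes\n")
  cat(sprintf("  <10 neighbors: %d | 10-99: %d | >=100: %d\n",
              x$bins["lt10"], x$bins["d10_99"], x$bins["ge100"]))
  cat("  hubs (>100 neighbors):", length(x$hubs),
      "| structural (>25):", length(x$structural), "\n")
  invisible(x)
}

#' Degree distribution and descriptive log-log slope
#'
#' Summarises the degree distribution (histogram and complementary CDF) and
#' reports the least-squares slope of log(count) versus log(degree) over
#' degrees >= 1 as a descriptive indication of heavy-tailed (scale-free-like)
#' topology. No significance claim is attached; with fewer than two distinct
#' positive degrees the slope is undefined and flagged.
#'
#' @param net an [igraph::graph].
#' @return List with `histogram` (data frame `degree`, `count`, `ccdf`),
#'   `slope` (numeric or `NA`), `slope_defined` (logical).
#' @export
scale_free_summary <- function(net) {
  d <- igraph::degree(net)
  d <- d[d >= 1]
  if (!length(d))
    return(list(histogram = data.frame(degree = integer(), count = integer(),
                                       ccdf = numeric()),
                slope = NA_real_, slope_defined = FALSE))
  tab <- table(d)
  deg <- as.integer(names(tab))
  count <- as.integer(tab)
  ccdf <- rev(cumsum(rev(count))) / sum(count)
  hist <- data.frame(degree = deg, count = count, ccdf = ccdf)
  if (length(deg) < 2) {
    return(list(histogram = hist, slope = NA_real_, slope_defined = FALSE))
  }
  fit <- lm(log(count) ~ log(deg))
  list(histogram = hist, slope = unname(coef(fit)[2]), slope_defined = TRUE)
}
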