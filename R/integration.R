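# Cross-examination of network membership with differential-expression
# calls: Venn partitions, overlap report, degree-class validation.

#' Construct a differential-expression call set for one comparison
#'
#' @param label unique comparison label (e.g. `"adg1_dawn"`).
#' @param mutant genotype / line identifier.
#' @param timepoint `"dawn"` (end of the dark phase) or `"dusk"` (end of
#'   the light phase).
#' @param calls named character vector of per-gene calls in
#'   `{"up", "down", "unchanged", "excluded"}`, or a `DETable` data frame
#'   from [pooled_paired_test()]/[de_test()].
#' @return A `de_call_set` list.
#' @export
de_call_set <- function(label, mutant, timepoint, calls) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!timepoint %in% c("dawn", "dusk"))
    stop("`timepoint` must be \"dawn\" or \"dusk\"", call. = FALSE)
  if (is.data.frame(calls)) {
    stopifnot(all(c("gene_id", "call") %in% names(calls)))
    calls <- setNames(calls$call, calls$gene_id)
  }
  if (!all(calls %in% c("up", "down", "unchanged", "excluded")))
    stop("calls must be up/down/unchanged/excluded", call. = FALSE)
  if (is.null(names(calls)) || anyDuplicated(names(calls)))
    stop("`calls` must be uniquely named by gene", call. = FALSE)
  structure(list(label = label, mutant = mutant, timepoint = timepoint,
                 calls = calls), class = "de_call_set")
}

call_genes <- function(cs, direction) names(cs$calls)[cs$calls == direction]

#' Disjoint Venn partition of 2-3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors (more than 3 sets is
#'   refused: the report format is Venn-bounded).
#' @param direction_filter unused placeholder kept for call-set filtering
#'   upstream; sets are partitioned as given.
#' @return An `ssr_venn` list: `regions` (named list over all `2^n - 1`
#'   region keys such as `"A"`, `"A&B"`), `counts` (named integer), and
#'   `union_size`.
#' @export
venn_partition <- function(sets, direction_filter = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (length(sets) < 2 || length(sets) > 3)
    stop("venn_partition supports 2 or 3 sets", call. = FALSE)
  if (anyDuplicated(names(sets))) stop("set names must be unique", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  # all 2^n - 1 region keys, in subset order
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  if (!length(universe)) {
    regions <- setNames(rep(list(character(0)), length(combos)), combos)
    return(structure(list(regions = regions,
                          counts = vapply(regions, length, integer(1)),
                          union_size = 0L),
                     class = "ssr_venn"))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key_of <- function(row) paste(names(sets)[row], collapse = "&")
  keys <- apply(member, 1, key_of)
  regions <- setNames(lapply(combos, function(k) universe[keys == k]), combos)
  counts <- vapply(regions, length, integer(1))
  structure(list(regions = regions, counts = counts,
                 union_size = length(universe)),
            class = "ssr_venn")
}

#' @export
print.ssr_venn <- function(x, ...) {
  cat("Venn partition (union:", x$union_size, "genes)\n")
  for (k in names(x$counts)) cat(sprintf("  %-12s %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' Cross-examine the co-expression network with DE calls
#'
#' Intersects the network gene set with per-comparison differential
#' expression calls: per-comparison up/down counts within the network,
#' union and intersection of dawn up-regulation across mutant lines, the
#' fraction of the network up at dawn in at least one line (with integer
#' percentages rounded half away from zero), and the validation of the
#' structural property that high-degree genes respond at dawn.
#'
#' @param net an [igraph::graph] (the final network) or an `ssr_expansion`.
#' @param degrees an [degree_summary()] of `net`.
#' @param calls list of [de_call_set()]s with unique labels.
#' @return An `ssr_overlap_report` list with stored gene sets (`sets`),
#'   counts, integer percentages, per-comparison table, dawn Venn partition
#'   across mutants (when 2-3 mutant lines have dawn calls), and the
#'   structural-class DE table.
#' @export
cross_examine <- function(net, degrees, calls) {
  if (inherits(net, "ssr_expansion")) net <- net$network
  stopifnot(inherits(degrees, "ssr_degree_summary"))
  labels <- vapply(calls, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("comparison labels must be unique", call. = FALSE)
  net_genes <- igraph::V(net)$name
  universe <- unique(unlist(lapply(calls, function(cs) names(cs$calls))))
  common <- intersect(net_genes, universe)
  if (!length(common))
    stop("network and DE call gene namespaces do not intersect", call. = FALSE)
  unmatched <- setdiff(net_genes, universe)
  if (length(unmatched))
    message(length(unmatched), " network genes have no DE call")

  per_comp <- do.call(rbind, lapply(calls, function(cs) {
    data.frame(label = cs$label, mutant = cs$mutant, timepoint = cs$timepoint,
               up_in_network = length(intersect(net_genes, call_genes(cs, "up"))),
               down_in_network = length(intersect(net_genes, call_genes(cs, "down"))),
               stringsAsFactors = FALSE)
  }))

  gather <- function(tp, dir) {
    sel <- Filter(function(cs) cs$timepoint == tp, calls)
    sets <- lapply(sel, function(cs) intersect(net_genes, call_genes(cs, dir)))
    names(sets) <- vapply(sel, `[[`, character(1), "mutant")
    sets
  }
  up_dawn <- gather("dawn", "up"); down_dawn <- gather("dawn", "down")
  up_dusk <- gather("dusk", "up"); down_dusk <- gather("dusk", "down")
  any_all <- function(sets) {
    if (!length(sets)) return(list(any = character(0), all = character(0)))
    list(any = sort(unique(unlist(sets))), all = sort(Reduce(intersect, sets)))
  }
  ud <- any_all(up_dawn); dd <- any_all(down_dawn)
  uk <- any_all(up_dusk); dk <- any_all(down_dusk)
  de_any <- sort(unique(c(ud$any, dd$any, uk$any, dk$any)))
  stable <- sort(setdiff(net_genes, de_any))

  n_net <- length(net_genes)
  counts <- c(network_size = n_net,
              up_dawn_any = length(ud$any), up_dawn_all = length(ud$all),
              down_dawn_any = length(dd$any), down_dawn_all = length(dd$all),
              up_dusk_any = length(uk$any), down_dusk_any = length(dk$any),
              stable = length(stable))
  pct <- c(up_dawn_any = percent_round(length(ud$any), n_net),
           down_dawn_any = percent_round(length(dd$any), n_net),
           stable = percent_round(length(stable), n_net))

  venn_dawn <- if (length(up_dawn) >= 2 && length(up_dawn) <= 3)
    venn_partition(up_dawn) else NULL

  structural <- degrees$structural
  struct_up <- intersect(structural, ud$any)
  structural_table <- data.frame(
    class = "degree>25", n = length(structural),
    up_dawn_any = length(struct_up),
    fraction_up_dawn = if (length(structural))
      length(struct_up) / length(structural) else NA_real_)

  structure(list(per_comparison = per_comp, counts = counts, percent = pct,
                 venn_dawn_up = venn_dawn,
                 structural_table = structural_table,
                 sets = list(up_dawn = up_dawn, down_dawn = down_dawn,
                             up_dusk = up_dusk, down_dusk = down_dusk,
                             up_dawn_any = ud$any, up_dawn_all = ud$all,
                             down_dawn_any = dd$any, stable = stable),
                 unmatched = unmatched),
            class = "ssr_overlap_report")
}

#' @export
print.ssr_overlap_report <- function(x, ...) {
  cat("Network / DE cross-examination\n")
  cat(sprintf("  network: %d genes\n", x$counts["network_size"]))
  cat(sprintf("  up at dawn in >=1 line: %d (%d%%); in all lines: %d\n",
              x$counts["up_dawn_any"], x$percent["up_dawn_any"],
              x$counts["up_dawn_all"]))
  cat(sprintf("  down at dawn in >=1 line: %d; stable: %d (%d%%)\n",
              x$counts["down_dawn_any"], x$counts["stable"],
              x$percent["stable"]))
  st <- x$structural_table
  cat(sprintf("  structural genes (>25 neighbors): %d, up at dawn: %d (%.0f%%)\n",
              st$n, st$up_dawn_any, 100 * st$fraction_up_dawn))
  invisible(x)
}
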