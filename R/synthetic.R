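# Seeded generators for synthetic compendia, dye-swap ratio tables and
# promoter sets with planted, fully recorded ground truth.

#' Specification for a synthetic expression compendium
#'
#' Describes a genes x samples compendium containing latent co-expressed
#' modules embedded in independent noise genes. Module genes are built as
#' `latent_r * shared_profile + sqrt(1 - latent_r^2) * noise`, so with unit
#' `noise_sd` the expected pairwise Pearson correlation inside a module is
#' `latent_r^2` (and the r-squared edge statistic `latent_r^4`).
#'
#' @param n_genes number of genes (rows).
#' @param n_samples number of samples (columns); at least 3.
#' @param modules list of planted modules, each `list(size =, latent_r =)`
#'   with `latent_r` in `[0, 1]`; module sizes must sum to at most `n_genes`.
#' @param noise_sd standard deviation of the independent noise component.
#' @param rng_seed integer seed; identical specs give byte-identical output.
#' @return A `compendium_spec` list.
#' @export
compendium_spec <- function(n_genes, n_samples, modules = list(),
                            noise_sd = 1, rng_seed = 1L) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_samples, "n_samples", min = 3L)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  mods <- do.call(rbind, lapply(modules, function(m) {
    stop_if_not_count(m$size, "module size", min = 2L)
    if (!is.numeric(m$latent_r) || m$latent_r < 0 || m$latent_r > 1)
      stop("module `latent_r` must lie in [0, 1]", call. = FALSE)
    data.frame(size = as.integer(m$size), latent_r = m$latent_r)
  }))
  if (is.null(mods)) mods <- data.frame(size = integer(), latent_r = numeric())
  if (sum(mods$size) > n_genes)
    stop("module sizes exceed `n_genes`", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 modules = mods, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "compendium_spec")
}

#' Generate a synthetic expression compendium with planted modules
#'
#' @param spec a [compendium_spec()].
#' @return A list with
#'   * `values`: numeric genes x samples matrix (gene IDs as rownames),
#'   * `truth`: data frame `gene_id`, `module` (`"M1"`, ... or `NA` for
#'     noise genes).
#' @examples
#' spec <- compendium_spec(100, 20,
#'   modules = list(list(size = 10, latent_r = 0.95)), rng_seed = 7)
#' sim <- gen_compendium(spec)
#' cor(sim$values[1, ], sim$values[2, ])^2  # high within the module
#' @export
gen_compendium <- function(spec) {
  stopifnot(inherits(spec, "compendium_spec"))
  with_seed(spec$rng_seed, {
    G <- spec$n_genes; S <- spec$n_samples
    gene_ids <- sprintf("G%05d", seq_len(G))
    sample_ids <- sprintf("S%03d", seq_len(S))
    values <- matrix(rnorm(G * S, sd = max(spec$noise_sd, .Machine$double.eps)),
                     nrow = G, ncol = S,
                     dimnames = list(gene_ids, sample_ids))
    if (spec$noise_sd == 0) values[] <- 0
    module <- rep(NA_character_, G)
    offset <- 0L
    for (m in seq_len(nrow(spec$modules))) {
      sz <- spec$modules$size[m]
      r <- spec$modules$latent_r[m]
      idx <- offset + seq_len(sz)
      offset <- offset + sz
      shared <- rnorm(S)
      eps <- matrix(rnorm(sz * S, sd = spec$noise_sd), nrow = sz)
      values[idx, ] <- r * matrix(shared, nrow = sz, ncol = S, byrow = TRUE) +
        sqrt(1 - r^2) * eps
      module[idx] <- sprintf("M%d", m)
    }
    list(values = values,
         truth = data.frame(gene_id = gene_ids, module = module,
                            stringsAsFactors = FALSE))
  })
}

#' Specification for dye-swap two-color log-ratio arrays
#'
#' Each biological replicate contributes a forward and a dye-swapped array;
#' a truly regulated gene has mean log2-ratio `+effect` on forward arrays
#' and `-effect` on swapped arrays, everything plus i.i.d. normal noise.
#' The number of regulated genes is assigned exactly as
#' `round(n_genes * de_fraction)`.
#'
#' @param n_genes number of genes.
#' @param n_pairs number of dye-swap array pairs (>= 2).
#' @param de_fraction proportion of differentially expressed genes in `[0, 1]`.
#' @param effect mean log2-ratio shift of DE genes.
#' @param sigma common log-ratio standard deviation (> 0).
#' @param rng_seed integer seed.
#' @param de_genes optional explicit character vector of gene IDs to make DE
#'   (overrides `de_fraction`); used to plant DE on known genes in fixtures.
#' @return A `two_color_spec` list.
#' @export
two_color_spec <- function(n_genes, n_pairs, de_fraction = 0, effect = 0,
                           sigma = 1, rng_seed = 1L, de_genes = NULL) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_pairs, "n_pairs", min = 2L)
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stop("`de_fraction` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
                 de_fraction = de_fraction, effect = effect, sigma = sigma,
                 rng_seed = as.integer(rng_seed), de_genes = de_genes),
            class = "two_color_spec")
}

#' Generate synthetic dye-swap log-ratio arrays with known DE genes
#'
#' @param spec a [two_color_spec()].
#' @return A list with
#'   * `ratios`: genes x arrays log2-ratio matrix (forward and swapped
#'     columns interleaved per pair),
#'   * `arrays`: data frame `array_id`, `replicate_id`, `orientation`
#'     (`"forward"`/`"swapped"`),
#'   * `truth`: data frame `gene_id`, `is_de`, `effect`.
#' @export
gen_two_color <- function(spec) {
  stopifnot(inherits(spec, "two_color_spec"))
  with_seed(spec$rng_seed, {
    G <- spec$n_genes; P <- spec$n_pairs
    gene_ids <- sprintf("G%05d", seq_len(G))
    if (!is.null(spec$de_genes)) {
      bad <- setdiff(spec$de_genes, gene_ids)
      if (length(bad))
        stop("unknown `de_genes`: ", paste(head(bad, 5), collapse = ", "),
             call. = FALSE)
      is_de <- gene_ids %in% spec$de_genes
    } else {
      n_de <- round(G * spec$de_fraction)
      is_de <- rep(FALSE, G)
      if (n_de > 0) is_de[sample.int(G, n_de)] <- TRUE
    }
    if (spec$effect == 0) is_de[] <- FALSE  # a zero shift is not DE
    eff <- ifelse(is_de, spec$effect, 0)
    ratios <- matrix(NA_real_, nrow = G, ncol = 2L * P)
    array_id <- character(2L * P)
    orientation <- character(2L * P)
    replicate_id <- character(2L * P)
    for (p in seq_len(P)) {
      fwd <- 2L * p - 1L; swp <- 2L * p
      ratios[, fwd] <- eff + rnorm(G, sd = spec$sigma)
      ratios[, swp] <- -eff + rnorm(G, sd = spec$sigma)
      array_id[c(fwd, swp)] <- sprintf("A%02d_%s", p, c("F", "S"))
      orientation[c(fwd, swp)] <- c("forward", "swapped")
      replicate_id[c(fwd, swp)] <- sprintf("R%02d", p)
    }
    dimnames(ratios) <- list(gene_ids, array_id)
    list(ratios = ratios,
         arrays = data.frame(array_id = array_id, replicate_id = replicate_id,
                             orientation = orientation, stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene_ids, is_de = is_de, effect = eff,
                            stringsAsFactors = FALSE))
  })
}

# IUPAC nucleotide degeneracy map (from Biostrings), e.g. K -> "GT".
iupac_choices <- function(ch) {
  map <- Biostrings::IUPAC_CODE_MAP
  out <- map[ch]
  if (anyNA(out))
    stop("invalid IUPAC characters: ",
         paste(unique(ch[is.na(out)]), collapse = ", "), call. = FALSE)
  strsplit(out, "", fixed = TRUE)
}

#' Expand an IUPAC pattern into all concrete DNA instances
#'
#' @param pattern IUPAC pattern string (e.g. `"ACGTGKC"`).
#' @param max_instances safety cap on the expansion size.
#' @return Character vector of concrete ACGT strings.
#' @export
iupac_expand <- function(pattern, max_instances = 4096L) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  choices <- iupac_choices(chars)
  n <- prod(lengths(choices))
  if (n > max_instances)
    stop("IUPAC pattern expands to ", n, " instances (cap ", max_instances, ")",
         call. = FALSE)
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(choices)), drop = FALSE], 1, paste0,
             collapse = ""))
}

#' Specification for synthetic promoter sets with planted motifs
#'
#' Background bases are i.i.d. with the stated GC fraction; each planted
#' IUPAC pattern is inserted into each promoter with its own probability at
#' a uniformly drawn, non-overlapping position, with degenerate positions
#' resolved uniformly at insertion time. Every insertion is recorded.
#'
#' @param n_promoters number of promoters.
#' @param length promoter length in bases (default 1000, the span upstream
#'   of the transcriptional start site used for motif analysis).
#' @param gc_fraction background GC proportion.
#' @param planted list of `list(pattern =, insertion_prob =)`.
#' @param rng_seed integer seed.
#' @return A `promoter_spec` list.
#' @export
promoter_spec <- function(n_promoters, length = 1000L, gc_fraction = 0.5,
                          planted = list(), rng_seed = 1L) {
  stop_if_not_count(n_promoters, "n_promoters")
  stop_if_not_count(length, "length")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  for (p in planted) {
    if (!is.character(p$pattern) || nchar(p$pattern) < 1)
      stop("planted `pattern` must be a non-empty string", call. = FALSE)
    if (nchar(p$pattern) > length)
      stop("planted pattern longer than the promoter", call. = FALSE)
    if (!is.numeric(p$insertion_prob) || p$insertion_prob < 0 || p$insertion_prob > 1)
      stop("`insertion_prob` must lie in [0, 1]", call. = FALSE)
    iupac_choices(strsplit(toupper(p$pattern), "")[[1]])  # validate
  }
  structure(list(n_promoters = as.integer(n_promoters), length = as.integer(length),
                 gc_fraction = gc_fraction, planted = planted,
                 rng_seed = as.integer(rng_seed)),
            class = "promoter_spec")
}

#' Generate synthetic promoters with planted motif instances
#'
#' @param spec a [promoter_spec()].
#' @return A list with
#'   * `sequences`: named character vector of ACGT sequences,
#'   * `truth`: data frame `gene_id`, `pattern`, `instance`, `start`
#'     recording every insertion.
#' @export
gen_promoters <- function(spec) {
  stopifnot(inherits(spec, "promoter_spec"))
  with_seed(spec$rng_seed, {
    N <- spec$n_promoters; L <- spec$length
    ids <- sprintf("P%04d", seq_len(N))
    gc <- spec$gc_fraction
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(N), function(i)
      paste0(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
             collapse = ""),
      character(1))
    names(seqs) <- ids
    truth <- list()
    for (i in seq_len(N)) {
      occupied <- integer(0)
      for (p in spec$planted) {
        if (runif(1) >= p$insertion_prob) next
        chars <- iupac_choices(strsplit(toupper(p$pattern), "")[[1]])
        inst <- paste0(vapply(chars, function(ch)
          ch[[sample.int(length(ch), 1L)]], character(1)), collapse = "")
        w <- nchar(inst)
        for (try in 1:100) {
          pos <- sample.int(L - w + 1L, 1L)
          span <- pos:(pos + w - 1L)
          if (!length(intersect(span, occupied))) {
            substr(seqs[i], pos, pos + w - 1L) <- inst
            occupied <- c(occupied, span)
            truth[[length(truth) + 1L]] <-
              data.frame(gene_id = ids[i], pattern = p$pattern,
                         instance = inst, start = pos, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), pattern = character(),
                 instance = character(), start = integer(),
                 stringsAsFactors = FALSE)
    list(sequences = seqs, truth = truth)
  })
}
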