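# Promoter motif over-representation: Boyer-Moore exact counting,
# known-motif enrichment with exact binomial / hypergeometric tails, and
# exhaustive k-mer over-representation against an empirical genome-sampled
# null.

# strong good-suffix shift table; p is the pattern as an integer vector.
# shift[k + 1] is the shift after a mismatch at 0-based pattern position k;
# shift[1] (full match) equals the pattern period, so overlapping
# occurrences are all visited.
bm_good_suffix <- function(p) {
  m <- length(p)
  shift <- integer(m + 1L)
  bpos <- integer(m + 2L)
  i <- m; j <- m + 1L
  bpos[i + 1L] <- j
  while (i > 0L) {
    while (j <= m && p[i] != p[j]) {
      if (shift[j + 1L] == 0L) shift[j + 1L] <- j - i
      j <- bpos[j + 1L]
    }
    i <- i - 1L; j <- j - 1L
    bpos[i + 1L] <- j
  }
  j <- bpos[1L]
  for (i in 0L:m) {
    if (shift[i + 1L] == 0L) shift[i + 1L] <- j
    if (i == j) j <- bpos[i + 1L]
  }
  shift
}

#' Count overlapping occurrences of a pattern with Boyer-Moore search
#'
#' Exact counting of a concrete (non-degenerate) pattern in a sequence
#' using Boyer-Moore search with both the bad-character and the strong
#' good-suffix rule. Occurrences are counted with overlap (the full-match
#' shift is the pattern period). Degenerate IUPAC patterns must be expanded
#' to concrete instances first (see [iupac_expand()]).
#'
#' @param sequence subject string.
#' @param pattern concrete pattern string; a pattern longer than the
#'   sequence yields 0.
#' @return Integer occurrence count.
#' @examples
#' boyer_moore_count("AAAAAA", "AAAA")    # 3, overlapping
#' boyer_moore_count("CCGATAACC", "GATAA")  # 1
#' @export
boyer_moore_count <- function(sequence, pattern) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(pattern), length(pattern) == 1L)
  m <- nchar(pattern); n <- nchar(sequence)
  if (m == 0L) stop("empty pattern", call. = FALSE)
  if (m > n) return(0L)
  p <- utf8ToInt(pattern)
  s <- utf8ToInt(sequence)
  bad <- integer(max(c(p, s)) + 1L)          # rightmost occurrence, 0 if absent
  bad[p] <- seq_len(m)
  gs <- bm_good_suffix(p)
  count <- 0L
  i <- 0L
  limit <- n - m
  while (i <= limit) {
    j <- m
    while (j >= 1L && p[j] == s[i + j]) j <- j - 1L
    if (j == 0L) {
      count <- count + 1L
      i <- i + gs[1L]
    } else {
      ch <- s[i + j]
      bc <- j - if (ch <= length(bad)) bad[ch] else 0L
      i <- i + max(gs[j + 1L], bc, 1L)
    }
  }
  count
}

#' Count motif occurrences and containment across a promoter set
#'
#' Expands an IUPAC pattern into concrete instances and counts, per
#' promoter, the total number of (overlapping) occurrences by Boyer-Moore
#' search; optionally also on the reverse complement strand.
#'
#' @param sequences named character vector of promoter sequences.
#' @param pattern IUPAC pattern.
#' @param reverse_complement also match the reverse-complement instances
#'   (default `FALSE`: promoter FASTA is assumed TSS-oriented).
#' @return Data frame `gene_id`, `count`, `contains`.
#' @export
count_motif <- function(sequences, pattern, reverse_complement = FALSE) {
  instances <- iupac_expand(pattern)
  if (reverse_complement) {
    rc <- vapply(instances, function(x)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
      character(1))
    instances <- unique(c(instances, rc))
  }
  counts <- vapply(sequences, function(s)
    sum(vapply(instances, function(p) boyer_moore_count(s, p), integer(1))),
    numeric(1))
  data.frame(gene_id = names(sequences), count = as.integer(counts),
             contains = counts > 0, stringsAsFactors = FALSE, row.names = NULL)
}

#' Known-motif over-representation in a promoter subset
#'
#' For each motif, counts the subset promoters containing at least one
#' match (the containment statistic behind "percent of promoters" tables)
#' and computes an upper-tail enrichment p-value: exact hypergeometric when
#' the background is a full promoter set, exact binomial when it is a
#' per-motif containment frequency. Normal approximations are deliberately
#' avoided since the interesting p-values are extreme tails.
#'
#' @param subset named character vector of subset promoter sequences.
#' @param motifs data frame with columns `name`, `pattern` (IUPAC).
#' @param background either a named character vector of background
#'   promoter sequences (the promoterome; hypergeometric test) or a numeric
#'   vector of per-motif containment frequencies in `[0, 1]` (recycled;
#'   binomial test).
#' @param threshold significance threshold on the p-value (default `1e-3`).
#' @param reverse_complement passed to [count_motif()].
#' @param statistic `"containment"` (default; promoters with >= 1 hit) or
#'   `"total"` (total occurrence counts over the subset, tested against a
#'   Poisson upper tail with the per-promoter rate estimated from the
#'   background promoter set; requires a sequence background).
#' @return Data frame `name`, `pattern`, `subset_hits`, `subset_size`,
#'   `background_freq`, `p_value`, `method`, `significant`.
#' @export
known_motif_enrichment <- function(subset, motifs, background,
                                   threshold = 1e-3,
                                   reverse_complement = FALSE,
                                   statistic = c("containment", "total")) {
  statistic <- match.arg(statistic)
  if (!length(subset)) stop("empty promoter subset", call. = FALSE)
  stopifnot(is.data.frame(motifs), all(c("name", "pattern") %in% names(motifs)))
  n <- length(subset)
  freq_mode <- is.numeric(background)
  if (freq_mode) {
    bg_freq <- rep_len(background, nrow(motifs))
    if (any(bg_freq < 0 | bg_freq > 1))
      stop("background frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (statistic == "total" && freq_mode)
    stop("`statistic = \"total\"` needs a background promoter set", call. = FALSE)
  res <- lapply(seq_len(nrow(motifs)), function(i) {
    cm <- count_motif(subset, motifs$pattern[i], reverse_complement)
    if (statistic == "total") {
      hits <- sum(cm$count)
      bg <- count_motif(background, motifs$pattern[i], reverse_complement)
      lambda <- n * mean(bg$count)
      p <- stats::ppois(hits - 1L, lambda, lower.tail = FALSE)
      return(data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
                        subset_hits = hits, subset_size = n,
                        background_freq = mean(bg$count), p_value = p,
                        method = "poisson_total", stringsAsFactors = FALSE))
    }
    hits <- sum(cm$contains)
    if (freq_mode) {
      p <- pbinom(hits - 1L, n, bg_freq[i], lower.tail = FALSE)
      data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
                 subset_hits = hits, subset_size = n,
                 background_freq = bg_freq[i], p_value = p,
                 method = "binomial", stringsAsFactors = FALSE)
    } else {
      bg <- count_motif(background, motifs$pattern[i], reverse_complement)
      K <- sum(bg$contains)
      N <- length(background)
      p <- phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
      data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
                 subset_hits = hits, subset_size = n,
                 background_freq = K / N, p_value = p,
                 method = "hypergeometric", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < threshold
  attr(out, "threshold") <- threshold
  out
}

# which k-mers (pure ACGT windows) each sequence contains; returns a
# logical sequences x kmers matrix over `kmers`
kmer_containment <- function(sequences, k, kmers) {
  M <- matrix(FALSE, nrow = length(sequences), ncol = length(kmers),
              dimnames = list(names(sequences), kmers))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    L <- nchar(s)
    if (L < k) next
    win <- substring(s, seq_len(L - k + 1L), k:L)
    win <- unique(win[grepl("^[ACGT]+$", win)])
    M[i, match(intersect(win, kmers), kmers)] <- TRUE
  }
  M
}

# all pure-ACGT k-mers observed in at least one sequence
observed_kmers <- function(sequences, k) {
  out <- unique(unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    win <- substring(s, seq_len(L - k + 1L), k:L)
    unique(win[grepl("^[ACGT]+$", win)])
  })))
  sort(out)
}

#' Exhaustive k-mer over-representation against a genome-sampled null
#'
#' For every k-mer occurring in at least one subset promoter, compares the
#' number of subset promoters containing it (the containment count) with
#' the same statistic on `B` random promoter sets of the same size sampled
#' without replacement from the genome promoter set. The empirical p-value
#' is `(1 + #\{null >= observed\}) / (B + 1)`, hence never below
#' `1 / (B + 1)`.
#'
#' The k-mer tabulation itself uses a single left-to-right window pass:
#' when every window of a sequence is counted, one scan enumerates all
#' k-mer occurrences at once, so a per-pattern search would do redundant
#' work; [boyer_moore_count()] remains the single-pattern counter used for
#' targeted motifs.
#'
#' @param subset named character vector of subset promoter sequences.
#' @param genome named character vector of genome (background) promoter
#'   sequences; must be larger than the subset.
#' @param k word length (>= 4).
#' @param B number of null promoter sets (>= 99; smaller nulls are refused
#'   because the p-value floor `1/(B+1)` would be too coarse).
#' @param rng_seed integer seed for the null sampling.
#' @return Data frame `kmer`, `observed`, `null_mean`, `p_value`, sorted by
#'   ascending p then k-mer.
#' @export
kmer_overrepresentation <- function(subset, genome, k, B = 1000L,
                                    rng_seed = 1L) {
  stop_if_not_count(k, "k", min = 4L)
  if (!is_count(B, min = 99L))
    stop("`B` must be at least 99 (empirical p resolution)", call. = FALSE)
  if (length(genome) <= length(subset))
    stop("the genome promoter set must be larger than the subset", call. = FALSE)
  kmers <- observed_kmers(subset, k)
  if (!length(kmers))
    return(data.frame(kmer = character(), observed = integer(),
                      null_mean = numeric(), p_value = numeric()))
  sub_M <- kmer_containment(subset, k, kmers)
  gen_M <- kmer_containment(genome, k, kmers)
  observed <- colSums(sub_M)
  ns <- length(subset); ng <- length(genome)
  with_seed(rng_seed, {
    ge_obs <- numeric(length(kmers))
    null_sum <- numeric(length(kmers))
    mode(gen_M) <- "numeric"
    for (b in seq_len(B)) {
      idx <- sample.int(ng, ns)
      stat <- colSums(gen_M[idx, , drop = FALSE])
      ge_obs <- ge_obs + (stat >= observed)
      null_sum <- null_sum + stat
    }
    p <- (1 + ge_obs) / (B + 1)
    out <- data.frame(kmer = kmers, observed = as.integer(observed),
                      null_mean = null_sum / B, p_value = p,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$p_value, out$kmer), , drop = FALSE]
  })
}
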