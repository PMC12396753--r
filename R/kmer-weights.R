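#' Extract k-mers around R-loop initiation and termination sites
#'
#' For every footprint \[i, j\] a sliding window of width `k` is shifted `p`
#' times around the initiation and termination boundaries, giving four k-mer
#' collections (multisets):
#' \describe{
#'   \item{r1}{windows ending at `i - 1`, shifted left: starts `i - k - t`,
#'     `t = 0..p` (just upstream of initiation);}
#'   \item{r2}{windows starting at `i`, shifted right: starts `i + t` (the
#'     R-loop's first blocks);}
#'   \item{r3}{windows ending at `j`, shifted left: starts `j - k + 1 - t`
#'     (the R-loop's last blocks);}
#'   \item{r4}{windows starting at `j + 1`, shifted right: starts
#'     `j + 1 + t` (just downstream of termination).}
#' }
#' Windows not fully inside the gene region are discarded; multiplicities are
#' retained (the same k-mer harvested twice counts twice).
#'
#' @param ds Preprocessed record tibble.
#' @param plasmid A [plasmid_sequence()].
#' @param k K-mer size.
#' @param p Padding: number of extra window shifts (region width `k + p`).
#' @return A tibble with columns `region` (`"r1".."r4"`), `start` (window
#'   start) and `kmer`, one row per harvested window.
#' @export
extract_region_kmers <- function(ds, plasmid, k, p) {
  stopifnot(k >= 1, p >= 0)
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  t <- rep(0:p, times = nrow(ds))
  i <- rep(ds$start, each = p + 1L)
  j <- rep(ds$end, each = p + 1L)
  win <- tibble(
    region = rep(c("r1", "r2", "r3", "r4"), each = length(t)),
    start = c(i - k - t, i + t, j - k + 1L - t, j + 1L + t)
  )
  win <- win[win$start >= b & win$start + k - 1L <= e, , drop = FALSE]
  win$kmer <- substring(plasmid$seq, win$start, win$start + k - 1L)
  as_tibble(win)
}

#' Entropy-based threshold for a ranked weight list
#'
#' Weights are rescaled by the top weight, `w' = w / w_1`; each rank gets the
#' entropy `H = -w' * log10(w')` and the running average
#' `h_n = mean(H_1..H_n)`. The cutoff rank is the (first) global maximum of
#' the running average: beyond it, adding a rank no longer adds significant
#' information (`(n - 1) h_n <= h_1 + ... + h_{n-1}`).
#'
#' @param weights Numeric vector of per-rank weights in decreasing order (one
#'   entry per tied weight group, not per k-mer).
#' @return A tibble with columns `rank`, `weight`, `w_prime`, `H`, `h` and a
#'   logical `highly_weighted` (rank <= cutoff); the cutoff rank is stored in
#'   attribute `"cutoff_rank"`.
#' @examples
#' entropy_threshold(c(0.03571, 0.03214, 0.02976))
#' @export
entropy_threshold <- function(weights) {
  stopifnot(length(weights) >= 1L, all(weights > 0),
            !is.unsorted(rev(weights)))
  w_prime <- weights / weights[[1]]
  H <- -w_prime * log10(w_prime)
  H[H == 0] <- 0   # normalise -0 from w' = 1
  h <- cumsum(H) / seq_along(H)
  cutoff <- which.max(h)   # first index attaining the global maximum
  out <- tibble(
    rank = seq_along(weights), weight = weights,
    w_prime = w_prime, H = H, h = h,
    highly_weighted = seq_along(weights) <= cutoff
  )
  attr(out, "cutoff_rank") <- cutoff
  out
}

#' Weight and rank the k-mers of each region
#'
#' Each distinct k-mer `s` observed in region `r_i` receives the weight
#' `w_i(s) = n_i(s) / (N * m_s)`, where `n_i(s)` counts occurrences of `s`
#' across all R-loops' `r_i` windows (with multiplicity), `N` is the number
#' of R-loops in the training set and `m_s` the number of (overlapping)
#' occurrences of `s` in the gene region. K-mers with exactly equal weight
#' share a rank; equality is decided on the reduced fraction `n/m` so
#' floating-point noise cannot split a tied group. The entropy threshold of
#' [entropy_threshold()] marks each region's highly weighted list.
#'
#' @param kmers Region k-mer tibble from [extract_region_kmers()].
#' @param plasmid A [plasmid_sequence()].
#' @param n_rloops Number of R-loops `N` in the training set.
#' @param k K-mer size (inferred from the k-mers when omitted).
#' @return A tibble with one row per (region, k-mer): columns `region`,
#'   `rank`, `kmer`, `n`, `m`, `weight`, `w_prime`, `H`, `h`,
#'   `highly_weighted`. Attributes `k` and `n_rloops` record provenance.
#' @export
kmer_weight_table <- function(kmers, plasmid, n_rloops, k = NULL) {
  stopifnot(n_rloops > 0)
  k <- k %||% nchar(kmers$kmer[[1]])
  m_all <- gene_kmer_counts(plasmid, k)
  tab <- kmers |>
    dplyr::count(.data$region, .data$kmer, name = "n") |>
    mutate(m = as.integer(m_all[.data$kmer]))
  if (any(tab$m == 0L)) {
    stop("k-mer observed in a region but absent from the gene region; ",
         "records and plasmid are inconsistent", call. = FALSE)
  }
  out <- tab |>
    mutate(weight = .data$n / (n_rloops * .data$m)) |>
    group_by(.data$region) |>
    dplyr::group_modify(~ rank_and_threshold(.x)) |>
    ungroup()
  attr(out, "k") <- k
  attr(out, "n_rloops") <- n_rloops
  out
}

# Rank one region's weight rows, grouping exact rational ties, and join the
# entropy-threshold columns (one H/h value per rank group, Table-style).
rank_and_threshold <- function(rows) {
  g <- mapply(gcd_int, rows$n, rows$m)
  key <- paste0(rows$n %/% g, "/", rows$m %/% g)
  ord <- order(-rows$weight, rows$kmer)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- match(key[ord], unique(key[ord]))
  groups <- rows |>
    group_by(.data$rank) |>
    summarise(weight = .data$weight[[1]], .groups = "drop")
  ent <- entropy_threshold(groups$weight)
  dplyr::left_join(rows, ent[, c("rank", "w_prime", "H", "h",
                                 "highly_weighted")], by = "rank")
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}
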