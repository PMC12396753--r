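#' Assign a grammar symbol to every k-mer (the dictionary)
#'
#' Builds the total symbol-assignment map `C(l, s)`: every k-mer over
#' \{A,C,G,T\} gets one *outside* symbol (used when the block lies outside an
#' R-loop) and one *inside* symbol (used within). Let `w*_i(s)` be the weight
#' of `s` in region `r_i` if `s` is in that region's highly weighted list and
#' 0 otherwise, and `w*(s)` their maximum. Then:
#' \itemize{
#'   \item `w*(s) = 0`: no information — `gamma` outside, `rho` inside;
#'   \item maximum attained both in a start region (r1/r2) and an end region
#'     (r3/r4): ambiguous — `delta` outside, `beta` inside;
#'   \item maximum from r1/r2 only: start-associated — `sigma` outside,
#'     `tau_hat` inside (stable hybrid, unstable duplex);
#'   \item maximum from r3/r4 only: end-associated — `sigma_hat` outside,
#'     `tau` inside (stable duplex, unstable hybrid).
#' }
#' Within one training set all four region weights of a k-mer share the
#' denominator `N * m_s`, so maxima and exact ties are decided on the integer
#' counts `n_i(s)`.
#'
#' @param weights Weight table from [kmer_weight_table()].
#' @param p Padding used when harvesting the k-mers (stored as provenance).
#' @param source Provenance label (e.g. the plasmid name).
#' @return A `rloop_dictionary`: tibble with columns `kmer`, `outside`,
#'   `inside`, total over all `4^k` k-mers; attributes `k`, `p`, `mode`,
#'   `seed`, `source`.
#' @export
assign_symbols <- function(weights, p, source = "training") {
  k <- attr(weights, "k")
  hi <- weights[weights$highly_weighted, c("region", "kmer", "n")]
  side <- hi |>
    mutate(side = ifelse(.data$region %in% c("r1", "r2"), "start_n", "end_n")) |>
    group_by(.data$kmer, .data$side) |>
    summarise(n = max(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "n",
                       values_fill = 0L)
  for (col in c("start_n", "end_n")) {
    if (!col %in% names(side)) side[[col]] <- integer(nrow(side))
  }
  all_kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  dict <- tibble(kmer = all_kmers) |>
    left_join(side, by = "kmer") |>
    mutate(
      start_n = dplyr::coalesce(.data$start_n, 0L),
      end_n = dplyr::coalesce(.data$end_n, 0L),
      outside = dplyr::case_when(
        start_n == 0L & end_n == 0L ~ "gamma",
        start_n == end_n ~ "delta",
        start_n > end_n ~ "sigma",
        TRUE ~ "sigma_hat"
      ),
      inside = dplyr::case_when(
        outside == "gamma" ~ "rho",
        outside == "delta" ~ "beta",
        outside == "sigma" ~ "tau_hat",
        TRUE ~ "tau"
      )
    ) |>
    select("kmer", "outside", "inside")
  new_dictionary(dict, k = k, p = p, mode = "single", seed = NA_integer_,
                 source = source)
}

new_dictionary <- function(dict, k, p, mode, seed, source) {
  structure(as_tibble(dict), k = k, p = p, mode = mode, seed = seed,
            source = source,
            class = c("rloop_dictionary", class(as_tibble(dict))))
}

#' Build a symbol dictionary from a training set
#'
#' Convenience pipeline: harvest region k-mers, weight and rank them, apply
#' the entropy threshold, and assign symbols.
#'
#' @param ds Preprocessed record tibble (one plasmid).
#' @param plasmid A [plasmid_sequence()].
#' @param k,p K-mer size and padding.
#' @return A `rloop_dictionary` (see [assign_symbols()]).
#' @export
build_symbol_dictionary <- function(ds, plasmid, k, p) {
  kmers <- extract_region_kmers(ds, plasmid, k, p)
  w <- kmer_weight_table(kmers, plasmid, n_rloops = nrow(ds), k = k)
  assign_symbols(w, p = p, source = plasmid$name)
}

#' Merge two plasmids' dictionaries into a union dictionary
#'
#' Agreeing entries are copied. Conflicts are resolved per (k-mer, context):
#' \describe{
#'   \item{deterministic}{an indeterminate symbol (`gamma`/`rho`) loses to a
#'     determinate one; any other disagreement becomes the ambiguity symbol
#'     of its context (`delta` outside, `beta` inside);}
#'   \item{stochastic}{one side's symbol is chosen uniformly at random,
#'     independently per entry, reproducibly under `seed`.}
#' }
#'
#' @param d1,d2 Dictionaries built with identical `(k, p)`.
#' @param mode Conflict-resolution mode.
#' @param seed Integer seed (required for `mode = "stochastic"`).
#' @return A union `rloop_dictionary`.
#' @export
merge_dictionaries <- function(d1, d2, mode = c("deterministic", "stochastic"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (!identical(attr(d1, "k"), attr(d2, "k")) ||
      !identical(attr(d1, "p"), attr(d2, "p"))) {
    stop("dictionaries were built with different (k, p)", call. = FALSE)
  }
  stopifnot(identical(d1$kmer, d2$kmer))
  out <- tibble(kmer = d1$kmer)
  if (mode == "stochastic") {
    if (is.null(seed)) stop("stochastic merge needs a seed", call. = FALSE)
    pick <- withr::with_seed(seed,
      matrix(sample(c(TRUE, FALSE), 2L * nrow(d1), replace = TRUE), ncol = 2L))
    out$outside <- ifelse(pick[, 1L], d1$outside, d2$outside)
    out$inside <- ifelse(pick[, 2L], d1$inside, d2$inside)
    # agreements are unaffected by the coin flips
  } else {
    out$outside <- resolve_det(d1$outside, d2$outside, indet = "gamma",
                               ambig = "delta")
    out$inside <- resolve_det(d1$inside, d2$inside, indet = "rho",
                              ambig = "beta")
  }
  new_dictionary(out, k = attr(d1, "k"), p = attr(d1, "p"), mode = mode,
                 seed = seed %||% NA_integer_,
                 source = paste(attr(d1, "source"), attr(d2, "source"),
                                sep = "+"))
}

resolve_det <- function(a, b, indet, ambig) {
  dplyr::case_when(
    a == b ~ a,
    a == indet ~ b,
    b == indet ~ a,
    TRUE ~ ambig
  )
}

#' Fraction of k-mers with a determinate symbol
#'
#' Reports how much of the `4^k` k-mer space the training data covered: the
#' fraction of k-mers not mapped to the indeterminate pair (`gamma`, `rho`).
#'
#' @param dict A `rloop_dictionary`.
#' @return A number in \[0, 1\].
#' @export
dictionary_coverage <- function(dict) {
  mean(dict$outside != "gamma")
}

#' Write / read a symbol dictionary as tab-separated text
#'
#' The file carries `# key\tvalue` provenance header lines (`k`, `p`,
#' `mode`, `seed`, `source`) followed by a `kmer / outside / inside` table.
#'
#' @param dict A `rloop_dictionary`.
#' @param path File path.
#' @return `write_dictionary()` returns `path` invisibly; `read_dictionary()`
#'   returns the dictionary.
#' @export
write_dictionary <- function(dict, path) {
  hdr <- sprintf("# %s\t%s",
                 c("k", "p", "mode", "seed", "source"),
                 c(attr(dict, "k"), attr(dict, "p"), attr(dict, "mode"),
                   attr(dict, "seed"), attr(dict, "source")))
  writeLines(c(hdr, paste(c("kmer", "outside", "inside"), collapse = "\t")),
             path)
  utils::write.table(as.data.frame(dict)[, c("kmer", "outside", "inside")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  new_dictionary(tab,
                 k = as.integer(meta[["k"]]), p = as.integer(meta[["p"]]),
                 mode = meta[["mode"]],
                 seed = suppressWarnings(as.integer(meta[["seed"]])),
                 source = meta[["source"]])
}
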