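#' Enumerate all candidate R-loop intervals on a plasmid
#'
#' A candidate `[i, j]` must admit a derivation in the grammar: its length is
#' a multiple of `k`, and at least one full k-block must remain on each side
#' (`i - b >= k`, `e - j >= k`) because the start and end rule families each
#' emit at least one non-alpha/omega terminal.
#'
#' @param plasmid A [plasmid_sequence()].
#' @param k Block size.
#' @param min_len Minimum candidate length (multiple of `k`, >= `k`).
#' @param max_len Optional maximum length cap (bounds enumeration cost);
#'   `NULL` allows the full gene region.
#' @return Tibble of candidates `start`, `end`; empty (with a warning) when
#'   the gene region is too short.
#' @export
enumerate_candidates <- function(plasmid, k, min_len = k, max_len = NULL) {
  stopifnot(min_len >= k, min_len %% k == 0)
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  longest <- e - k - (b + k) + 1L
  max_len <- min(max_len %||% longest, longest)
  if (max_len < min_len) {
    warning("gene region too short for any candidate R-loop", call. = FALSE)
    return(tibble(start = integer(), end = integer()))
  }
  lens <- seq.int(min_len, max_len, by = k)
  starts <- seq.int(b + k, e - k - min_len + 1L)
  cand <- tidyr::expand_grid(start = starts, len = lens) |>
    mutate(end = .data$start + .data$len - 1L) |>
    filter(.data$end <= e - k) |>
    select("start", "end")
  cand
}

#' Normalized probability distribution over candidate R-loop words
#'
#' Scores every candidate's word under the fitted grammar and normalizes so
#' the probabilities sum to one. The default `method = "prefix"` evaluates
#' each candidate in O(1) from per-position prefix sums of rule
#' log-probabilities (pre-R-loop blocks are anchored at `b`, post blocks at
#' `e`, interior blocks at the candidate start, so each family admits a
#' cumulative decomposition). `method = "enumerate"` constructs and scores
#' every word explicitly and is retained as the independent oracle.
#'
#' If every candidate has probability zero under the model, a uniform
#' distribution is returned with a warning.
#'
#' @param cands Candidate tibble from [enumerate_candidates()].
#' @param plasmid A [plasmid_sequence()].
#' @param dict A `rloop_dictionary`.
#' @param model A `rloop_grammar`.
#' @param method `"prefix"` (fast) or `"enumerate"` (oracle).
#' @return `cands` with columns `log_prob` (unnormalized, floored) and
#'   `prob` (normalized; sums to one).
#' @export
word_distribution <- function(cands, plasmid, dict, model,
                              method = c("prefix", "enumerate")) {
  method <- match.arg(method)
  if (nrow(cands) == 0L) stop("empty candidate set", call. = FALSE)
  k <- attr(dict, "k")
  lp <- if (method == "prefix") {
    candidate_logprobs_prefix(cands, plasmid, dict, model, k)
  } else {
    purrr::map_dbl(seq_len(nrow(cands)), function(r) {
      w <- encode_rloop_word(plasmid, cands$start[[r]], cands$end[[r]], k, dict)
      word_probability(w, model, log = TRUE)
    })
  }
  lse <- logsumexp(lp)
  if (!is.finite(lse)) {
    warning("all candidate words have probability zero; ",
            "falling back to a uniform distribution", call. = FALSE)
    prob <- rep(1 / length(lp), length(lp))
  } else {
    prob <- ifelse(lp <= .LOG_FLOOR, 0, exp(lp - lse))
    prob <- prob / sum(prob)
  }
  dplyr::mutate(cands, log_prob = lp, prob = prob)
}

# O(1)-per-candidate scoring via prefix sums in log space.
candidate_logprobs_prefix <- function(cands, plasmid, dict, model, k) {
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  probs <- rule_prob_lookup(model)
  lookup_out <- stats::setNames(dict$outside, dict$kmer)
  lookup_in <- stats::setNames(dict$inside, dict$kmer)

  # Pre-R-loop blocks are anchored at b: block t covers [b+(t-1)k, b+tk-1].
  n_pre_max <- (e - b + 1L) %/% k
  pre_starts <- b + k * seq_len(n_pre_max) - k
  pre_sym <- unname(lookup_out[substring(plasmid$seq, pre_starts,
                                         pre_starts + k - 1L)])
  A_chain <- log_safe(probs[rule_key("S", pre_sym, "chain")])
  A_trans <- log_safe(probs[rule_key("S", pre_sym, "transition")])
  pre_cum <- c(0, cumsum(A_chain))            # pre_cum[t+1] = sum of first t

  # Interior blocks keyed by absolute start position u in [b, e-k+1].
  u <- seq.int(b, e - k + 1L)
  in_sym <- unname(lookup_in[substring(plasmid$seq, u, u + k - 1L)])
  B_chain <- log_safe(probs[rule_key("R", in_sym, "chain")])
  B_trans <- log_safe(probs[rule_key("R", in_sym, "transition")])
  # cumB[u] = B_chain[u] + cumB[u - k] (phase-wise running sum).
  cumB <- B_chain
  for (off in seq.int(k + 1L, length(u))) {
    cumB[off] <- cumB[off] + cumB[off - k]
  }
  at <- function(vec, pos) vec[pos - b + 1L]   # index by absolute position

  # Post blocks are anchored at e: r-th from the right starts at e - r*k + 1.
  n_post_max <- (e - b + 1L) %/% k
  w_r <- e - k * seq_len(n_post_max) + 1L
  post_sym <- unname(lookup_out[substring(plasmid$seq, w_r, w_r + k - 1L)])
  C_chain <- log_safe(probs[rule_key("Q", post_sym, "chain")])
  C_term <- log_safe(probs[rule_key("Q", post_sym, "transition")])
  D <- numeric(n_post_max)                     # D[q]: q post blocks
  D[1L] <- C_term[1L]
  if (n_post_max >= 2L) {
    for (q in 2:n_post_max) D[q] <- D[q - 1L] + C_chain[q]
  }

  i <- cands$start
  j <- cands$end
  n_pre <- (i - b) %/% k
  q <- (e - j) %/% k
  nb <- (j - i + 1L) %/% k
  pre_lp <- pre_cum[n_pre] + A_trans[n_pre]
  trans_pos <- j - k + 1L
  inside_lp <- at(B_trans, trans_pos)
  multi <- nb >= 2L
  if (any(multi)) {
    hi <- at(cumB, j[multi] - 2L * k + 1L)
    lo <- ifelse(i[multi] - k >= b, at(cumB, i[multi] - k), 0)
    inside_lp[multi] <- inside_lp[multi] + (hi - lo)
  }
  lp <- pre_lp + inside_lp + D[q]
  pmax(lp, .LOG_ZERO)
}

#' Per-nucleotide R-loop probability track from a word distribution
#'
#' The probability that nucleotide `t` is inside an R-loop is the total
#' probability of the candidate words covering `t` — the expectation of the
#' coverage indicator under the word distribution.
#'
#' @param dist Output of [word_distribution()].
#' @param plasmid A [plasmid_sequence()].
#' @return Tibble `position` (all of `[b, e]`), `prob` (in \[0, 1\]).
#' @export
per_nucleotide_track <- function(dist, plasmid) {
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  G <- e - b + 1L
  delta <- numeric(G + 1L)
  add <- rowsum(c(dist$prob, -dist$prob),
                c(dist$start - b + 1L, dist$end - b + 2L))
  delta[as.integer(rownames(add))] <- add[, 1L]
  q <- cumsum(delta[seq_len(G)])
  tibble(position = seq.int(b, e), prob = pmin(1, pmax(0, q)))
}

#' One-model prediction track
#'
#' Convenience wrapper: enumerate candidates, score them under the grammar,
#' and reduce to the per-nucleotide track.
#'
#' @inheritParams word_distribution
#' @inheritParams enumerate_candidates
#' @return Tibble `position`, `prob`.
#' @export
predict_track <- function(plasmid, dict, model, min_len = NULL,
                          max_len = NULL, method = "prefix") {
  k <- attr(dict, "k")
  cands <- enumerate_candidates(plasmid, k, min_len %||% k, max_len)
  dist <- word_distribution(cands, plasmid, dict, model, method = method)
  per_nucleotide_track(dist, plasmid)
}

#' Ensemble prediction from subsample-trained grammar models
#'
#' Implements the full training protocol: for each of `n_models` models an
#' independent `subsample_frac` subsample (without replacement) is drawn from
#' each plasmid's full training dataset; a dictionary is built per plasmid
#' and merged into a union dictionary (when two or more plasmids are given);
#' all subsampled footprints are encoded as words and a grammar is fitted;
#' each plasmid gets a prediction track. The final track per plasmid is the
#' per-nucleotide mean over models, with the standard error of the mean.
#' All randomness derives from `seed`, so reruns are bit-identical.
#'
#' @param train Record tibble (the full training dataset; may span several
#'   plasmids via the `plasmid` column).
#' @param plasmids A [plasmid_sequence()] or list of them (names matched
#'   against the records' `plasmid` column).
#' @param k,p Dictionary parameters.
#' @param n_models Ensemble size (protocol default 30).
#' @param subsample_frac Per-model training fraction (protocol default 0.10).
#' @param mode Union-dictionary conflict resolution, see
#'   [merge_dictionaries()].
#' @param seed Master seed.
#' @param min_len,max_len Candidate length bounds (see
#'   [enumerate_candidates()]).
#' @param pseudocount Passed to [fit_grammar()].
#' @return An object of class `rloop_ensemble`: list with `tracks` (named
#'   list of tibbles `position`, `mean`, `sem`), `models` (fitted grammars)
#'   and `params`.
#' @export
ensemble_predict <- function(train, plasmids, k = 4, p = 13, n_models = 30,
                             subsample_frac = 0.10,
                             mode = c("stochastic", "deterministic"),
                             seed = 1L, min_len = NULL, max_len = NULL,
                             pseudocount = 0) {
  mode <- match.arg(mode)
  if (inherits(plasmids, "plasmid_sequence")) plasmids <- list(plasmids)
  names(plasmids) <- purrr::map_chr(plasmids, "name")
  stopifnot(n_models >= 1L, all(train$plasmid %in% names(plasmids)))
  per_plasmid <- split(train, train$plasmid)
  n_pl <- length(per_plasmid)
  seeds <- matrix(derive_seeds(seed, n_models * (n_pl + 1L)), nrow = n_models)

  model_fits <- purrr::map(seq_len(n_models), function(m) {
    sub <- purrr::imap(per_plasmid, function(ds, nm) {
      size <- max(1L, round(subsample_frac * nrow(ds)))
      s <- seeds[m, match(nm, names(per_plasmid))]
      withr::with_seed(s, ds[sample.int(nrow(ds), size), , drop = FALSE])
    })
    dicts <- purrr::imap(sub, function(ds, nm) {
      build_symbol_dictionary(ds, plasmids[[nm]], k, p)
    })
    dict <- Reduce(function(a, b) {
      merge_dictionaries(a, b, mode = mode, seed = seeds[m, n_pl + 1L])
    }, dicts)
    words <- purrr::imap(sub, function(ds, nm) {
      purrr::map(seq_len(nrow(ds)), function(r) {
        encode_rloop_word(plasmids[[nm]], ds$start[[r]], ds$end[[r]], k, dict)
      })
    })
    model <- fit_grammar(purrr::flatten(unname(words)), pseudocount)
    tracks <- purrr::map(plasmids, function(pl) {
      predict_track(pl, dict, model, min_len = min_len, max_len = max_len)
    })
    list(model = model, dict = dict, tracks = tracks)
  })

  tracks <- purrr::map(names(plasmids), function(nm) {
    mat <- do.call(cbind,
                   purrr::map(model_fits, ~ .x$tracks[[nm]]$prob))
    mean_ <- rowMeans(mat)
    sem <- if (ncol(mat) == 1L) rep(0, nrow(mat)) else
      apply(mat, 1L, stats::sd) / sqrt(ncol(mat))
    tibble(position = model_fits[[1L]]$tracks[[nm]]$position,
           mean = mean_, sem = sem)
  })
  names(tracks) <- names(plasmids)
  structure(
    list(tracks = tracks,
         models = purrr::map(model_fits, "model"),
         params = list(k = k, p = p, n_models = n_models,
                       subsample_frac = subsample_frac, mode = mode,
                       seed = seed)),
    class = "rloop_ensemble"
  )
}

#' @export
print.rloop_ensemble <- function(x, ...) {
  cat("<rloop_ensemble>", x$params$n_models, "model(s), k =", x$params$k,
      ", p =", x$params$p, ", mode =", x$params$mode, "\n")
  cat("tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.rloop_grammar
#' @export
tidy.rloop_ensemble <- function(x, ...) {
  purrr::imap(x$models, function(m, idx) {
    dplyr::mutate(tidy(m), model = idx)
  }) |>
    dplyr::bind_rows() |>
    select("model", dplyr::everything())
}

#' Export a probability track as bedGraph
#'
#' Writes `chrom start0 end0 value` lines (0-based half-open) for a
#' single-model or ensemble-mean track.
#'
#' @param track Tibble with `position` and `prob` (or `mean`).
#' @param plasmid A [plasmid_sequence()] (supplies the chrom name).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, plasmid, path) {
  value <- if ("prob" %in% names(track)) track$prob else track$mean
  utils::write.table(
    data.frame(chrom = plasmid$name, start = track$position - 1L,
               end = track$position, value = value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
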