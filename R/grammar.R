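#' Tile the gene region into parsing blocks around one R-loop
#'
#' The gene region \[b, e\] is tiled exactly, relative to an R-loop \[i, j\]
#' whose length is a multiple of `k`:
#' \itemize{
#'   \item `[b, i-1]` splits left-to-right into `floor((i-b)/k)` k-blocks
#'     followed by an `alpha` block of length `(i-b) %% k` ending at `i - 1`;
#'   \item `[i, j]` splits into `(j-i+1)/k` k-blocks (the R-loop interior);
#'   \item `[j+1, e]` starts with an `omega` block of length `(e-j) %% k`
#'     followed by `floor((e-j)/k)` k-blocks ending at `e`.
#' }
#' `alpha` and `omega` model the experimentally imprecise branch-migration
#' boundaries and may be empty; they are always present in the word.
#'
#' @param plasmid A [plasmid_sequence()].
#' @param start,end R-loop interval `[i, j]`, 1-based inclusive;
#'   `(end - start + 1)` must be a multiple of `k`.
#' @param k Block size.
#' @return A tibble of blocks in genomic order: columns `start`, `end`
#'   (inclusive; `end = start - 1` for an empty alpha/omega), `type` in
#'   `pre`, `alpha`, `inside`, `omega`, `post`.
#' @export
parse_blocks <- function(plasmid, start, end, k) {
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  if (!(b <= start && start < end && end <= e)) {
    stop("R-loop [", start, ", ", end, "] not within gene region", call. = FALSE)
  }
  if ((end - start + 1L) %% k != 0L) {
    stop("R-loop length must be a multiple of k", call. = FALSE)
  }
  n_pre <- (start - b) %/% k
  a_len <- (start - b) %% k
  n_in <- (end - start + 1L) %/% k
  o_len <- (e - end) %% k
  n_post <- (e - end) %/% k
  pre_starts <- b + k * seq_len(n_pre) - k
  in_starts <- start + k * seq_len(n_in) - k
  post_starts <- end + o_len + k * seq_len(n_post) - k + 1L
  blk_start <- c(pre_starts, start - a_len, in_starts, end + 1L, post_starts)
  blk_end <- c(pre_starts + k - 1L, start - 1L, in_starts + k - 1L,
               end + o_len, post_starts + k - 1L)
  tibble(
    start = blk_start,
    end = blk_end,
    type = rep(c("pre", "alpha", "inside", "omega", "post"),
               c(n_pre, 1L, n_in, 1L, n_post))
  )
}

#' Encode one R-loop as a word over the grammar alphabet
#'
#' Applies the symbol dictionary to the parsing blocks: k-blocks before and
#' after the R-loop map through the *outside* context, interior blocks
#' through the *inside* context; `alpha` and `omega` are emitted regardless
#' of their (possibly empty) sequence content.
#'
#' @inheritParams parse_blocks
#' @param dict A `rloop_dictionary` with matching `k`.
#' @return Character vector of terminal symbols (the word); the block tiling
#'   is attached as attribute `"blocks"`.
#' @export
encode_rloop_word <- function(plasmid, start, end, k, dict) {
  stopifnot(identical(as.integer(attr(dict, "k")), as.integer(k)))
  blocks <- parse_blocks(plasmid, start, end, k)
  lookup_out <- stats::setNames(dict$outside, dict$kmer)
  lookup_in <- stats::setNames(dict$inside, dict$kmer)
  kmers <- substring(plasmid$seq, blocks$start, blocks$end)
  ty <- blocks$type
  word <- character(length(kmers))
  word[ty == "alpha"] <- "alpha"
  word[ty == "omega"] <- "omega"
  outside <- ty == "pre" | ty == "post"
  word[outside] <- lookup_out[kmers[outside]]
  inside <- ty == "inside"
  word[inside] <- lookup_in[kmers[inside]]
  if (anyNA(word) || any(word == "")) {
    stop("block sequence not in dictionary (non-ACGT characters?)",
         call. = FALSE)
  }
  attr(word, "blocks") <- blocks
  word
}

#' Recover the unique rule derivation of an R-loop word
#'
#' The grammar is right-linear and unambiguous: each word has exactly one
#' derivation. Every pre-alpha terminal contributes an S-rule (the last one
#' the transition `S -> x alpha R`), every interior terminal an R-rule (the
#' last one `R -> y omega Q`), and every post-omega terminal a Q-rule (the
#' last one the terminating `Q -> x`). Concatenating the right-hand sides of
#' the returned rules reproduces the word exactly.
#'
#' @param word Character vector of terminals containing exactly one `alpha`
#'   and one `omega` (in that order), with at least one terminal before
#'   `alpha`, between them, and after `omega`.
#' @return Tibble of applied rules in order: columns `lhs`, `terminal`,
#'   `role`, `rule`.
#' @export
derive_rule_sequence <- function(word) {
  s <- word_segments(word)
  rules <- tibble(
    lhs = rep(c("S", "R", "Q"),
              c(length(s$pre), length(s$ins), length(s$post))),
    terminal = c(s$pre, s$ins, s$post),
    role = c(seg_roles(s$pre), seg_roles(s$ins), seg_roles(s$post))
  )
  rules$rule <- rule_label(rules$lhs, rules$terminal, rules$role)
  rules
}

seg_roles <- function(terms) {
  c(rep("chain", length(terms) - 1L), "transition")
}

# Validated split of a word into its pre-alpha / interior / post-omega parts.
word_segments <- function(word) {
  a <- which(word == "alpha")
  o <- which(word == "omega")
  if (length(a) != 1L || length(o) != 1L || a >= o) {
    stop("word must contain exactly one alpha then one omega", call. = FALSE)
  }
  pre <- word[seq_len(a - 1L)]
  ins <- word[(a + 1L):(o - 1L)]
  post <- word[seq(o + 1L, length.out = length(word) - o)]
  if (length(pre) < 1L || length(ins) < 1L || length(post) < 1L) {
    stop("word needs at least one terminal before alpha, between alpha and ",
         "omega, and after omega", call. = FALSE)
  }
  if (!all(c(pre, post) %in% .outside_symbols()) ||
      !all(ins %in% .inside_symbols())) {
    stop("word mixes inside- and outside-context symbols", call. = FALSE)
  }
  list(pre = pre, ins = ins, post = post)
}

# "lhs terminal role" keys of a word's derivation, without tibble overhead.
word_rule_keys <- function(word) {
  s <- word_segments(word)
  c(rule_key("S", s$pre, seg_roles(s$pre)),
    rule_key("R", s$ins, seg_roles(s$ins)),
    rule_key("Q", s$post, seg_roles(s$post)))
}

#' Fit production-rule probabilities from a corpus of R-loop words
#'
#' Because each word has a unique derivation, maximum-likelihood estimation
#' is relative-frequency counting of rule applications:
#' `P(X -> v) = (count(X -> v) + pseudocount) /
#'              (count(X) + pseudocount * 8)`
#' (each nonterminal has 8 rules). The default `pseudocount = 0` keeps
#' unobserved rules at probability zero.
#'
#' @param words List of terminal-symbol words (see [encode_rloop_word()]).
#' @param pseudocount Additive smoothing constant (>= 0).
#' @return An object of class `rloop_grammar`: list with the rule tibble
#'   (`lhs`, `terminal`, `role`, `rule`, `count`, `prob`), `n_words` and
#'   `pseudocount`. Per-lhs probabilities sum to one.
#' @export
fit_grammar <- function(words, pseudocount = 0) {
  stopifnot(length(words) >= 1L, pseudocount >= 0)
  tab <- table(unlist(lapply(words, word_rule_keys)))
  rules <- grammar_rules()
  hit <- match(rule_key(rules$lhs, rules$terminal, rules$role), names(tab))
  rules$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  rules <- rules |>
    group_by(.data$lhs) |>
    mutate(prob = (.data$count + pseudocount) /
             (sum(.data$count) + pseudocount * dplyr::n())) |>
    ungroup() |>
    mutate(prob = ifelse(is.nan(.data$prob), 0, .data$prob))
  structure(
    list(rules = rules, n_words = length(words), pseudocount = pseudocount),
    class = "rloop_grammar"
  )
}

#' @export
print.rloop_grammar <- function(x, ...) {
  cat("<rloop_grammar> fitted on", x$n_words, "word(s), pseudocount",
      x$pseudocount, "\n")
  used <- x$rules[x$rules$prob > 0, c("rule", "count", "prob")]
  print(as.data.frame(used), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a fitted R-loop grammar
#'
#' @param x A `rloop_grammar`.
#' @param ... Unused.
#' @return `tidy()`: one row per production rule with `lhs`, `terminal`,
#'   `role`, `rule`, `count`, `prob`. `glance()`: a one-row summary with the
#'   corpus size, number of rules used, and the corpus log-likelihood.
#' @export
tidy.rloop_grammar <- function(x, ...) {
  x$rules
}

#' @rdname tidy.rloop_grammar
#' @export
glance.rloop_grammar <- function(x, ...) {
  used <- x$rules$count > 0
  tibble(
    n_words = x$n_words,
    n_rules_used = sum(used),
    log_lik = sum(x$rules$count[used] * log(x$rules$prob[used])),
    pseudocount = x$pseudocount
  )
}

#' Probability of an R-loop word under a fitted grammar
#'
#' The product of the probabilities of the word's unique rule derivation;
#' zero as soon as any applied rule has probability zero.
#'
#' @param word Terminal-symbol word.
#' @param model A `rloop_grammar`.
#' @param log Return the (floored) log probability instead.
#' @return A probability, or its log with `log = TRUE` (zero-probability
#'   words give a large negative sentinel, never `-Inf`).
#' @export
word_probability <- function(word, model, log = FALSE) {
  probs <- rule_prob_lookup(model)[word_rule_keys(word)]
  lp <- sum(log_safe(probs))
  if (log) max(lp, .LOG_ZERO) else if (lp <= .LOG_FLOOR) 0 else exp(lp)
}

rule_key <- function(lhs, terminal, role) paste(lhs, terminal, role)

rule_prob_lookup <- function(model) {
  stats::setNames(model$rules$prob,
                  rule_key(model$rules$lhs, model$rules$terminal,
                           model$rules$role))
}

#' Sample R-loop words from a fitted grammar
#'
#' Forward generation from the start symbol `S`, sampling each rewrite from
#' the fitted rule distribution. Used for generative-consistency checks
#' (sample, refit, compare probabilities).
#'
#' @param model A `rloop_grammar` whose per-lhs probabilities sum to 1.
#' @param n Number of words.
#' @param seed Optional integer seed.
#' @param max_steps Safety bound on derivation length per word.
#' @return List of terminal-symbol words.
#' @export
sample_words <- function(model, n, seed = NULL, max_steps = 10000L) {
  by_lhs <- purrr::map(c(S = "S", R = "R", Q = "Q"), function(l) {
    sub <- model$rules[model$rules$lhs == l, ]
    list(terminal = sub$terminal, role = sub$role, prob = sub$prob)
  })
  bridge <- c(S = "alpha", R = "omega", Q = NA_character_)
  nxt <- c(S = "R", R = "Q")
  draw <- function() {
    word <- character()
    lhs <- "S"
    for (step in seq_len(max_steps)) {
      sub <- by_lhs[[lhs]]
      idx <- sample.int(length(sub$prob), 1L, prob = sub$prob)
      word <- c(word, sub$terminal[[idx]])
      if (sub$role[[idx]] == "transition") {
        if (lhs == "Q") return(word)
        word <- c(word, bridge[[lhs]])
        lhs <- nxt[[lhs]]
      }
    }
    stop("derivation exceeded max_steps; chain probabilities too close to 1",
         call. = FALSE)
  }
  run <- function() purrr::map(seq_len(n), ~ draw())
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
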