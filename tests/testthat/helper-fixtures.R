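# In-code fixtures shared across the suite: tiny deterministic plasmids,
# record tibbles, and randomly fitted grammar models.

tiny_plasmid <- function(n = 40L, gene_start = 1L, gene_end = n,
                         name = "p", seed = 42L) {
  seq <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  plasmid_sequence(name, seq, gene_start, gene_end)
}

records <- function(starts, ends, plasmid = "p", topology = "supercoiled") {
  tibble::tibble(plasmid = plasmid, topology = topology,
                 start = as.integer(starts), end = as.integer(ends),
                 read_id = as.character(seq_along(starts)))
}

# Dictionary mapping every k-mer to a single (outside, inside) pair.
uniform_dictionary <- function(k, outside = "sigma_hat", inside = "tau_hat",
                               p = 0L) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rloopgrammar:::new_dictionary(
    tibble::tibble(kmer = kmers, outside = outside, inside = inside),
    k = as.integer(k), p = as.integer(p), mode = "single",
    seed = NA_integer_, source = "uniform")
}

# A grammar fitted on randomly sampled valid words so that all invariants of
# a genuinely fitted model (per-lhs normalization) hold by construction.
random_model <- function(seed = 1L, n_words = 40L, pseudocount = 0.5) {
  words <- withr::with_seed(seed, purrr::map(seq_len(n_words), function(i) {
    out <- rloopgrammar:::.outside_symbols()
    ins <- rloopgrammar:::.inside_symbols()
    c(sample(out, sample(1:4, 1), replace = TRUE), "alpha",
      sample(ins, sample(1:5, 1), replace = TRUE), "omega",
      sample(out, sample(1:4, 1), replace = TRUE))
  }))
  fit_grammar(words, pseudocount = pseudocount)
}

random_word <- function(seed) {
  withr::with_seed(seed, {
    out <- rloopgrammar:::.outside_symbols()
    ins <- rloopgrammar:::.inside_symbols()
    c(sample(out, sample(1:6, 1), replace = TRUE), "alpha",
      sample(ins, sample(1:8, 1), replace = TRUE), "omega",
      sample(out, sample(1:6, 1), replace = TRUE))
  })
}

# Re-derive a word from an applied-rule table by replaying the right-hand
# sides (independent check of derive_rule_sequence).
replay_rules <- function(rules) {
  word <- character()
  for (r in seq_len(nrow(rules))) {
    word <- c(word, rules$terminal[[r]])
    if (rules$role[[r]] == "transition") {
      if (rules$lhs[[r]] == "S") word <- c(word, "alpha")
      if (rules$lhs[[r]] == "R") word <- c(word, "omega")
    }
  }
  word
}

write_fasta_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_bed_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
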