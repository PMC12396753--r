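test_that("candidate enumeration respects the derivability constraints", {
  pl12 <- tiny_plasmid(12)
  c12 <- enumerate_candidates(pl12, 4, min_len = 4)
  expect_equal(nrow(c12), 1L)
  expect_equal(c(c12$start, c12$end), c(5L, 8L))
  pl16 <- tiny_plasmid(16)
  c16 <- enumerate_candidates(pl16, 4)
  # brute-force oracle: every [i, j] with length a multiple of k and one
  # full block of margin on each side (alpha/omega absorb the remainders)
  grid <- expand.grid(i = 1:16, j = 1:16)
  grid <- grid[grid$j > grid$i &
                 (grid$j - grid$i + 1L) %% 4L == 0L &
                 grid$i - 1L >= 4L & 16L - grid$j >= 4L, ]
  expect_equal(nrow(c16), nrow(grid))
  expect_setequal(paste(c16$start, c16$end), paste(grid$i, grid$j))
  expect_true(all(paste(c16$start, c16$end) %in%
                    c("5 8", "5 12", "6 9", "7 10", "8 11", "9 12")))
  expect_true(all((c16$end - c16$start + 1L) %% 4 == 0))
  expect_warning(out <- enumerate_candidates(pl16, 4, min_len = 12),
                 "too short")
  expect_equal(nrow(out), 0L)
})

test_that("word distributions normalize to one", {
  spec <- synthetic_spec(gene_length = 300, flank = 40, n_rloops = 60,
                         seed = 4)
  d <- generate_smrf_dataset(spec)
  ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
  dict <- build_symbol_dictionary(ds, d$plasmid, 4, 13)
  words <- purrr::map(seq_len(nrow(ds)), function(r)
    encode_rloop_word(d$plasmid, ds$start[r], ds$end[r], 4, dict))
  model <- fit_grammar(words)
  cands <- enumerate_candidates(d$plasmid, 4)
  dist <- word_distribution(cands, d$plasmid, dict, model)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
  expect_true(all(dist$prob >= 0))
  # single candidate gets everything (uniform fallback if its raw
  # probability is zero, hence the tolerated warning)
  one <- suppressWarnings(
    word_distribution(cands[1, ], d$plasmid, dict, model))
  expect_equal(one$prob, 1)
  expect_error(word_distribution(cands[0, ], d$plasmid, dict, model),
               "empty")
})

test_that("all-zero distributions fall back to uniform with a warning", {
  pl <- tiny_plasmid(20)
  dict <- uniform_dictionary(4)
  # model trained on words that never use sigma_hat/tau_hat rules
  model <- fit_grammar(list(c("sigma", "alpha", "tau", "omega", "sigma")))
  cands <- enumerate_candidates(pl, 4)
  expect_warning(dist <- word_distribution(cands, pl, dict, model),
                 "uniform")
  expect_equal(dist$prob, rep(1 / nrow(cands), nrow(cands)))
})

test_that("fast scoring equals explicit word enumeration", {
  for (s in 1:3) {
    spec <- synthetic_spec(gene_length = 160 + 40 * s, flank = 30,
                           n_rloops = 50, n_start_sites = 6,
                           n_end_sites = 4, seed = s)
    d <- generate_smrf_dataset(spec)
    ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
    dict <- build_symbol_dictionary(ds, d$plasmid, 4, 7)
    words <- purrr::map(seq_len(nrow(ds)), function(r)
      encode_rloop_word(d$plasmid, ds$start[r], ds$end[r], 4, dict))
    model <- fit_grammar(words, pseudocount = if (s == 1) 0 else 0.1)
    cands <- enumerate_candidates(d$plasmid, 4)
    fast <- word_distribution(cands, d$plasmid, dict, model,
                              method = "prefix")
    slow <- word_distribution(cands, d$plasmid, dict, model,
                              method = "enumerate")
    expect_lt(max(abs(fast$prob - slow$prob)), 1e-10)
    t_fast <- per_nucleotide_track(fast, d$plasmid)
    t_slow <- per_nucleotide_track(slow, d$plasmid)
    expect_lt(max(abs(t_fast$prob - t_slow$prob)), 1e-10)
  }
})

test_that("per-nucleotide probabilities are coverage expectations", {
  pl <- tiny_plasmid(24)
  dist <- tibble::tibble(start = 9L, end = 16L, prob = 1)
  tr <- per_nucleotide_track(dist, pl)
  expect_equal(tr$prob, as.numeric(tr$position >= 9 & tr$position <= 16))
  # sum over positions equals the expected R-loop length
  spec <- synthetic_spec(gene_length = 240, flank = 30, n_rloops = 40,
                         seed = 9)
  d <- generate_smrf_dataset(spec)
  ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
  dict <- build_symbol_dictionary(ds, d$plasmid, 4, 7)
  words <- purrr::map(seq_len(nrow(ds)), function(r)
    encode_rloop_word(d$plasmid, ds$start[r], ds$end[r], 4, dict))
  model <- fit_grammar(words, pseudocount = 0.2)
  cands <- enumerate_candidates(d$plasmid, 4)
  dist2 <- word_distribution(cands, d$plasmid, dict, model)
  tr2 <- per_nucleotide_track(dist2, d$plasmid)
  expect_equal(sum(tr2$prob),
               sum(dist2$prob * (dist2$end - dist2$start + 1)),
               tolerance = 1e-9)
  expect_true(all(tr2$prob >= 0 & tr2$prob <= 1))
})

test_that("ensembles are reproducible and degenerate SEM is zero", {
  spec <- synthetic_spec(gene_length = 300, flank = 40, n_rloops = 80,
                         seed = 2)
  d <- generate_smrf_dataset(spec)
  ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
  e1 <- ensemble_predict(ds, d$plasmid, n_models = 4, seed = 7, p = 7)
  e2 <- ensemble_predict(ds, d$plasmid, n_models = 4, seed = 7, p = 7)
  expect_identical(e1$tracks, e2$tracks)
  expect_true(all(e1$tracks$synthetic$sem >= 0))
  single <- ensemble_predict(ds, d$plasmid, n_models = 1, seed = 7, p = 7)
  expect_equal(single$tracks$synthetic$sem, rep(0, 300))
  td <- tidy(e1)
  expect_equal(sort(unique(td$model)), 1:4)
})

test_that("prediction mass concentrates on the planted footprint region", {
  hits <- vapply(1:5, function(s) {
    spec <- synthetic_spec(gene_length = 500, flank = 50, n_rloops = 150,
                           seed = s)
    d <- generate_smrf_dataset(spec)
    ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
    ens <- ensemble_predict(ds, d$plasmid, n_models = 2, seed = s + 50,
                            subsample_frac = 0.5, p = 13)
    tr <- ens$tracks$synthetic
    peak <- tr$position[which.max(tr$mean)]
    lo <- min(attr(d$plasmid, "start_sites"))
    hi <- max(attr(d$plasmid, "end_sites")) + 8L
    peak >= lo && peak <= hi
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("tracks export as bedGraph", {
  pl <- tiny_plasmid(16)
  tr <- tibble::tibble(position = 1:16, prob = seq(0, 1, length.out = 16))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_track_bedgraph(tr, pl, path)
  bg <- utils::read.table(path)
  expect_equal(nrow(bg), 16L)
  expect_equal(bg[[2]], 0:15)
  expect_equal(bg[[3]], 1:16)
  expect_equal(bg[[4]], tr$prob)
})
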