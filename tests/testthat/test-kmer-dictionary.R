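test_that("region k-mer windows slide as specified", {
  pl <- plasmid_sequence("p", "ACGTACGTACGTACGTACGT")  # 20 nt
  # one footprint [9, 12], k = 2, p = 1
  ds <- records(9, 12)
  km <- extract_region_kmers(ds, pl, k = 2, p = 1)
  got <- split(km$start, km$region)
  expect_equal(got$r1, c(7L, 6L))        # [i-k-t, i-1-t], t = 0, 1
  expect_equal(got$r2, c(9L, 10L))       # [i+t, ...]
  expect_equal(got$r3, c(11L, 10L))      # ending at j, shifted left
  expect_equal(got$r4, c(13L, 14L))      # starting at j+1, shifted right
  expect_equal(km$kmer, substring(pl$seq, km$start, km$start + 1L))
})

test_that("windows outside the gene region are discarded", {
  pl <- plasmid_sequence("p", "ACGTACGTACGTACGTACGT", 5, 16)
  km <- extract_region_kmers(records(5, 12), pl, k = 4, p = 2)
  expect_false("r1" %in% km$region)      # footprint starts at b
  expect_true(all(km$start >= 5 & km$start + 3 <= 16))
  # p = 0: exactly one window per region for an interior footprint
  km0 <- extract_region_kmers(records(9, 12), pl, k = 2, p = 0)
  expect_equal(as.vector(table(km0$region)), rep(1L, 4))
  # k = 4, p = 13: at most 14 windows per region
  spec <- synthetic_spec(gene_length = 400, n_rloops = 10, seed = 2)
  d <- generate_smrf_dataset(spec)
  ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
  km13 <- extract_region_kmers(ds[1, ], d$plasmid, 4, 13)
  expect_true(all(table(km13$region) <= 14))
})

test_that("weights follow n / (N m) with exact rational tie grouping", {
  # AATTCCGGAA...: choose footprints so harvested k-mers are known
  pl <- plasmid_sequence("p", "AATTCCGGAATTCCGG")
  ds <- records(c(5, 13), c(8, 16))   # r1 windows: [3,4] "TT" and [11,12] "TT"
  km <- extract_region_kmers(ds, pl, k = 2, p = 0)
  w <- kmer_weight_table(km, pl, n_rloops = 2L)
  r1 <- w[w$region == "r1", ]
  expect_equal(r1$kmer, "TT")
  expect_equal(r1$n, 2L)
  # m: overlapping occurrences of TT in the full gene region
  m_oracle <- sum(vapply(1:15, function(s)
    substring(pl$seq, s, s + 1) == "TT", logical(1)))
  expect_equal(r1$m, m_oracle)
  expect_equal(r1$weight, 2 / (2 * m_oracle))
  # equal-weight k-mers share one rank (rank count < k-mer count)
  r2 <- w[w$region == "r2", ]         # "CC" from both footprints
  expect_equal(r2$kmer, "CC")
  expect_true(all(w$weight > 0))
})

test_that("entropy thresholding reproduces the published worked example", {
  # hyper-negatively supercoiled pFC53, region r4: printed raw weights
  et <- entropy_threshold(c(0.03571, 0.03214, 0.02976))
  # w' is a ratio of two 5-dp-rounded inputs; rounding propagates to
  # ~2.6e-4 on the ratio (H and h are flat there and stay within 5e-5)
  expect_lt(max(abs(et$w_prime - c(1.00000, 0.90000, 0.83333))), 2.6e-4)
  expect_lt(max(abs(et$H - c(0.00000, 0.04118, 0.06598))), 5e-5)
  expect_lt(max(abs(et$h - c(0.00000, 0.02059, 0.03572))), 5e-5)
  # rank-29 weight group (0.00893) rescales to 0.25000 with H = 0.15051
  et29 <- entropy_threshold(c(0.03571, 0.00893))
  expect_lt(abs(et29$w_prime[[2]] - 0.25000), 2.6e-4)
  expect_lt(abs(et29$H[[2]] - 0.15051), 5e-5)
})

test_that("entropy threshold is the log10-based running-average argmax", {
  # degenerate: all weights equal
  flat <- entropy_threshold(rep(0.2, 1))
  expect_equal(attr(flat, "cutoff_rank"), 1L)
  expect_equal(flat$H, 0)
  # property: cutoff equals brute-force argmax on random ranked vectors
  for (s in 1:200) {
    w <- withr::with_seed(s, sort(unique(round(stats::runif(30), 6)),
                                  decreasing = TRUE))
    et <- entropy_threshold(w)
    wp <- w / w[[1]]
    H <- -wp * log10(wp)
    h_brute <- vapply(seq_along(H), function(n) mean(H[1:n]), numeric(1))
    expect_equal(attr(et, "cutoff_rank"), which.max(h_brute))
    expect_equal(et$h[attr(et, "cutoff_rank")], max(h_brute))
  }
})

test_that("rank groups carry one entropy value per distinct weight", {
  # two tied k-mers must share a rank and an h entry
  pl <- plasmid_sequence("p", "AACCAACCGGTTGGTT")
  ds <- records(5, 8)
  km <- extract_region_kmers(ds, pl, k = 2, p = 1)
  w <- kmer_weight_table(km, pl, n_rloops = 1L)
  per_region <- split(w, w$region)
  for (reg in per_region) {
    expect_lte(max(reg$rank), nrow(reg))
    # within a rank, weights identical; across ranks, strictly decreasing
    grp <- tapply(reg$weight, reg$rank, unique)
    expect_true(all(lengths(grp) == 1L))
    expect_true(all(diff(unlist(grp)) < 0))
  }
})

test_that("symbol assignment implements the highly-weighted max rule", {
  fake <- tibble::tibble(
    region = c("r2", "r4", "r1", "r4", "r2", "r3"),
    kmer = c("AA", "AC", "AG", "AG", "AT", "AT"),
    n = c(5L, 4L, 3L, 3L, 7L, 2L),
    highly_weighted = TRUE
  )
  attr(fake, "k") <- 2L
  dict <- assign_symbols(fake, p = 0)
  lk <- function(s) unlist(dict[dict$kmer == s, c("outside", "inside")],
                           use.names = FALSE)
  expect_equal(lk("AA"), c("sigma", "tau_hat"))       # start regions only
  expect_equal(lk("AC"), c("sigma_hat", "tau"))       # end regions only
  expect_equal(lk("AG"), c("delta", "beta"))          # exact start/end tie
  expect_equal(lk("AT"), c("sigma", "tau_hat"))       # start max beats end
  expect_equal(lk("GG"), c("gamma", "rho"))           # never highly weighted
  # the map is total over all 4^k k-mers with context-legal symbols
  expect_equal(nrow(dict), 16L)
  expect_true(all(dict$outside %in% c("sigma", "sigma_hat", "gamma", "delta")))
  expect_true(all(dict$inside %in% c("tau", "tau_hat", "rho", "beta")))
})

test_that("union merge resolves conflicts per mode", {
  d1 <- uniform_dictionary(2, "sigma", "tau_hat")
  d2 <- uniform_dictionary(2, "sigma", "tau_hat")
  d2$outside[1] <- "sigma_hat"   # determinate conflict
  d2$inside[1] <- "tau"
  d2$outside[2] <- "gamma"       # indeterminate loses
  d2$inside[2] <- "rho"
  det <- merge_dictionaries(d1, d2, "deterministic")
  expect_equal(det$outside[1], "delta")
  expect_equal(det$inside[1], "beta")
  expect_equal(det$outside[2], "sigma")
  expect_equal(det$inside[2], "tau_hat")
  expect_equal(det$outside[3:16], d1$outside[3:16])   # agreements copied
  sto1 <- merge_dictionaries(d1, d2, "stochastic", seed = 4)
  sto2 <- merge_dictionaries(d1, d2, "stochastic", seed = 4)
  expect_identical(as.data.frame(sto1), as.data.frame(sto2))
  expect_true(all(sto1$outside[1] %in% c("sigma", "sigma_hat")))
  d3 <- uniform_dictionary(3)
  expect_error(merge_dictionaries(d1, d3, "deterministic"), "k, p")
})

test_that("dictionaries serialize and round-trip as TSV", {
  spec <- synthetic_spec(gene_length = 400, n_rloops = 50, seed = 3)
  d <- generate_smrf_dataset(spec)
  ds <- suppressMessages(preprocess_rloops(d$rloops, d$plasmid, 4))
  dict <- build_symbol_dictionary(ds, d$plasmid, 4, 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_equal(as.data.frame(back), as.data.frame(dict))
  expect_equal(attr(back, "k"), 4L)
  expect_equal(attr(back, "p"), 7L)
  cov <- dictionary_coverage(dict)
  expect_gte(cov, 0)
  expect_lte(cov, 1)
  expect_equal(cov, mean(dict$inside != "rho"))
})
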