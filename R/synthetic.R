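#' Specification for a synthetic SMRF-seq-like dataset
#'
#' Describes a plasmid with a gene region carrying planted
#' initiation-favouring and termination-favouring k-mers, and an R-loop
#' population whose initiation sites cluster (mixture of Gaussians over the
#' gene region) and shift towards the promoter as negative supercoiling
#' increases. Defaults emulate the published study conditions: a ~1.4 kb
#' gene region inside a plasmid, ~600 footprints per condition, two
#' initiation clusters, G-rich initiation motifs.
#'
#' @param gene_length Gene-region length (nt).
#' @param flank Plasmid backbone length on each side of the gene region.
#' @param start_kmers Planted initiation-favouring k-mers (all one length,
#'   disjoint from `end_kmers`).
#' @param end_kmers Planted termination-favouring k-mers.
#' @param n_start_sites,n_end_sites Number of planted motif copies.
#' @param clusters Tibble of the initiation mixture: `mean` and `sd` as
#'   fractions of the gene length, `weight` summing to 1.
#' @param topology `"linear"`, `"supercoiled"` or `"hyper_negative"`; shifts
#'   the cluster means left by 0, 5% or 15% of the gene length.
#' @param n_rloops Number of footprints.
#' @param snap_prob Probability that a footprint boundary snaps to a planted
#'   motif (initiation: motif occupies the R-loop's first k-mer; termination:
#'   the motif directly follows the footprint).
#' @param mean_length,min_length Footprint length distribution: `min_length`
#'   plus a geometric number of k-blocks with mean `mean_length - min_length`.
#' @param boundary_sd Standard deviation (nt) of the Gaussian read-out error
#'   added to both footprint boundaries, emulating the single-molecule
#'   footprinting imprecision that the padding parameter p absorbs.
#' @param gc_skew In `[-1, 1]`; shifts background composition towards G/C
#'   (R-loop-prone sequences are G-rich on the non-template strand).
#' @param complexity Background sequence complexity in (0, 1]. Values below
#'   1 build the background from a small reused tile vocabulary (about
#'   `complexity * 64` tiles) with 5% point substitutions, emulating the
#'   low-complexity, repeat-rich character of CpG-island-class sequence; 1
#'   gives an i.i.d. background.
#' @param seed Master seed for sequence and footprint generation.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(gene_length = 1400L, flank = 120L,
                           start_kmers = c("GGTT", "GTGG"),
                           end_kmers = c("TTGG", "TGTT"),
                           n_start_sites = 24L, n_end_sites = 16L,
                           clusters = tibble(mean = c(0.30, 0.60),
                                             sd = c(0.05, 0.07),
                                             weight = c(0.45, 0.55)),
                           topology = "supercoiled",
                           n_rloops = 600L, snap_prob = 0.6,
                           mean_length = 240L, min_length = 40L,
                           boundary_sd = 12, seed = 1L, gc_skew = 0,
                           complexity = 0.25) {
  k <- unique(nchar(c(start_kmers, end_kmers)))
  stopifnot(length(k) == 1L,
            length(intersect(start_kmers, end_kmers)) == 0L,
            gene_length > 3L * k, flank >= 0L, n_rloops >= 1L,
            snap_prob >= 0, snap_prob <= 1,
            abs(sum(clusters$weight) - 1) < 1e-8,
            min_length >= k, mean_length > min_length)
  structure(
    list(gene_length = as.integer(gene_length), flank = as.integer(flank),
         start_kmers = start_kmers, end_kmers = end_kmers, k = k,
         n_start_sites = as.integer(n_start_sites),
         n_end_sites = as.integer(n_end_sites),
         clusters = clusters, topology = topology,
         n_rloops = as.integer(n_rloops), snap_prob = snap_prob,
         mean_length = as.integer(mean_length),
         min_length = as.integer(min_length), boundary_sd = boundary_sd,
         seed = as.integer(seed), gc_skew = gc_skew,
         complexity = complexity),
    class = "synthetic_spec"
  )
}

# Greedy minimum-spacing filter so planted motifs never overwrite each other.
thin_sites <- function(sites, min_gap) {
  keep <- integer()
  last <- -Inf
  for (s in sites) {
    if (s - last >= min_gap) {
      keep <- c(keep, s)
      last <- s
    }
  }
  keep
}

topology_shift <- function(topology) {
  switch(topology, linear = 0, supercoiled = 0.05, hyper_negative = 0.15,
         stop("unknown topology '", topology, "'", call. = FALSE))
}

# Cluster means in gene coordinates after the topology-dependent left shift.
cluster_positions <- function(spec) {
  shift <- topology_shift(spec$topology)
  mutate(spec$clusters,
         mean_nt = pmax(0.05, .data$mean - shift) * spec$gene_length,
         sd_nt = .data$sd * spec$gene_length)
}

#' Generate a synthetic plasmid with planted motifs
#'
#' A uniform-random (optionally GC-skewed) background sequence of length
#' `2 * flank + gene_length`, with `start_kmers` planted at loci drawn from
#' the initiation clusters and `end_kmers` planted downstream of each start
#' locus (around one mean footprint length away). Planted locus positions
#' are recorded in attributes `"start_sites"` and `"end_sites"` (positions
#' of the motif's first nucleotide, internal coordinates).
#'
#' @param spec A [synthetic_spec()].
#' @return A [plasmid_sequence()] named `"synthetic"` with gene region
#'   `[flank + 1, flank + gene_length]`.
#' @export
generate_plasmid <- function(spec) {
  withr::with_seed(spec$seed, {
    pr_gc <- (1 + spec$gc_skew) / 4
    pr_at <- (1 - spec$gc_skew) / 4
    pr <- c(pr_at, pr_gc, pr_gc, pr_at)
    len <- 2L * spec$flank + spec$gene_length
    base <- if (spec$complexity < 1) {
      # Low-complexity background, as in CpG-island-class sequence: a small
      # tile vocabulary reused along the whole plasmid (so background k-mer
      # types recur genome-wide), softened by point substitutions.
      n_tiles <- max(4L, round(spec$complexity * 64))
      tiles <- replicate(n_tiles, paste(
        sample(c("A", "C", "G", "T"), sample(6:10, 1), replace = TRUE,
               prob = pr), collapse = ""))
      seq_str <- paste(sample(tiles, ceiling(len / 6), replace = TRUE),
                       collapse = "")
      out <- strsplit(substr(seq_str, 1L, len), "")[[1]]
      mut <- which(stats::runif(len) < 0.05)
      out[mut] <- sample(c("A", "C", "G", "T"), length(mut),
                         replace = TRUE, prob = pr)
      out
    } else {
      sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = pr)
    }
    b <- spec$flank + 1L
    cl <- cluster_positions(spec)
    comp <- sample.int(nrow(cl), spec$n_start_sites, replace = TRUE,
                       prob = cl$weight)
    start_off <- round(stats::rnorm(spec$n_start_sites, cl$mean_nt[comp],
                                    cl$sd_nt[comp]))
    start_sites <- sort(unique(
      b + pmin(pmax(start_off, spec$k), spec$gene_length %/% 2L)))
    start_sites <- thin_sites(start_sites, 2L * spec$k)
    # Termination sites follow the distribution implied by initiation plus a
    # typical footprint length; they are kept clear of initiation sites so
    # the two planted classes stay functionally distinct (a window around an
    # initiation site must not harvest a termination motif).
    comp2 <- sample.int(nrow(cl), spec$n_end_sites, replace = TRUE,
                        prob = cl$weight)
    end_off <- round(stats::rnorm(spec$n_end_sites,
                                  cl$mean_nt[comp2] + spec$mean_length,
                                  cl$sd_nt[comp2] + spec$mean_length / 6))
    end_sites <- sort(unique(
      b + pmin(pmax(end_off, spec$min_length + 2L * spec$k),
               spec$gene_length - 3L * spec$k)))
    end_sites <- thin_sites(end_sites, 3L * spec$k)
    clear <- purrr::map_lgl(end_sites, function(v) {
      all(abs(v - start_sites) > 40L)
    })
    end_sites <- end_sites[clear]
    plant <- function(pos, motif) {
      base[pos:(pos + nchar(motif) - 1L)] <<- strsplit(motif, "")[[1]]
    }
    # Each site carries the concatenation of its whole motif set (a
    # composite initiation/termination element), so every footprint
    # snapping to a site contributes to every planted k-mer equally and the
    # sliding windows still reach all copies after footprint lengths are
    # rounded to multiples of k.
    for (v in start_sites) plant(v, paste(spec$start_kmers, collapse = ""))
    for (v in end_sites) plant(v, paste(spec$end_kmers, collapse = ""))
    pl <- plasmid_sequence("synthetic", paste(base, collapse = ""),
                           gene_start = b,
                           gene_end = spec$flank + spec$gene_length)
    attr(pl, "start_sites") <- start_sites
    attr(pl, "end_sites") <- end_sites
    pl
  })
}

#' Generate synthetic R-loop footprints
#'
#' Initiation positions are drawn from the cluster mixture; with probability
#' `snap_prob` a footprint snaps to the nearest planted initiation motif so
#' the motif occupies its first k-mer. Lengths are `min_length` plus a
#' geometric number of k-blocks. With probability `snap_prob` the
#' termination snaps to a planted termination motif near the sampled end (so
#' the motif directly follows the footprint). Records are clipped to the
#' gene region. Raw footprint lengths are *not* multiples of k;
#' [preprocess_rloops()] performs that adjustment, as for experimental data.
#'
#' @param spec A [synthetic_spec()].
#' @param plasmid Plasmid from [generate_plasmid()] (same spec).
#' @param bed Optional path: write the footprints as BED.
#' @return Record tibble (`plasmid`, `topology`, `start`, `end`, `read_id`).
#' @export
generate_rloops <- function(spec, plasmid, bed = NULL) {
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  start_sites <- attr(plasmid, "start_sites")
  end_sites <- attr(plasmid, "end_sites")
  cl <- cluster_positions(spec)
  ds <- withr::with_seed(spec$seed + 1L, {
    n <- spec$n_rloops
    comp <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$weight)
    i0 <- b + round(stats::rnorm(n, cl$mean_nt[comp], cl$sd_nt[comp]))
    snap_i <- stats::runif(n) < spec$snap_prob
    nearest <- function(x, sites) {
      idx <- findInterval(x, sites)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(sites))
      ifelse(abs(x - sites[hi]) < abs(x - sites[lo]), sites[hi], sites[lo])
    }
    i <- ifelse(snap_i, nearest(i0, start_sites), i0)
    # single-molecule footprinting reads the boundaries imprecisely (up to
    # ~15 nt); the padding parameter p exists to absorb exactly this
    i <- i + round(stats::rnorm(n, 0, spec$boundary_sd))
    i <- pmin(pmax(i, b + spec$k), e - spec$min_length)
    blocks <- stats::rgeom(n, spec$k / (spec$mean_length - spec$min_length +
                                          spec$k))
    j0 <- i + spec$min_length - 1L + spec$k * blocks
    # Termination lands floor(k/2) nt short of the element so that rounding
    # the footprint length to a multiple of k (ties up, shifting j by up to
    # +k/2) never moves the element upstream of the footprint end.
    slack <- spec$k %/% 2L
    snap_j <- stats::runif(n) < spec$snap_prob
    j <- purrr::map2_int(j0, seq_len(n), function(jj, idx) {
      if (!snap_j[[idx]]) return(as.integer(jj))
      ok <- end_sites[end_sites - 1L - slack >= i[[idx]] + spec$min_length - 1L]
      if (length(ok) == 0L) return(as.integer(jj))
      as.integer(ok[which.min(abs(ok - 1L - jj))] - 1L - slack)
    })
    j <- j + round(stats::rnorm(n, 0, spec$boundary_sd))
    j <- pmin(pmax(j, i + spec$k - 1L), e)
    tibble(plasmid = plasmid$name, topology = spec$topology,
           start = as.integer(i), end = as.integer(j),
           read_id = as.character(seq_len(n)))
  })
  if (!is.null(bed)) write_rloop_bed(ds, bed)
  ds
}

#' Generate a complete synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with `plasmid`, `rloops` (raw records) and `spec`.
#' @export
generate_smrf_dataset <- function(spec) {
  plasmid <- generate_plasmid(spec)
  list(plasmid = plasmid, rloops = generate_rloops(spec, plasmid),
       spec = spec)
}
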