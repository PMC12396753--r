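#' Read single-molecule R-loop footprints from BED
#'
#' Each BED record is one R-loop interval on the plasmid. BED 0-based
#' half-open `[start, end)` coordinates are converted to internal 1-based
#' inclusive `[i, j] = [start + 1, end]`, the convention used by every
#' downstream formula. Records extending beyond the gene region are clipped
#' (with a warning); empty or inverted intervals are rejected with a message.
#'
#' @param path BED file with >= 3 columns; column 4, when present, is kept as
#'   a read identifier (several R-loops detected on one molecule share it).
#' @param plasmid A [plasmid_sequence()]; the BED `chrom` must match its name.
#' @param topology Label attached to every record, conventionally one of
#'   `"linear"`, `"supercoiled"`, `"hyper_negative"`.
#' @return A tibble with columns `plasmid`, `topology`, `start`, `end`,
#'   `read_id` (internal 1-based inclusive coordinates).
#' @export
read_rloop_bed <- function(path, plasmid, topology = "supercoiled") {
  raw <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file must have at least 3 columns", call. = FALSE)
  chrom <- as.character(raw[[1]])
  unknown <- setdiff(unique(chrom), plasmid$name)
  if (length(unknown) > 0L) {
    stop("BED chrom ", paste(unknown, collapse = ", "),
         " does not match plasmid '", plasmid$name, "'", call. = FALSE)
  }
  start0 <- as.integer(raw[[2]])
  end0 <- as.integer(raw[[3]])
  bad <- start0 >= end0
  if (any(bad)) {
    message(sum(bad), " BED record(s) rejected: start >= end (lines ",
            paste(utils::head(which(bad), 5L), collapse = ", "), " ...)")
  }
  ds <- tibble(
    plasmid = chrom[!bad],
    topology = topology,
    start = start0[!bad] + 1L,
    end = end0[!bad],
    read_id = if (ncol(raw) >= 4L) as.character(raw[[4]][!bad]) else
      as.character(seq_len(sum(!bad)))
  )
  clip_to_gene_region(ds, plasmid)
}

clip_to_gene_region <- function(ds, plasmid) {
  b <- plasmid$gene_start
  e <- plasmid$gene_end
  out <- ds[ds$plasmid != plasmid$name | (ds$end >= b & ds$start <= e), ,
            drop = FALSE]
  dropped <- nrow(ds) - nrow(out)
  if (dropped > 0L) {
    warning(dropped, " record(s) entirely outside the gene region dropped",
            call. = FALSE)
  }
  sel <- out$plasmid == plasmid$name
  clipped <- sel & (out$start < b | out$end > e)
  out$start[sel] <- pmax(out$start[sel], b)
  out$end[sel] <- pmin(out$end[sel], e)
  if (any(clipped)) {
    warning(sum(clipped), " record(s) clipped to the gene region [",
            b, ", ", e, "]", call. = FALSE)
  }
  as_tibble(out)
}

#' Write R-loop records as BED
#'
#' Inverse of [read_rloop_bed()]: internal 1-based inclusive `[i, j]` becomes
#' BED `[i - 1, j)`.
#'
#' @param ds Record tibble (`plasmid`, `start`, `end`, optional `read_id`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rloop_bed <- function(ds, path) {
  bed <- data.frame(
    chrom = ds$plasmid,
    start = ds$start - 1L,
    end = ds$end,
    name = if ("read_id" %in% names(ds)) ds$read_id else seq_len(nrow(ds))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Treat every footprint interval as an independent molecule
#'
#' A small fraction of single-molecule reads carries more than one R-loop;
#' the single-R-loop grammar treats each interval as if it came from a
#' separate molecule. Each interval becomes one record with a unique
#' `record_id`; the original `read_id` is retained for audit.
#'
#' @param ds Record tibble.
#' @return The same records with a unique `record_id` column; the number of
#'   output rows equals the total number of intervals.
#' @export
split_multi_rloop_reads <- function(ds) {
  dplyr::mutate(ds, record_id = dplyr::row_number())
}

#' Round each R-loop length to a multiple of k
#'
#' The parsing of the R-loop segment \[i, j\] into k-blocks requires the
#' length to be a multiple of k. Termination indices are adjusted minimally:
#' the length is rounded to the nearest multiple of k with ties rounded up; a
#' length that would round to zero is promoted to k; the new `j` is clipped
#' to the gene-region end and, if clipping breaks divisibility, rounded down
#' to the largest valid end. Records that cannot reach length k are dropped
#' with a message.
#'
#' @param ds Record tibble.
#' @param plasmid A [plasmid_sequence()].
#' @param k Block size (nucleotides).
#' @return Adjusted record tibble; every row satisfies
#'   `(end - start + 1) %% k == 0`.
#' @export
adjust_rloop_lengths <- function(ds, plasmid, k) {
  stopifnot(k >= 1)
  e <- plasmid$gene_end
  len <- ds$end - ds$start + 1L
  target <- k * pmax(1L, floor(len / k + 0.5))   # nearest multiple, ties up
  j <- ds$start - 1L + as.integer(target)
  over <- j > e
  j[over] <- ds$start[over] - 1L + k * ((e - ds$start[over] + 1L) %/% k)
  out <- dplyr::mutate(ds, end = as.integer(j))
  short <- out$end - out$start + 1L < k
  if (any(short)) {
    message(sum(short), " record(s) dropped: adjusted length < k")
    out <- out[!short, , drop = FALSE]
  }
  out
}

#' Full footprint pre-processing
#'
#' Clips records to the gene region, splits multi-R-loop reads into
#' independent records, rounds lengths to multiples of k, and drops
#' footprints without at least one full k-block of gene sequence on each
#' side (`start - b >= k`, `e - end >= k`): the grammar's start and end rule
#' families each emit at least one block, so such footprints admit no
#' derivation as words.
#'
#' @inheritParams adjust_rloop_lengths
#' @return Preprocessed record tibble.
#' @export
preprocess_rloops <- function(ds, plasmid, k) {
  out <- ds |>
    clip_to_gene_region(plasmid) |>
    split_multi_rloop_reads() |>
    adjust_rloop_lengths(plasmid, k)
  margin <- out$start - plasmid$gene_start >= k &
    plasmid$gene_end - out$end >= k
  if (any(!margin)) {
    message(sum(!margin), " record(s) dropped: no full k-block between ",
            "footprint and gene-region boundary")
  }
  out[margin, , drop = FALSE]
}

#' Split records into training and holdout sets
#'
#' Randomly reserves `round(holdout_frac * n)` records as a holdout set (the
#' protocol reserves one third); the rest form the full training dataset from
#' which per-model subsamples are drawn.
#'
#' @param ds Record tibble.
#' @param holdout_frac Fraction held out, in (0, 1); default 1/3.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with tibbles `train` and `holdout` (disjoint, exhaustive).
#' @export
split_train_holdout <- function(ds, holdout_frac = 1 / 3, seed = 1L) {
  n <- nrow(ds)
  if (n < 3L) stop("need at least 3 records to split", call. = FALSE)
  stopifnot(holdout_frac > 0, holdout_frac < 1)
  n_hold <- round(holdout_frac * n)
  idx <- withr::with_seed(seed, sample.int(n, n_hold))
  list(train = ds[-idx, , drop = FALSE], holdout = ds[idx, , drop = FALSE])
}
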