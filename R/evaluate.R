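#' Empirical per-nucleotide R-loop frequency
#'
#' The experimental probability that a nucleotide is inside an R-loop: the
#' number of footprints covering it divided by the number of footprints in
#' the set (coverage counting on inclusive intervals).
#'
#' @param ds Record tibble (e.g. a holdout set); must be nonempty.
#' @param plasmid A [plasmid_sequence()].
#' @return Tibble `position` (all of `[b, e]`), `prob`.
#' @export
empirical_track <- function(ds, plasmid) {
  if (nrow(ds) == 0L) stop("empty record set", call. = FALSE)
  cov <- IRanges::coverage(IRanges::IRanges(ds$start, ds$end),
                           width = plasmid$gene_end)
  pos <- seq.int(plasmid$gene_start, plasmid$gene_end)
  tibble(position = pos, prob = as.numeric(cov)[pos] / nrow(ds))
}

#' Compare a predicted track with an empirical track
#'
#' @param pred Predicted track (`position` plus `prob` or `mean`).
#' @param emp Empirical track from [empirical_track()]; must cover the same
#'   positions.
#' @return One-row tibble: `rmsd` (root mean square deviation), `pearson`
#'   (Pearson correlation; `NA` with a warning when either track is
#'   constant), `n_positions`.
#' @export
compare_tracks <- function(pred, emp) {
  x <- if ("prob" %in% names(pred)) pred$prob else pred$mean
  if (!identical(as.integer(pred$position), as.integer(emp$position))) {
    stop("tracks cover different position ranges", call. = FALSE)
  }
  y <- emp$prob
  pearson <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant track: Pearson correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(x, y)
  }
  tibble(rmsd = sqrt(mean((x - y)^2)), pearson = pearson,
         n_positions = length(x))
}

#' Three-fold cross-validation over a (k, p) parameter grid
#'
#' Partitions the records into three non-overlapping folds (sizes differing
#' by at most one). For each fold and each `(k, p)` pair, a model is trained
#' on the other two folds (via [ensemble_predict()]; by default one model on
#' the full training portion) and its track is compared with the validation
#' fold's empirical track. The best pair has the lowest mean RMSD, ties
#' broken by the highest mean Pearson correlation.
#'
#' @param ds Record tibble (single plasmid).
#' @param plasmid A [plasmid_sequence()].
#' @param k_grid,p_grid Parameter grids (protocol grid: k = 3,4,5; p = 7,13).
#' @param seed Master seed (fold assignment and model training).
#' @param n_models,subsample_frac,mode Passed to [ensemble_predict()];
#'   defaults train one model per fold on the whole training portion.
#' @param max_len Candidate length cap, passed through.
#' @return Tibble with one row per `(k, p, fold)`: `k`, `p`, `fold`, `rmsd`,
#'   `pearson`. Summarise with [select_best_params()].
#' @export
threefold_cv <- function(ds, plasmid, k_grid = c(3, 4, 5), p_grid = c(7, 13),
                         seed = 1L, n_models = 1L, subsample_frac = 1,
                         mode = "stochastic", max_len = NULL) {
  n <- nrow(ds)
  if (n < 3L) stop("need at least 3 records for 3 folds", call. = FALSE)
  fold <- withr::with_seed(seed, sample(rep_len(1:3, n)))
  grid <- tidyr::expand_grid(k = k_grid, p = p_grid, fold = 1:3)
  seeds <- derive_seeds(seed + 1L, nrow(grid))
  purrr::pmap_dfr(list(grid$k, grid$p, grid$fold, seeds),
                  function(k, p, f, s) {
    train <- ds[fold != f, , drop = FALSE]
    val <- ds[fold == f, , drop = FALSE]
    train_k <- preprocess_rloops(train, plasmid, k)
    ens <- ensemble_predict(train_k, plasmid, k = k, p = p,
                            n_models = n_models,
                            subsample_frac = subsample_frac, mode = mode,
                            seed = s, max_len = max_len)
    cmp <- compare_tracks(ens$tracks[[plasmid$name]],
                          empirical_track(val, plasmid))
    tibble(k = k, p = p, fold = f, rmsd = cmp$rmsd, pearson = cmp$pearson)
  })
}

#' Pick the best (k, p) pair from a cross-validation grid
#'
#' @param cv_grid Output of [threefold_cv()].
#' @return One-row tibble `k`, `p`, `mean_rmsd`, `mean_pearson` for the pair
#'   with lowest mean RMSD (ties: highest mean Pearson).
#' @export
select_best_params <- function(cv_grid) {
  cv_grid |>
    group_by(.data$k, .data$p) |>
    summarise(mean_rmsd = mean(.data$rmsd),
              mean_pearson = mean(.data$pearson), .groups = "drop") |>
    arrange(.data$mean_rmsd, dplyr::desc(.data$mean_pearson)) |>
    dplyr::slice(1L)
}

#' Summarise production-rule probabilities across topologies
#'
#' For ensembles trained per topology, summarises each rule's probability
#' distribution (median, quartiles, whiskers at 1.5 IQR) and optionally
#' tests per-rule differences between topologies with pairwise t-tests under
#' Bonferroni adjustment.
#'
#' @param ensembles Named list (topology -> `rloop_ensemble` or list of
#'   `rloop_grammar` models).
#' @return List with `summary` (tibble: `topology`, `rule`, `median`, `q1`,
#'   `q3`, `lo`, `hi`, `n_models`) and `tests` (tibble: `rule`, `group1`,
#'   `group2`, `p_adj`; `NULL` with fewer than two topologies).
#' @export
rule_probability_report <- function(ensembles) {
  probs <- purrr::imap_dfr(ensembles, function(ens, topo) {
    models <- if (inherits(ens, "rloop_ensemble")) ens$models else ens
    purrr::imap_dfr(models, function(m, idx) {
      dplyr::mutate(tidy(m), model = idx, topology = topo)
    })
  })
  summary <- probs |>
    group_by(.data$topology, .data$rule) |>
    summarise(
      median = stats::median(.data$prob),
      q1 = stats::quantile(.data$prob, 0.25),
      q3 = stats::quantile(.data$prob, 0.75),
      n_models = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      lo = pmax(.data$q1 - 1.5 * (.data$q3 - .data$q1), 0),
      hi = .data$q3 + 1.5 * (.data$q3 - .data$q1)
    )
  tests <- NULL
  if (length(unique(probs$topology)) >= 2L) {
    tests <- probs |>
      group_by(.data$rule) |>
      dplyr::group_modify(function(g, key) {
        if (stats::sd(g$prob) == 0) {
          combs <- utils::combn(unique(g$topology), 2L)
          return(tibble(group1 = combs[1L, ], group2 = combs[2L, ],
                        p_adj = 1))
        }
        pt <- stats::pairwise.t.test(g$prob, g$topology,
                                     p.adjust.method = "bonferroni")
        as_tibble(as.table(pt$p.value), .name_repair = ~ c(
          "group1", "group2", "p_adj")) |>
          filter(!is.na(.data$p_adj))
      }) |>
      ungroup()
  }
  list(summary = summary, tests = tests)
}
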