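#' The R-loop grammar alphabet and production rules
#'
#' The grammar annotates a gene region relative to one R-loop \[i, j\] with a
#' ten-letter terminal alphabet. `alpha` and `omega` mark the (possibly empty,
#' length 0..k-1) branch-migration segments at R-loop initiation and
#' termination. Outside the R-loop a k-mer block is a DNA:DNA duplex with a
#' free RNA transcript: `sigma` (prone to open), `sigma_hat` (stable),
#' `gamma` (no information), `delta` (ambiguous). Inside the R-loop a block is
#' an RNA:DNA hybrid with a displaced DNA strand: `tau` (prone to revert),
#' `tau_hat` (stable), `rho` (no information), `beta` (ambiguous).
#'
#' Three right-linear rule families generate every R-loop word:
#' \describe{
#'   \item{S-rules}{`S -> x S` and `S -> x alpha R` for `x` an outside symbol
#'     (the region before initiation).}
#'   \item{R-rules}{`R -> y R` and `R -> y omega Q` for `y` an inside symbol
#'     (the RNA:DNA hybrid).}
#'   \item{Q-rules}{`Q -> x Q` and the terminating `Q -> x` (the region after
#'     termination).}
#' }
#'
#' @return `rg_alphabet()` returns the 10 terminal symbols; `grammar_rules()`
#'   returns a tibble with one row per production rule (24 rules) and columns
#'   `lhs`, `terminal`, `role` (`"chain"` or `"transition"`) and `rule`, the
#'   display form of the rule.
#' @examples
#' rg_alphabet()
#' grammar_rules()
#' @export
rg_alphabet <- function() {
  c("alpha", "omega", .outside_symbols(), .inside_symbols())
}

.outside_symbols <- function() c("sigma", "sigma_hat", "gamma", "delta")
.inside_symbols <- function() c("tau", "tau_hat", "rho", "beta")

#' @rdname rg_alphabet
#' @export
grammar_rules <- function() {
  out <- .outside_symbols()
  ins <- .inside_symbols()
  rules <- dplyr::bind_rows(
    tibble(lhs = "S", terminal = out, role = "chain"),
    tibble(lhs = "S", terminal = out, role = "transition"),
    tibble(lhs = "R", terminal = ins, role = "chain"),
    tibble(lhs = "R", terminal = ins, role = "transition"),
    tibble(lhs = "Q", terminal = out, role = "chain"),
    tibble(lhs = "Q", terminal = out, role = "transition")
  )
  rules$rule <- rule_label(rules$lhs, rules$terminal, rules$role)
  rules
}

rule_label <- function(lhs, terminal, role) {
  rhs <- ifelse(
    role == "chain",
    paste(terminal, lhs),
    dplyr::case_when(
      lhs == "S" ~ paste(terminal, "alpha R"),
      lhs == "R" ~ paste(terminal, "omega Q"),
      TRUE ~ terminal
    )
  )
  paste(lhs, "->", rhs)
}
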