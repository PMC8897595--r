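#' Counts-per-million normalization
#'
#' `cpm_ij = count_ij / library_size_j * 1e6`. Library sizes default to
#' the column sums, in which case each column of the result sums to 1e6
#' exactly; explicit `lib_sizes` (e.g. the nominal sizes a simulation was
#' sampled at) are supported for offset-style normalization.
#'
#' @param counts numeric matrix, miRNAs x samples, raw counts >= 0.
#' @param lib_sizes optional named/ordered vector of library sizes, one
#'   per column; default `colSums(counts)`.
#' @return matrix of cpm values, same dimnames.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (length(lib_sizes) != ncol(counts))
    stop("need one library size per sample")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' log2(cpm + 1) expression values
#'
#' @inheritParams cpm
#' @return matrix of `log2(cpm + 1)` values.
#' @export
log2_cpm1 <- function(counts, lib_sizes = NULL) log2(cpm(counts, lib_sizes) + 1)

#' Classify miRNAs as AGO-loaded or unloaded from RIP vs input counts
#'
#' Re-implements the loading call: expression is `log2(cpm + 1)` per
#' sample; miRNAs passing the expression floor (default 5, i.e. about
#' 31 cpm) under the chosen scope form the eligible set, which is ranked
#' by `delta = x_rip - x_input` (descending; ties broken
#' lexicographically by id). The top `top_fraction` of the eligible set
#' (default 20%) is called `loaded_top`, the bottom `bottom_fraction`
#' `unloaded_bottom`, the remainder `neutral`; miRNAs failing the floor
#' are `below_floor`.
#'
#' @param counts raw count matrix with input and RIP columns.
#' @param input_col,rip_col column names (default `"input"`, `"rip"`).
#' @param top_fraction,bottom_fraction fractions of the eligible set
#'   called at each extreme; sizes are `floor(fraction * n_eligible)`,
#'   but at least 1 when any miRNA is eligible.
#' @param floor minimum `log2(cpm + 1)` expression (default 5).
#' @param floor_scope which sample(s) must meet the floor: `"either"`
#'   (default), `"input"`, `"rip"`, or `"both"`.
#' @param statistic ranking statistic: `"log2cpm_delta"` (default,
#'   difference of `log2(cpm+1)`) or `"cpm_ratio"`
#'   (`log2((cpm_rip + 0.5) / (cpm_input + 0.5))`).
#' @param lib_sizes optional explicit library sizes, see [cpm()].
#' @return `data.frame`: `mirna_id`, `x_input`, `x_rip`, `delta`,
#'   `class` in `{loaded_top, unloaded_bottom, neutral, below_floor}`.
#' @export
classify_loading <- function(counts, input_col = "input", rip_col = "rip",
                             top_fraction = 0.2, bottom_fraction = 0.2,
                             floor = 5.0,
                             floor_scope = c("either", "input", "rip", "both"),
                             statistic = c("log2cpm_delta", "cpm_ratio"),
                             lib_sizes = NULL) {
  floor_scope <- match.arg(floor_scope)
  statistic <- match.arg(statistic)
  if (top_fraction + bottom_fraction > 1)
    stop("top_fraction + bottom_fraction must not exceed 1")
  counts <- as.matrix(counts)
  stopifnot(all(c(input_col, rip_col) %in% colnames(counts)))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("mirna_%d", seq_len(nrow(counts)))

  x <- log2_cpm1(counts, lib_sizes)
  x_input <- x[, input_col]
  x_rip <- x[, rip_col]
  delta <- if (statistic == "log2cpm_delta") {
    x_rip - x_input
  } else {
    cp <- cpm(counts, lib_sizes)
    log2((cp[, rip_col] + 0.5) / (cp[, input_col] + 0.5))
  }

  eligible <- switch(floor_scope,
    either = x_input >= floor | x_rip >= floor,
    input  = x_input >= floor,
    rip    = x_rip >= floor,
    both   = x_input >= floor & x_rip >= floor)

  class <- rep("below_floor", length(ids))
  n_el <- sum(eligible)
  if (n_el >= 1L) {
    k_top <- max(1L, floor(top_fraction * n_el))
    k_bot <- max(1L, floor(bottom_fraction * n_el))
    if (k_top + k_bot > n_el) {        # tiny eligible sets: top wins first
      k_top <- min(k_top, n_el)
      k_bot <- n_el - k_top
    }
    el_idx <- which(eligible)
    ord <- el_idx[order(-delta[el_idx], ids[el_idx])]
    class[el_idx] <- "neutral"
    class[ord[seq_len(k_top)]] <- "loaded_top"
    if (k_bot > 0L)
      class[ord[(n_el - k_bot + 1L):n_el]] <- "unloaded_bottom"
  }
  data.frame(mirna_id = ids, x_input = unname(x_input),
             x_rip = unname(x_rip), delta = unname(delta), class = class,
             row.names = NULL)
}

#' Plot-ready table for the loading scatter
#'
#' Emits one row per miRNA with both expression axes, the loading class,
#' and a highlight flag for ids of interest (e.g. the miR-30a/d/e-3p
#' family).
#'
#' @param calls output of [classify_loading()].
#' @param highlight character vector of miRNA ids to flag.
#' @return `data.frame`: `mirna_id`, `x_input`, `x_rip`, `class`,
#'   `highlight`.
#' @export
loading_scatter_data <- function(calls, highlight = character(0)) {
  data.frame(mirna_id = calls$mirna_id, x_input = calls$x_input,
             x_rip = calls$x_rip, class = calls$class,
             highlight = calls$mirna_id %in% highlight)
}
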