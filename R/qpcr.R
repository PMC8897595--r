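#' ChIP-qPCR percent of input
#'
#' Assuming perfect per-cycle doubling, the input Ct is first adjusted
#' for the fraction of chromatin it represents
#' (`ct_input - log2(1 / input_fraction)`), then
#' `percent = 100 * 2^(adjusted_input_ct - ct_ip)`.
#'
#' @param ct_ip IP-sample Ct (cycles).
#' @param ct_input input-sample Ct (cycles).
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return percent of input (vectorized over the Ct arguments).
#' @examples
#' percent_input(25, 28, 0.10)  # 80
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Express a fold enrichment relative to a reference
#'
#' Plain ratio: control regions are expressed as enrichment over an
#' intergenic reference region, and satellite enrichment relative to the
#' wild-type pull-down, by dividing fold values.
#'
#' @param fold_target fold (or percent-input) value of the target.
#' @param fold_reference fold value of the reference; must be > 0.
#' @return `fold_target / fold_reference`.
#' @export
relative_to_reference <- function(fold_target, fold_reference) {
  if (any(fold_reference <= 0)) stop("reference fold must be positive")
  fold_target / fold_reference
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2^-[(ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c)]`
#' for a sample condition `s` against a control condition `c`, with a
#' reference (normalizer) gene measured in both.
#'
#' @param ct_target_s,ct_ref_s target and reference-gene Ct in the sample
#'   condition.
#' @param ct_target_c,ct_ref_c the same in the control condition.
#' @return fold change (vectorized).
#' @export
ddct_expression <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}

#' Recover per-target fold changes from a Ct table
#'
#' Averages technical replicates per (sample, target) and applies
#' [ddct_expression()] per target against the reference gene and control
#' condition. Exact round-trip of [gen_ct_table()] at zero noise.
#'
#' @param ct `data.frame` with `sample`, `target`, `ct` (and optionally
#'   `replicate`) columns.
#' @param reference_target reference (normalizer) gene name.
#' @param control_sample control-condition sample name.
#' @param treated_sample treated-condition sample name.
#' @return `data.frame`: `target`, `fold`.
#' @export
expression_folds <- function(ct, reference_target = "Gapdh",
                             control_sample = "control",
                             treated_sample = "treated") {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct)))
  mean_ct <- aggregate(ct ~ sample + target, data = ct, FUN = mean)
  get_ct <- function(s, tg) {
    v <- mean_ct$ct[mean_ct$sample == s & mean_ct$target == tg]
    if (length(v) != 1L)
      stop("missing Ct for sample '", s, "', target '", tg, "'")
    v
  }
  targets <- setdiff(unique(ct$target), reference_target)
  folds <- vapply(targets, function(tg) {
    ddct_expression(get_ct(treated_sample, tg),
                    get_ct(treated_sample, reference_target),
                    get_ct(control_sample, tg),
                    get_ct(control_sample, reference_target))
  }, numeric(1))
  data.frame(target = targets, fold = unname(folds), row.names = NULL)
}

#' Summarize replicate fold values per condition and test the difference
#'
#' Mean and SD per condition plus a two-sided unpaired t test between the
#' two conditions (Student by default, matching the usual "unpaired
#' t test"; Welch selectable).
#'
#' @param results `data.frame` with `condition` and `value` columns;
#'   exactly two conditions.
#' @param welch use the Welch (unequal-variance) variant?
#' @return list: `summary` (`data.frame`: `condition`, `n`, `mean`,
#'   `sd`), `t`, `df`, `p` (two-sided).
#' @export
summarize_replicates <- function(results, welch = FALSE) {
  stopifnot(all(c("condition", "value") %in% names(results)))
  conds <- unique(results$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions required, got ", length(conds))
  g1 <- results$value[results$condition == conds[1L]]
  g2 <- results$value[results$condition == conds[2L]]
  smry <- data.frame(condition = conds,
                     n = c(length(g1), length(g2)),
                     mean = c(mean(g1), mean(g2)),
                     sd = c(sd(g1), sd(g2)))
  if (sd(c(g1, g2)) == 0) {       # identical flat groups: no evidence
    return(list(summary = smry, t = 0, df = length(c(g1, g2)) - 2L, p = 1))
  }
  if (sd(g1) == 0 && sd(g2) == 0) {  # flat but different: infinite evidence
    return(list(summary = smry, t = Inf,
                df = length(c(g1, g2)) - 2L, p = 0))
  }
  tt <- t.test(g1, g2, var.equal = !welch, alternative = "two.sided")
  list(summary = smry, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
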