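#' Specification of a synthetic RIP/input small-RNA count table
#'
#' Emulates the structure of a matched AGO-RIP vs input small-RNA-seq
#' experiment: each miRNA has a baseline input abundance (nominal cpm) and
#' a planted log2 fold change in the RIP sample (positive for the enriched
#' set, negative for the depleted set, zero otherwise). Counts are sampled
#' independently per miRNA at the nominal library sizes, either
#' negative-binomially or (jointly) multinomially; dispersion 0 yields
#' deterministic rounded expected counts.
#'
#' @param n_mirnas number of miRNAs.
#' @param enriched_ids,depleted_ids disjoint character vectors of miRNA ids
#'   (ids are `sprintf("miR-%04d", 1:n)`).
#' @param base_expression nominal input cpm per miRNA; scalar or length-n
#'   vector; the default spreads a 1e6 total evenly.
#' @param effect_log2fc planted |log2 fold change| (RIP minus input).
#' @param library_size_input,library_size_rip nominal library sizes.
#' @param noise_model `"nb"` (negative binomial, `dispersion` as the NB
#'   dispersion, i.e. `size = 1/dispersion`) or `"multinomial"`.
#' @param dispersion NB dispersion; 0 switches noise off.
#' @param rng_seed integer seed.
#' @return a list of class `count_table_spec`.
#' @export
count_table_spec <- function(n_mirnas = 500L, enriched_ids = character(0),
                             depleted_ids = character(0),
                             base_expression = NULL, effect_log2fc = 2,
                             library_size_input = 2e6, library_size_rip = 2e6,
                             noise_model = c("nb", "multinomial"),
                             dispersion = 0.05, rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  ids <- sprintf("miR-%04d", seq_len(n_mirnas))
  if (length(intersect(enriched_ids, depleted_ids)))
    stop("enriched and depleted id sets overlap")
  if (!all(c(enriched_ids, depleted_ids) %in% ids))
    stop("unknown miRNA ids in enriched/depleted sets")
  if (library_size_input <= 0 || library_size_rip <= 0)
    stop("library sizes must be positive")
  if (is.null(base_expression)) base_expression <- 1e6 / n_mirnas
  base_expression <- rep_len(base_expression, n_mirnas)
  structure(list(n_mirnas = as.integer(n_mirnas), ids = ids,
                 enriched_ids = enriched_ids, depleted_ids = depleted_ids,
                 base_expression = base_expression,
                 effect_log2fc = effect_log2fc,
                 library_size_input = library_size_input,
                 library_size_rip = library_size_rip,
                 noise_model = noise_model, dispersion = dispersion,
                 rng_seed = as.integer(rng_seed)),
            class = "count_table_spec")
}

#' Generate a RIP/input count table with known enrichment truth
#'
#' @param spec a [count_table_spec()].
#' @return list with `counts` (integer matrix, miRNAs x `c("input","rip")`),
#'   `lib_sizes` (the nominal library sizes used for sampling) and `truth`
#'   (`data.frame`: `mirna_id`, `class` in
#'   `{enriched, depleted, neutral}`, `true_log2fc`, and the nominal
#'   expected cpm per sample).
#' @export
gen_count_table <- function(spec) {
  stopifnot(inherits(spec, "count_table_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_mirnas
  delta <- rep(0, n)
  delta[spec$ids %in% spec$enriched_ids] <- spec$effect_log2fc
  delta[spec$ids %in% spec$depleted_ids] <- -spec$effect_log2fc

  cpm_input <- spec$base_expression / sum(spec$base_expression) * 1e6
  cpm_rip <- cpm_input * 2^delta
  mu_input <- cpm_input / 1e6 * spec$library_size_input
  mu_rip <- cpm_rip / 1e6 * spec$library_size_rip

  draw <- function(mu, lib) {
    if (spec$noise_model == "multinomial") {
      as.integer(rmultinom(1, size = round(lib), prob = mu / sum(mu)))
    } else if (spec$dispersion <= 0) {
      as.integer(round(mu))
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
    }
  }
  counts <- cbind(input = draw(mu_input, spec$library_size_input),
                  rip = draw(mu_rip, spec$library_size_rip))
  rownames(counts) <- spec$ids
  cls <- ifelse(delta > 0, "enriched", ifelse(delta < 0, "depleted", "neutral"))
  list(counts = counts,
       lib_sizes = c(input = spec$library_size_input,
                     rip = spec$library_size_rip),
       truth = data.frame(mirna_id = spec$ids, class = cls,
                          true_log2fc = delta,
                          expected_cpm_input = cpm_input,
                          expected_cpm_rip = cpm_rip))
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Two conditions (control, treated) x (targets + one reference gene) x
#' replicates, assuming perfect per-cycle doubling: the treated-condition
#' target Ct sits `log2(true_fold)` cycles below the control-condition Ct,
#' the reference gene is flat across conditions, and i.i.d. Gaussian cycle
#' noise is added on top. A noiseless table is recovered exactly by
#' [expression_folds()].
#'
#' @param targets `data.frame` with columns `name`, `true_fold` (> 0) and
#'   `ct_reference` (the control-condition Ct of that target).
#' @param noise_sd SD of the additive Ct noise, in cycles.
#' @param rng_seed integer seed.
#' @param reference_target name of the reference (normalizer) gene.
#' @param reference_ct its Ct, identical in both conditions before noise.
#' @param n_replicates technical replicates per (sample, target).
#' @param samples names of the control and treated conditions.
#' @return list with `ct` (`data.frame`: `sample`, `target`, `assay`, `ct`,
#'   `replicate`) and `truth` (`data.frame`: `target`, `true_fold`).
#' @export
gen_ct_table <- function(targets, noise_sd = 0, rng_seed = 1L,
                         reference_target = "Gapdh", reference_ct = 18,
                         n_replicates = 3L,
                         samples = c(control = "control", treated = "treated")) {
  stopifnot(all(c("name", "true_fold", "ct_reference") %in% names(targets)))
  if (any(targets$true_fold <= 0)) stop("true_fold must be positive")
  set.seed(rng_seed)
  rows <- list()
  add <- function(sample, target, ct0) {
    data.frame(sample = sample, target = target, assay = "RT",
               ct = ct0 + rnorm(n_replicates, 0, noise_sd),
               replicate = seq_len(n_replicates))
  }
  for (s in c(samples[["control"]], samples[["treated"]])) {
    rows[[length(rows) + 1L]] <- add(s, reference_target, reference_ct)
    for (i in seq_len(nrow(targets))) {
      ct0 <- if (s == samples[["control"]]) targets$ct_reference[i] else
        targets$ct_reference[i] - log2(targets$true_fold[i])
      rows[[length(rows) + 1L]] <- add(s, targets$name[i], ct0)
    }
  }
  list(ct = do.call(rbind, rows),
       truth = data.frame(target = targets$name, true_fold = targets$true_fold))
}

#' Per-nucleus colocalized-foci counts under the scene model
#'
#' Count-level view of the image-scene generator: each nucleus carries a
#' Poisson number of marker foci, each independently colocalized with a
#' chromocenter with probability `p_coloc`. Used for statistical
#' calibration experiments where rendering full images adds nothing.
#'
#' @param n_nuclei nuclei per group.
#' @param foci_mean Poisson mean marker foci per nucleus.
#' @param p_coloc per-focus colocalization probability.
#' @return integer vector of per-nucleus colocalized counts.
#' @export
gen_coloc_counts <- function(n_nuclei, foci_mean = 15, p_coloc = 0.5) {
  n_foci <- rpois(n_nuclei, foci_mean)
  rbinom(n_nuclei, n_foci, p_coloc)
}
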