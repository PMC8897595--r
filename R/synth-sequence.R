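#' Specification of a synthetic tandem-repeat array
#'
#' Describes a mouse major-satellite-like tandem array: `n_units` copies of a
#' `unit_length`-bp monomer (234 bp by default, the major-satellite unit
#' size), AT-rich i.i.d. background, with target-site motifs planted at fixed
#' offsets inside the unit so ground-truth site counts are exact.
#'
#' @param unit_length monomer length in bp (default 234).
#' @param n_units number of tandem copies.
#' @param gc_fraction background GC content in `[0, 1]`; default 0.36,
#'   an AT-rich composition typical of pericentromeric satellite.
#' @param planted_sites `data.frame` with columns `motif` (DNA string),
#'   `offset_in_unit` (1-based start position of the motif inside each
#'   unit), `every_k_units` (plant in units 1, 1+k, 1+2k, ...).
#' @param rng_seed integer seed; the generator is fully deterministic
#'   given the spec.
#' @return a list of class `tandem_repeat_spec`.
#' @export
tandem_repeat_spec <- function(unit_length = 234L, n_units = 100L,
                               gc_fraction = 0.36,
                               planted_sites = NULL, rng_seed = 1L) {
  if (is.null(planted_sites)) {
    planted_sites <- data.frame(motif = character(0),
                                offset_in_unit = integer(0),
                                every_k_units = integer(0))
  }
  stopifnot(unit_length >= 0, n_units >= 0,
            gc_fraction >= 0, gc_fraction <= 1,
            all(c("motif", "offset_in_unit", "every_k_units") %in%
                  names(planted_sites)))
  planted_sites$motif <- toupper(planted_sites$motif)
  if (nrow(planted_sites)) {
    if (!all(is_dna(planted_sites$motif)))
      stop("planted motifs must be ACGT only")
    if (any(planted_sites$offset_in_unit < 1L))
      stop("offset_in_unit is 1-based and must be >= 1")
    if (any(planted_sites$offset_in_unit + nchar(planted_sites$motif) - 1L >
              unit_length))
      stop("planted motif extends past the unit boundary")
    if (any(planted_sites$every_k_units < 1L))
      stop("every_k_units must be >= 1")
  }
  structure(list(unit_length = as.integer(unit_length),
                 n_units = as.integer(n_units),
                 gc_fraction = gc_fraction,
                 planted_sites = planted_sites,
                 rng_seed = as.integer(rng_seed)),
            class = "tandem_repeat_spec")
}

#' Generate a tandem-repeat sequence with planted seed sites
#'
#' Builds the array unit by unit: i.i.d. background at the spec's GC
#' fraction with each planted motif written at its offset in the scheduled
#' units. Background positions that spuriously re-create a planted motif
#' outside the truth positions are redrawn (locally, bounded attempts), so
#' every planted motif occurs in the output exactly at its truth positions.
#' Spurious occurrences of *other* motifs are left alone.
#'
#' @param spec a [tandem_repeat_spec()].
#' @param max_attempts bound on redraw rounds before giving up.
#' @return list with `sequence` (single DNA string, length
#'   `unit_length * n_units`) and `truth` (`data.frame` of planted sites:
#'   `motif`, `unit`, `offset_in_unit`, `start` -- 1-based position in the
#'   full sequence -- and `strand`, always `"+"`).
#' @export
gen_tandem_repeat <- function(spec, max_attempts = 1000L) {
  stopifnot(inherits(spec, "tandem_repeat_spec"))
  set.seed(spec$rng_seed)
  L <- spec$unit_length * spec$n_units
  if (L == 0L) {
    return(list(sequence = "",
                truth = data.frame(motif = character(0), unit = integer(0),
                                   offset_in_unit = integer(0),
                                   start = integer(0), strand = character(0))))
  }
  ps <- spec$planted_sites
  truth <- do.call(rbind, c(list(
    data.frame(motif = character(0), unit = integer(0),
               offset_in_unit = integer(0), start = integer(0))),
    lapply(seq_len(nrow(ps)), function(i) {
      units <- seq.int(1L, spec$n_units, by = ps$every_k_units[i])
      data.frame(motif = ps$motif[i], unit = units,
                 offset_in_unit = ps$offset_in_unit[i],
                 start = (units - 1L) * spec$unit_length + ps$offset_in_unit[i])
    })))

  chars <- sample_bases(L, spec$gc_fraction)
  planted_mask <- logical(L)  # positions owned by planted motifs
  for (r in seq_len(nrow(truth))) {
    idx <- truth$start[r]:(truth$start[r] + nchar(truth$motif[r]) - 1L)
    if (any(planted_mask[idx]) &&
        !identical(chars[idx], strsplit(truth$motif[r], "")[[1]])) {
      # overlapping planted motifs must agree where they overlap
      prev <- chars[idx]
      new <- strsplit(truth$motif[r], "")[[1]]
      if (any(planted_mask[idx] & prev != new))
        stop("planted motifs overlap inconsistently")
    }
    chars[idx] <- strsplit(truth$motif[r], "")[[1]]
    planted_mask[idx] <- TRUE
  }

  motifs <- unique(truth$motif)
  for (attempt in seq_len(max_attempts)) {
    seq_str <- paste(chars, collapse = "")
    spurious <- NULL
    for (m in motifs) {
      hits <- find_sites(seq_str, m)
      planted_here <- truth$start[truth$motif == m]
      extra <- setdiff(hits, planted_here)
      if (length(extra))
        spurious <- rbind(spurious, cbind(start = extra, len = nchar(m)))
    }
    if (is.null(spurious)) {
      return(list(sequence = seq_str,
                  truth = cbind(truth, strand = rep("+", nrow(truth)))))
    }
    fixable <- FALSE
    for (j in seq_len(nrow(spurious))) {
      idx <- spurious[j, "start"]:(spurious[j, "start"] + spurious[j, "len"] - 1L)
      free <- idx[!planted_mask[idx]]
      if (length(free)) {
        chars[free] <- sample_bases(length(free), spec$gc_fraction)
        fixable <- TRUE
      }
    }
    if (!fixable)
      stop("spurious motif occurrence lies entirely inside planted sites; ",
           "motif too permissive to reject")
  }
  stop("failed to remove spurious motif occurrences after ", max_attempts,
       " attempts")
}

#' Write synthetic repeat annotations in RepeatMasker dialects
#'
#' Emits either the classic RepeatMasker `.out` alignment summary (1-based
#' inclusive query coordinates, three header lines) or the UCSC `rmsk`
#' database table dump (tab-separated, 0-based half-open `genoStart`).
#' Coordinates in `regions` use the package-internal convention
#' (0-based half-open) and are converted on write; parsing the file back
#' with [parse_annotations()] recovers them exactly.
#'
#' @param regions `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `repeat_name`, `strand` (`"+"`/`"-"`), optionally
#'   `repeat_class` (default `"Satellite"`) and `score`.
#' @param file output path.
#' @param dialect `"out"` or `"ucsc_table"`.
#' @return `file`, invisibly.
#' @export
gen_repeatmasker_file <- function(regions, file, dialect = c("out", "ucsc_table")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("chrom", "start", "end", "repeat_name", "strand") %in%
                  names(regions)))
  if (nrow(regions) && any(regions$start >= regions$end))
    stop("regions must satisfy start < end")
  if (nrow(regions) && !all(regions$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  rclass <- if ("repeat_class" %in% names(regions)) regions$repeat_class else
    rep("Satellite", nrow(regions))
  score <- if ("score" %in% names(regions)) regions$score else
    rep(10000L, nrow(regions))

  if (dialect == "out") {
    hdr <- c(
      "   SW   perc perc perc  query     position in query    matching repeat      position in repeat",
      "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family  begin end (left) ID",
      "")
    lines <- hdr
    if (nrow(regions)) {
      body <- vapply(seq_len(nrow(regions)), function(i) {
        sprintf("%6d  %4.1f  %3.1f  %3.1f  %s  %d %d (%d) %s %s %s %d %d (%d) %d",
                as.integer(score[i]), 1.0, 0.0, 0.0,
                regions$chrom[i],
                regions$start[i] + 1L, regions$end[i], 0L,
                if (regions$strand[i] == "+") "+" else "C",
                regions$repeat_name[i], rclass[i],
                1L, regions$end[i] - regions$start[i], 0L, i)
      }, character(1))
      lines <- c(lines, body)
    }
    writeLines(lines, file)
  } else {
    if (nrow(regions) == 0L) {
      writeLines(character(0), file)
      return(invisible(file))
    }
    df <- data.frame(
      bin = 0L, swScore = as.integer(score), milliDiv = 10L, milliDel = 0L,
      milliIns = 0L, genoName = regions$chrom, genoStart = regions$start,
      genoEnd = regions$end, genoLeft = 0L, strand = regions$strand,
      repName = regions$repeat_name, repClass = rclass, repFamily = rclass,
      repStart = 1L, repEnd = regions$end - regions$start, repLeft = 0L,
      id = seq_len(nrow(regions)))
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
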