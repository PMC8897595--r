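#' Parse RepeatMasker annotations
#'
#' Reads either the classic RepeatMasker `.out` alignment summary or the
#' UCSC `rmsk` database table dump and normalizes both to the internal
#' coordinate convention (0-based, half-open). `.out` query coordinates
#' are 1-based inclusive; `rmsk` `genoStart`/`genoEnd` are already
#' 0-based half-open. Header and comment lines are skipped; malformed
#' lines raise an error naming the line.
#'
#' @param file path to the annotation file.
#' @param dialect `"out"` or `"ucsc_table"`.
#' @return `data.frame` with `annotation_id` (file order), `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`),
#'   `repeat_name`, `repeat_class`, `score`.
#' @export
parse_annotations <- function(file, dialect = c("out", "ucsc_table")) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  if (dialect == "out") {
    # skip the banner: header lines don't start with a numeric SW score
    body <- grepl("^\\s*\\d", lines)
    lines <- lines[body]
    if (!length(lines)) return(empty_annotations())
    fields <- strsplit(trimws(lines), "\\s+")
    rows <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 11L)
        stop("malformed .out line ", which(body)[i], ": expected >= 11 fields, got ",
             length(f))
      beg <- suppressWarnings(as.integer(f[6L]))
      end <- suppressWarnings(as.integer(f[7L]))
      if (is.na(beg) || is.na(end))
        stop("malformed .out line ", which(body)[i],
             ": non-integer query begin/end (columns 6-7)")
      data.frame(chrom = f[5L],
                 start = beg - 1L,           # 1-based inclusive -> 0-based
                 end = end,
                 strand = if (f[9L] == "C") "-" else "+",
                 repeat_name = f[10L],
                 repeat_class = f[11L],
                 score = as.numeric(f[1L]))
    })
    ann <- do.call(rbind, rows)
  } else {
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) return(empty_annotations())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    rows <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 12L)
        stop("malformed rmsk table line ", i, ": expected >= 12 fields, got ",
             length(f))
      st <- suppressWarnings(as.integer(f[7L]))
      en <- suppressWarnings(as.integer(f[8L]))
      if (is.na(st) || is.na(en))
        stop("malformed rmsk table line ", i,
             ": non-integer genoStart/genoEnd (columns 7-8)")
      data.frame(chrom = f[6L], start = st, end = en, strand = f[10L],
                 repeat_name = f[11L], repeat_class = f[12L],
                 score = as.numeric(f[2L]))
    })
    ann <- do.call(rbind, rows)
  }
  if (any(ann$start < 0L | ann$start >= ann$end))
    stop("annotation with invalid interval (start < 0 or start >= end)")
  cbind(annotation_id = seq_len(nrow(ann)), ann)
}

empty_annotations <- function() {
  data.frame(annotation_id = integer(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             repeat_name = character(0), repeat_class = character(0),
             score = numeric(0))
}

#' Filter annotations by repeat name
#'
#' Exact-name match by default (`"GSAT_MM"`, the mouse major-satellite
#' label); set `glob = TRUE` to interpret the pattern as a shell glob.
#'
#' @param annotations output of [parse_annotations()].
#' @param name_pattern repeat name or glob pattern.
#' @param glob interpret `name_pattern` as a glob?
#' @return the matching subset, row order preserved.
#' @export
filter_by_name <- function(annotations, name_pattern = "GSAT_MM",
                           glob = FALSE) {
  keep <- if (glob) {
    grepl(utils::glob2rx(name_pattern), annotations$repeat_name)
  } else {
    annotations$repeat_name == name_pattern
  }
  annotations[keep, , drop = FALSE]
}

#' Select long satellite regions from annotations
#'
#' Merges same-chromosome annotations whose gaps are at most `merge_gap`
#' bp apart (the default 0 merges only bookended/overlapping annotations,
#' i.e. is pure per-annotation filtering for separated hits) and keeps
#' merged regions of at least `min_length` bp -- the "at least 20 kb"
#' rule used to pick the four analysed major-satellite regions. Strand is
#' ignored for merging. Output is sorted by (chrom, start) and retains
#' the contributing annotation ids.
#'
#' @param annotations output of [parse_annotations()] (typically after
#'   [filter_by_name()]).
#' @param min_length minimum merged-region length in bp (default 20000).
#' @param merge_gap maximum gap, in bp, bridged when merging (default 0).
#' @return `data.frame`: `region_id` (`chrom:start-end`), `chrom`,
#'   `start`, `end`, `length`, `source_annotation_ids` (comma-separated).
#' @export
select_regions <- function(annotations, min_length = 20000L, merge_gap = 0L) {
  if (merge_gap < 0L) stop("merge_gap must be non-negative")
  if (nrow(annotations) == 0L) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0),
                      source_annotation_ids = character(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    source_annotation_ids = vapply(revmap, function(i)
      paste(sort(annotations$annotation_id[i]), collapse = ","), character(1)))
  out$length <- out$end - out$start
  out <- out[out$length >= min_length, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
               out[, c("chrom", "start", "end", "length",
                       "source_annotation_ids")])
  rownames(out) <- NULL
  out
}

#' Attach genomic sequences to selected regions
#'
#' Extracts each region's sequence from a FASTA file (uppercased) and
#' verifies the extracted length. Regions on contigs absent from the
#' FASTA, or extending past a contig end, raise an error listing the
#' offenders.
#'
#' @param regions output of [select_regions()].
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @return `regions` with a `sequence` column appended.
#' @export
attach_sequences <- function(regions, fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(regions$chrom), names(seqs))
  if (length(missing))
    stop("contigs missing from FASTA: ", paste(missing, collapse = ", "))
  too_long <- regions$end > Biostrings::width(seqs)[match(regions$chrom,
                                                          names(seqs))]
  if (any(too_long))
    stop("regions extend past contig end: ",
         paste(regions$region_id[too_long], collapse = ", "))
  regions$sequence <- vapply(seq_len(nrow(regions)), function(i) {
    toupper(as.character(Biostrings::subseq(seqs[[regions$chrom[i]]],
                                            start = regions$start[i] + 1L,
                                            end = regions$end[i])))
  }, character(1))
  stopifnot(all(nchar(regions$sequence) == regions$length))
  regions
}
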