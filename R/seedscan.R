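#' Derive a target-site motif from a mature miRNA sequence
#'
#' The canonical seed-site taxonomy: an 8mer site is the perfect
#' Watson-Crick match to miRNA positions 2-8 with an adenine opposite
#' position 1; on the target DNA read 5'->3' that is the reverse
#' complement of positions 2-8 followed by `"A"`. The 7mer-m8 drops the
#' trailing A; the 7mer-A1 pairs only positions 2-7, again with the
#' terminal A.
#'
#' @param mirna_id miRNA name (e.g. `"miR-30a-3p"`).
#' @param mature_sequence mature miRNA, 5'->3', RNA alphabet (ACGU; T is
#'   accepted and read as U), length >= 8.
#' @param site_type one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`.
#' @return `data.frame` with `mirna_id`, `site_type`, `motif` (DNA,
#'   read 5'->3' on the target strand).
#' @examples
#' seed_motif("miR-x", "UGGAAGACUAGGUU")  # motif GTCTTCCA
#' @export
seed_motif <- function(mirna_id, mature_sequence,
                       site_type = c("8mer", "7mer-m8", "7mer-A1")) {
  site_type <- match.arg(site_type)
  seq <- toupper(rna_to_dna(mature_sequence))
  if (grepl("[^ACGT]", seq))
    stop("mature sequence of ", mirna_id, " contains non-ACGU characters")
  if (nchar(seq) < 8L)
    stop("mature sequence of ", mirna_id, " is shorter than 8 nt")
  motif <- switch(site_type,
    "8mer"    = paste0(revcomp_dna(substr(seq, 2L, 8L)), "A"),
    "7mer-m8" = revcomp_dna(substr(seq, 2L, 8L)),
    "7mer-A1" = paste0(revcomp_dna(substr(seq, 2L, 7L)), "A"))
  data.frame(mirna_id = mirna_id, site_type = site_type, motif = motif)
}

# 1-based start positions of all (overlapping) exact occurrences of motif.
# N in the sequence never matches.
find_sites <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m == 0L) stop("empty motif")
  if (n < m) return(integer(0))
  s <- charToRaw(toupper(sequence))
  mo <- charToRaw(toupper(motif))
  hit <- s[seq_len(n - m + 1L)] == mo[1L]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      hit <- hit & (s[(1L + k):(n - m + 1L + k)] == mo[1L + k])
    }
  }
  which(hit)
}

#' Count seed-site occurrences in a sequence
#'
#' Slides the motif along the sequence and counts every (possibly
#' overlapping) exact occurrence; `N` bases never match. With
#' `strand_mode = "both"` the reverse complement of the sequence is
#' scanned as well and counts are reported per strand.
#'
#' @param sequence DNA string (ACGTN).
#' @param motif DNA motif string, or the one-row `data.frame` returned by
#'   [seed_motif()].
#' @param strand_mode `"annotated"` (scan the given strand only) or
#'   `"both"`.
#' @return named integer vector: `c("+" = n)` for `"annotated"`,
#'   `c("+" = n_fwd, "-" = n_rev)` for `"both"`.
#' @export
count_sites <- function(sequence, motif, strand_mode = c("annotated", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (is.data.frame(motif)) motif <- motif$motif
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) > 0L)
  fwd <- length(find_sites(sequence, motif))
  if (strand_mode == "annotated") return(c("+" = fwd))
  rev <- length(find_sites(revcomp_dna(sequence), motif))
  c("+" = fwd, "-" = rev)
}

#' Scan satellite regions for seed sites of a set of miRNAs
#'
#' Derives one motif per miRNA (identical mature sequences give identical
#' motifs, hence identical counts) and counts occurrences in every
#' region's sequence.
#'
#' @param mirnas `data.frame` with `mirna_id` and `mature_sequence`.
#' @param regions `data.frame` of regions carrying a `sequence` column
#'   (see [attach_sequences()]) and a `region_id` column.
#' @param site_type passed to [seed_motif()].
#' @param strand_mode passed to [count_sites()]; default `"both"` since
#'   major satellites are transcribed from both strands.
#' @return `data.frame` (the site-count table): `mirna_id`, `site_type`,
#'   `motif`, `region_id`, `strand`, `count` -- one row per
#'   miRNA x region x scanned strand.
#' @export
scan_regions <- function(mirnas, regions, site_type = "8mer",
                         strand_mode = c("both", "annotated")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(all(c("mirna_id", "mature_sequence") %in% names(mirnas)))
  if (nrow(mirnas) == 0L) {
    return(data.frame(mirna_id = character(0), site_type = character(0),
                      motif = character(0), region_id = character(0),
                      strand = character(0), count = integer(0)))
  }
  stopifnot(all(c("region_id", "sequence") %in% names(regions)))
  if (any(is.na(regions$sequence) | regions$sequence == ""))
    stop("all regions must carry an attached sequence")
  motifs <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i)
    seed_motif(mirnas$mirna_id[i], mirnas$mature_sequence[i], site_type)))
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    rows <- lapply(seq_len(nrow(regions)), function(j) {
      cts <- count_sites(regions$sequence[j], motifs$motif[i], strand_mode)
      data.frame(mirna_id = motifs$mirna_id[i], site_type = site_type,
                 motif = motifs$motif[i], region_id = regions$region_id[j],
                 strand = names(cts), count = unname(as.integer(cts)))
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank miRNAs by total seed-site count
#'
#' Totals counts over regions and strands, sorts descending, and breaks
#' ties lexicographically by miRNA id so the ranking is deterministic.
#' The per-region breakdown is retained as a wide table.
#'
#' @param table a site-count table from [scan_regions()].
#' @param top_n how many miRNAs to keep (`Inf` for all; a `top_n` larger
#'   than the table returns the full ranking).
#' @return `data.frame`: `rank`, `mirna_id`, `total`, plus one
#'   `count.<region_id>` column per region (summed over strands).
#' @export
rank_mirnas <- function(table, top_n = 5L) {
  if (nrow(table) == 0L) {
    return(data.frame(rank = integer(0), mirna_id = character(0),
                      total = integer(0)))
  }
  tot <- aggregate(count ~ mirna_id, data = table, FUN = sum)
  names(tot)[2L] <- "total"
  byreg <- aggregate(count ~ mirna_id + region_id, data = table, FUN = sum)
  wide <- reshape(byreg, idvar = "mirna_id", timevar = "region_id",
                  direction = "wide")
  out <- merge(tot, wide, by = "mirna_id", sort = FALSE)
  out <- out[order(-out$total, out$mirna_id), , drop = FALSE]
  out <- head(out, n = min(top_n, nrow(out)))
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Read mature miRNA records
#'
#' Accepts a FASTA file of mature sequences (RNA or DNA alphabet; T is
#' read as U) or a two-column tab-separated file (`id<TAB>sequence`, no
#' header).
#'
#' @param file path.
#' @param format `"fasta"` or `"tsv"`; guessed from the extension by
#'   default.
#' @return `data.frame` with `mirna_id`, `mature_sequence` (RNA alphabet).
#' @export
read_mirnas <- function(file, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", file, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(file)
    data.frame(mirna_id = names(ss),
               mature_sequence = toupper(dna_to_rna(as.character(ss))),
               row.names = NULL)
  } else {
    df <- read.table(file, sep = "\t", header = FALSE,
                     col.names = c("mirna_id", "mature_sequence"),
                     stringsAsFactors = FALSE)
    df$mature_sequence <- toupper(dna_to_rna(df$mature_sequence))
    df
  }
}
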