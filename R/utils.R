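#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rbinom rnbinom rmultinom runif quantile
#'   wilcox.test t.test sd aggregate reshape
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) !grepl("[^ACGT]", x)

#' Reverse complement of a DNA string
#'
#' Plain character-level reverse complement used throughout the seed-site
#' scanner. Uppercase ACGTN only; N complements to N.
#'
#' @param x a single DNA string.
#' @return the reverse complement, same case-normalised alphabet.
#' @export
revcomp_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) stop("revcomp_dna: non-ACGTN character in input")
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# draw n iid bases at a given GC fraction
sample_bases <- function(n, gc_fraction) {
  if (n == 0L) return(character(0))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}
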