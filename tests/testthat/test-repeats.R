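make_ann <- function(chrom, start, end) {
  n <- length(start)
  data.frame(annotation_id = seq_len(n), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = rep("+", n), repeat_name = rep("GSAT_MM", n),
             repeat_class = rep("Satellite", n), score = rep(100, n))
}

test_that("both dialects normalize to the same 0-based half-open interval", {
  regs <- data.frame(chrom = "chr9", start = 100L, end = 334L,
                     repeat_name = "GSAT_MM", strand = "+")
  f_out <- withr::local_tempfile()
  f_ucsc <- withr::local_tempfile()
  gen_repeatmasker_file(regs, f_out, "out")
  gen_repeatmasker_file(regs, f_ucsc, "ucsc_table")
  # the .out file carries 1-based inclusive coordinates on disk
  body <- grep("^\\s*\\d", readLines(f_out), value = TRUE)
  expect_match(body, " 101 334 ")
  a_out <- parse_annotations(f_out, "out")
  a_ucsc <- parse_annotations(f_ucsc, "ucsc_table")
  for (a in list(a_out, a_ucsc)) {
    expect_equal(a$start, 100L)
    expect_equal(a$end, 334L)
    expect_equal(a$end - a$start, 234L)
  }
})

test_that("malformed annotation lines are reported with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("header", "junk line", "10 1.0 0.0 0.0 chr1 xx 200 (0) + GSAT_MM Satellite 1 100 (0) 1"), f)
  expect_error(parse_annotations(f, "out"), "line 3")
  f2 <- withr::local_tempfile()
  writeLines("too\tfew\tcolumns", f2)
  expect_error(parse_annotations(f2, "ucsc_table"), "expected >= 12")
})

test_that("name filtering keeps exact matches only, unless a glob is asked", {
  ann <- make_ann(rep("chr1", 3), c(0, 500, 1000), c(100, 600, 1100))
  ann$repeat_name <- c("GSAT_MM", "SYNREP_MM", "GSAT_MM")
  expect_equal(nrow(filter_by_name(ann)), 2)
  expect_equal(nrow(filter_by_name(ann[0, ])), 0)
  expect_equal(nrow(filter_by_name(ann, "*_MM", glob = TRUE)), 3)

  set.seed(5)
  big <- make_ann(rep("chr1", 1000), seq(0, by = 1000, length.out = 1000),
                  seq(500, by = 1000, length.out = 1000))
  big$repeat_name <- paste0("REP_", sample(1e6, 1000))
  planted <- sample(1000, 37)
  big$repeat_name[planted] <- "GSAT_MM"
  expect_equal(nrow(filter_by_name(big)), 37)
})

test_that("region selection applies the 20 kb threshold and merge gap", {
  ann <- make_ann(rep("chr1", 3), c(0, 50000, 100000),
                  c(25000, 69999, 150000))
  sel <- select_regions(ann)
  expect_equal(sel$length, c(25000, 50000))

  ann2 <- make_ann(rep("chr2", 2), c(0, 15100), c(15000, 30100))
  expect_equal(nrow(select_regions(ann2, merge_gap = 0)), 0)
  sel2 <- select_regions(ann2, merge_gap = 500)
  expect_equal(sel2$length, 30100)
  expect_equal(sel2$source_annotation_ids, "1,2")

  expect_error(select_regions(ann, merge_gap = -1), "non-negative")
})

test_that("region selection equals the quadratic merge-filter oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(5:25, 1)
    chrom <- sample(c("chr1", "chr2", "chrX"), n, replace = TRUE)
    start <- sample(0:60000, n)
    len <- sample(500:30000, n, replace = TRUE)
    ann <- make_ann(chrom, start, start + len)
    gap <- sample(c(0, 100, 5000), 1)
    minl <- sample(c(10000, 20000), 1)
    got <- select_regions(ann, min_length = minl, merge_gap = gap)
    want <- oracle_select_regions(ann, min_length = minl, merge_gap = gap)
    expect_equal(got[c("chrom", "start", "end")], want,
                 info = paste("seed", seed))
  }
})

test_that("region selection is idempotent and regions stay disjoint", {
  set.seed(77)
  ann <- make_ann(rep("chr1", 30), sample(0:200000, 30),
                  sample(0:200000, 30) + 25000)
  ann$end <- ann$start + sample(1000:40000, 30, replace = TRUE)
  sel <- select_regions(ann, min_length = 5000, merge_gap = 200)
  again <- select_regions(
    data.frame(annotation_id = seq_len(nrow(sel)), chrom = sel$chrom,
               start = sel$start, end = sel$end, strand = "+",
               repeat_name = "GSAT_MM", repeat_class = "Satellite",
               score = 0),
    min_length = 5000, merge_gap = 200)
  expect_equal(again[c("chrom", "start", "end")],
               sel[c("chrom", "start", "end")])
  by_chr <- split(sel, sel$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("sequences are attached and validated against the FASTA", {
  seqs <- Biostrings::DNAStringSet(c(chrA = "ACGTACGTAC", chrB = "TTTTTTTTTT"))
  regions <- data.frame(region_id = "chrA:0-10", chrom = "chrA",
                        start = 0L, end = 10L, length = 10L,
                        source_annotation_ids = "1")
  out <- attach_sequences(regions, seqs)
  expect_equal(out$sequence, "ACGTACGTAC")

  beyond <- transform(regions, end = 12L, length = 12L)
  expect_error(attach_sequences(beyond, seqs), "past contig end")
  missing <- transform(regions, chrom = "chrZ")
  expect_error(attach_sequences(missing, seqs), "chrZ")
})

test_that("generated satellite FASTA round-trips through extraction", {
  sp <- tandem_repeat_spec(unit_length = 100, n_units = 30, rng_seed = 8,
                           planted_sites = data.frame(
                             motif = "TTAGGGTT", offset_in_unit = 20,
                             every_k_units = 1))
  tr <- gen_tandem_repeat(sp)
  f <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ctg1 = tr$sequence)), f)
  regions <- data.frame(region_id = "ctg1:0-3000", chrom = "ctg1",
                        start = 0L, end = 3000L, length = 3000L,
                        source_annotation_ids = "1")
  out <- attach_sequences(regions, f)
  expect_identical(out$sequence, tr$sequence)
})
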