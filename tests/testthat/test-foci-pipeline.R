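# a small, quick scene used by several tests
small_spec <- function(..., chromocenters_per_nucleus = 8,
                       marker_foci_per_nucleus = 5) {
  image_scene_spec(image_shape = c(256L, 256L), n_nuclei = 2L,
                   nucleus_radius_px = c(45, 50),
                   chromocenters_per_nucleus = chromocenters_per_nucleus,
                   marker_foci_per_nucleus = marker_foci_per_nucleus, ...)
}

test_that("scene generation is deterministic given the spec seed", {
  a <- gen_nuclear_images(small_spec(rng_seed = 5))
  b <- gen_nuclear_images(small_spec(rng_seed = 5))
  expect_identical(a, b)
  c <- gen_nuclear_images(small_spec(rng_seed = 6))
  expect_false(identical(a$dapi, c$dapi))
})

test_that("truth is identical regardless of the number of z slices", {
  a <- gen_nuclear_images(small_spec(rng_seed = 7, z_slices = 1L))
  b <- gen_nuclear_images(small_spec(rng_seed = 7, z_slices = 5L))
  expect_identical(a$truth, b$truth)
  expect_equal(dim(b$dapi)[3], 5)
})

test_that("full colocalization pins every focus to a chromocenter center", {
  sc <- gen_nuclear_images(small_spec(rng_seed = 8, p_coloc = 1, snr = 1000,
                                      chromocenters_per_nucleus = 15,
                                      marker_foci_per_nucleus = 5))
  expect_true(all(sc$truth$foci$colocalized))
  cc <- sc$truth$chromocenters
  d <- vapply(seq_len(nrow(sc$truth$foci)), function(i) {
    f <- sc$truth$foci[i, ]
    min(sqrt((cc$row - f$row)^2 + (cc$col - f$col)^2))
  }, numeric(1))
  expect_true(all(d <= 1))
})

test_that("zero colocalization keeps foci away from chromocenters", {
  sc <- gen_nuclear_images(small_spec(rng_seed = 9, p_coloc = 0))
  expect_false(any(sc$truth$foci$colocalized))
  cc <- sc$truth$chromocenters
  r_cc <- 4
  d <- vapply(seq_len(nrow(sc$truth$foci)), function(i) {
    f <- sc$truth$foci[i, ]
    min(sqrt((cc$row - f$row)^2 + (cc$col - f$col)^2))
  }, numeric(1))
  expect_true(all(d >= 2 * r_cc))
})

test_that("planted foci are local maxima of the emitted image", {
  sc <- gen_nuclear_images(small_spec(rng_seed = 10, snr = 50))
  img <- max_project(sc$marker)
  for (i in seq_len(nrow(sc$truth$foci))) {
    f <- sc$truth$foci[i, ]
    win <- img[(f$row - 4):(f$row + 4), (f$col - 4):(f$col + 4)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_true(max(abs(peak - 5)) <= 1, label = paste("focus", i))
  }
})

test_that("nuclei are segmented with centroids on the planted positions", {
  sc <- gen_nuclear_images(small_spec(rng_seed = 12))
  seg <- segment_nuclei(max_project(sc$dapi))
  expect_equal(nrow(seg$nuclei), 2)
  for (i in seq_len(2)) {
    d <- sqrt((sc$truth$nuclei$row - seg$nuclei$centroid_row[i])^2 +
                (sc$truth$nuclei$col - seg$nuclei$centroid_col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("border-touching nuclei are discarded when asked", {
  img <- matrix(0, 120, 120)
  img[1:30, 40:70] <- 1       # touches row 1
  img[60:100, 40:80] <- 1     # interior
  p <- pipeline_params(nucleus_diameter_px = c(20, 60))
  seg <- segment_nuclei(img, p)
  expect_equal(nrow(seg$nuclei), 1)
  expect_false(seg$nuclei$border_touching)
  p2 <- pipeline_params(nucleus_diameter_px = c(20, 60),
                        discard_border_nuclei = FALSE)
  expect_equal(nrow(segment_nuclei(img, p2)$nuclei), 2)
})

test_that("a noise-only image yields zero nuclei with a warning", {
  set.seed(71)
  img <- matrix(runif(64 * 64, 0, 0.02), 64, 64)
  expect_warning(seg <- segment_nuclei(img), "no nuclei")
  expect_equal(nrow(seg$nuclei), 0)
})

test_that("the full chain recovers per-nucleus colocalized counts", {
  ok <- 0L
  tot <- 0L
  for (seed in 101:103) {
    sc <- gen_nuclear_images(image_scene_spec(rng_seed = seed))
    q <- quantify_scene(sc$dapi, sc$marker)
    tr <- sc$truth
    expect_equal(nrow(q$nuclei), nrow(tr$nuclei))
    for (i in seq_len(nrow(q$nuclei))) {
      d <- sqrt((tr$nuclei$row - q$nuclei$centroid_row[i])^2 +
                  (tr$nuclei$col - q$nuclei$centroid_col[i])^2)
      tn <- which.min(d)
      t_col <- sum(tr$foci$colocalized[tr$foci$nucleus_id == tn])
      got <- q$counts$n_marker_colocalized[
        q$counts$nucleus_id == q$nuclei$nucleus_id[i]]
      tot <- tot + 1L
      if (abs(got - t_col) <= 1) ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("recovered colocalization tracks the planted fraction", {
  # count-level view of the scene model: monotone in p_coloc
  set.seed(72)
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p)
    mean(gen_coloc_counts(200, 15, p)), numeric(1))
  expect_true(all(diff(means) > 0))

  # scene endpoints through the imaging chain
  lo <- gen_nuclear_images(small_spec(rng_seed = 14, p_coloc = 0))
  hi <- gen_nuclear_images(small_spec(rng_seed = 14, p_coloc = 1))
  q_lo <- quantify_scene(lo$dapi, lo$marker)
  q_hi <- quantify_scene(hi$dapi, hi$marker)
  expect_gt(mean(q_hi$counts$n_marker_colocalized),
            mean(q_lo$counts$n_marker_colocalized))
  expect_lte(mean(q_lo$counts$n_marker_colocalized), 1)
})

test_that("scenes round-trip through TIFF stacks and truth CSV", {
  sc <- gen_nuclear_images(small_spec(rng_seed = 15))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, "t")
  dapi <- read_image_stack(paths[["dapi"]])
  marker <- read_image_stack(paths[["marker"]])
  expect_equal(dim(dapi), dim(sc$dapi))
  expect_equal(dapi, sc$dapi, tolerance = 1e-9)
  expect_equal(marker, sc$marker, tolerance = 1e-9)
  tr <- read.csv(paths[["truth"]])
  expect_equal(sum(tr$object == "nucleus"), nrow(sc$truth$nuclei))
  expect_equal(sum(tr$object == "focus"), nrow(sc$truth$foci))
  expect_equal(sum(tr$colocalized[tr$object == "focus"]),
               sum(sc$truth$foci$colocalized))
})
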