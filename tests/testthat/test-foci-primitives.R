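test_that("max projection is the per-pixel maximum over z", {
  one <- array(runif(64), dim = c(8, 8, 1))
  expect_equal(max_project(one), one[, , 1])
  two <- array(c(1:16, 16:1), dim = c(4, 4, 2))
  expect_equal(max_project(two), pmax(two[, , 1], two[, , 2]))
  set.seed(61)
  st <- array(runif(20 * 15 * 5), dim = c(20, 15, 5))
  expect_equal(max_project(st), oracle_max_project(st))
})

test_that("Otsu separates a two-valued image and flags constants", {
  img <- matrix(c(rep(0, 50), rep(1000, 14)), 8, 8)
  thr <- otsu_threshold(img)
  expect_gt(as.numeric(thr), 0)
  expect_lt(as.numeric(thr), 1000)
  expect_equal(sum(img > as.numeric(thr)), 14)

  flat <- matrix(7, 5, 5)
  thr2 <- otsu_threshold(flat)
  expect_equal(as.numeric(thr2), 7)
  expect_false(attr(thr2, "foreground"))
})

test_that("Otsu equals the exhaustive 256-candidate search", {
  set.seed(62)
  for (i in 1:30) {
    img <- matrix(sample(0:255, 300, replace = TRUE,
                         prob = runif(256)^2), 20, 15)
    expect_equal(as.numeric(otsu_threshold(img)), oracle_otsu(img),
                 info = paste("case", i))
  }
})

test_that("speckle enhancement is a white top-hat", {
  flat <- matrix(3.2, 20, 20)
  expect_equal(enhance_speckles(flat, 7), matrix(0, 20, 20))

  # a bright spot smaller than the element survives, background drops out
  img <- matrix(0.1, 31, 31)
  img[14:18, 14:18] <- 0.9
  enh <- enhance_speckles(img, 15)
  expect_equal(enh[16, 16], 0.8)
  expect_equal(enh[2, 2], 0)

  set.seed(63)
  for (k in c(5, 9)) {
    img <- matrix(runif(30 * 25), 30, 25)
    brush <- EBImage::makeBrush(k, "disc")
    expect_equal(enhance_speckles(img, k), oracle_top_hat(img, brush),
                 info = paste("element", k))
  }
})

test_that("robust background threshold trims then adds SDs", {
  expect_equal(robust_background_threshold(rep(7, 100)), 7)
  # pixels 1..100, 5% trims: retain 6..95; mean 50.5; population SD
  v <- 6:95
  expected <- mean(v) + 2 * sqrt(mean((v - mean(v))^2))
  expect_equal(robust_background_threshold(1:100), expected)
  expect_equal(expected, 102.458, tolerance = 1e-3)

  thrs <- vapply(c(0, 1, 2, 4), function(k)
    robust_background_threshold(1:100, n_sd = k), numeric(1))
  expect_true(all(diff(thrs) > 0))
  expect_error(robust_background_threshold(1:2, 0.5, 0.5), "trimming")
})

test_that("component labeling equals flood fill for both connectivities", {
  set.seed(64)
  for (i in 1:15) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4L, 8L)) {
      got <- majsat:::label_components(mask, conn)
      want <- oracle_label(mask, conn)
      # same partition: labels must map 1:1
      expect_equal(got > 0, want > 0)
      if (max(want) > 0) {
        expect_equal(max(got), max(want))
        tab <- table(got[got > 0], want[want > 0])
        expect_true(all(rowSums(tab > 0) == 1))
        expect_true(all(colSums(tab > 0) == 1))
      }
    }
  }
})

test_that("foci detection gates by circular-equivalent area", {
  img <- matrix(0, 64, 64)
  img[10:11, 10:11] <- 1          # area 4 < pi*(5/2)^2: gated out
  img[30:40, 30:40] <- 1          # area 121, within [19.6, 962]
  det <- detect_foci(img, diameter_range = c(5, 35))
  expect_equal(nrow(det$foci), 1)
  expect_equal(det$foci$area, 121)
  expect_equal(det$foci$centroid_row, 35)

  empty <- matrix(0, 32, 32)
  expect_equal(nrow(detect_foci(empty, diameter_range = c(5, 35))$foci), 0)
})

test_that("intensity is measured on the original image, not the enhanced", {
  enh <- matrix(0, 32, 32)
  enh[10:14, 10:14] <- 1
  orig <- matrix(0.2, 32, 32)
  orig[10:14, 10:14] <- 0.7
  det <- detect_foci(enh, original = orig, diameter_range = c(3, 20))
  expect_equal(det$foci$mean_intensity, 0.7)
  expect_equal(det$foci$integrated_intensity, 0.7 * 25)
})

test_that("object relation rules agree with the per-pixel oracle", {
  # child fully inside a parent: both rules agree
  parents <- matrix(0L, 20, 20)
  parents[2:10, 2:10] <- 1L
  parents[12:19, 12:19] <- 2L
  kids <- matrix(0L, 20, 20)
  kids[4:6, 4:6] <- 1L
  kid_df <- data.frame(focus_id = 1L, centroid_row = 5, centroid_col = 5)
  expect_equal(relate_objects(kid_df, kids, parents, "centroid_in_parent"), 1L)
  expect_equal(relate_objects(kid_df, kids, parents, "max_overlap"), 1L)

  # centroid on background but 40% overlap: NA vs parent
  kids2 <- matrix(0L, 20, 20)
  kids2[9:13, 4:8] <- 1L          # rows 9,10 inside parent 1, rest outside
  cent <- c(mean(9:13), mean(4:8))
  kid2_df <- data.frame(focus_id = 1L, centroid_row = cent[1],
                        centroid_col = cent[2])
  expect_true(is.na(relate_objects(kid2_df, kids2, parents,
                                   "centroid_in_parent")))
  expect_equal(relate_objects(kid2_df, kids2, parents, "max_overlap"), 1L)

  set.seed(65)
  for (i in 1:10) {
    pl <- oracle_label(matrix(runif(625) < 0.4, 25, 25), 8L)
    cl <- oracle_label(matrix(runif(625) < 0.2, 25, 25), 8L)
    if (max(cl) == 0 || max(pl) == 0) next
    meas <- majsat:::measure_objects(cl)
    kid_df <- data.frame(focus_id = meas$label,
                         centroid_row = meas$centroid_row,
                         centroid_col = meas$centroid_col)
    for (rule in c("centroid_in_parent", "max_overlap")) {
      expect_equal(relate_objects(kid_df, cl, pl, rule),
                   unname(oracle_relate(cl, pl, rule)),
                   info = paste(i, rule))
    }
  }
})

test_that("group comparison gives exact small-sample Mann-Whitney p values", {
  same <- compare_groups(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5))
  expect_equal(same$p, 1)

  sep <- compare_groups(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$U, 9)
  expect_equal(sep$p, 0.1)
  expect_equal(oracle_mw_exact_p(c(5, 6, 7), c(1, 2, 3)), 0.1)
  expect_equal(sep$method, "exact")

  doubled <- compare_groups(2 * c(5, 6, 7), 2 * c(1, 2, 3))
  expect_equal(doubled$U, sep$U)
  expect_equal(doubled$p, sep$p)
})

test_that("group comparison matches the enumeration oracle on random draws", {
  set.seed(66)
  for (i in 1:10) {
    a <- sample(1:100, 4)
    b <- sample(101:200, 5) - sample(0:120, 5)
    if (any(duplicated(c(a, b)))) next
    cg <- compare_groups(a, b)
    expect_equal(cg$p, oracle_mw_exact_p(a, b), tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("group summaries report median and quartiles", {
  cg <- compare_groups(c(1, 2, 3, 4, 100), c(7, 7, 7))
  expect_equal(cg$groups$median, c(3, 7))
  expect_equal(cg$groups$q1[1], unname(quantile(c(1, 2, 3, 4, 100), 0.25)))
  expect_true(all(cg$groups$q1 <= cg$groups$median))
  expect_true(all(cg$groups$median <= cg$groups$q3))
})
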