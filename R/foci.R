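#' Default parameters of the foci-quantification chain
#'
#' Mirrors the standard CellProfiler-style settings for this kind of
#' quantification (RobustBackground Global thresholding for foci; typical
#' object diameters 5-35 px for DAPI foci, 7-35 px for the marker channel) and
#' exposes the remaining knobs with documented defaults: Otsu nuclei with
#' a 40-200 px diameter gate and border removal standing in for manual
#' nucleus editing, white top-hat speckle enhancement, and a
#' deterministic centroid-in-parent relation rule.
#'
#' The top-hat element (default 15 px) is sized for the foci actually
#' present (up to ~10 px) rather than the 35 px gate maximum: the opening
#' undershoots wherever the element overhangs the nuclear rim, so an
#' element of diameter `k` turns the rim into a bright annulus about
#' `k/2` px wide that swallows peripheral foci when `k` is large.
#'
#' @param nucleus_diameter_px `(min, max)` nucleus diameter gate in px.
#' @param discard_border_nuclei drop nuclei touching the image border?
#' @param speckle_feature_size_px disk diameter of the top-hat element.
#' @param foci_threshold RobustBackground parameters
#'   (`trim_low`, `trim_high`, `n_sd`).
#' @param dapi_foci_diameter_px,marker_foci_diameter_px `(min, max)`
#'   typical object diameters per channel, in px.
#' @param relation_rule `"centroid_in_parent"` or `"max_overlap"`.
#' @return a named list of parameters.
#' @export
pipeline_params <- function(nucleus_diameter_px = c(40, 200),
                            discard_border_nuclei = TRUE,
                            speckle_feature_size_px = 15L,
                            foci_threshold = list(trim_low = 0.05,
                                                  trim_high = 0.05,
                                                  n_sd = 2),
                            dapi_foci_diameter_px = c(5, 35),
                            marker_foci_diameter_px = c(7, 35),
                            relation_rule = c("centroid_in_parent",
                                              "max_overlap")) {
  stopifnot(nucleus_diameter_px[1] < nucleus_diameter_px[2],
            dapi_foci_diameter_px[1] < dapi_foci_diameter_px[2],
            marker_foci_diameter_px[1] < marker_foci_diameter_px[2],
            foci_threshold$trim_low >= 0, foci_threshold$trim_low < 0.5,
            foci_threshold$trim_high >= 0, foci_threshold$trim_high < 0.5)
  list(nucleus_diameter_px = nucleus_diameter_px,
       discard_border_nuclei = discard_border_nuclei,
       speckle_feature_size_px = speckle_feature_size_px,
       foci_threshold = foci_threshold,
       dapi_foci_diameter_px = dapi_foci_diameter_px,
       marker_foci_diameter_px = marker_foci_diameter_px,
       relation_rule = match.arg(relation_rule))
}

#' Maximum-intensity z-projection
#'
#' @param stack 3D array (rows x cols x z) or a 2D matrix (returned
#'   unchanged).
#' @return 2D matrix of per-pixel maxima over z.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3L)
  apply(stack, c(1L, 2L), max)
}

#' Otsu threshold over a 256-bin histogram
#'
#' Bins the image's intensity range into 256 equal-width bins and returns
#' the bin boundary maximizing the between-class variance; ties break to
#' the lowest qualifying threshold. Foreground is `image > threshold`.
#' A constant image is degenerate: the constant is returned with
#' attribute `foreground = FALSE`.
#'
#' @param image numeric matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold value; attribute `foreground` is `FALSE` when the
#'   image is constant.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0)
    return(structure(rng[1L], foreground = FALSE))
  bin <- pmin(floor((v - rng[1L]) / diff(rng) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, n_bins)
  p <- h / length(v)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-n_bins])     # lowest maximizer among bins 1..n-1
  structure(rng[1L] + k / n_bins * diff(rng), foreground = TRUE)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a small union-find, then relabeled
# densely in first-pixel (column-major) order.
label_components <- function(mask, connectivity = 8L) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  n_lab <- max(lab)
  if (n_lab == 0L) return(lab)
  if (connectivity == 8L && n_lab > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n_lab)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (i in seq_len(nrow(pairs))) {
        a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(n_lab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_dense(lab)
}

# relabel positive labels as 1..K in order of first (column-major) pixel
relabel_dense <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  first <- tapply(pos, lab[pos], min)
  old <- as.integer(names(first))[order(first)]
  map <- integer(max(old))
  map[old] <- seq_along(old)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# per-label area, centroid (row, col; 1-based), border flag, intensities
measure_objects <- function(lab, intensity = NULL) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      border_touching = logical(0),
                      mean_intensity = numeric(0),
                      integrated_intensity = numeric(0)))
  }
  H <- nrow(lab); W <- ncol(lab)
  l <- lab[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(l)
  labs <- which(area > 0L)
  cr <- as.numeric(rowsum(rows, l)[, 1] / area[labs])
  cc <- as.numeric(rowsum(cols, l)[, 1] / area[labs])
  border <- as.logical(rowsum(as.numeric(rows == 1L | rows == H |
                                           cols == 1L | cols == W), l)[, 1] > 0)
  out <- data.frame(label = labs, area = area[labs],
                    centroid_row = cr, centroid_col = cc,
                    border_touching = border)
  if (!is.null(intensity)) {
    tot <- as.numeric(rowsum(intensity[idx], l)[, 1])
    out$mean_intensity <- tot / out$area
    out$integrated_intensity <- tot
  }
  out
}

# drop labels not in `keep` and relabel densely; returns list(lab, map)
# where map[new] = old
filter_labels <- function(lab, keep) {
  lab[!(lab %in% keep)] <- 0L
  relabel_dense(lab)
}

#' Segment nuclei from a projected DAPI image
#'
#' Otsu binarization, hole filling, 8-connected components, an area gate
#' derived from the nucleus diameter range (`pi * (d/2)^2`), and optional
#' removal of border-touching objects (the automated stand-in for manual
#' nucleus editing).
#'
#' @param dapi_projection 2D numeric matrix (max-projected DAPI).
#' @param params a [pipeline_params()] list.
#' @return list: `nuclei` (`data.frame`: `nucleus_id`, `area`,
#'   `centroid_row`, `centroid_col`, `border_touching`) and `labels`
#'   (integer label matrix matching `nucleus_id`). Zero nuclei after
#'   gating is returned (with a warning), not an error.
#' @export
segment_nuclei <- function(dapi_projection, params = pipeline_params()) {
  thr <- otsu_threshold(dapi_projection)
  if (identical(attr(thr, "foreground"), FALSE)) {
    warning("constant image: no nuclei found")
    return(list(nuclei = empty_nuclei(), labels = matrix(0L,
      nrow(dapi_projection), ncol(dapi_projection))))
  }
  mask <- dapi_projection > as.numeric(thr)
  mask <- matrix(as.numeric(EBImage::fillHull(
    matrix(as.numeric(mask), nrow(mask)))), nrow(mask))
  lab <- label_components(mask)
  meas <- measure_objects(lab)
  gate <- pi * (params$nucleus_diameter_px / 2)^2
  keep <- meas$label[meas$area >= gate[1] & meas$area <= gate[2]]
  if (params$discard_border_nuclei)
    keep <- setdiff(keep, meas$label[meas$border_touching])
  if (!length(keep)) {
    warning("no nuclei passed the size/border gates")
    return(list(nuclei = empty_nuclei(),
                labels = matrix(0L, nrow(lab), ncol(lab))))
  }
  lab <- filter_labels(lab, keep)
  meas <- measure_objects(lab)
  nuclei <- data.frame(nucleus_id = meas$label, area = meas$area,
                       centroid_row = meas$centroid_row,
                       centroid_col = meas$centroid_col,
                       border_touching = meas$border_touching)
  list(nuclei = nuclei, labels = lab)
}

empty_nuclei <- function() {
  data.frame(nucleus_id = integer(0), area = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             border_touching = logical(0))
}

#' White top-hat speckle enhancement
#'
#' Image minus its morphological (grayscale) opening with a disk
#' structuring element of the given diameter: bright features smaller
#' than the element are kept, larger structures (e.g. the nuclear body)
#' are suppressed. Output is clamped at 0.
#'
#' @param image 2D numeric matrix.
#' @param feature_size_px disk diameter in px (rounded up to odd).
#' @return enhanced matrix, same size, all values >= 0.
#' @export
enhance_speckles <- function(image, feature_size_px = 15L) {
  k <- as.integer(feature_size_px)
  if (k < 1L) stop("feature size must be >= 1 px")
  if (k %% 2L == 0L) k <- k + 1L
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0, nrow(image), ncol(image)))
  brush <- EBImage::makeBrush(k, shape = "disc")
  # grayscale morphology is affine-equivariant; work on [0, 1] because the
  # morphology backend clamps intensities to that range
  scaled <- (image - rng[1L]) / diff(rng)
  opened <- matrix(as.numeric(EBImage::opening(scaled, brush)),
                   nrow(image)) * diff(rng) + rng[1L]
  pmax(image - opened, 0)
}

#' RobustBackground threshold
#'
#' Sorts the pixels, discards the `trim_low` and `trim_high` fractions at
#' the extremes (`floor(trim * n)` pixels each), and returns
#' `mean + n_sd * SD` of the remainder (population SD, denominator `n`).
#' The Global strategy applies one such threshold to the whole image.
#'
#' @param pixels numeric vector or matrix of intensities.
#' @param trim_low,trim_high trimmed fractions in `[0, 0.5)`.
#' @param n_sd number of SDs above the trimmed mean (default 2).
#' @return threshold value.
#' @export
robust_background_threshold <- function(pixels, trim_low = 0.05,
                                        trim_high = 0.05, n_sd = 2) {
  v <- sort(as.numeric(pixels))
  n <- length(v)
  lo <- floor(trim_low * n)
  hi <- floor(trim_high * n)
  if (lo + hi >= n) stop("trimming removed all pixels")
  v <- v[(lo + 1L):(n - hi)]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  m + n_sd * s
}

#' Detect foci in a speckle-enhanced image
#'
#' Global RobustBackground binarization of the enhanced image,
#' 8-connected components, and a circular-equivalent area gate
#' `[pi*(dmin/2)^2, pi*(dmax/2)^2]`. Intensities are measured on the
#' *original* (pre-enhancement) image.
#'
#' @param enhanced output of [enhance_speckles()].
#' @param original the un-enhanced projected image (intensity source);
#'   defaults to `enhanced`.
#' @param diameter_range `(min, max)` typical object diameter in px.
#' @param threshold_params list with `trim_low`, `trim_high`, `n_sd`.
#' @param restrict_to_mask optional logical/0-1 matrix; detection is
#'   confined to its nonzero pixels (the threshold itself stays global).
#' @param connectivity pixel connectivity for component labeling; the
#'   default 4 matches the reference tool's labeling of foci and keeps
#'   diagonal chains of near-threshold noise from bridging neighbouring
#'   foci.
#' @return list: `foci` (`data.frame`: `focus_id`, `area`,
#'   `centroid_row`, `centroid_col`, `mean_intensity`,
#'   `integrated_intensity`) and `labels` (label matrix).
#' @export
detect_foci <- function(enhanced, original = enhanced,
                        diameter_range = c(5, 35),
                        threshold_params = list(trim_low = 0.05,
                                                trim_high = 0.05, n_sd = 2),
                        restrict_to_mask = NULL, connectivity = 4L) {
  thr <- robust_background_threshold(enhanced,
                                     threshold_params$trim_low,
                                     threshold_params$trim_high,
                                     threshold_params$n_sd)
  mask <- enhanced > thr
  if (!is.null(restrict_to_mask)) mask <- mask & (restrict_to_mask != 0)
  lab <- label_components(mask, connectivity = connectivity)
  meas <- measure_objects(lab, intensity = original)
  gate <- pi * (diameter_range / 2)^2
  keep <- meas$label[meas$area >= gate[1] & meas$area <= gate[2]]
  lab <- filter_labels(lab, keep)
  meas <- measure_objects(lab, intensity = original)
  foci <- data.frame(focus_id = meas$label, area = meas$area,
                     centroid_row = meas$centroid_row,
                     centroid_col = meas$centroid_col,
                     mean_intensity = meas$mean_intensity,
                     integrated_intensity = meas$integrated_intensity)
  list(foci = foci, labels = lab)
}

#' Relate child objects to parent objects
#'
#' `"centroid_in_parent"`: a child's parent is the parent object whose
#' mask contains the child's centroid pixel (rounded to the nearest
#' pixel), `NA` over background. `"max_overlap"`: the parent sharing the
#' most pixels with the child, ties to the lower parent id, `NA` when
#' there is no overlap with any parent.
#'
#' @param children `data.frame` of child objects (needs `centroid_row`,
#'   `centroid_col` and the id column named by `id_col`).
#' @param child_labels integer label matrix of the children.
#' @param parent_labels integer label matrix of the parents.
#' @param rule relation rule.
#' @param id_col name of the child id column (default `"focus_id"`).
#' @return integer vector of parent ids, aligned with `children` rows
#'   (`NA` = no parent).
#' @export
relate_objects <- function(children, child_labels, parent_labels,
                           rule = c("centroid_in_parent", "max_overlap"),
                           id_col = "focus_id") {
  rule <- match.arg(rule)
  if (nrow(children) == 0L) return(integer(0))
  if (rule == "centroid_in_parent") {
    r <- pmin(pmax(round(children$centroid_row), 1L), nrow(parent_labels))
    c_ <- pmin(pmax(round(children$centroid_col), 1L), ncol(parent_labels))
    p <- parent_labels[cbind(r, c_)]
    return(ifelse(p > 0L, p, NA_integer_))
  }
  vapply(children[[id_col]], function(cid) {
    pix <- child_labels == cid
    pl <- parent_labels[pix]
    pl <- pl[pl > 0L]
    if (!length(pl)) return(NA_integer_)
    tab <- tabulate(pl)
    as.integer(which.max(tab))        # which.max: lowest id wins ties
  }, integer(1))
}

#' Per-nucleus focus and colocalization counts
#'
#' For each nucleus: the number of DAPI foci (chromocenters), the number
#' of marker foci, and the number of marker foci whose DAPI-focus parent
#' is set (the colocalized count of the imaging readout).
#'
#' @param marker_foci marker focus `data.frame` carrying
#'   `parent_nucleus_id` and `parent_dapi_focus_id` columns.
#' @param dapi_foci DAPI focus `data.frame` carrying `parent_nucleus_id`.
#' @param nuclei nucleus `data.frame` from [segment_nuclei()].
#' @return `data.frame`: `nucleus_id`, `n_dapi_foci`, `n_marker_foci`,
#'   `n_marker_colocalized`.
#' @export
colocalized_counts <- function(marker_foci, dapi_foci, nuclei) {
  ids <- nuclei$nucleus_id
  cnt <- function(x) vapply(ids, function(i) sum(x == i, na.rm = TRUE),
                            integer(1))
  data.frame(
    nucleus_id = ids,
    n_dapi_foci = cnt(dapi_foci$parent_nucleus_id),
    n_marker_foci = cnt(marker_foci$parent_nucleus_id),
    n_marker_colocalized = vapply(ids, function(i)
      sum(marker_foci$parent_nucleus_id == i &
            !is.na(marker_foci$parent_dapi_focus_id), na.rm = TRUE),
      integer(1)))
}

#' Compare per-nucleus counts between two groups
#'
#' Two-sided Mann-Whitney U test (exact null when `n1 * n2 <= 400` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction) plus median and quartiles (linear
#' interpolation, R's default type 7) per group.
#'
#' @param counts_a,counts_b numeric vectors of per-nucleus counts.
#' @param labels group labels, length 2.
#' @return list: `groups` (`data.frame`: `group`, `n`, `median`, `q1`,
#'   `q3`), `U` (statistic for the first group), `p` (two-sided),
#'   `method`.
#' @export
compare_groups <- function(counts_a, counts_b, labels = c("A", "B")) {
  stopifnot(length(counts_a) > 0, length(counts_b) > 0)
  exact <- (length(counts_a) * length(counts_b) <= 400) &&
    !any(duplicated(c(counts_a, counts_b)))
  wt <- suppressWarnings(
    wilcox.test(counts_a, counts_b, alternative = "two.sided",
                exact = exact, correct = TRUE))
  q <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  qa <- q(counts_a); qb <- q(counts_b)
  list(groups = data.frame(group = labels,
                           n = c(length(counts_a), length(counts_b)),
                           median = c(qa[2], qb[2]),
                           q1 = c(qa[1], qb[1]),
                           q3 = c(qa[3], qb[3])),
       U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Run the full quantification chain on a two-channel scene
#'
#' Max-projects both channels, segments nuclei on DAPI, enhances
#' speckles in both channels, detects DAPI foci (chromocenters) and
#' marker foci with their channel-specific diameter gates, relates foci
#' to nuclei and marker foci to DAPI foci, and tabulates per-nucleus
#' counts.
#'
#' @param dapi_stack,marker_stack 3D arrays (or 2D matrices) of the two
#'   channels.
#' @param params a [pipeline_params()] list.
#' @return list: `nuclei`, `dapi_foci`, `marker_foci` (records with
#'   parent links), `counts` (per-nucleus table from
#'   [colocalized_counts()]), and `labels` (list of the three label
#'   matrices).
#' @export
quantify_scene <- function(dapi_stack, marker_stack,
                           params = pipeline_params()) {
  dapi <- max_project(dapi_stack)
  marker <- max_project(marker_stack)
  seg <- segment_nuclei(dapi, params)

  dapi_enh <- enhance_speckles(dapi, params$speckle_feature_size_px)
  marker_enh <- enhance_speckles(marker, params$speckle_feature_size_px)
  df <- detect_foci(dapi_enh, dapi, params$dapi_foci_diameter_px,
                    params$foci_threshold)
  mf <- detect_foci(marker_enh, marker, params$marker_foci_diameter_px,
                    params$foci_threshold)

  df$foci$parent_nucleus_id <- relate_objects(df$foci, df$labels,
                                              seg$labels,
                                              params$relation_rule)
  mf$foci$parent_nucleus_id <- relate_objects(mf$foci, mf$labels,
                                              seg$labels,
                                              params$relation_rule)
  mf$foci$parent_dapi_focus_id <- relate_objects(mf$foci, mf$labels,
                                                 df$labels,
                                                 params$relation_rule)
  counts <- colocalized_counts(mf$foci, df$foci, seg$nuclei)
  list(nuclei = seg$nuclei, dapi_foci = df$foci, marker_foci = mf$foci,
       counts = counts,
       labels = list(nuclei = seg$labels, dapi_foci = df$labels,
                     marker_foci = mf$labels))
}
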