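#' Specification of a synthetic two-channel nuclear scene
#'
#' Emulates an interphase-nucleus immunofluorescence field: DAPI-stained
#' nuclei containing bright chromocenters (clustered pericentromeric
#' heterochromatin) and a marker channel (e.g. H3K9me3) with discrete
#' foci, a controllable fraction of which sit exactly on chromocenter
#' centers. Defaults describe one 640x640 field with 5 non-overlapping
#' nuclei of 45-55 px radius, on the order of 15 chromocenters and 15
#' marker foci per nucleus (typical mESC counts), SNR 10 and 3 z-slices.
#'
#' All placed objects respect minimum separations (chromocenters >= 16 px
#' apart; marker foci >= 16 px apart; non-colocalized foci at least
#' `2 * chromocenter_radius_px` from every chromocenter center) so that
#' every planted object is individually resolvable, as the discrete foci
#' in the emulated micrographs are.
#'
#' @param image_shape `(rows, cols)` in px.
#' @param n_nuclei nuclei per field.
#' @param nucleus_radius_px `(min, max)` nucleus radius in px.
#' @param chromocenters_per_nucleus Poisson mean (at least 1 is drawn).
#' @param chromocenter_radius_px nominal chromocenter radius in px.
#' @param marker_foci_per_nucleus Poisson mean marker foci per nucleus.
#' @param p_coloc probability that a marker focus is placed on a (free)
#'   chromocenter center; if no unoccupied chromocenter remains the focus
#'   is placed in the nucleoplasm and its truth flag records that.
#' @param snr nucleus-amplitude-to-noise-SD ratio (noise SD before the
#'   optical blur).
#' @param psf_sigma_px SD, in px, of the Gaussian optical blur applied to
#'   each rendered frame (signal plus noise): microscope images are
#'   band-limited, so pixel-independent noise would be unrealistic. Set
#'   to 0 to disable.
#' @param z_slices number of z-slices (>= 1); foci live in the middle
#'   (focal) slice, other slices carry the attenuated nuclear body only.
#' @param bit_depth output bit depth (16).
#' @param rng_seed integer seed.
#' @return a list of class `image_scene_spec`.
#' @export
image_scene_spec <- function(image_shape = c(640L, 640L), n_nuclei = 5L,
                             nucleus_radius_px = c(45, 55),
                             chromocenters_per_nucleus = 15,
                             chromocenter_radius_px = 4,
                             marker_foci_per_nucleus = 15,
                             p_coloc = 0.5, snr = 10, psf_sigma_px = 0.5,
                             z_slices = 3L,
                             bit_depth = 16L, rng_seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 64L),
            n_nuclei >= 0L, nucleus_radius_px[1] <= nucleus_radius_px[2],
            chromocenter_radius_px > 0, p_coloc >= 0, p_coloc <= 1,
            snr > 0, psf_sigma_px >= 0, z_slices >= 1L, bit_depth == 16L)
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = nucleus_radius_px,
                 chromocenters_per_nucleus = chromocenters_per_nucleus,
                 chromocenter_radius_px = chromocenter_radius_px,
                 marker_foci_per_nucleus = marker_foci_per_nucleus,
                 p_coloc = p_coloc, snr = snr,
                 psf_sigma_px = psf_sigma_px,
                 z_slices = as.integer(z_slices),
                 bit_depth = as.integer(bit_depth),
                 rng_seed = as.integer(rng_seed)),
            class = "image_scene_spec")
}

# rejection-sample an integer pixel position satisfying distance constraints:
# at least avoid$dist[k] away from avoid$xy[k, ], at most max_dist from `near`
place_point <- function(r_range, c_range, avoid = NULL,
                        near = NULL, max_dist = Inf, attempts = 5000L) {
  for (i in seq_len(attempts)) {
    p <- c(round(runif(1, r_range[1], r_range[2])),
           round(runif(1, c_range[1], c_range[2])))
    if (!is.null(near) && sqrt(sum((p - near)^2)) > max_dist) next
    if (!is.null(avoid) && nrow(avoid$xy)) {
      d <- sqrt((avoid$xy[, 1] - p[1])^2 + (avoid$xy[, 2] - p[2])^2)
      if (any(d < avoid$dist)) next
    }
    return(p)
  }
  NULL
}

# add a radially symmetric profile f(d) to img inside a window around (r0,c0)
add_profile <- function(img, r0, c0, radius, f) {
  H <- nrow(img); W <- ncol(img)
  rr <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  img[rr, cc] <- img[rr, cc] + f(d)
  img
}

#' Generate a two-channel nuclear scene with ground truth
#'
#' Renders the DAPI channel as soft nuclear disks plus brighter Gaussian
#' chromocenter blobs, and the marker channel as Gaussian spots at the
#' focus positions over a faint nucleoplasmic background; adds Gaussian
#' read noise set by the SNR, quantizes to 16 bit, and returns the truth
#' tables. With more than one z-slice the chromocenters and foci are
#' confined to the focal (middle) slice and the nuclear body is
#' attenuated elsewhere, so a max projection recovers the focal content;
#' the truth is identical for any `z_slices`.
#'
#' @param spec an [image_scene_spec()].
#' @return list: `dapi`, `marker` (H x W x Z arrays in `[0, 1]`,
#'   quantized to 16 bit) and `truth`, a list of `data.frame`s:
#'   `nuclei` (`nucleus_id`, `row`, `col`, `radius`),
#'   `chromocenters` (`nucleus_id`, `chromocenter_id`, `row`, `col`),
#'   `foci` (`nucleus_id`, `focus_id`, `row`, `col`, `colocalized`,
#'   `chromocenter_id`).
#' @export
gen_nuclear_images <- function(spec) {
  stopifnot(inherits(spec, "image_scene_spec"))
  set.seed(spec$rng_seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  r_cc <- spec$chromocenter_radius_px
  amp_nuc <- 0.35; amp_cc <- 0.35; amp_spot <- 0.6; amp_bg <- 0.06
  sigma_cc <- 0.5 * r_cc; sigma_spot <- 1.8
  sep_cc <- 16; sep_focus <- 16

  # --- place nuclei -------------------------------------------------------
  nuclei <- data.frame(nucleus_id = integer(0), row = numeric(0),
                       col = numeric(0), radius = numeric(0))
  for (i in seq_len(spec$n_nuclei)) {
    r_nuc <- runif(1, spec$nucleus_radius_px[1], spec$nucleus_radius_px[2])
    margin <- r_nuc + 4
    p <- place_point(c(margin, H - margin), c(margin, W - margin),
                     avoid = list(xy = cbind(nuclei$row, nuclei$col),
                                  dist = nuclei$radius + r_nuc + 6))
    if (is.null(p))
      stop("could not place ", spec$n_nuclei, " non-overlapping nuclei; ",
           "reduce n_nuclei or nucleus radius")
    nuclei <- rbind(nuclei, data.frame(nucleus_id = i, row = p[1],
                                       col = p[2], radius = r_nuc))
  }

  # --- place chromocenters and marker foci per nucleus --------------------
  ccs <- data.frame(nucleus_id = integer(0), chromocenter_id = integer(0),
                    row = numeric(0), col = numeric(0))
  foci <- data.frame(nucleus_id = integer(0), focus_id = integer(0),
                     row = numeric(0), col = numeric(0),
                     colocalized = logical(0), chromocenter_id = integer(0))
  for (i in seq_len(nrow(nuclei))) {
    nc <- c(nuclei$row[i], nuclei$col[i]); r_nuc <- nuclei$radius[i]
    # keep objects clear of the nuclear rim: the top-hat enhancement turns
    # the rim into a bright annulus (~element radius wide) that would
    # swallow peripheral objects
    inner <- r_nuc - max(2 * r_cc + 2, 15)
    n_cc <- max(1L, rpois(1, spec$chromocenters_per_nucleus))
    pts <- matrix(numeric(0), 0, 2)
    for (k in seq_len(n_cc)) {
      p <- place_point(c(nc[1] - inner, nc[1] + inner),
                       c(nc[2] - inner, nc[2] + inner),
                       avoid = list(xy = pts, dist = rep(sep_cc, nrow(pts))),
                       near = nc, max_dist = inner)
      if (is.null(p)) break                     # nucleus full, keep fewer
      pts <- rbind(pts, p)
    }
    ccs <- rbind(ccs, data.frame(nucleus_id = i,
                                 chromocenter_id = seq_len(nrow(pts)),
                                 row = pts[, 1], col = pts[, 2]))

    n_f <- rpois(1, spec$marker_foci_per_nucleus)
    free_cc <- seq_len(nrow(pts))
    fpts <- matrix(numeric(0), 0, 2)
    frec <- NULL
    for (k in seq_len(n_f)) {
      want_coloc <- runif(1) < spec$p_coloc
      p <- NULL
      if (want_coloc && length(free_cc)) {
        # a chromocenter can host a focus only if the focus would stay
        # resolvable from every focus already placed
        usable <- free_cc
        if (nrow(fpts)) {
          usable <- free_cc[vapply(free_cc, function(j)
            min(sqrt((fpts[, 1] - pts[j, 1])^2 +
                       (fpts[, 2] - pts[j, 2])^2)) >= sep_focus,
            logical(1))]
        }
        if (length(usable)) {
          j <- if (length(usable) == 1L) usable else sample(usable, 1L)
          free_cc <- setdiff(free_cc, j)
          p <- pts[j, ]; coloc <- TRUE; cc_id <- j
        }
      }
      if (is.null(p)) {
        avoid_xy <- rbind(as.matrix(pts), fpts)
        avoid_d <- c(rep(2 * r_cc, nrow(pts)), rep(sep_focus, nrow(fpts)))
        p <- place_point(c(nc[1] - inner, nc[1] + inner),
                         c(nc[2] - inner, nc[2] + inner),
                         avoid = list(xy = avoid_xy, dist = avoid_d),
                         near = nc, max_dist = inner)
        if (is.null(p)) next                    # nucleus full at this spot
        coloc <- FALSE; cc_id <- NA_integer_
      }
      fpts <- rbind(fpts, p)
      frec <- rbind(frec, data.frame(nucleus_id = i, focus_id = k,
                                     row = p[1], col = p[2],
                                     colocalized = coloc,
                                     chromocenter_id = cc_id))
    }
    if (!is.null(frec)) foci <- rbind(foci, frec)
  }
  rownames(ccs) <- rownames(foci) <- NULL

  # --- render -------------------------------------------------------------
  body <- matrix(0, H, W)          # nuclear disks (all slices)
  focal_extra <- matrix(0, H, W)   # chromocenters + spots (focal slice only)
  marker_bg <- matrix(0, H, W)
  marker_spots <- matrix(0, H, W)
  for (i in seq_len(nrow(nuclei))) {
    soft_disk <- local({
      r0 <- nuclei$radius[i]
      function(d) amp_nuc / (1 + exp((d - r0) / 2))
    })
    body <- add_profile(body, nuclei$row[i], nuclei$col[i],
                        nuclei$radius[i] + 12, soft_disk)
    marker_bg <- add_profile(marker_bg, nuclei$row[i], nuclei$col[i],
                             nuclei$radius[i] + 12,
                             local({
                               r0 <- nuclei$radius[i]
                               function(d) amp_bg / (1 + exp((d - r0) / 2))
                             }))
  }
  for (i in seq_len(nrow(ccs))) {
    focal_extra <- add_profile(focal_extra, ccs$row[i], ccs$col[i],
                               4 * sigma_cc,
                               function(d) amp_cc * exp(-d^2 / (2 * sigma_cc^2)))
  }
  for (i in seq_len(nrow(foci))) {
    marker_spots <- add_profile(marker_spots, foci$row[i], foci$col[i],
                                4 * sigma_spot,
                                function(d) amp_spot * exp(-d^2 / (2 * sigma_spot^2)))
  }

  noise_sd <- amp_nuc / spec$snr
  maxval <- 2^spec$bit_depth - 1
  quantize <- function(m) round(pmin(pmax(m, 0), 1) * maxval) / maxval
  focal <- ceiling(spec$z_slices / 2)
  dapi <- array(0, dim = c(H, W, spec$z_slices))
  marker <- array(0, dim = c(H, W, spec$z_slices))
  blur <- function(m) {
    if (spec$psf_sigma_px <= 0) return(m)
    matrix(as.numeric(EBImage::gblur(m, sigma = spec$psf_sigma_px)), H, W)
  }
  for (z in seq_len(spec$z_slices)) {
    # the nuclear body is thicker than the inter-slice spacing, so every
    # slice sees it at full intensity; chromocenters and foci are thinner
    # than one slice and appear only in the focal plane
    d_sig <- body + if (z == focal) focal_extra else 0
    m_sig <- marker_bg + if (z == focal) marker_spots else 0
    dapi[, , z] <- quantize(blur(d_sig + matrix(rnorm(H * W, 0, noise_sd), H, W)))
    marker[, , z] <- quantize(blur(m_sig + matrix(rnorm(H * W, 0, noise_sd), H, W)))
  }

  list(dapi = dapi, marker = marker,
       truth = list(nuclei = nuclei, chromocenters = ccs, foci = foci))
}

#' Write a generated scene to multi-page TIFF + truth CSV
#'
#' @param scene output of [gen_nuclear_images()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named vector of the three file paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
             marker = file.path(dir, paste0(prefix, "_marker.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")))
  as_pages <- function(a) lapply(seq_len(dim(a)[3]), function(z) a[, , z])
  tiff::writeTIFF(as_pages(scene$dapi), paths["dapi"], bits.per.sample = 16L)
  tiff::writeTIFF(as_pages(scene$marker), paths["marker"],
                  bits.per.sample = 16L)
  tr <- scene$truth
  long <- rbind(
    data.frame(object = "nucleus", nucleus_id = tr$nuclei$nucleus_id,
               object_id = tr$nuclei$nucleus_id, row = tr$nuclei$row,
               col = tr$nuclei$col, radius = tr$nuclei$radius,
               colocalized = NA),
    data.frame(object = "chromocenter",
               nucleus_id = tr$chromocenters$nucleus_id,
               object_id = tr$chromocenters$chromocenter_id,
               row = tr$chromocenters$row, col = tr$chromocenters$col,
               radius = NA, colocalized = NA),
    data.frame(object = "focus", nucleus_id = tr$foci$nucleus_id,
               object_id = tr$foci$focus_id, row = tr$foci$row,
               col = tr$foci$col, radius = NA,
               colocalized = tr$foci$colocalized))
  write.table(long, paths["truth"], sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}

#' Read a multi-page TIFF as a 3D array
#'
#' @param path TIFF file (pages = z-slices).
#' @return numeric array, rows x cols x z, intensities in `[0, 1]`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}
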