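# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# overlapping motif occurrences by explicit position-by-position comparison
oracle_count_sites <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (n < m) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == motif) hits <- hits + 1L
  }
  hits
}

# quadratic interval merge (gap <= merge_gap) then length filter, per chrom
oracle_select_regions <- function(ann, min_length, merge_gap) {
  out <- list()
  for (ch in sort(unique(ann$chrom))) {
    a <- ann[ann$chrom == ch, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    groups <- list()
    for (i in seq_len(nrow(a))) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        if (a$start[i] - groups[[g]]$end <= merge_gap &&
            a$end[i] >= groups[[g]]$start - merge_gap) {
          groups[[g]]$start <- min(groups[[g]]$start, a$start[i])
          groups[[g]]$end <- max(groups[[g]]$end, a$end[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <-
          list(start = a$start[i], end = a$end[i])
    }
    # sweep until stable: late annotations can bridge earlier groups
    repeat {
      merged <- FALSE
      if (length(groups) > 1L) {
        for (i in seq_len(length(groups) - 1L)) {
          for (j in (i + 1L):length(groups)) {
            gi <- groups[[i]]; gj <- groups[[j]]
            if (gj$start - gi$end <= merge_gap && gi$start - gj$end <= merge_gap) {
              groups[[i]] <- list(start = min(gi$start, gj$start),
                                  end = max(gi$end, gj$end))
              groups[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
    for (g in groups) {
      if (g$end - g$start >= min_length)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = g$start,
                                              end = g$end)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-pixel loop maximum projection
oracle_max_project <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      for (z in seq_len(d[3])) out[r, c] <- max(out[r, c], stack[r, c, z])
    }
  }
  out
}

# exhaustive 256-candidate Otsu search over the same equal-width binning
oracle_otsu <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  bin <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  best_k <- NA_integer_
  best_var <- -Inf
  n <- length(v)
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(bin <= k)
    w1 <- n - w0
    if (w0 == 0L || w1 == 0L) next
    mu0 <- mean(bin[bin <= k])
    mu1 <- mean(bin[bin > k])
    sb <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (sb > best_var + 1e-12) {
      best_var <- sb
      best_k <- k
    }
  }
  rng[1] + best_k / n_bins * diff(rng)
}

# grayscale top-hat by explicit neighborhood min (erosion) then max
# (dilation), ignoring out-of-image positions; the structuring element is
# an input (a 0/1 matrix with odd sides), only the morphology is re-derived
oracle_top_hat <- function(image, brush) {
  rad <- (nrow(brush) - 1L) / 2L
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[as.logical(brush[cbind(offs$dr + rad + 1L,
                                      offs$dc + rad + 1L)]), ]
  H <- nrow(image); W <- ncol(image)
  nb_apply <- function(src, fun, init) {
    out <- matrix(init, H, W)
    for (i in seq_len(nrow(offs))) {
      rs <- seq_len(H) + offs$dr[i]
      cs <- seq_len(W) + offs$dc[i]
      ok_r <- rs >= 1 & rs <= H
      ok_c <- cs >= 1 & cs <= W
      out[ok_r, ok_c] <- fun(out[ok_r, ok_c], src[rs[ok_r], cs[ok_c]])
    }
    out
  }
  er <- nb_apply(image, pmin, Inf)
  di <- nb_apply(er, pmax, -Inf)
  pmax(image - di, 0)
}

# flood-fill connected-component labeling (queue-based), 4 or 8 connectivity
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        for (i in seq_len(nrow(nbr))) {
          r <- p[1] + nbr[i, 1]; c <- p[2] + nbr[i, 2]
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# per-pixel parent assignment oracle: for every child object, count overlap
# with every parent label and apply the stated rule
oracle_relate <- function(child_labels, parent_labels, rule) {
  kids <- sort(unique(child_labels[child_labels > 0]))
  vapply(kids, function(k) {
    pix <- which(child_labels == k)
    if (rule == "centroid_in_parent") {
      H <- nrow(child_labels)
      rows <- ((pix - 1) %% H) + 1
      cols <- ((pix - 1) %/% H) + 1
      r <- round(mean(rows)); c <- round(mean(cols))
      p <- parent_labels[r, c]
      return(if (p > 0) as.integer(p) else NA_integer_)
    }
    pl <- parent_labels[pix]
    pl <- pl[pl > 0]
    if (!length(pl)) return(NA_integer_)
    cnt <- table(pl)
    best <- max(cnt)
    as.integer(min(as.integer(names(cnt)[cnt == best])))
  }, integer(1))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(g1) {
    g2 <- pooled[-g1]
    sum(outer(pooled[g1], g2, ">")) + 0.5 * sum(outer(pooled[g1], g2, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
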