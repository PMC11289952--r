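#' RNL clustering of a cone-catch image into discriminable patch classes
#'
#' Agglomerative perceptual segmentation. Starting from single-pixel regions
#' inside the mask, adjacent regions are merged whenever their chromatic
#' distance is below `t_color` AND their achromatic distance is below `t_lum`
#' (a pair is considered discriminable as soon as it exceeds either
#' threshold). Merging proceeds smallest combined distance
#' `sqrt(dS^2 + dL^2)` first, recomputing region means after every merge,
#' until no adjacent pair is mergeable; finally, class labels whose pooled
#' means are still mutually indiscriminable are fused globally, so every pair
#' of output classes differs by at least `t_color` chromatic or `t_lum`
#' achromatic JNDs. Ties are broken by the lower class index, making the
#' procedure deterministic.
#'
#' @param img A [cone_catch_image()], normally acuity-modeled and ranked-
#'   filtered first.
#' @param vs A [visual_system()].
#' @param t_color Chromatic discrimination threshold in Delta S (default 2).
#' @param t_lum Achromatic threshold in Delta S (default 4).
#' @param mask Logical background mask; defaults to the image's own.
#' @return An object of class `clustered_image`: list with `class_map`
#'   (`H x W` integer matrix, `NA` outside the mask; labels 1..k by
#'   decreasing abundance), `class_table` (one row per class: abundance as
#'   fraction of mask pixels, mean catch per channel, luminance, saturation)
#'   and `px_per_mm`.
#' @export
rnl_cluster <- function(img, vs, t_color = 2, t_lum = 4, mask = NULL) {
  stopifnot(inherits(img, "cone_catch_image"))
  if (t_color <= 0 || t_lum <= 0) stop("thresholds must be positive")
  if (is.null(mask)) mask <- img$mask
  if (!any(mask)) stop("empty mask: no background pixels to cluster")

  H <- dim(img$catch)[1]; W <- dim(img$catch)[2]
  nch <- length(img$channels)
  chrom_idx <- match(vs$chromatic_channels, img$channels)
  lum_idx <- match(vs$luminance_channel, img$channels)
  wc <- chromatic_weber(vs)
  wl <- unname(vs$weber[match(vs$luminance_channel, vs$channel_names)])

  pix <- which(mask)                      # linear indices into H x W
  id <- matrix(NA_integer_, H, W)
  id[pix] <- seq_along(pix)
  qmat <- matrix(NA_real_, length(pix), nch)
  for (ch in seq_len(nch)) qmat[, ch] <- img$catch[, , ch][pix]

  # ---- phase 1: union-find over adjacent sub-threshold pixel pairs -------
  edges <- adjacency_pairs(id, H, W)
  parent <- seq_along(pix)
  if (nrow(edges) > 0) {
    fa <- log(qmat[edges[, 1], , drop = FALSE])
    fb <- log(qmat[edges[, 2], , drop = FALSE])
    dS <- rnl_delta_s_log(fa[, chrom_idx, drop = FALSE] -
                            fb[, chrom_idx, drop = FALSE], wc)
    dL <- abs(fa[, lum_idx] - fb[, lum_idx]) / wl
    mergeable <- dS < t_color & dL < t_lum
    parent <- union_find(parent, edges[mergeable, , drop = FALSE])
  }
  root <- uf_roots(parent)
  labels0 <- match(root, unique(root))    # compact region ids

  # region stats: per-channel catch sums and pixel counts
  nreg <- max(labels0)
  counts <- tabulate(labels0, nreg)
  sums <- rowsum(qmat, labels0)

  # region adjacency from pixel edges
  redges <- unique(cbind(pmin(labels0[edges[, 1]], labels0[edges[, 2]]),
                         pmax(labels0[edges[, 1]], labels0[edges[, 2]])))
  redges <- redges[redges[, 1] != redges[, 2], , drop = FALSE]

  # ---- phase 2: agglomerate adjacent regions -----------------------------
  merged <- agglomerate(sums, counts, redges, chrom_idx, lum_idx, wc, wl,
                        t_color, t_lum)
  lab1 <- merged$map[labels0]

  # ---- phase 3: fuse globally indiscriminable class labels ---------------
  k1 <- max(lab1)
  sums2 <- rowsum(qmat, lab1)
  counts2 <- tabulate(lab1, k1)
  all_pairs <- if (k1 >= 2) t(utils::combn(k1, 2)) else
    matrix(integer(), 0, 2)
  merged2 <- agglomerate(sums2, counts2, all_pairs, chrom_idx, lum_idx,
                         wc, wl, t_color, t_lum)
  lab2 <- merged2$map[lab1]

  # relabel 1..k by decreasing abundance (ties: first occurrence)
  ab <- tabulate(lab2, max(lab2))
  ord <- order(-ab, seq_along(ab))
  relab <- integer(length(ab)); relab[ord] <- seq_along(ab)
  lab <- relab[lab2]

  class_map <- matrix(NA_integer_, H, W)
  class_map[pix] <- lab

  k <- max(lab)
  csum <- rowsum(qmat, lab)
  cn <- tabulate(lab, k)
  cmean <- csum / cn
  sat <- vapply(seq_len(k), function(i) {
    q <- cmean[i, chrom_idx]
    delta_s_chromatic(q, rep(exp(mean(log(q))), length(q)), vs)
  }, numeric(1))
  class_table <- data.frame(
    class = seq_len(k),
    abundance = cn / sum(cn),
    luminance = cmean[, lum_idx],
    saturation = sat
  )
  colnames(cmean) <- img$channels
  class_table <- cbind(class_table, cmean)

  structure(
    list(class_map = class_map, class_table = class_table,
         px_per_mm = img$px_per_mm),
    class = "clustered_image"
  )
}

#' @export
print.clustered_image <- function(x, ...) {
  cat(sprintf("clustered image: %d x %d px, %d classes\n",
              nrow(x$class_map), ncol(x$class_map), nrow(x$class_table)))
  print(x$class_table, digits = 3)
  invisible(x)
}

# pairs of region ids for 4-adjacent in-mask pixels
adjacency_pairs <- function(id, H, W) {
  right <- cbind(as.vector(id[, -W]), as.vector(id[, -1]))
  down <- cbind(as.vector(id[-H, ]), as.vector(id[-1, ]))
  e <- rbind(right, down)
  e[stats::complete.cases(e), , drop = FALSE]
}

union_find <- function(parent, edges) {
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) {  # path compression
      nxt <- parent[i]
      parent[i] <<- r
      i <- nxt
    }
    r
  }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  parent
}

uf_roots <- function(parent) {
  repeat {
    p2 <- parent[parent]
    if (identical(p2, parent)) return(parent)
    parent <- p2
  }
}

# greedy smallest-distance-first merging of regions connected by `pairs`
# (sums: nreg x nch catch sums, counts: pixel counts); returns map old -> new
agglomerate <- function(sums, counts, pairs, chrom_idx, lum_idx, wc, wl,
                        t_color, t_lum) {
  nreg <- nrow(sums)
  alive <- rep(TRUE, nreg)
  map <- seq_len(nreg)
  pairs <- matrix(as.integer(pairs), ncol = 2)

  repeat {
    if (nrow(pairs) == 0) break
    fa <- log(sums[pairs[, 1], , drop = FALSE] / counts[pairs[, 1]])
    fb <- log(sums[pairs[, 2], , drop = FALSE] / counts[pairs[, 2]])
    dS <- rnl_delta_s_log(fa[, chrom_idx, drop = FALSE] -
                            fb[, chrom_idx, drop = FALSE], wc)
    dL <- abs(fa[, lum_idx] - fb[, lum_idx]) / wl
    d <- cbind(dS, dL)
    ok <- d[, 1] < t_color & d[, 2] < t_lum
    if (!any(ok)) break
    comb <- sqrt(d[, 1]^2 + d[, 2]^2)
    comb[!ok] <- Inf
    best <- which(comb == min(comb))
    if (length(best) > 1) {  # tie-break: lowest index pair
      bp <- pairs[best, , drop = FALSE]
      best <- best[order(bp[, 1], bp[, 2])[1]]
    }
    a <- pairs[best, 1]; b <- pairs[best, 2]
    sums[a, ] <- sums[a, ] + sums[b, ]
    counts[a] <- counts[a] + counts[b]
    alive[b] <- FALSE
    pairs[pairs == b] <- a
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0) {
      pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                     pmax(pairs[, 1], pairs[, 2]))
      pairs <- unique(pairs)
    }
    map[map == b] <- a
  }
  list(map = match(map, sort(unique(map))))
}
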