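#' Transition matrix of a clustered image
#'
#' Tallies class transitions between sample pairs spaced `spacing` pixels
#' apart along every horizontal and vertical transect of the class map (both
#' samples must fall inside the mask). Diagonal entries are synonymous
#' (same-class) transitions, off-diagonal entries nonsynonymous. Directional
#' counts are kept separately; `counts` is their sum.
#'
#' @param clustered A `clustered_image` from [rnl_cluster()].
#' @param spacing Transect sample spacing in pixels (default 1 = adjacent).
#' @return An object of class `transition_matrix`: list with `counts`,
#'   `horizontal`, `vertical` (k x k matrices, ordered pairs tallied left to
#'   right / top to bottom), `spacing` and `k`.
#' @export
transition_matrix <- function(clustered, spacing = 1) {
  stopifnot(inherits(clustered, "clustered_image"), spacing >= 1)
  cm <- clustered$class_map
  k <- nrow(clustered$class_table)
  H <- nrow(cm); W <- ncol(cm)
  s <- as.integer(spacing)

  tally <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    m <- matrix(0L, k, k)
    if (any(keep)) {
      t0 <- table(factor(a[keep], levels = seq_len(k)),
                  factor(b[keep], levels = seq_len(k)))
      m <- matrix(as.integer(t0), k, k)
    }
    m
  }
  hz <- if (W > s) tally(cm[, seq_len(W - s), drop = FALSE],
                         cm[, seq_len(W - s) + s, drop = FALSE])
        else matrix(0L, k, k)
  vt <- if (H > s) tally(cm[seq_len(H - s), , drop = FALSE],
                         cm[seq_len(H - s) + s, , drop = FALSE])
        else matrix(0L, k, k)

  structure(list(counts = hz + vt, horizontal = hz, vertical = vt,
                 spacing = s, k = k),
            class = "transition_matrix")
}

# unordered-pair (symmetrized) off-diagonal frequencies of a count matrix
offdiag_freq <- function(m) {
  sym <- m + t(m)
  ut <- upper.tri(sym)
  counts <- sym[ut]
  idx <- which(ut, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], count = counts)
}

shannon_evenness <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(NaN)
  if (length(p) == 1) return(1)
  p <- p / sum(p)
  -sum(p * log(p)) / log(length(p))
}

#' Color adjacency statistics (CAA)
#'
#' Geometry of the clustered color pattern: `CAA.PT` is the mean
#' 4-connected patch size over the mask in square millimeters; `CAA.Qc` the
#' Shannon evenness of class abundances (1 for a single class); `CAA.Qt` the
#' Shannon evenness of off-diagonal (nonsynonymous) transition frequencies
#' (1 when exactly one boundary type exists, NaN when none), with `.hrz` /
#' `.vrt` variants computed from the directional transition matrices alone;
#' `CAA.Asp` is the ratio of horizontal to vertical nonsynonymous transition
#' rates (elongation of pattern grain; `Inf`/`NaN` when a direction has no
#' boundaries).
#'
#' @param clustered A `clustered_image`.
#' @param tm Its [transition_matrix()].
#' @return Named numeric vector.
#' @export
caa_stats <- function(clustered, tm) {
  ab <- clustered$class_table$abundance
  k <- length(ab)

  qc <- if (k == 1) 1 else {
    p <- ab / sum(ab)
    -sum(p[p > 0] * log(p[p > 0])) / log(k)
  }

  qt_of <- function(m) shannon_evenness(offdiag_freq(m)$count)

  rate <- function(m) {
    tot <- sum(m)
    if (tot == 0) return(NaN)
    (tot - sum(diag(m))) / tot
  }
  rh <- rate(tm$horizontal); rv <- rate(tm$vertical)
  asp <- if (is.nan(rh) || is.nan(rv)) NaN
         else if (rv == 0 && rh == 0) NaN
         else if (rv == 0) Inf else rh / rv

  c(CAA.PT = mean_patch_area(clustered),
    CAA.Qc = qc,
    CAA.Qt = qt_of(tm$counts),
    CAA.Qt.hrz = qt_of(tm$horizontal),
    CAA.Qt.vrt = qt_of(tm$vertical),
    CAA.Asp = asp)
}

# mean 4-connected component area (mm^2) of the class map over the mask
mean_patch_area <- function(clustered) {
  cm <- clustered$class_map
  H <- nrow(cm); W <- ncol(cm)
  pix <- which(!is.na(cm))
  id <- matrix(NA_integer_, H, W)
  id[pix] <- seq_along(pix)
  edges <- adjacency_pairs(id, H, W)
  same <- cm[pix[edges[, 1]]] == cm[pix[edges[, 2]]]
  parent <- union_find(seq_along(pix), edges[same, , drop = FALSE])
  root <- uf_roots(parent)
  sizes <- tabulate(match(root, unique(root)))
  mean(sizes) / clustered$px_per_mm^2
}

#' Visual contrast statistics (VCA)
#'
#' Contrast between clustered pattern elements weighted by their relative
#' abundances. Over all unordered class pairs with weights proportional to
#' the product of the two abundances: `VCA.ML` is the weighted mean pairwise
#' luminance contrast (JND), `VCA.MC` the weighted mean pairwise chromatic
#' contrast, `VCA.MSL` the weighted standard deviation of pairwise luminance
#' contrast. `VCA.CVS` is the abundance-weighted coefficient of variation of
#' class saturation (chromatic distance of each class mean from the
#' achromatic locus). `VCA.MLum` / `VCA.MSat` are abundance-weighted means
#' of class luminance catch and saturation. Pairwise statistics are NaN when
#' fewer than 2 classes exist.
#'
#' @param clustered A `clustered_image`.
#' @param vs A [visual_system()].
#' @return Named numeric vector.
#' @export
vca_stats <- function(clustered, vs) {
  ct <- clustered$class_table
  k <- nrow(ct)
  ab <- ct$abundance
  out <- c(VCA.ML = NaN, VCA.MC = NaN, VCA.MSL = NaN, VCA.CVS = NaN,
           VCA.MLum = sum(ab * ct$luminance),
           VCA.MSat = sum(ab * ct$saturation))
  if (k < 2) return(out)

  pr <- t(utils::combn(k, 2))
  w <- ab[pr[, 1]] * ab[pr[, 2]]
  w <- w / sum(w)
  qm <- as.matrix(ct[, match(vs$channel_names, colnames(ct))])
  chrom <- match(vs$chromatic_channels, vs$channel_names)
  dL <- delta_s_luminance(ct$luminance[pr[, 1]], ct$luminance[pr[, 2]], vs)
  dS <- delta_s_chromatic(qm[pr[, 1], chrom, drop = FALSE],
                          qm[pr[, 2], chrom, drop = FALSE], vs)
  ml <- sum(w * dL)
  out["VCA.ML"] <- ml
  out["VCA.MC"] <- sum(w * dS)
  out["VCA.MSL"] <- sqrt(sum(w * (dL - ml)^2))
  msat <- sum(ab * ct$saturation)
  out["VCA.CVS"] <- if (msat == 0) NaN
                    else sqrt(sum(ab * (ct$saturation - msat)^2)) / msat
  out
}

#' Boundary strength statistics (BSA)
#'
#' Contrast across pattern-element boundaries weighted by how much boundary
#' each class pair shares: weights are the normalized off-diagonal
#' (symmetrized) transition frequencies. `BSA.BML` / `BSA.BMS` are the
#' boundary-weighted mean luminance contrast and mean saturation difference;
#' `BSA.BCVL` / `BSA.BCVSsat` the corresponding boundary-weighted
#' coefficients of variation. All NaN when the image has no nonsynonymous
#' transitions.
#'
#' @param clustered A `clustered_image`.
#' @param tm Its [transition_matrix()].
#' @param vs A [visual_system()].
#' @return Named numeric vector.
#' @export
bsa_stats <- function(clustered, tm, vs) {
  out <- c(BSA.BML = NaN, BSA.BMS = NaN, BSA.BCVL = NaN, BSA.BCVSsat = NaN)
  od <- offdiag_freq(tm$counts)
  od <- od[od$count > 0, , drop = FALSE]
  if (nrow(od) == 0) return(out)
  w <- od$count / sum(od$count)
  ct <- clustered$class_table
  dL <- delta_s_luminance(ct$luminance[od$i], ct$luminance[od$j], vs)
  dSat <- abs(ct$saturation[od$i] - ct$saturation[od$j])
  bml <- sum(w * dL); bms <- sum(w * dSat)
  out["BSA.BML"] <- bml
  out["BSA.BMS"] <- bms
  out["BSA.BCVL"] <- if (bml == 0) NaN else sqrt(sum(w * (dL - bml)^2)) / bml
  out["BSA.BCVSsat"] <- if (bms == 0) NaN
                        else sqrt(sum(w * (dSat - bms)^2)) / bms
  out
}

#' Local edge intensity statistics (LEIA)
#'
#' Edge contrast of the unsegmented (acuity-modeled, ranked-filtered) image:
#' chromatic Delta S and achromatic Delta L between every in-mask pixel and
#' its right neighbour (horizontal, `.hrz`) and lower neighbour (vertical,
#' `.vrt`). The pooled and per-direction contrast distributions are
#' summarized by their mean, coefficient of variation, and excess kurtosis
#' (normal = 0; NaN under zero variance).
#'
#' @param img A filtered [cone_catch_image()].
#' @param vs A [visual_system()].
#' @param mask Logical mask, default the image's own.
#' @return Named numeric vector (`Lum.*` from Delta L, `Col.*` from
#'   Delta S, with `.hrz`/`.vrt` variants).
#' @export
leia_stats <- function(img, vs, mask = NULL) {
  stopifnot(inherits(img, "cone_catch_image"))
  if (is.null(mask)) mask <- img$mask
  if (!any(mask)) stop("empty mask")
  H <- dim(img$catch)[1]; W <- dim(img$catch)[2]
  chrom <- match(vs$chromatic_channels, img$channels)
  lumc <- match(vs$luminance_channel, img$channels)
  wc <- chromatic_weber(vs)
  wl <- unname(vs$weber[match(vs$luminance_channel, vs$channel_names)])

  logc <- log(img$catch)
  pair_contrasts <- function(off) {   # off = "h" (right) or "v" (down)
    if (off == "h") {
      a <- cbind(rep(seq_len(H), W - 1), rep(seq_len(W - 1), each = H))
      b <- cbind(a[, 1], a[, 2] + 1L)
    } else {
      a <- cbind(rep(seq_len(H - 1), W), rep(seq_len(W), each = H - 1))
      b <- cbind(a[, 1] + 1L, a[, 2])
    }
    keep <- mask[a] & mask[b]
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    if (nrow(a) == 0) return(list(dS = numeric(0), dL = numeric(0)))
    df <- vapply(seq_along(img$channels),
                 function(ch) logc[, , ch][a] - logc[, , ch][b],
                 numeric(nrow(a)))
    df <- matrix(df, ncol = length(img$channels))
    list(dS = rnl_delta_s_log(df[, chrom, drop = FALSE], wc),
         dL = abs(df[, lumc]) / wl)
  }

  hz <- pair_contrasts("h"); vt <- pair_contrasts("v")
  summarize <- function(x, prefix, suffix = "") {
    nm <- function(s) paste0(prefix, ".", s, suffix)
    if (length(x) == 0) {
      out <- c(NaN, NaN, NaN)
    } else {
      m <- mean(x)
      v <- mean((x - m)^2)
      cov <- if (m == 0) NaN else sqrt(v) / m
      kur <- if (v == 0) NaN else mean((x - m)^4) / v^2 - 3
      out <- c(m, cov, kur)
    }
    names(out) <- c(nm("mean"), nm("CoV"), nm("kurtosis"))
    out
  }
  c(summarize(c(hz$dL, vt$dL), "Lum"),
    summarize(hz$dL, "Lum", ".hrz"),
    summarize(vt$dL, "Lum", ".vrt"),
    summarize(c(hz$dS, vt$dS), "Col"),
    summarize(hz$dS, "Col", ".hrz"),
    summarize(vt$dS, "Col", ".vrt"))
}

#' The pattern-statistic registry
#'
#' Fixed-order catalogue of every statistic the pipeline emits, keyed by
#' `Family.Name`. The order defines CSV column order and the greedy scan
#' order of the correlation filter.
#'
#' @return Character vector of statistic names.
#' @export
stat_registry <- function() {
  c("CAA.PT", "CAA.Qc", "CAA.Qt", "CAA.Qt.hrz", "CAA.Qt.vrt", "CAA.Asp",
    "VCA.ML", "VCA.MC", "VCA.MSL", "VCA.CVS", "VCA.MLum", "VCA.MSat",
    "BSA.BML", "BSA.BMS", "BSA.BCVL", "BSA.BCVSsat",
    "Lum.mean", "Lum.CoV", "Lum.kurtosis",
    "Lum.mean.hrz", "Lum.CoV.hrz", "Lum.kurtosis.hrz",
    "Lum.mean.vrt", "Lum.CoV.vrt", "Lum.kurtosis.vrt",
    "Col.mean", "Col.CoV", "Col.kurtosis",
    "Col.mean.hrz", "Col.CoV.hrz", "Col.kurtosis.hrz",
    "Col.mean.vrt", "Col.CoV.vrt", "Col.kurtosis.vrt")
}

#' All pattern statistics for one image at one viewing distance
#'
#' Convenience wrapper producing one `StatRecord` row: metadata columns
#' followed by every statistic in [stat_registry()] order.
#'
#' @param clustered A `clustered_image`.
#' @param filtered The filtered [cone_catch_image()] the clustering was
#'   computed from (used for LEIA).
#' @param vs A [visual_system()].
#' @param image_id,species Identifiers carried into the row.
#' @param distance_cm Viewing distance tag.
#' @return One-row data.frame.
#' @export
compute_pattern_stats <- function(clustered, filtered, vs,
                                  image_id = NA_character_,
                                  species = NA_character_,
                                  distance_cm = NA_real_) {
  tm <- transition_matrix(clustered)
  vals <- c(caa_stats(clustered, tm),
            vca_stats(clustered, vs),
            bsa_stats(clustered, tm, vs),
            leia_stats(filtered, vs))
  vals <- vals[stat_registry()]
  cbind(data.frame(image_id = image_id, species = species,
                   distance_cm = distance_cm),
        as.data.frame(as.list(vals), check.names = FALSE))
}
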