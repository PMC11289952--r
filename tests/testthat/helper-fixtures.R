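# Toy image builders used across test files.

# cone-catch image with a constant catch per channel
uniform_image <- function(h = 8, w = 8, catches = c(0.5, 0.5, 0.5, 0.5),
                          px_per_mm = 1) {
  catch <- array(rep(catches, each = h * w), c(h, w, 4))
  cone_catch_image(catch, px_per_mm)
}

# image colored by a class map (values index rows of `colors`)
mosaic_image <- function(class_map, colors, px_per_mm = 1) {
  h <- nrow(class_map); w <- ncol(class_map)
  catch <- array(0, c(h, w, 4))
  for (ch in 1:4) catch[, , ch] <- matrix(colors[class_map, ch], h, w)
  cone_catch_image(catch, px_per_mm)
}

# clustered_image built directly from a known class map + class colors,
# bypassing rnl_cluster (for pattern-statistic oracles)
toy_clustered <- function(class_map, colors, px_per_mm = 1,
                          vs = visual_system()) {
  k <- max(class_map, na.rm = TRUE)
  ab <- tabulate(class_map[!is.na(class_map)], k)
  sat <- vapply(seq_len(k), function(i) {
    q <- colors[i, 1:3]
    delta_s_chromatic(q, rep(exp(mean(log(q))), 3), vs)
  }, numeric(1))
  ct <- data.frame(class = seq_len(k), abundance = ab / sum(ab),
                   luminance = colors[, 4], saturation = sat)
  cm <- colors
  colnames(cm) <- c("sw", "mw", "lw", "dbl")
  structure(list(class_map = class_map, class_table = cbind(ct, cm),
                 px_per_mm = px_per_mm),
            class = "clustered_image")
}

# two colors separated by given chromatic and luminance JND distances
two_colors <- function(ds, dl, vs = visual_system()) {
  rnlscape:::class_color_means(2, ds, dl, vs)
}

checkerboard <- function(n = 4) {
  outer(seq_len(n), seq_len(n), function(i, j) ((i + j) %% 2) + 1L)
}
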