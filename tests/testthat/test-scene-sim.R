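vs <- visual_system()

test_that("identical seed and config give bit-identical scenes", {
  cfg <- scene_config(seed = 42)
  a <- make_scene(cfg, vs)
  b <- make_scene(cfg, vs)
  expect_identical(a$image$catch, b$image$catch)
  expect_identical(a$class_map, b$class_map)
  expect_identical(a$image$mask, b$image$mask)
})

test_that("zero spreads and zero noise give a perfectly uniform image", {
  cfg <- scene_config(chromatic_spread = 0, luminance_spread = 0,
                      pixel_noise_sd = 0, seed = 1)
  sc <- make_scene(cfg, vs)
  for (ch in 1:4)
    expect_equal(length(unique(as.vector(sc$image$catch[, , ch]))), 1L)
})

test_that("huge patches yield exactly two connected patches (flood fill)", {
  # diameter for which the seed-density rule gives exactly 2 Voronoi cells
  a <- 64 * 64
  d_mm <- sqrt(2 * a / pi) / 4          # px -> mm at 4 px/mm
  cfg <- scene_config(n_patch_classes = 2, mean_patch_diameter_mm = d_mm,
                      pixel_noise_sd = 0, seed = 3)
  sc <- make_scene(cfg, vs)
  # flood-fill oracle on the emitted class map
  lab <- matrix(0L, 64, 64)
  nc <- 0L
  for (s in seq_along(sc$class_map)) {
    if (lab[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      if (lab[p] != 0L) next
      lab[p] <- nc
      i <- (p - 1) %% 64 + 1; j <- (p - 1) %/% 64 + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] >= 1 && nb[1] <= 64 && nb[2] >= 1 && nb[2] <= 64) {
          q <- (nb[2] - 1) * 64 + nb[1]
          if (lab[q] == 0L && sc$class_map[q] == sc$class_map[p])
            queue <- c(queue, q)
        }
      }
    }
  }
  expect_equal(nc, 2L)
})

test_that("realized chromatic spread matches the request within 5%", {
  for (k in c(2, 3, 5)) {
    cols <- rnlscape:::class_color_means(k, 6, 4, vs)
    pairs <- t(utils::combn(k, 2))
    ds <- delta_s_chromatic(cols[pairs[, 1], 1:3, drop = FALSE],
                            cols[pairs[, 2], 1:3, drop = FALSE], vs)
    expect_equal(mean(ds), 6, tolerance = 0.05)
    dl <- delta_s_luminance(cols[pairs[, 1], 4], cols[pairs[, 2], 4], vs)
    expect_equal(mean(dl), 4, tolerance = 0.05)
  }
})

test_that("the background mask keeps at least 70% of pixels", {
  sc <- make_scene(scene_config(seed = 2), vs)
  expect_gte(mean(sc$image$mask), 0.7)
})

test_that("non-positive class colors are rejected", {
  expect_error(scene_config(n_patch_classes = 2,
                            class_colors = matrix(c(-1, 1, 1, 1, 1, 1, 1, 1),
                                                  2, 4)),
               "positive")
})

test_that("a study has the right bookkeeping and a valid tree", {
  cfg <- group_effect_config(n_species_per_level = c(5, 4, 3),
                             n_images_per_species = 2)
  st <- make_study(cfg, scene_config(image_size = c(16, 16)), vs)
  expect_equal(nrow(st$species), 12L)
  expect_equal(sum(lengths(st$scenes)), 24L)
  expect_equal(ape::Ntip(st$tree), 12L)
  expect_setequal(st$tree$tip.label, st$species$species)
  # newick round trip preserves tips
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(st$tree, f)
  expect_setequal(ape::read.tree(f)$tip.label, st$species$species)
  # assay values sit inside their level's class interval
  sc <- score_species(st$assays)
  merged <- merge(sc, st$species, by = "species")
  expect_identical(merged$analysis_group, merged$defense_level)
})

test_that("studies are reproducible under a fixed master seed", {
  cfg <- group_effect_config(n_species_per_level = c(1, 1, 1),
                             n_images_per_species = 1)
  a <- make_study(cfg, scene_config(image_size = c(16, 16)), vs)
  b <- make_study(cfg, scene_config(image_size = c(16, 16)), vs)
  expect_identical(a$assays, b$assays)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$scenes[[1]][[1]]$image$catch,
                   b$scenes[[1]][[1]]$image$catch)
})
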