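vs <- visual_system()
cols2 <- two_colors(6, 4, vs)   # 6 JND chromatic, 4 JND luminance apart

test_that("transition counts match hand counts on toy images", {
  # uniform 4x4: 2 * 4 * 3 = 24 synonymous transitions
  un <- toy_clustered(matrix(1L, 4, 4), matrix(cols2[1, ], 1))
  tm <- transition_matrix(un)
  expect_equal(sum(diag(tm$counts)), 24L)
  expect_equal(sum(tm$counts) - sum(diag(tm$counts)), 0L)

  # 4x4 checkerboard: all 24 transitions nonsynonymous, 12 per direction
  cb <- toy_clustered(checkerboard(4), cols2)
  tmc <- transition_matrix(cb)
  expect_equal(sum(diag(tmc$counts)), 0L)
  expect_equal(sum(tmc$counts), 24L)
  expect_equal(sum(tmc$horizontal), 12L)
  expect_equal(sum(tmc$vertical), 12L)

  # width-1 vertical stripes: horizontal all nonsynonymous, vertical all
  # synonymous
  st <- toy_clustered(matrix(rep(rep(c(1L, 2L), 2), each = 4), 4, 4), cols2)
  tms <- transition_matrix(st)
  expect_equal(sum(tms$horizontal) - sum(diag(tms$horizontal)), 12L)
  expect_equal(sum(diag(tms$vertical)), 12L)

  # directional counts always sum to the pooled counts
  expect_identical(tmc$counts, tmc$horizontal + tmc$vertical)
})

test_that("CAA statistics match hand-derived values", {
  cb <- toy_clustered(checkerboard(4), cols2)
  tm <- transition_matrix(cb)
  s <- caa_stats(cb, tm)
  expect_equal(unname(s["CAA.PT"]), 1)          # 16 components of 1 px
  expect_equal(unname(s["CAA.Qc"]), 1)          # equal abundances
  expect_equal(unname(s["CAA.Qt"]), 1)          # single boundary type
  expect_equal(unname(s["CAA.Asp"]), 1)         # isotropic pattern

  # vertical stripes: no vertical boundaries -> infinite aspect ratio
  st <- toy_clustered(matrix(rep(rep(c(1L, 2L), 2), each = 4), 4, 4), cols2)
  sa <- caa_stats(st, transition_matrix(st))
  expect_true(is.infinite(sa["CAA.Asp"]))

  # uniform image: no off-diagonal transitions at all
  un <- toy_clustered(matrix(1L, 4, 4), matrix(cols2[1, ], 1))
  su <- caa_stats(un, transition_matrix(un))
  expect_true(is.nan(su["CAA.Qt"]))
  expect_equal(unname(su["CAA.Qc"]), 1)
})

test_that("VCA statistics match the single-pair closed form", {
  cm <- checkerboard(4)
  cl <- toy_clustered(cm, cols2)
  s <- vca_stats(cl, vs)
  expect_equal(unname(s["VCA.ML"]), 4, tolerance = 1e-9)
  expect_equal(unname(s["VCA.MSL"]), 0, tolerance = 1e-9)
  expect_equal(unname(s["VCA.MC"]), 6, tolerance = 1e-9)

  # single class: pairwise statistics undefined
  un <- toy_clustered(matrix(1L, 4, 4), matrix(cols2[1, ], 1))
  su <- vca_stats(un, vs)
  expect_true(all(is.nan(su[c("VCA.ML", "VCA.MC", "VCA.MSL")])))

  # all classes achromatic -> zero saturation everywhere -> CVS undefined
  ach <- matrix(c(0.5, 0.5, 0.5, 0.4,
                  0.5, 0.5, 0.5, 0.7), 2, 4, byrow = TRUE)
  sa <- vca_stats(toy_clustered(cm, ach), vs)
  expect_true(is.nan(sa["VCA.CVS"]))
})

test_that("BSA statistics match a brute-force oracle", {
  cb <- toy_clustered(checkerboard(4), cols2)
  s <- bsa_stats(cb, transition_matrix(cb), vs)
  expect_equal(unname(s["BSA.BML"]), 4, tolerance = 1e-9)
  expect_equal(unname(s["BSA.BCVL"]), 0, tolerance = 1e-9)

  un <- toy_clustered(matrix(1L, 4, 4), matrix(cols2[1, ], 1))
  expect_true(all(is.nan(bsa_stats(un, transition_matrix(un), vs))))

  # three-class image against independent recomputation from the matrix
  cols3 <- rnlscape:::class_color_means(3, 5, 6, vs)
  cm3 <- matrix(1L, 6, 6); cm3[, 3:4] <- 2L; cm3[, 5:6] <- 3L
  cm3[1, 1] <- 3L
  cl3 <- toy_clustered(cm3, cols3)
  tm3 <- transition_matrix(cl3)
  s3 <- bsa_stats(cl3, tm3, vs)
  sym <- tm3$counts + t(tm3$counts)
  tot <- 0; wsum <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    dl <- delta_s_luminance(cols3[i, 4], cols3[j, 4], vs)
    tot <- tot + sym[i, j] * dl
    wsum <- wsum + sym[i, j]
  }
  expect_equal(unname(s3["BSA.BML"]), unname(tot / wsum), tolerance = 1e-9)
})

test_that("LEIA matches hand counts on a step edge and degenerates cleanly", {
  un <- uniform_image(8, 8)
  su <- leia_stats(un, vs)
  expect_equal(unname(su["Lum.mean"]), 0)
  expect_equal(unname(su["Col.mean"]), 0)
  expect_true(is.nan(su["Lum.kurtosis"]))   # zero variance

  # vertical step of 4 luminance JND on an 8x8 mask: one contrasting
  # horizontal pair per row, 8 * 7 horizontal pairs total
  cols <- two_colors(0, 4, vs)
  cm <- matrix(1L, 8, 8); cm[, 5:8] <- 2L
  img <- mosaic_image(cm, cols)
  s <- leia_stats(img, vs)
  expect_equal(unname(s["Lum.mean.hrz"]), 4 * 8 / (8 * 7), tolerance = 1e-9)
  expect_equal(unname(s["Lum.mean.vrt"]), 0)
  expect_equal(unname(s["Col.mean"]), 0, tolerance = 1e-9)
})

test_that("statistics are invariant to translation and relabeling", {
  cols3 <- rnlscape:::class_color_means(3, 5, 5, vs)
  base <- matrix(1L, 10, 10); base[3:5, 3:7] <- 2L; base[7:9, 2:4] <- 3L
  shifted <- base[c(9:10, 1:8), c(10, 1:9)]   # cyclic translation
  relab <- c(2L, 3L, 1L)[base]                # relabeled classes
  dim(relab) <- dim(base)

  a <- toy_clustered(base, cols3)
  b <- toy_clustered(shifted, cols3)
  c3 <- toy_clustered(relab, cols3[c(3, 1, 2), ])

  for (cl in list(b, c3)) {
    sa <- caa_stats(a, transition_matrix(a))
    sb <- caa_stats(cl, transition_matrix(cl))
    # translation moves boundaries across the image edge, so compare the
    # label-free statistics
    expect_equal(unname(sa["CAA.Qc"]), unname(sb["CAA.Qc"]), tolerance = 1e-9)
  }
  # relabeling leaves everything identical
  sa <- c(caa_stats(a, transition_matrix(a)), vca_stats(a, vs),
          bsa_stats(a, transition_matrix(a), vs))
  sc <- c(caa_stats(c3, transition_matrix(c3)), vca_stats(c3, vs),
          bsa_stats(c3, transition_matrix(c3), vs))
  expect_equal(sa, sc, tolerance = 1e-9)
})

test_that("compute_pattern_stats emits the full registry", {
  sc <- make_scene(scene_config(image_size = c(24, 24), seed = 4), vs)
  cl <- rnl_cluster(sc$image, vs)
  row <- compute_pattern_stats(cl, sc$image, vs, "im1", "sp1", 2)
  expect_identical(setdiff(names(row), c("image_id", "species",
                                         "distance_cm")),
                   stat_registry())
})
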