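#' Scene configuration for the synthetic background generator
#'
#' Describes one synthetic cone-catch background: a Voronoi mosaic of patch
#' classes whose class-mean colors are placed at exact perceptual spacings in
#' the observer's RNL space, with multiplicative lognormal pixel noise.
#'
#' @param image_size Height and width in pixels (length-2 integer).
#' @param px_per_mm Physical scale, pixels per millimeter.
#' @param n_patch_classes Number of patch color classes (>= 1).
#' @param mean_patch_diameter_mm Nominal patch diameter in millimeters;
#'   controls the density of Voronoi seeds (one seed per
#'   `pi * (d/2)^2` of image area).
#' @param class_colors Optional `k x 4` matrix of class mean catches
#'   (columns sw, mw, lw, dbl). When `NULL`, class means are generated so
#'   that the mean pairwise chromatic distance equals `chromatic_spread` and
#'   the mean pairwise achromatic distance equals `luminance_spread`.
#' @param chromatic_spread Target mean pairwise chromatic Delta S between
#'   class means (>= 0).
#' @param luminance_spread Target mean pairwise achromatic Delta S (>= 0).
#' @param pixel_noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal pixel noise (~ relative catch noise; 0 = noiseless).
#' @param animal_fraction Fraction of the image occupied by the central
#'   "animal" ellipse excluded from the background mask (< 0.3, so at least
#'   70% of pixels are background).
#' @param seed Integer RNG seed: identical seed and configuration give a
#'   bit-identical scene.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(64, 64),
                         px_per_mm = 4,
                         n_patch_classes = 3,
                         mean_patch_diameter_mm = 8,
                         class_colors = NULL,
                         chromatic_spread = 6,
                         luminance_spread = 6,
                         pixel_noise_sd = 0.05,
                         animal_fraction = 0.15,
                         seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 4),
            px_per_mm > 0, n_patch_classes >= 1,
            mean_patch_diameter_mm > 0,
            chromatic_spread >= 0, luminance_spread >= 0,
            pixel_noise_sd >= 0, animal_fraction >= 0, animal_fraction < 0.3)
  if (!is.null(class_colors)) {
    class_colors <- as.matrix(class_colors)
    if (nrow(class_colors) != n_patch_classes || ncol(class_colors) != 4)
      stop("'class_colors' must be a n_patch_classes x 4 matrix")
    if (any(class_colors <= 0)) stop("class colors must be strictly positive")
  }
  structure(
    list(image_size = as.integer(image_size), px_per_mm = px_per_mm,
         n_patch_classes = as.integer(n_patch_classes),
         mean_patch_diameter_mm = mean_patch_diameter_mm,
         class_colors = class_colors,
         chromatic_spread = chromatic_spread,
         luminance_spread = luminance_spread,
         pixel_noise_sd = pixel_noise_sd,
         animal_fraction = animal_fraction,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Generate one synthetic cone-catch background
#'
#' Builds a Voronoi patch mosaic with the configured patch scale, assigns
#' each Voronoi cell a patch class, colors pixels with the class mean catch
#' times multiplicative lognormal noise, and cuts a central elliptical
#' "animal" out of the background mask. The emitted ground-truth class map
#' makes every downstream stage testable against a known segmentation.
#'
#' @param config A [scene_config()].
#' @param vs A [visual_system()] (used to place class means at exact
#'   perceptual spacings).
#' @return A list with `image` (a [cone_catch_image()] with mask),
#'   `class_map` (ground-truth `H x W` integer matrix) and `class_colors`
#'   (`k x 4` matrix of class mean catches).
#' @examples
#' sc <- make_scene(scene_config(seed = 7))
#' table(sc$class_map)
#' @export
make_scene <- function(config, vs = visual_system()) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    k <- config$n_patch_classes
    cols <- config$class_colors
    if (is.null(cols))
      cols <- class_color_means(k, config$chromatic_spread,
                                config$luminance_spread, vs)

    d_px <- config$mean_patch_diameter_mm * config$px_per_mm
    n_seeds <- max(k, round(H * W / (pi * (d_px / 2)^2)))
    sy <- stats::runif(n_seeds, 0.5, H + 0.5)
    sx <- stats::runif(n_seeds, 0.5, W + 0.5)
    seed_class <- rep_len(seq_len(k), n_seeds)[sample.int(n_seeds)]

    gy <- rep(seq_len(H), times = W)
    gx <- rep(seq_len(W), each = H)
    nearest <- max.col(-(outer(gy, sy, "-")^2 + outer(gx, sx, "-")^2),
                       ties.method = "first")
    class_map <- matrix(seed_class[nearest], H, W)

    catch <- array(0, c(H, W, 4))
    for (ch in 1:4) {
      base <- matrix(cols[class_map, ch], H, W)
      if (config$pixel_noise_sd > 0)
        base <- base * exp(matrix(stats::rnorm(H * W, 0, config$pixel_noise_sd),
                                  H, W))
      catch[, , ch] <- base
    }

    mask <- matrix(TRUE, H, W)
    if (config$animal_fraction > 0) {
      # central ellipse covering animal_fraction of the image
      a <- sqrt(config$animal_fraction * H * W / pi * (H / W))
      b <- sqrt(config$animal_fraction * H * W / pi * (W / H))
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      inside <- ((gy - cy) / a)^2 + ((gx - cx) / b)^2 <= 1
      mask[cbind(gy[inside], gx[inside])] <- FALSE
    }

    img <- cone_catch_image(catch, config$px_per_mm, rownames_chan(), mask)
    list(image = img, class_map = class_map, class_colors = cols)
  })
}

rownames_chan <- function() c("sw", "mw", "lw", "dbl")

# k class mean catches around a neutral point (0.5 catch in every channel),
# equally spaced on a circle in RNL chromatic coordinates and on a line in
# log luminance, scaled so the mean pairwise distances match the requested
# spreads exactly.
class_color_means <- function(k, chromatic_spread, luminance_spread, vs) {
  base <- 0.5
  cols <- matrix(base, k, 4,
                 dimnames = list(NULL, c("sw", "mw", "lw", "dbl")))
  if (k == 1) return(cols)
  bs <- rnl_chromatic_basis(vs)
  wl <- unname(vs$weber[match(vs$luminance_channel, vs$channel_names)])

  ang <- 2 * pi * (seq_len(k) - 1) / k
  pts <- cbind(cos(ang), sin(ang))
  mean_unit <- mean(stats::dist(pts))
  r <- if (chromatic_spread > 0) chromatic_spread / mean_unit else 0
  for (i in seq_len(k)) {
    f <- (bs$B %*% (r * pts[i, ])) * bs$w      # log-catch offsets
    cols[i, 1:3] <- base * exp(as.vector(f))
  }

  lum <- seq_len(k) - (k + 1) / 2              # centered integer spacings
  mean_lum <- mean(stats::dist(lum))
  s <- if (luminance_spread > 0) luminance_spread / mean_lum else 0
  cols[, 4] <- base * exp(lum * s * wl)
  cols
}

#' Group-effect configuration for a synthetic study
#'
#' Describes a study of several species in three chemical-defense levels,
#' each species photographed on several backgrounds whose scene parameters
#' are perturbed by the species' defense-level effect (multipliers on the
#' chromatic and luminance patch contrast, i.e. on edge contrast).
#'
#' @param defense_levels Labels of the three defense levels.
#' @param n_species_per_level Species count per level (each >= 1).
#' @param n_images_per_species Backgrounds per species (>= 1).
#' @param chromatic_mult,luminance_mult Per-level multipliers applied to the
#'   base scene's `chromatic_spread` / `luminance_spread`.
#' @param n_extracts Whole-body assay extracts per species.
#' @param tree_seed Seed for the pure-birth species tree.
#' @param seed Master seed for species scenes and assay draws.
#' @return An object of class `group_effect_config`.
#' @export
group_effect_config <- function(defense_levels = c("undefended",
                                                   "toxic_moderate",
                                                   "toxic_high"),
                                n_species_per_level = c(5, 4, 3),
                                n_images_per_species = 15,
                                chromatic_mult = c(1, 1.5, 1.5),
                                luminance_mult = c(1, 1.5, 1.5),
                                n_extracts = 2,
                                tree_seed = 1,
                                seed = 1) {
  stopifnot(length(defense_levels) == 3,
            !anyDuplicated(defense_levels),
            length(n_species_per_level) == 3,
            all(n_species_per_level >= 1),
            n_images_per_species >= 1,
            length(chromatic_mult) == 3, length(luminance_mult) == 3,
            n_extracts >= 1)
  structure(
    list(defense_levels = defense_levels,
         n_species_per_level = as.integer(n_species_per_level),
         n_images_per_species = as.integer(n_images_per_species),
         chromatic_mult = chromatic_mult,
         luminance_mult = luminance_mult,
         n_extracts = as.integer(n_extracts),
         tree_seed = as.integer(tree_seed),
         seed = as.integer(seed)),
    class = "group_effect_config"
  )
}

#' Generate a full synthetic study
#'
#' Builds the species tree, species and assay tables, and all background
#' scenes for a study of `sum(n_species_per_level)` species. Assay indices
#' are drawn uniformly within the index interval of each species' defense
#' level, so defense classification round-trips exactly; scene parameters are
#' the base configuration with the level's contrast multipliers applied.
#'
#' @param group_cfg A [group_effect_config()].
#' @param base_scene A [scene_config()] giving the shared scene parameters.
#' @param vs A [visual_system()].
#' @return A list with `species` (data.frame: species, defense_level),
#'   `assays` (data.frame: species, extract_id, extract_type,
#'   unpalatability_index, toxicity_index), `tree` (an ape `phylo`, unit
#'   height, one tip per species), and `scenes` (named list; per species a
#'   list of [make_scene()] outputs).
#' @export
make_study <- function(group_cfg, base_scene = scene_config(),
                       vs = visual_system()) {
  stopifnot(inherits(group_cfg, "group_effect_config"),
            inherits(base_scene, "scene_config"))
  nsp <- sum(group_cfg$n_species_per_level)
  species <- sprintf("species_%02d", seq_len(nsp))
  level <- rep(group_cfg$defense_levels, group_cfg$n_species_per_level)

  tree <- withr::with_seed(group_cfg$tree_seed, {
    tr <- ape::rphylo(nsp, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr$tip.label <- species
    tr
  })

  assays <- withr::with_seed(group_cfg$seed, {
    do.call(rbind, lapply(seq_len(nsp), function(i) {
      lev <- match(level[i], group_cfg$defense_levels)
      n <- group_cfg$n_extracts
      unpal <- switch(lev, rep(0, n), stats::runif(n, 0.01, 0.73),
                      stats::runif(n, 0.74, 1))
      tox <- switch(lev, rep(0, n), stats::runif(n, 0.2, 0.8),
                    stats::runif(n, 0.2, 0.8))
      data.frame(species = species[i],
                 extract_id = sprintf("%s_e%d", species[i], seq_len(n)),
                 extract_type = "whole_body",
                 unpalatability_index = unpal,
                 toxicity_index = tox)
    }))
  })

  scenes <- vector("list", nsp)
  names(scenes) <- species
  for (i in seq_len(nsp)) {
    lev <- match(level[i], group_cfg$defense_levels)
    cfg <- base_scene
    cfg$chromatic_spread <- cfg$chromatic_spread * group_cfg$chromatic_mult[lev]
    cfg$luminance_spread <- cfg$luminance_spread * group_cfg$luminance_mult[lev]
    scenes[[i]] <- lapply(seq_len(group_cfg$n_images_per_species), function(j) {
      cfg$seed <- spawn_seed(group_cfg$seed, i * 1000L + j)
      make_scene(cfg, vs)
    })
  }

  list(species = data.frame(species = species, defense_level = level),
       assays = assays, tree = tree, scenes = scenes)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
spawn_seed <- function(master, offset) {
  as.integer((as.double(master) * 48271 + as.double(offset) * 16807) %%
               2147483647)
}
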