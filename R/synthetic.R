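#' Synthetic study configuration
#'
#' Describes a synthetic hyperspectral variety-identification study with the
#' statistical structure a line-scan NIR bean experiment assumes: `K` classes
#' with distinct smooth endmember reflectance curves, `beans_per_scene`
#' non-overlapping elliptical beans per scene on a near-zero background, a
#' multiplicative center-to-edge path-length gain (curved samples are
#' brighter at the center at every band), and additive per-pixel per-band
#' noise.
#'
#' Class endmembers are a shared smooth base curve scaled by class-specific
#' amplitudes minus class-specific Gaussian absorption features — varieties
#' of one commodity show roughly parallel NIR curves separated mostly by
#' overall reflectance level, with subtler band-position differences.
#'
#' @param n_classes number of varieties (default 4).
#' @param beans_per_scene beans per image (default 50).
#' @param scenes_per_class images per variety (default 6).
#' @param rows,cols scene size in pixels (default 256 x 320).
#' @param wavelengths band grid in nm (default 874–1734 nm in 5 nm steps).
#' @param amplitudes per-class overall reflectance scaling of the base curve.
#' @param n_features Gaussian absorption features per class.
#' @param feature_depth,feature_width ranges (min, max) for feature depth
#'   (relative reflectance) and width (nm, Gaussian sigma).
#' @param feature_range wavelength interval (nm) feature centers are drawn
#'   from; kept inside the grid so derivative filters see whole features.
#' @param feature_min_sep minimum separation (nm) between any two feature
#'   centers across all classes.
#' @param shape_gain center-to-edge brightness ratio of a bean (>= 1);
#'   1 disables the shape effect.
#' @param noise_sd additive per-pixel per-band noise sd in reflectance units.
#' @param noise_dist `"gaussian"` or `"student_t"` (df 3, scaled to
#'   `noise_sd`) for heavy-tail robustness checks.
#' @param background_level background reflectance (default 0.02).
#' @param bean_radius range (min, max) of ellipse semi-axes in pixels.
#' @param white_level,dark_level raw counts of the reference frames.
#' @param seed RNG seed for endmember feature placement and scene seeds.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_classes = 4, beans_per_scene = 50,
                         scenes_per_class = 6, rows = 256, cols = 320,
                         wavelengths = seq(874, 1734, by = 5),
                         amplitudes = seq(0.72, 1.14,
                                          length.out = n_classes),
                         n_features = 3,
                         feature_depth = c(0.08, 0.14),
                         feature_width = c(14, 22),
                         feature_range = c(950, 1650),
                         feature_min_sep = 25,
                         shape_gain = 1.6, noise_sd = 0.02,
                         noise_dist = c("gaussian", "student_t"),
                         background_level = 0.02,
                         bean_radius = c(5, 9),
                         white_level = 3000, dark_level = 100,
                         seed = 1) {
  noise_dist <- match.arg(noise_dist)
  stopifnot(n_classes >= 2, beans_per_scene >= 1, scenes_per_class >= 1,
            shape_gain >= 1, noise_sd >= 0, length(amplitudes) == n_classes,
            bean_radius[1] >= 2, bean_radius[2] >= bean_radius[1])
  if (feature_range[1] < min(wavelengths) ||
      feature_range[2] > max(wavelengths))
    stop("feature_range must lie within the wavelength grid")
  structure(as.list(environment()), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<scene_config> %d classes x %d scenes x %d beans, %dx%d px, ",
    "%d bands\n  shape_gain %.2f, noise_sd %.3f (%s), seed %d\n"),
    x$n_classes, x$scenes_per_class, x$beans_per_scene, x$rows, x$cols,
    length(x$wavelengths), x$shape_gain, x$noise_sd, x$noise_dist, x$seed))
  invisible(x)
}

# smooth twice-differentiable NIR-like base reflectance curve
.base_curve <- function(wl) {
  z <- (wl - min(wl)) / diff(range(wl))
  0.62 + 0.16 * sin(2.2 * z + 0.4) - 0.08 * z
}

#' Per-class endmember spectra
#'
#' Builds the class endmembers: a shared smooth base curve scaled by each
#' class's amplitude, minus that class's Gaussian absorption features.
#' Feature centers are drawn (deterministically from `cfg$seed`) inside
#' `cfg$feature_range` with at least `cfg$feature_min_sep` nm between any two
#' centers across all classes, so every class pair differs in at least one
#' feature.  Curves are checked to stay in (0, 1).
#'
#' @param cfg a [scene_config()].
#' @return `n_classes x n_bands` matrix with attribute `"features"`: a
#'   data.frame (`class`, `center_nm`, `depth`, `width_nm`) of the planted
#'   absorption features.
#' @export
make_endmembers <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  wl <- cfg$wavelengths
  K <- cfg$n_classes
  nf <- cfg$n_features
  set.seed(cfg$seed)
  total <- K * nf
  centers <- numeric(0)
  for (tries in 1:2000) {
    cand <- runif(1, cfg$feature_range[1], cfg$feature_range[2])
    if (!length(centers) || min(abs(centers - cand)) >= cfg$feature_min_sep)
      centers <- c(centers, cand)
    if (length(centers) == total) break
  }
  if (length(centers) < total)
    stop("could not place ", total, " feature centers with min separation ",
         cfg$feature_min_sep, " nm; widen feature_range or reduce n_features")
  feats <- data.frame(
    class = rep(seq_len(K), each = nf),
    center_nm = centers,
    depth = runif(total, cfg$feature_depth[1], cfg$feature_depth[2]),
    width_nm = runif(total, cfg$feature_width[1], cfg$feature_width[2]))
  base <- .base_curve(wl)
  E <- matrix(0, K, length(wl))
  for (k in seq_len(K)) {
    shape <- base
    fk <- feats[feats$class == k, ]
    for (i in seq_len(nrow(fk)))
      shape <- shape - fk$depth[i] *
        exp(-(wl - fk$center_nm[i])^2 / (2 * fk$width_nm[i]^2))
    E[k, ] <- cfg$amplitudes[k] * shape
  }
  if (any(E <= 0) || any(E >= 1))
    stop("endmember curves leave (0, 1); reduce amplitudes or feature depth")
  attr(E, "features") <- feats
  E
}

#' Render one synthetic scene
#'
#' Places `beans_per_scene` non-overlapping axis-aligned ellipses on a
#' jittered grid (beans on a conveyor tray do not touch), assigns each
#' foreground pixel the spectrum `endmember x gain + noise` where the
#' elliptical path-length gain rises from 1 at the bean edge to `shape_gain`
#' at the center, and synthesizes raw counts plus white/dark reference frames
#' such that [reflectance_correct()] recovers the designed reflectance in
#' expectation.
#'
#' @param cfg a [scene_config()].
#' @param class_label variety (1..n_classes) imaged in this scene.
#' @param scene_seed RNG seed for geometry and noise.
#' @param endmembers optional endmember matrix from [make_endmembers()]
#'   (recomputed from `cfg` if omitted).
#' @return list with elements `raw` ([hypercube()] of raw counts), `refs`
#'   ([reference_frames()]), `truth` ([bean_label_map()]), `gain` (matrix of
#'   the designed gain field, 0 on background) and `class_label`.
#' @export
render_scene <- function(cfg, class_label, scene_seed,
                         endmembers = make_endmembers(cfg)) {
  stopifnot(inherits(cfg, "scene_config"),
            class_label >= 1, class_label <= cfg$n_classes)
  rows <- cfg$rows; cols <- cfg$cols
  B <- length(cfg$wavelengths)
  set.seed(scene_seed)
  # jittered-grid placement: guarantees non-overlap by construction
  rmax <- cfg$bean_radius[2]
  jit <- 3
  cell <- ceiling(2 * (rmax + jit) + 2)
  gr <- rows %/% cell; gc <- cols %/% cell
  if (gr * gc < cfg$beans_per_scene)
    stop("cannot place ", cfg$beans_per_scene, " beans of radius <= ", rmax,
         " in a ", rows, "x", cols, " scene without overlap; ",
         "use smaller beans or fewer per scene")
  cells <- sample(gr * gc, cfg$beans_per_scene)
  labels <- matrix(0L, rows, cols)
  gain <- matrix(0, rows, cols)
  for (i in seq_len(cfg$beans_per_scene)) {
    ci <- (cells[i] - 1L) %/% gc
    cj <- (cells[i] - 1L) %% gc
    a <- runif(1, cfg$bean_radius[1], cfg$bean_radius[2])
    b <- runif(1, cfg$bean_radius[1], cfg$bean_radius[2])
    cy <- ci * cell + cell / 2 + runif(1, -jit, jit)
    cx <- cj * cell + cell / 2 + runif(1, -jit, jit)
    yy <- max(1, floor(cy - a)):min(rows, ceiling(cy + a))
    xx <- max(1, floor(cx - b)):min(cols, ceiling(cx + b))
    d2 <- outer((yy - cy)^2 / a^2, (xx - cx)^2 / b^2, "+")
    inside <- d2 <= 1
    labels[yy, xx][inside] <- i
    gain[yy, xx][inside] <-
      1 + (cfg$shape_gain - 1) * sqrt(pmax(0, 1 - d2[inside]))
  }
  truth <- bean_label_map(labels > 0L, labels)
  npx <- rows * cols
  refl <- matrix(cfg$background_level, npx, B)
  fg <- which(truth$mask)
  if (length(fg))
    refl[fg, ] <- (gain[fg] %o% rep(1, B)) *
      (rep(1, length(fg)) %o% endmembers[class_label, ])
  span <- cfg$white_level - cfg$dark_level
  raw <- refl * span + cfg$dark_level
  if (cfg$noise_sd > 0) {
    noise <- if (cfg$noise_dist == "gaussian") {
      rnorm(npx * B, 0, cfg$noise_sd * span)
    } else {
      rt(npx * B, df = 3) * cfg$noise_sd * span / sqrt(3)
    }
    raw <- raw + noise
  }
  dim(raw) <- c(rows, cols, B)
  list(raw = hypercube(raw, cfg$wavelengths,
                       list(scene_seed = scene_seed,
                            class_label = class_label)),
       refs = reference_frames(white = rep(cfg$white_level, B),
                               dark = rep(cfg$dark_level, B)),
       truth = truth, gain = gain, class_label = as.integer(class_label))
}

#' Scene seeds of a study
#'
#' Deterministic per-scene seeds derived from `cfg$seed`; scene `s` of class
#' `k` always gets the same seed for a given configuration seed.
#'
#' @param cfg a [scene_config()].
#' @return data.frame with `scene_id`, `class_label`, `scene_seed`.
#' @export
study_plan <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  n <- cfg$n_classes * cfg$scenes_per_class
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  data.frame(scene_id = seq_len(n),
             class_label = rep(seq_len(cfg$n_classes),
                               each = cfg$scenes_per_class),
             scene_index = rep(seq_len(cfg$scenes_per_class),
                               cfg$n_classes),
             scene_seed = seeds)
}

#' Materialize a full synthetic study
#'
#' Renders `scenes_per_class` scenes for each class with seeds from
#' [study_plan()].  Bit-identical for identical configurations.  Note a
#' default-size study holds ~2.7 GB of raw cubes; use
#' [extract_study_spectra()] for a memory-light streaming path.
#'
#' @param cfg a [scene_config()].
#' @return list of [render_scene()] results, one per scene, each with an
#'   added `scene_id`.
#' @export
make_study <- function(cfg) {
  plan <- study_plan(cfg)
  E <- make_endmembers(cfg)
  lapply(seq_len(nrow(plan)), function(i) {
    sc <- render_scene(cfg, plan$class_label[i], plan$scene_seed[i],
                       endmembers = E)
    sc$scene_id <- plan$scene_id[i]
    sc
  })
}

#' Extract all study spectra scene-by-scene
#'
#' Streaming pipeline runner: for each scene of the study renders the raw
#' cube, applies reflectance correction, builds the mask ([build_mask()]),
#' zeroes the background, optionally applies a preprocessing method, and
#' extracts pixel spectra — discarding the cube before the next scene.
#'
#' @param cfg a [scene_config()].
#' @param pre a [preprocess_config()] or `NULL` for no preprocessing.
#' @param mask_band_nm,mask_threshold,min_area forwarded to [build_mask()].
#' @return list with `pixels` (pixel-level [spectra_dataset()] over all
#'   scenes), `plan` (the [study_plan()] table with a `n_beans` column).
#' @export
extract_study_spectra <- function(cfg, pre = NULL, mask_band_nm = 1200,
                                  mask_threshold = NULL, min_area = 20) {
  plan <- study_plan(cfg)
  E <- make_endmembers(cfg)
  parts <- vector("list", nrow(plan))
  nb <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sc <- render_scene(cfg, plan$class_label[i], plan$scene_seed[i],
                       endmembers = E)
    cube <- reflectance_correct(sc$raw, sc$refs)
    lmap <- build_mask(cube, band_nm = mask_band_nm,
                       threshold = mask_threshold, min_area = min_area)
    cube <- apply_mask(cube, lmap)
    if (!is.null(pre)) cube <- preprocess_cube(cube, lmap, pre)
    parts[[i]] <- extract_pixel_spectra(cube, lmap, plan$class_label[i],
                                        scene_id = plan$scene_id[i])
    nb[i] <- lmap$n_beans
  }
  plan$n_beans <- nb
  list(pixels = bind_spectra(parts), plan = plan)
}
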