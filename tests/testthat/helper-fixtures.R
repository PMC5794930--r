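# Small fixtures shared across test files; everything is generated in code.

# desk-size scene configuration (a few small beans, short grid runs fast)
small_cfg <- function(...) {
  args <- list(rows = 96, cols = 128, beans_per_scene = 6,
               scenes_per_class = 3, bean_radius = c(4, 6), seed = 42)
  over <- list(...)
  args[names(over)] <- over
  if (!is.null(over$wavelengths) && is.null(over$feature_range)) {
    wl <- over$wavelengths
    args$feature_range <- if (length(wl) >= 4)
      c(wl[2], wl[length(wl) - 1]) else range(wl)
    args$feature_min_sep <- 0
    args$n_features <- 1
  }
  do.call(scene_config, args)
}

# deterministic toy spectra dataset: K well-separated Gaussian blobs
toy_dataset <- function(K = 2, n = 10, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n * p, mean = sep * k), n, p)))
  spectra_dataset(X, rep(seq_len(K), each = n),
                  data.frame(scene_id = rep(seq_len(K), each = n),
                             bean_id = seq_len(K * n)),
                  seq_len(p))
}

# masked scene + pixel spectra in one call
masked_scene <- function(cfg, class_label = 1, scene_seed = 7) {
  sc <- render_scene(cfg, class_label, scene_seed)
  cube <- reflectance_correct(sc$raw, sc$refs)
  wl <- cfg$wavelengths
  band <- if (min(wl) <= 1200 && max(wl) >= 1200) 1200 else wl[length(wl) %/% 2]
  lmap <- build_mask(cube, band_nm = band)
  list(scene = sc, cube = apply_mask(cube, lmap), lmap = lmap)
}

# smooth endmember used as the clean signal in denoiser oracles
clean_signal <- function(n = 173) {
  cfg <- scene_config(seed = 1)
  as.numeric(make_endmembers(cfg)[1, seq_len(n)])
}
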