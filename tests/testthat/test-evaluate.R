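# a noiseless flat-bean study is the degenerate separable case: every cell
# of the cross-prediction matrix must be perfect
test_that("noiseless unit-gain studies give 100% in all four cells", {
  cfg <- small_cfg(noise_sd = 0, shape_gain = 1)
  ex <- run_experiment(cfg, cal_per_class = 2, pixels_per_class = 150,
                       C = 16, gamma = 0.5, seed = 2)
  expect_equal(ex$results$accuracy, rep(100, 4))
  expect_equal(sort(unique(ex$results$train_on)), c("average", "pixel"))
})

test_that("run_experiment with a full wavelength set equals all bands", {
  cfg <- small_cfg(noise_sd = 0, shape_gain = 1,
                   wavelengths = seq(1000, 1315, 5))
  full_ws <- structure(list(selected = cfg$wavelengths,
                            indices = seq_along(cfg$wavelengths),
                            scores = rep(1, length(cfg$wavelengths))),
                       class = "wavelength_set")
  a <- run_experiment(cfg, cal_per_class = 2, pixels_per_class = 100,
                      seed = 3)
  b <- run_experiment(cfg, cal_per_class = 2, pixels_per_class = 100,
                      seed = 3, ws = full_ws)
  expect_equal(a$results, b$results)
})

test_that("prediction maps classify every foreground pixel correctly when clean", {
  cfg <- small_cfg(noise_sd = 0)
  E <- make_endmembers(cfg)
  train_parts <- lapply(1:2, function(k) {
    ms <- masked_scene(cfg, class_label = k, scene_seed = 100 + k)
    extract_pixel_spectra(ms$cube, ms$lmap, k, scene_id = k)
  })
  m <- svm_train(bind_spectra(train_parts), C = 16, gamma = 0.5)
  ms <- masked_scene(cfg, class_label = 2, scene_seed = 300)
  pm <- predict_scene(m, ms$cube, ms$lmap, scene_id = 9)
  fg <- ms$lmap$mask
  expect_true(all(pm$labels[fg] == 2L))
  expect_true(all(pm$labels[!fg] == 0L))
  expect_equal(sum(pm$labels > 0), sum(fg))
  # per-bean vote: unanimous beans vote their class
  vote <- per_bean_vote(pm, ms$lmap, truth = 2)
  expect_equal(vote$accuracy, 100)
  expect_true(all(vote$bean_labels == 2L))
  expect_error(predict_scene(m, hypercube(ms$cube$data[, , 1:10],
                                          cfg$wavelengths[1:10]),
                             ms$lmap), "bands")
})

test_that("per-bean majority vote follows the documented tie rule", {
  lmap <- bean_label_map(matrix(TRUE, 2, 5), matrix(1L, 2, 5))
  map <- structure(list(labels = matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L,
                                          2L, 2L), 2, 5),
                        scene_id = 1, legend = NULL),
                   class = "prediction_map")
  expect_equal(per_bean_vote(map, lmap)$bean_labels[[1]], 2L)  # 6 vs 4
  tie <- structure(list(labels = matrix(c(rep(1L, 5), rep(3L, 5)), 2, 5),
                        scene_id = 1, legend = NULL),
                   class = "prediction_map")
  expect_equal(per_bean_vote(tie, lmap)$bean_labels[[1]], 1L)  # 5-5 tie
  empty <- structure(list(labels = matrix(0L, 2, 5), scene_id = 1,
                          legend = NULL), class = "prediction_map")
  expect_warning(v <- per_bean_vote(empty, lmap), "skipped")
  expect_true(is.na(v$bean_labels[[1]]))
})

test_that("bean-level votes are at least as accurate as raw pixels", {
  cfg <- small_cfg(noise_sd = 0.06)  # noisy enough for pixel errors
  E <- make_endmembers(cfg)
  train_parts <- lapply(1:2, function(k) {
    ms <- masked_scene(cfg, class_label = k, scene_seed = 400 + k)
    extract_pixel_spectra(ms$cube, ms$lmap, k, scene_id = k)
  })
  m <- svm_train(bind_spectra(train_parts), C = 16, gamma = 0.5)
  for (s in 1:2) {
    ms <- masked_scene(cfg, class_label = 1, scene_seed = 500 + s)
    pm <- predict_scene(m, ms$cube, ms$lmap)
    px_acc <- 100 * mean(pm$labels[ms$lmap$mask] == 1L)
    vote <- per_bean_vote(pm, ms$lmap, truth = 1)
    expect_gte(vote$accuracy, px_acc)
  }
})

test_that("rendered maps are deterministic with the fixed palette", {
  set.seed(41)
  labels <- matrix(sample(0:4, 30 * 20, replace = TRUE), 30, 20)
  map <- structure(list(labels = labels, scene_id = 1,
                        legend = hsibean:::.class_palette(4)),
                   class = "prediction_map")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.png"); p2 <- file.path(dir, "b.png")
  render_map(map, p1); render_map(map, p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
  img <- png::readPNG(p1)
  expect_equal(dim(img)[1:2], dim(labels))
  cols <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = ","))
  expect_length(cols, 5)  # 4 classes + black background
  expect_true("0,0,0" %in% cols)
})

test_that("reports, matrices and label maps export to plain text", {
  dir <- withr::local_tempdir()
  rep <- eval_report(c(1, 1, 2, 2), c(1, 2, 2, 2))
  write_eval_report(rep, file.path(dir, "r.json"))
  back <- jsonlite::fromJSON(file.path(dir, "r.json"))
  expect_equal(back$accuracy, 75)
  cfg <- small_cfg(noise_sd = 0, shape_gain = 1)
  ex <- run_experiment(cfg, cal_per_class = 2, pixels_per_class = 100)
  write_experiment_csv(ex, file.path(dir, "m.csv"), features = "full",
                       method = "none")
  tidy <- read.csv(file.path(dir, "m.csv"))
  expect_equal(names(tidy), c("train_on", "test_on", "features", "method",
                              "cal_acc", "pred_acc", "n"))
  expect_equal(nrow(tidy), 4)
  lmap <- bean_label_map(matrix(c(TRUE, FALSE), 2, 2),
                         matrix(c(1L, 0L, 1L, 0L), 2, 2))
  write_label_map_csv(lmap, file.path(dir, "l.csv"))
  expect_equal(unname(as.matrix(read.csv(file.path(dir, "l.csv"),
                                         header = FALSE))),
               lmap$labels, ignore_attr = TRUE)
  # d2 plot export renders to a file
  wl <- seq(874, 1734, 5)
  d2 <- second_derivative(rbind(0.8 - 0.1 * exp(-(wl - 1199)^2 / 800),
                                0.8 - 0.2 * exp(-(wl - 1399)^2 / 800)),
                          wavelengths = wl)
  f <- file.path(dir, "d2.png")
  grDevices::png(f, width = 400, height = 300)
  plot_second_derivative(d2, select_wavelengths(d2, max_k = 5))
  grDevices::dev.off()
  expect_gt(file.info(f)$size, 0)
})
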