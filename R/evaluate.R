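#' Run the pixel-wise vs. sample-average cross-prediction experiment
#'
#' The central experiment: from one synthetic study it trains (a) a
#' pixel-wise model on randomly sampled calibration pixels and (b) a
#' sample-average model on the calibration bean means, then evaluates both
#' models on both prediction-set views (all prediction pixels, and the
#' prediction bean means).  The four cells expose the sample-shape effect:
#' average-trained models see only the narrow spectral spread of bean means
#' and fail on shape-brightened pixels, while pixel-trained models cover the
#' full spread and predict bean means well.
#'
#' @param cfg a [scene_config()].
#' @param pre optional [preprocess_config()] applied scene-wise before
#'   extraction.
#' @param cal_per_class calibration scenes per class (default 4).
#' @param pixels_per_class calibration pixels sampled per class (default
#'   2000).
#' @param ws optional `wavelength_set` restricting both models to selected
#'   bands (`NULL` = full spectra).
#' @param C,gamma,kernel SVM hyperparameters (see [svm_train()]).
#' @param seed RNG seed for the pixel sampling.
#' @return object of class `experiment_matrix`: list with `results` (tidy
#'   data.frame: `train_on`, `test_on`, `accuracy`, `n`), `reports` (the
#'   four [eval_report()]s keyed `pixel->pixel` etc.), `models` (the two
#'   bundles), `plan`.
#' @export
run_experiment <- function(cfg, pre = NULL, cal_per_class = 4,
                           pixels_per_class = 2000, ws = NULL,
                           C = 256, gamma = 0.5, kernel = "rbf", seed = 1) {
  ext <- extract_study_spectra(cfg, pre = pre)
  pixels <- ext$pixels
  if (!is.null(ws)) pixels <- subset_bands(pixels, ws)
  plan <- make_splits(ext$plan, cal_per_class = cal_per_class,
                      pixels_per_class_cal = pixels_per_class)
  averages <- average_by_bean(pixels)
  in_cal_px <- pixels$meta$scene_id %in% plan$cal_scenes
  in_cal_av <- averages$meta$scene_id %in% plan$cal_scenes
  take <- function(ds, rows)
    spectra_dataset(ds$X[rows, , drop = FALSE], ds$y[rows],
                    ds$meta[rows, , drop = FALSE], ds$wavelengths)
  cal_px <- sample_pixels(pixels, plan, seed = seed)
  cal_av <- take(averages, which(in_cal_av))
  pred_px <- take(pixels, which(!in_cal_px))
  pred_av <- take(averages, which(!in_cal_av))
  if (!nrow(pred_px$X) || !nrow(pred_av$X))
    stop("empty prediction view; check the split plan")

  m_px <- svm_train(cal_px, C = C, gamma = gamma, kernel = kernel)
  m_av <- svm_train(cal_av, C = C, gamma = gamma, kernel = kernel)

  cells <- list(
    `pixel->pixel` = svm_predict(m_px, pred_px)$report,
    `pixel->average` = svm_predict(m_px, pred_av)$report,
    `average->average` = svm_predict(m_av, pred_av)$report,
    `average->pixel` = svm_predict(m_av, pred_px)$report)
  results <- data.frame(
    train_on = c("pixel", "pixel", "average", "average"),
    test_on = c("pixel", "average", "average", "pixel"),
    accuracy = vapply(cells, `[[`, numeric(1), "accuracy"),
    n = vapply(cells, `[[`, numeric(1), "n"),
    row.names = NULL)
  structure(list(results = results, reports = cells,
                 models = list(pixel = m_px, average = m_av),
                 plan = plan),
            class = "experiment_matrix")
}

#' @export
print.experiment_matrix <- function(x, ...) {
  cat("<experiment_matrix>\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Per-pixel prediction map of one scene
#'
#' Classifies every foreground pixel of a (preprocessed) scene with a
#' trained bundle; the background keeps the 0 sentinel.
#'
#' @param bundle an [svm_train()] bundle.
#' @param cube reflectance [hypercube()] preprocessed identically to the
#'   bundle's calibration data.
#' @param lmap [bean_label_map()] of the scene.
#' @param ws optional `wavelength_set` (must match the bundle's band count).
#' @param scene_id recorded in the map.
#' @return object of class `prediction_map`: list with `labels` (integer
#'   matrix, 0 = background), `scene_id`, `legend` (class -> color).
#' @export
predict_scene <- function(bundle, cube, lmap, ws = NULL, scene_id = 1L) {
  ds <- extract_pixel_spectra(cube, lmap, class_label = 1L,
                              scene_id = scene_id)
  if (!is.null(ws)) ds <- subset_bands(ds, ws)
  if (ncol(ds$X) != ncol(bundle$SV))
    stop("scene provides ", ncol(ds$X), " bands but the model expects ",
         ncol(bundle$SV), "; preprocess/subset the scene like the training data")
  pred <- svm_predict(bundle, ds$X)$labels
  labels <- matrix(0L, nrow(lmap$mask), ncol(lmap$mask))
  labels[cbind(ds$meta$row, ds$meta$col)] <- pred
  structure(list(labels = labels, scene_id = scene_id,
                 legend = .class_palette(length(bundle$classes))),
            class = "prediction_map")
}

# fixed palette: class1 red, class2 green, class3 blue, class4 yellow,
# further classes cycled through magenta/cyan/orange; background black
.class_palette <- function(K) {
  base <- c("#FF0000", "#00FF00", "#0000FF", "#FFFF00",
            "#FF00FF", "#00FFFF", "#FF8000")
  stats::setNames(rep_len(base, K), seq_len(K))
}

#' Majority vote of pixel predictions within each bean
#'
#' Collapses a per-pixel prediction map to one label per bean instance
#' (majority vote, ties toward the smallest class label) — the quantitative
#' surrogate for judging whether each bean is identified correctly.
#'
#' @param map a [predict_scene()] map.
#' @param lmap the scene's [bean_label_map()].
#' @param truth optional true class of the scene (scalar or per-bean
#'   vector) for an accuracy figure.
#' @return list with `bean_labels` (named integer vector, one per bean),
#'   and when truth is given `accuracy` (percent of beans correct).
#' @export
per_bean_vote <- function(map, lmap, truth = NULL) {
  stopifnot(inherits(map, "prediction_map"), inherits(lmap, "bean_label_map"))
  if (!identical(dim(map$labels), dim(lmap$labels)))
    stop("map and label geometry differ")
  votes <- integer(lmap$n_beans)
  for (bid in seq_len(lmap$n_beans)) {
    px <- map$labels[lmap$labels == bid]
    px <- px[px > 0L]
    if (!length(px)) {
      warning("bean ", bid, " has no classified pixels; skipped")
      votes[bid] <- NA_integer_
      next
    }
    tab <- table(px)
    votes[bid] <- as.integer(names(tab)[which.max(tab)])  # first max = smallest
  }
  names(votes) <- seq_len(lmap$n_beans)
  out <- list(bean_labels = votes)
  if (!is.null(truth)) {
    truth <- rep_len(as.integer(truth), lmap$n_beans)
    ok <- !is.na(votes)
    out$accuracy <- 100 * mean(votes[ok] == truth[ok])
  }
  out
}

#' Render a prediction map as a PNG image
#'
#' Lossless PNG with the fixed class palette (class 1 red, 2 green, 3 blue,
#' 4 yellow) and black background; identical maps give byte-identical files.
#'
#' @param map a [predict_scene()] map.
#' @param path destination `.png`.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path) {
  stopifnot(inherits(map, "prediction_map"))
  pal <- map$legend
  rgb <- t(grDevices::col2rgb(c("#000000", pal))) / 255
  img <- array(0, c(nrow(map$labels), ncol(map$labels), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[map$labels + 1L, ch], nrow(map$labels))
  png::writePNG(img, path)
  invisible(path)
}

#' Replicate the cross-prediction experiment over seeded studies
#'
#' Renders `n_rep` independent synthetic studies (seeds derived from
#' `base_seed`), runs [run_experiment()] on each and collects the four
#' cross-prediction accuracies — the replication unit behind the pipeline's
#' headline summaries (median accuracies and the pixel/average asymmetry
#' gap).
#'
#' @param n_rep number of replicate studies (default 5).
#' @param base_seed base RNG seed; study `i` uses `base_seed * 1000 + i`.
#' @param shape_gain center-to-edge gain of the generator (see
#'   [scene_config()]).
#' @param cfg_args named list of further [scene_config()] overrides.
#' @param ... forwarded to [run_experiment()] (e.g. `C`, `gamma`, `pre`).
#' @return data.frame with one row per replicate: `seed`, `pixel2pixel`,
#'   `pixel2average`, `average2average`, `average2pixel`, `gap`
#'   (pixel2average - average2pixel).
#' @export
replicate_experiments <- function(n_rep = 5, base_seed = 1, shape_gain = 1.6,
                                  cfg_args = list(), ...) {
  out <- lapply(seq_len(n_rep), function(i) {
    s <- base_seed * 1000 + i
    cfg <- do.call(scene_config,
                   c(list(shape_gain = shape_gain, seed = s), cfg_args))
    ex <- run_experiment(cfg, seed = s + 7, ...)
    acc <- ex$results$accuracy
    names(acc) <- paste(ex$results$train_on, ex$results$test_on, sep = "2")
    data.frame(seed = s, t(acc), gap = acc[["pixel2average"]] -
                 acc[["average2pixel"]],
               n_pixel = ex$results$n[ex$results$test_on == "pixel"][1],
               n_average = ex$results$n[ex$results$test_on == "average"][1])
  })
  do.call(rbind, out)
}

#' Write an experiment matrix as tidy CSV
#'
#' Columns: `train_on`, `test_on`, `features`, `method`, `cal_acc`,
#' `pred_acc`, `n`.
#'
#' @param em an [run_experiment()] result.
#' @param path destination `.csv`.
#' @param features feature-set tag (e.g. `"full"` or `"optimal"`).
#' @param method preprocessing tag recorded in the file.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(em, path, features = "full",
                                 method = "none") {
  stopifnot(inherits(em, "experiment_matrix"))
  df <- em$results
  df$features <- features
  df$method <- method
  df$cal_acc <- ifelse(df$train_on == "pixel",
                       em$models$pixel$cal_accuracy,
                       em$models$average$cal_accuracy)
  names(df)[names(df) == "accuracy"] <- "pred_acc"
  write.csv(df[, c("train_on", "test_on", "features", "method",
                   "cal_acc", "pred_acc", "n")], path, row.names = FALSE)
  invisible(path)
}
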