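test_that("scene splits follow the 4+2 whole-image design", {
  plan <- study_plan(scene_config(seed = 1))
  sp <- make_splits(plan, cal_per_class = 4)
  expect_length(sp$cal_scenes, 16)
  expect_length(sp$pred_scenes, 8)
  expect_length(intersect(sp$cal_scenes, sp$pred_scenes), 0)
  for (k in 1:4) {
    ids <- plan$scene_id[plan$class_label == k]
    expect_length(intersect(sp$cal_scenes, ids), 4)
    expect_length(intersect(sp$pred_scenes, ids), 2)
  }
  # 4 cal + 2 pred scenes x 50 beans = 200 / 100 beans per class
  expect_equal(4 * 50, 200); expect_equal(2 * 50, 100)
  expect_error(make_splits(plan, cal_per_class = 6), "non-empty")
})

test_that("pixel sampling is stratified, seeded and bounded", {
  set.seed(30)
  n <- 300
  px <- spectra_dataset(matrix(rnorm(n * 4), n, 4),
                        rep(1:2, each = n / 2),
                        data.frame(scene_id = rep(c(1, 2, 3), each = n / 3),
                                   bean_id = 1, row = 1, col = seq_len(n)),
                        1:4)
  plan <- structure(list(cal_scenes = c(1, 2), pred_scenes = 3,
                         pixels_per_class_cal = 40), class = "split_plan")
  s1 <- sample_pixels(px, plan, seed = 5)
  expect_equal(as.vector(table(s1$y)), c(40, 40))
  expect_true(all(s1$meta$scene_id %in% c(1, 2)))
  s2 <- sample_pixels(px, plan, seed = 6)
  expect_false(identical(s1$meta$col, s2$meta$col))
  expect_identical(sample_pixels(px, plan, seed = 5)$meta, s1$meta)
  plan$pixels_per_class_cal <- 1e5
  expect_error(sample_pixels(px, plan), "only")
})

test_that("the separable 4-point toy reproduces the hard-margin solution", {
  # two points per class on a line: analytic hard-margin boundary x1 = 2,
  # margin width 2 => |f| = 1 at the support vectors (1,0) and (3,0)
  X <- rbind(c(0, 0), c(1, 0), c(3, 0), c(4, 0))
  ds <- spectra_dataset(X, c(1, 1, 2, 2),
                        data.frame(scene_id = 1, bean_id = 1:4), 1:2)
  m <- svm_train(ds, C = 1e6, gamma = 1e-4)  # g -> 0: linear-limit surrogate
  expect_equal(m$cal_accuracy, 100)
  dv <- decision_values(m, X)
  expect_equal(as.numeric(decision_values(m, rbind(c(2, 0)))), 0,
               tolerance = 1e-3)
  expect_equal(as.numeric(dv[2]), 1, tolerance = 0.05)
  expect_equal(as.numeric(dv[3]), -1, tolerance = 0.05)
  expect_true(all(dv[ds$y == 1] > 0) && all(dv[ds$y == 2] < 0))
})

test_that("the XOR pattern is separated by the RBF kernel", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  ds <- spectra_dataset(X, c(1, 1, 2, 2),
                        data.frame(scene_id = 1, bean_id = 1:4), 1:2)
  # closed form: the RBF Gram matrix of 4 distinct points is full rank,
  # so a perfect interpolant exists
  G <- exp(-1 * as.matrix(dist(X))^2)
  expect_equal(qr(G)$rank, 4)
  m <- svm_train(ds, C = 1e4, gamma = 1)
  expect_equal(m$cal_accuracy, 100)
})

test_that("single-class or degenerate inputs are errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(svm_train(spectra_dataset(X, rep(1, 10),
                                         data.frame(scene_id = 1,
                                                    bean_id = 1:10), 1:2)),
               ">= 2 classes")
  expect_error(svm_train(spectra_dataset(X, c(1, rep(2, 9)),
                                         data.frame(scene_id = 1,
                                                    bean_id = 1:10), 1:2)),
               ">= 2 samples")
})

test_that("every binary problem satisfies the KKT conditions", {
  ds <- toy_dataset(K = 4, n = 15, p = 6, sep = 1.2, seed = 33)
  C <- 4
  m <- svm_train(ds, C = C, gamma = 0.3)
  expect_equal(nrow(m$pairs), 6)
  for (p in seq_len(6)) {
    expect_lt(abs(sum(m$pair_coef[[p]])), 1e-6)
    expect_lte(max(abs(m$pair_coef[[p]])), C + 1e-9)
  }
})

test_that("the bundle's decision functions reproduce libsvm exactly", {
  ds <- toy_dataset(K = 3, n = 20, p = 5, sep = 1.5, seed = 34)
  m <- svm_train(ds, C = 8, gamma = 0.2)
  # libsvm orders classes by first appearance: a scrambled appearance order
  # must not change the fitted model's predictions
  perm <- c(41:60, 1:20, 21:40)  # classes appear as 3, 1, 2
  ds_perm <- spectra_dataset(ds$X[perm, ], ds$y[perm], ds$meta[perm, ],
                             ds$wavelengths)
  m_perm <- svm_train(ds_perm, C = 8, gamma = 0.2)
  # solver reaches the optimum along a different working-set path, so the
  # coefficients agree only to libsvm's termination tolerance
  expect_equal(decision_values(m_perm, ds$X), decision_values(m, ds$X),
               tolerance = 1e-2)
  expect_equal(svm_predict(m_perm, ds)$labels, svm_predict(m, ds)$labels)
  ref <- e1071::svm(ds$X, factor(ds$y), type = "C-classification",
                    kernel = "radial", cost = 8, gamma = 0.2, scale = FALSE)
  pr <- predict(ref, ds$X, decision.values = TRUE)
  expect_equal(decision_values(m, ds$X),
               attr(pr, "decision.values"), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(svm_predict(m, ds)$labels, as.integer(as.character(pr)))
  # stored training predictions equal a fresh aggregation
  expect_equal(svm_predict(m, ds)$labels, m$train_pred)
})

test_that("prediction is row-wise and accuracy is plain arithmetic", {
  ds <- toy_dataset(K = 2, n = 10, p = 3, sep = 5, seed = 35)
  m <- svm_train(ds, C = 10, gamma = 0.5)
  wrong <- ds
  wrong$y[1] <- 2L  # 1 of 4 truth labels wrong in a 4-row slice
  slice <- spectra_dataset(ds$X[c(1, 2, 11, 12), ], wrong$y[c(1, 2, 11, 12)],
                           ds$meta[c(1, 2, 11, 12), ], ds$wavelengths)
  rep4 <- svm_predict(m, slice)$report
  expect_equal(rep4$accuracy, 75)
  expect_equal(sum(rep4$confusion), 4)
  perm <- sample(nrow(ds$X))
  expect_equal(svm_predict(m, ds$X[perm, ])$labels,
               svm_predict(m, ds$X)$labels[perm])
  expect_error(svm_predict(m, ds$X[, 1:2]), "band count")
})

test_that("ties in the one-vs-one vote go to the smallest label", {
  bundle <- structure(list(
    classes = c(1L, 2L, 3L), C = 1, gamma = 1, kernel = "rbf",
    scale = FALSE, center = 0, scaling = 1, wavelengths = 1,
    pairs = t(combn(3, 2)),
    SV = matrix(0, 1, 1),
    pair_sv = list(1L, 1L, 1L),
    pair_coef = list(0, 0, 0),
    # a 3-cycle: 1 beats 2, 3 beats 1, 2 beats 3 -> one vote each
    b = c(1, -1, 1)), class = "svm_bundle")
  expect_equal(svm_predict(bundle, matrix(0, 1, 1))$labels, 1L)
})

test_that("grid search returns the argmax with deterministic tie-breaks", {
  ds <- toy_dataset(K = 2, n = 20, p = 3, sep = 6, seed = 36)
  single <- grid_search(ds, C_grid = 2, g_grid = 0.5, folds = 4)
  expect_equal(single$C, 2); expect_equal(single$gamma, 0.5)
  gs <- grid_search(ds, C_grid = c(1, 16), g_grid = c(0.1, 1), folds = 4,
                    seed = 3)
  expect_equal(nrow(gs$trace), 4)
  # independent oracle loop over the same folds
  oracle <- apply(gs$trace, 1, function(row) {
    set.seed(3)
    fold <- integer(nrow(ds$X))
    for (k in sort(unique(ds$y))) {
      idx <- sample(which(ds$y == k))
      fold[idx] <- rep_len(1:4, length(idx))
    }
    correct <- 0
    for (f in 1:4) {
      m <- svm_train(spectra_dataset(ds$X[fold != f, ], ds$y[fold != f],
                                     ds$meta[fold != f, ], ds$wavelengths),
                     C = row[["C"]], gamma = row[["gamma"]])
      correct <- correct + sum(svm_predict(m, ds$X[fold == f, ])$labels ==
                                 ds$y[fold == f])
    }
    100 * correct / nrow(ds$X)
  })
  expect_equal(gs$trace$cv_accuracy, as.numeric(oracle))
  expect_equal(gs$cv_accuracy, 100)  # separable toy: some point separates
  best <- which(gs$trace$cv_accuracy == max(gs$trace$cv_accuracy))
  expect_equal(c(gs$C, gs$gamma),
               as.numeric(gs$trace[best[1], c("C", "gamma")]))
  expect_error(grid_search(ds, folds = 50), "smallest class")
})

test_that("the Laplacian kernel variant agrees with kernlab", {
  ds <- toy_dataset(K = 2, n = 15, p = 4, sep = 3, seed = 37)
  m <- svm_train(ds, C = 10, gamma = 0.5, kernel = "laplacian")
  expect_equal(m$cal_accuracy, 100)
  ref <- kernlab::ksvm(ds$X, factor(ds$y), type = "C-svc",
                       kernel = "laplacedot", kpar = list(sigma = 0.5),
                       C = 10, scaled = FALSE)
  expect_equal(svm_predict(m, ds$X)$labels,
               as.integer(as.character(kernlab::predict(ref, ds$X))))
})

test_that("bundles serialize to JSON+binary and round-trip", {
  ds <- toy_dataset(K = 3, n = 12, p = 5, sep = 2, seed = 38)
  m <- svm_train(ds, C = 4, gamma = 0.25)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "bundle")
  save_svm_bundle(m, stem)
  m2 <- load_svm_bundle(stem)
  expect_equal(svm_predict(m2, ds$X)$labels, svm_predict(m, ds$X)$labels)
  expect_equal(decision_values(m2, ds$X), decision_values(m, ds$X),
               tolerance = 1e-14)
  # re-saving the loaded bundle is bit-identical
  save_svm_bundle(m2, file.path(dir, "bundle2"))
  expect_identical(readBin(paste0(stem, ".bin"), "raw", 1e6),
                   readBin(file.path(dir, "bundle2.bin"), "raw", 1e6))
})
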