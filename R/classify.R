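#' Calibration/prediction split of a study
#'
#' Assigns the first `cal_per_class` scenes of every class (in scene order)
#' to the calibration set and the remaining scenes to the prediction set —
#' the whole-image split conventional for conveyor studies (4 calibration +
#' 2 prediction images per variety).
#'
#' @param plan scene table with columns `scene_id` and `class_label`
#'   (e.g. from [study_plan()] or [extract_study_spectra()]).
#' @param cal_per_class calibration scenes per class (default 4).
#' @param pixels_per_class_cal pixels sampled per class for pixel-wise
#'   calibration (default 2000).
#' @return object of class `split_plan`: list with `cal_scenes`,
#'   `pred_scenes` (scene ids), `pixels_per_class_cal`.
#' @export
make_splits <- function(plan, cal_per_class = 4, pixels_per_class_cal = 2000) {
  stopifnot(all(c("scene_id", "class_label") %in% names(plan)))
  cal <- integer(0); pred <- integer(0)
  for (k in sort(unique(plan$class_label))) {
    ids <- plan$scene_id[plan$class_label == k]
    if (length(ids) < cal_per_class + 1)
      stop("class ", k, " has ", length(ids), " scene(s); need at least ",
           cal_per_class + 1, " for a non-empty prediction set")
    cal <- c(cal, ids[seq_len(cal_per_class)])
    pred <- c(pred, ids[-seq_len(cal_per_class)])
  }
  structure(list(cal_scenes = cal, pred_scenes = pred,
                 pixels_per_class_cal = pixels_per_class_cal),
            class = "split_plan")
}

#' Randomly sample calibration pixels per class
#'
#' Draws exactly `plan$pixels_per_class_cal` pixel spectra per class,
#' uniformly without replacement, from the calibration scenes.
#'
#' @param pixels pixel-level [spectra_dataset()] (all scenes; rows from
#'   non-calibration scenes are excluded first).
#' @param plan a [make_splits()] plan.
#' @param seed RNG seed.
#' @return [spectra_dataset()] with `K * pixels_per_class_cal` rows.
#' @export
sample_pixels <- function(pixels, plan, seed = 1) {
  stopifnot(inherits(pixels, "spectra_dataset"), inherits(plan, "split_plan"))
  in_cal <- pixels$meta$scene_id %in% plan$cal_scenes
  n <- plan$pixels_per_class_cal
  set.seed(seed)
  rows <- unlist(lapply(sort(unique(pixels$y)), function(k) {
    avail <- which(in_cal & pixels$y == k)
    if (length(avail) < n)
      stop("class ", k, " has only ", length(avail),
           " calibration pixels; ", n, " requested")
    sort(sample(avail, n))
  }))
  spectra_dataset(pixels$X[rows, , drop = FALSE], pixels$y[rows],
                  pixels$meta[rows, , drop = FALSE], pixels$wavelengths)
}

# kernel matrix between rows of X and rows of SV
.kernel_matrix <- function(X, SV, gamma, kernel) {
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * tcrossprod(X, SV)
  d2[d2 < 0] <- 0
  if (kernel == "rbf") exp(-gamma * d2) else exp(-gamma * sqrt(d2))
}

#' Train a one-vs-one soft-margin SVM
#'
#' Trains the K(K-1)/2 binary soft-margin SVMs of the one-vs-one multiclass
#' scheme with a Gaussian RBF kernel `exp(-g ||xi - xj||^2)` (the
#' `"laplacian"` kernel `exp(-g ||xi - xj||)` is available as the literal
#' unsquared reading some texts print).  RBF problems are solved by libsvm
#' (via e1071) and the per-binary-problem support vectors, coefficients
#' `alpha_i y_i` and bias are unpacked into the bundle; Laplacian problems
#' are solved pairwise by kernlab.  Every binary problem satisfies the KKT
#' conditions `sum(alpha_i y_i) = 0` and `0 <= alpha_i <= C`.
#'
#' Prediction ([svm_predict()]) evaluates the stored decision functions
#' `f(x) = sum alpha_i y_i K(x, x_i) + b` directly, so a saved bundle is
#' self-contained.
#'
#' @param ds calibration [spectra_dataset()] (>= 2 classes, >= 2 samples
#'   per class).
#' @param C soft-margin penalty.
#' @param gamma kernel width parameter g.
#' @param kernel `"rbf"` (default) or `"laplacian"`.
#' @param scale standardize columns before training (default FALSE;
#'   reflectance is already on a common scale).
#' @return object of class `svm_bundle`.
#' @export
svm_train <- function(ds, C = 256, gamma = 0.5, kernel = c("rbf", "laplacian"),
                      scale = FALSE) {
  stopifnot(inherits(ds, "spectra_dataset"))
  kernel <- match.arg(kernel)
  classes <- sort(unique(ds$y))
  if (length(classes) < 2) stop("need >= 2 classes to train an SVM")
  if (any(table(ds$y) < 2)) stop("need >= 2 samples per class")
  X <- ds$X
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (scale) {
    ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  K <- length(classes)
  pairs <- t(combn(K, 2))
  bundle <- list(classes = classes, C = C, gamma = gamma, kernel = kernel,
                 scale = scale, center = ctr, scaling = scl,
                 wavelengths = ds$wavelengths, pairs = pairs)
  if (kernel == "rbf") {
    y <- factor(ds$y, levels = classes)
    m <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
    # unpack libsvm's compressed one-vs-one layout; libsvm orders classes by
    # first appearance in the data (m$labels), not by label value, so map
    # every internal pair back onto the canonical sorted (a, b) pairs and
    # flip signs where the internal orientation is reversed
    ord <- m$labels
    starts <- cumsum(c(0L, m$nSV))
    rows_of <- function(i) if (m$nSV[i] == 0L) integer(0) else
      (starts[i] + 1L):(starts[i] + m$nSV[i])
    bundle$SV <- m$SV
    bundle$pair_sv <- bundle$pair_coef <- vector("list", nrow(pairs))
    bundle$b <- numeric(nrow(pairs))
    key <- paste(pairs[, 1], pairs[, 2])
    p <- 0L
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      p <- p + 1L
      a <- ord[i]; b2 <- ord[j]  # class positions in sorted `classes`
      idx <- c(rows_of(i), rows_of(j))
      co <- c(m$coefs[rows_of(i), j - 1L], m$coefs[rows_of(j), i])
      b0 <- -m$rho[p]
      if (a > b2) { co <- -co; b0 <- -b0; tmp <- a; a <- b2; b2 <- tmp }
      slot <- match(paste(a, b2), key)
      nz <- co != 0
      bundle$pair_sv[[slot]] <- idx[nz]
      bundle$pair_coef[[slot]] <- co[nz]
      bundle$b[slot] <- b0
    }
    bundle$n_sv <- m$nSV
  } else {
    # explicit pairwise training keeps the decision orientation unambiguous
    SV <- NULL
    bundle$pair_sv <- bundle$pair_coef <- vector("list", nrow(pairs))
    bundle$b <- numeric(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      a <- classes[pairs[p, 1]]; b2 <- classes[pairs[p, 2]]
      sub <- ds$y %in% c(a, b2)
      yb <- ifelse(ds$y[sub] == a, 1, -1)
      m <- kernlab::ksvm(X[sub, , drop = FALSE], factor(yb, levels = c(1, -1)),
                         type = "C-svc", kernel = "laplacedot",
                         kpar = list(sigma = gamma), C = C, scaled = FALSE)
      svi <- kernlab::SVindex(m)
      co <- kernlab::coef(m)[[1]]
      b0 <- -kernlab::b(m)
      Xsv <- X[sub, , drop = FALSE][svi, , drop = FALSE]
      # orient so that positive decision means class `a`
      f <- .kernel_matrix(X[sub, , drop = FALSE], Xsv, gamma,
                          "laplacian") %*% co + b0
      if (mean(sign(f)[yb == 1]) < mean(sign(f)[yb == -1])) {
        co <- -co; b0 <- -b0
      }
      off <- if (is.null(SV)) 0L else nrow(SV)
      SV <- rbind(SV, Xsv)
      bundle$pair_sv[[p]] <- off + seq_along(co)
      bundle$pair_coef[[p]] <- as.numeric(co)
      bundle$b[p] <- b0
    }
    bundle$SV <- SV
    bundle$n_sv <- NA_integer_
  }
  class(bundle) <- "svm_bundle"
  tr <- svm_predict(bundle, ds)
  bundle$train_pred <- tr$labels
  bundle$cal_accuracy <- tr$report$accuracy
  bundle
}

#' @export
print.svm_bundle <- function(x, ...) {
  cat(sprintf(
    "<svm_bundle> %d classes, %s kernel, C=%g, g=%g, %d SV rows, cal %.3f%%\n",
    length(x$classes), x$kernel, x$C, x$gamma, nrow(x$SV), x$cal_accuracy))
  invisible(x)
}

#' Pairwise decision values of a bundle
#'
#' Evaluates `f_p(x) = sum alpha_i y_i K(x, x_i) + b_p` for every binary
#' problem `p`; positive means the pair's first (smaller) class.
#'
#' @param bundle an [svm_train()] bundle.
#' @param X spectra matrix on the training band grid.
#' @param chunk rows per block (bounds the kernel-matrix memory).
#' @return numeric matrix, `nrow(X)` x `n_pairs`.
#' @export
decision_values <- function(bundle, X, chunk = 8192) {
  if (ncol(X) != ncol(bundle$SV))
    stop("band count ", ncol(X), " does not match training (",
         ncol(bundle$SV), ")")
  if (bundle$scale)
    X <- sweep(sweep(X, 2, bundle$center), 2, bundle$scaling, "/")
  np <- nrow(bundle$pairs)
  dv <- matrix(0, nrow(X), np)
  for (start in seq(1, nrow(X), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(X))
    Km <- .kernel_matrix(X[rows, , drop = FALSE], bundle$SV, bundle$gamma,
                         bundle$kernel)
    for (p in seq_len(np))
      dv[rows, p] <- Km[, bundle$pair_sv[[p]], drop = FALSE] %*%
        bundle$pair_coef[[p]] + bundle$b[p]
  }
  colnames(dv) <- apply(bundle$pairs, 1, function(pr)
    paste0(bundle$classes[pr[1]], "/", bundle$classes[pr[2]]))
  dv
}

#' Predict with a one-vs-one SVM bundle
#'
#' Majority vote over the pairwise decision functions; ties break toward the
#' smallest class label.  When `ds` carries truth labels an evaluation
#' report (accuracy percent + confusion matrix) is attached.
#'
#' @param bundle an [svm_train()] bundle.
#' @param ds a [spectra_dataset()] or plain spectra matrix.
#' @return list with `labels` (integer predictions) and `report`
#'   ([eval_report()] or NULL).
#' @export
svm_predict <- function(bundle, ds) {
  X <- if (inherits(ds, "spectra_dataset")) ds$X else as.matrix(ds)
  dv <- decision_values(bundle, X)
  K <- length(bundle$classes)
  votes <- matrix(0L, nrow(X), K)
  for (p in seq_len(nrow(bundle$pairs))) {
    a <- bundle$pairs[p, 1]; b <- bundle$pairs[p, 2]
    pos <- dv[, p] > 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  # max.col with ties.method "first" = smallest class label (sorted classes)
  labels <- bundle$classes[max.col(votes, ties.method = "first")]
  report <- NULL
  if (inherits(ds, "spectra_dataset") && length(ds$y))
    report <- eval_report(ds$y, labels, bundle$classes)
  list(labels = labels, report = report)
}

#' Classification accuracy report
#'
#' Accuracy is the percentage of correctly classified samples taken from all
#' samples; the confusion matrix counts truth (rows) against prediction
#' (columns).
#'
#' @param truth,pred integer label vectors.
#' @param classes label universe (default: union observed).
#' @return object of class `eval_report`: list with `accuracy` (percent),
#'   `confusion`, `n`.
#' @export
eval_report <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  structure(list(accuracy = 100 * mean(truth == pred),
                 confusion = unclass(confusion), n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %.3f%% of %d samples\n", x$accuracy, x$n))
  invisible(x)
}

#' Grid search of (C, gamma) by stratified cross-validation
#'
#' Evaluates every grid point by stratified k-fold cross-validated accuracy
#' and returns the argmax; ties break toward smaller C, then smaller gamma.
#'
#' @param ds calibration [spectra_dataset()].
#' @param C_grid,g_grid candidate values (defaults: the log-2 grids
#'   `2^(-4..12)` and `2^(-10..4)` conventional for RBF-SVM chemometrics).
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param kernel forwarded to [svm_train()].
#' @return list with `C`, `gamma`, `cv_accuracy` and `trace` (data.frame of
#'   all grid points with their CV accuracy).
#' @export
grid_search <- function(ds, C_grid = 2^(-4:12), g_grid = 2^(-10:4),
                        folds = 5, seed = 1, kernel = "rbf") {
  stopifnot(inherits(ds, "spectra_dataset"), folds >= 2)
  classes <- sort(unique(ds$y))
  if (min(table(ds$y)) < folds)
    stop("folds (", folds, ") exceeds the size of the smallest class (",
         min(table(ds$y)), ")")
  set.seed(seed)
  fold <- integer(nrow(ds$X))
  for (k in classes) {
    idx <- sample(which(ds$y == k))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  C_grid <- sort(C_grid); g_grid <- sort(g_grid)
  grid <- expand.grid(gamma = g_grid, C = C_grid)[, c("C", "gamma")]
  cv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      m <- svm_train(spectra_dataset(ds$X[tr, , drop = FALSE], ds$y[tr],
                                     ds$meta[tr, , drop = FALSE],
                                     ds$wavelengths),
                     C = grid$C[i], gamma = grid$gamma[i], kernel = kernel)
      pr <- svm_predict(m, ds$X[te, , drop = FALSE])
      correct <- correct + sum(pr$labels == ds$y[te])
    }
    cv[i] <- 100 * correct / nrow(ds$X)
  }
  best <- which.max(cv)  # first max: smaller C, then smaller gamma
  list(C = grid$C[best], gamma = grid$gamma[best], cv_accuracy = cv[best],
       trace = cbind(grid, cv_accuracy = cv))
}

#' Save / load an SVM bundle
#'
#' `save_svm_bundle()` writes a documented two-file container: a JSON
#' metadata file (`<stem>.json`: classes, kernel, hyperparameters, pair
#' layout, array shapes) and a little-endian binary file (`<stem>.bin`) with
#' the support-vector matrix, coefficients and biases as 64-bit floats.
#' Identical bundles produce bit-identical files.
#'
#' @param bundle an [svm_train()] bundle.
#' @param stem output path without extension.
#' @return `stem`, invisibly.
#' @export
save_svm_bundle <- function(bundle, stem) {
  stopifnot(inherits(bundle, "svm_bundle"))
  meta <- list(classes = bundle$classes, C = bundle$C, gamma = bundle$gamma,
               kernel = bundle$kernel, scale = bundle$scale,
               wavelengths = bundle$wavelengths,
               pairs = unclass(bundle$pairs),
               pair_sv = bundle$pair_sv,
               n_coef = vapply(bundle$pair_coef, length, 1L),
               sv_dim = dim(bundle$SV), b = bundle$b,
               cal_accuracy = bundle$cal_accuracy)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(stem, ".json"))
  con <- file(paste0(stem, ".bin"), "wb"); on.exit(close(con))
  writeBin(c(as.vector(bundle$SV), unlist(bundle$pair_coef),
             bundle$center, bundle$scaling),
           con, size = 8L, endian = "little")
  invisible(stem)
}

#' @rdname save_svm_bundle
#' @export
load_svm_bundle <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"), simplifyMatrix = FALSE)
  con <- file(paste0(stem, ".bin"), "rb"); on.exit(close(con))
  p <- meta$sv_dim[2]
  nsv <- meta$sv_dim[1]
  v <- readBin(con, "double", n = nsv * p + sum(meta$n_coef) + 2 * p,
               size = 8L, endian = "little")
  SV <- matrix(v[seq_len(nsv * p)], nsv, p)
  off <- nsv * p
  pair_coef <- vector("list", length(meta$n_coef))
  for (i in seq_along(meta$n_coef)) {
    pair_coef[[i]] <- v[off + seq_len(meta$n_coef[i])]
    off <- off + meta$n_coef[i]
  }
  bundle <- list(classes = as.integer(meta$classes), C = meta$C,
                 gamma = meta$gamma, kernel = meta$kernel,
                 scale = as.logical(meta$scale),
                 center = v[off + seq_len(p)],
                 scaling = v[off + p + seq_len(p)],
                 wavelengths = as.numeric(meta$wavelengths),
                 pairs = do.call(rbind, lapply(meta$pairs, as.integer)),
                 pair_sv = lapply(meta$pair_sv, as.integer),
                 pair_coef = pair_coef, b = as.numeric(meta$b),
                 SV = SV, cal_accuracy = meta$cal_accuracy)
  class(bundle) <- "svm_bundle"
  bundle
}

#' Write an evaluation report as JSON
#'
#' @param report an [eval_report()].
#' @param path destination `.json`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  writeLines(jsonlite::toJSON(list(accuracy = report$accuracy,
                                   n = report$n,
                                   confusion = unclass(report$confusion)),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
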