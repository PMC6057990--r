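#' Perceptual blurring specification
#'
#' Gaussian blurring of classifier input features at the measured perceptual
#' change thresholds: ~36 Hz for frequency, ~450 deg/s for intensity and
#' 23600 deg/s^2 for slip acceleration. Each feature value is replaced by a
#' draw from a Gaussian centered on the value with SD equal to the fraction
#' of its threshold. In the standard comparison `f` and `i` are blurred at
#' 100%, 50% or 30% of threshold while `sa` is always blurred at 100% (the
#' most unfavorable condition for the slip code).
#'
#' @param threshold_f Frequency change threshold, Hz (default 36).
#' @param threshold_i Intensity change threshold, deg/s (default 450).
#' @param threshold_sa Acceleration change threshold, deg/s^2 (default 23600).
#' @param fraction_f_i Blur fraction applied to `f` and `i`, in (0, 1].
#' @param fraction_sa Blur fraction applied to `sa` (default 1).
#' @return An object of class `blur_spec`.
#' @export
blur_spec <- function(threshold_f = 36, threshold_i = 450,
                      threshold_sa = 23600, fraction_f_i = 1,
                      fraction_sa = 1) {
  stopifnot(threshold_f > 0, threshold_i > 0, threshold_sa > 0,
            fraction_f_i > 0, fraction_f_i <= 1,
            fraction_sa > 0, fraction_sa <= 1)
  structure(list(threshold_f = threshold_f, threshold_i = threshold_i,
                 threshold_sa = threshold_sa, fraction_f_i = fraction_f_i,
                 fraction_sa = fraction_sa),
            class = "blur_spec")
}

#' Blur classifier input features at perceptual thresholds
#'
#' Substitutes each value of the `f`, `i` and `sa` (or `sa_med`) columns by a
#' random pick from a Gaussian with mean equal to the value and SD equal to
#' the blur fraction times the variable's perceptual threshold. Labels and
#' context columns are untouched; deterministic given the seed.
#'
#' @param table data.frame with any of columns `f`, `i`, `sa`, `sa_med`.
#' @param spec A [blur_spec()].
#' @param seed Integer seed.
#' @return The table with blurred feature columns.
#' @export
blur_features <- function(table, spec = blur_spec(), seed = 1L) {
  stopifnot(is.data.frame(table), inherits(spec, "blur_spec"))
  sds <- c(f = spec$threshold_f * spec$fraction_f_i,
           i = spec$threshold_i * spec$fraction_f_i,
           sa = spec$threshold_sa * spec$fraction_sa,
           sa_med = spec$threshold_sa * spec$fraction_sa)
  cols <- intersect(names(sds), names(table))
  if (!length(cols)) stop("no blurrable feature column (f, i, sa) in table")
  with_seed(seed, {
    for (cl in cols) {
      v <- table[[cl]]
      ok <- !is.na(v)
      v[ok] <- rnorm(sum(ok), mean = v[ok], sd = sds[[cl]])
      table[[cl]] <- v
    }
  })
  table
}

#' Default hyper-parameter grids for classifier model selection
#'
#' Linear SVM: cost C on a log grid 0.01..100. RBF SVM: the same C grid
#' crossed with kernel width gamma at 0.1x, 1x and 10x the scale heuristic
#' `1 / n_features` (features are standardized before fitting). Logistic
#' regression: ridge penalty lambda = 1/C on the same grid.
#'
#' @param n_features Number of input features (sets the gamma scale).
#' @return List of per-family parameter data.frames.
#' @export
default_grids <- function(n_features = 3) {
  C <- 10^(-2:2)
  gscale <- 1 / n_features
  list(
    linear_svm = data.frame(C = C),
    rbf_svm = expand.grid(C = C, gamma = gscale * c(0.1, 1, 10)),
    logistic = data.frame(lambda = 1 / C)
  )
}

# ---- one-against-all machinery ------------------------------------------

# Fit one binary decision-function classifier: positive class vs rest.
# Decision values are sign-oriented on the training data so that larger
# means more positive-class.
fit_binary <- function(x, y_pos, family, params) {
  yb <- factor(ifelse(y_pos, "pos", "rest"), levels = c("pos", "rest"))
  if (family == "logistic") {
    xg <- if (ncol(x) == 1) cbind(x, 0) else x
    fit <- glmnet::glmnet(xg, yb, family = "binomial", alpha = 0,
                          lambda = params$lambda, standardize = FALSE)
    dec_fun <- function(newx) {
      nxg <- if (ncol(newx) == 1) cbind(newx, 0) else newx
      -drop(predict(fit, nxg, type = "link"))  # link is for 2nd level
    }
  } else {
    kern <- if (family == "linear_svm") "linear" else "radial"
    args <- list(x = x, y = yb, kernel = kern, cost = params$C,
                 scale = FALSE)
    if (family == "rbf_svm") args$gamma <- params$gamma
    fit <- do.call(e1071::svm, args)
    dec_fun <- function(newx) {
      drop(attr(predict(fit, newx, decision.values = TRUE),
                "decision.values"))
    }
  }
  dec_train <- dec_fun(x)
  flip <- mean(dec_train[y_pos]) < mean(dec_train[!y_pos])
  function(newx) {
    d <- dec_fun(newx)
    if (flip) -d else d
  }
}

# One-against-all fit: one decision function per class; predict by argmax.
ova_fit <- function(x, y, family, params) {
  lv <- levels(y)
  funs <- lapply(lv, function(cl) fit_binary(x, y == cl, family, params))
  names(funs) <- lv
  structure(list(decision = funs, levels = lv), class = "ova_model")
}

ova_predict <- function(model, newx) {
  dec <- vapply(model$decision, function(f) f(newx),
                numeric(nrow(newx)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  factor(model$levels[max.col(dec, ties.method = "first")],
         levels = model$levels)
}

# Stratified k-fold assignment (returns integer fold per row).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split: returns logical TRUE = train.
stratified_split <- function(y, train_fraction) {
  train <- logical(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n_tr <- max(1, round(train_fraction * length(idx)))
    train[idx[seq_len(min(n_tr, length(idx) - 1))]] <- TRUE
  }
  train
}

#' Train, model-select and score a one-against-all classifier
#'
#' The classifier comparison procedure: stratified train/test split (80/20 by
#' default), grid search over three classifier families — linear SVM, RBF
#' SVM and ridge logistic regression — by stratified 10-fold cross-validation
#' on the training split, selection of the family and hyper-parameters with
#' the best mean CV accuracy, and evaluation of that model on the held-out
#' test set. Features are standardized with training-split statistics only.
#' Multi-class problems use a one-against-all scheme with argmax over the
#' per-class decision functions.
#'
#' @param x Numeric matrix or data.frame of features (rows = sweeps).
#' @param y Class labels (coerced to factor).
#' @param seed Integer seed (controls split and fold assignment).
#' @param grids Hyper-parameter grids, see [default_grids()].
#' @param train_fraction Fraction of data in the training split (default 0.8).
#' @param n_folds Cross-validation folds (default 10).
#' @return List with `score` (held-out accuracy), `classifier_chosen`,
#'   `params` (chosen hyper-parameters), `cv_score` (best mean CV accuracy),
#'   `n_train`, `n_test`.
#' @export
train_and_select <- function(x, y, seed = 1L, grids = NULL,
                             train_fraction = 0.8, n_folds = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(factor(y))
  stopifnot(nrow(x) == length(y), nlevels(y) >= 2)
  if (is.null(grids)) grids <- default_grids(ncol(x))
  if (min(table(y)) < n_folds) {
    stop(sprintf(paste0("each class needs at least %d samples for %d-fold ",
                        "stratified cross-validation; smallest class has %d. ",
                        "Provide more sweeps per texture or reduce n_folds."),
                 n_folds, n_folds, min(table(y))))
  }
  with_seed(seed, {
    train <- stratified_split(y, train_fraction)
    x_tr <- x[train, , drop = FALSE]; y_tr <- droplevels(y[train])
    x_te <- x[!train, , drop = FALSE]; y_te <- y[!train]
    ctr <- colMeans(x_tr)
    scl <- apply(x_tr, 2, sd)
    scl[scl == 0] <- 1
    x_tr <- scale(x_tr, ctr, scl)
    x_te <- scale(x_te, ctr, scl)
    fold <- stratified_folds(y_tr, n_folds)
    best <- list(cv = -Inf)
    for (family in names(grids)) {
      grid <- grids[[family]]
      for (gi in seq_len(nrow(grid))) {
        params <- as.list(grid[gi, , drop = FALSE])
        accs <- vapply(seq_len(n_folds), function(kf) {
          tr <- fold != kf
          m <- ova_fit(x_tr[tr, , drop = FALSE], droplevels(y_tr[tr]),
                       family, params)
          mean(ova_predict(m, x_tr[!tr, , drop = FALSE]) == y_tr[!tr])
        }, numeric(1))
        cv <- mean(accs)
        if (cv > best$cv) best <- list(cv = cv, family = family,
                                       params = params)
      }
    }
    final <- ova_fit(x_tr, y_tr, best$family, best$params)
    score <- mean(ova_predict(final, x_te) == y_te)
    list(score = score, classifier_chosen = best$family,
         params = best$params, cv_score = best$cv,
         n_train = sum(train), n_test = sum(!train))
  })
}

#' Run the blurred classification tasks
#'
#' For every blur level and feature set, trains and model-selects classifiers
#' on the per-sweep feature table for two tasks: identifying the texture out
#' of five (`identity5`; chance 0.2) and discriminating pairs of textures
#' with neighboring grain size (`pair`; chance 0.5; score averaged across the
#' four neighboring pairs). `f` and `i` are blurred at the given fraction of
#' their perceptual thresholds; `sa` is always blurred at
#' `fraction_sa` (default 100%). Rows with missing features (sweeps without
#' slips, for sa-containing sets) are dropped per feature set.
#'
#' @param features A `feature_table` from [build_feature_table()], or its
#'   `sweeps` data.frame.
#' @param blur_fractions Blur fractions for `f`/`i` (default 1, 0.5, 0.3).
#' @param feature_sets Named list of feature-column subsets (default `f`,
#'   `i`, `sa`, and combined `f/i/sa`).
#' @param tasks Character subset of `c("identity5", "pair")`.
#' @param seed Integer seed.
#' @param spec Base [blur_spec()] carrying the thresholds.
#' @param n_repeats Median score over this many seed-varied repeats of the
#'   split/selection procedure (default 1).
#' @param whisker,speed,distance Optional context filters.
#' @param ... Passed to [train_and_select()] (e.g. `n_folds`).
#' @return data.frame: `task`, `feature_set`, `blur_fraction`, `score`
#'   (median over repeats; for the pair task the mean across the four
#'   neighboring pairs), `n`.
#' @export
run_tasks <- function(features, blur_fractions = c(1, 0.5, 0.3),
                      feature_sets = list(f = "f", i = "i", sa = "sa",
                                          "f/i/sa" = c("f", "i", "sa")),
                      tasks = c("identity5", "pair"), seed = 1L,
                      spec = blur_spec(), n_repeats = 1,
                      whisker = NULL, speed = NULL, distance = NULL, ...) {
  tab <- if (inherits(features, "feature_table")) features$sweeps else features
  stopifnot(is.data.frame(tab))
  if (!"sa" %in% names(tab) && "sa_med" %in% names(tab)) {
    tab$sa <- tab$sa_med
  }
  if (!is.null(whisker)) tab <- tab[tab$whisker == whisker, ]
  if (!is.null(speed)) tab <- tab[tab$speed == speed, ]
  if (!is.null(distance)) tab <- tab[tab$distance == distance, ]
  tasks <- match.arg(tasks, c("identity5", "pair"), several.ok = TRUE)
  nb_pairs <- data.frame(a = texture_order[1:4], b = texture_order[2:5])
  out <- list()
  cnt <- 0L
  for (bf in blur_fractions) {
    bspec <- blur_spec(threshold_f = spec$threshold_f,
                       threshold_i = spec$threshold_i,
                       threshold_sa = spec$threshold_sa,
                       fraction_f_i = bf, fraction_sa = spec$fraction_sa)
    cnt <- cnt + 1L
    blurred <- blur_features(tab, bspec, seed = child_seed(seed, cnt))
    for (fs in names(feature_sets)) {
      cols <- feature_sets[[fs]]
      sub <- blurred[complete.cases(blurred[, cols, drop = FALSE]), ]
      for (task in tasks) {
        run_one <- function(x, y, base_seed) {
          scores <- vapply(seq_len(n_repeats), function(r) {
            train_and_select(x, y, seed = child_seed(base_seed, r), ...)$score
          }, numeric(1))
          median(scores)
        }
        cnt <- cnt + 1L
        if (task == "identity5") {
          sc <- run_one(sub[, cols, drop = FALSE], sub$texture,
                        child_seed(seed, cnt))
          n_used <- nrow(sub)
        } else {
          pr <- vapply(seq_len(nrow(nb_pairs)), function(pi) {
            ss <- sub[sub$texture %in% c(nb_pairs$a[pi], nb_pairs$b[pi]), ]
            run_one(ss[, cols, drop = FALSE], ss$texture,
                    child_seed(seed, cnt + pi))
          }, numeric(1))
          cnt <- cnt + nrow(nb_pairs)
          sc <- mean(pr)
          n_used <- nrow(sub)
        }
        out[[length(out) + 1L]] <- data.frame(
          task = task, feature_set = fs, blur_fraction = bf,
          score = sc, n = n_used, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
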