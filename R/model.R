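#' Split a feature table into train / validation / test sets
#'
#' 60/20/20 split preserving both the class mix and the volume
#' distribution. Per-class split sizes use largest-remainder rounding with
#' ties broken toward the split with the largest global deficit (classes
#' processed in decreasing size), which keeps per-class proportions within
#' one region of the fractions. Within each class, rows are ordered by
#' volume and allocated by a proportional quota walk, randomised by
#' shuffling the split labels inside consecutive windows of 5 rows — so
#' each split samples every part of the volume distribution.
#'
#' @param table data.frame/data.table with columns `label` and `volume_cc`.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed; the split is a pure function of
#'   `(table, fractions, seed)`.
#' @return the table with a `split` column added
#'   (train/validation/test).
#' @export
split_dataset <- function(table, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  tab <- data.table::as.data.table(table)
  if (!all(c("label", "volume_cc") %in% names(tab)))
    stop("table needs `label` and `volume_cc` columns")
  splits <- c("train", "validation", "test")
  counts <- sort(table(tab$label), decreasing = TRUE)
  classes <- names(counts)
  if (any(counts < 3))
    warning("a class has fewer rows than splits; best-effort allocation")

  # per-class sizes: largest remainder, ties to the largest global deficit
  alloc <- matrix(0L, length(classes), 3,
                  dimnames = list(classes, splits))
  cum <- c(0, 0, 0)
  total <- 0
  for (ci in seq_along(classes)) {
    n <- as.integer(counts[ci])
    raw <- n * fractions
    base <- floor(raw)
    rem <- n - sum(base)
    total <- total + n
    deficit <- total * fractions - (cum + base)
    ord <- order(-(raw - base), -deficit, seq_len(3))
    add <- integer(3)
    if (rem > 0) add[ord[seq_len(rem)]] <- 1L
    alloc[ci, ] <- as.integer(base + add)
    cum <- cum + alloc[ci, ]
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  tab$split <- NA_character_
  for (ci in seq_along(classes)) {
    rows <- which(tab$label == classes[ci])
    rows <- rows[order(tab$volume_cc[rows])]
    sizes <- alloc[ci, ]
    left <- sizes
    seq_labels <- character(length(rows))
    for (i in seq_along(rows)) {
      frac_left <- ifelse(sizes > 0, left / sizes, -Inf)
      s <- which.max(frac_left)
      seq_labels[i] <- splits[s]
      left[s] <- left[s] - 1L
    }
    # seeded shuffle inside volume-adjacent windows keeps volume balance
    for (i in seq(1, length(rows), by = 5)) {
      w <- i:min(i + 4, length(rows))
      if (length(w) > 1) seq_labels[w] <- seq_labels[sample(w)]
    }
    tab$split[rows] <- seq_labels
  }
  tab
}

balanced_class_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Fit a class-weighted L2-penalised logistic regression
#'
#' Maximizes the class-weighted log-likelihood with an L2 penalty of
#' strength `1/C` on the coefficients (the intercept is unpenalised), by
#' BFGS with analytic gradients, initialised at zero — deterministic given
#' the data. `'balanced'` class weights are `n_total / (2 * n_class)`, so
#' equal class counts give weight 1 to both classes. Perfect separation
#' yields a converged-at-cap result with a warning, not a failure.
#'
#' @param x numeric matrix of features (columns named).
#' @param y binary response (0/1).
#' @param C inverse regularisation strength (> 0).
#' @param max_iter iteration cap.
#' @param class_weight `"balanced"`, a named numeric vector
#'   `c("0" = ., "1" = .)`, or NULL for unit weights.
#' @param fit_intercept include an intercept.
#' @param tol convergence tolerance (relative objective change).
#' @param threshold probability cutoff for the binary label.
#' @return A `logistic_model`: `intercept` (w0), `coefficients` (named
#'   w1..wn), hyperparameters, `threshold`, `converged`.
#' @export
fit_logistic <- function(x, y, C = 1, max_iter = 10,
                         class_weight = "balanced", fit_intercept = TRUE,
                         tol = 1e-4, threshold = 0.5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(x)))
  cw <- if (identical(class_weight, "balanced")) balanced_class_weights(y)
        else if (is.null(class_weight)) c("0" = 1, "1" = 1)
        else class_weight
  s <- ifelse(y == 1, cw[["1"]], cw[["0"]])
  p_ix <- if (fit_intercept) 1 + seq_len(ncol(x)) else seq_len(ncol(x))
  X <- if (fit_intercept) cbind(1, x) else x

  nll <- function(w) {
    eta <- drop(X %*% w)
    # numerically stable weighted cross-entropy
    log1pexp <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    ll <- sum(s * (y * eta - log1pexp))
    pen <- sum(w[p_ix]^2) / (2 * C)
    -ll + pen
  }
  grad <- function(w) {
    p <- stats::plogis(drop(X %*% w))
    g <- drop(crossprod(X, s * (p - y)))
    g[p_ix] <- g[p_ix] + w[p_ix] / C
    g
  }
  res <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  if (res$convergence != 0)
    warning("logistic fit stopped at the iteration cap (max_iter = ",
            max_iter, ")")
  w <- res$par
  intercept <- if (fit_intercept) w[1] else 0
  coefs <- stats::setNames(if (fit_intercept) w[-1] else w, nm)
  structure(list(intercept = intercept, coefficients = coefs,
                 hyperparameters = list(C = C, penalty = "l2",
                                        max_iter = max_iter,
                                        class_weight = class_weight,
                                        fit_intercept = fit_intercept),
                 threshold = threshold,
                 converged = res$convergence == 0),
            class = "logistic_model")
}

#' Construct a logistic model from known coefficients
#'
#' For evaluating a published model without refitting, e.g. the
#' single-feature ADC model `w0 = 1.96`, `w1 = -1.74`.
#'
#' @param intercept w0.
#' @param coefficients named numeric vector w1..wn.
#' @param threshold probability cutoff.
#' @return A `logistic_model`.
#' @export
logistic_model <- function(intercept, coefficients, threshold = 0.5) {
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 hyperparameters = list(C = 1, penalty = "l2",
                                        max_iter = 10,
                                        class_weight = "balanced",
                                        fit_intercept = TRUE),
                 threshold = threshold, converged = TRUE),
            class = "logistic_model")
}

#' Predicted probability of the positive class
#'
#' `P = 1 / (1 + exp(-(w0 + w1 x1 + ... + wn xn)))`.
#'
#' @param model a `logistic_model`.
#' @param x data.frame/matrix (or named vector) covering every model
#'   feature by name.
#' @return numeric probabilities in (0, 1).
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "logistic_model"))
  nm <- names(model$coefficients)
  if (is.null(dim(x))) x <- t(as.matrix(x))
  x <- as.matrix(as.data.frame(x))
  missing <- setdiff(nm, colnames(x))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "))
  eta <- model$intercept + drop(x[, nm, drop = FALSE] %*% model$coefficients)
  stats::plogis(eta)
}

#' @rdname predict_probability
#' @return `predict_label` returns 0/1 at the model threshold
#'   (`P >= threshold` is positive).
#' @export
predict_label <- function(model, x) {
  as.integer(predict_probability(model, x) >= model$threshold)
}

#' Decision boundary of a single-feature logistic model
#'
#' The feature value at which the predicted probability is exactly 0.5:
#' `-w0 / w1`.
#'
#' @param model a `logistic_model` with exactly one nonzero coefficient.
#' @return scalar feature value.
#' @export
decision_boundary_1d <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  if (length(model$coefficients) != 1)
    stop("decision boundary requires exactly one feature")
  w1 <- unname(model$coefficients[1])
  if (w1 == 0) stop("zero coefficient: no decision boundary")
  -model$intercept / w1
}

stratified_folds <- function(y, k = 3, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    if (length(ix) < k)
      stop("stratification error: class ", cls, " has fewer rows than folds")
    fold[ix] <- rep(seq_len(k), length.out = length(ix))
  }
  fold
}

#' Choose the number of mRMR features by cross-validated balanced accuracy
#'
#' For k = 1..k_max, fits the logistic model on the top-k ranked features
#' under stratified threefold cross-validation over the pooled training and
#' validation rows, and picks the k with the highest mean balanced accuracy
#' (ties toward smaller k — fewer features, same accuracy).
#'
#' @param table feature table with `split` and `target` columns.
#' @param ranking an `mrmr_ranking`.
#' @param k_max largest feature count to try (capped at the ranking
#'   length).
#' @param folds number of CV folds.
#' @param seed fold-assignment seed.
#' @param cv_pool `"pooled"` (train + validation, the default) or
#'   `"validation_only"`.
#' @param ... hyperparameters passed to [fit_logistic()].
#' @return list: `k` (chosen count), `trace` (data.table k, cv_balanced_accuracy).
#' @export
select_feature_count_cv <- function(table, ranking, k_max = 20, folds = 3,
                                    seed = 1L, cv_pool = "pooled", ...) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  tab <- data.table::as.data.table(table)
  pool <- switch(cv_pool,
                 pooled = tab[tab$split %in% c("train", "validation"), ],
                 validation_only = tab[tab$split == "validation", ],
                 stop("unknown cv_pool: ", cv_pool))
  y <- pool$target
  fold <- stratified_folds(y, folds, seed)
  k_max <- min(k_max, length(ranking$features))
  trace <- data.table::data.table(k = seq_len(k_max),
                                  cv_balanced_accuracy = NA_real_)
  for (k in seq_len(k_max)) {
    feats <- ranking$features[seq_len(k)]
    bas <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_logistic(as.matrix(pool[tr, feats, with = FALSE]), y[tr], ...)
      pred <- predict_label(m, pool[!tr, feats, with = FALSE])
      confusion_metrics(y[!tr], pred)$balanced_accuracy
    }, 0)
    trace$cv_balanced_accuracy[k] <- mean(bas)
  }
  list(k = trace$k[which.max(trace$cv_balanced_accuracy)], trace = trace)
}

#' Grid search over the logistic hyperparameter domain
#'
#' Exhaustively scores C, class-weight scheme, iteration cap and intercept
#' choices (L2 penalty throughout) by the same cross-validated balanced
#' accuracy as [select_feature_count_cv()], jointly with the feature count;
#' ties are broken toward the reference configuration
#' (C = 1, 'balanced', max_iter = 10, intercept).
#'
#' @inheritParams select_feature_count_cv
#' @param C_grid,max_iter_grid,fit_intercept_grid scalar grids.
#' @param class_weight_grid list of class-weight schemes.
#' @return list: `best` (hyperparameter list + k), `results` (data.table).
#' @export
tune_hyperparameters <- function(table, ranking, k_max = 20, folds = 3,
                                 seed = 1L,
                                 C_grid = c(0.001, 0.01, 0.1, 1, 2, 10),
                                 max_iter_grid = c(10, 50, 100, 500),
                                 class_weight_grid =
                                   list("balanced",
                                        c("0" = 0.2, "1" = 0.8),
                                        c("0" = 1, "1" = 10)),
                                 fit_intercept_grid = c(TRUE, FALSE)) {
  ref <- list(C = 1, max_iter = 10, cw = 1L, fit_intercept = TRUE)
  grid <- expand.grid(C = C_grid, max_iter = max_iter_grid,
                      cw = seq_along(class_weight_grid),
                      fit_intercept = fit_intercept_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- select_feature_count_cv(
      table, ranking, k_max, folds, seed,
      C = grid$C[g], max_iter = grid$max_iter[g],
      class_weight = class_weight_grid[[grid$cw[g]]],
      fit_intercept = grid$fit_intercept[g])
    data.table::data.table(grid[g, ], k = sel$k,
      cv_balanced_accuracy =
        max(sel$trace$cv_balanced_accuracy))
  })
  res <- data.table::rbindlist(res)
  is_ref <- res$C == ref$C & res$max_iter == ref$max_iter &
    res$cw == ref$cw & res$fit_intercept == ref$fit_intercept
  ord <- order(-res$cv_balanced_accuracy, -is_ref)
  best <- res[ord[1], ]
  list(best = list(C = best$C, max_iter = best$max_iter,
                   class_weight = class_weight_grid[[best$cw]],
                   fit_intercept = best$fit_intercept, k = best$k,
                   cv_balanced_accuracy = best$cv_balanced_accuracy),
       results = res)
}
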