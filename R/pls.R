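#' Autoscale a predictor matrix
#'
#' Centers and scales every column to mean 0, SD 1 — required because element
#' concentrations span five orders of magnitude between macronutrients and
#' trace elements. Zero-variance columns are excluded and recorded so that
#' test data can be projected with the training parameters.
#'
#' @param X Numeric matrix or data frame (samples x predictors, >= 2 rows).
#' @return List with `X` (scaled matrix, retained columns only) and `params`
#'   (an `ion_scaling`: `mean`, `sd`, `kept`, `dropped`).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 samples to scale", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  kept <- names(mu)[sdv > 0] %||% which(sdv > 0)
  if (length(kept) == 0) {
    stop("all predictors are constant; nothing to scale", call. = FALSE)
  }
  dropped <- setdiff(colnames(X) %||% seq_len(ncol(X)), kept)
  params <- structure(
    list(mean = mu, sd = sdv, kept = kept, dropped = dropped),
    class = "ion_scaling"
  )
  list(X = apply_scaling(params, X), params = params)
}

#' Apply stored scaling parameters to new data
#'
#' @param params An `ion_scaling` from [autoscale()].
#' @param X New data with (at least) the retained predictor columns.
#' @return Scaled matrix over the retained columns.
#' @export
apply_scaling <- function(params, X) {
  X <- as.matrix(X)
  miss <- setdiff(params$kept, colnames(X))
  if (length(miss) > 0) {
    stop(
      "new data lack predictor column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  Xk <- X[, params$kept, drop = FALSE]
  sweep(
    sweep(Xk, 2, params$mean[params$kept], "-"),
    2, params$sd[params$kept], "/"
  )
}

#' One-hot class indicator matrix
#'
#' @param classes Vector of class labels (>= 2 distinct).
#' @return n x K 0/1 matrix; columns are the sorted unique labels, every row
#'   sums to 1.
#' @export
one_hot <- function(classes) {
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  if (length(lev) < 2) {
    stop("need >= 2 distinct classes to fit a classifier", call. = FALSE)
  }
  Y <- matrix(0, nrow = length(classes), ncol = length(lev),
    dimnames = list(NULL, lev)
  )
  Y[cbind(seq_along(classes), match(classes, lev))] <- 1
  Y
}

#' Fit a PLS2 model by NIPALS
#'
#' Extracts `ncomp` latent components from a scaled predictor matrix and a
#' multivariate response (here the class indicator matrix): for each
#' component, the weight vector `w` is iterated to convergence
#' (`||w_new - w_old|| < tol`, at most `max_iter` sweeps), scores `t = X w`,
#' X-loadings `p = X't/t't`, Y-loadings `q = Y't/t't`, then X and Y are
#' deflated by the rank-one score contribution. Scores of successive
#' components are orthogonal. On non-convergence the weight is restarted from
#' the dominant eigenvector of X'YY'X (with a warning) and accepted after one
#' refinement sweep.
#'
#' @param Xs Scaled predictor matrix (from [autoscale()]).
#' @param Y Response matrix (e.g. from [one_hot()]), row-aligned with `Xs`.
#' @param ncomp Number of latent components (>= 1; truncated to
#'   `min(n - 1, p)` with a warning if larger).
#' @param scaling Optional `ion_scaling` to store for prediction on raw data.
#' @param classes Optional vector of training class labels (enables class
#'   prediction).
#' @param tol,max_iter NIPALS convergence controls.
#' @return An `ion_pls` model: weights `W`, X-loadings `P`, Y-loadings `Q`,
#'   scores `T`, rotation `R = W (P'W)^-1`, plus scaling/class metadata.
#' @export
fit_pls2 <- function(Xs, Y, ncomp, scaling = NULL, classes = NULL,
                     tol = 1e-10, max_iter = 500) {
  Xs <- as.matrix(Xs)
  Y <- as.matrix(Y)
  stopifnot(nrow(Xs) == nrow(Y), ncomp >= 1)
  n <- nrow(Xs)
  p <- ncol(Xs)
  a_max <- min(n - 1, p)
  if (ncomp > a_max) {
    warning("ncomp truncated to min(n - 1, p) = ", a_max, call. = FALSE)
    ncomp <- a_max
  }
  pred_names <- colnames(Xs) %||% paste0("X", seq_len(p))
  Xa <- Xs
  Ya <- Y
  W <- matrix(0, p, ncomp, dimnames = list(pred_names, NULL))
  P <- matrix(0, p, ncomp, dimnames = list(pred_names, NULL))
  Q <- matrix(0, ncol(Y), ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    w <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(Xa, u)[, 1]
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) break
      w_new <- w_new / nw
      tt <- Xa %*% w_new
      q <- crossprod(Ya, tt)[, 1] / sum(tt^2)
      u <- (Ya %*% q) / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      warning(
        "NIPALS did not converge for component ", a,
        "; restarting from the dominant eigenvector",
        call. = FALSE
      )
      M <- crossprod(crossprod(Ya, Xa)) # X'YY'X
      w <- eigen(M, symmetric = TRUE)$vectors[, 1]
      tt <- Xa %*% w
      q <- crossprod(Ya, tt)[, 1] / sum(tt^2)
    }
    tt <- Xa %*% w
    t2 <- sum(tt^2)
    if (t2 < .Machine$double.eps) {
      warning("component ", a, " has zero variance; stopping at ", a - 1,
        call. = FALSE
      )
      ncomp <- a - 1
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Q <- Q[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      break
    }
    p_a <- crossprod(Xa, tt)[, 1] / t2
    q_a <- crossprod(Ya, tt)[, 1] / t2
    W[, a] <- w
    P[, a] <- p_a
    Q[, a] <- q_a
    Tm[, a] <- tt
    Xa <- Xa - tcrossprod(tt, p_a)
    Ya <- Ya - tcrossprod(tt, q_a)
  }
  if (ncomp < 1) stop("no usable components could be extracted", call. = FALSE)
  R <- W %*% solve(crossprod(P, W))
  structure(
    list(
      W = W, P = P, Q = Q, T = Tm, R = R,
      ncomp = ncomp,
      scaling = scaling,
      classes = classes,
      class_levels = colnames(Y),
      y_means = colMeans(Y),
      predictors = pred_names
    ),
    class = "ion_pls"
  )
}

#' @export
print.ion_pls <- function(x, ...) {
  cat(
    "<ion_pls> ", x$ncomp, " components, ", length(x$predictors),
    " predictors, ", length(x$class_levels), " response columns\n",
    sep = ""
  )
  invisible(x)
}

#' Project new samples into a PLS model's score space
#'
#' `scores = scaled(Xnew) %*% R`; the training matrix reproduces the stored
#' scores. If the model holds scaling parameters, raw data are scaled first.
#'
#' @param model An `ion_pls`.
#' @param Xnew Matrix/data frame with the model's predictor columns.
#' @param ncomp Number of components to keep (default: all fitted).
#' @return Score matrix (nrow(Xnew) x ncomp).
#' @export
pls_transform <- function(model, Xnew, ncomp = model$ncomp) {
  stopifnot(inherits(model, "ion_pls"), ncomp >= 1, ncomp <= model$ncomp)
  Xnew <- as.matrix(Xnew)
  if (!is.null(model$scaling)) {
    Xnew <- apply_scaling(model$scaling, Xnew)
  } else {
    miss <- setdiff(model$predictors, colnames(Xnew) %||% character(0))
    if (!is.null(colnames(Xnew)) && length(miss) > 0) {
      stop(
        "new data lack predictor column(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    if (!is.null(colnames(Xnew))) {
      Xnew <- Xnew[, model$predictors, drop = FALSE]
    }
  }
  Xnew %*% model$R[, seq_len(ncomp), drop = FALSE]
}

# centroids and pooled within-class covariance of training scores,
# truncated to ncomp components
score_geometry <- function(model, ncomp) {
  Tm <- model$T[, seq_len(ncomp), drop = FALSE]
  cl <- model$classes
  lev <- sort(unique(cl))
  centroids <- vapply(
    lev,
    function(k) colMeans(Tm[cl == k, , drop = FALSE]),
    numeric(ncomp)
  )
  centroids <- t(matrix(centroids, nrow = ncomp,
    dimnames = list(NULL, lev)
  ))
  centered <- Tm - centroids[match(cl, lev), , drop = FALSE]
  df <- nrow(Tm) - length(lev)
  S <- if (df > 0) crossprod(centered) / df else diag(ncomp)
  list(levels = lev, centroids = centroids, cov = S)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Projects test samples into score space and assigns each to the nearest
#' training-class centroid under the Mahalanobis metric (pooled within-class
#' score covariance; ridge-regularized with eps = 1e-8 * trace/ncomp if
#' singular) or the Euclidean metric (`centroid`), or by the largest
#' predicted class indicator (`max`). Distance ties go to the
#' lexicographically smallest class label.
#'
#' @param model An `ion_pls` fitted with class labels.
#' @param Xnew New samples (rows) over the model's predictors.
#' @param distance One of `"mahalanobis"`, `"centroid"`, `"max"`.
#' @param ncomp Components to use (default: all fitted).
#' @return Character vector of predicted class labels.
#' @export
predict_classes <- function(model, Xnew,
                            distance = c("mahalanobis", "centroid", "max"),
                            ncomp = model$ncomp) {
  distance <- match.arg(distance)
  if (is.null(model$classes)) {
    stop("model was fitted without class labels", call. = FALSE)
  }
  scores <- pls_transform(model, Xnew, ncomp = ncomp)
  geo <- score_geometry(model, ncomp)
  if (distance == "max") {
    Yhat <- scores %*% t(model$Q[, seq_len(ncomp), drop = FALSE])
    Yhat <- sweep(Yhat, 2, model$y_means, "+")
    Yhat <- Yhat[, sort(colnames(Yhat)), drop = FALSE]
    idx <- max.col(Yhat, ties.method = "first")
    return(colnames(Yhat)[idx])
  }
  if (distance == "mahalanobis") {
    S <- geo$cov
    ok <- FALSE
    Sinv <- tryCatch(
      {
        v <- solve(S)
        ok <- kappa(S) < 1e12
        v
      },
      error = function(e) NULL
    )
    if (is.null(Sinv) || !ok) {
      warning("singular score covariance; applying ridge regularization",
        call. = FALSE
      )
      eps <- 1e-8 * sum(diag(S)) / ncol(S)
      Sinv <- solve(S + diag(eps, ncol(S)))
    }
  } else {
    Sinv <- diag(ncol(scores))
  }
  D <- t(apply(scores, 1, function(s) {
    diff <- sweep(geo$centroids, 2, s, "-")
    rowSums((diff %*% Sinv) * diff)
  }))
  if (nrow(scores) == 1) D <- matrix(D, nrow = 1)
  colnames(D) <- geo$levels # sorted, so "first" tie-break is lexicographic
  geo$levels[max.col(-D, ties.method = "first")]
}

#' Select the number of latent components by cross-validated error rate
#'
#' Repeated stratified k-fold cross-validation: within every fold the
#' training part is re-autoscaled, a model with `max_comp` components is
#' fitted once, and held-out samples are classified with each truncation
#' `A = 1..max_comp` (components are nested, so one fit serves all
#' candidates). The selected A minimizes the mean classification error rate
#' (CER); ties go to the smallest A.
#'
#' @param X Raw (unscaled) predictor matrix.
#' @param classes Class labels, row-aligned with `X`.
#' @param max_comp Largest candidate number of components (default:
#'   `min(n - 1, p)`, every extractable component).
#' @param folds,repeats CV geometry (default 5-fold, 50 repeats).
#' @param distance Prediction metric (see [predict_classes()]).
#' @param seed Integer seed for fold assignment (mandatory).
#' @return An `ion_cv`: tibble of `ncomp`, `cer_mean`, `cer_sd` with the
#'   selected A in `selected`.
#' @export
select_ncomp_cv <- function(X, classes, max_comp = NULL, folds = 5,
                            repeats = 50,
                            distance = "mahalanobis", seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(folds >= 2)
  X <- as.matrix(X)
  classes <- as.character(classes)
  n <- nrow(X)
  max_comp <- max_comp %||% min(n - 1, ncol(X))
  a_hi <- min(max_comp, ncol(X), n - ceiling(n / folds) - 1)
  if (a_hi < max_comp) {
    warning("max_comp truncated to ", a_hi, " (rank/size limit)", call. = FALSE)
  }
  cer <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(repeats), function(rep_i) {
      fold_id <- stratified_folds(classes, folds)
      errs <- matrix(NA_real_, nrow = folds, ncol = a_hi)
      wrong <- matrix(0, nrow = folds, ncol = a_hi)
      count <- numeric(folds)
      for (f in seq_len(folds)) {
        test <- which(fold_id == f)
        if (length(test) == 0) next
        train <- setdiff(seq_len(n), test)
        sc <- autoscale(X[train, , drop = FALSE])
        fit <- suppressWarnings(fit_pls2(
          sc$X, one_hot(classes[train]),
          ncomp = min(a_hi, length(train) - 1, ncol(sc$X)),
          scaling = sc$params, classes = classes[train]
        ))
        for (a in seq_len(a_hi)) {
          pred <- predict_classes(
            fit, X[test, , drop = FALSE],
            distance = distance, ncomp = min(a, fit$ncomp)
          )
          wrong[f, a] <- sum(pred != classes[test])
        }
        count[f] <- length(test)
      }
      colSums(wrong) / sum(count)
    }, numeric(a_hi))
  })
  cer <- matrix(cer, nrow = a_hi)
  res <- tibble::tibble(
    ncomp = seq_len(a_hi),
    cer_mean = rowMeans(cer),
    cer_sd = apply(cer, 1, stats::sd)
  )
  structure(
    list(
      results = res,
      selected = res$ncomp[which.min(res$cer_mean)],
      folds = folds, repeats = repeats, distance = distance
    ),
    class = "ion_cv"
  )
}

#' @export
print.ion_cv <- function(x, ...) {
  cat(
    "<ion_cv> ", x$folds, "-fold x ", x$repeats,
    " repeats; selected ncomp = ", x$selected, "\n",
    sep = ""
  )
  print(x$results)
  invisible(x)
}

# class-stratified fold labels: within each class, a random permutation is
# dealt round-robin over a randomly rotated fold order, so per-class fold
# sizes differ by at most one
stratified_folds <- function(classes, folds) {
  fold_id <- integer(length(classes))
  for (k in unique(classes)) {
    idx <- sample(which(classes == k))
    start <- sample.int(folds, 1)
    fold_id[idx] <- ((start + seq_along(idx) - 2) %% folds) + 1
  }
  fold_id
}

#' Variable importance in projection
#'
#' Global VIP of predictor j:
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#' `SS_a = sum_k q_ak^2 t_a't_a`, the Y variance explained by component a.
#' The mean squared global VIP over predictors is always 1. The per-class
#' variant restricts SS to one response column, giving each deficiency its
#' own importance profile.
#'
#' @param model A fitted `ion_pls`.
#' @param per_class If `TRUE`, return the p x K per-class matrix.
#' @return Named numeric vector (global) or matrix (per-class).
#' @export
vip_scores <- function(model, per_class = FALSE) {
  stopifnot(inherits(model, "ion_pls"))
  if (model$ncomp < 1) stop("model has no components", call. = FALSE)
  W <- model$W
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/") # (w_ja/||w_a||)^2
  t2 <- colSums(model$T^2)
  p <- nrow(W)
  if (!per_class) {
    ss <- colSums(model$Q^2) * t2
    return(stats::setNames(
      sqrt(p * as.vector(Wn2 %*% ss) / sum(ss)),
      rownames(W)
    ))
  }
  K <- nrow(model$Q)
  out <- matrix(0, p, K, dimnames = list(rownames(W), rownames(model$Q)))
  for (k in seq_len(K)) {
    ss_k <- model$Q[k, ]^2 * t2
    out[, k] <- sqrt(p * as.vector(Wn2 %*% ss_k) / sum(ss_k))
  }
  out
}

#' Principal component analysis by SVD
#'
#' Centers (and optionally autoscales) the matrix, then takes its singular
#' value decomposition. Sign convention: within each component the loading of
#' largest magnitude is positive.
#'
#' @param X Samples x variables matrix (>= 2 rows).
#' @param scale Scale columns to unit SD?
#' @return An `ion_pca`: `scores`, `loadings`, `explained` (variance
#'   fractions), `center`, `scale`.
#' @export
pca_svd <- function(X, scale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 samples", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sdv <- rep(1, ncol(X))
  if (scale) {
    sdv <- apply(X, 2, stats::sd)
    if (any(sdv == 0)) stop("constant column cannot be scaled", call. = FALSE)
    Xc <- sweep(Xc, 2, sdv, "/")
  }
  sv <- svd(Xc)
  flip <- vapply(seq_along(sv$d), function(a) {
    v <- sv$v[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  V <- sweep(sv$v, 2, flip, "*")
  U <- sweep(sv$u, 2, flip, "*")
  scores <- sweep(U, 2, sv$d, "*")
  colnames(scores) <- paste0("PC", seq_along(sv$d))
  dimnames(V) <- list(colnames(X), colnames(scores))
  structure(
    list(
      scores = scores,
      loadings = V,
      sdev = sv$d / sqrt(nrow(X) - 1),
      explained = sv$d^2 / sum(sv$d^2),
      center = mu,
      scale = if (scale) sdv else NULL
    ),
    class = "ion_pca"
  )
}

#' @export
print.ion_pca <- function(x, ...) {
  cat(
    "<ion_pca> ", ncol(x$scores), " components; PC1 ",
    round(100 * x$explained[1], 1), "%, PC2 ",
    if (length(x$explained) > 1) round(100 * x$explained[2], 1) else 0,
    "%\n",
    sep = ""
  )
  invisible(x)
}

#' Fit a PLS-DA classifier from an ionome table
#'
#' Data-frame-first wrapper around the engine: extracts the element columns,
#' autoscales, one-hot encodes the class labels, optionally selects the
#' number of components by cross-validation, and fits the final model on all
#' rows.
#'
#' @param data A tibble with a `class` column and element columns (e.g. one
#'   species x tissue stratum of an `ion_table`).
#' @param elements Predictor columns (default: [element_cols()]).
#' @param ncomp Number of components; `NULL` selects by CV.
#' @param max_comp,folds,cv_repeats CV controls when `ncomp` is `NULL`.
#' @param distance Prediction metric.
#' @param seed Seed for CV fold assignment (required when `ncomp` is `NULL`).
#' @return An `ion_pls` with `$cv` attached when CV was run.
#' @export
plsda <- function(data, elements = element_cols(data), ncomp = NULL,
                  max_comp = NULL, folds = 5, cv_repeats = 50,
                  distance = "mahalanobis", seed = NULL) {
  stopifnot("class" %in% names(data))
  X <- as.matrix(dplyr::as_tibble(data)[, elements])
  classes <- as.character(data$class)
  cv <- NULL
  if (is.null(ncomp)) {
    if (is.null(seed)) {
      stop("`seed` is required for CV component selection", call. = FALSE)
    }
    cv <- select_ncomp_cv(
      X, classes,
      max_comp = max_comp, folds = folds,
      repeats = cv_repeats, distance = distance, seed = seed
    )
    ncomp <- cv$selected
  }
  sc <- autoscale(X)
  model <- fit_pls2(
    sc$X, one_hot(classes),
    ncomp = ncomp, scaling = sc$params, classes = classes
  )
  model$cv <- cv
  model
}
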