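test_that("autoscaling centers, scales, and survives degenerate columns", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  sc <- autoscale(X)
  expect_equal(sc$X[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(sc$X), c(a = 0, b = 0))
  expect_equal(apply(sc$X, 2, sd), c(a = 1, b = 1))
  # re-applying the training parameters reproduces the training matrix
  expect_equal(apply_scaling(sc$params, X), sc$X)
  # constant columns are excluded and recorded
  Xc <- cbind(X, const = c(5, 5, 5))
  scc <- autoscale(Xc)
  expect_equal(scc$params$dropped, "const")
  expect_equal(colnames(scc$X), c("a", "b"))
  expect_error(autoscale(cbind(k = c(2, 2, 2))), "constant")
  expect_error(apply_scaling(sc$params, cbind(a = 1:3)), "lack")
})

test_that("one-hot encoding is deterministic with unit row sums", {
  Y <- one_hot(c("a", "b", "a"))
  expect_equal(Y, matrix(c(1, 0, 1, 0, 1, 0), 3, 2,
    dimnames = list(NULL, c("a", "b"))
  ))
  Y2 <- one_hot(c("zeta", "alpha", "mid", "alpha"))
  expect_equal(colnames(Y2), c("alpha", "mid", "zeta")) # sorted
  expect_true(all(rowSums(Y2) == 1))
  expect_equal(ncol(Y2), 3)
  expect_error(one_hot(c("a", "a")), "2 distinct")
})

test_that("NIPALS components match the eigen and least-squares oracles", {
  withr::with_seed(101, {
    for (i in 1:5) {
      X <- matrix(rnorm(200), 20, 10)
      colnames(X) <- paste0("V", 1:10)
      cl <- sample(rep(c("a", "b", "c"), length.out = 20))
      sc <- autoscale(X)
      Y <- one_hot(cl)
      m <- fit_pls2(sc$X, Y, ncomp = 5)
      # first weight vector: dominant eigenvector of X'YY'X (up to sign)
      ev <- eigen(crossprod(crossprod(Y, sc$X)), symmetric = TRUE)$vectors[, 1]
      expect_lt(
        min(max(abs(m$W[, 1] - ev)), max(abs(m$W[, 1] + ev))),
        1e-6
      )
      # scores of successive components are orthogonal
      G <- crossprod(m$T)
      expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
      # full-rank fit reproduces the least-squares projection of Y
      mf <- fit_pls2(sc$X, Y, ncomp = 10)
      proj <- sc$X %*% solve(crossprod(sc$X), crossprod(sc$X, Y))
      expect_lt(max(abs(mf$T %*% t(mf$Q) - proj)), 1e-6)
    }
  })
})

test_that("weights are unit norm and ncomp is capped at min(n-1, p)", {
  blobs <- separable_blobs()
  sc <- autoscale(blobs$X)
  m <- fit_pls2(sc$X, one_hot(blobs$classes), ncomp = 3)
  expect_equal(colSums(m$W^2), rep(1, 3), tolerance = 1e-12)
  expect_warning(
    m2 <- fit_pls2(sc$X, one_hot(blobs$classes), ncomp = 50),
    "truncated"
  )
  expect_lte(m2$ncomp, min(nrow(blobs$X) - 1, ncol(blobs$X)))
})

test_that("score projection is self-consistent and centered", {
  blobs <- separable_blobs()
  sc <- autoscale(blobs$X)
  m <- fit_pls2(sc$X, one_hot(blobs$classes),
    ncomp = 2,
    scaling = sc$params, classes = blobs$classes
  )
  # training data reproduce the stored scores
  expect_equal(pls_transform(m, blobs$X), m$T, tolerance = 1e-10)
  # a sample at the training mean projects to the origin
  at_mean <- matrix(sc$params$mean, 1, dimnames = list(NULL, colnames(blobs$X)))
  expect_equal(as.vector(pls_transform(m, at_mean)), c(0, 0), tolerance = 1e-12)
  # single new sample gives a 1 x A row
  expect_equal(dim(pls_transform(m, blobs$X[1, , drop = FALSE])), c(1, 2))
  bad <- blobs$X[, 1:3]
  expect_error(pls_transform(m, bad), "V4")
})

test_that("class prediction honors the distance metric and tie contract", {
  blobs <- separable_blobs()
  sc <- autoscale(blobs$X)
  m <- fit_pls2(sc$X, one_hot(blobs$classes),
    ncomp = 2,
    scaling = sc$params, classes = blobs$classes
  )
  # separable training data are perfectly recovered by all metrics
  for (dist in c("mahalanobis", "centroid", "max")) {
    expect_equal(predict_classes(m, blobs$X, distance = dist), blobs$classes)
  }
  # symmetric two-class toy: the exact midpoint is equidistant from both
  # centroids and the tie breaks to the lexicographically smaller label
  Xt <- cbind(p = c(1, -1, 1, -1))
  sct <- autoscale(Xt)
  mt <- fit_pls2(sct$X, one_hot(c("b", "a", "b", "a")),
    ncomp = 1,
    scaling = sct$params, classes = c("b", "a", "b", "a")
  )
  mid <- matrix(0, 1, dimnames = list(NULL, "p"))
  expect_equal(predict_classes(mt, mid, distance = "centroid"), "a")
})

test_that("mahalanobis and centroid metrics agree under isotropic covariance", {
  # constructed toy: within-class score scatter is isotropic by symmetry
  withr::with_seed(33, {
    centers <- rbind(c(6, 0, 0, 0), c(0, 6, 0, 0), c(0, 0, 6, 0))
    X <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(rnorm(60, sd = 0.5), 15, 4), 2, centers[k, ], "+")
    }))
    colnames(X) <- paste0("V", 1:4)
    cl <- rep(c("a", "b", "c"), each = 15)
    sc <- autoscale(X)
    m <- fit_pls2(sc$X, one_hot(cl), ncomp = 2, scaling = sc$params, classes = cl)
    Xnew <- matrix(rnorm(40, sd = 3), 10, 4,
      dimnames = list(NULL, colnames(X))
    )
    expect_equal(
      predict_classes(m, Xnew, distance = "mahalanobis"),
      predict_classes(m, Xnew, distance = "centroid")
    )
  })
})

test_that("cross-validated component selection finds separable structure", {
  blobs <- separable_blobs()
  cv <- select_ncomp_cv(blobs$X, blobs$classes,
    max_comp = 4, folds = 5,
    repeats = 3, seed = 17
  )
  expect_equal(min(cv$results$cer_mean[cv$results$ncomp >= 2]), 0)
  expect_lte(cv$selected, 3)
  # CER is a rate
  expect_true(all(cv$results$cer_mean >= 0 & cv$results$cer_mean <= 1))
  # same seed, same result
  cv2 <- select_ncomp_cv(blobs$X, blobs$classes,
    max_comp = 4, folds = 5,
    repeats = 3, seed = 17
  )
  expect_identical(cv$results, cv2$results)
  expect_error(select_ncomp_cv(blobs$X, blobs$classes), "seed")
})

test_that("pure-noise labels give chance-level CV error", {
  withr::with_seed(55, {
    X <- matrix(rnorm(70 * 6), 70, 6)
    colnames(X) <- paste0("V", 1:6)
    cl <- sample(rep(c("a", "b"), length.out = 70))
  })
  cv <- select_ncomp_cv(X, cl, max_comp = 3, folds = 5, repeats = 10, seed = 2)
  # null expectation 1 - 1/K = 0.5 within Monte-Carlo error
  expect_lt(abs(min(cv$results$cer_mean) - 0.5), 0.12)
})

test_that("VIP scores satisfy their algebraic identities", {
  blobs <- separable_blobs()
  sc <- autoscale(blobs$X)
  m <- fit_pls2(sc$X, one_hot(blobs$classes), ncomp = 2)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  # per-class matrix has one column per class, same normalization per column
  vk <- vip_scores(m, per_class = TRUE)
  expect_equal(dim(vk), c(5, 3))
  expect_equal(colMeans(vk^2), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-10)
  # p = 1: the single predictor has VIP exactly 1
  one <- cbind(z = rnorm(12))
  cl2 <- rep(c("a", "b"), 6)
  m1 <- fit_pls2(autoscale(one)$X, one_hot(cl2), ncomp = 1)
  expect_equal(unname(vip_scores(m1)), 1, tolerance = 1e-12)
  # one component, equal absolute weights on 2 predictors: both VIP 1
  X2 <- cbind(u = c(1, -1, 1, -1), w = c(-1, 1, -1, 1)) + rnorm(8, sd = 1e-9)
  m2 <- fit_pls2(autoscale(X2)$X, one_hot(c("a", "b", "a", "b")), ncomp = 1)
  expect_equal(unname(vip_scores(m2)), c(1, 1), tolerance = 1e-4)
})

test_that("PLS fit agrees with an established reference implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(77, {
    X <- matrix(rnorm(20 * 10), 20, 10)
    colnames(X) <- paste0("V", 1:10)
    cl <- sample(rep(c("a", "b", "c", "d"), 5))
  })
  Xs <- scale(X)
  Y <- one_hot(cl)
  A <- 3
  mine <- fit_pls2(Xs, Y, ncomp = A)
  ref <- mixOmics::pls(Xs, Y, ncomp = A, scale = FALSE, mode = "regression")
  for (a in seq_len(A)) {
    d_same <- max(abs(mine$T[, a] - ref$variates$X[, a]))
    d_flip <- max(abs(mine$T[, a] + ref$variates$X[, a]))
    expect_lt(min(d_same, d_flip), 1e-6)
  }
  # predicted responses on new data agree
  Xn <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, colnames(X)))
  yhat_mine <- (Xn %*% mine$R) %*% t(mine$Q) +
    matrix(colMeans(Y), 5, 4, byrow = TRUE)
  yhat_ref <- predict(ref, Xn)$predict[, , A]
  expect_lt(max(abs(yhat_mine - yhat_ref)), 1e-6)
})

test_that("prediction is invariant to training sample order", {
  blobs <- separable_blobs()
  perm <- withr::with_seed(9, sample(nrow(blobs$X)))
  sc1 <- autoscale(blobs$X)
  m1 <- fit_pls2(sc1$X, one_hot(blobs$classes),
    ncomp = 2,
    scaling = sc1$params, classes = blobs$classes
  )
  sc2 <- autoscale(blobs$X[perm, ])
  m2 <- fit_pls2(sc2$X, one_hot(blobs$classes[perm]),
    ncomp = 2,
    scaling = sc2$params, classes = blobs$classes[perm]
  )
  Xn <- matrix(rnorm(50, sd = 4), 10, 5,
    dimnames = list(NULL, colnames(blobs$X))
  )
  expect_equal(predict_classes(m1, Xn), predict_classes(m2, Xn))
})

test_that("PCA by SVD reconstructs, normalizes and orients consistently", {
  withr::with_seed(13, X <- matrix(rnorm(60), 12, 5))
  colnames(X) <- paste0("V", 1:5)
  p <- pca_svd(X)
  expect_equal(sum(p$explained), 1)
  # full reconstruction
  rec <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(rec - scale(X, scale = FALSE))), 1e-8)
  # agreement with prcomp up to sign
  ref <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (a in 1:4) {
    expect_lt(
      min(
        max(abs(p$scores[, a] - ref$x[, a])),
        max(abs(p$scores[, a] + ref$x[, a]))
      ),
      1e-8
    )
  }
  # sign convention: the dominant loading of each component is positive
  for (a in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, a]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # collinear cloud: PC1 carries everything
  line <- cbind(1:10, 2 * (1:10))
  pl <- pca_svd(line)
  expect_equal(pl$explained[1], 1)
})

test_that("the plsda wrapper selects components and fits on all rows", {
  tab <- small_table(seed = 21)
  ylb <- tab[tab$tissue == "YLB", ]
  m <- suppressWarnings(plsda(ylb, cv_repeats = 2, seed = 5))
  expect_s3_class(m, "ion_pls")
  expect_s3_class(m$cv, "ion_cv")
  expect_equal(m$ncomp, m$cv$selected)
  expect_equal(nrow(m$T), nrow(ylb))
  # tidy/glance surfaces
  td <- tidy(m)
  expect_true(all(c("term", "component", "weight", "vip") %in% names(td)))
  g <- glance(m)
  expect_equal(g$n, nrow(ylb))
  expect_true(g$x_variance_explained > 0 && g$x_variance_explained <= 1)
  expect_error(plsda(ylb), "seed")
})
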