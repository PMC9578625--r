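# The discriminant core: scaling, class statistics, scores, posteriors,
# the quadratic variant and restricted models.

test_that("Pareto scaling follows the documented convention", {
  # hand-derived: train {0, 2}, test {4}; population sd of {0,2,4} is
  # sqrt(8/3); divisor is its square root; scaled test = 2 / divisor
  tr <- matrix(c(0, 2), ncol = 1, dimnames = list(NULL, "CA"))
  te <- matrix(4, ncol = 1, dimnames = list(NULL, "CA"))
  ps <- pareto_scale(tr, te)
  expect_equal(ps$scaling$center[["CA"]], 2)
  expect_equal(ps$scaling$scale[["CA"]], sqrt(sqrt(8 / 3)))
  expect_equal(unname(ps$test[1, 1]), 2 / sqrt(sqrt(8 / 3)),
               tolerance = 1e-12)
  # round-trip to machine precision
  back <- apply_scaling(ps$train, ps$scaling, invert = TRUE)
  expect_equal(unname(back), unname(tr))
  # zero-variance column errors, naming the column
  cz <- matrix(c(1, 1), ncol = 1, dimnames = list(NULL, "HN"))
  expect_error(pareto_scale(cz), "HN")
})

test_that("class statistics use the population (1/n) covariance", {
  x <- matrix(c(1, 3, 10, 14), ncol = 1, dimnames = list(NULL, "CA"))
  y <- c("A", "A", "B", "B")
  st <- fit_class_stats(x, y)
  expect_equal(st$means["A", "CA"], 2)
  expect_equal(st$cov$A[1, 1], 1)          # population, not 2 (n-1 form)
  expect_equal(st$cov$B[1, 1], 4)
  # permutation invariance
  perm <- sample(4)
  st2 <- fit_class_stats(x[perm, , drop = FALSE], y[perm])
  expect_equal(st2$means, st$means)
  expect_equal(st2$cov, st$cov)
  # classes need two members
  expect_error(fit_class_stats(x, c("A", "A", "A", "B")), "B")
})

test_that("pooled covariance is the count-weighted average", {
  covs <- list(A = matrix(1), B = matrix(3))
  expect_equal(pooled_covariance(covs, c(A = 2L, B = 2L))[1, 1], 2)
  # identical covariances pool to themselves; single class passes through
  covs2 <- list(A = diag(2), B = diag(2))
  expect_equal(pooled_covariance(covs2, c(A = 5L, B = 9L)), diag(2))
  expect_equal(pooled_covariance(list(A = matrix(7)), c(A = 4L))[1, 1], 7)
  expect_error(pooled_covariance(covs, c(A = 2L, B = 2L), N = 5), "sum")
})

test_that("discriminant scores match the Gaussian-density oracle", {
  set.seed(401)
  inst <- random_instance(K = 3, M = 2, n_per_class = 30)
  model <- slda_fit(inst$x, inst$y)
  q <- matrix(rnorm(40, sd = 2), ncol = 2,
              dimnames = list(NULL, colnames(inst$x)))
  sc <- discriminant_score(model, q)
  # score differences equal log-posterior-ratio differences of the
  # shared-covariance Gaussian model, up to a class-independent constant
  ll <- t(apply(q, 1L, function(x)
    vapply(model$classes, function(k)
      log(model$priors[[k]]) +
        log_mvn(x, model$means[k, ], model$pooled_cov), numeric(1))))
  expect_equal(sc - sc[, 1L], ll - ll[, 1L], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(discriminant_score(model, q[, 1, drop = FALSE]), "features")
})

test_that("posterior probabilities are a stable, invariant softmax", {
  expect_equal(unname(posterior_probabilities(c(a = 1, b = 1))),
               c(0.5, 0.5))
  expect_equal(unname(posterior_probabilities(c(0, log(3)))),
               c(0.25, 0.75))
  s <- matrix(rnorm(12), 3, dimnames = list(NULL, c("A", "B", "C", "D")[1:4]))
  p0 <- posterior_probabilities(s)
  expect_equal(rowSums(p0), rep(1, 3))
  expect_equal(posterior_probabilities(s + 100), p0)    # shift invariance
  # huge scores do not overflow
  expect_equal(unname(posterior_probabilities(c(1e4, 1e4))), c(0.5, 0.5))
  # order preserved
  expect_equal(apply(p0, 1, which.max), apply(s, 1, which.max))
})

test_that("QDA reduces to LDA under shared covariances, else differs", {
  set.seed(402)
  inst <- random_instance(K = 3, M = 2, n_per_class = 25)
  model <- slda_fit(inst$x, inst$y)
  q <- matrix(rnorm(60, sd = 2), ncol = 2,
              dimnames = list(NULL, colnames(inst$x)))
  # force all class covariances to the pooled one: rankings must agree
  model_shared <- model
  model_shared$per_class_cov <- stats::setNames(
    rep(list(model$pooled_cov), 3), model$classes)
  lda_pred <- model$classes[max.col(discriminant_score(model, q),
                                    ties.method = "first")]
  qda_pred <- model$classes[max.col(qda_score(model_shared, q),
                                    ties.method = "first")]
  expect_identical(qda_pred, lda_pred)

  # 1-D, equal means, unequal variances: the boundary is in |x - mu|,
  # checked against the explicit density oracle
  x1 <- matrix(c(-1, 1, -3, 3) * 0.5, ncol = 1,
               dimnames = list(NULL, "CA"))
  x1 <- rbind(x1, x1 * 2)
  y1 <- rep(c("A", "A", "B", "B"), 2)
  m1 <- slda_fit(x1, y1)
  qs <- seq(-4, 4, by = 0.37)
  qm <- matrix(qs, ncol = 1, dimnames = list(NULL, "CA"))
  got <- m1$classes[max.col(qda_score(m1, qm), ties.method = "first")]
  want <- vapply(qs, function(x) {
    d <- vapply(c("A", "B"), function(k)
      log(0.5) + log_mvn(x, m1$means[k, ], m1$per_class_cov[[k]]),
      numeric(1))
    c("A", "B")[which.max(d)]
  }, character(1))
  expect_identical(got, want)
  expect_true(all(got[abs(qs) < 0.5] == "A"))   # narrow class wins center
  expect_true(all(got[abs(qs) > 3] == "B"))     # wide class wins tails
})

test_that("regularization rescues singular covariances", {
  # two identical points per class: zero covariance everywhere
  x <- matrix(c(1, 1, 5, 5), ncol = 1, dimnames = list(NULL, "CA"))
  m <- slda_fit(x, c("A", "A", "B", "B"))
  expect_gt(m$regularization_lambda, 0)
  sc <- discriminant_score(m, matrix(c(1.2), dimnames = list(NULL, "CA")))
  expect_equal(colnames(sc)[which.max(sc)], "A")
})

test_that("model fitting composes and degenerate cases behave", {
  set.seed(403)
  inst <- random_instance(K = 4, M = 3, n_per_class = 20)
  m <- slda_fit(inst$x, inst$y)
  expect_equal(sum(m$priors), 1)
  expect_equal(m$pooled_cov,
               pooled_covariance(m$per_class_cov, m$counts), tolerance = 1e-12)
  expect_true(isSymmetric(m$pooled_cov))
  # duplicating every row: same means/cov/priors
  m2 <- slda_fit(rbind(inst$x, inst$x), c(inst$y, inst$y))
  expect_equal(m2$means, m$means)
  expect_equal(m2$pooled_cov, m$pooled_cov)
  expect_equal(m2$priors, m$priors)
  # single-class model always predicts that class
  xa <- inst$x[inst$y == "A", , drop = FALSE]
  ma <- slda_fit(xa, rep("A", nrow(xa)))
  sc <- discriminant_score(ma, inst$x)
  expect_equal(ncol(sc), 1L)
})

test_that("restricted models use exactly the present shifts", {
  model <- separated_class_model(c("A", "G", "L"), sep = 12)
  train <- sample_protein(model, 300L, seed = 21L, id = "tr")$spins
  # glycine query under subset iii: 5 columns, G retained and predicted
  g_idx <- which(train$residue_type == "G")[1]
  query <- as_spin_table(as.data.frame(train)[g_idx, , drop = FALSE],
                         warn = FALSE)
  fr <- fit_restricted(train, c("HN", "N", "CO", "CA", "HA"),
                       allowed_types = c("A", "G", "L"),
                       query = shift_matrix(query,
                                            c("HN", "N", "CO", "CA", "HA")))
  expect_setequal(fr$model$shift_names, c("HN", "N", "CO", "CA", "HA"))
  expect_true("G" %in% fr$model$classes)
  # full 7-shift pattern: G is structurally impossible and dropped
  fr7 <- fit_restricted(train, canonical_shifts(),
                        allowed_types = c("A", "G", "L"),
                        query = NULL)
  expect_false("G" %in% fr7$model$classes)
  expect_setequal(fr7$model$classes, c("A", "L"))
  expect_error(fit_restricted(train, character(0), c("A")), "no usable")
})

test_that("classification is deterministic and honors shift dropout", {
  model <- separated_class_model(sep = 12)
  train <- sample_protein(model, 400L, seed = 31L, id = "tr")$spins
  test <- sample_protein(model, 40L, seed = 32L, id = "te")$spins
  c1 <- classify_spins(test, train, "iii")
  c2 <- classify_spins(test, train, "iii")
  expect_identical(c1$posteriors, c2$posteriors)      # bit-identical
  expect_equal(rowSums(c1$posteriors), rep(1, nrow(test)),
               ignore_attr = TRUE)
  # dropping one shift from a query only changes the columns used
  one <- as.data.frame(test)[1, , drop = FALSE]
  one$HA <- NA_real_
  c3 <- classify_spins(as_spin_table(one, warn = FALSE), train, "iii")
  expect_false(grepl("HA", c3$table$shifts_used))
  expect_true(grepl("CA", c3$table$shifts_used))
})

test_that("models serialize to JSON and back", {
  set.seed(404)
  inst <- random_instance(K = 3, M = 3, n_per_class = 15)
  sc <- pareto_scale(inst$x)
  m <- slda_fit(sc$train, inst$y, scaling = sc$scaling)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$means, m$means)
  expect_equal(m2$pooled_cov, m$pooled_cov, tolerance = 1e-12)
  expect_equal(m2$priors, m$priors)
  expect_equal(m2$scaling$center, m$scaling$center)
  q <- sc$train[1:5, , drop = FALSE]
  expect_equal(discriminant_score(m2, q), discriminant_score(m, q),
               tolerance = 1e-9)
})
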