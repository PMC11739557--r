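test_that("build_profiles takes exact natural logs and reports offenders", {
  mask <- new_mask(array(TRUE, dim = c(3, 1, 1)))
  mk <- function(vals, id) new_volume(array(vals, dim = c(3, 1, 1)), id = id)
  p <- build_profiles(list(mk(c(1, exp(1), exp(2)), "a"),
                           mk(c(2, 2, 2), "b")),
                      mask, labels = c("HC", "ET1"))
  expect_equal(p$values[1, ], c(0, 1, 2), tolerance = 1e-15)

  # scaling one subject's scan shifts its row by exactly ln c
  p2 <- build_profiles(list(mk(c(1, exp(1), exp(2)), "a"),
                            mk(5 * c(2, 2, 2), "b")),
                       mask, labels = c("HC", "ET1"))
  expect_equal(p2$values[2, ] - p$values[2, ], rep(log(5), 3),
               tolerance = 1e-12)

  # random fixture vs element-wise log oracle
  v <- rand_volume(dims = c(3, 1, 1), seed = 2, voxel_size = c(1, 1, 1))
  p3 <- build_profiles(list(v, mk(c(1, 1, 1), "c")), mask, c("HC", "ET1"))
  expect_equal(p3$values[1, ], log(as.vector(v$data)), tolerance = 0)

  expect_error(build_profiles(list(mk(c(0, 1, 1), "bad"), mk(c(1, 1, 1), "ok")),
                              mask, c("HC", "ET1")),
               "subject 1")
})

test_that("double centering matches the hand-worked 2x2 case and its defining property", {
  p <- manual_profiles(matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE),
                       labels = c("HC", "ET1"))
  r <- double_center(p)
  expect_equal(r$values, matrix(c(0, 0, 1, -1), 2, 2, byrow = TRUE),
               tolerance = 1e-15)
  expect_equal(r$reference_offset, c(-1, 1), tolerance = 1e-15)

  set.seed(4)
  p10 <- manual_profiles(matrix(stats::rnorm(500, 5), 10, 50),
                         labels = rep(c("HC", "ET1"), each = 5))
  r10 <- double_center(p10)
  expect_lt(max(abs(rowMeans(r10$values))), 1e-10)
  expect_lt(max(abs(colMeans(r10$values[1:5, ]))), 1e-10)

  # naive two-step oracle
  X <- p10$values - rowMeans(p10$values)
  X <- sweep(X, 2, colMeans(X[1:5, ]))
  expect_equal(r10$values, X, tolerance = 1e-14)

  expect_error(double_center(manual_profiles(matrix(1, 3, 4),
                                             labels = rep("ET1", 3))),
               "no control")
})

test_that("PCA handles rank-1 input and satisfies the spectral identities", {
  u <- c(1, -1, 2) / sqrt(6)
  v <- stats::rnorm(30)
  p <- manual_profiles(outer(u, v), labels = c("HC", "HC", "ET1"),
                       state = "residual")
  b <- run_pca(p)
  expect_equal(b$variance_fractions[1], 1, tolerance = 1e-12)

  set.seed(6)
  Y <- matrix(stats::rnorm(240), 6, 40)
  Y <- Y - rowMeans(Y)
  p6 <- manual_profiles(Y, labels = rep(c("HC", "ET1"), 3), state = "residual")
  b6 <- run_pca(p6)
  V <- b6$voxel_components
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-10)
  # reconstruction: scores x components' reproduces the residual matrix
  expect_equal(b6$subject_scores %*% t(V), Y, tolerance = 1e-10)

  # dense SVD oracle, sign-aligned
  sv <- svd(Y)
  for (k in seq_len(ncol(V))) {
    s <- sign(sum(V[, k] * sv$v[, k]))
    expect_equal(V[, k], s * sv$v[, k], tolerance = 1e-8)
  }
  expect_equal(b6$variance_fractions, sv$d^2 / sum(sv$d^2), tolerance = 1e-10)

  expect_error(run_pca(manual_profiles(matrix(0, 4, 9),
                                       labels = rep(c("HC", "ET1"), 2),
                                       state = "residual")),
               "rank 0")
})

test_that("the PCA sign convention puts higher mean scores on patients", {
  set.seed(61)
  Y <- matrix(stats::rnorm(200), 10, 20)
  Y <- Y - rowMeans(Y)
  b <- run_pca(manual_profiles(Y, labels = rep(c("HC", "ET1"), each = 5),
                               state = "residual"))
  dm <- colMeans(b$subject_scores[6:10, ]) - colMeans(b$subject_scores[1:5, ])
  expect_true(all(dm >= -1e-12))
})

test_that("component selection returns the shortest prefix reaching the variance target", {
  fake <- structure(list(variance_fractions = c(0.30, 0.15, 0.10, 0.08, 0.37)),
                    class = "ssm_pca")
  expect_identical(select_components(fake, 0.5), 1:3)
  fake2 <- structure(list(variance_fractions = c(0.60, 0.40)), class = "ssm_pca")
  expect_identical(select_components(fake2, 0.5), 1L)
  expect_error(select_components(fake, 1.2), "strictly between")
})

test_that("the logistic search keeps a dominant discriminating component", {
  set.seed(8)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  S <- cbind(ifelse(y == 1, 1, -1) + stats::rnorm(n, sd = 0.05),
             matrix(stats::rnorm(n * 4), n, 4))
  b <- manual_basis(S, labels = ifelse(y == 1, "ET1", "HC"))
  fit <- fit_logistic_combination(b, 1:5)
  expect_true(1L %in% fit$selected_pcs)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("the AIC-best subset matches brute-force enumeration and can be non-contiguous", {
  set.seed(9)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  S <- cbind(y + stats::rnorm(n, sd = 1.2),
             stats::rnorm(n),
             y + stats::rnorm(n, sd = 1.2),
             matrix(stats::rnorm(n * 3), n, 3))
  labels <- ifelse(y == 1, "ET1", "HC")
  b <- manual_basis(S, labels = labels)
  fit <- fit_logistic_combination(b, 1:6)

  # independent oracle: re-apply the documented criterion naively
  pv <- apply(S, 2, function(s) stats::t.test(s[y == 1], s[y == 0])$p.value)
  keep <- which(pv < 0.05)
  best_aic <- Inf; best_sub <- NULL
  for (sz in 1:min(4, length(keep)))
    for (sub in utils::combn(keep, sz, simplify = FALSE)) {
      m <- suppressWarnings(stats::glm(y ~ S[, sub], family = stats::binomial()))
      if (stats::AIC(m) < best_aic) { best_aic <- stats::AIC(m); best_sub <- sub }
    }
  expect_identical(sort(fit$selected_pcs), sort(as.integer(best_sub)))
  expect_identical(sort(fit$selected_pcs), c(1L, 3L))  # non-contiguous set
  expect_equal(fit$aic, best_aic, tolerance = 1e-8)
})

test_that("pattern assembly is the normalized weighted component sum", {
  set.seed(10)
  Y <- matrix(stats::rnorm(300), 10, 30)
  Y <- Y - rowMeans(Y)
  b <- run_pca(manual_profiles(Y, labels = rep(c("HC", "ET1"), 5),
                               state = "residual"))
  p1 <- build_pattern(b, 1L, 1)
  expect_equal(p1$weights, b$voxel_components[, 1], tolerance = 1e-12)

  coefs <- c(0.8, -0.5, 1.7)
  p3 <- build_pattern(b, c(1L, 3L, 4L), coefs)
  # direct voxel-by-voxel summation oracle
  oracle <- numeric(30)
  for (i in 1:3) oracle <- oracle + coefs[i] * b$voxel_components[, c(1, 3, 4)[i]]
  expect_equal(p3$weights, oracle / sqrt(sum(oracle^2)), tolerance = 1e-12)

  pneg <- build_pattern(b, c(1L, 3L, 4L), -coefs)
  expect_equal(pneg$weights, -p3$weights, tolerance = 1e-12)
  expect_equal(pneg$derivation_scores, -p3$derivation_scores, tolerance = 1e-12)

  expect_error(build_pattern(b, c(1L, 2L), c(0, 0)), "zero")
})

test_that("global scaling of any subject's scan leaves residuals, scores and patterns unchanged", {
  sim <- tiny_cohort(seed = 23)
  scans <- sim$scans
  labels <- sim$truth$group_labels
  mask <- cohort_mask(scans)
  d1 <- derive_pattern(scans, labels, mask = mask)

  scans2 <- scans
  scans2[[4]] <- new_volume(3.7 * scans[[4]]$data,
                            voxel_size = scans[[4]]$voxel_size,
                            id = scans[[4]]$id)
  d2 <- derive_pattern(scans2, labels, mask = mask)
  expect_equal(d2$profiles$values, d1$profiles$values, tolerance = 1e-10)
  expect_equal(abs(d2$basis$subject_scores), abs(d1$basis$subject_scores),
               tolerance = 1e-8)
  expect_equal(d2$pattern$weights, d1$pattern$weights, tolerance = 1e-8)
})

test_that("patterns survive a save/load round trip", {
  sim <- tiny_cohort(seed = 29)
  d <- derive_pattern(sim$scans, sim$truth$group_labels)
  prefix <- file.path(withr::local_tempdir(), "etp")
  save_pattern(d$pattern, prefix)
  p2 <- load_pattern(prefix)
  expect_equal(p2$weights, d$pattern$weights, tolerance = 1e-10)
  expect_equal(p2$reference_offset, d$pattern$reference_offset, tolerance = 1e-10)
  expect_identical(p2$selected_pcs, d$pattern$selected_pcs)
  s1 <- score_scan(sim$scans[[1]], d$pattern)
  s2 <- score_scan(sim$scans[[1]], p2)
  expect_equal(s1, s2, tolerance = 1e-10)
})
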