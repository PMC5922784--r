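test_that("confusion_model validates simplex constraints", {
  expect_error(confusion_model(diag(2) * 2, c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(confusion_model(diag(2), c(0.7, 0.2)), "beta must sum")
  bad <- matrix(c(0.5, 0.4, 0.5, 0.6), 2)
  expect_error(confusion_model(bad, c(0.5, 0.5)), "column")
})

test_that("e_step reduces to the identity allocation under identity confusion", {
  m <- confusion_model(diag(2), c(0.5, 0.5))
  ws <- e_step(m, c(3, 7))
  expect_equal(unname(ws$phi), diag(c(3, 7)))
  expect_equal(unname(ws$psi), c(3, 7))
})

test_that("e_step applies Bayes' rule per aligned family", {
  # one aligned family reachable from both origins
  m <- confusion_model(matrix(c(1, 1), 1), c(0.4, 0.6))
  ws <- e_step(m, 10)
  expect_equal(unname(ws$phi), matrix(c(4, 6), 1))
})

test_that("e_step matches a per-read brute-force posterior and conserves reads", {
  set.seed(31)
  for (rep in 1:5) {
    m <- rand_model(5, 4)
    y <- rand_counts(m, 200L)
    ws <- e_step(m, y)
    # brute force: each read aligned to i contributes its posterior over j
    phi_bf <- matrix(0, 5, 4)
    for (i in 1:5) {
      post <- m$alpha[i, ] * m$beta
      post <- post / sum(post)
      for (r in seq_len(y[i])) phi_bf[i, ] <- phi_bf[i, ] + post
    }
    expect_equal(unname(ws$phi), phi_bf, tolerance = 1e-9)
    expect_equal(unname(rowSums(ws$phi)), unname(as.numeric(y)), tolerance = 1e-6)
    expect_equal(sum(ws$psi), sum(y), tolerance = 1e-6)
  }
})

test_that("e_step errors when a counted family is unreachable", {
  alpha <- matrix(c(1, 0, 1, 0), 2) # aligned family 2 never reached
  m <- confusion_model(alpha, c(0.5, 0.5))
  expect_error(e_step(m, c(5, 5)), "unreachable")
  # zero-count unreachable rows are fine and stay zero
  ws <- e_step(m, c(5, 0))
  expect_equal(unname(ws$phi[2, ]), c(0, 0))
})

test_that("m_step renormalizes allocations into valid parameters", {
  ws <- structure(
    list(phi = diag(c(3, 7)), psi = c(3, 7), y = c(3, 7)),
    class = "em_workspace"
  )
  upd <- m_step(ws)
  expect_equal(unname(upd$alpha), diag(2))
  expect_equal(unname(upd$beta), c(0.3, 0.7))

  ws2 <- structure(
    list(phi = matrix(c(2, 2, 1, 3), 2), psi = c(4, 4), y = c(3, 5)),
    class = "em_workspace"
  )
  upd2 <- m_step(ws2)
  expect_equal(unname(upd2$alpha[, 1]), c(0.5, 0.5))

  set.seed(4)
  for (rep in 1:5) {
    phi <- matrix(rgamma(20, 2), 5, 4)
    ws3 <- structure(
      list(phi = phi, psi = colSums(phi), y = rowSums(phi)),
      class = "em_workspace"
    )
    upd3 <- m_step(ws3)
    expect_equal(unname(colSums(upd3$alpha)), rep(1, 4), tolerance = 1e-12)
    expect_equal(sum(upd3$beta), 1, tolerance = 1e-12)
    expect_equal(unname(upd3$alpha), sweep(phi, 2, colSums(phi), "/"),
      tolerance = 1e-12
    )
  }
})

test_that("m_step keeps the previous column when a family explains no reads", {
  phi <- cbind(c(4, 6), c(0, 0))
  ws <- structure(list(phi = phi, psi = colSums(phi), y = c(4, 6)),
    class = "em_workspace"
  )
  prev <- matrix(c(0.4, 0.6, 0.9, 0.1), 2)
  upd <- m_step(ws, prev_alpha = prev)
  expect_equal(upd$alpha[, 2], prev[, 2])
  expect_gt(upd$beta[2], 0)
  expect_equal(sum(upd$beta), 1, tolerance = 1e-12)
  expect_error(m_step(ws), "previous alpha")
})

test_that("observed log-likelihood has its closed forms and scales linearly", {
  m <- confusion_model(diag(2), c(0.5, 0.5))
  expect_equal(observed_log_likelihood(m, c(1, 1)), 2 * log(0.5))

  set.seed(12)
  for (rep in 1:5) {
    mm <- rand_model(4, 3)
    y <- rand_counts(mm, 60L)
    marg <- as.vector(mm$alpha %*% mm$beta)
    ll_bf <- 0 # per-read plain summation
    for (i in seq_along(y)) {
      for (r in seq_len(y[i])) ll_bf <- ll_bf + log(marg[i])
    }
    expect_equal(observed_log_likelihood(mm, y), ll_bf, tolerance = 1e-9)
    expect_equal(observed_log_likelihood(mm, 3 * y),
      3 * observed_log_likelihood(mm, y),
      tolerance = 1e-9
    )
  }
})

test_that("identity confusion yields the empirical proportions in <= 2 iterations", {
  y <- c(a = 13, b = 57, c = 30)
  fit <- fit_plsa(diag(3), rep(1 / 3, 3), y)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_equal(unname(fit$model$beta), unname(y / sum(y)), tolerance = 1e-14)
  expect_equal(unname(fit$model$alpha), diag(3))
})

test_that("a single origin family degenerates to beta = 1 and alpha = y/sum(y)", {
  y <- c(4, 6, 10)
  fit <- fit_plsa(matrix(c(0.2, 0.3, 0.5), 3), 1, y)
  expect_equal(unname(fit$model$beta), 1)
  expect_equal(unname(fit$model$alpha[, 1]), y / sum(y))
})

test_that("the log-likelihood trace is non-decreasing on random instances", {
  set.seed(77)
  for (rep in 1:10) {
    m <- rand_model(6, 4)
    y <- rand_counts(m, 500L)
    a0 <- matrix(0, 6, 4)
    for (j in 1:4) a0[, j] <- rand_simplex(6)
    fit <- fit_plsa(a0, rand_simplex(4), y, max_iter = 300L)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
})

test_that("with fixed alpha the EM reaches the grid-search maximizer of beta", {
  set.seed(19)
  for (rep in 1:3) {
    alpha <- cbind(rand_simplex(2), rand_simplex(2))
    y <- c(sample(5:50, 1), sample(5:50, 1))
    fit <- fit_plsa(alpha, c(0.5, 0.5), y,
      tol = 1e-10, max_iter = 5000L,
      fix_alpha = TRUE
    )
    grid <- seq(0.001, 0.999, by = 0.001)
    ll <- vapply(grid, function(b) {
      sum(y * log(as.vector(alpha %*% c(b, 1 - b))))
    }, numeric(1))
    b_grid <- grid[which.max(ll)]
    expect_lt(abs(fit$model$beta[1] - b_grid), 1e-3)
    expect_equal(unname(fit$model$alpha), alpha) # untouched
  }
})

test_that("corrected_profile rounds half away from zero with bounded drift", {
  fit <- list(model = confusion_model(diag(2), c(0.256, 0.744)))
  class(fit) <- "em_result"
  prof <- corrected_profile(fit, c(26, 74))
  expect_equal(prof$count_hat, c(26L, 74L))

  fit1 <- list(model = confusion_model(matrix(c(0.3, 0.7), 2), 1))
  class(fit1) <- "em_result"
  expect_equal(corrected_profile(fit1, c(30, 70))$count_hat, 100L)

  set.seed(88)
  for (rep in 1:10) {
    M <- sample(3:25, 1)
    beta <- rand_simplex(M)
    alpha <- diag(M)
    fitr <- list(model = confusion_model(alpha, beta))
    class(fitr) <- "em_result"
    y <- as.integer(rmultinom(1, 1e5, beta))
    prof <- corrected_profile(fitr, y)
    expect_lte(abs(sum(prof$count_hat) - 1e5), M / 2)
  }
})

test_that("fitted parameters always satisfy the simplex constraints", {
  set.seed(101)
  for (rep in 1:8) {
    N <- sample(3:8, 1)
    M <- sample(2:min(N, 6), 1)
    m <- rand_model(N, M)
    y <- rand_counts(m, 800L)
    a0 <- matrix(0, N, M)
    for (j in 1:M) a0[, j] <- rand_simplex(N)
    fit <- fit_plsa(a0, rand_simplex(M), y, max_iter = 500L)
    expect_equal(unname(colSums(fit$model$alpha)), rep(1, M), tolerance = 1e-9)
    expect_equal(sum(fit$model$beta), 1, tolerance = 1e-9)
    ws <- e_step(fit$model, y)
    expect_equal(unname(rowSums(ws$phi)), unname(as.numeric(y)), tolerance = 1e-6)
  }
})

test_that("parameter recovery: beta is recovered under the true confusion matrix", {
  # With both alpha and beta free the mixture is overparameterized (many
  # maxima fit the N observed counts equally well), so the sampling-error
  # recovery statement applies to beta fitted under the known confusion
  # structure; the learned-initialization workflow test covers the free case.
  cfg <- simulation_config(10, 15, 1e5, concentration = 40, cross_rate = 0.3, seed = 202)
  truth <- sample_truth(cfg)
  y <- simulate_counts(truth, 1e5L, seed = 203)
  fit <- fit_plsa(truth$alpha, rep(1 / 10, 10), y,
    universe = truth$universe, max_iter = 2000L, fix_alpha = TRUE
  )
  tv <- sum(abs(fit$model$beta - truth$beta)) / 2
  expect_lt(tv, 0.02)
})
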