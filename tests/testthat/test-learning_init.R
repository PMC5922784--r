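joint_mat <- function(m, origins, aligned) {
  matrix(as.integer(m), length(origins), length(aligned),
    dimnames = list(origins, aligned), byrow = TRUE
  )
}

test_that("learning distributions are row/column relative frequencies", {
  j <- joint_mat(c(10, 0, 0, 10), c("c1", "c2"), c("a1", "a2"))
  pr <- estimate_learning_distributions(j)
  expect_equal(unname(pr$alpha_L), diag(2))
  expect_equal(unname(pr$gamma_L), diag(2))

  j2 <- joint_mat(c(8, 2), "c1", c("a1", "a2"))
  pr2 <- estimate_learning_distributions(j2)
  expect_equal(unname(pr2$alpha_L[, "c1"]), c(0.8, 0.2))

  expect_error(
    estimate_learning_distributions(joint_mat(rep(0, 4), c("c1", "c2"), c("a1", "a2"))),
    "all zero"
  )
})

test_that("learning distributions match brute-force normalization on a random matrix", {
  set.seed(14)
  j <- matrix(rpois(20 * 30, 2), 20, 30,
    dimnames = list(sprintf("c%02d", 1:20), sprintf("a%02d", 1:30))
  )
  pr <- estimate_learning_distributions(j)
  for (org in colnames(pr$alpha_L)) {
    expect_equal(pr$alpha_L[, org], j[org, ] / sum(j[org, ]), tolerance = 1e-12)
    expect_equal(sum(pr$alpha_L[, org]), 1, tolerance = 1e-9)
  }
  for (al in colnames(pr$gamma_L)) {
    expect_equal(pr$gamma_L[, al], j[, al] / sum(j[, al]), tolerance = 1e-12)
    expect_equal(sum(pr$gamma_L[, al]), 1, tolerance = 1e-9)
  }
  # zero-total origins/aligned families are dropped
  j["c01", ] <- 0L
  j[, "a01"] <- 0L
  pr0 <- estimate_learning_distributions(j)
  expect_false("c01" %in% colnames(pr0$alpha_L))
  expect_false("a01" %in% colnames(pr0$gamma_L))
})

test_that("initialize_alpha copies learned columns when universes coincide", {
  set.seed(2)
  model <- sample_truth(simulation_config(5, 6, 1000, seed = 2))
  joint <- simulate_counts(model, 50000L, seed = 3, labeled = TRUE)
  pr <- estimate_learning_distributions(joint)
  a0 <- initialize_alpha(pr, model$universe)
  for (j in colnames(pr$alpha_L)) {
    expect_equal(a0[, j], pr$alpha_L[rownames(a0), j], tolerance = 1e-6)
  }
})

test_that("initialize_alpha splits remaining mass over new-only aligned families", {
  # learning: c1 puts 0.54/0.36 on shared a1/a2, 0.10 on learning-only aL
  j3 <- joint_mat(c(54, 36, 10), "c1", c("a1", "a2", "aL"))
  pr3 <- estimate_learning_distributions(j3)
  u <- family_universe(c("a1", "a2", "n1", "n2"), c("c1", "EXTRA"))
  a0 <- initialize_alpha(pr3, u)
  # shared families copy alpha_L (0.54, 0.36); the remaining 0.10 splits equally
  expect_equal(unname(a0[c("a1", "a2"), "c1"]), c(0.54, 0.36), tolerance = 1e-9)
  expect_equal(unname(a0[c("n1", "n2"), "c1"]), c(0.05, 0.05), tolerance = 1e-9)
  # EXTRA absent from learning: uniform 1/N
  expect_equal(unname(a0[, "EXTRA"]), rep(0.25, 4), tolerance = 1e-9)
})

test_that("initialize_alpha columns are simplex vectors with positive entries", {
  set.seed(8)
  for (rep in 1:10) {
    origins <- c(sprintf("c%d", 1:4), "EXTRA")
    aligned_l <- sprintf("a%d", 1:6)
    j <- matrix(rpois(5 * 6, 3), 5, 6, dimnames = list(origins, aligned_l))
    j[1, 1] <- j[1, 1] + 1L
    pr <- estimate_learning_distributions(j)
    u <- family_universe(
      c(sample(aligned_l, 4), "b1", "b2"),
      c(sprintf("c%d", c(1, 3, 5)), "EXTRA")
    )
    a0 <- initialize_alpha(pr, u)
    expect_equal(unname(colSums(a0)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(a0 >= 1e-13))
  }
})

test_that("initialize_beta applies the learned origin shares of observed counts", {
  # gamma_L(c1, a1) = 0.5 with y[a1] = 100 of 200 total -> contribution 0.25
  j <- joint_mat(c(50, 0, 50, 100), c("c1", "c2"), c("a1", "a2"))
  pr <- estimate_learning_distributions(j)
  u <- family_universe(c("a1", "a2"), c("c1", "c2", "EXTRA"))
  y <- c(a1 = 100L, a2 = 100L)
  b0 <- initialize_beta(pr, y, u)
  expect_equal(unname(b0["c1"]), 0.25, tolerance = 1e-9)
  expect_equal(sum(b0), 1, tolerance = 1e-12)
  expect_true(all(b0 >= 1e-13))
})

test_that("initialize_beta gives new-only families the remaining mass equally", {
  j <- joint_mat(c(60, 40), "c1", c("a1", "a2"))
  pr <- estimate_learning_distributions(j)
  u <- family_universe(c("a1", "a2"), c("c1", "cNew", "EXTRA"))
  y <- c(a1 = 30L, a2 = 10L)
  b0 <- initialize_beta(pr, y, u)
  # c1 takes all observed mass (gamma = 1 everywhere): remaining 0 shared
  expect_equal(unname(b0["c1"]), 1, tolerance = 1e-9)
  expect_equal(unname(b0["cNew"]), unname(b0["EXTRA"]))
  expect_equal(sum(b0), 1, tolerance = 1e-12)
})

test_that("initialize_beta sums to one on random instances", {
  set.seed(23)
  for (rep in 1:10) {
    model <- rand_model(7, 5)
    joint <- simulate_counts(model, 5000L, seed = 100 + rep, labeled = TRUE)
    pr <- estimate_learning_distributions(joint)
    y <- rand_counts(model, 2000L)
    b0 <- initialize_beta(pr, y, model$universe)
    expect_equal(sum(b0), 1, tolerance = 1e-12)
    expect_true(all(b0 > 0))
  }
})

test_that("learned initialization approaches the generating confusion matrix", {
  cfg <- simulation_config(8, 10, 1e5, concentration = 30, cross_rate = 0.25, seed = 55)
  model <- sample_truth(cfg)
  joint <- simulate_counts(model, 2e5L, seed = 56, labeled = TRUE)
  pr <- estimate_learning_distributions(joint)
  a0 <- initialize_alpha(pr, model$universe)
  # per-column total variation within multinomial sampling error
  tv <- apply(abs(a0 - model$alpha), 2, sum) / 2
  reads_per_origin <- 2e5 * model$beta
  expect_true(all(tv < 10 / sqrt(reads_per_origin) + 0.01))
})
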