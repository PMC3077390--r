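# Synthetic subject tables mirroring the study demographics, no imaging.
make_subjects <- function(n_control = 31L, n_patient = 33L, seed = 1L) {
  set.seed(seed)
  n <- n_control + n_patient
  data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = c(rep("control", n_control), rep("patient", n_patient)),
    age = c(rnorm(n_control, 35.4, 8.82), rnorm(n_patient, 39.4, 8.82)),
    education = c(rnorm(n_control, 13.9, 2.5), rnorm(n_patient, 11.6, 2.4)),
    duration = c(rep(0, n_control), pmax(0, rnorm(n_patient, 12.7, 8.99))),
    panss_total = c(rep(NA, n_control), rnorm(n_patient, 38.7, 6)),
    stringsAsFactors = FALSE)
}

test_that("group regression handles constant and noiseless responses", {
  sub <- make_subjects(seed = 2)
  r <- group_regression(rep(5, 64), sub)
  expect_equal(r$coefficient, 0)
  expect_gt(r$p, 0.99)
  y <- 2 * (sub$group == "patient")
  r2 <- group_regression(y, sub)
  expect_equal(r2$coefficient, 2, tolerance = 1e-12)
  expect_error(group_regression(rnorm(10), sub), "length")
  expect_error(group_regression(rnorm(6), make_subjects(3L, 3L)),
               "too few")
  collinear <- make_subjects(seed = 3)
  collinear$education <- collinear$age * 2
  expect_error(group_regression(rnorm(64), collinear), "collinear")
})

test_that("group regression matches the normal-equations oracle on random small designs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(8:12, 1)
    sub <- data.frame(
      id = sprintf("S%02d", 1:n),
      group = sample(rep(c("control", "patient"), length.out = n)),
      age = rnorm(n, 37, 9),
      education = rnorm(n, 13, 2.5),
      duration = abs(rnorm(n, 5, 5)),
      stringsAsFactors = FALSE)
    sub$duration[sub$group == "control"] <- 0
    y <- rnorm(n)
    r <- group_regression(y, sub)
    X <- cbind(1, sub$group == "patient", sub$age, sub$education,
               sub$duration)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - 5)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    t_or <- beta[2] / se
    expect_equal(r$coefficient, beta[2], tolerance = 1e-10)
    expect_equal(r$t, t_or, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(t_or), n - 5), tolerance = 1e-10)
  }
})

test_that("simulated group effects are recovered without bias", {
  set.seed(7)
  beta <- 0.8
  est <- replicate(1000, {
    sub <- make_subjects(seed = sample.int(1e6, 1))
    y <- beta * (sub$group == "patient") + 0.02 * sub$age + rnorm(64, 0, 1)
    group_regression(y, sub)$coefficient
  })
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta), 2 * se_mean + 1e-8)
})

test_that("regression p values are calibrated under the null", {
  set.seed(19)
  pvals <- replicate(400, {
    sub <- make_subjects(seed = sample.int(1e6, 1))
    group_regression(rnorm(64), sub)$p
  })
  frac <- mean(pvals < 0.05)
  ci <- 0.05 + c(-3, 3) * sqrt(0.05 * 0.95 / 400)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("ROI-level analysis returns one row per bundle and metric and checks completeness", {
  sub <- make_subjects(seed = 4)
  means <- data.frame(id = sub$id, bundle = "fornix_L", metric = "fa",
                      value = rnorm(64, 0.5, 0.05))
  tab <- roi_analysis(means, sub)
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("bundle", "metric", "coefficient", "t", "p"))
  expect_error(roi_analysis(means[-5, ], sub), "S005")
  two <- rbind(means,
               transform(means, metric = "rd", value = rnorm(64, 4e-4)))
  tab2 <- roi_analysis(two, sub)
  expect_equal(nrow(tab2), 2L)
  expect_equal(tab2$metric, c("fa", "rd"))
})

test_that("pointwise analysis flags exactly the points below alpha over the family", {
  sub <- make_subjects(seed = 5)
  set.seed(5)
  prof <- matrix(rnorm(64 * 30, 0.5, 0.05), 64, 30)
  prof[sub$group == "patient", 14:16] <-
    prof[sub$group == "patient", 14:16] - 0.1
  res <- tractwise_analysis(prof, sub, smoothed = TRUE)
  expect_equal(nrow(res), 30L)
  expect_identical(res$significant, res$p < 0.05 / 30)
  # degenerate threshold: alpha such that alpha/family = 1 flags all points
  res_all <- tractwise_analysis(prof, sub, alpha = 30, smoothed = TRUE)
  expect_true(all(res_all$significant))
  # Bonferroni monotonicity: lowering alpha never adds a flag
  res_lo <- tractwise_analysis(prof, sub, alpha = 0.01, smoothed = TRUE)
  expect_true(all(which(res_lo$significant) %in% which(res$significant)))
  # unsmoothed input is smoothed with a notice
  expect_message(tractwise_analysis(prof, sub, smoothed = FALSE),
                 "smoothing")
})

test_that("pointwise analysis accepts long-format profiles", {
  sub <- make_subjects(4L, 4L, seed = 6)
  set.seed(6)
  long <- expand.grid(id = sub$id, point = 1:30,
                      stringsAsFactors = FALSE)
  long$bundle <- "tube"
  long$metric <- "fa"
  long$value <- rnorm(nrow(long), 0.5, 0.02)
  long$smoothed <- TRUE
  res <- tractwise_analysis(long, sub)
  expect_equal(nrow(res), 30L)
  mat <- matrix(NA_real_, 8, 30)
  for (i in 1:8) {
    rows <- long[long$id == sub$id[i], ]
    mat[i, ] <- rows$value[order(rows$point)]
  }
  res_m <- tractwise_analysis(mat, sub, smoothed = TRUE)
  expect_equal(res$p, res_m$p, tolerance = 1e-12)
})

test_that("partial correlation matches its definition, symmetry and invariances", {
  set.seed(9)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  # k = 0 equals plain Pearson (estimate and p)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(x, x)$r, 1)
  C <- cbind(rnorm(40), rnorm(40))
  a <- partial_correlation(x, y, C)
  b <- partial_correlation(y, x, C)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  # affine invariance in x, y, and covariates
  a2 <- partial_correlation(3 * x - 1, -2 * y + 5, C)
  expect_equal(abs(a2$r), abs(a$r), tolerance = 1e-10)
  expect_equal(a2$r, -a$r, tolerance = 1e-10)
  a3 <- partial_correlation(x, y, sweep(C, 2, c(2, 0.5), "*"))
  expect_equal(a3$r, a$r, tolerance = 1e-10)
  expect_error(partial_correlation(x, rep(1, 40), C), "residual variance")
  expect_error(partial_correlation(rnorm(5), rnorm(5), matrix(rnorm(10), 5)),
               "too few")
})

test_that("partial correlation matches the precision-matrix oracle and is unbiased", {
  set.seed(13)
  # construction with exact partial r = 0.5 given the covariate
  rho <- 0.5
  est <- replicate(1000, {
    c1 <- rnorm(33)
    u <- rnorm(33)
    v <- rho * u + sqrt(1 - rho^2) * rnorm(33)
    partial_correlation(u + c1, v + c1, c1)$r
  })
  expect_lt(abs(mean(est) - rho), 0.05)
  # precision-matrix oracle on one draw with two covariates
  n <- 200
  C <- cbind(rnorm(n), rnorm(n))
  x <- 0.4 * C[, 1] + rnorm(n)
  y <- 0.3 * C[, 2] + 0.5 * x + rnorm(n)
  S <- cov(cbind(x, y, C))
  P <- solve(S)
  oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(partial_correlation(x, y, C)$r, oracle, tolerance = 1e-10)
})

test_that("clinical correlation is patients-only, validates inputs and flags by family", {
  sub <- make_subjects(seed = 15)
  set.seed(151)
  prof <- matrix(rnorm(64 * 30, 0.5, 0.05), 64, 30)
  pat <- sub$group == "patient"
  # couple the score to point 10 strongly
  sub$panss_total[pat] <- 40 - 60 * prof[pat, 10] + rnorm(33, 0, 0.5)
  res <- clinical_correlation(prof, sub, scores = "panss_total",
                              smoothed = TRUE)
  expect_equal(nrow(res), 30L)
  expect_true(res$significant[10])
  expect_lt(res$r[10], 0)
  expect_identical(res$significant, res$p < 0.05 / 30)
  expect_error(clinical_correlation(prof, sub, scores = "nonexistent"),
               "missing")
  sub2 <- sub
  sub2$panss_total[pat] <- 21
  expect_error(clinical_correlation(prof, sub2, scores = "panss_total",
                                    smoothed = TRUE), "residual variance")
  few <- make_subjects(10L, 4L, seed = 16)
  expect_error(clinical_correlation(matrix(rnorm(14 * 30), 14), few,
                                    scores = "panss_total"), "8 patients")
})
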