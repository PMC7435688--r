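test_that("sample classification reflects detection and metabolite calls", {
  det <- rbind(isma1 = c(TRUE, FALSE, FALSE), isma2 = c(FALSE, FALSE, TRUE))
  colnames(det) <- c("s1", "s2", "s3")
  calls <- data.frame(sample_id = c("s1", "s2", "s3"),
                      detected = c(TRUE, FALSE, TRUE))
  cls <- classify_samples(det, calls)
  expect_identical(cls$encoder, c(TRUE, FALSE, TRUE))
  expect_identical(cls$converter, c(TRUE, FALSE, TRUE))

  meta <- data.frame(sample_id = c("s1", "s3"), age = c(40, 60))
  expect_warning(cls2 <- classify_samples(det, calls, meta), "missing metadata")
  expect_identical(cls2$sample_id, c("s1", "s3"))
  expect_identical(cls2$age, c(40, 60))
})

test_that("classification matches planted truth under perfect detection", {
  st <- small_study(seed = 33, n_samples = 100, detect_prob_delta = 1,
                    background_fp_epsilon = 0)
  tpm <- compute_tpm(st$counts,
                     setNames(st$gene_info$length_nt, st$gene_info$gene_id))
  planted <- st$gene_info$gene_id[st$gene_info$planted]
  cl <- data.frame(cluster_id = "isma", representative = planted[1],
                   member = planted)
  det <- detection_matrix(tpm, cl)
  cls <- classify_samples(det, metabolite_calls(st$metabolites))
  truth_enc <- st$samples$encoder_truth[match(cls$sample_id, st$samples$sample_id)]
  # converter == encoder presence when delta = 1, epsilon = 0
  expect_identical(cls$converter, truth_enc)
  # detection-based encoder call can only miss truth through read dropout
  expect_gt(mean(cls$encoder == truth_enc), 0.95)
})

test_that("odds ratio matches the cross-product and its invariances", {
  r <- odds_ratio(40, 15, 10, 89)
  expect_equal(r$odds_ratio, (40 * 89) / (15 * 10), tolerance = 1e-12)
  expect_false(r$correction_applied)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  expect_equal(odds_ratio(10, 10, 5, 5)$odds_ratio, 1.0)

  # swapping both rows and both columns leaves the OR unchanged
  expect_equal(odds_ratio(89, 10, 15, 40)$odds_ratio, r$odds_ratio)
  # transposing the table inverts it
  expect_equal(odds_ratio(15, 40, 89, 10)$odds_ratio, 1 / r$odds_ratio,
               tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- odds_ratio(12, 3, 0, 20)
  expect_true(r$correction_applied)
  # independent hand computation with +0.5 everywhere
  or_hand <- (12.5 * 20.5) / (3.5 * 0.5)
  se_hand <- sqrt(1 / 12.5 + 1 / 3.5 + 1 / 0.5 + 1 / 20.5)
  expect_equal(r$odds_ratio, or_hand, tolerance = 1e-12)
  expect_equal(r$ci_low, exp(log(or_hand) - qnorm(0.975) * se_hand),
               tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(or_hand) + qnorm(0.975) * se_hand),
               tolerance = 1e-12)

  expect_error(odds_ratio(0, 0, 5, 5), "margin")
  fr <- odds_ratio(40, 15, 10, 89, method = "fisher")
  expect_equal(fr$method, "fisher")
  expect_true(fr$ci_low < fr$ci_high)
})

test_that("metabolite transform applies pseudo-count, log10 and z-scoring", {
  x <- c(0, 1e-3, 1e-1)
  z <- transform_metabolite(x)
  lg <- c(-5, -3, -1)                       # zero becomes log10(1e-5) = -5
  expect_equal(z, (lg - mean(lg)) / sd(lg), tolerance = 1e-12)

  z2 <- transform_metabolite(c(1e-3, 1e-1))
  expect_equal(z2, c(-1, 1) / sqrt(2), tolerance = 1e-4)

  set.seed(10)
  y <- rlnorm(50)
  zy <- transform_metabolite(y)
  expect_equal(mean(zy), 0, tolerance = 1e-12)
  expect_equal(sd(zy), 1, tolerance = 1e-12)
  # idempotent on already-standardized log data up to the log/pseudo step
  expect_error(transform_metabolite(rep(2, 10)), "constant")
  expect_error(transform_metabolite(c(-1, 2)), "non-negative")
})

test_that("linear fits agree with the normal equations", {
  x <- 1:20
  d <- data.frame(y = 2 * x + 1, x = x)
  f <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
  expect_equal(f$sigma2, 0, tolerance = 1e-20)

  set.seed(12)
  n <- 100
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
  beta <- c(0.5, -1, 2, 0)
  y <- drop(X %*% beta) + rnorm(n)
  dd <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], x3 = X[, 4])
  f2 <- fit_linear(y ~ x1 + x2 + x3, dd)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)       # normal equations
  expect_equal(unname(coef(f2)), unname(drop(beta_oracle)), tolerance = 1e-8)
  res <- y - drop(X %*% beta_oracle)
  s2 <- sum(res^2) / (n - 4)
  se_oracle <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(unname(f2$se), unname(se_oracle), tolerance = 1e-8)

  dd$x4 <- dd$x1 + dd$x2                             # exact collinearity
  expect_error(fit_linear(y ~ x1 + x2 + x3 + x4, dd), "x4")
})

test_that("linear model recovers the planted serum TC effect with nominal coverage", {
  cfg <- simulation_config(lipid_effect_beta = -0.15, noise_sd = 0.9, seed = 1)
  covered <- 0
  set.seed(314)
  for (r in 1:100) {
    enc <- runif(5000) < 0.5
    ph <- simulate_host_phenotypes(enc, cfg, seed = NULL)
    f <- fit_linear(TC ~ encoder + age + sex + antibiotics + statin, ph)
    est <- coef(f)[["encoderTRUE"]]
    se <- f$se[["encoderTRUE"]]
    if (est - 1.96 * se <= -0.15 && -0.15 <= est + 1.96 * se) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("logistic IRLS matches glm and flags separation", {
  set.seed(21)
  d <- data.frame(x = rnorm(200), z = rnorm(200))
  d$y <- runif(200) < plogis(0.5 + 1.2 * d$x)
  f <- fit_logistic(y ~ x + z, d)
  g <- glm(y ~ x + z, data = d, family = binomial())
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-3)

  # balanced null: slope within 3 SE of zero
  d0 <- data.frame(x = rnorm(400))
  d0$y <- rep(c(TRUE, FALSE), 200)
  f0 <- fit_logistic(y ~ x, d0)
  expect_lt(abs(coef(f0)[["x"]]), 3 * f0$se[["x"]])

  # perfectly separable toy data
  ds <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(F, F, F, T, T, T))
  expect_error(fit_logistic(y ~ x, ds), "separat")
})

test_that("logistic solution beats random coefficient vectors in likelihood", {
  set.seed(31)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$y <- runif(200) < plogis(0.3 - 0.8 * d$x1 + 0.5 * d$x2)
  f <- fit_logistic(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  ll <- function(b) {
    p <- plogis(drop(X %*% b))
    sum(d$y * log(p) + (1 - d$y) * log(1 - p))
  }
  lls <- replicate(1000, ll(coef(f) + rnorm(3, 0, 0.5)))
  expect_true(all(f$loglik >= lls))
})

test_that("random-intercept ML reduces to OLS when tau^2 is zero", {
  set.seed(41)
  d <- data.frame(x = rnorm(120), g = rep(1:30, each = 4))
  d$y <- 1 + 0.5 * d$x + rnorm(120)          # no group effect
  fm <- fit_random_intercept(y ~ x, d, d$g)
  fl <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(fm)), unname(coef(fl)), tolerance = 1e-6)
  expect_lt(fm$tau2, 1e-4)
  # the mixed optimum can never fall below the tau^2 = 0 likelihood
  n <- nrow(d)
  sigma2_ols <- sum((d$y - cbind(1, d$x) %*% coef(fl))^2) / n
  ll_ols <- -0.5 * n * (log(2 * pi * sigma2_ols) + 1)
  expect_gte(fm$loglik, ll_ols - 1e-8)
})

test_that("random-intercept ML recovers planted variance components", {
  set.seed(51)
  k <- 200; m <- 5
  g <- rep(seq_len(k), each = m)
  u <- rnorm(k, 0, sqrt(0.5))
  d <- data.frame(x = rnorm(k * m), g = g)
  d$y <- 2 - 0.3 * d$x + u[g] + rnorm(k * m, 0, 1)
  f <- fit_random_intercept(y ~ x, d, d$g)
  expect_equal(f$sigma2, 1, tolerance = 0.15)
  expect_equal(f$tau2, 0.5, tolerance = 0.15 / 0.5)
  expect_equal(coef(f)[["x"]], -0.3, tolerance = 0.15 / 0.3)

  expect_error(fit_random_intercept(y ~ x, d[seq(1, k * m, m), ],
                                    d$g[seq(1, k * m, m)]), "singleton")
})

test_that("balanced one-way fits match the closed-form ML estimators and lme4", {
  set.seed(61)
  k <- 30; m <- 4; N <- k * m
  g <- rep(seq_len(k), each = m)
  y <- 2 + rnorm(k, 0, sqrt(0.5))[g] + rnorm(N, 0, 1)
  d <- data.frame(y = y, g = g)
  f <- fit_random_intercept(y ~ 1, d, d$g)
  gm <- tapply(y, g, mean)
  SSW <- sum((y - gm[g])^2)
  SSB <- m * sum((gm - mean(y))^2)
  sig2_cf <- SSW / (N - k)                  # balanced one-way ML
  tau2_cf <- max(0, SSB / k - sig2_cf) / m
  expect_equal(f$sigma2, sig2_cf, tolerance = 1e-4)
  expect_equal(f$tau2, tau2_cf, tolerance = 1e-3)
  expect_equal(unname(coef(f)[1]), mean(y), tolerance = 1e-8)

  lf <- lme4::lmer(y ~ 1 + (1 | g), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(f$tau2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(coef(f)[1]), unname(lme4::fixef(lf)[1]), tolerance = 1e-6)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(71)
  for (r in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Woolf intervals cover a planted odds ratio near 40", {
  set.seed(81)
  covered <- 0
  p0 <- 0.10                                 # converter risk, non-encoders
  odds1 <- 40 * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  for (r in 1:100) {
    enc <- runif(300) < 0.5
    conv <- runif(300) < ifelse(enc, p1, p0)
    ct <- contingency_counts(data.frame(encoder = enc, converter = conv))
    or <- odds_ratio(ct["a"], ct["b"], ct["c"], ct["d"])
    if (or$ci_low <= 40 && 40 <= or$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 90)
})
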