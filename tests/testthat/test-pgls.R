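test_that("with V = I the PGLS fit is exactly ordinary least squares", {
  set.seed(101)
  n <- 30
  d <- data.frame(species = sprintf("s%02d", 1:n),
                  y = rnorm(n), x1 = rnorm(n), x2 = runif(n))
  V <- diag(n); dimnames(V) <- list(d$species, d$species)
  fit <- fit_pgls(y ~ x1 + x2, d, V)
  ols <- lm(y ~ x1 + x2, d)
  sm <- summary(ols)$coefficients
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sm[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$tval), unname(sm[, 3]), tolerance = 1e-10)
  expect_equal(unname(fit$pval), unname(sm[, 4]), tolerance = 1e-10)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-10)
})

test_that("a noiseless linear response is recovered exactly", {
  set.seed(102)
  V <- random_vcv(15)
  d <- data.frame(species = rownames(V), x = rnorm(15))
  d$y <- 2 - 3 * d$x
  fit <- fit_pgls(y ~ x, d, V)
  expect_equal(unname(fit$coefficients), c(2, -3), tolerance = 1e-10)
  expect_equal(fit$sigma2, 0, tolerance = 1e-12)
})

test_that("fit_pgls matches the eigen-whitening OLS oracle", {
  set.seed(103)
  for (i in 1:100) {
    n <- sample(6:12, 1)
    V <- random_vcv(n)
    X <- cbind(1, matrix(rnorm(n * 2), n))
    y <- rnorm(n, sd = 2)
    d <- data.frame(species = rownames(V), y = y, x1 = X[, 2], x2 = X[, 3])
    fit <- fit_pgls(y ~ x1 + x2, d, V)
    or <- gls_whitening_oracle(X, y, V)
    expect_equal(unname(fit$coefficients), or$beta, tolerance = 1e-8)
    expect_equal(fit$logLik, or$logLik, tolerance = 1e-8)
    expect_equal(fit$AIC, -2 * or$logLik + 2 * fit$k, tolerance = 1e-8)
  }
})

test_that("ML fit agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(104)
  tr <- ape::rphylo(25, 1, 0)
  V <- brownian_vcv(tr)
  d <- data.frame(species = tr$tip.label, x = rnorm(25))
  d$y <- 1 + 0.5 * d$x + as.vector(t(chol(V)) %*% rnorm(25))
  fit <- fit_pgls(y ~ x, d, V)
  gfit <- nlme::gls(y ~ x, data = d,
                    correlation = ape::corBrownian(1, tr, form = ~species),
                    method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(gfit)),
               tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(gfit)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(gfit)$tTable[, "Std.Error"]), tolerance = 1e-6)
})

test_that("fit is invariant to simultaneous permutation of rows and V", {
  set.seed(105)
  V <- random_vcv(12)
  d <- data.frame(species = rownames(V), y = rnorm(12), x = rnorm(12))
  f1 <- fit_pgls(y ~ x, d, V)
  perm <- sample(12)
  f2 <- fit_pgls(y ~ x, d[perm, ], V)   # V realigned via species names
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
})

test_that("GLS equals OLS on an equal-branch star phylogeny", {
  tr <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2,F:2,G:2,H:2);")
  set.seed(106)
  d <- data.frame(species = tr$tip.label, y = rnorm(8), x = rnorm(8))
  fit <- fit_pgls(y ~ x, d, brownian_vcv(tr))
  ols <- lm(y ~ x, d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(unname(fit$se),
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)
})

test_that("adding a predictor never decreases the ML log-likelihood", {
  set.seed(107)
  for (i in 1:10) {
    V <- random_vcv(15)
    d <- data.frame(species = rownames(V), y = rnorm(15),
                    x = rnorm(15), junk = rnorm(15))
    f0 <- fit_pgls(y ~ x, d, V)
    f1 <- fit_pgls(y ~ x + junk, d, V)
    expect_gte(f1$logLik, f0$logLik - 1e-10)
  }
})

test_that("singular designs and degenerate inputs raise clear errors", {
  set.seed(108)
  V <- random_vcv(10)
  d <- data.frame(species = rownames(V), y = rnorm(10), x = rnorm(10))
  d$x2 <- 2 * d$x
  expect_error(fit_pgls(y ~ x + x2, d, V), "collinear.*x2")
  expect_error(fit_pgls(y ~ x, d, matrix(-diag(10), 10,
                                         dimnames = dimnames(V))),
               "positive")
})

test_that("t-tests are calibrated under a correctly specified Brownian null", {
  set.seed(109)
  tr <- ape::rphylo(80, 1, 0)
  V <- brownian_vcv(tr)
  R <- chol(V)
  x <- rnorm(80)
  p <- replicate(400, {
    d <- data.frame(species = tr$tip.label,
                    y = 1 + as.vector(t(R) %*% rnorm(80)), x = x)
    fit_pgls(y ~ x, d, V)$pval[["x"]]
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.05 - 2 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("PGLS slope estimates are unbiased under the generating model", {
  set.seed(110)
  tr <- ape::rphylo(40, 1, 0)
  V <- brownian_vcv(tr)
  R <- chol(V)
  x <- rnorm(40)
  est <- replicate(500, {
    d <- data.frame(species = tr$tip.label,
                    y = 1 + 0.7 * x + as.vector(t(R) %*% rnorm(40)) * 0.5,
                    x = x)
    fit_pgls(y ~ x, d, V)$coefficients[["x"]]
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.7), 4 * mc_se)
})

test_that("95% confidence intervals cover the truth at the nominal rate", {
  set.seed(111)
  tr <- ape::rphylo(40, 1, 0)
  V <- brownian_vcv(tr)
  R <- chol(V)
  x <- rnorm(40)
  covered <- replicate(500, {
    d <- data.frame(species = tr$tip.label,
                    y = 1 + 0.7 * x + as.vector(t(R) %*% rnorm(40)) * 0.5,
                    x = x)
    f <- fit_pgls(y ~ x, d, V)
    half <- qt(0.975, f$df.residual) * f$se[["x"]]
    abs(f$coefficients[["x"]] - 0.7) <= half
  })
  rate <- mean(covered)
  expect_gt(rate, 0.95 - 2 * sqrt(0.95 * 0.05 / 500))
  expect_lte(rate, 1)
})

test_that("the single-predictor suite crosses responses and predictors", {
  set.seed(112)
  V <- random_vcv(20)
  d <- data.frame(species = rownames(V),
                  geo_density = rnorm(20), eco_density = rnorm(20),
                  log_body_mass = rnorm(20), ssi_habitat = runif(20, 1, 4),
                  ssi_diet = runif(20, 0, 3))
  tab <- single_predictor_suite(d, V)
  expect_equal(nrow(tab), 12)  # 2 responses x 3 predictors x 2 rows
  expect_setequal(unique(tab$predictor),
                  c("log_body_mass", "ssi_habitat", "ssi_diet"))
  # each slope row equals the corresponding direct fit
  f <- fit_pgls(eco_density ~ ssi_habitat, d, V)
  row <- tab[tab$response == "eco_density" &
               tab$predictor == "ssi_habitat" & tab$term == "ssi_habitat", ]
  expect_equal(row$estimate, f$coefficients[["ssi_habitat"]])
  expect_equal(row$p_value, f$pval[["ssi_habitat"]])
  # a constant response has zero slopes
  d$flat <- 5
  tab0 <- single_predictor_suite(d, V, responses = "flat")
  expect_equal(tab0$estimate[tab0$term != "(Intercept)"], rep(0, 3),
               tolerance = 1e-10)
})

test_that("dredging fits every term subset and ranks by AIC", {
  set.seed(113)
  V <- random_vcv(25)
  d <- data.frame(species = rownames(V), y = rnorm(25), x1 = rnorm(25),
                  x2 = rnorm(25), f = factor(sample(c("a", "b", "c"), 25,
                                                    TRUE)),
                  x3 = rnorm(25), x4 = rnorm(25))
  dr <- dredge_pgls(y ~ x1 + x2 + x3 + x4 + f, d, V)
  expect_length(dr$fits, 32)           # 2^5 subsets, factor block atomic
  expect_equal(dr$table$delta[1], 0)   # best model first
  expect_true(all(diff(dr$table$AIC) >= -1e-12))
  # every subset AIC matches an independent direct fit of that formula
  for (i in sample(32, 8)) {
    f_i <- dr$fits[[i]]
    direct <- fit_pgls(f_i$formula, d, V)
    expect_equal(f_i$AIC, direct$AIC, tolerance = 1e-9)
    expect_equal(f_i$coefficients, direct$coefficients, tolerance = 1e-9)
  }
  expect_error(dredge_pgls(y ~ x1, d, V, max_terms = 0), "refusing")
})

test_that("model averaging matches the worked two-model example", {
  mk <- function(beta, se, aic) {
    structure(list(coefficients = beta, se = se, AIC = aic,
                   df.residual = 1e9, k = length(beta) + 1,
                   terms = names(beta)), class = "pgls_fit")
  }
  fits <- list(mk(c(x = 1), c(x = 0), 10), mk(c(x = 3), c(x = 0), 10))
  avg <- select_and_average(fits)
  expect_equal(avg$coefficients$estimate, 2)
  expect_equal(avg$coefficients$se, 1)  # 0.5*|1-2| + 0.5*|3-2|
  expect_equal(sum(avg$models$weight), 1)
  # a single retained model reproduces its own coefficients
  solo <- select_and_average(list(mk(c(a = 0.4, b = -1), c(a = 0.1, b = 0.2),
                                     5)))
  expect_equal(solo$coefficients$estimate, c(0.4, -1))
  expect_equal(solo$coefficients$se, c(0.1, 0.2))
})

test_that("full model averaging matches an independent implementation", {
  set.seed(114)
  for (rep in 1:20) {
    n_mod <- sample(2:6, 1)
    terms <- letters[1:4]
    fits <- lapply(seq_len(n_mod), function(i) {
      tm <- sample(terms, sample(1:4, 1))
      beta <- setNames(rnorm(length(tm)), tm)
      se <- setNames(runif(length(tm), 0.1, 1), tm)
      structure(list(coefficients = beta, se = se,
                     AIC = runif(1, 100, 104),
                     df.residual = sample(5:50, 1),
                     k = length(beta) + 1, terms = tm),
                class = "pgls_fit")
    })
    avg <- select_and_average(fits)
    aics <- sapply(fits, `[[`, "AIC")
    or <- average_oracle(lapply(fits, `[[`, "coefficients"),
                         lapply(fits, `[[`, "se"),
                         sapply(fits, `[[`, "df.residual"), aics)
    got <- avg$coefficients
    expect_equal(setNames(got$estimate, got$term),
                 or[got$term, "estimate"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(got$se, unname(or[got$term, "se"]), tolerance = 1e-10)
    expect_equal(got$adj_se, unname(or[got$term, "adj_se"]),
                 tolerance = 1e-10)
    # z/p relationship
    expect_equal(got$z_value, abs(got$estimate) / got$adj_se)
    expect_equal(got$p_value, 2 * pnorm(-got$z_value))
  }
})

test_that("dredging over identical trees yields zero cross-tree variance", {
  set.seed(115)
  tr <- ape::rphylo(15, 1, 0)
  d <- data.frame(species = tr$tip.label, y = rnorm(15), x1 = rnorm(15),
                  x2 = rnorm(15))
  rep_trees <- rep(list(tr), 4)
  stab <- dredge_over_trees(y ~ x1 + x2, d, rep_trees, consensus = tr)
  expect_equal(nrow(stab), 3)  # intercept + x1 + x2 of the full model
  expect_equal(stab$sd, rep(0, 3), tolerance = 1e-12)
  expect_equal(stab$mean, stab$consensus, tolerance = 1e-12)
  expect_equal(stab$sign_agreement, rep(1, 3))
})
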