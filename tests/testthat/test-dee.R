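test_that("single-line likelihoods reduce to their closed forms", {
  # one mutation, zero DEGs: probability is exactly pi0
  ll <- dee_loglik(list(pi0 = 0.3, shape = 1, scale = 2), "zero_gamma",
                   data.frame(m = 1, d = 0))
  expect_equal(as.numeric(ll), log(0.3), tolerance = 1e-12)
  # no spike, one mutation, d = 3: shifted-gamma interval F(3) - F(2)
  ll2 <- dee_loglik(list(pi0 = 0, shape = 0.7, scale = 3), "zero_gamma",
                    data.frame(m = 1, d = 3))
  expect_equal(as.numeric(ll2),
               log(pgamma(3, 0.7, scale = 3) - pgamma(2, 0.7, scale = 3)),
               tolerance = 1e-10)
  # zero mutations force d = 0
  ll3 <- dee_loglik(list(pi0 = 0.5, shape = 1, scale = 1), "zero_gamma",
                    data.frame(m = c(0, 0), d = c(0, 2)))
  expect_equal(unname(attr(ll3, "by_line")), c(0, -Inf))
})

test_that("the three model kinds agree where they nest", {
  lines <- data.frame(m = c(3, 7, 10), d = c(2, 9, 40))
  p <- list(pi0 = 0.25, pi1 = 0, shape = 0.8, scale = 4)
  expect_equal(as.numeric(dee_loglik(p, "zero_gamma", lines)),
               as.numeric(dee_loglik(p, "zero_one_gamma", lines)),
               tolerance = 1e-8)
  p0 <- list(pi0 = 0, shape = 0.8, scale = 4)
  # pi0 = 0 zero_gamma equals a pure shifted gamma; compare per line
  for (i in seq_len(nrow(lines))) {
    m <- lines$m[i]; d <- lines$d[i]
    direct <- log(pgamma(d - m + 1, m * 0.8, scale = 4) -
                    pgamma(max(d - m, 0), m * 0.8, scale = 4))
    expect_equal(attr(dee_loglik(p0, "zero_gamma", lines[i, ]), "by_line")[1],
                 direct, tolerance = 1e-8)
  }
})

test_that("interval probabilities per line sum to one over all DEG counts", {
  cases <- list(list(pi0 = 0.4, shape = 0.5, scale = 3, m = 4),
                list(pi0 = 0, shape = 2, scale = 1.5, m = 6),
                list(pi0 = 0.8, shape = 1, scale = 10, m = 3))
  for (cs in cases) {
    dmax <- ceiling(10 * cs$m * (1 + cs$shape * cs$scale)) + 50
    probs <- exp(vapply(0:dmax, function(d) {
      as.numeric(dee_loglik(cs[c("pi0", "shape", "scale")], "zero_gamma",
                            data.frame(m = cs$m, d = d)))
    }, numeric(1)))
    expect_equal(sum(probs), 1, tolerance = 1e-6)
  }
})

test_that("analytic likelihood matches forward simulation (Monte-Carlo oracle)", {
  set.seed(77)
  n <- 1e5
  cases <- list(
    list(model = "zero_gamma", pi0 = 0.5, pi1 = 0, shape = 1, scale = 2,
         m = 3, d = 2),
    list(model = "zero_gamma", pi0 = 0.2, pi1 = 0, shape = 0.3, scale = 8,
         m = 5, d = 4),
    list(model = "gamma", pi0 = 0, pi1 = 0, shape = 1.2, scale = 2,
         m = 4, d = 9))
  for (cs in cases) {
    if (cs$model == "gamma") {
      tot <- rgamma(n, shape = cs$m * cs$shape, scale = cs$scale)
    } else {
      j <- rbinom(n, cs$m, 1 - cs$pi0)
      tot <- j + ifelse(j > 0, rgamma(n, shape = j * cs$shape, scale = cs$scale), 0)
    }
    emp <- mean(tot >= cs$d & tot < cs$d + 1)
    ana <- exp(as.numeric(dee_loglik(cs[c("pi0", "pi1", "shape", "scale")],
                                     cs$model, data.frame(m = cs$m, d = cs$d))))
    se <- sqrt(emp * (1 - emp) / n)
    expect_lt(abs(emp - ana), 3 * se + 1e-4)
  }
})

test_that("degenerate all-zero DEG data drives pi0 to the top interval", {
  lines <- data.frame(m = c(5, 8, 12, 6), d = 0)
  f <- fit_dee(lines, "zero_gamma",
               optimizer_cfg = list(maxit = 300, n_restarts = 1), seed = 2)
  expect_identical(f$pi0_interval, c(0.8, 1.0))
  expect_gt(f$pi0, 0.8)
})

test_that("fitting is invariant to line order and reproducible by seed", {
  set.seed(55)
  m <- rpois(12, 40)
  lines <- data.frame(m = m, d = draw_dee_totals(m, 0.4, 0.5, 20))
  f1 <- suppressWarnings(
    fit_dee(lines, "zero_gamma", pi0_interval = c(0.2, 0.6),
            optimizer_cfg = list(maxit = 300, n_restarts = 1), seed = 9))
  f2 <- suppressWarnings(
    fit_dee(lines[sample(nrow(lines)), ], "zero_gamma",
            pi0_interval = c(0.2, 0.6),
            optimizer_cfg = list(maxit = 300, n_restarts = 1), seed = 9))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("model selection minimizes AIC with ties toward fewer parameters", {
  mk <- function(kind, ll) dee_fit_from_params(kind, pi0 = 0.1, shape = 1,
                                               scale = 1)
  f2 <- dee_fit_from_params("gamma", shape = 1, scale = 1)
  f2$loglik <- -100; f2$aic <- 2 * 2 + 200; f2$bic <- 2 * log(28) + 200
  f3 <- dee_fit_from_params("zero_gamma", pi0 = 0.1, shape = 1, scale = 1)
  f3$loglik <- -99; f3$aic <- 2 * 3 + 198; f3$bic <- 3 * log(28) + 198
  # AIC: 204 both ways -> tie broken toward the 2-parameter fit
  expect_equal(f2$aic, f3$aic)
  best <- select_model(list(f3, f2))
  expect_identical(best$model_kind, "gamma")
  # single fit returns itself
  expect_identical(select_model(list(f3))$model_kind, "zero_gamma")
  # clearly better loglik wins regardless of order
  f3b <- f3; f3b$loglik <- -80; f3b$aic <- 6 + 160
  expect_identical(select_model(list(f2, f3b))$model_kind, "zero_gamma")
})

test_that("dee_mean matches its closed forms and limits", {
  expect_equal(dee_mean(dee_fit_from_params("zero_gamma", pi0 = 1,
                                            shape = 1, scale = 1)), 0)
  # the published parameter set gives 14.3 to one decimal
  f <- dee_fit_from_params("zero_gamma", pi0 = 0.42, shape = 0.0118,
                           scale = 2005)
  expect_equal(round(dee_mean(f), 1), 14.3)
  # shift-only limit: shape -> 0 means every non-null mutation causes 1 DEG
  f0 <- dee_fit_from_params("zero_gamma", pi0 = 0, shape = 1e-12, scale = 1)
  expect_equal(dee_mean(f0), 1, tolerance = 1e-9)
  # three-component bookkeeping
  f3 <- dee_fit_from_params("zero_one_gamma", pi0 = 0.3, pi1 = 0.2,
                            shape = 2, scale = 5)
  expect_equal(dee_mean(f3), 0.2 + 0.5 * 11)
})

test_that("category probabilities sum to one and match closed forms", {
  expect_equal(unname(dee_category_probs(
    dee_fit_from_params("zero_gamma", pi0 = 1, shape = 1, scale = 1))),
    c(1, 0, 0))
  p <- dee_category_probs(dee_fit_from_params("zero_gamma", pi0 = 0,
                                              shape = 1, scale = 1))
  expect_equal(unname(p), c(0, 1 - exp(-1), exp(-1)), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:8) {
    kind <- sample(c("gamma", "zero_gamma", "zero_one_gamma"), 1)
    pi0 <- if (kind == "gamma") 0 else runif(1)
    pi1 <- if (kind == "zero_one_gamma") runif(1, 0, 1 - pi0) else 0
    f <- dee_fit_from_params(kind, pi0 = pi0, pi1 = pi1,
                             shape = rlnorm(1), scale = rlnorm(1, 1))
    expect_equal(sum(dee_category_probs(f)), 1, tolerance = 1e-10)
  }
})

test_that("simulated mutation-DEG correlations behave at the boundaries", {
  f_null <- dee_fit_from_params("zero_gamma", pi0 = 1, shape = 1, scale = 1)
  r <- simulate_deg_counts(f_null, mutation_counts = 1:10, n_iter = 50, seed = 1)
  expect_true(all(is.na(r$correlations)))
  # large effects, no spike: correlation positive in essentially all trials
  f_big <- dee_fit_from_params("zero_gamma", pi0 = 0, shape = 10, scale = 10)
  r2 <- simulate_deg_counts(f_big, mutation_counts = 1:28, n_iter = 400, seed = 2)
  expect_gt(mean(r2$correlations > 0, na.rm = TRUE), 0.99)
  # determinism
  r3 <- simulate_deg_counts(f_big, mutation_counts = 1:28, n_iter = 400, seed = 2)
  expect_identical(r2$correlations, r3$correlations)
  # degenerate: all mutation counts equal
  r4 <- simulate_deg_counts(f_big, mutation_counts = rep(5, 8), n_iter = 20,
                            seed = 3)
  expect_true(all(is.na(r4$correlations)))
  # percentile of an observed correlation
  r5 <- simulate_deg_counts(f_big, mutation_counts = 1:28, n_iter = 200,
                            seed = 4, observed_cor = 0)
  expect_lt(r5$percentile, 0.05)
})

test_that("invalid parameters are rejected", {
  lines <- data.frame(m = 3, d = 1)
  expect_error(dee_loglik(list(pi0 = 1.2, shape = 1, scale = 1),
                          "zero_gamma", lines), "spike")
  expect_error(dee_loglik(list(pi0 = 0.5, pi1 = 0.6, shape = 1, scale = 1),
                          "zero_one_gamma", lines), "spike")
  expect_error(dee_loglik(list(pi0 = 0.1, shape = -1, scale = 1),
                          "zero_gamma", lines), "positive")
  expect_error(fit_dee(lines[0, ], "zero_gamma"), "2 lines")
})
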