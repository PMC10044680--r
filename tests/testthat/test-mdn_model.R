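# direct-formula oracle for the mixture NLL: sum the K density terms
# numerically, no log-space tricks
oracle_nll <- function(w, mu, sigma, y) {
  -log(sum(w / (y * sigma * sqrt(2 * pi)) * exp(-(log(y) - mu)^2 / (2 * sigma^2))))
}

test_that("mixture NLL matches closed forms and the direct-formula oracle", {
  p1 <- mixture_params(1, 0, 1)
  expect_equal(lognormal_mixture_nll(p1, 1), log(sqrt(2 * pi)), tolerance = 1e-12)
  # degenerate two-component mixture equals its single component
  p2 <- mixture_params(c(0.5, 0.5), c(0.3, 0.3), c(0.7, 0.7))
  expect_equal(lognormal_mixture_nll(p2, 2.5),
               lognormal_mixture_nll(mixture_params(1, 0.3, 0.7), 2.5))
  # general mixture against the independent oracle
  w <- c(0.3, 0.7); mu <- c(0, 1); sigma <- c(0.5, 1.0)
  expect_equal(lognormal_mixture_nll(mixture_params(w, mu, sigma), 2.0),
               oracle_nll(w, mu, sigma, 2.0), tolerance = 1e-10)
  expect_error(lognormal_mixture_nll(p1, 0), "positive")
  expect_error(lognormal_mixture_nll(p1, -3), "positive")
})

test_that("mixture density integrates to one", {
  set.seed(4)
  for (rep in 1:5) {
    K <- sample(1:4, 1)
    w <- rexp(K); w <- w / sum(w)
    p <- mixture_params(w, rnorm(K, 1, 1), runif(K, 0.2, 1.5))
    dens <- function(y) {
      vapply(y, function(yy) exp(-lognormal_mixture_nll(p, yy)), numeric(1))
    }
    total <- stats::integrate(dens, 0, Inf, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
})

test_that("mixture CDF hits known values and limits", {
  p <- mixture_params(1, 0, 1)
  expect_equal(mixture_cdf(p, 1), 0.5)
  expect_equal(mixture_cdf(p, 1e12), 1, tolerance = 1e-9)
  expect_equal(mixture_cdf(p, 1e-12), 0, tolerance = 1e-9)
  expect_equal(mixture_cdf(p, -1), 0)
  p2 <- mixture_params(c(1, 0), c(log(4), log(50)), c(0.3, 0.3))
  expect_equal(mixture_cdf(p2, 4), 0.5, tolerance = 1e-9)
})

test_that("quantile inverts the CDF and is monotone", {
  expect_equal(mixture_quantile(mixture_params(1, log(3), 0.5), 0.5), 3,
               tolerance = 1e-7)
  set.seed(12)
  for (rep in 1:20) {
    K <- sample(1:3, 1)
    w <- rexp(K); w <- w / sum(w)
    p <- mixture_params(w, rnorm(K, 1, 1.5), runif(K, 0.1, 1.2))
    for (q in c(0.025, 0.5, 0.975)) {
      expect_equal(mixture_cdf(p, mixture_quantile(p, q)), q, tolerance = 1e-6)
    }
    qs <- vapply(c(0.25, 0.5, 0.75), function(q) mixture_quantile(p, q), numeric(1))
    expect_true(all(diff(qs) >= 0))
  }
  expect_error(mixture_quantile(mixture_params(1, 0, 1), 1.2), "probability")
})

test_that("exceedance probability complements the CDF and decreases in t", {
  p <- mixture_params(1, log(10), 1)
  expect_equal(prob_above(p, 10), 0.5)
  ts <- c(1, 5, 10, 20, 50)
  pa <- vapply(ts, function(t) prob_above(p, t), numeric(1))
  expect_true(all(diff(pa) < 0))
  expect_equal(pa + vapply(ts, function(t) mixture_cdf(p, t), numeric(1)),
               rep(1, 5), tolerance = 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  K <- 2
  w <- tmbcal:::.init_weights(c(3, 6, 4, 3 * K))
  X <- matrix(rnorm(15), 5, 3)
  z <- rnorm(5)
  lg <- tmbcal:::.mdn_loss_grad(w, X, z, K, 1e-3)
  for (wn in names(w)) {
    numeric_grad <- w[[wn]] * 0
    for (i in seq_along(numeric_grad)) {
      bump <- function(eps) {
        wp <- w
        wp[[wn]][i] <- wp[[wn]][i] + eps
        tmbcal:::.mdn_loss_grad(wp, X, z, K, 1e-3, grad = FALSE)$loss
      }
      numeric_grad[i] <- (bump(1e-6) - bump(-1e-6)) / 2e-6
    }
    expect_equal(lg$grads[[wn]], numeric_grad, tolerance = 1e-5)
  }
})

test_that("forward pass yields valid mixture parameters deterministically", {
  tab <- constant_input_table(400, 0.8, 0.5, seed = 31)
  tab$nonsyn_per_mb <- rexp(400, 0.2)
  fit <- mdn_fit(tab, model_config(hidden_sizes = c(16, 8), n_components = 3),
                 train_config(seed = 2, max_epochs = 15, batch_size = 128))
  p <- predict(fit, tab)
  expect_equal(rowSums(p$weights), rep(1, 400), tolerance = 1e-6)
  expect_true(all(p$sigma >= 1e-3))
  p2 <- predict(fit, tab)
  expect_identical(p, p2)
  # identical inputs give identical parameter rows
  same <- predict(fit, tab[c(1, 1), ])
  expect_identical(same$mu[1, ], same$mu[2, ])
})

test_that("training is bit-reproducible under a fixed seed", {
  tab <- constant_input_table(600, 1, 0.5, seed = 7)
  cfg <- model_config(hidden_sizes = c(8, 8), n_components = 2)
  tc <- train_config(seed = 13, max_epochs = 10, batch_size = 128)
  f1 <- mdn_fit(tab, cfg, tc)
  f2 <- mdn_fit(tab, cfg, tc)
  expect_identical(f1$log$val_nll, f2$log$val_nll)
  expect_identical(f1$weights, f2$weights)
  # row order canonicalized by sorting restores the same fit
  perm <- tab[sample.int(nrow(tab)), ]
  f3 <- mdn_fit(perm[order(perm$sample_id), ], cfg, tc)
  expect_identical(f1$weights, f3$weights)
})

test_that("a K=1 fit with constant input recovers the closed-form MLE", {
  tab <- constant_input_table(4000, 1, 0.6, seed = 19)
  fit <- mdn_fit(tab, model_config(n_components = 1, hidden_sizes = c(32, 16)),
                 train_config(seed = 3, max_epochs = 500, patience = 40))
  p <- predict(fit, tab[1, ])
  z <- log(tab$exomic_tmb + fit$config$label_offset)
  expect_lt(abs(p$mu[1, 1] - mean(z)), 0.03)
  expect_lt(abs(p$sigma[1, 1] - stats::sd(z)), 0.03)
})

test_that("shifting labels multiplicatively shifts fitted mu by the log constant", {
  tab <- constant_input_table(2000, 0.5, 0.4, seed = 23)
  cfg <- model_config(n_components = 1, hidden_sizes = c(16, 8), label_offset = 1e-9)
  tc <- train_config(seed = 9, max_epochs = 150)
  base <- predict(mdn_fit(tab, cfg, tc), tab[1, ])
  shifted_tab <- tab
  shifted_tab$exomic_tmb <- tab$exomic_tmb * exp(1)   # ln y + 1
  shifted <- predict(mdn_fit(shifted_tab, cfg, tc), tab[1, ])
  expect_equal(shifted$mu[1, 1] - base$mu[1, 1], 1, tolerance = 0.03)
})

test_that("checkpoints round-trip through JSON exactly", {
  tab <- constant_input_table(500, 1, 0.5, seed = 5)
  fit <- mdn_fit(tab, model_config(hidden_sizes = c(8, 4), n_components = 2),
                 train_config(seed = 11, max_epochs = 5, batch_size = 128))
  path <- tempfile(fileext = ".json")
  mdn_save(fit, path)
  back <- mdn_load(path)
  p1 <- predict(fit, tab[1:10, ])
  p2 <- predict(back, tab[1:10, ])
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the linear baseline recovers a noiseless line and is symmetric", {
  tab <- data.frame(sample_id = 1:50, nonsyn_per_mb = seq(0, 10, length.out = 50),
                    all_per_mb = 0, hotspot_per_mb = 0, ancestry = "EUR")
  tab$exomic_tmb <- 2 * tab$nonsyn_per_mb + 1
  fit <- linear_baseline_fit(tab)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-12)
  # symmetric predictive distribution: median == mean
  newdata <- tab[1:5, ]
  expect_equal(baseline_quantile(fit, newdata, 0.5), predict(fit, newdata))
  expect_error(
    linear_baseline_fit(transform(tab, all_per_mb = nonsyn_per_mb),
                        input_config(use_all = TRUE)),
    "rank")
})
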