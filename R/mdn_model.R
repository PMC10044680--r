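# Mixture-of-log-normals density regression: mixture parameter container and
# distribution math, the fully connected mixture density network trained by
# negative log-likelihood (analytic gradients + Adam), and the fixed-variance
# linear baseline.

#' Mixture-of-log-normals parameters
#'
#' Holds per-sample parameters of a K-component log-normal mixture over
#' exomic TMB: component weights, log-scale means and log-scale SDs. One row
#' per sample; a single parameter set is the n = 1 case.
#'
#' @param weights n x K matrix (or length-K vector) of mixture weights; each
#'   row must sum to 1 within 1e-6.
#' @param mu n x K matrix (or vector) of log-scale means.
#' @param sigma n x K matrix (or vector) of log-scale SDs, all > 0.
#' @return object of class `mixture_params`.
#' @export
mixture_params <- function(weights, mu, sigma) {
  to_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  weights <- to_mat(weights); mu <- to_mat(mu); sigma <- to_mat(sigma)
  if (!all(dim(weights) == dim(mu)) || !all(dim(mu) == dim(sigma))) {
    stop("weights, mu and sigma must have matching dimensions")
  }
  if (any(abs(rowSums(weights) - 1) > 1e-6)) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (any(sigma <= 0)) stop("all sigma must be > 0")
  structure(list(weights = weights, mu = mu, sigma = sigma),
            class = "mixture_params")
}

n_mixtures <- function(params) nrow(params$weights)

#' Subset per-sample mixture parameters
#' @param params a [mixture_params()] set.
#' @param i row index.
#' @return `mixture_params` for the selected samples.
#' @export
params_subset <- function(params, i) {
  mixture_params(params$weights[i, , drop = FALSE],
                 params$mu[i, , drop = FALSE],
                 params$sigma[i, , drop = FALSE])
}

# log(sum(exp(x))) by row, max-shifted
.row_logsumexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

# Broadcast an n-row params set against a length-m observation vector:
# valid when n == m, n == 1, or m == 1.
.broadcast <- function(params, y) {
  n <- n_mixtures(params); m <- length(y)
  if (n == m) return(list(params = params, y = y))
  if (n == 1L) {
    rep_row <- function(x) matrix(x, nrow = m, ncol = ncol(x), byrow = TRUE)
    return(list(params = mixture_params(rep_row(params$weights),
                                        rep_row(params$mu),
                                        rep_row(params$sigma)), y = y))
  }
  if (m == 1L) return(list(params = params, y = rep(y, n)))
  stop("length of observations does not match number of parameter rows")
}

#' Negative log-likelihood of a log-normal mixture
#'
#' Computes `-log sum_k w_k * dlnorm(y, mu_k, sigma_k)` in log-space with a
#' max shift for numerical stability.
#'
#' @param params a [mixture_params()] (one row, or one row per observation).
#' @param y positive observations.
#' @return per-observation NLL vector.
#' @export
lognormal_mixture_nll <- function(params, y) {
  if (any(!is.finite(y)) || any(y <= 0)) stop("y must be positive and finite")
  b <- .broadcast(params, y)
  params <- b$params; y <- b$y
  z <- log(y)
  logphi <- -log(params$sigma) - 0.5 * log(2 * pi) -
    0.5 * ((z - params$mu) / params$sigma)^2
  ll <- .row_logsumexp(log(params$weights) + logphi) - z
  -ll
}

#' CDF of a log-normal mixture
#'
#' `sum_k w_k * pnorm((log t - mu_k) / sigma_k)`; 0 for `t <= 0`.
#'
#' @param params a [mixture_params()].
#' @param t evaluation point(s).
#' @return CDF value per parameter row (or per `t` when one row is given).
#' @export
mixture_cdf <- function(params, t) {
  b <- .broadcast(params, t)
  params <- b$params; t <- b$y
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    z <- log(t[pos])
    p <- params_subset(params, which(pos))
    out[pos] <- rowSums(p$weights * stats::pnorm((z - p$mu) / p$sigma))
  }
  out
}

#' Probability that the response exceeds a threshold
#'
#' @param params a [mixture_params()].
#' @param t threshold(s), > 0.
#' @return `1 - mixture_cdf(params, t)`.
#' @export
prob_above <- function(params, t) 1 - mixture_cdf(params, t)

#' Quantile of a log-normal mixture
#'
#' Inverts the CDF by bisection in log space on the bracketing interval
#' `[min_k exp(mu_k - 8 sigma_k), max_k exp(mu_k + 8 sigma_k)]` to a
#' relative tolerance of 1e-8. `mixture_quantile(params, 0.5)` is the
#' model's point estimate (the predictive median).
#'
#' @param params a [mixture_params()].
#' @param q probability in (0, 1), scalar.
#' @return quantile per parameter row.
#' @export
mixture_quantile <- function(params, q) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must be a single probability in (0, 1)")
  }
  lo <- apply(params$mu - 8 * params$sigma, 1, min)
  hi <- apply(params$mu + 8 * params$sigma, 1, max)
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    below <- mixture_cdf(params, exp(mid)) < q
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-9) break
  }
  exp((lo + hi) / 2)
}

#' Predictive median of a log-normal mixture
#' @param params a [mixture_params()].
#' @return per-row median.
#' @export
mixture_median <- function(params) mixture_quantile(params, 0.5)

#' Predictive mean of a log-normal mixture
#'
#' Closed form `sum_k w_k exp(mu_k + sigma_k^2 / 2)`.
#'
#' @param params a [mixture_params()].
#' @return per-row mean.
#' @export
mixture_mean <- function(params) {
  rowSums(params$weights * exp(params$mu + params$sigma^2 / 2))
}

# ---------------------------------------------------------------------------
# Network configuration and design matrices

#' Mixture density network configuration
#'
#' @param hidden_sizes sizes of the fully connected hidden layers.
#' @param n_components number of log-normal mixture components K.
#' @param inputs an [input_config()] choosing which per-Mb counts and
#'   whether ancestry enter the predictor vector.
#' @param label_offset small positive offset added to exomic TMB before the
#'   log-likelihood so zero-TMB samples stay inside the log-normal support.
#' @param sigma_floor lower bound added to the softplus-transformed SDs,
#'   preventing component collapse.
#' @return list of class `mdn_config`.
#' @export
model_config <- function(hidden_sizes = c(128, 64, 32), n_components = 3,
                         inputs = input_config(), label_offset = 0.01,
                         sigma_floor = 1e-3) {
  stopifnot(n_components >= 1, label_offset > 0, sigma_floor > 0,
            all(hidden_sizes >= 1))
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 n_components = as.integer(n_components),
                 inputs = inputs, label_offset = label_offset,
                 sigma_floor = sigma_floor),
            class = "mdn_config")
}

#' Optimization settings for [mdn_fit()]
#'
#' Adam with early stopping on validation NLL; the seed fully determines
#' initialization, the validation split and batch order.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param val_fraction fraction of the training table held out for early
#'   stopping.
#' @param seed integer RNG seed.
#' @return list of class `mdn_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 512,
                         max_epochs = 1000, patience = 20,
                         val_fraction = 0.1, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, val_fraction > 0, val_fraction < 0.5)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "mdn_train_config")
}

.ancestry_onehot <- function(ancestry) {
  ancestry <- as.character(ancestry)
  ancestry[!ancestry %in% ANCESTRY_LEVELS] <- "OTHER"
  m <- outer(ancestry, ANCESTRY_LEVELS, `==`) * 1
  colnames(m) <- paste0("ancestry_", ANCESTRY_LEVELS)
  m
}

# Predictor matrix for the network: log1p of the active per-Mb counts,
# plus the ancestry one-hot when configured.
.build_design <- function(table, inputs, transform = log1p) {
  cols <- list(nonsyn = transform(table$nonsyn_per_mb))
  if (isTRUE(inputs$use_all)) cols$all <- transform(table$all_per_mb)
  if (isTRUE(inputs$use_hotspot)) cols$hotspot <- transform(table$hotspot_per_mb)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (isTRUE(inputs$use_ancestry)) X <- cbind(X, .ancestry_onehot(table$ancestry))
  X
}

# ---------------------------------------------------------------------------
# Network internals

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.init_weights <- function(sizes) {
  # Glorot-uniform layers; consumes RNG in a fixed order
  weights <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    s <- sqrt(6 / (fan_in + fan_out))
    weights[[paste0("W", l)]] <- matrix(stats::runif(fan_in * fan_out, -s, s),
                                        fan_in, fan_out)
    weights[[paste0("b", l)]] <- numeric(fan_out)
  }
  weights
}

# Forward pass to raw output; returns activations for backprop.
.mdn_forward_raw <- function(weights, X, n_layers) {
  H <- list(X)
  A <- list()
  for (l in seq_len(n_layers)) {
    A[[l]] <- sweep(H[[l]] %*% weights[[paste0("W", l)]], 2,
                    weights[[paste0("b", l)]], `+`)
    H[[l + 1L]] <- if (l < n_layers) .softplus(A[[l]]) else A[[l]]
  }
  list(A = A, H = H, out = H[[n_layers + 1L]])
}

.split_output <- function(out, K, sigma_floor) {
  logits <- out[, 1:K, drop = FALSE]
  mu <- out[, (K + 1):(2 * K), drop = FALSE]
  s <- out[, (2 * K + 1):(3 * K), drop = FALSE]
  m <- apply(logits, 1, max)
  w <- exp(logits - m)
  w <- w / rowSums(w)
  sigma <- .softplus(s) + sigma_floor
  list(logits = logits, w = w, mu = mu, s = s, sigma = sigma)
}

# Mean NLL of z = log(y + offset) and gradients w.r.t. every weight.
.mdn_loss_grad <- function(weights, X, z, K, sigma_floor, grad = TRUE) {
  n_layers <- length(weights) / 2L
  fw <- .mdn_forward_raw(weights, X, n_layers)
  p <- .split_output(fw$out, K, sigma_floor)
  B <- nrow(X)
  logphi <- -log(p$sigma) - 0.5 * log(2 * pi) - 0.5 * ((z - p$mu) / p$sigma)^2
  Lk <- log(p$w) + logphi
  lse <- .row_logsumexp(Lk)
  loss <- mean(-lse + z)
  if (!grad) return(list(loss = loss))
  r <- exp(Lk - lse)                       # responsibilities
  dlogits <- (p$w - r) / B
  dmu <- -r * (z - p$mu) / p$sigma^2 / B
  dsigma <- -r * ((z - p$mu)^2 / p$sigma^3 - 1 / p$sigma) / B
  ds <- dsigma * stats::plogis(p$s)        # softplus'
  dOut <- cbind(dlogits, dmu, ds)
  grads <- vector("list", length(weights))
  names(grads) <- names(weights)
  dH <- dOut
  for (l in rev(seq_len(n_layers))) {
    dA <- if (l < n_layers) dH * stats::plogis(fw$A[[l]]) else dH
    grads[[paste0("W", l)]] <- crossprod(fw$H[[l]], dA)
    grads[[paste0("b", l)]] <- colSums(dA)
    if (l > 1L) dH <- dA %*% t(weights[[paste0("W", l)]])
  }
  list(loss = loss, grads = grads)
}

# ---------------------------------------------------------------------------

#' Fit the mixture density network
#'
#' Trains a fully connected network (default hidden layers 128/64/32 with
#' softplus activations) whose output layer parameterizes a K-component
#' log-normal mixture over exomic TMB; the mean negative log-likelihood of
#' the offset labels is minimized by Adam with early stopping on a held-out
#' validation split. Gradients are analytic. Training is fully deterministic
#' given `train_config$seed`.
#'
#' @param table training data.frame with columns `nonsyn_per_mb`,
#'   `all_per_mb`, `hotspot_per_mb`, `ancestry`, `exomic_tmb` (the
#'   percentile cap of [cap_training_set()] is expected to have been applied
#'   upstream).
#' @param config a [model_config()].
#' @param train a [train_config()].
#' @return object of class `mdn`: weights, configs, per-epoch training log
#'   (`epoch`, `train_nll`, `val_nll`) and the restored best epoch.
#' @export
mdn_fit <- function(table, config = model_config(), train = train_config()) {
  stopifnot(inherits(config, "mdn_config"), inherits(train, "mdn_train_config"))
  X <- .build_design(table, config$inputs)
  y <- table$exomic_tmb
  if (any(!is.finite(y)) || any(y < 0)) stop("exomic_tmb labels must be finite and >= 0")
  z <- log(y + config$label_offset)
  n <- nrow(X)
  K <- config$n_components
  if (n < 10 * K) stop("too few samples to fit the mixture")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(train$seed)

  sizes <- c(ncol(X), config$hidden_sizes, 3L * K)
  weights <- .init_weights(sizes)
  # Start mu outputs near the label mean and sigma near the label SD so the
  # first epochs are not spent escaping an arbitrary scale.
  n_layers <- length(sizes) - 1L
  bL <- weights[[paste0("b", n_layers)]]
  bL[(K + 1):(2 * K)] <- mean(z) + 0.1 * seq(-1, 1, length.out = K) * max(stats::sd(z), 0.1)
  sd0 <- max(stats::sd(z), 0.05)
  bL[(2 * K + 1):(3 * K)] <- log(expm1(sd0))  # softplus^-1
  weights[[paste0("b", n_layers)]] <- bL

  perm <- sample.int(n)
  n_val <- max(1L, floor(train$val_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[-seq_len(n_val)]
  Xtr <- X[train_idx, , drop = FALSE]; ztr <- z[train_idx]
  Xval <- X[val_idx, , drop = FALSE]; zval <- z[val_idx]
  ntr <- length(train_idx)

  m_state <- lapply(weights, function(w) w * 0)
  v_state <- lapply(weights, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  best_val <- Inf; best_weights <- weights; best_epoch <- 0L; wait <- 0L
  log_epoch <- integer(); log_train <- numeric(); log_val <- numeric()

  for (epoch in seq_len(train$max_epochs)) {
    order_idx <- sample.int(ntr)
    starts <- seq(1L, ntr, by = train$batch_size)
    epoch_loss <- 0
    for (s0 in starts) {
      idx <- order_idx[s0:min(s0 + train$batch_size - 1L, ntr)]
      lg <- .mdn_loss_grad(weights, Xtr[idx, , drop = FALSE], ztr[idx],
                           K, config$sigma_floor)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (batch starting at %d)", epoch, s0))
      }
      epoch_loss <- epoch_loss + lg$loss * length(idx)
      step <- step + 1L
      corr <- train$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      for (wn in names(weights)) {
        g <- lg$grads[[wn]]
        m_state[[wn]] <- b1 * m_state[[wn]] + (1 - b1) * g
        v_state[[wn]] <- b2 * v_state[[wn]] + (1 - b2) * g^2
        weights[[wn]] <- weights[[wn]] - corr * m_state[[wn]] / (sqrt(v_state[[wn]]) + eps)
      }
    }
    val_nll <- .mdn_loss_grad(weights, Xval, zval, K, config$sigma_floor, grad = FALSE)$loss
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, epoch_loss / ntr)
    log_val <- c(log_val, val_nll)
    if (val_nll < best_val - 1e-7) {
      best_val <- val_nll; best_weights <- weights; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train$patience) break
    }
  }

  structure(list(weights = best_weights, config = config, train = train,
                 input_names = colnames(X),
                 log = data.frame(epoch = log_epoch, train_nll = log_train,
                                  val_nll = log_val),
                 best_epoch = best_epoch, best_val_nll = best_val),
            class = "mdn")
}

#' Predict mixture parameters for new samples
#'
#' @param object a fitted [mdn_fit()] model.
#' @param newdata data.frame with the model's input columns.
#' @param ... unused.
#' @return a [mixture_params()] set, one row per sample.
#' @export
predict.mdn <- function(object, newdata, ...) {
  X <- .build_design(newdata, object$config$inputs)
  if (ncol(X) != length(object$input_names)) {
    stop("newdata does not match the model's input schema")
  }
  n_layers <- length(object$weights) / 2L
  out <- .mdn_forward_raw(object$weights, X, n_layers)$out
  p <- .split_output(out, object$config$n_components, object$config$sigma_floor)
  mixture_params(p$w, p$mu, p$sigma)
}

#' Held-out NLL of a fitted model
#'
#' Mean negative log-likelihood of the offset labels under the predicted
#' mixtures; comparable across models sharing the same `label_offset`.
#'
#' @param object fitted `mdn`.
#' @param newdata data.frame with inputs and `exomic_tmb`.
#' @return mean NLL.
#' @export
mdn_nll <- function(object, newdata) {
  params <- predict(object, newdata)
  mean(lognormal_mixture_nll(params, newdata$exomic_tmb + object$config$label_offset))
}

#' @export
print.mdn <- function(x, ...) {
  cat(sprintf("mixture density network: %d -> %s -> %d log-normal components\n",
              length(x$input_names), paste(x$config$hidden_sizes, collapse = "/"),
              x$config$n_components))
  cat(sprintf("  best epoch %d, validation NLL %.4f\n", x$best_epoch, x$best_val_nll))
  invisible(x)
}

#' Save / load a fitted network as a JSON checkpoint
#'
#' Weights are written at full precision so a reloaded model reproduces
#' predictions exactly.
#'
#' @param model fitted `mdn`.
#' @param path checkpoint path.
#' @return `path` invisibly ([mdn_save()]) or the model ([mdn_load()]).
#' @export
mdn_save <- function(model, path) {
  payload <- list(
    class = "tmbcal_mdn_checkpoint",
    config = list(hidden_sizes = model$config$hidden_sizes,
                  n_components = model$config$n_components,
                  inputs = unclass(model$config$inputs),
                  label_offset = model$config$label_offset,
                  sigma_floor = model$config$sigma_floor),
    train = unclass(model$train),
    input_names = model$input_names,
    best_epoch = model$best_epoch,
    best_val_nll = model$best_val_nll,
    log = model$log,
    weights = model$weights
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mdn_save
#' @export
mdn_load <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cfg <- model_config(
    hidden_sizes = payload$config$hidden_sizes,
    n_components = payload$config$n_components,
    inputs = do.call(input_config, payload$config$inputs),
    label_offset = payload$config$label_offset,
    sigma_floor = payload$config$sigma_floor
  )
  weights <- payload$weights
  weights <- lapply(weights, function(w) if (is.list(w)) do.call(rbind, w) else w)
  # vectors stay vectors; matrices come back as matrices
  tc <- do.call(train_config, payload$train)
  structure(list(weights = weights, config = cfg, train = tc,
                 input_names = payload$input_names,
                 log = as.data.frame(payload$log),
                 best_epoch = payload$best_epoch,
                 best_val_nll = payload$best_val_nll),
            class = "mdn")
}

# ---------------------------------------------------------------------------
# Fixed-variance linear baseline

#' Fit the fixed-variance normal linear baseline
#'
#' Ordinary least squares of exomic TMB on the raw per-Mb counts (and
#' ancestry dummies when configured), with a single global residual
#' variance — the homoscedastic normal model that minimizing MSE implies.
#' Its predictive distribution `Normal(x'beta, MSE)` supplies the baseline
#' analogues of the mixture's quantiles and exceedance probabilities.
#'
#' @param table training data.frame (same schema as [mdn_fit()]).
#' @param inputs an [input_config()].
#' @return object of class `tmb_baseline` with `coefficients` and `sigma2`.
#' @export
linear_baseline_fit <- function(table, inputs = input_config()) {
  X <- .baseline_design(table, inputs)
  y <- table$exomic_tmb
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient baseline design")
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  structure(list(coefficients = fit$coefficients,
                 sigma2 = mean(res^2),
                 inputs = inputs),
            class = "tmb_baseline")
}

.baseline_design <- function(table, inputs) {
  cols <- list(intercept = rep(1, nrow(table)),
               nonsyn = table$nonsyn_per_mb)
  if (isTRUE(inputs$use_all)) cols$all <- table$all_per_mb
  if (isTRUE(inputs$use_hotspot)) cols$hotspot <- table$hotspot_per_mb
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (isTRUE(inputs$use_ancestry)) {
    oh <- .ancestry_onehot(table$ancestry)
    X <- cbind(X, oh[, -1, drop = FALSE])  # EUR as reference level
  }
  X
}

#' @export
predict.tmb_baseline <- function(object, newdata, ...) {
  X <- .baseline_design(newdata, object$inputs)
  drop(X %*% object$coefficients)
}

#' Baseline predictive-distribution helpers
#'
#' Exceedance probability, quantile and per-observation NLL under the
#' baseline's `Normal(mean, MSE)` predictive distribution.
#'
#' @param fit a [linear_baseline_fit()].
#' @param newdata data.frame of inputs (with `exomic_tmb` for the NLL).
#' @param t threshold; `q` probability in (0, 1).
#' @return numeric vector per sample.
#' @export
baseline_prob_above <- function(fit, newdata, t) {
  mu <- predict(fit, newdata)
  1 - stats::pnorm(t, mean = mu, sd = sqrt(fit$sigma2))
}

#' @rdname baseline_prob_above
#' @param q probability in (0, 1).
#' @export
baseline_quantile <- function(fit, newdata, q) {
  stopifnot(q > 0, q < 1)
  stats::qnorm(q, mean = predict(fit, newdata), sd = sqrt(fit$sigma2))
}

#' @rdname baseline_prob_above
#' @export
baseline_nll <- function(fit, newdata) {
  mu <- predict(fit, newdata)
  -stats::dnorm(newdata$exomic_tmb, mean = mu, sd = sqrt(fit$sigma2), log = TRUE)
}
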