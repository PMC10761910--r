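# Shallow fully-connected neural network for normalized droplet diameter,
# implemented directly with matrix algebra: two ReLU hidden layers (wide and
# shallow suits the ~1000-record dataset better than deep and narrow), a
# linear output head, mean-squared-error loss with an L2 weight penalty, and
# minibatch Adam. Features are z-scored on training statistics; the target is
# the raw normalized diameter.

#' Neural-network specification
#'
#' Defaults: hidden layers of 512 and 16 ReLU units, Adam with learning rate
#' 3e-4 and batches of 32, L2 penalty 0.001 on the weights, up to 1000 epochs
#' with early stopping (patience 50) on a 10% validation slice, and the
#' 7-feature input set (viscosity ratio excluded).
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param l2 L2 penalty coefficient applied to weights (not biases).
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience in epochs.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping.
#' @param include_viscosity_ratio Whether the viscosity ratio enters the
#'   feature set (excluded by default for this model).
#' @param seed RNG seed controlling initialization, the validation slice and
#'   minibatch order; training is reproducible given the seed.
#' @return A list of class `nn_spec`.
#' @export
nn_spec <- function(hidden = c(512L, 16L), learning_rate = 3e-4,
                    batch_size = 32L, l2 = 1e-3, max_epochs = 1000L,
                    patience = 50L, val_fraction = 0.1,
                    include_viscosity_ratio = FALSE, seed = 0L) {
  structure(list(
    hidden = as.integer(hidden), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), l2 = l2,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    val_fraction = val_fraction,
    include_viscosity_ratio = include_viscosity_ratio,
    seed = as.integer(seed)
  ), class = "nn_spec")
}

.relu <- function(x) x * (x > 0)

.nn_forward <- function(w, x) {
  a1 <- .relu(sweep(x %*% w$W1, 2, w$b1, `+`))
  a2 <- .relu(sweep(a1 %*% w$W2, 2, w$b2, `+`))
  drop(a2 %*% w$W3) + w$b3
}

.nn_init <- function(p, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(
    W1 = matrix(stats::rnorm(p * h1, 0, sqrt(2 / p)), p, h1),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, 0, sqrt(2 / h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(stats::rnorm(h2, 0, sqrt(2 / h2)), h2, 1),
    b3 = 0
  )
}

#' Fit the neural-network diameter model
#'
#' Trains the shallow network described by [nn_spec()] on a droplet dataset.
#' Inputs are z-scored on the training statistics; the target is the
#' normalized diameter. Training minimizes mean squared error plus an L2
#' weight penalty using minibatch Adam, with early stopping on a held-out
#' validation slice; the weights from the best validation epoch are kept.
#'
#' @param data A droplet dataset.
#' @param spec An [nn_spec()].
#' @return An object of class `diameter_nn`.
#' @export
fit_diameter_nn <- function(data, spec = nn_spec()) {
  stopifnot(inherits(spec, "nn_spec"))
  feats <- featurize(data, include_viscosity_ratio = spec$include_viscosity_ratio)
  x_all <- as.matrix(feats)
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  y_all <- d$norm_diameter
  if (nrow(x_all) == 0) stop("training data is empty", call. = FALSE)
  if (any(!is.finite(x_all)) || any(!is.finite(y_all))) {
    stop("non-finite feature or target values", call. = FALSE)
  }
  centers <- colMeans(x_all)
  scales <- apply(x_all, 2, stats::sd)
  scales[scales == 0] <- 1
  x_all <- sweep(sweep(x_all, 2, centers), 2, scales, `/`)

  n <- nrow(x_all)
  withr::with_seed(spec$seed, {
    n_val <- max(1L, floor(spec$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    x_tr <- x_all[-val_idx, , drop = FALSE]; y_tr <- y_all[-val_idx]
    x_va <- x_all[val_idx, , drop = FALSE]; y_va <- y_all[val_idx]

    w <- .nn_init(ncol(x_all), spec$hidden)
    m <- lapply(w, function(p) p * 0)
    v <- lapply(w, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    t_step <- 0L
    best <- list(loss = Inf, w = w, epoch = 0L)
    wait <- 0L
    history <- vector("list", spec$max_epochs)
    n_tr <- nrow(x_tr)

    for (epoch in seq_len(spec$max_epochs)) {
      perm <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = spec$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + spec$batch_size - 1L, n_tr)]
        xb <- x_tr[idx, , drop = FALSE]; yb <- y_tr[idx]
        mb <- length(idx)
        z1 <- sweep(xb %*% w$W1, 2, w$b1, `+`); a1 <- .relu(z1)
        z2 <- sweep(a1 %*% w$W2, 2, w$b2, `+`); a2 <- .relu(z2)
        yhat <- drop(a2 %*% w$W3) + w$b3
        d3 <- matrix(2 * (yhat - yb) / mb, ncol = 1)
        g <- list(
          W3 = crossprod(a2, d3) + 2 * spec$l2 * w$W3,
          b3 = sum(d3)
        )
        d2 <- (d3 %*% t(w$W3)) * (z2 > 0)
        g$W2 <- crossprod(a1, d2) + 2 * spec$l2 * w$W2
        g$b2 <- colSums(d2)
        d1 <- (d2 %*% t(w$W2)) * (z1 > 0)
        g$W1 <- crossprod(xb, d1) + 2 * spec$l2 * w$W1
        g$b1 <- colSums(d1)
        t_step <- t_step + 1L
        for (nm in names(w)) {
          m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g[[nm]]
          v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g[[nm]]^2
          mhat <- m[[nm]] / (1 - b1a^t_step)
          vhat <- v[[nm]] / (1 - b2a^t_step)
          w[[nm]] <- w[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      train_loss <- mean((.nn_forward(w, x_tr) - y_tr)^2)
      val_loss <- mean((.nn_forward(w, x_va) - y_va)^2)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop(sprintf(
          "training failure: non-finite loss at epoch %d (train %g, val %g); try a smaller learning rate",
          epoch, train_loss, val_loss), call. = FALSE)
      }
      history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, w = w, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })

  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, TRUE)]))
  structure(list(
    weights = best$w, centers = centers, scales = scales,
    features = colnames(feats), spec = spec, history = history,
    best_epoch = best$epoch, val_loss = best$loss, n = n
  ), class = "diameter_nn")
}

#' @export
print.diameter_nn <- function(x, ...) {
  cat("Neural-network diameter model: ", length(x$features), " features -> ",
      paste(x$spec$hidden, collapse = "/"), " ReLU units -> 1\n", sep = "")
  cat("trained on", x$n, "records; best epoch", x$best_epoch,
      sprintf("(validation MSE %.3g)", x$val_loss), "\n")
  invisible(x)
}
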