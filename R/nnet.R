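# SELU constants (self-normalizing networks)
.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

selu <- function(x) {
  .selu_lambda * ifelse(x > 0, x, .selu_alpha * (exp(x) - 1))
}

selu_grad <- function(x) {
  .selu_lambda * ifelse(x > 0, 1, .selu_alpha * exp(x))
}

#' Specify a feed-forward regression network
#'
#' One or more fully connected hidden layers with SELU activation and a
#' single linear output unit. Hidden sizes are expressed as fractions of the
#' input dimension (each typically in \[0.2, 0.6\]); sizes that round below
#' one are clamped to one with a warning. Optional alpha dropout (the
#' self-normalizing dropout variant matched to SELU) between hidden layers.
#'
#' @param n_inputs Number of input descriptors.
#' @param hidden_ratios Numeric vector of hidden-layer sizes relative to
#'   `n_inputs` (length = number of hidden layers).
#' @param dropout_p Dropout probability in \[0, 0.5\].
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_inputs, hidden_ratios = 0.3, dropout_p = 0) {
  stopifnot(n_inputs >= 1, length(hidden_ratios) >= 1,
            dropout_p >= 0, dropout_p <= 0.5)
  sizes <- round(hidden_ratios * n_inputs)
  if (any(sizes < 1)) {
    warning("hidden layer size(s) below 1 clamped to 1", call. = FALSE)
    sizes <- pmax(sizes, 1)
  }
  structure(
    list(n_inputs = as.integer(n_inputs), hidden_sizes = as.integer(sizes),
         hidden_ratios = hidden_ratios, dropout_p = dropout_p,
         activation = "selu"),
    class = "network_spec"
  )
}

#' Initialize network weights
#'
#' Weights are drawn from the normal distribution with variance `1/fan_in`
#' (the self-normalizing initialization appropriate for SELU); biases start
#' at zero. Deterministic given `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return An object of class `bbb_network` (untrained).
#' @export
init_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  dims <- c(spec$n_inputs, spec$hidden_sizes, 1L)
  withr::with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1)) {
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(1 / dims[l])),
                       nrow = dims[l], ncol = dims[l + 1])
      b[[l]] <- rep(0, dims[l + 1])
    }
  })
  structure(
    list(spec = spec, W = W, b = b, training_log = NULL, stopped_epoch = NA),
    class = "bbb_network"
  )
}

#' @export
print.bbb_network <- function(x, ...) {
  cat("<bbb_network> ", x$spec$n_inputs, " inputs -> ",
      paste(x$spec$hidden_sizes, collapse = " -> "), " -> 1",
      if (!is.na(x$stopped_epoch)) paste0(" (best epoch ", x$stopped_epoch, ")"),
      "\n", sep = "")
  invisible(x)
}

# forward pass keeping intermediates for backprop; optional alpha dropout
# masks applied to hidden activations during training
net_forward_full <- function(net, X, dropout_masks = NULL) {
  L <- length(net$W)
  A <- list(X)  # A[[l]]: input to layer l
  Z <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      H <- selu(Z[[l]])
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
        m <- dropout_masks[[l]]
        H <- m$a * (H * m$keep + m$alpha_prime * (1 - m$keep)) + m$b
      }
      A[[l + 1]] <- H
    }
  }
  list(A = A, Z = Z, yhat = drop(Z[[L]]))
}

# alpha-dropout mask for one layer: dropped units are set to the SELU
# saturation value, then an affine correction restores mean and variance
make_alpha_dropout_masks <- function(net, n_rows, p) {
  if (p <= 0) return(NULL)
  alpha_prime <- -.selu_lambda * .selu_alpha
  q <- 1 - p
  a <- (q + alpha_prime^2 * q * p)^(-1 / 2)
  b <- -a * p * alpha_prime
  lapply(seq_len(length(net$W) - 1), function(l) {
    keep <- matrix(as.numeric(runif(n_rows * ncol(net$W[[l]])) < q),
                   nrow = n_rows)
    list(keep = keep, alpha_prime = alpha_prime, a = a, b = b)
  })
}

#' Forward pass of a network
#'
#' Deterministic inference (dropout disabled).
#'
#' @param net A `bbb_network`.
#' @param x Numeric matrix (rows = samples) or vector of length `n_inputs`,
#'   on the scaled input scale.
#' @return Numeric vector of scaled outputs.
#' @export
net_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == net$spec$n_inputs)
  net_forward_full(net, x)$yhat
}

#' Analytic gradient of the network output with respect to its inputs
#'
#' Exact partial derivatives of the scaled output with respect to the scaled
#' inputs at each row of `x` (local linear sensitivity of the model).
#'
#' @inheritParams net_forward
#' @return Matrix `nrow(x)` x `n_inputs` of gradients.
#' @export
net_input_gradient <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == net$spec$n_inputs)
  fw <- net_forward_full(net, x)
  L <- length(net$W)
  # backprop d yhat / d a_l
  G <- matrix(1, nrow = nrow(x), ncol = 1)
  for (l in rev(seq_len(L))) {
    G <- G %*% t(net$W[[l]])
    if (l > 1) G <- G * selu_grad(fw$Z[[l - 1]])
  }
  G
}

#' Train a network with early termination
#'
#' Minimizes mean squared error on the training rows with the Adam optimizer
#' and mini-batches, monitoring the loss on a disjoint stop set each epoch.
#' Training halts when the stop-set loss has not improved for `patience`
#' epochs (or at `max_epochs`), and the weights from the best stop-set epoch
#' are restored.
#'
#' @param net An initialized `bbb_network`.
#' @param x,y Training inputs/outputs (scaled).
#' @param stop_x,stop_y Stop-set inputs/outputs (scaled), disjoint from the
#'   training rows.
#' @param max_epochs,patience Early-termination controls.
#' @param learn_rate,batch_size Adam step size and mini-batch size.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return The trained `bbb_network` with `training_log` (tibble of per-epoch
#'   train and stop losses) and `stopped_epoch` (best epoch) filled in.
#' @export
train_network <- function(net, x, y, stop_x, stop_y,
                          max_epochs = 1000, patience = 20,
                          learn_rate = 1e-3, batch_size = 32, seed = 1) {
  stopifnot(inherits(net, "bbb_network"))
  x <- as.matrix(x); stop_x <- as.matrix(stop_x)
  if (max_epochs == 0) return(net)
  L <- length(net$W)
  p_drop <- net$spec$dropout_p

  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0

  best <- list(W = net$W, b = net$b,
               loss = mean((net_forward(net, stop_x) - stop_y)^2),
               epoch = 0L)
  log_epoch <- integer(0); log_train <- numeric(0); log_stop <- numeric(0)
  wait <- 0

  withr::with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(nrow(x))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (idx in batches) {
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        masks <- make_alpha_dropout_masks(net, nrow(xb), p_drop)
        fw <- net_forward_full(net, xb, dropout_masks = masks)
        err <- fw$yhat - yb
        delta <- matrix(2 * err / length(err), ncol = 1)
        for (l in rev(seq_len(L))) {
          gW <- t(fw$A[[l]]) %*% delta
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(net$W[[l]])
            if (!is.null(masks) && !is.null(masks[[l - 1]])) {
              m <- masks[[l - 1]]
              delta <- delta * (m$a * m$keep)
            }
            delta <- delta * selu_grad(fw$Z[[l - 1]])
          }
          t_adam <- t_step + 1
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^t_adam)
          vhW <- vW[[l]] / (1 - beta2^t_adam)
          mhb <- mb[[l]] / (1 - beta1^t_adam)
          vhb <- vb[[l]] / (1 - beta2^t_adam)
          net$W[[l]] <- net$W[[l]] - learn_rate * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - learn_rate * mhb / (sqrt(vhb) + eps)
        }
        t_step <- t_step + 1
      }
      train_loss <- mean((net_forward(net, x) - y)^2)
      stop_loss <- mean((net_forward(net, stop_x) - stop_y)^2)
      if (!is.finite(train_loss) || !is.finite(stop_loss)) {
        stop(sprintf("non-finite loss at epoch %d (train %g, stop %g)",
                     epoch, train_loss, stop_loss), call. = FALSE)
      }
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, train_loss)
      log_stop <- c(log_stop, stop_loss)
      if (stop_loss < best$loss - 1e-12) {
        best <- list(W = net$W, b = net$b, loss = stop_loss, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  })

  net$W <- best$W
  net$b <- best$b
  net$stopped_epoch <- best$epoch
  net$training_log <- tibble::tibble(epoch = log_epoch,
                                     train_loss = log_train,
                                     stop_loss = log_stop)
  net
}

#' @export
tidy.bbb_network <- function(x, ...) {
  x$training_log %||% tibble::tibble(epoch = integer(0),
                                     train_loss = numeric(0),
                                     stop_loss = numeric(0))
}

#' @export
glance.bbb_network <- function(x, ...) {
  tibble::tibble(
    n_inputs = x$spec$n_inputs,
    hidden = paste(x$spec$hidden_sizes, collapse = "/"),
    dropout_p = x$spec$dropout_p,
    stopped_epoch = x$stopped_epoch,
    best_stop_loss = if (is.null(x$training_log)) NA_real_ else
      min(x$training_log$stop_loss)
  )
}

#' @export
autoplot.bbb_network <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "stop_loss"),
                        names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean squared error (scaled units)",
                  colour = NULL)
}
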