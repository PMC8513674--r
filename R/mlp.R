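#' Dense feed-forward binary classifier (two ReLU hidden layers)
#'
#' A compact multilayer perceptron used as the cross-algorithm validator:
#' two rectified-linear hidden layers, a sigmoid output unit, binary
#' cross-entropy loss, Adam optimization on mini-batches, Glorot-uniform
#' weight initialization and early stopping on validation loss. No
#' regularization.
#'
#' @param x numeric matrix (z-scored features).
#' @param y 0/1 vector (1 = class `present`).
#' @param hidden hidden layer sizes, default `c(50, 40)`.
#' @param batch_size mini-batch size, default 4.
#' @param epochs maximum training epochs, default 100.
#' @param patience early-stopping patience on validation loss, default 2.
#' @param learning_rate Adam step size, default 1e-3.
#' @param x_val,y_val validation data for early stopping (required when
#'   `patience` is finite).
#' @param seed integer seed for initialization and batch shuffling.
#' @return object of class `mlp_model` (weight list + metadata).
#' @export
mlp_fit <- function(x, y, hidden = c(50, 40), batch_size = 4, epochs = 100,
                    patience = 2, learning_rate = 1e-3,
                    x_val = NULL, y_val = NULL, seed = 1) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(hidden) == 2)
  use_val <- !is.null(x_val)
  if (!use_val) patience <- Inf
  rng <- local_rng(seed)

  sizes <- c(ncol(x), hidden, 1L)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(rng$runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  W <- lapply(1:3, function(l) glorot(sizes[l], sizes[l + 1]))
  b <- lapply(1:3, function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  forward <- function(X) {
    z1 <- sweep(X %*% W[[1]], 2, b[[1]], "+"); a1 <- pmax(z1, 0)
    z2 <- sweep(a1 %*% W[[2]], 2, b[[2]], "+"); a2 <- pmax(z2, 0)
    z3 <- sweep(a2 %*% W[[3]], 2, b[[3]], "+")
    p <- 1 / (1 + exp(-z3))
    list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, p = p)
  }
  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  adam_update <- function(l, dW, db) {
    mW[[l]] <<- beta1 * mW[[l]] + (1 - beta1) * dW
    vW[[l]] <<- beta2 * vW[[l]] + (1 - beta2) * dW^2
    mb[[l]] <<- beta1 * mb[[l]] + (1 - beta1) * db
    vb[[l]] <<- beta2 * vb[[l]] + (1 - beta2) * db^2
    mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
    mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
    W[[l]] <<- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
    b[[l]] <<- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
  }

  best <- list(loss = Inf, W = W, b = b)
  bad_epochs <- 0L
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    idx <- rng$sample(n)
    for (start in seq(1, n, by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1, n)]
      X <- x[take, , drop = FALSE]; yy <- y[take]
      f <- forward(X)
      m <- length(take)
      dz3 <- (f$p - yy) / m                       # d(BCE)/dz3
      dW3 <- crossprod(f$a2, dz3); db3 <- colSums(dz3)
      da2 <- dz3 %*% t(W[[3]])
      dz2 <- da2 * (f$z2 > 0)
      dW2 <- crossprod(f$a1, dz2); db2 <- colSums(dz2)
      da1 <- dz2 %*% t(W[[2]])
      dz1 <- da1 * (f$z1 > 0)
      dW1 <- crossprod(X, dz1); db1 <- colSums(dz1)
      step <- step + 1L
      adam_update(3, dW3, db3)
      adam_update(2, dW2, db2)
      adam_update(1, dW1, db1)
    }
    if (use_val) {
      vloss <- bce(forward(as.matrix(x_val))$p, as.numeric(y_val))
      if (vloss < best$loss - 1e-8) {
        best <- list(loss = vloss, W = W, b = b)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= patience) break
      }
    }
  }
  if (use_val) { W <- best$W; b <- best$b }
  structure(list(W = W, b = b, sizes = sizes,
                 val_loss = if (use_val) best$loss else NA_real_,
                 epochs_run = ep),
            class = "mlp_model")
}

#' Predict class-1 probabilities from a fitted MLP
#'
#' @param object an [mlp_fit()] model.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of sigmoid outputs in (0, 1).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  a1 <- pmax(sweep(X %*% object$W[[1]], 2, object$b[[1]], "+"), 0)
  a2 <- pmax(sweep(a1 %*% object$W[[2]], 2, object$b[[2]], "+"), 0)
  z3 <- sweep(a2 %*% object$W[[3]], 2, object$b[[3]], "+")
  as.vector(1 / (1 + exp(-z3)))
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> layers %s, %d epoch(s)%s\n",
              paste(x$sizes, collapse = "-"), x$epochs_run,
              if (!is.na(x$val_loss))
                sprintf(", best val loss %.4f", x$val_loss) else ""))
  invisible(x)
}
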