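# Three-layer feedforward network (2 inputs -> H hidden -> 3 outputs, sigmoid
# activations throughout) with min-max normalization and Levenberg-Marquardt
# backpropagation training.  This is the prediction core of the package and
# is implemented from scratch: the residual Jacobian is assembled by
# backpropagation over the full batch and each step solves
# (J'J + mu I) delta = -J'r with the usual multiplicative damping schedule.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a per-dimension min-max normalizer
#'
#' Affine map sending each dimension's observed `[min, max]` onto
#' `[lo, hi]`.  The default target `(0.05, 0.95)` keeps targets strictly
#' inside the sigmoid's open range so they remain attainable.  A constant
#' dimension maps to the midpoint `(lo + hi) / 2` and its inverse is pinned
#' to the constant.
#'
#' @param data numeric matrix, samples in rows.
#' @param lo,hi target interval endpoints.
#' @return An object of class `minmax_norm` with `$apply` / `$invert`
#'   closures and the stored `(min, max, lo, hi)` per dimension.
#' @export
fit_normalizer <- function(data, lo = 0.05, hi = 0.95) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("need at least one sample", call. = FALSE)
  mn <- apply(data, 2, min)
  mx <- apply(data, 2, max)
  span <- mx - mn
  constant <- span <= 0
  scale <- ifelse(constant, 0, (hi - lo) / ifelse(constant, 1, span))
  offset <- ifelse(constant, (lo + hi) / 2, lo - mn * scale)
  nm <- structure(list(min = mn, max = mx, lo = lo, hi = hi,
                       scale = scale, offset = offset, constant = constant),
                  class = "minmax_norm")
  nm
}

#' Apply or invert a min-max normalizer
#' @param norm a `minmax_norm`.
#' @param x numeric matrix (samples in rows) or vector of one sample.
#' @return matrix/vector on the normalized scale (`normalize`) or the
#'   original scale (`denormalize`).
#' @export
normalize <- function(norm, x) {
  vec <- !is.matrix(x)
  x <- if (vec) matrix(x, nrow = 1) else x
  out <- sweep(sweep(x, 2, norm$scale, `*`), 2, norm$offset, `+`)
  if (vec) as.numeric(out) else out
}

#' @rdname normalize
#' @export
denormalize <- function(norm, x) {
  vec <- !is.matrix(x)
  x <- if (vec) matrix(x, nrow = 1) else x
  out <- x
  for (j in seq_len(ncol(x))) {
    if (norm$constant[j]) {
      out[, j] <- norm$min[j]
    } else {
      out[, j] <- (x[, j] - norm$offset[j]) / norm$scale[j]
    }
  }
  if (vec) as.numeric(out) else out
}

#' Initialize a 2-H-3 sigmoid network
#'
#' Seeded Nguyen-Widrow-style initialization: hidden rows are drawn
#' uniformly, rescaled to magnitude `0.7 * H^(1/2)` (two inputs), with
#' biases spread uniformly over the same magnitude; output weights are small
#' uniform.  The same seed always yields the same weights.
#'
#' @param n_hidden number of hidden units H, in `[1, 100]`.
#' @param seed integer RNG seed.
#' @return An object of class `mlp_model` (untrained: normalizers unset).
#' @export
init_mlp <- function(n_hidden, seed = 1L) {
  if (!is.numeric(n_hidden) || length(n_hidden) != 1L || n_hidden < 1 ||
      n_hidden > 100 || n_hidden != round(n_hidden)) {
    stop("n_hidden must be an integer in [1, 100]", call. = FALSE)
  }
  h <- as.integer(n_hidden)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  beta <- 0.7 * h^(1 / 2)  # Nguyen-Widrow magnitude for 2 inputs
  w1 <- matrix(stats::runif(h * 2, -1, 1), h, 2)
  w1 <- beta * w1 / sqrt(rowSums(w1^2))
  b1 <- stats::runif(h, -beta, beta)
  w2 <- matrix(stats::runif(3 * h, -0.5, 0.5), 3, h)
  b2 <- stats::runif(3, -0.5, 0.5)
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 n_hidden = h, activation = "sigmoid",
                 input_norm = NULL, output_norm = NULL, seed = seed),
            class = "mlp_model")
}

#' Number of trainable parameters of an `mlp_model`
#' @param model an `mlp_model`.
#' @return integer: `(2 + 1) * H + (H + 1) * 3`.
#' @export
n_params <- function(model) {
  h <- model$n_hidden
  as.integer(3 * h + (h + 1) * 3)
}

# Pack / unpack parameters into a flat vector (order: w1, b1, w2, b2).
pack_params <- function(model) {
  c(as.numeric(model$w1), model$b1, as.numeric(model$w2), model$b2)
}

unpack_params <- function(model, theta) {
  h <- model$n_hidden
  i <- 0L
  model$w1 <- matrix(theta[i + seq_len(2 * h)], h, 2); i <- i + 2L * h
  model$b1 <- theta[i + seq_len(h)]; i <- i + h
  model$w2 <- matrix(theta[i + seq_len(3 * h)], 3, h); i <- i + 3L * h
  model$b2 <- theta[i + seq_len(3)]
  model
}

# Forward pass on the normalized scale.  x: n x 2.  Returns list(yhat, a1)
# with yhat n x 3, a1 n x H.
mlp_forward <- function(model, x) {
  a1 <- sigmoid(x %*% t(model$w1) + matrix(model$b1, nrow(x), model$n_hidden,
                                           byrow = TRUE))
  yhat <- sigmoid(a1 %*% t(model$w2) + matrix(model$b2, nrow(x), 3,
                                              byrow = TRUE))
  list(yhat = yhat, a1 = a1)
}

# Residuals r = vec(yhat - y) (stacked by output component: n rows of output
# 1, then output 2, then 3) and their Jacobian wrt the packed parameters,
# assembled by backpropagation over the whole batch.
mlp_residual_jacobian <- function(model, x, y) {
  n <- nrow(x); h <- model$n_hidden
  fw <- mlp_forward(model, x)
  r <- as.numeric(fw$yhat - y)           # length 3n, component-major
  s2 <- fw$yhat * (1 - fw$yhat)          # n x 3   sigma'(z2)
  s1 <- fw$a1 * (1 - fw$a1)              # n x H   sigma'(z1)
  p <- 3L * h + (h + 1L) * 3L
  jac <- matrix(0, 3L * n, p)
  for (k in 1:3) {
    rows <- (k - 1L) * n + seq_len(n)
    # d r_k / d z2_k = s2[, k]; other outputs do not depend on z2_k
    g2 <- s2[, k]                                  # n
    # hidden-layer sensitivities: d z2_k / d a1_j = w2[k, j]
    gh <- g2 * matrix(model$w2[k, ], n, h, byrow = TRUE) * s1   # n x H
    # w1 (H x 2), column-major in theta: (j, i) at (i - 1) * h + j
    jac[rows, seq_len(h)]       <- gh * x[, 1]     # d/d w1[, 1]
    jac[rows, h + seq_len(h)]   <- gh * x[, 2]     # d/d w1[, 2]
    jac[rows, 2L * h + seq_len(h)] <- gh           # d/d b1
    # w2 (3 x h) column-major: (k, j) at 3h + (j - 1) * 3 + k
    w2cols <- 3L * h + (seq_len(h) - 1L) * 3L + k
    jac[rows, w2cols] <- g2 * fw$a1
    jac[rows, 3L * h + 3L * h + k] <- g2           # d/d b2[k]
  }
  list(r = r, jac = jac)
}

#' Levenberg-Marquardt training configuration
#'
#' @param max_epochs maximum accepted LM steps; default 1000.
#' @param goal normalized-MSE performance goal; default 0.001.
#' @param learning_rate recorded for fidelity with the usual toolbox
#'   configuration but inert: LM has no learning-rate parameter.
#' @param mu0 initial damping; `mu_inc`/`mu_dec` multiplicative schedule on
#'   rejection/acceptance; `mu_max` divergence cap.
#' @param seed integer seed (recorded; initialization uses the model's own
#'   seed).
#' @return list of class `training_config`.
#' @export
training_config <- function(max_epochs = 1000L, goal = 1e-3,
                            learning_rate = 0.01, mu0 = 1e-3, mu_inc = 10,
                            mu_dec = 0.1, mu_max = 1e10, seed = 1L) {
  stopifnot(goal > 0, max_epochs >= 1, mu0 > 0, mu_inc > 1, mu_dec < 1)
  structure(list(max_epochs = as.integer(max_epochs), goal = goal,
                 learning_rate = learning_rate, mu0 = mu0, mu_inc = mu_inc,
                 mu_dec = mu_dec, mu_max = mu_max, seed = as.integer(seed)),
            class = "training_config")
}

#' Train the network by Levenberg-Marquardt backpropagation
#'
#' Full-batch LM on the normalized scale: normalizers are fitted to the
#' training data (inputs and outputs independently), then each epoch solves
#' `(J'J + mu I) delta = -J'r` with `J` the backpropagated residual
#' Jacobian.  A step is accepted if it lowers the MSE (`mu` is then
#' decreased) and rejected otherwise (`mu` increased and the step re-solved).
#' Training stops when the MSE reaches `goal`, after `max_epochs` accepted
#' steps, or when `mu` exceeds `mu_max`.  Performance is the mean squared
#' error of the network output over all samples and output components, on
#' the normalized scale.
#'
#' @param model an `mlp_model` from [init_mlp()].
#' @param x numeric matrix n x 2 of postures (rad): plane of elevation,
#'   elevation.
#' @param y numeric matrix n x 3 of passive torques (N m, world axes).
#' @param cfg a `training_config`.
#' @return list `model` (trained `mlp_model` with normalizers attached) and
#'   `history` (class `training_history`: per-epoch MSE, `epochs_run`,
#'   `goal_met`).
#' @export
train_lm <- function(model, x, y, cfg = training_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 1L || nrow(x) != nrow(y)) {
    stop("x and y must be nonempty with equal row counts", call. = FALSE)
  }
  if (ncol(x) != 2L || ncol(y) != 3L) {
    stop("expected 2 input and 3 output dimensions", call. = FALSE)
  }
  model$input_norm <- fit_normalizer(x)
  model$output_norm <- fit_normalizer(y)
  xn <- normalize(model$input_norm, x)
  yn <- normalize(model$output_norm, y)

  theta <- pack_params(model)
  p <- length(theta)
  mu <- cfg$mu0
  rj <- mlp_residual_jacobian(model, xn, yn)
  mse <- mean(rj$r^2)
  history <- mse
  epochs <- 0L
  while (mse > cfg$goal && epochs < cfg$max_epochs && mu <= cfg$mu_max) {
    jtj <- crossprod(rj$jac)
    jtr <- crossprod(rj$jac, rj$r)
    accepted <- FALSE
    while (!accepted && mu <= cfg$mu_max) {
      delta <- tryCatch(
        solve(jtj + mu * diag(p), -jtr),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- unpack_params(model, theta + as.numeric(delta))
        r_new <- as.numeric(mlp_forward(cand, xn)$yhat - yn)
        mse_new <- mean(r_new^2)
        if (is.finite(mse_new) && mse_new < mse) {
          theta <- theta + as.numeric(delta)
          model <- cand
          mse <- mse_new
          mu <- mu * cfg$mu_dec
          accepted <- TRUE
        } else {
          mu <- mu * cfg$mu_inc
        }
      } else {
        mu <- mu * cfg$mu_inc
      }
    }
    if (!accepted) break
    epochs <- epochs + 1L
    history <- c(history, mse)
    if (!is.finite(mse)) {
      stop("training diverged: non-finite loss", call. = FALSE)
    }
    rj <- mlp_residual_jacobian(model, xn, yn)
  }
  hist <- structure(list(mse = history, epochs_run = epochs,
                         goal_met = mse <= cfg$goal, final_mse = mse),
                    class = "training_history")
  list(model = model, history = hist)
}

#' Predict passive torque for a posture
#'
#' Normalize, forward pass, denormalize.  Raw network outputs lie strictly
#' in (0, 1); predictions are therefore bounded by the output normalizer's
#' inverse image of that interval.
#'
#' @param object a trained `mlp_model`.
#' @param x numeric 2-vector (plane of elevation, elevation; rad) or an
#'   n x 2 matrix of postures.
#' @param ... unused.
#' @return numeric 3-vector or n x 3 matrix of torques (N m, world axes).
#' @export
predict.mlp_model <- function(object, x, ...) {
  if (is.null(object$input_norm)) {
    stop("model has not been trained (no normalizers attached)",
         call. = FALSE)
  }
  vec <- !is.matrix(x)
  xm <- if (vec) matrix(x, nrow = 1) else x
  yn <- mlp_forward(object, normalize(object$input_norm, xm))$yhat
  out <- denormalize(object$output_norm, yn)
  if (vec) as.numeric(out) else out
}

#' Sweep the number of hidden units
#'
#' Trains one seeded network per requested hidden-layer size on the same
#' data and configuration, and tabulates how fast each reaches the goal.
#'
#' @param x,y training data as in [train_lm()].
#' @param h_values integer vector of hidden-unit counts (e.g. `5:20`).
#' @param cfg a `training_config`; its `seed` seeds each initialization.
#' @return `data.frame` sorted by `h`: `h`, `epochs_run`, `goal_met`,
#'   `final_mse`.
#' @export
hidden_unit_sweep <- function(x, y, h_values = 5:20, cfg = training_config()) {
  h_values <- sort(unique(as.integer(h_values)))
  rows <- lapply(h_values, function(h) {
    fit <- train_lm(init_mlp(h, seed = cfg$seed), x, y, cfg)
    data.frame(h = h, epochs_run = fit$history$epochs_run,
               goal_met = fit$history$goal_met,
               final_mse = fit$history$final_mse)
  })
  do.call(rbind, rows)
}

#' Serialize a trained model to JSON / read it back
#'
#' Weights are stored row-major with the normalizer parameters, seed and
#' layer size, so a model round-trips exactly.
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @export
write_mlp_json <- function(model, path) {
  norm_fields <- function(nm) if (is.null(nm)) NULL else
    list(min = nm$min, max = nm$max, lo = nm$lo, hi = nm$hi)
  obj <- list(n_hidden = model$n_hidden, activation = model$activation,
              seed = model$seed,
              w1 = as.numeric(t(model$w1)), b1 = model$b1,
              w2 = as.numeric(t(model$w2)), b2 = model$b2,
              input_norm = norm_fields(model$input_norm),
              output_norm = norm_fields(model$output_norm))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @return `read_mlp_json`: the deserialized `mlp_model`.
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- as.integer(obj$n_hidden)
  rebuild_norm <- function(nf) {
    if (is.null(nf)) return(NULL)
    span <- nf$max - nf$min
    constant <- span <= 0
    scale <- ifelse(constant, 0, (nf$hi - nf$lo) / ifelse(constant, 1, span))
    offset <- ifelse(constant, (nf$lo + nf$hi) / 2, nf$lo - nf$min * scale)
    structure(list(min = nf$min, max = nf$max, lo = nf$lo, hi = nf$hi,
                   scale = scale, offset = offset, constant = constant),
              class = "minmax_norm")
  }
  structure(list(w1 = matrix(obj$w1, h, 2, byrow = TRUE), b1 = obj$b1,
                 w2 = matrix(obj$w2, 3, h, byrow = TRUE), b2 = obj$b2,
                 n_hidden = h, activation = obj$activation,
                 input_norm = rebuild_norm(obj$input_norm),
                 output_norm = rebuild_norm(obj$output_norm),
                 seed = obj$seed),
            class = "mlp_model")
}
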