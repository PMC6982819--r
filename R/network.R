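#' Network architecture specification
#'
#' The predictor is a fully connected feed-forward network with one hidden
#' layer: seven inputs (stance phase fraction and the six CoM kinematic
#' channels), twenty sigmoid hidden units, and eleven linear outputs (two
#' GRFs, three stance-leg joint torques, six segment angles).  The
#' architecture mirrors the affine CoM-to-outputs approximation: a weighted
#' sum of the CoM kinematics, passed through one mild nonlinearity.
#'
#' @param input_dim,hidden_dim,output_dim layer sizes.
#' @return A `network_spec` list.
#' @export
network_spec <- function(input_dim = 7L, hidden_dim = 20L, output_dim = 11L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, output_dim >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = as.integer(output_dim),
                 hidden_activation = "sigmoid", output_activation = "linear"),
            class = "network_spec")
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch mini-batch size (columns, i.e. phase samples).
#' @param seed seed fixing initialization and shuffling.
#' @param val_frac fraction of training columns held out for early stopping
#'   (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 3e-3, epochs = 300L, batch = 1024L, seed = 1L,
                         val_frac = 0.1, patience = 50L) {
  structure(list(lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
                 seed = as.integer(seed), val_frac = val_frac,
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Build a feed-forward network with seeded Glorot initialization
#'
#' @param spec a [network_spec()].
#' @param seed integer seed; the same seed reproduces the same weights.
#' @return An `ffnn` model: list of weight matrices `W1` (hidden x in), `b1`,
#'   `W2` (out x hidden), `b2`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(as.integer(seed))
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  structure(list(W1 = glorot(spec$hidden_dim, spec$input_dim),
                 b1 = numeric(spec$hidden_dim),
                 W2 = glorot(spec$output_dim, spec$hidden_dim),
                 b2 = numeric(spec$output_dim),
                 spec = spec),
            class = "ffnn")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass
#'
#' @param model an `ffnn`.
#' @param X input matrix (input_dim x N).
#' @return Output matrix (output_dim x N).
#' @export
forward_pass <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != model$spec$input_dim)
    stop(sprintf("forward_pass: expected %d input rows, got %d",
                 model$spec$input_dim, nrow(X)), call. = FALSE)
  H <- sigmoid(model$W1 %*% X + model$b1)
  model$W2 %*% H + model$b2
}

#' Train the network by mini-batch Adam on mean squared error
#'
#' Inputs and labels are column-aligned: every resampled phase point of every
#' stance is one (input, output) training pair.  The loss is the MSE over all
#' output channels (train on normalized labels so the channels weigh
#' comparably).  Training is reproducible: the seed fixes the validation
#' split, shuffling and (through [build_network()]) the initial weights.
#'
#' @param model an `ffnn` from [build_network()].
#' @param X input matrix (input_dim x N).
#' @param Y label matrix (output_dim x N).
#' @param cfg a [train_config()].
#' @return The trained model, with attribute `loss_curve` (data frame of
#'   epoch, training loss, validation loss).
#' @export
train_network <- function(model, X, Y, cfg = train_config()) {
  stopifnot(inherits(model, "ffnn"), inherits(cfg, "train_config"))
  if (!is.matrix(X) || !is.matrix(Y) || ncol(X) != ncol(Y))
    stop("train_network: X and Y must be column-aligned matrices", call. = FALSE)
  N <- ncol(X)
  set.seed(cfg$seed)
  idx <- sample.int(N)
  nval <- floor(cfg$val_frac * N)
  vi <- idx[seq_len(nval)]
  ti <- idx[setdiff(seq_len(N), seq_len(nval))]
  Xt <- X[, ti, drop = FALSE]; Yt <- Y[, ti, drop = FALSE]
  Xv <- X[, vi, drop = FALSE]; Yv <- Y[, vi, drop = FALSE]
  Nt <- ncol(Xt)

  pars <- c("W1", "b1", "W2", "b2")
  mom <- setNames(lapply(pars, function(p) model[[p]] * 0), pars)
  vel <- mom
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, model = model, epoch = 0L)
  curve <- matrix(NA_real_, cfg$epochs, 3)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(Nt)
    bl <- 0; nb <- 0
    for (s0 in seq(1, Nt, by = cfg$batch)) {
      jb <- ord[s0:min(s0 + cfg$batch - 1, Nt)]
      Xb <- Xt[, jb, drop = FALSE]; Yb <- Yt[, jb, drop = FALSE]
      nB <- ncol(Xb)
      A1 <- model$W1 %*% Xb + model$b1
      H <- sigmoid(A1)
      P <- model$W2 %*% H + model$b2
      E <- P - Yb
      bl <- bl + mean(E^2); nb <- nb + 1
      dP <- 2 * E / (nB * nrow(Yb))
      g <- list(W2 = dP %*% t(H), b2 = rowSums(dP))
      dH <- crossprod(model$W2, dP) * H * (1 - H)
      g$W1 <- dH %*% t(Xb)
      g$b1 <- rowSums(dH)
      step <- step + 1L
      for (p in pars) {
        mom[[p]] <- b1a * mom[[p]] + (1 - b1a) * g[[p]]
        vel[[p]] <- b2a * vel[[p]] + (1 - b2a) * g[[p]]^2
        mhat <- mom[[p]] / (1 - b1a^step)
        vhat <- vel[[p]] / (1 - b2a^step)
        model[[p]] <- model[[p]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tl <- bl / nb
    vl <- if (nval > 0) mean((forward_pass(model, Xv) - Yv)^2) else tl
    curve[ep, ] <- c(ep, tl, vl)
    if (!is.finite(tl))
      stop("train_network: loss diverged (NaN); lower the learning rate", call. = FALSE)
    if (vl < best$loss - 1e-12) best <- list(loss = vl, model = model, epoch = ep)
    if (nval > 0 && ep - best$epoch >= cfg$patience) break
  }
  out <- if (nval > 0) best$model else model
  out$spec <- model$spec
  attr(out, "loss_curve") <- data.frame(epoch = curve[, 1], train = curve[, 2],
                                        val = curve[, 3])[!is.na(curve[, 1]), ]
  out
}

#' Predict the 11-channel output block for a feature block
#'
#' Applies the stored feature normalization (if attached to the model),
#' runs the forward pass column by column, and de-normalizes the outputs
#' back to physical units with the stored training extrema.
#'
#' @param model a trained `ffnn`, optionally carrying `x_stats` / `y_stats`
#'   ([compute_norm_stats()] objects frozen on the training fold).
#' @param features matrix with `input_dim` rows (e.g. a 7 x 200
#'   `feature_block`).
#' @return Matrix of predictions (output_dim x ncol(features)), in physical
#'   units when `y_stats` is present.
#' @export
predict_outputs <- function(model, features) {
  X <- unclass(features)
  if (!is.null(model$x_stats)) X <- apply_norm(X, model$x_stats)
  P <- forward_pass(model, X)
  if (!is.null(model$y_stats)) P <- invert_norm(P, model$y_stats)
  P
}

#' Normalized root-mean-square error (percent)
#'
#' `100 * RMSE(pred, obs) / normalizer`, with the normalizer defaulting to
#' the observed range `max(obs) - min(obs)`.
#'
#' @param pred,obs equal-length numeric vectors.
#' @param normalizer positive scale; the observed range by default.
#' @return NRMSE in percent.
#' @export
compute_nrmse <- function(pred, obs, normalizer = diff(range(obs))) {
  if (length(pred) != length(obs))
    stop("compute_nrmse: pred and obs must have equal length", call. = FALSE)
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("compute_nrmse: undefined metric (normalizer must be positive)", call. = FALSE)
  100 * sqrt(mean((pred - obs)^2)) / normalizer
}

#' Serialize / restore a trained model as plain JSON
#'
#' Stores layer shapes and flat weight arrays (plus any attached
#' normalization statistics), loadable without any learning framework.
#'
#' @param model an `ffnn`.
#' @param path JSON file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `ffnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ffnn"))
  obj <- list(spec = unclass(model$spec),
              W1 = as.numeric(model$W1), b1 = model$b1,
              W2 = as.numeric(model$W2), b2 = model$b2)
  for (st in c("x_stats", "y_stats"))
    if (!is.null(model[[st]]))
      obj[[st]] <- list(lo = as.numeric(model[[st]]$lo),
                        hi = as.numeric(model[[st]]$hi),
                        names = names(model[[st]]$lo))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, obj$spec[c("input_dim", "hidden_dim", "output_dim")])
  model <- structure(list(
    W1 = matrix(obj$W1, spec$hidden_dim, spec$input_dim),
    b1 = obj$b1,
    W2 = matrix(obj$W2, spec$output_dim, spec$hidden_dim),
    b2 = obj$b2, spec = spec), class = "ffnn")
  for (st in c("x_stats", "y_stats"))
    if (!is.null(obj[[st]])) {
      nms <- obj[[st]]$names
      if (is.null(nms) || all(is.na(nms))) nms <- NULL
      model[[st]] <- structure(list(lo = setNames(obj[[st]]$lo, nms),
                                    hi = setNames(obj[[st]]$hi, nms)),
                               class = "norm_stats")
    }
  model
}
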