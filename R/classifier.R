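# "i-AlexNet": a 1-D-adapted AlexNet-style stack with the canonical terminal
# classifier layers removed and a 50-unit fully-connected head attached.
# Channel widths are about 1/8 of the canonical network so the model trains
# on one CPU in minutes. Training uses class-weighted cross-entropy and SGD
# with momentum: delta_{t+1} = delta_t - beta * grad + alpha * (delta_t -
# delta_{t-1}).

#' Rectified linear unit
#'
#' `b = max(0, a)`, elementwise.
#' @param a Numeric vector/matrix/array.
#' @return Same shape as `a`.
#' @export
relu <- function(a) pmax(a, 0)

#' Two-dimensional convolution (flip-and-slide)
#'
#' `H(l, b) = sum_m sum_n X(l - m, b - n) k(m, n)`: true convolution with the
#' kernel flipped, zero padding mode configurable.
#'
#' @param X Numeric matrix.
#' @param kernel Numeric matrix, no larger than `X` in either dimension.
#' @param mode `"same"` (output size of `X`, default) or `"full"`.
#' @return Numeric matrix.
#' @export
conv2d <- function(X, kernel, mode = c("same", "full")) {
  mode <- match.arg(mode)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nrow(X) || kc > ncol(X)) stop("kernel larger than input")
  nr <- nrow(X) + kr - 1L; nc <- ncol(X) + kc - 1L
  full <- matrix(0, nr, nc)
  for (m in seq_len(kr)) for (n in seq_len(kc)) {
    full[(m:(m + nrow(X) - 1L)), (n:(n + ncol(X) - 1L))] <-
      full[(m:(m + nrow(X) - 1L)), (n:(n + ncol(X) - 1L))] + kernel[m, n] * X
  }
  if (mode == "full") return(full)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nrow(X)), c0 + seq_len(ncol(X)), drop = FALSE]
}

#' Max pooling (2-D, factor 2)
#'
#' Each non-overlapping 2x2 sub-block is replaced by its maximum, so a 4x4
#' chunk of the feature map yields a 2x2 chunk. Odd dimensions are padded
#' with `-Inf` (with a warning) before pooling.
#'
#' @param X Numeric matrix.
#' @return Matrix with half the rows and columns (rounded up).
#' @export
maxpool <- function(X) {
  if (nrow(X) %% 2L || ncol(X) %% 2L) {
    warning("odd dimension padded for pooling")
    X <- rbind(X, if (nrow(X) %% 2L) -Inf)
    X <- cbind(X, if (ncol(X) %% 2L) -Inf)
  }
  nr <- nrow(X) %/% 2L; nc <- ncol(X) %/% 2L
  out <- matrix(-Inf, nr, nc)
  for (di in 0:1) for (dj in 0:1)
    out <- pmax(out, X[2 * seq_len(nr) - di, 2 * seq_len(nc) - dj, drop = FALSE])
  out
}

#' Numerically stable softmax
#'
#' `exp(a_x) / sum_y exp(a_y)` with max-subtraction; sums to 1.
#' @param a Numeric vector.
#' @return Probability vector of the same length.
#' @export
softmax <- function(a) {
  z <- exp(a - max(a))
  z / sum(z)
}

#' Model configuration for the i-AlexNet classifier
#'
#' @param input_length Number of input features (length of the 1-D signal
#'   fed to the conv stack).
#' @param n_classes Number of output classes.
#' @param conv_blocks List with vectors `channels`, `kernel`, `pool` (one
#'   entry per block). Default: five blocks with channels
#'   `c(12, 32, 48, 48, 32)` (about 1/8 of the canonical widths), kernels
#'   `c(7, 5, 3, 3, 3)`, pooling after blocks 1, 2 and 5.
#' @param fc_hidden Units in the added fully-connected layer (default 50).
#' @param lr Learning rate beta (> 0).
#' @param momentum Momentum alpha in `[0, 1)`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param norm `"lrn"` (local response normalization, the AlexNet choice) or
#'   `"none"`.
#' @param seed Seed for initialization and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_length, n_classes = 2,
                         conv_blocks = list(channels = c(12, 32, 48, 48, 32),
                                            kernel = c(7, 5, 3, 3, 3),
                                            pool = c(TRUE, TRUE, FALSE, FALSE, TRUE)),
                         fc_hidden = 50, lr = 0.02, momentum = 0.9,
                         epochs = 30, batch_size = 32, norm = "lrn",
                         seed = 1L) {
  if (fc_hidden < 1) stop("fc_hidden must be >= 1")
  if (lr <= 0) stop("lr must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes), conv_blocks = conv_blocks,
                 fc_hidden = as.integer(fc_hidden), lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), norm = norm,
                 seed = as.integer(seed)),
            class = "model_config")
}

# minimal input length so every pooled stage keeps >= 1 sample
.min_input_length <- function(conv_blocks) 2^sum(conv_blocks$pool)

#' Build an untrained i-AlexNet model
#'
#' Five 1-D convolution blocks (ReLU, optional local response normalization,
#' optional max pooling) followed by the replacement head: a fully-connected
#' layer of `fc_hidden` units (default 50), ReLU, a fully-connected output
#' layer and softmax. Parameters are He-initialized from the configured
#' seed, so two builds with the same seed are identical.
#'
#' @param cfg A [model_config].
#' @return A list of class `ialexnet` with `config`, `arch`, `params` and
#'   `prev_params` (for the momentum difference term).
#' @export
build_ialexnet <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  minL <- .min_input_length(cfg$conv_blocks)
  if (cfg$input_length < minL)
    stop(sprintf("input length %d too short for the conv stack (minimum %d)",
                 cfg$input_length, minL))
  cb <- cfg$conv_blocks
  arch <- list()
  L <- cfg$input_length; C <- 1L
  for (i in seq_along(cb$channels)) {
    arch[[length(arch) + 1L]] <- list(type = "conv", k = cb$kernel[i],
                                      cin = C, cout = cb$channels[i],
                                      name = sprintf("conv%d", i))
    arch[[length(arch) + 1L]] <- list(type = "relu")
    if (cfg$norm == "lrn" && i <= 2L)
      arch[[length(arch) + 1L]] <- list(type = "lrn", n = 5L, k = 2,
                                        alpha = 1e-4, beta = 0.75)
    if (cb$pool[i]) {
      arch[[length(arch) + 1L]] <- list(type = "pool")
      L <- (L + 1L) %/% 2L
    }
    C <- cb$channels[i]
  }
  arch[[length(arch) + 1L]] <- list(type = "flatten")
  arch[[length(arch) + 1L]] <- list(type = "fc", nin = L * C,
                                    nout = cfg$fc_hidden, name = "fc_head")
  arch[[length(arch) + 1L]] <- list(type = "relu")
  arch[[length(arch) + 1L]] <- list(type = "fc", nin = cfg$fc_hidden,
                                    nout = cfg$n_classes, name = "fc_out")
  params <- with_seed(cfg$seed, {
    p <- list()
    for (ly in arch) {
      if (identical(ly$type, "conv")) {
        fan <- ly$k * ly$cin
        p[[paste0(ly$name, "_W")]] <-
          matrix(stats::rnorm(ly$k * ly$cin * ly$cout, 0, sqrt(2 / fan)),
                 ly$k * ly$cin, ly$cout)
        p[[paste0(ly$name, "_b")]] <- numeric(ly$cout)
      } else if (identical(ly$type, "fc")) {
        p[[paste0(ly$name, "_W")]] <-
          matrix(stats::rnorm(ly$nin * ly$nout, 0, sqrt(2 / ly$nin)),
                 ly$nin, ly$nout)
        p[[paste0(ly$name, "_b")]] <- numeric(ly$nout)
      }
    }
    p
  })
  structure(list(config = cfg, arch = arch, params = params,
                 prev_params = params, classes = NULL),
            class = "ialexnet")
}

#' @export
print.ialexnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<ialexnet> input %d, %d classes, %d parameters%s\n",
              x$config$input_length, x$config$n_classes, np,
              if (is.null(x$classes)) " (untrained)" else ""))
  invisible(x)
}

## ---- internal 1-D layers (batch array N x L x C) ---------------------------

conv1d_forward <- function(A, W, b, k) {
  dims <- dim(A); N <- dims[1]; L <- dims[2]; C <- dims[3]
  p <- (k - 1L) %/% 2L
  Ap <- array(0, c(N, L + 2L * p + (k - 1L) %% 2L, C))
  Ap[, p + seq_len(L), ] <- A
  cols <- vector("list", k)
  for (j in seq_len(k)) cols[[j]] <- matrix(Ap[, j:(j + L - 1L), , drop = FALSE], N * L, C)
  Xc <- do.call(cbind, cols)
  Z <- sweep(Xc %*% W, 2, b, "+")
  list(out = array(Z, c(N, L, ncol(W))), Xc = Xc, dims = dims, pad = dim(Ap)[2])
}

conv1d_backward <- function(dOut, cache, W, k) {
  dims <- cache$dims; N <- dims[1]; L <- dims[2]; C <- dims[3]
  dZ <- matrix(dOut, N * L, dim(dOut)[3])
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dXc <- dZ %*% t(W)
  p <- (k - 1L) %/% 2L
  dAp <- array(0, c(N, cache$pad, C))
  for (j in seq_len(k)) {
    blk <- array(dXc[, (j - 1L) * C + seq_len(C), drop = FALSE], c(N, L, C))
    dAp[, j:(j + L - 1L), ] <- dAp[, j:(j + L - 1L), , drop = FALSE] + blk
  }
  list(dA = dAp[, p + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

pool1d_forward <- function(A) {
  dims <- dim(A)
  L <- dims[2]
  if (L %% 2L) {
    A2 <- array(-Inf, c(dims[1], L + 1L, dims[3]))
    A2[, seq_len(L), ] <- A
    A <- A2; L <- L + 1L
  }
  a1 <- A[, seq(1L, L, 2L), , drop = FALSE]
  a2 <- A[, seq(2L, L, 2L), , drop = FALSE]
  first <- a1 >= a2
  list(out = pmax(a1, a2), first = first, inL = dims[2])
}

pool1d_backward <- function(dOut, cache) {
  dims <- dim(dOut)
  L2 <- dims[2]
  dA <- array(0, c(dims[1], 2L * L2, dims[3]))
  dA[, seq(1L, 2L * L2, 2L), ] <- dOut * cache$first
  dA[, seq(2L, 2L * L2, 2L), ] <- dOut * !cache$first
  dA[, seq_len(cache$inL), , drop = FALSE]
}

lrn_forward <- function(A, n, k, alpha, beta) {
  C <- dim(A)[3]
  half <- n %/% 2L
  A2 <- A^2
  S <- array(0, dim(A))
  for (c0 in seq_len(C)) {
    win <- max(1L, c0 - half):min(C, c0 + half)
    S[, , c0] <- apply(A2[, , win, drop = FALSE], c(1, 2), sum)
  }
  denom <- (k + alpha * S)^beta
  list(out = A / denom, denom = denom, S = S, A = A,
       n = n, k = k, alpha = alpha, beta = beta)
}

lrn_backward <- function(dOut, cache) {
  A <- cache$A; C <- dim(A)[3]; half <- cache$n %/% 2L
  base <- cache$k + cache$alpha * cache$S
  t1 <- dOut / cache$denom
  m <- dOut * A * base^(-cache$beta - 1)
  dA <- t1
  for (j in seq_len(C)) {
    win <- max(1L, j - half):min(C, j + half)
    dA[, , j] <- dA[, , j] - 2 * cache$alpha * cache$beta * A[, , j] *
      apply(m[, , win, drop = FALSE], c(1, 2), sum)
  }
  dA
}

forward_pass <- function(model, X) {
  N <- nrow(X)
  A <- array(X, c(N, ncol(X), 1L))
  caches <- list()
  flat <- NULL
  for (i in seq_along(model$arch)) {
    ly <- model$arch[[i]]
    if (ly$type == "conv") {
      cc <- conv1d_forward(A, model$params[[paste0(ly$name, "_W")]],
                           model$params[[paste0(ly$name, "_b")]], ly$k)
      caches[[i]] <- cc; A <- cc$out
    } else if (ly$type == "relu") {
      if (is.null(flat)) { caches[[i]] <- A > 0; A <- A * (A > 0) }
      else { caches[[i]] <- flat > 0; flat <- flat * (flat > 0) }
    } else if (ly$type == "lrn") {
      cc <- lrn_forward(A, ly$n, ly$k, ly$alpha, ly$beta)
      caches[[i]] <- cc; A <- cc$out
    } else if (ly$type == "pool") {
      cc <- pool1d_forward(A)
      caches[[i]] <- cc; A <- cc$out
    } else if (ly$type == "flatten") {
      caches[[i]] <- dim(A)
      flat <- matrix(A, N, prod(dim(A)[-1]))
    } else if (ly$type == "fc") {
      caches[[i]] <- flat
      flat <- sweep(flat %*% model$params[[paste0(ly$name, "_W")]], 2,
                    model$params[[paste0(ly$name, "_b")]], "+")
    }
  }
  Z <- flat
  P <- t(apply(Z, 1, softmax))
  list(probs = P, logits = Z, caches = caches)
}

backward_pass <- function(model, fw, dZ) {
  grads <- list()
  g <- dZ
  flat_mode <- TRUE
  A <- NULL
  for (i in rev(seq_along(model$arch))) {
    ly <- model$arch[[i]]
    if (ly$type == "fc") {
      W <- model$params[[paste0(ly$name, "_W")]]
      grads[[paste0(ly$name, "_W")]] <- crossprod(fw$caches[[i]], g)
      grads[[paste0(ly$name, "_b")]] <- colSums(g)
      g <- g %*% t(W)
    } else if (ly$type == "relu") {
      g <- g * fw$caches[[i]]
    } else if (ly$type == "flatten") {
      g <- array(g, fw$caches[[i]])
      flat_mode <- FALSE
    } else if (ly$type == "pool") {
      g <- pool1d_backward(g, fw$caches[[i]])
    } else if (ly$type == "lrn") {
      g <- lrn_backward(g, fw$caches[[i]])
    } else if (ly$type == "conv") {
      bb <- conv1d_backward(g, fw$caches[[i]],
                            model$params[[paste0(ly$name, "_W")]], ly$k)
      grads[[paste0(ly$name, "_W")]] <- bb$dW
      grads[[paste0(ly$name, "_b")]] <- bb$db
      g <- bb$dA
    }
  }
  grads
}

#' One SGD-with-momentum step
#'
#' Applies `delta_{t+1} = delta_t - beta * grad + alpha * (delta_t -
#' delta_{t-1})` to every parameter tensor and shifts `delta_{t-1}` to the
#' old `delta_t`.
#'
#' @param state List with `params` and `prev_params` (identical shapes).
#' @param gradients Named list matching `params`.
#' @param beta Learning rate.
#' @param alpha Momentum weight.
#' @return Updated state.
#' @export
sgd_momentum_step <- function(state, gradients, beta, alpha) {
  new_params <- state$params
  for (nm in names(state$params)) {
    g <- gradients[[nm]]
    if (is.null(g)) g <- 0
    if (length(g) > 1 && !all(dim(as.matrix(g)) == dim(as.matrix(state$params[[nm]]))))
      stop("gradient shape mismatch for ", nm)
    new_params[[nm]] <- state$params[[nm]] - beta * g +
      alpha * (state$params[[nm]] - state$prev_params[[nm]])
  }
  state$prev_params <- state$params
  state$params <- new_params
  state
}

weighted_ce <- function(P, y_idx, w) {
  wi <- w[y_idx]
  eps <- 1e-12
  sum(wi * -log(pmax(P[cbind(seq_len(nrow(P)), y_idx)], eps))) / sum(wi)
}

#' Train an i-AlexNet model
#'
#' Minimizes class-weighted cross-entropy with [sgd_momentum_step]. Batches
#' are reshuffled each epoch from a seed derived from the model seed, so the
#' loss history is bit-reproducible. Optional early stopping on validation
#' loss (off by default).
#'
#' @param model An untrained [build_ialexnet] model.
#' @param X,y Training features (rows) and labels.
#' @param Xval,yval Optional validation split for the loss curve.
#' @param weights Optional named per-class weights (e.g. from
#'   [class_weights]); default uniform.
#' @param patience Early-stop patience in epochs; `Inf` disables (default).
#' @return The trained model, with `$history` (per-epoch `train_loss`,
#'   `val_loss`) and `$classes`.
#' @export
train_ialexnet <- function(model, X, y, Xval = NULL, yval = NULL,
                           weights = NULL, patience = Inf) {
  stopifnot(inherits(model, "ialexnet"))
  cfg <- model$config
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("training needs at least two classes")
  y_idx <- match(as.character(y), classes)
  w <- rep(1, length(classes)); names(w) <- classes
  if (!is.null(weights)) w[names(weights)] <- weights
  w <- w / mean(w)
  N <- nrow(X)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100L + ep), sample.int(N))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      fw <- forward_pass(model, X[idx, , drop = FALSE])
      if (!all(is.finite(fw$logits)))
        stop("training diverged (non-finite activations); reduce the learning rate")
      loss <- weighted_ce(fw$probs, y_idx[idx], w)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss); reduce the learning rate")
      Y <- matrix(0, length(idx), length(classes))
      Y[cbind(seq_along(idx), y_idx[idx])] <- 1
      wi <- w[y_idx[idx]]
      dZ <- (fw$probs - Y) * wi / sum(wi)
      grads <- backward_pass(model, fw, dZ)
      model[c("params", "prev_params")] <-
        sgd_momentum_step(model[c("params", "prev_params")], grads,
                          cfg$lr, cfg$momentum)[c("params", "prev_params")]
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    hist_tr <- c(hist_tr, ep_loss / nb)
    if (!is.null(Xval)) {
      fwv <- forward_pass(model, Xval)
      vl <- weighted_ce(fwv$probs, match(as.character(yval), classes), w)
      hist_val <- c(hist_val, vl)
      if (vl < best_val - 1e-9) { best_val <- vl; wait <- 0L } else wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$classes <- classes
  model$history <- list(train_loss = hist_tr,
                        val_loss = if (length(hist_val)) hist_val else NULL)
  model
}

#' Predict class probabilities
#'
#' @param object A trained `ialexnet`.
#' @param newdata Feature matrix (rows = beats).
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict.ialexnet <- function(object, newdata, ...) {
  P <- forward_pass(object, as.matrix(newdata))$probs
  colnames(P) <- object$classes %||% paste0("class", seq_len(ncol(P)))
  P
}

#' Classification metrics from truth and predictions
#'
#' Confusion matrix plus accuracy and macro-averaged precision, recall and
#' F1, all in percent. Classes absent from the predictions contribute zero
#' precision/recall, as in the macro convention.
#'
#' @param truth,pred Label vectors of equal length.
#' @param classes Optional class ordering; defaults to the sorted union.
#' @return A list of class `ecg_metrics`: `accuracy`, `precision`, `recall`,
#'   `f1` (percent), `confusion` (truth rows x prediction columns).
#' @export
compute_metrics <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes)) classes <- sort(union(truth, pred))
  cm <- table(factor(truth, classes), factor(pred, classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = 100 * sum(tp) / sum(cm),
                 precision = 100 * mean(prec), recall = 100 * mean(rec),
                 f1 = 100 * mean(f1), confusion = unclass(cm)),
            class = "ecg_metrics")
}

#' @export
print.ecg_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.1f%%\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' Argmax predictions against the true labels; see [compute_metrics].
#'
#' @param model Trained `ialexnet`.
#' @param X,y Test features and labels.
#' @return An `ecg_metrics` object.
#' @export
evaluate_model <- function(model, X, y) {
  if (!nrow(X)) stop("empty test set")
  P <- predict(model, X)
  compute_metrics(y, colnames(P)[max.col(P, ties.method = "first")],
                  classes = model$classes)
}

#' Two-stage normal/anomalous decision
#'
#' Stage 1 is the classifier verdict (argmax of `beat_probs`). An
#' "anomalous" verdict passes through unchanged. A "normal" verdict is
#' confirmed only when (a) the beat's preceding RR interval lies within
#' `rr_tol` of the running median RR and (b) the Pearson correlation with the
#' running normal-beat template is at least `corr_min`; otherwise the beat is
#' escalated to "anomalous". With fewer than 3 prior beats of context the
#' stage-1 verdict is used alone.
#'
#' @param beat_probs Named probability vector from the classifier.
#' @param rr_history Preceding RR intervals (seconds), most recent last.
#' @param beat Numeric vector of the beat's samples.
#' @param template Running mean of beats previously deemed normal (same
#'   length as `beat`), or `NULL`.
#' @param rr_tol Relative RR tolerance (default 0.2, i.e. +/-20 percent).
#' @param corr_min Minimum template correlation (default 0.8).
#' @param normal_label,anomalous_label Class names (defaults `"normal"`,
#'   `"anomalous"`).
#' @return `"normal"` or `"anomalous"`.
#' @export
two_stage_decision <- function(beat_probs, rr_history, beat, template,
                               rr_tol = 0.2, corr_min = 0.8,
                               normal_label = "normal",
                               anomalous_label = "anomalous") {
  stage1 <- names(beat_probs)[which.max(beat_probs)]
  if (!identical(stage1, normal_label)) return(anomalous_label)
  if (length(rr_history) < 3L || is.null(template)) return(stage1)
  rr_med <- stats::median(rr_history[-length(rr_history)])
  rr_last <- rr_history[length(rr_history)]
  rr_ok <- abs(rr_last - rr_med) <= rr_tol * rr_med
  corr_ok <- isTRUE(stats::cor(beat, template) >= corr_min)
  if (rr_ok && corr_ok) normal_label else anomalous_label
}
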