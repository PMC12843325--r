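## Compact convolutional network for template identification -----------------
##
## Architecture: two conv blocks (conv -> batch-norm -> ReLU -> 2x2 max-pool)
## with 18 7x7 and 45 5x5 filters, a 1024-unit fully connected layer whose
## ReLU activation is the embedding, dropout 0.5, and a linear softmax
## classifier. Convolutions are lowered to matrix products via im2col
## (Rcpp kernels); conv biases are omitted since batch-norm's shift absorbs
## them. All activations use (H, W, C, N) array layout.

relu <- function(x) x * (x > 0)

#' Initialize the template-identification network
#'
#' @param n_class Number of training identities (softmax width).
#' @param input_h,input_w Input template size in pixels.
#' @param conv1,conv2 Filter counts of the two conv blocks.
#' @param k1,k2 Kernel sizes.
#' @param fc Width of the fully connected embedding layer.
#' @param seed Seed for the He-normal weight initialization.
#' @return An untrained model of class `gait_cnn`.
#' @export
geinet <- function(n_class, input_h = 120L, input_w = 80L, conv1 = 18L,
                   k1 = 7L, conv2 = 45L, k2 = 5L, fc = 1024L, seed = 1L) {
  stopifnot(n_class >= 2L)
  oh1 <- input_h - k1 + 1L; ow1 <- input_w - k1 + 1L
  ph1 <- oh1 %/% 2L; pw1 <- ow1 %/% 2L
  oh2 <- ph1 - k2 + 1L; ow2 <- pw1 - k2 + 1L
  ph2 <- oh2 %/% 2L; pw2 <- ow2 %/% 2L
  if (min(oh1, ow1, ph1, pw1, oh2, ow2, ph2, pw2) < 1L)
    stop("input ", input_h, "x", input_w, " is too small for kernels ",
         k1, "/", k2, " with two 2x2 poolings", call. = FALSE)
  nf <- ph2 * pw2 * conv2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  params <- list(
    W1 = he(k1 * k1, conv1), g1 = rep(1, conv1), be1 = rep(0, conv1),
    W2 = he(k2 * k2 * conv1, conv2), g2 = rep(1, conv2),
    be2 = rep(0, conv2),
    W3 = he(nf, fc), b3 = rep(0, fc),
    W4 = matrix(rnorm(fc * n_class, 0, sqrt(1 / fc)), fc, n_class),
    b4 = rep(0, n_class))
  structure(list(
    params = params,
    bn = list(mu1 = rep(0, conv1), var1 = rep(1, conv1),
              mu2 = rep(0, conv2), var2 = rep(1, conv2)),
    arch = list(h = input_h, w = input_w, c1 = conv1, k1 = k1, c2 = conv2,
                k2 = k2, fc = fc, n_class = n_class,
                oh1 = oh1, ow1 = ow1, ph1 = ph1, pw1 = pw1,
                oh2 = oh2, ow2 = ow2, ph2 = ph2, pw2 = pw2, nf = nf),
    classes = NULL, log = NULL),
    class = "gait_cnn")
}

## forward pass; X is (H, W, 1, N) or an (H*W*N x 1) matrix in the
## channel-column layout. Returns logits, embedding and (when training) the
## cache needed for backprop. Dropout mask comes from the current RNG
## stream.
cnn_forward <- function(model, X, training = FALSE, dropout = 0.5) {
  p <- model$params; a <- model$arch
  if (is.array(X) && length(dim(X)) == 4L) {
    N <- dim(X)[4]
    dim(X) <- c(a$h * a$w * N, 1L)
  } else {
    N <- nrow(X) %/% (a$h * a$w)
  }
  cols1 <- im2col_mat_cpp(X, a$h, a$w, N, a$k1, a$k1)
  z1 <- cols1 %*% p$W1
  bn1 <- bnrelu_fwd_cpp(z1, p$g1, p$be1, model$bn$mu1, model$bn$var1,
                        training, 0.1, 1e-5)
  pool1 <- maxpool2_mat_cpp(bn1$out, a$oh1, a$ow1, N)
  cols2 <- im2col_mat_cpp(pool1$y, a$ph1, a$pw1, N, a$k2, a$k2)
  z2 <- cols2 %*% p$W2
  bn2 <- bnrelu_fwd_cpp(z2, p$g2, p$be2, model$bn$mu2, model$bn$var2,
                        training, 0.1, 1e-5)
  pool2 <- maxpool2_mat_cpp(bn2$out, a$oh2, a$ow2, N)
  Xf <- flatten_rows_cpp(pool2$y, N)
  z3 <- sweep(Xf %*% p$W3, 2, p$b3, `+`)
  emb <- relu(z3)
  if (training && dropout > 0) {
    mask <- matrix((runif(length(emb)) >= dropout) / (1 - dropout),
                   nrow(emb), ncol(emb))
    d3 <- emb * mask
  } else {
    mask <- NULL
    d3 <- emb
  }
  logits <- sweep(d3 %*% p$W4, 2, p$b4, `+`)
  cache <- if (training)
    list(cols1 = cols1, bn1 = bn1, pool1 = pool1,
         cols2 = cols2, bn2 = bn2, pool2 = pool2, Xf = Xf,
         z3 = z3, emb = emb, mask = mask, d3 = d3, N = N)
  list(logits = logits, emb = emb, cache = cache,
       bn_updates = if (training) list(mu1 = bn1$run_mu, var1 = bn1$run_var,
                                       mu2 = bn2$run_mu, var2 = bn2$run_var))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## cross-entropy loss + full gradient for one batch
cnn_loss_grad <- function(model, X, y, dropout = 0.5) {
  p <- model$params; a <- model$arch
  fw <- cnn_forward(model, X, training = TRUE, dropout = dropout)
  cc <- fw$cache
  N <- cc$N
  prob <- softmax(fw$logits)
  loss <- -mean(log(pmax(prob[cbind(seq_len(N), y)], 1e-12)))
  acc <- mean(max.col(prob) == y)

  dlog <- prob
  dlog[cbind(seq_len(N), y)] <- dlog[cbind(seq_len(N), y)] - 1
  dlog <- dlog / N

  gW4 <- crossprod(cc$d3, dlog)
  gb4 <- colSums(dlog)
  dd3 <- dlog %*% t(p$W4)
  demb <- if (is.null(cc$mask)) dd3 else dd3 * cc$mask
  dz3 <- demb * (cc$z3 > 0)
  gW3 <- crossprod(cc$Xf, dz3)
  gb3 <- colSums(dz3)
  dXf <- dz3 %*% t(p$W3)

  dpool2 <- unflatten_rows_cpp(dXf, a$ph2 * a$pw2)
  da2 <- maxpool2_mat_back_cpp(dpool2, cc$pool2$idx,
                               as.numeric(a$oh2 * a$ow2) * N)
  bb2 <- bnrelu_bwd_cpp(da2, cc$bn2$out, cc$bn2$xhat, cc$bn2$inv_std, p$g2)
  gW2 <- crossprod(cc$cols2, bb2$dz)
  dcols2 <- bb2$dz %*% t(p$W2)
  dpool1 <- col2im_mat_cpp(dcols2, a$ph1, a$pw1, N, a$k2, a$k2, a$c1)
  da1 <- maxpool2_mat_back_cpp(dpool1, cc$pool1$idx,
                               as.numeric(a$oh1 * a$ow1) * N)
  bb1 <- bnrelu_bwd_cpp(da1, cc$bn1$out, cc$bn1$xhat, cc$bn1$inv_std, p$g1)
  gW1 <- crossprod(cc$cols1, bb1$dz)

  list(loss = loss, acc = acc,
       grads = list(W1 = gW1, g1 = bb1$dgamma, be1 = bb1$dbeta,
                    W2 = gW2, g2 = bb2$dgamma, be2 = bb2$dbeta,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4),
       bn_updates = fw$bn_updates)
}

## AdamW / Adam step over the parameter list; decoupled weight decay is
## applied to weight matrices only
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  decay_set <- c("W1", "W2", "W3", "W4")
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nm %in% decay_set)
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

## cosine learning-rate schedule with linear warm-up (per epoch)
lr_schedule <- function(epoch, base_lr, max_epochs, warmup = 5L,
                        cosine = TRUE) {
  if (epoch <= warmup) return(base_lr * epoch / warmup)
  if (!cosine) return(base_lr)
  prog <- (epoch - warmup) / max(1L, max_epochs - warmup)
  base_lr * 0.5 * (1 + cos(pi * min(1, prog)))
}

#' Training configuration
#'
#' The `"loto"` protocol uses AdamW (learning rate `1e-3`, weight decay
#' `1e-4`) with a cosine schedule and 5-epoch warm-up; the
#' `"gallery_probe"` protocol uses plain Adam at a constant learning rate.
#' Both use cross-entropy loss, batch size 32 and early stopping with a
#' patience of 10 epochs on the validation loss. The identical
#' configuration is reused across input representations so that performance
#' differences are attributable to the templates alone.
#'
#' @param protocol `"loto"` or `"gallery_probe"`.
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay (AdamW; 0 under Adam).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs (also the cosine period).
#' @param warmup_epochs Linear warm-up length.
#' @param patience Early-stopping patience in epochs.
#' @param dropout Dropout rate on the embedding layer.
#' @param seed Training seed (shuffling, dropout, init).
#' @return A `train_config` list.
#' @export
train_config <- function(protocol = c("loto", "gallery_probe"), lr = 1e-3,
                         weight_decay = NULL, batch_size = 32L,
                         max_epochs = 200L, warmup_epochs = 5L,
                         patience = 10L, dropout = 0.5, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(weight_decay))
    weight_decay <- if (protocol == "loto") 1e-4 else 0
  structure(list(protocol = protocol, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 patience = as.integer(patience), dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

## stack a list of templates/matrices into the (H, W, 1, N) input array
templates_to_array <- function(templates) {
  mats <- lapply(templates, function(t)
    if (inherits(t, "gait_template")) t$pixels else t)
  if (!is.matrix(mats[[1]]))
    stop("templates must be gait_template objects or matrices",
         call. = FALSE)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(h, w, 1L, length(mats)))
}

#' Train the identification network on templates
#'
#' Minibatch training with cross-entropy loss; optimizer and schedule are
#' set by the protocol in [train_config()]. Early stopping monitors the
#' validation loss and restores the best parameters. Training is
#' deterministic given `cfg$seed`.
#'
#' @param templates List of [gait_template] objects (or plain matrices).
#' @param labels Identity labels (factor or character), one per template; at
#'   least two distinct identities.
#' @param val_templates,val_labels Held-out validation split (required for
#'   early stopping; pass `NULL` to train for exactly `max_epochs`).
#' @param cfg A [train_config()].
#' @param net_args Optional list overriding [geinet()] architecture
#'   arguments (e.g. smaller filter counts for toy problems).
#' @return A trained `gait_cnn`; `$log` holds the per-epoch training record
#'   and `$classes` the identity levels.
#' @export
train_gait_cnn <- function(templates, labels, val_templates = NULL,
                           val_labels = NULL, cfg = train_config(),
                           net_args = list()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training needs at least 2 identities", call. = FALSE)
  X <- templates_to_array(templates)
  y <- as.integer(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  model <- do.call(geinet, utils::modifyList(
    list(n_class = nlevels(labels), input_h = dim(X)[1],
         input_w = dim(X)[2], seed = cfg$seed), net_args))
  model$classes <- levels(labels)

  has_val <- !is.null(val_templates)
  if (has_val) {
    Xv <- templates_to_array(val_templates)
    yv <- as.integer(factor(val_labels, levels = levels(labels)))
  }
  state <- list(t = 0L,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  n <- length(y)
  best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0L)
  wait <- 0L
  log <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_schedule(epoch, cfg$lr, cfg$max_epochs, cfg$warmup_epochs,
                      cosine = cfg$protocol == "loto")
    idx <- sample.int(n)
    tl <- 0; ta <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      b <- idx[start:min(n, start + cfg$batch_size - 1L)]
      if (length(b) < 2L) next   # batch-norm needs > 1 sample
      res <- cnn_loss_grad(model, X[, , , b, drop = FALSE], y[b],
                           dropout = cfg$dropout)
      upd <- adam_step(model$params, res$grads, state, lr,
                       weight_decay = cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
      model$bn <- res$bn_updates
      tl <- tl + res$loss; ta <- ta + res$acc; nb <- nb + 1L
    }
    rec <- list(epoch = epoch, lr = lr, train_loss = tl / nb,
                train_acc = ta / nb, val_loss = NA_real_,
                val_acc = NA_real_)
    if (has_val) {
      ev <- evaluate_batches(model, Xv, yv)
      rec$val_loss <- ev$loss; rec$val_acc <- ev$acc
      if (ev$loss < best$loss - 1e-6) {
        best <- list(loss = ev$loss, params = model$params, bn = model$bn,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log[[epoch]] <- rec
    if (has_val && wait >= cfg$patience) break
  }
  if (has_val && is.finite(best$loss)) {
    model$params <- best$params
    model$bn <- best$bn
  }
  model$log <- tibble::as_tibble(do.call(rbind,
    lapply(log[!vapply(log, is.null, logical(1))], as.data.frame)))
  model$cfg <- cfg
  model
}

## eval-mode loss/accuracy in memory-bounded batches
evaluate_batches <- function(model, X, y, batch = 64L) {
  n <- dim(X)[4]
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch)) {
    b <- start:min(n, start + batch - 1L)
    fw <- cnn_forward(model, X[, , , b, drop = FALSE], training = FALSE)
    pr <- softmax(fw$logits)
    loss <- loss + sum(-log(pmax(pr[cbind(seq_along(b), y[b])], 1e-12)))
    correct <- correct + sum(max.col(pr) == y[b])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict from a trained identification network
#'
#' @param object A trained `gait_cnn`.
#' @param templates List of templates (or matrices).
#' @param type `"class"` (predicted identity), `"prob"` (softmax matrix) or
#'   `"embedding"` (penultimate 1024-d activations).
#' @param ... Unused.
#' @return Character vector, probability matrix, or embedding matrix.
#' @export
predict.gait_cnn <- function(object, templates,
                             type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  X <- templates_to_array(templates)
  n <- dim(X)[4]
  out <- NULL
  for (start in seq(1L, n, by = 64L)) {
    b <- start:min(n, start + 63L)
    fw <- cnn_forward(object, X[, , , b, drop = FALSE], training = FALSE)
    piece <- switch(type,
                    class = ,
                    prob = softmax(fw$logits),
                    embedding = fw$emb)
    out <- rbind(out, piece)
  }
  if (type == "class") object$classes[max.col(out)] else out
}

#' @export
print.gait_cnn <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<gait_cnn> %dx%d input, conv %d@%dx%d + conv %d@%dx%d, fc %d, %d classes\n",
    a$h, a$w, a$c1, a$k1, a$k1, a$c2, a$k2, a$k2, a$fc, a$n_class))
  if (!is.null(x$log) && nrow(x$log))
    cat(sprintf("  trained %d epoch(s), final val acc %.3f\n",
                nrow(x$log), x$log$val_acc[nrow(x$log)]))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
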