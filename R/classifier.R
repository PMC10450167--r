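#' @title Purine/pyrimidine base-type classifier
#' @description A small feed-forward network mapping a 403-value residue
#'   descriptor to purine/pyrimidine log-probabilities: one fully connected
#'   hidden layer of 403 units with ReLU activation, a dropout layer active
#'   during training only, and a 2-unit output layer with log-softmax
#'   normalization. Training minimizes the negative log-likelihood with the
#'   ADAM optimizer. Two weight sets of the same architecture are intended
#'   in practice, one per experimental modality (cryo-EM and MX maps differ
#'   in fine detail); the package trains them from data rather than shipping
#'   fixed weights. Inference is deterministic: dropout is disabled and no
#'   RNG is consumed.
#' @name classifier
NULL

#' Training configuration
#' @param epochs number of passes over the training set (default 1000)
#' @param batch_size descriptors per parameter update (default 20)
#' @param learning_rate ADAM learning rate (default 1e-5)
#' @param dropout_p dropout probability between the layers (default 0.5)
#' @param validation_fraction held-out fraction (default 0.1)
#' @param seed RNG seed controlling init, split, shuffling and dropout
#' @return list of class `na_training_config`
#' @export
training_config <- function(epochs = 1000L, batch_size = 20L,
                            learning_rate = 1e-5, dropout_p = 0.5,
                            validation_fraction = 0.1, seed = 1L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            dropout_p >= 0, dropout_p < 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout_p = dropout_p,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "na_training_config")
}

.as_xy <- function(data) {
  # accepts list(x=matrix, labels=character) or a list of
  # list(descriptor=..., label=...) pairs
  if (is.list(data) && !is.null(data$x)) {
    x <- data$x; labels <- data$labels
  } else {
    x <- do.call(rbind, lapply(data, function(d) {
      v <- d$descriptor
      if (is.list(v)) v$values else v
    }))
    labels <- vapply(data, `[[`, "", "label")
  }
  stopifnot(ncol(x) == 403L)
  y <- match(labels, c("PURINE", "PYRIMIDINE"))
  if (anyNA(y)) stop("labels must be PURINE or PYRIMIDINE")
  list(x = as.matrix(x), y = y)
}

forward_logprobs <- function(model, x) {
  h <- x %*% model$W1
  h <- sweep(h, 2, model$b1, "+")
  h[h < 0] <- 0
  z <- h %*% model$W2
  z <- sweep(z, 2, model$b2, "+")
  mx <- pmax(z[, 1], z[, 2])
  lse <- mx + log(exp(z[, 1] - mx) + exp(z[, 2] - mx))
  z - lse
}

#' Train the base-type classifier
#'
#' @param data training data: either `list(x = n x 403 matrix, labels =
#'   character)` (as produced by [training_set()]) or a list of
#'   `list(descriptor =, label =)` pairs
#' @param config a [training_config()]
#' @param modality label stored with the model, "EM" or "MX"
#' @return object of class `na_classifier` with weight matrices `W1`
#'   (403 x 403), `b1`, `W2` (403 x 2), `b2` and `training_meta` (config,
#'   seed, accuracy trajectory)
#' @export
train_classifier <- function(data, config = training_config(),
                             modality = "EM") {
  d <- .as_xy(data)
  x <- d$x; y <- d$y
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("training data must contain at least 2 examples of each class")
  }
  set.seed(config$seed)
  n <- nrow(x)
  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  lim1 <- sqrt(6 / (403 + 403)); lim2 <- sqrt(6 / (403 + 2))
  model <- list(W1 = matrix(stats::runif(403 * 403, -lim1, lim1), 403, 403),
                b1 = rep(0, 403),
                W2 = matrix(stats::runif(403 * 2, -lim2, lim2), 403, 2),
                b2 = rep(0, 2), modality = modality)
  m <- lapply(model[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  lr <- config$learning_rate
  p_drop <- config$dropout_p
  onehot <- cbind(y == 1L, y == 2L) * 1
  history <- NULL
  acc <- function(idx) {
    lp <- forward_logprobs(model, x[idx, , drop = FALSE])
    mean((lp[, 1] < lp[, 2]) + 1L == y[idx])
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      xb <- x[b, , drop = FALSE]
      h <- sweep(xb %*% model$W1, 2, model$b1, "+")
      relu_mask <- h > 0
      h[!relu_mask] <- 0
      if (p_drop > 0) {
        keep <- matrix(stats::runif(length(h)) >= p_drop, nrow(h), ncol(h))
        hd <- h * keep / (1 - p_drop)
      } else {
        keep <- NULL
        hd <- h
      }
      z <- sweep(hd %*% model$W2, 2, model$b2, "+")
      mx <- pmax(z[, 1], z[, 2])
      p <- exp(z - (mx + log(exp(z[, 1] - mx) + exp(z[, 2] - mx))))
      dz <- (p - onehot[b, , drop = FALSE]) / length(b)
      gW2 <- t(hd) %*% dz
      gb2 <- colSums(dz)
      dh <- dz %*% t(model$W2)
      if (!is.null(keep)) dh <- dh * keep / (1 - p_drop)
      dh <- dh * relu_mask
      gW1 <- t(xb) %*% dh
      gb1 <- colSums(dh)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      tstep <- tstep + 1
      for (nm in names(grads)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^tstep)
        vhat <- v[[nm]] / (1 - beta2^tstep)
        model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (epoch %% max(1L, config$epochs %/% 20L) == 0L ||
        epoch == config$epochs) {
      history <- rbind(history,
                       data.frame(epoch = epoch, train_acc = acc(tr_idx),
                                  val_acc = acc(val_idx)))
    }
  }
  model$training_meta <- list(config = config, seed = config$seed,
                              n_train = length(tr_idx), n_val = n_val,
                              history = history,
                              final_train_acc = utils::tail(history$train_acc,
                                                            1),
                              final_val_acc = utils::tail(history$val_acc, 1))
  class(model) <- "na_classifier"
  model
}

#' @export
print.na_classifier <- function(x, ...) {
  cat(sprintf("<na_classifier> modality %s", x$modality))
  if (!is.null(x$training_meta)) {
    cat(sprintf(", train acc %.3f, val acc %.3f",
                x$training_meta$final_train_acc,
                x$training_meta$final_val_acc))
  }
  cat("\n")
  invisible(x)
}

#' Log-probabilities of purine/pyrimidine for descriptors
#'
#' @param model `na_classifier`
#' @param descriptor a `na_descriptor`, a length-403 vector, or an n x 403
#'   matrix
#' @return matrix with columns `log_p_purine`, `log_p_pyrimidine` (single
#'   input: named length-2 vector)
#' @export
predict_base_class <- function(model, descriptor) {
  v <- descriptor
  if (is.list(v)) v <- v$values
  single <- is.null(dim(v))
  if (single) v <- matrix(v, nrow = 1)
  if (ncol(v) != 403L) {
    stop("descriptor dimension ", ncol(v), " != 403")
  }
  lp <- forward_logprobs(model, v)
  colnames(lp) <- c("log_p_purine", "log_p_pyrimidine")
  if (single) lp[1, ] else lp
}

#' Classification accuracy on labelled descriptors
#' @param model `na_classifier`
#' @param data same formats as [train_classifier()]
#' @return fraction of correctly argmax-classified examples
#' @export
evaluate <- function(model, data) {
  d <- .as_xy(data)
  if (nrow(d$x) == 0L) stop("empty evaluation data")
  lp <- forward_logprobs(model, d$x)
  mean((lp[, 1] < lp[, 2]) + 1L == d$y)
}

#' Save / load a classifier as a portable text container
#'
#' Weights are written in full precision alongside a JSON metadata header;
#' no deep-learning runtime is needed to reload the model.
#' @param model `na_classifier`
#' @param path file path
#' @return `path` (save) or `na_classifier` (load)
#' @export
save_classifier <- function(model, path) {
  meta <- list(modality = model$modality,
               dims = c(403L, 403L, 2L),
               training_meta = model$training_meta["final_val_acc"])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#META ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  for (nm in c("W1", "b1", "W2", "b2")) {
    writeLines(paste0("#PARAM ", nm, " ", length(model[[nm]])), con)
    writeLines(sprintf("%.17g", as.numeric(model[[nm]])), con)
  }
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "#META "))
  meta <- jsonlite::fromJSON(sub("^#META ", "", lines[1]))
  model <- list(modality = meta$modality)
  i <- 2L
  shapes <- list(W1 = c(403L, 403L), b1 = 403L, W2 = c(403L, 2L), b2 = 2L)
  for (nm in c("W1", "b1", "W2", "b2")) {
    hdr <- strsplit(lines[i], " ")[[1]]
    stopifnot(hdr[1] == "#PARAM", hdr[2] == nm)
    len <- as.integer(hdr[3])
    vals <- as.numeric(lines[(i + 1L):(i + len)])
    sh <- shapes[[nm]]
    model[[nm]] <- if (length(sh) == 2L) matrix(vals, sh[1], sh[2]) else vals
    i <- i + len + 1L
  }
  class(model) <- "na_classifier"
  model
}
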