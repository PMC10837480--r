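#' Encode an ROI for the classifier
#'
#' Directors are fed to the network as double-angle channels
#' `(cos 2 theta, sin 2 theta)` per node. Raw angles have an artificial
#' discontinuity at the pi wrap; the double-angle encoding is continuous,
#' bounded in `[-1, 1]`, and manifestly head-tail symmetric:
#' `encode(theta) == encode(theta + pi)` element-wise.
#'
#' @param roi a `defect_roi` or a square matrix of directors.
#' @return numeric array `(2, side, side)`; channel 1 is `cos 2 theta`,
#'   channel 2 `sin 2 theta`.
#' @export
encode_roi <- function(roi) {
  th <- if (inherits(roi, "defect_roi")) roi$theta else roi
  s <- nrow(th)
  out <- array(NA_real_, dim = c(2L, s, s))
  out[1L, , ] <- cos(2 * th)
  out[2L, , ] <- sin(2 * th)
  out
}

## Dataset encoding: matrix (N, 2*s^2), flat column i + (j-1)*s + (c-1)*s^2.
encode_dataset <- function(theta_array) {
  N <- dim(theta_array)[1L]
  s <- dim(theta_array)[2L]
  cbind(matrix(cos(2 * theta_array), N, s * s),
        matrix(sin(2 * theta_array), N, s * s))
}

## Patch transforms: rotating a sample by alpha rotates the grid AND adds
## alpha to every director (mod pi); reflecting about the vertical
## centreline flips x and maps theta -> pi - theta. All act on the item
## dimension of an (N, s, s) array at once.
rot_patch <- function(th, quarter) {
  n <- dim(th)[2L]
  switch(as.character(quarter %% 4L),
         "0" = th,
         "1" = {  # +pi/2
           a <- aperm(th, c(1L, 3L, 2L))[, n:1, , drop = FALSE]
           reduce_mod_pi(a + pi / 2)
         },
         "2" = reduce_mod_pi(th[, n:1, n:1, drop = FALSE] + pi),
         "3" = {  # -pi/2
           a <- aperm(th, c(1L, 3L, 2L))[, , n:1, drop = FALSE]
           reduce_mod_pi(a - pi / 2)
         })
}

reflect_patch <- function(th) {
  n <- dim(th)[2L]
  reduce_mod_pi(pi - th[, n:1, , drop = FALSE])
}

#' Augment a labelled ROI dataset by rotations and reflections
#'
#' Enlarges a training set eightfold: three new copies of each ROI rotated
#' by `-pi/2`, `pi` and `pi/2` (a rotation rotates the patch grid and adds
#' the angle to every director, mod pi), then the enlarged set doubled by
#' reflection about the vertical centreline. Defect type is invariant
#' under both operations, so labels are copied unchanged. 4,500 input
#' ROIs become 36,000 training inputs.
#'
#' @param dataset a `roi_dataset` (square patches).
#' @return a `roi_dataset` with `8 * n` items; `meta$aug` records the
#'   group element.
#' @export
augment_rois <- function(dataset) {
  th <- dataset$theta
  if (dim(th)[2L] != dim(th)[3L])
    stop_nemadef("augmentation requires square ROIs", "nemadef_invalid_input")
  rots <- lapply(0:3, function(q) rot_patch(th, q))
  all <- c(rots, lapply(rots, reflect_patch))
  tags <- c(sprintf("rot%d", c(0L, 90L, 180L, 270L)),
            sprintf("rot%d+reflect", c(0L, 90L, 180L, 270L)))
  n <- dim(th)[1L]
  theta <- array(NA_real_, dim = c(8L * n, dim(th)[2L], dim(th)[3L]))
  for (k in seq_len(8L)) theta[(k - 1L) * n + seq_len(n), , ] <- all[[k]]
  meta <- do.call(rbind, replicate(8L, dataset$meta, simplify = FALSE))
  meta$aug <- rep(tags, each = n)
  structure(list(theta = theta, label = rep(dataset$label, 8L),
                 meta = meta, spacing = dataset$spacing),
            class = "roi_dataset")
}

#' Training configuration for the defect classifier
#'
#' Defaults follow the reference training recipe: plain SGD (no momentum,
#' no weight decay) with batch size 64, 30 epochs at learning rate 0.025
#' for the first 15 and 0.005 for the last 15, Glorot-normal weight
#' initialization, 50% dropout on the fully connected layer, and a 10%
#' validation holdout scored at the end of each epoch with dropout
#' disabled.
#'
#' @param batch_size SGD batch size.
#' @param epochs training epochs.
#' @param lr_schedule numeric vector of per-epoch learning rates
#'   (recycled to `epochs`).
#' @param dropout_fc dropout fraction on the FC hidden layer, in `[0, 1)`.
#' @param validation_fraction holdout fraction, in `(0, 1)`.
#' @param features feature maps per convolutional layer.
#' @param fc width of the fully connected hidden layer.
#' @param seed integer seed controlling initialization, the validation
#'   split, epoch shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 64L, epochs = 30L,
                         lr_schedule = c(rep(0.025, 15L), rep(0.005, 15L)),
                         dropout_fc = 0.5, validation_fraction = 0.10,
                         features = 32L, fc = 100L, seed = 1L) {
  if (batch_size < 1L) stop_nemadef("batch_size must be >= 1", "nemadef_parameter_error")
  if (dropout_fc < 0 || dropout_fc >= 1)
    stop_nemadef("dropout_fc must be in [0, 1)", "nemadef_parameter_error")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_nemadef("validation_fraction must be in (0, 1)", "nemadef_parameter_error")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_schedule = rep_len(lr_schedule, epochs),
                 dropout_fc = dropout_fc,
                 validation_fraction = validation_fraction,
                 features = as.integer(features), fc = as.integer(fc),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the convolutional defect classifier
#'
#' Fits the three-class network (+1/2, none, -1/2) on encoded director
#' ROIs: two 3x3 valid convolutions with 32 feature maps each (9x9 -> 7x7
#' -> 5x5, no pooling), ReLU activations, a 100-unit fully connected ReLU
#' layer with dropout, and a softmax output. Minimizes the cross-entropy
#' \eqn{C = -\sum_i \sum_c y_{i,c} \log p_{i,c}} (batch mean) by plain
#' stochastic gradient descent under the schedule in `cfg`. Training is a
#' pure function of the data and `cfg$seed`.
#'
#' Augment the training set with [augment_rois()] beforehand; no
#' augmentation happens here.
#'
#' @param dataset a labelled `roi_dataset` (see [generate_labeled_rois()],
#'   [augment_rois()]).
#' @param cfg a [train_config()].
#' @return an object of class `defect_cnn` with the trained parameters,
#'   the fixed class order, the input-encoding version, `cfg`, and a
#'   per-epoch `log` data.frame (`epoch`, `lr`, `train_loss`, `train_acc`,
#'   `val_loss`, `val_acc`).
#' @seealso [predict.defect_cnn()], [save_defect_cnn()]
#' @export
train_defect_cnn <- function(dataset, cfg = train_config()) {
  if (!inherits(dataset, "roi_dataset") || dim(dataset$theta)[1L] == 0L)
    stop_nemadef("`dataset` must be a non-empty roi_dataset", "nemadef_invalid_input")
  if (is.null(dataset$label) || anyNA(dataset$label))
    stop_nemadef("`dataset` must be fully labelled", "nemadef_invalid_input")
  side <- dim(dataset$theta)[2L]
  X <- encode_dataset(dataset$theta)
  y <- as.integer(factor(dataset$label, levels = defect_classes()))
  if (length(unique(y)) < 3L)
    warning("not all three classes present in training data; model may degenerate")
  N <- length(y)
  keep <- 1 - cfg$dropout_fc
  with_seed(cfg$seed, {
    par <- nn_init(side = side, features = cfg$features, fc = cfg$fc)
    n_val <- max(1L, as.integer(round(cfg$validation_fraction * N)))
    val_idx <- sample.int(N, n_val)
    tr_idx <- setdiff(seq_len(N), val_idx)
    log <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr <- cfg$lr_schedule[ep]
      ord <- sample(tr_idx)
      losses <- accs <- numeric(0)
      for (s in seq(1L, length(ord), by = cfg$batch_size)) {
        b <- ord[s:min(length(ord), s + cfg$batch_size - 1L)]
        Xb <- X[b, , drop = FALSE]
        yb <- y[b]
        mask <- if (cfg$dropout_fc > 0) {
          matrix(stats::rbinom(length(b) * cfg$fc, 1L, keep) / keep,
                 length(b), cfg$fc)
        } else NULL
        fw <- nn_forward(par, Xb, drop_mask = mask)
        losses <- c(losses, cross_entropy(fw$prob, yb))
        accs <- c(accs, mean(max.col(fw$prob) == yb))
        gr <- nn_backward(par, fw, Xb, yb, drop_mask = mask)
        par <- nn_sgd_step(par, gr, lr)
      }
      val <- nn_eval(par, X[val_idx, , drop = FALSE], y[val_idx])
      log[[ep]] <- data.frame(epoch = ep, lr = lr,
                              train_loss = mean(losses),
                              train_acc = mean(accs),
                              val_loss = val$loss, val_acc = val$acc)
    }
    structure(list(par = par, classes = defect_classes(),
                   encoding = "double-angle-v1", side = side,
                   cfg = cfg, n_train = length(tr_idx), n_val = n_val,
                   log = do.call(rbind, log)),
              class = "defect_cnn")
  })
}

nn_eval <- function(par, X, y, chunk = 1024L) {
  loss <- 0; correct <- 0; n <- nrow(X)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    p <- nn_forward(par, X[s:e, , drop = FALSE])$prob
    loss <- loss + cross_entropy(p, y[s:e]) * (e - s + 1L)
    correct <- correct + sum(max.col(p) == y[s:e])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict defect classes for ROIs
#'
#' Inference is deterministic: dropout is disabled and the softmax output
#' gives three class probabilities summing to 1 per ROI, in the model's
#' fixed class order (+1/2, none, -1/2).
#'
#' @param object a trained [train_defect_cnn()] model.
#' @param newdata a `roi_dataset`, a single `defect_roi`, or an
#'   `(n, side, side)` array of director patches.
#' @param type `"class"` for the argmax label, `"prob"` for the
#'   probability matrix.
#' @param ... unused.
#' @return factor of labels, or numeric matrix `(n, 3)` with class-named
#'   columns.
#' @export
predict.defect_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  th <- if (inherits(newdata, "roi_dataset")) newdata$theta
        else if (inherits(newdata, "defect_roi")) {
          array(newdata$theta, dim = c(1L, dim(newdata$theta)))
        } else if (is.array(newdata) && length(dim(newdata)) == 3L) newdata
        else stop_nemadef("unsupported `newdata` type", "nemadef_invalid_input")
  if (dim(th)[2L] != object$side || dim(th)[3L] != object$side)
    stop_nemadef(sprintf("ROI shape %dx%d does not match the trained input %dx%d",
                         dim(th)[2L], dim(th)[3L], object$side, object$side),
                 "nemadef_invalid_input")
  X <- encode_dataset(th)
  n <- nrow(X)
  prob <- matrix(NA_real_, n, 3L, dimnames = list(NULL, object$classes))
  for (s in seq(1L, n, by = 1024L)) {
    e <- min(n, s + 1023L)
    prob[s:e, ] <- nn_forward(object$par, X[s:e, , drop = FALSE])$prob
  }
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob)], levels = object$classes)
}

#' @export
print.defect_cnn <- function(x, ...) {
  d <- x$par$dims
  cat(sprintf(paste0("<defect_cnn> conv %dx%d x%d -> conv %dx%d x%d -> fc %d -> softmax %d\n",
                     "  classes: %s; encoding %s\n",
                     "  trained %d epochs on %d ROIs (val %d); final val acc %.3f\n"),
              d$K, d$K, d$features, d$K, d$K, d$features, d$fc, d$classes,
              paste(x$classes, collapse = ", "), x$encoding,
              nrow(x$log), x$n_train, x$n_val,
              x$log$val_acc[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.defect_cnn <- function(object, ...) {
  print(object)
  cat("training log (last 5 epochs):\n")
  print(utils::tail(object$log, 5L), row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.defect_cnn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c(1, 2),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1, col = c(1, 2),
                   bty = "n")
  graphics::matplot(x$log$epoch, cbind(x$log$train_acc, x$log$val_acc),
                    type = "l", lty = 1, col = c(1, 2),
                    xlab = "epoch", ylab = "accuracy", ylim = c(0, 1))
  invisible(x)
}

#' Serialize a trained classifier to portable JSON
#'
#' The container embeds the architecture descriptor, the fixed class
#' order, the input-encoding version, the training configuration and log,
#' and all parameters at full precision.
#'
#' @param model a `defect_cnn`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_defect_cnn <- function(model, path) {
  par <- model$par
  ser <- list(
    format = "nemadef-cnn-1",
    classes = model$classes,
    encoding = model$encoding,
    side = model$side,
    dims = par$dims,
    cfg = unclass(model$cfg),
    n_train = model$n_train, n_val = model$n_val,
    log = model$log,
    # flat column-major vectors; shapes are implied by the dims descriptor
    weights = lapply(par[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                     as.numeric))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_defect_cnn()]
#'
#' @param path JSON file path.
#' @return a `defect_cnn`.
#' @export
load_defect_cnn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "nemadef-cnn-1"))
    stop_nemadef("unrecognized model container format", "nemadef_invalid_input")
  d <- ser$dims
  par <- nn_init(side = as.integer(d$side), channels = as.integer(d$channels),
                 features = as.integer(d$features), fc = as.integer(d$fc),
                 classes = as.integer(d$classes), K = as.integer(d$K))
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    w <- ser$weights[[nm]]
    par[[nm]] <- if (is.matrix(par[[nm]])) matrix(unlist(w), nrow(par[[nm]]),
                                                  ncol(par[[nm]]))
                 else as.numeric(unlist(w))
  }
  cfg <- ser$cfg
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg$epochs <- as.integer(cfg$epochs)
  class(cfg) <- "train_config"
  structure(list(par = par, classes = ser$classes, encoding = ser$encoding,
                 side = as.integer(ser$side), cfg = cfg,
                 n_train = ser$n_train, n_val = ser$n_val,
                 log = as.data.frame(ser$log)),
            class = "defect_cnn")
}
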