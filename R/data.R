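# one-hot target coding: output unit (label + 1) is 1, all others 0
one_hot <- function(labels, n_classes) {
  D <- matrix(0, length(labels), n_classes)
  D[cbind(seq_along(labels), labels + 1L)] <- 1
  D
}

#' Generate a synthetic MNIST-like classification dataset
#'
#' Each class gets a fixed random prototype in `[0,1]^n_features`; samples
#' are the prototype plus Gaussian noise, clipped back to `[0,1]`. With the
#' defaults the classes are well separated (a nearest-prototype classifier
#' exceeds 95% test accuracy), emulating the flat-vector digit data used
#' for the energy experiments without any download.
#'
#' @param n_train,n_test Split sizes (defaults 500 / 200).
#' @param n_classes Number of classes, >= 2 (default 10).
#' @param n_features Feature count (default 784, a flattened 28 x 28 image).
#' @param noise_sd Gaussian noise standard deviation (default 1.0,
#'   chosen so a small-sample perceptron lands in the mid-80s to mid-90s
#'   accuracy range typical of flat-vector digit data; the class
#'   prototypes remain trivially separable to a nearest-prototype
#'   classifier).
#' @param seed Optional integer seed.
#' @return Object of class `anvn_dataset`: list with `X_train`, `y_train`,
#'   `X_test`, `y_test` (labels 0-based), `prototypes`
#'   (`n_classes x n_features`), `n_classes`, `noise_sd`.
#' @export
make_synthetic <- function(n_train = 500, n_test = 200, n_classes = 10,
                           n_features = 784, noise_sd = 1.0, seed = NULL) {
  if (n_train < 1 || n_test < 1) {
    stop("split sizes must be positive", call. = FALSE)
  }
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  protos <- matrix(stats::runif(n_classes * n_features), n_classes,
                   n_features)
  draw <- function(n) {
    y <- rep_len(seq_len(n_classes) - 1L, n)
    X <- protos[y + 1L, , drop = FALSE]
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * n_features, sd = noise_sd), n,
                      n_features)
      X <- pmin(pmax(X, 0), 1)
    }
    list(X = X, y = y)
  }
  tr <- draw(n_train)
  te <- draw(n_test)
  structure(
    list(X_train = tr$X, y_train = tr$y, X_test = te$X, y_test = te$y,
         prototypes = protos, n_classes = as.integer(n_classes),
         noise_sd = noise_sd),
    class = "anvn_dataset"
  )
}

#' Generate a correlated variant of a dataset for transfer-learning runs
#'
#' Draws a second prototype set and mixes it with the original prototypes
#' (convex combination, default weight 0.5), then samples new train/test
#' splits with the same sizes and noise. Emulates retraining on a similar
#' but distinct dataset.
#'
#' @param data An `anvn_dataset`.
#' @param mix Weight on the original prototypes in the convex mix.
#' @param seed Optional integer seed.
#' @return A new `anvn_dataset`.
#' @export
make_transfer_variant <- function(data, mix = 0.5, seed = NULL) {
  stopifnot(inherits(data, "anvn_dataset"))
  if (!is.null(seed)) set.seed(seed)
  n_classes <- data$n_classes
  n_features <- ncol(data$X_train)
  protos <- mix * data$prototypes +
    (1 - mix) * matrix(stats::runif(n_classes * n_features), n_classes,
                       n_features)
  out <- make_synthetic(
    n_train = nrow(data$X_train), n_test = nrow(data$X_test),
    n_classes = n_classes, n_features = n_features,
    noise_sd = data$noise_sd
  )
  # resample from the mixed prototypes
  redraw <- function(n, y) {
    X <- protos[y + 1L, , drop = FALSE]
    if (data$noise_sd > 0) {
      X <- pmin(pmax(X + matrix(stats::rnorm(n * n_features,
                                             sd = data$noise_sd),
                                n, n_features), 0), 1)
    }
    X
  }
  out$X_train <- redraw(nrow(out$X_train), out$y_train)
  out$X_test <- redraw(nrow(out$X_test), out$y_test)
  out$prototypes <- protos
  out
}

#' @export
print.anvn_dataset <- function(x, ...) {
  cat("anvn dataset:", nrow(x$X_train), "train /", nrow(x$X_test), "test,",
      x$n_classes, "classes,", ncol(x$X_train), "features\n")
  invisible(x)
}

#' Read an IDX image/label file pair
#'
#' Reads the big-endian IDX binary format (magic 0x00000803 for images,
#' 0x00000801 for labels). Pixels are rescaled to `[0,1]` and images are
#' flattened row-major.
#'
#' @param images_path,labels_path Paths to the image and label files.
#' @param n_test Number of trailing samples assigned to the test split
#'   (default 0: everything goes to train).
#' @param n_classes Number of classes (default 10).
#' @return An `anvn_dataset` (with `prototypes = NULL`).
#' @export
read_idx <- function(images_path, labels_path, n_test = 0, n_classes = 10) {
  img <- file(images_path, "rb")
  on.exit(close(img), add = TRUE)
  magic <- readBin(img, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    stop("bad magic number in image file", call. = FALSE)
  }
  dims <- readBin(img, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; nr <- dims[2]; nc <- dims[3]
  raw_px <- readBin(img, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(raw_px) != n * nr * nc) {
    stop("image file truncated", call. = FALSE)
  }
  lab <- file(labels_path, "rb")
  on.exit(close(lab), add = TRUE)
  magic_l <- readBin(lab, "integer", 1, size = 4, endian = "big")
  if (!identical(magic_l, 2049L)) {
    stop("bad magic number in label file", call. = FALSE)
  }
  n_l <- readBin(lab, "integer", 1, size = 4, endian = "big")
  if (n_l != n) stop("image/label count mismatch", call. = FALSE)
  y <- readBin(lab, "integer", n, size = 1, signed = FALSE)
  if (length(y) != n) stop("label file truncated", call. = FALSE)
  # bytes are stored row-major per image; fill rows of X in file order
  X <- matrix(raw_px / 255, nrow = n, ncol = nr * nc, byrow = TRUE)
  idx_test <- if (n_test > 0) seq.int(n - n_test + 1L, n) else integer()
  structure(
    list(X_train = X[setdiff(seq_len(n), idx_test), , drop = FALSE],
         y_train = y[setdiff(seq_len(n), idx_test)],
         X_test = X[idx_test, , drop = FALSE], y_test = y[idx_test],
         prototypes = NULL, n_classes = as.integer(n_classes),
         noise_sd = NA_real_),
    class = "anvn_dataset"
  )
}

#' Write samples to an IDX image/label file pair
#'
#' Inverse of [read_idx()]: features in `[0,1]` are scaled to bytes and
#' written with the big-endian IDX headers. Mainly for round-trip tests and
#' interoperability.
#'
#' @param X Sample matrix (rows) with features in `[0,1]`; the feature
#'   count must be a perfect square or `nrow_px`/`ncol_px` given.
#' @param y Integer labels.
#' @param images_path,labels_path Output paths.
#' @param nrow_px,ncol_px Image dimensions (default: square root of the
#'   feature count).
#' @return Invisibly, the image path.
#' @export
write_idx <- function(X, y, images_path, labels_path,
                      nrow_px = NULL, ncol_px = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) != length(y)) {
    stop("image/label count mismatch", call. = FALSE)
  }
  if (is.null(nrow_px)) {
    s <- sqrt(ncol(X))
    if (s != floor(s)) {
      stop("feature count is not square; give `nrow_px`/`ncol_px`",
           call. = FALSE)
    }
    nrow_px <- ncol_px <- as.integer(s)
  }
  img <- file(images_path, "wb")
  on.exit(close(img), add = TRUE)
  writeBin(c(2051L, nrow(X), nrow_px, ncol_px), img, size = 4,
           endian = "big")
  writeBin(as.integer(round(t(X) * 255)), img, size = 1)
  lab <- file(labels_path, "wb")
  on.exit(close(lab), add = TRUE)
  writeBin(c(2049L, length(y)), lab, size = 4, endian = "big")
  writeBin(as.integer(y), lab, size = 1)
  invisible(images_path)
}

#' Export a dataset's splits as CSV files
#'
#' Writes `train.csv` and `test.csv` (label column first, then features)
#' into a directory.
#'
#' @param data An `anvn_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset_csv <- function(data, dir) {
  stopifnot(inherits(data, "anvn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(X, y, path) {
    df <- data.frame(label = y, X)
    utils::write.csv(df, path, row.names = FALSE)
  }
  dump(data$X_train, data$y_train, file.path(dir, "train.csv"))
  if (nrow(data$X_test) > 0) {
    dump(data$X_test, data$y_test, file.path(dir, "test.csv"))
  }
  invisible(dir)
}
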