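#' Filter genes expressed in too few cells
#'
#' Removes genes with nonzero counts in strictly fewer than
#' `min_fraction * n_cells` cells. The removed gene symbols are attached as
#' the `"removed_genes"` attribute so downstream marker analysis can return
#' to the full matrix (the filter is temporary, for embedding only).
#'
#' @param matrix Genes-by-cells count matrix.
#' @param min_fraction Minimum expressing-cell fraction (default 0.01).
#' @return The filtered matrix, with `attr(, "removed_genes")`.
#' @export
filter_rare_genes <- function(matrix, min_fraction = 0.01) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  n_expr <- Matrix::rowSums(matrix > 0)
  keep <- n_expr >= min_fraction * ncol(matrix)  # strict "fewer than" removed
  if (!any(keep)) abort("rare-gene filter removed every gene")
  out <- matrix[keep, , drop = FALSE]
  attr(out, "removed_genes") <- rownames(matrix)[!keep]
  out
}

#' Median-library normalisation with log1p transform
#'
#' Scales each cell's counts to the median library size of the matrix, then
#' applies `log(1 + x)`. Deterministic; this is the expression scale used for
#' autoencoder training and marker testing.
#'
#' @param matrix Genes-by-cells count matrix.
#' @return Dense genes-by-cells numeric matrix of normalised values, with the
#'   per-cell size factors in `attr(, "size_factors")`.
#' @export
normalize_counts <- function(matrix) {
  lib <- Matrix::colSums(matrix)
  if (any(lib == 0)) {
    abort(paste0("cells with zero total counts: ",
                 paste(head(colnames(matrix)[lib == 0], 5L), collapse = ", ")))
  }
  sf <- lib / median(lib)
  out <- as.matrix(matrix) / rep(sf, each = nrow(matrix))
  out <- log1p(out)
  attr(out, "size_factors") <- sf
  out
}

#' Train the three-layer autoencoder
#'
#' Compresses normalised expression into a low-dimensional embedding with a
#' three-layer network: input, a single embedded layer of `latent_dim` units
#' (default 10), and a reconstructed output. The encoder applies `activation`
#' (tanh or linear); the decoder is linear. Training minimises mean squared
#' reconstruction error by full-batch Adam gradient descent for a fixed
#' number of epochs (no early stopping), so a run is fully reproducible from
#' `(X, hyperparameters, seed)`.
#'
#' @param X Normalised matrix, genes x cells (as from [normalize_counts()])
#'   or cells x features; cells are detected as the dimension matching
#'   `cell_dim` ("cols" keeps genes-as-rows input).
#' @param latent_dim Embedding width (default 10).
#' @param epochs Fixed epoch count (default 500).
#' @param learning_rate Adam step size (default 1e-2).
#' @param activation `"tanh"` or `"linear"` encoder nonlinearity.
#' @param scale_genes Standardise each gene (feature) to zero mean and unit
#'   variance before training (default TRUE), so reconstruction error weighs
#'   informative moderately-expressed genes on a par with abundant ones. The
#'   centring/scaling vectors are stored in the model and re-applied by
#'   [encode()].
#' @param seed Integer seed for weight initialisation.
#' @param cell_dim `"cols"` (default, genes x cells) or `"rows"`.
#' @return An `autoencoder` object: encoder/decoder weights, the per-epoch
#'   training loss log, and metadata.
#' @export
train_autoencoder <- function(X, latent_dim = 10L, epochs = 500L,
                              learning_rate = 1e-2,
                              activation = c("tanh", "linear"),
                              scale_genes = TRUE,
                              seed = 1L, cell_dim = c("cols", "rows")) {
  activation <- match.arg(activation)
  cell_dim <- match.arg(cell_dim)
  X <- as.matrix(X)
  if (cell_dim == "cols") X <- t(X)  # internally cells x features
  if (!all(is.finite(X))) abort("non-finite values in autoencoder input")
  n <- nrow(X); p <- ncol(X)
  if (n <= latent_dim) abort("need more cells than latent dimensions")
  stopifnot(latent_dim >= 1L, epochs >= 1L)
  if (scale_genes) {
    centre <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, centre, "-"), 2L, scl, "/")
  } else {
    centre <- NULL; scl <- NULL
  }

  set.seed(derive_seed(seed, "autoencoder_init"))
  sc1 <- sqrt(1 / p); sc2 <- sqrt(1 / latent_dim)
  W1 <- matrix(rnorm(p * latent_dim, sd = sc1), p, latent_dim)
  b1 <- numeric(latent_dim)
  W2 <- matrix(rnorm(latent_dim * p, sd = sc2), latent_dim, p)
  b2 <- numeric(p)

  init <- .ae_train_adam(X, W1, b1, W2, b2, as.integer(epochs),
                         learning_rate, activation == "tanh")
  W1 <- init$W1; b1 <- drop(init$b1); W2 <- init$W2; b2 <- drop(init$b2)
  loss_log <- drop(init$loss)

  structure(list(
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    centre = centre, scale = scl,
    activation = activation, latent_dim = as.integer(latent_dim),
    input_dim = p, feature_names = colnames(X),
    training_log = tibble(epoch = seq_len(epochs), loss = loss_log),
    seed = as.integer(seed), learning_rate = learning_rate
  ), class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> %d -> %d -> %d (%s encoder), %d epochs, final MSE %.4g\n",
              x$input_dim, x$latent_dim, x$input_dim, x$activation,
              nrow(x$training_log), tail_loss(x)))
  invisible(x)
}

tail_loss <- function(model) model$training_log$loss[nrow(model$training_log)]

#' Tidy the training log of an autoencoder
#'
#' @param x An `autoencoder`.
#' @param ... Unused.
#' @return Tibble with `epoch` and reconstruction `loss`.
#' @method tidy autoencoder
#' @export
tidy.autoencoder <- function(x, ...) x$training_log

#' One-row summary of an autoencoder fit
#'
#' @param x An `autoencoder`.
#' @param ... Unused.
#' @return Tibble: input_dim, latent_dim, activation, epochs, initial and
#'   final reconstruction MSE.
#' @method glance autoencoder
#' @export
glance.autoencoder <- function(x, ...) {
  tibble(input_dim = x$input_dim, latent_dim = x$latent_dim,
         activation = x$activation, epochs = nrow(x$training_log),
         initial_loss = x$training_log$loss[1L], final_loss = tail_loss(x))
}

#' Encode cells into the autoencoder embedding
#'
#' Deterministic forward pass through the encoder half only.
#'
#' @param model An `autoencoder`.
#' @param X Matrix on the same scale and gene set as training input
#'   (genes x cells by default, see `cell_dim`).
#' @param cell_dim `"cols"` or `"rows"`, as in [train_autoencoder()].
#' @return Cells-by-latent_dim embedding matrix, rownames = cell ids.
#' @export
encode <- function(model, X, cell_dim = c("cols", "rows")) {
  cell_dim <- match.arg(cell_dim)
  X <- as.matrix(X)
  if (cell_dim == "cols") X <- t(X)
  if (ncol(X) != model$input_dim) {
    abort(sprintf("input has %d features but model expects %d", ncol(X), model$input_dim))
  }
  if (!is.null(model$centre)) {
    X <- sweep(sweep(X, 2L, model$centre, "-"), 2L, model$scale, "/")
  }
  act <- if (model$activation == "tanh") tanh else identity
  H <- act(sweep(X %*% model$W1, 2L, model$b1, "+"))
  colnames(H) <- paste0("dim", seq_len(model$latent_dim))
  H
}

#' Serialise an autoencoder to a flat-text container
#'
#' Writes a JSON file holding metadata (latent_dim, activation, seed) and the
#' flattened weight arrays, readable with [read_autoencoder()].
#'
#' @param model An `autoencoder`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_autoencoder <- function(model, path) {
  obj <- list(
    latent_dim = model$latent_dim, activation = model$activation,
    seed = model$seed, input_dim = model$input_dim,
    feature_names = model$feature_names,
    W1 = as.numeric(model$W1), b1 = model$b1,
    W2 = as.numeric(model$W2), b2 = model$b2,
    centre = model$centre, scale = model$scale,
    training_loss = model$training_log$loss
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a serialised autoencoder
#'
#' @param path Path written by [write_autoencoder()].
#' @return An `autoencoder`.
#' @export
read_autoencoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$input_dim; k <- obj$latent_dim
  structure(list(
    W1 = matrix(obj$W1, p, k), b1 = obj$b1,
    W2 = matrix(obj$W2, k, p), b2 = obj$b2,
    centre = obj$centre, scale = obj$scale,
    activation = obj$activation, latent_dim = as.integer(k), input_dim = p,
    feature_names = obj$feature_names,
    training_log = tibble(epoch = seq_along(obj$training_loss),
                          loss = obj$training_loss),
    seed = as.integer(obj$seed), learning_rate = NA_real_
  ), class = "autoencoder")
}
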