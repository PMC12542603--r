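test_that("rare-gene filter applies a strict fewer-than rule", {
  set.seed(1)
  m <- matrix(0L, 5, 100,
              dimnames = list(paste0("G", 1:5), paste0("c", 1:100)))
  m[1, ] <- 5L                    # ubiquitous
  m[2, 1] <- 1L                   # exactly 1% of 100 cells -> retained
  m[3, 1:3] <- 2L                 # 3%
  # G4, G5 all-zero -> removed
  out <- filter_rare_genes(Matrix::Matrix(m, sparse = TRUE), 0.01)
  expect_identical(rownames(out), c("G1", "G2", "G3"))
  expect_setequal(attr(out, "removed_genes"), c("G4", "G5"))
  expect_error(filter_rare_genes(Matrix::Matrix(m[4:5, ], sparse = TRUE)),
               "every gene")
})

test_that("rare-gene filter agrees with an independent recount", {
  co <- small_cohort()
  thr <- 0.05
  out <- filter_rare_genes(co$counts, thr)
  frac <- apply(as.matrix(co$counts), 1L, function(r) mean(r > 0))
  expect_setequal(rownames(out), names(frac)[frac >= thr])
})

test_that("normalisation scales to median library and is scale invariant", {
  m <- toy_counts()[, 1:3]  # avoid the zero-count cell4? keep cells with counts
  m <- m[, Matrix::colSums(m) > 0]
  norm <- normalize_counts(m)
  # equal library sizes: scaling is the identity
  eq <- Matrix::Matrix(matrix(c(2, 0, 1, 1, 2, 0), 3, 2,
                              dimnames = list(c("A", "B", "C"), c("x", "y"))),
                       sparse = TRUE)
  expect_equal(unname(as.matrix(normalize_counts(eq))),
               unname(log1p(as.matrix(eq))), ignore_attr = TRUE)
  # doubling all counts of one cell leaves its normalised profile unchanged
  # (median library pinned by the other cells)
  five <- matrix(c(4, 3, 3, 4, 4, 3, 4, 3, 1, 1), 2, 5,
                 dimnames = list(c("A", "B"), paste0("c", 1:5)))
  doubled <- five; doubled[, "c5"] <- doubled[, "c5"] * 2
  expect_equal(normalize_counts(Matrix::Matrix(doubled, sparse = TRUE))[, "c5"],
               normalize_counts(Matrix::Matrix(five, sparse = TRUE))[, "c5"],
               tolerance = 1e-12)
  # direct recomputation
  lib <- Matrix::colSums(m)
  ref <- log1p(t(t(as.matrix(m)) / (lib / median(lib))))
  expect_equal(unname(as.matrix(norm)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-total cell is a hard error naming the barcode
  z <- cbind(as.matrix(eq), bad = c(0, 0, 0))
  expect_error(normalize_counts(Matrix::Matrix(z, sparse = TRUE)), "bad")
})

test_that("autoencoder recovers a noiseless low-rank matrix", {
  set.seed(3)
  n <- 300; p <- 40; k <- 6
  X <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * p), k, p)
  m <- train_autoencoder(X, latent_dim = 10L, epochs = 800L,
                         activation = "linear", scale_genes = FALSE,
                         seed = 2L, cell_dim = "rows")
  expect_lt(glance(m)$final_loss, 0.01 * mean(X^2))
  # loss log shape
  expect_identical(nrow(tidy(m)), 800L)
  expect_lte(glance(m)$final_loss, glance(m)$initial_loss)
})

test_that("training is deterministic and defaults to 10 latent dimensions", {
  set.seed(4)
  X <- matrix(rnorm(80 * 15), 15, 80)  # genes x cells
  a <- train_autoencoder(X, epochs = 50L, seed = 9L)
  b <- train_autoencoder(X, epochs = 50L, seed = 9L)
  expect_identical(a$W1, b$W1)
  expect_identical(a$training_log, b$training_log)
  expect_identical(a$latent_dim, 10L)
  c2 <- train_autoencoder(X, epochs = 50L, seed = 10L)
  expect_false(identical(a$W1, c2$W1))
})

test_that("encode is a deterministic row-wise map", {
  set.seed(5)
  X <- matrix(rnorm(60 * 12), 12, 60,
              dimnames = list(paste0("g", 1:12), paste0("c", 1:60)))
  m <- train_autoencoder(X, latent_dim = 4L, epochs = 30L, seed = 1L)
  emb <- encode(m, X)
  expect_identical(dim(emb), c(60L, 4L))
  # permuting cells permutes rows identically
  perm <- sample(60)
  expect_equal(unname(encode(m, X[, perm])), unname(emb[perm, ]))
  # duplicated cells map to identical embeddings
  dup <- X[, c(1, 1)]
  e2 <- encode(m, dup)
  expect_equal(e2[1, ], e2[2, ])
  expect_error(encode(m, X[1:5, ]), "features")
})

test_that("serialised models reproduce embeddings exactly", {
  set.seed(6)
  X <- matrix(rnorm(50 * 8), 8, 50,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:50)))
  m <- train_autoencoder(X, latent_dim = 3L, epochs = 20L, seed = 3L)
  f <- withr::local_tempfile(fileext = ".json")
  write_autoencoder(m, f)
  m2 <- read_autoencoder(f)
  expect_equal(encode(m2, X), encode(m, X))
  expect_identical(m2$latent_dim, m$latent_dim)
  expect_identical(m2$activation, m$activation)
})

test_that("embedding separates cell types on synthetic data", {
  co <- small_cohort()
  keep <- filter_rare_genes(suppressMessages(exclude_genes(co$counts)))
  norm <- normalize_counts(keep)
  m <- train_autoencoder(norm, epochs = 200L, seed = 1L)
  emb <- encode(m, norm)
  types <- co$annotation$cell_type
  set.seed(7)
  idx <- sample(nrow(emb), 400)
  d <- as.matrix(stats::dist(emb[idx, ]))
  same <- outer(types[idx], types[idx], "==")
  diag(same) <- NA
  between <- mean(d[!same & !is.na(same)])
  within <- mean(d[same & !is.na(same)])
  expect_gt(between, within)
})
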