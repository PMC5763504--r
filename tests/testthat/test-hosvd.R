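rel_err <- function(a, b) fnorm(a - b) / fnorm(b)

test_that("a rank-1 tensor concentrates the core in one entry", {
  u <- c(3, 4) / 5
  v <- c(1, 2, 2) / 3
  w <- c(2, 1, 2) / 3
  x <- dense_tensor(outer(outer(u, v), w))
  fit <- hosvd(x)
  core <- abs(fit$core)
  expect_equal(core[1, 1, 1], 1, tolerance = 1e-10)
  core[1, 1, 1] <- 0
  expect_lt(max(core), 1e-10)
})

test_that("mode factors match an independent eigendecomposition oracle", {
  for (dims in list(c(3, 4, 5), c(2, 3, 2, 2))) {
    x <- seeded_tensor(dims, seed = sum(dims))
    fit <- hosvd(x)
    for (k in seq_along(dims)) {
      M <- unfold(x, k)
      eig <- eigen(tcrossprod(M), symmetric = TRUE)
      r <- ncol(fit$factors[[k]])
      for (j in seq_len(r)) {
        # compare up to sign, column by column (eigenvalues are distinct
        # with probability 1 for these seeds)
        a <- fit$factors[[k]][, j]
        b <- eig$vectors[, j]
        expect_lt(min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))), 1e-8)
      }
    }
  }
})

test_that("full HOSVD reconstructs the tensor and conserves its norm", {
  x <- seeded_tensor(c(5, 6, 7), seed = 42)
  fit <- hosvd(x)
  expect_lt(rel_err(reconstruct(fit), x), 1e-10)
  expect_lt(abs(fnorm(fit$core) - fnorm(x)) / fnorm(x), 1e-8)
})

test_that("factors are orthonormal and core slices are all-orthogonal", {
  x <- seeded_tensor(c(4, 3, 5), seed = 9)
  fit <- hosvd(x)
  for (k in 1:3) {
    u <- fit$factors[[k]]
    expect_lt(max(abs(crossprod(u) - diag(ncol(u)))), 1e-10)
    # all-orthogonality: distinct slices along mode k have zero inner
    # product; rows of the mode-k core unfolding are mutually orthogonal
    g <- tcrossprod(unfold(fit$core, k))
    off <- g - diag(diag(g))
    expect_lt(max(abs(off)) / fnorm(fit$core)^2, 1e-8)
  }
})

test_that("on a matrix the core diagonal reproduces the singular values", {
  set.seed(5)
  m <- matrix(rnorm(20), 4, 5)
  fit <- hosvd(dense_tensor(m))
  sv <- svd(m)$d
  expect_equal(abs(diag(fit$core[, 1:4])), sv, tolerance = 1e-10)
  off <- fit$core
  off[cbind(1:4, 1:4)] <- 0
  expect_lt(max(abs(off)), 1e-10)
})

test_that("negating a factor column and its core slice leaves the
           reconstruction unchanged", {
  x <- seeded_tensor(c(3, 4, 5), seed = 8)
  fit <- hosvd(x)
  flipped <- fit
  flipped$factors[[2]][, 3] <- -flipped$factors[[2]][, 3]
  idx <- slice.index(flipped$core, 2) == 3
  flipped$core[idx] <- -flipped$core[idx]
  expect_lt(rel_err(reconstruct(flipped), reconstruct(fit)), 1e-12)
})

test_that("reconstruct matches a naive quintuple-loop summation", {
  x <- seeded_tensor(c(2, 3, 2), seed = 13)
  fit <- hosvd(x)
  naive <- array(0, dim(x))
  dcore <- dim(fit$core)
  for (l1 in seq_len(dcore[1])) for (l2 in seq_len(dcore[2])) {
    for (l3 in seq_len(dcore[3])) {
      naive <- naive + fit$core[l1, l2, l3] *
        outer(outer(fit$factors[[1]][, l1], fit$factors[[2]][, l2]),
              fit$factors[[3]][, l3])
    }
  }
  expect_lt(rel_err(naive, x), 1e-12)
})

test_that("reconstruct handles degenerate cores and identity factors", {
  zero <- structure(list(core = array(0, c(2, 2, 2)),
                         factors = replicate(3, diag(2), simplify = FALSE),
                         mode_names = paste0("m", 1:3),
                         mode_categories = replicate(3, c("1", "2"),
                                                     simplify = FALSE),
                         dims = c(2L, 2L, 2L)),
                    class = "td_hosvd")
  expect_true(all(reconstruct(zero) == 0))
  set.seed(2)
  zero$core <- array(rnorm(8), c(2, 2, 2))
  expect_equal(as.numeric(reconstruct(zero)), as.numeric(zero$core))
  bad <- zero
  bad$factors[[2]] <- diag(3)
  expect_error(reconstruct(bad), "core dimension")
})

test_that("rank_core orders a diagonal core by absolute value", {
  fit <- structure(list(core = array(0, c(3, 3, 3)),
                        factors = replicate(3, diag(3), simplify = FALSE),
                        mode_names = c("gene", "tissue", "treatment"),
                        mode_categories = replicate(3, as.character(1:3),
                                                    simplify = FALSE),
                        dims = c(3L, 3L, 3L)),
                   class = "td_hosvd")
  fit$core[cbind(1:3, 1:3, 1:3)] <- c(3, -5, 1)
  top <- rank_core(fit, n = 3)
  expect_equal(top$l_gene, c(2L, 1L, 3L))
  expect_equal(top$value, c(-5, 3, 1))
})

test_that("rank_core agrees with an exhaustive sort and honours fixed
           indices", {
  x <- seeded_tensor(c(3, 4, 2), seed = 77,
                     mode_names = c("gene", "tissue", "treatment"))
  fit <- hosvd(x)
  ranked <- rank_core(fit)
  # independent oracle: flatten all entries and sort
  grid <- expand.grid(l1 = 1:3, l2 = 1:4, l3 = 1:2)
  vals <- mapply(function(a, b, c) fit$core[a, b, c],
                 grid$l1, grid$l2, grid$l3)
  ord <- order(-abs(vals), grid$l1, grid$l2, grid$l3)
  expect_equal(ranked$value, vals[ord])
  expect_equal(ranked$l_gene, grid$l1[ord])

  fixed <- rank_core(fit, fixed = list(tissue = 2))
  expect_true(all(fixed$l_tissue == 2L))
  expect_equal(nrow(fixed), 3L * 2L)
  expect_true(all(diff(abs(fixed$value)) <= 1e-12))
  expect_error(rank_core(fit, fixed = list(tissue = 9)), "out of range")
})

test_that("find_contrast_vector picks the matching column with
           deterministic ties", {
  base <- structure(list(core = array(0, c(2, 2)),
                         factors = list(diag(2), diag(2)),
                         mode_names = c("gene", "treatment"),
                         mode_categories = list(c("g1", "g2"),
                                                c("control", "stress")),
                         dims = c(2L, 2L)),
                    class = "td_hosvd")
  # identity columns score equally against (1, -1): tie -> lowest index
  expect_equal(find_contrast_vector(base, 2, c(1, -1)), 1L)
  base$factors[[2]] <- cbind(c(1, 1), c(1, -1)) / sqrt(2)
  expect_equal(find_contrast_vector(base, 2, c(1, -1)), 2L)
  expect_equal(find_contrast_vector(base, "treatment", c(1, 1)), 1L)
  expect_error(find_contrast_vector(base, 2, c(1, -1, 0)),
               "must equal the mode dimension")
})

test_that("a built-in additive treatment effect yields an opposite-sign
           treatment vector", {
  set.seed(31)
  x <- array(rnorm(200 * 2 * 4), c(200, 2, 4))
  x[1:40, 2, ] <- x[1:40, 2, ] + 3  # treated level shifted for some genes
  fit <- hosvd(dense_tensor(x, c("gene", "treatment", "tissue")))
  l1 <- find_contrast_vector(fit, "treatment", c(1, -1))
  v <- fit$factors[[2]][, l1]
  expect_lt(v[1] * v[2], 0)
})
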