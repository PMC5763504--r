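test_that("a gene with zero components scores S = 0, p = 1", {
  set.seed(1)
  u <- matrix(rnorm(300), 100, 3)
  u[7, ] <- 0
  res <- score_genes(u, omega_set(1:3))
  expect_equal(res$statistic[7], 0)
  expect_equal(res$p_raw[7], 1)
  expect_true(all(res$statistic >= 0))
})

test_that("single-vector statistic is calibrated against a Monte-Carlo
           oracle", {
  set.seed(2)
  u <- matrix(rnorm(2000), 2000, 1)
  res <- score_genes(u, omega_set(1))
  sigma <- sd(u[, 1])
  i <- which.min(abs(u[, 1] - sigma))  # component closest to sigma
  expect_equal(res$statistic[i], (u[i, 1] / sigma)^2, tolerance = 1e-12)
  # MC oracle for the upper tail of chi^2_1 at 1
  set.seed(3)
  draws <- rnorm(1e6)^2
  mc <- mean(draws > 1)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(pchisq(1, 1, lower.tail = FALSE) - mc), 3 * se)
})

test_that("p_raw is strictly decreasing in the statistic", {
  set.seed(4)
  u <- matrix(rnorm(500), 100, 5)
  res <- score_genes(u, omega_set(1:5))
  ord <- order(res$statistic)
  expect_true(all(diff(res$p_raw[ord]) <= 0))
  distinct <- diff(res$statistic[ord]) > 1e-12
  expect_true(all(diff(res$p_raw[ord])[distinct] < 0))
})

test_that("score_genes rejects degenerate inputs", {
  u <- cbind(rnorm(10), rep(1, 10))
  expect_error(score_genes(u, omega_set(2)), "zero variance")
  expect_error(score_genes(u, omega_set(5)), "exceeds the gene factor rank")
  expect_error(omega_set(integer(0)), "non-empty")
  expect_error(omega_set(c(1, 1)), "distinct")
})

test_that("BH step-up reproduces the hand-derived example and caps at 1", {
  expect_equal(adjust_pvalues(c(0.001, 0.01, 0.02, 0.5)),
               c(0.004, 0.02, 2 / 75, 0.5), tolerance = 1e-12)
  expect_equal(adjust_pvalues(rep(0.03, 5)), rep(0.03, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted P-values never fall below raw ones", {
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(50)
    expect_true(all(adjust_pvalues(p) >= p))
  }
})

test_that("experimental local FDR behaves like an fdr on its inputs", {
  set.seed(6)
  p_null <- runif(500)
  f_null <- adjust_pvalues(p_null, "local-fdr")
  expect_true(all(f_null >= 0 & f_null <= 1))
  expect_gt(mean(f_null), 0.8)  # pure null: fdr near 1 almost everywhere
  p_mix <- c(rbeta(100, 0.1, 10), runif(900))
  f_mix <- adjust_pvalues(p_mix, "local-fdr")
  expect_lt(mean(f_mix[order(p_mix)[1:50]]), 0.5)
  # non-decreasing in p
  expect_true(all(diff(f_mix[order(p_mix)]) >= 0))
})

test_that("selection uses a strict threshold and preserves gene order", {
  set.seed(7)
  u <- matrix(rnorm(600), 200, 3)
  res <- adjust_pvalues(score_genes(u, omega_set(1:3)))
  res$p_adjusted <- rep(0.5, 200)
  sel <- select_genes(res, 0.01)
  expect_length(selected_genes(sel), 0)
  # a tie exactly at the threshold is excluded
  res$p_adjusted[c(1, 2)] <- c(0.01, 0.0099)
  sel <- select_genes(res, 0.01)
  expect_equal(selected_genes(sel), "g2")
  expect_error(select_genes(res, 1.5), "in \\(0, 1\\)")
})

test_that("selection is invariant to sign flips of omega vectors", {
  set.seed(8)
  u <- matrix(rnorm(1000), 200, 5)
  a <- select_genes(adjust_pvalues(score_genes(u, omega_set(1:3))), 0.05)
  u[, 2] <- -u[, 2]
  b <- select_genes(adjust_pvalues(score_genes(u, omega_set(1:3))), 0.05)
  expect_identical(selected_genes(a), selected_genes(b))
})

test_that("permuting gene rows permutes the selection identically", {
  set.seed(9)
  u <- matrix(rnorm(500), 100, 5)
  rownames(u) <- paste0("gene", 1:100)
  a <- select_genes(adjust_pvalues(score_genes(u, omega_set(1:4))), 0.2)
  perm <- sample(100)
  b <- select_genes(adjust_pvalues(score_genes(u[perm, ], omega_set(1:4))),
                    0.2)
  expect_setequal(selected_genes(a), selected_genes(b))
})

test_that("with zero-mean orthonormal vectors the statistic is a function
           of row norms", {
  set.seed(10)
  raw <- matrix(rnorm(300 * 4), 300, 4)
  raw <- sweep(raw, 2, colMeans(raw))   # zero-mean columns
  q <- qr.Q(qr(raw))                    # orthonormal, still zero-mean
  expect_lt(max(abs(colMeans(q))), 1e-12)
  res <- score_genes(q, omega_set(1:4))
  rn <- rowSums(q^2)
  expect_equal(order(res$statistic), order(rn))
  expect_equal(res$statistic / max(res$statistic), rn / max(rn),
               tolerance = 1e-10)
})

test_that("raw P-values are uniform under an i.i.d. normal gene factor", {
  set.seed(11)
  u <- matrix(rnorm(20000 * 3), 20000, 3)
  res <- score_genes(u, omega_set(1:3))
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 20000)
    expect_lt(abs(mean(res$p_raw < alpha) - alpha), 3 * se)
  }
})

test_that("BH keeps the selected fraction at the nominal level on
           pure-noise tensors", {
  frac <- vapply(1:20, function(seed) {
    spec <- synthetic_spec(n_genes = 400, n_tissues = 5, n_treatments = 5,
                           sets = 5, genes_per_set = 20,
                           tissues_per_set = 2, signal_mean = 0,
                           seed = 100 + seed)
    sim <- generate_synthetic(spec)
    fit <- hosvd(sim$tensor)
    sel <- select_genes(
      adjust_pvalues(score_genes(fit$factors[[1]], omega_set(1:5))), 0.01)
    mean(sel$selected)
  }, numeric(1))
  se <- sd(frac) / sqrt(20)
  expect_lte(mean(frac), 0.01 + 3 * max(se, 1e-4))
})

test_that("choose_omega walks the ranked core collecting distinct gene
           vectors", {
  fit <- structure(list(core = array(0, c(4, 3, 3)),
                        factors = list(diag(4), diag(3), diag(3)),
                        mode_names = c("gene", "tissue", "treatment"),
                        mode_categories = list(as.character(1:4),
                                               as.character(1:3),
                                               as.character(1:3)),
                        dims = c(4L, 3L, 3L)),
                   class = "td_hosvd")
  fit$core[cbind(1:3, 1:3, 1:3)] <- c(2, -7, 4)
  om <- choose_omega(fit, n_vectors = 2, gene_mode = "gene")
  expect_equal(om$indices, c(2L, 3L))
  expect_equal(om$provenance, "core-ranked")
  # the full core enumeration always offers every gene index; only
  # requests beyond the gene-mode rank can fail
  expect_error(choose_omega(fit, n_vectors = 5), "distinct gene-mode")

  x <- seeded_tensor(c(5, 3, 4), seed = 21,
                     mode_names = c("gene", "tissue", "treatment"))
  hf <- hosvd(x)
  om2 <- choose_omega(hf, n_vectors = 3, gene_mode = "gene")
  # exhaustive oracle
  ranked <- rank_core(hf)
  expect_equal(om2$indices, unique(ranked$l_gene)[1:3])
})
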