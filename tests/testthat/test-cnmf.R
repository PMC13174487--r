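test_that("an exact rank-2 matrix is recovered at k = 2", {
  set.seed(1)
  h <- rbind(c(runif(10), rep(0, 10)), c(rep(0, 10), runif(10)))
  w <- matrix(runif(80), 40, 2)
  x <- t(w %*% h)
  rownames(x) <- sprintf("G%02d", 1:20); colnames(x) <- sprintf("C%02d", 1:40)
  fit <- fit_cnmf(x, k_grid = 2, n_restarts = 5, seed = 3, k = 2,
                  maxit = 2000, tol = 1e-13)
  mod <- fit$models[["2"]]
  expect_lt(mod$error, 1e-6)
  expect_true(all(match_cosines(h, mod$loadings) >= 0.99))
})

test_that("k = 1 consensus matches the best rank-1 approximation", {
  set.seed(2)
  x <- matrix(rexp(30 * 20), 30, 20)
  rownames(x) <- sprintf("G%02d", 1:30); colnames(x) <- sprintf("C%02d", 1:20)
  fit <- fit_cnmf(x, k_grid = 1, n_restarts = 4, seed = 5, k = 1,
                  maxit = 3000, tol = 1e-14)
  # closed-form oracle: leading singular pair (nonnegative by Perron-
  # Frobenius on a positive matrix)
  sv <- svd(x)
  best_err <- sqrt(sum((x - sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1]))^2)) /
    sqrt(sum(x^2))
  expect_lt(abs(fit$models[["1"]]$error - best_err), 1e-8)
})

test_that("the published preset pins 13 factors", {
  expect_identical(cnmf_paper_preset()$k, 13L)
  set.seed(3)
  x <- matrix(rexp(40 * 30), 40, 30)
  rownames(x) <- sprintf("G%02d", 1:40); colnames(x) <- sprintf("C%02d", 1:30)
  pre <- cnmf_paper_preset()
  fit <- fit_cnmf(x, k_grid = pre$k, n_restarts = 3, seed = 1, k = pre$k,
                  maxit = 100)
  expect_identical(fit$selected_k, 13L)
})

test_that("consensus reconstruction error does not exceed the worst restart", {
  for (seed in 1:3) {
    pl <- planted_nmf(3, n = 60, g = 30, seed = seed)
    fit <- fit_cnmf(pl$x, k_grid = 3, n_restarts = 6, seed = seed, k = 3)
    mod <- fit$models[["3"]]
    # restarts stop at a finite HALS tolerance, so allow numerical slop
    expect_lte(mod$error, max(mod$restart_errors) + 1e-6)
  }
})

test_that("nonnegativity and unit-L2 loading rows hold", {
  pl <- planted_nmf(4, n = 50, g = 24, seed = 9)
  fit <- fit_cnmf(pl$x, k_grid = 4, n_restarts = 5, seed = 2, k = 4)
  mod <- fit$models[["4"]]
  expect_true(all(mod$usages >= 0))
  expect_true(all(mod$loadings >= 0))
  expect_equal(unname(sqrt(rowSums(mod$loadings^2))), rep(1, 4),
               tolerance = 1e-8)
})

test_that("anchor similarity matches hand-computed cosines", {
  loadings <- rbind(c(1, 0, 1, 2),
                    c(0, 1, 1, 0),
                    c(2, 0, 0, 1))
  colnames(loadings) <- c("ANCH", "ORTHO", "MIX", "NEAR")
  rk <- anchor_similarity(loadings, "ANCH")
  expect_equal(rk$similarity[rk$gene == "ANCH"], 1)
  expect_equal(rk$similarity[rk$gene == "ORTHO"], 0)
  # brute cosine for the other two columns
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(rk$similarity[rk$gene == "MIX"],
               cosv(loadings[, "ANCH"], loadings[, "MIX"]))
  expect_equal(rk$similarity[rk$gene == "NEAR"],
               cosv(loadings[, "ANCH"], loadings[, "NEAR"]))
  expect_setequal(rk$rank, 1:4)
  expect_error(anchor_similarity(loadings, "ABSENT"), "absent")
})

test_that("anchor ranking breaks similarity ties lexicographically", {
  loadings <- cbind(A = c(1, 0), ZZ = c(1, 0), BB = c(1, 0), X = c(0, 1))
  rk <- anchor_similarity(loadings, "A")
  tied <- rk$gene[rk$similarity == 1]
  expect_equal(tied, sort(tied))
})

test_that("a gene sharing a planted program with the anchor ranks high", {
  # anchor program holds 5 genes; the remaining 95 genes load on two of
  # four other factors each, so the anchor's companions should occupy the
  # top decile of the similarity ranking
  gen <- function(seed) {
    set.seed(seed)
    g <- 100; k <- 5; n <- 120
    h <- matrix(0, k, g)
    h[1, 1:5] <- 1 + runif(5)
    for (j in 6:g) {
      fs <- sample(2:k, 2)
      h[fs, j] <- 1 + runif(2)
    }
    h <- h + matrix(0.02 * runif(k * g), k, g)
    w <- matrix(rexp(n * k), n, k)
    x <- t(w %*% h + matrix(abs(rnorm(n * g, 0, 0.05)), n, g))
    rownames(x) <- sprintf("G%03d", 1:g); colnames(x) <- sprintf("C%03d", 1:n)
    x
  }
  hits <- vapply(1:25, function(s) {
    x <- gen(400 + s)
    fit <- fit_cnmf(x, k_grid = 5, n_restarts = 4, seed = s, k = 5)
    rk <- anchor_similarity(fit$models[["5"]]$loadings, "G001")
    all(rk$rank[rk$gene %in% sprintf("G%03d", 2:5)] <= 10)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
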