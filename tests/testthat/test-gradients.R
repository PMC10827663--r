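test_that("row sparsification keeps the top fraction with index tie-break", {
  set.seed(10)
  block <- matrix(stats::rnorm(180 * 180), 180, 180)
  sp <- sparsify_rows(block, 0.10)
  expect_true(all(rowSums(sp != 0) == 18))
  expect_identical(sparsify_rows(block, 1.0), block)
  # retained values are unchanged
  expect_true(all(sp[sp != 0] == block[sp != 0]))

  # ties at the cutoff resolved by lowest column index, vs sort oracle
  tied <- matrix(rep(c(5, 5, 5, 1, 1, 1), 4), 4, 6, byrow = TRUE)
  tied[2, ] <- c(1, 5, 5, 5, 1, 1)
  expect_equal(sparsify_rows(tied, 0.5), oracle_sparsify(tied, 0.5))
  set.seed(11)
  coarse <- matrix(sample(1:4, 90, replace = TRUE), 9, 10)
  expect_equal(sparsify_rows(coarse, 0.3), oracle_sparsify(coarse, 0.3))

  expect_error(sparsify_rows(matrix(c(1, NA, 2, 3), 2, 2), 0.5),
               "non-finite")
  expect_error(sparsify_rows(block, 0), "density")
})

test_that("normalized-angle affinity matches closed forms and the oracle", {
  # identical rows -> 1; orthogonal non-negative rows -> 0.5
  b <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 1, 0, 1))
  a <- cosine_affinity(b)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0.5)
  expect_equal(diag(a), rep(1, 3))

  set.seed(12)
  r <- matrix(stats::rnorm(36), 6, 6)
  expect_equal(cosine_affinity(r), oracle_affinity(r), tolerance = 1e-12)

  z <- r; z[2, ] <- 0
  expect_error(cosine_affinity(z), "row\\(s\\): 2")
})

test_that("diffusion embedding agrees with the dense eigendecomposition
           oracle up to column sign", {
  for (seed in 1:5) {
    W <- random_affinity(20, seed)
    for (alpha in c(0, 0.5)) {
      g <- diffusion_embedding(W, alpha = alpha, k = 5)
      o <- oracle_diffusion(W, alpha = alpha, k = 5)
      expect_equal(g$eigenvalues, o$values, tolerance = 1e-10)
      for (j in 1:5) {
        u <- g$components[, j] / sqrt(sum(g$components[, j]^2))
        v <- o$vectors[, j] / sqrt(sum(o$vectors[, j]^2))
        expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
      }
    }
  }
})

test_that("embedding is invariant to node relabeling", {
  W <- random_affinity(15, 3)
  g <- diffusion_embedding(W, k = 4)
  set.seed(13)
  perm <- sample(15)
  gp <- diffusion_embedding(W[perm, perm], k = 4)
  for (j in 1:4) {
    a <- g$components[perm, j]
    b <- gp$components[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-10)
  }
})

test_that("the leading gradient separates two weakly coupled communities", {
  set.seed(14)
  n <- 20
  W <- matrix(0.02, n, n)
  W[1:10, 1:10] <- 0.9
  W[11:20, 11:20] <- 0.9
  W <- W + matrix(stats::runif(n * n, 0, 0.02), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  g <- diffusion_embedding(W, k = 3)
  signs <- sign(g$components[, 1])
  expect_true(all(signs[1:10] == signs[1]) &&
                all(signs[11:20] == -signs[1]))
})

test_that("embedding validates its input", {
  W <- random_affinity(10, 4)
  expect_error(diffusion_embedding(W, k = 10), "smaller")
  Wn <- W; Wn[1, 2] <- Wn[1, 2] + 0.5
  expect_error(diffusion_embedding(Wn, k = 3), "symmetric")
  # two disconnected cliques fail by default, embed largest permissively
  W2 <- matrix(0, 9, 9)
  W2[1:5, 1:5] <- 0.8; W2[6:9, 6:9] <- 0.8
  diag(W2) <- 1
  expect_error(diffusion_embedding(W2, k = 2), "disconnected")
  g <- suppressWarnings(
    diffusion_embedding(W2, k = 2, on_disconnected = "largest_component"))
  expect_true(all(is.na(g$components[6:9, ])))
  expect_true(all(is.finite(g$components[1:5, ])))
})

test_that("eigenvalue ordering and variance shares are well-formed", {
  g <- diffusion_embedding(random_affinity(25, 6), k = 8)
  expect_true(all(diff(g$eigenvalues) <= 1e-12))
  expect_true(all(g$variance_explained >= 0 & g$variance_explained <= 1))
  expect_lte(sum(g$variance_explained), 1 + 1e-12)
})

test_that("Procrustes rotation is exact on constructed cases", {
  set.seed(15)
  tmpl <- matrix(stats::rnorm(180 * 5), 180, 5)
  # identity case
  R <- procrustes_rotation(tmpl, tmpl)
  expect_equal(R, diag(5), tolerance = 1e-12)
  # random orthogonal rotation is undone
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5, 5)))
  R2 <- procrustes_rotation(tmpl %*% Q, tmpl)
  expect_lt(norm(tmpl %*% Q %*% R2 - tmpl, "F"), 1e-8)
  # single negated column produces a sign flip
  flipped <- tmpl
  flipped[, 3] <- -flipped[, 3]
  R3 <- procrustes_rotation(flipped, tmpl)
  expect_equal(diag(R3), c(1, 1, -1, 1, 1), tolerance = 1e-8)
})

test_that("alignment preserves the span and resolves sign indeterminacy", {
  W <- random_affinity(30, 7)
  g <- diffusion_embedding(W, k = 6)
  tmpl <- diffusion_embedding(random_affinity(30, 8), k = 6)$components
  al <- align_gradients(g, tmpl)
  # aligned columns are exact linear combinations of raw columns
  proj <- g$components %*% solve(crossprod(g$components),
                                 crossprod(g$components, al$components))
  expect_lt(max(abs(proj - al$components)), 1e-10)
  # repeated runs give identical aligned output
  al2 <- align_gradients(diffusion_embedding(W, k = 6), tmpl)
  expect_identical(al$components, al2$components)
})

test_that("two subjects differing by an orthogonal rotation align
           identically", {
  set.seed(16)
  base <- matrix(stats::rnorm(40 * 6), 40, 6)
  tmpl <- matrix(stats::rnorm(40 * 6), 40, 6)
  Q <- qr.Q(qr(matrix(stats::rnorm(36), 6, 6)))
  a1 <- structure(list(components = base, aligned = FALSE),
                  class = "gradient_set")
  a2 <- structure(list(components = base %*% Q, aligned = FALSE),
                  class = "gradient_set")
  r1 <- align_gradients(a1, tmpl)
  r2 <- align_gradients(a2, tmpl)
  expect_equal(r1$components, r2$components, tolerance = 1e-8)
})

test_that("template building averages connectivity before embedding", {
  set.seed(17)
  tcoord <- (seq_len(40) - 0.5) / 40
  mk <- function(jit) {
    U <- cbind(sqrt(2) * cos(2 * pi * tcoord), sqrt(2) * sin(2 * pi * tcoord),
               sqrt(2) * cos(4 * pi * tcoord)) + jit
    B <- 0.25 + 0.3 * tcrossprod(U)
    diag(B) <- 0
    B
  }
  cfg <- grad_config(n_gradients_computed = 5)
  b1 <- mk(matrix(stats::rnorm(120, 0, 0.05), 40, 3))
  b2 <- mk(matrix(stats::rnorm(120, 0, 0.05), 40, 3))
  tm <- build_template(list(b1, b2), cfg)
  direct <- embed_block((b1 + b2) / 2, cfg)
  expect_equal(tm$components, direct$components)
  # single-subject template equals that subject's embedding
  tm1 <- build_template(list(b1), cfg)
  expect_equal(tm1$components, embed_block(b1, cfg)$components)
  # averaging FC first differs from averaging embeddings
  e_mean <- (embed_block(b1, cfg)$components +
               embed_block(b2, cfg)$components) / 2
  expect_gt(max(abs(tm$components - e_mean)), 1e-6)
  expect_error(build_template(list()), "empty cohort")
})

test_that("templates round-trip through disk with their sidecar", {
  set.seed(18)
  cfg <- grad_config(n_gradients_computed = 4)
  B <- random_affinity(30, 19)
  tm <- build_template(0.2 + 0.5 * B, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_template(tm, path)
  back <- read_template(path)
  expect_equal(back$components, tm$components)
  expect_equal(back$eigenvalues, tm$eigenvalues, tolerance = 1e-12)
})
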