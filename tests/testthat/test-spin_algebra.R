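test_that("expansions follow the singlet-pair product rule", {
  e <- expand_structure(vb_structure(pairs = "1-2"))
  expect_setequal(paste(e$keys, e$coef), c("ab 1", "ba -1"))

  e2 <- expand_structure(vb_structure(pairs = list(c(1, 2), c(3, 4))))
  expect_setequal(paste(e2$keys, e2$coef),
                  c("abab 1", "baab -1", "abba -1", "baba 1"))

  e3 <- expand_structure(vb_structure(pairs = "1-2", unpaired = 3))
  expect_setequal(paste(e3$keys, e3$coef), c("aba 1", "baa -1"))
  expect_equal(length(e2$keys), 2^2)  # 2^(N/2 - S) terms
})

test_that("structure overlaps match hand-computed values", {
  s1 <- vb_structure(pairs = list(c(1, 2), c(3, 4)))
  s2 <- vb_structure(pairs = list(c(1, 4), c(2, 3)))
  expect_equal(structure_overlap(s1, s1, normalize = FALSE), 4)
  expect_equal(structure_overlap(s1, s2, normalize = FALSE), -2)
  expect_equal(structure_overlap(s1, s2), -1/2)
  expect_equal(structure_overlap(s1, s1), 1)
  expect_equal(structure_overlap(s2, s1), structure_overlap(s1, s2))
  expect_error(structure_overlap(s1, vb_structure(pairs = "1-2", unpaired = c(3, 5))),
               "different singly occupied")
})

test_that("gramian verdicts match the frozen small cases", {
  s1 <- vb_structure(pairs = list(c(1, 2), c(3, 4)))
  s2 <- vb_structure(pairs = list(c(1, 4), c(2, 3)))
  s3 <- vb_structure(pairs = list(c(1, 3), c(2, 4)))

  expect_false(gramian(list(s1, s1))$independent)

  g <- gramian(list(s1, s2))
  expect_equal(g$matrix, matrix(c(1, -1/2, -1/2, 1), 2), tolerance = 1e-12)
  expect_equal(sort(g$eigenvalues), c(1/2, 3/2), tolerance = 1e-12)
  expect_true(g$independent)

  expect_false(gramian(list(s1, s2, s3))$independent)
  expect_error(gramian(list(s1, vb_structure(pairs = "1-2", doubly_occupied = 3,
                                             vacant = 4))),
               "different subspaces")
})

test_that("gramian verdict agrees with exact QR rank on whole spaces", {
  cases <- list(c(4, 0), c(4, 2), c(5, 1), c(6, 0), c(6, 2))
  for (cs in cases) {
    N <- cs[1]; two_s <- cs[2]
    sp <- active_space(N, N, two_s / 2)
    sts <- enumerate_structures(sp, subspace = vb_subspace())
    expect_lte(length(sts), 70)
    full_rank_expected <- oracle_rank(sts) == length(sts)
    expect_identical(gramian(sts)$independent, full_rank_expected)
    # random subsets, fixed seed
    set.seed(42)
    for (rep in 1:10) {
      k <- sample(2:min(6, length(sts)), 1)
      sub <- sts[sample(length(sts), k)]
      expect_identical(gramian(sub)$independent, oracle_rank(sub) == k,
                       info = sprintf("N=%d 2S=%d rep=%d", N, two_s, rep))
    }
  }
})

test_that("rank of the full covalent space equals the branching-diagram count", {
  for (cs in list(c(2, 0), c(3, 1), c(4, 0), c(4, 2), c(5, 1), c(6, 0),
                  c(6, 2), c(7, 1), c(8, 0))) {
    N <- cs[1]; two_s <- cs[2]
    sp <- active_space(N, N, two_s / 2)
    sts <- enumerate_structures(sp, subspace = vb_subspace())
    expect_equal(oracle_rank(sts), count_independent(N, two_s / 2),
                 info = sprintf("N=%d 2S=%d", N, two_s))
  }
})

test_that("count_independent reproduces the published set sizes", {
  expect_equal(count_independent(5, 1/2), 5)
  expect_equal(count_independent(8, 0), 14)
  expect_equal(count_independent(4, 1), 3)
  expect_equal(count_independent(2, 0), 1)
  expect_error(count_independent(5, 0), "parity")
})

test_that("sign conventions do not affect overlap magnitudes or verdicts", {
  s1 <- vb_structure(pairs = list(c(1, 2), c(3, 4)))
  s2 <- vb_structure(pairs = list(c(1, 4), c(2, 3)))
  base <- gramian(list(s1, s2))$eigenvalues
  for (ord in list(c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    e1 <- expand_structure(s1, orbital_order = ord)
    e2 <- expand_structure(s2, orbital_order = ord)
    expect_equal(abs(structure_overlap(e1, e2)), 1/2, tolerance = 1e-12)
  }
  expect_equal(sort(base), c(1/2, 3/2), tolerance = 1e-12)
})

test_that("Chirgwin-Coulson weights match closed forms and conserve to 1", {
  expect_equal(chirgwin_coulson_weights(c(0.6, 0.8), diag(2)), c(0.36, 0.64))
  S <- diag(4); S[1, 3] <- S[3, 1] <- 0.2
  expect_equal(chirgwin_coulson_weights(c(1, 0, 0, 0), S), c(1, 0, 0, 0))
  expect_equal(chirgwin_coulson_weights(c(1, 1), matrix(c(1, -0.5, -0.5, 1), 2)),
               c(0.5, 0.5))
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    A <- matrix(rnorm(n * n), n)
    S <- stats::cov2cor(crossprod(A) + diag(n))
    w <- chirgwin_coulson_weights(rnorm(n), S)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(chirgwin_coulson_weights(c(1, 1), matrix(c(1, -1.5, -1.5, 1), 2)),
               "c'Sc")
})
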