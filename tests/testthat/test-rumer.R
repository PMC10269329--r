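test_that("non-crossing predicate matches the pictorial rule", {
  ord4 <- rumer_ordering(1:4)
  expect_true(is_noncrossing(vb_structure(pairs = list(c(1, 2), c(3, 4))), ord4))
  expect_true(is_noncrossing(vb_structure(pairs = list(c(1, 4), c(2, 3))), ord4))
  expect_false(is_noncrossing(vb_structure(pairs = list(c(1, 3), c(2, 4))), ord4))
  # pentagon with one dummy: any structure bonding first and last orbital is
  # forbidden under the sequential ordering
  ord5 <- rumer_ordering(1:5)
  for (other in list(c(2, 3), c(2, 4), c(3, 4))) {
    s <- vb_structure(pairs = list(c(1, 5), other),
                      unpaired = setdiff(1:5, c(1, 5, other)))
    expect_false(is_noncrossing(s, ord5))
  }
  expect_error(is_noncrossing(vb_structure(pairs = "1-2"), ord4),
               "singly occupied")
})

test_that("C5H5 sequential Rumer set is the five known structures", {
  sp <- active_space(5, 5, 1/2)
  set <- generate_rumer_set(sp)
  expect_length(set$structures, 5)
  got <- sort(vapply(set$structures, pkg_struct_string, character(1)))
  want <- sort(vapply(list(
    vb_structure(pairs = list(c(1, 2), c(3, 4)), unpaired = 5),
    vb_structure(pairs = list(c(1, 2), c(4, 5)), unpaired = 3),
    vb_structure(pairs = list(c(2, 3), c(4, 5)), unpaired = 1),
    vb_structure(pairs = list(c(1, 4), c(2, 3)), unpaired = 5),
    vb_structure(pairs = list(c(2, 5), c(3, 4)), unpaired = 1)),
    pkg_struct_string, character(1)))
  expect_identical(got, want)
  expect_true(set$gramian$independent)
  expect_equal(count_distinct_bonds(set), 6)
})

test_that("Rumer set sizes hit the Catalan / branching-diagram limits", {
  # even N, S = 0: Catalan(N/2)
  for (N in c(4, 6, 8)) {
    sp <- active_space(N, N, 0)
    set <- generate_rumer_set(sp)
    expect_length(set$structures, catalan(N / 2))
    expect_true(set$gramian$independent)
  }
  # a non-singlet case
  sp <- active_space(4, 4, 1)
  set <- generate_rumer_set(sp)
  expect_length(set$structures, count_independent(4, 1))
  expect_true(set$gramian$independent)
})

test_that("4 singly occupied, S = 0: exactly the two non-crossing pairings", {
  sp <- active_space(4, 4, 0)
  set <- generate_rumer_set(sp, ordering = rumer_ordering(1:4))
  got <- sort(vapply(set$structures, pkg_struct_string, character(1)))
  want <- sort(vapply(list(
    vb_structure(pairs = list(c(1, 2), c(3, 4))),
    vb_structure(pairs = list(c(1, 4), c(2, 3)))), pkg_struct_string, character(1)))
  expect_identical(got, want)
  expect_equal(count_distinct_bonds(set), 4)
})

test_that("Kekule set of the pentagon uses only five distinct bonds", {
  kek <- kekule_c5h5()
  expect_equal(count_distinct_bonds(kek), 5)
  expect_true(gramian(kek)$independent)  # it is a complete set
})

test_that("odd-difference rule holds for sequential orderings", {
  for (cs in list(c(5, 1), c(6, 0), c(7, 1))) {
    N <- cs[1]
    sp <- active_space(N, N, cs[2] / 2)
    set <- generate_rumer_set(sp)
    for (s in set$structures) {
      if (nrow(s$pairs))
        expect_true(all((s$pairs[, 2] - s$pairs[, 1]) %% 2 == 1),
                    info = sprintf("N=%d: %s", N, pkg_struct_string(s)))
    }
  }
})

test_that("count_rumer_sets matches the closed form and its N = 2 degeneracy", {
  expect_equal(count_rumer_sets(8, r = 8), 2520)
  expect_equal(count_rumer_sets(4, r = 4), 3)
  expect_equal(count_rumer_sets(2, r = 2), 1)
  expect_equal(factorial(8), 40320)  # total orbital numberings for n = 8
})

test_that("distinct-set enumeration equals the closed form for even N", {
  for (N in c(4, 6)) {
    sp <- active_space(N, N, 0)
    sets <- enumerate_distinct_rumer_sets(sp)
    expect_length(sets, count_rumer_sets(N, r = N))
    # every set is a genuine Rumer set: right size and independent
    for (st in sets[seq_len(min(5, length(sets)))]) {
      expect_length(st$structures, count_independent(N, 0))
      expect_true(gramian(st$structures)$independent)
    }
  }
})

test_that("distinct-set enumeration dedupes odd-N orderings to N!/2", {
  sp <- active_space(5, 5, 1/2)
  sets <- enumerate_distinct_rumer_sets(sp)
  expect_length(sets, factorial(5) / 2)
  expect_true(all(vapply(sets, function(st)
    length(st$structures) == 5L, logical(1))))
})

test_that("the ordering guard refuses infeasible enumerations", {
  sp <- active_space(8, 8, 0)
  expect_error(enumerate_distinct_rumer_sets(sp, max_n = 6), "sampling")
})

test_that("every distinct 4e/4o singlet set passes the independence test", {
  sp <- active_space(4, 4, 0)
  sets <- enumerate_distinct_rumer_sets(sp)
  expect_length(sets, 3)
  for (st in sets) expect_true(gramian(st$structures)$independent)
})
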