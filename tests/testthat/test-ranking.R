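test_that("user-bond scores follow N_B - N_UDB + 1", {
  udb <- list(c(1, 2), c(5, 6))
  s_all <- vb_structure(pairs = list(c(1, 2), c(5, 6)), unpaired = c(3, 4))
  s_none <- vb_structure(pairs = list(c(1, 6), c(4, 5)), unpaired = c(2, 3))
  s_one <- vb_structure(pairs = list(c(1, 2), c(4, 5)), unpaired = c(3, 6))
  expect_equal(score_user_bonds(s_all, udb), 1)
  expect_equal(score_user_bonds(s_none, udb), 3)
  expect_equal(score_user_bonds(s_one, list(c(1, 2))), 2)
  expect_error(score_user_bonds(s_all, list()), "nonempty")
})

test_that("user-radical scores follow N_R - N_UDR + 1", {
  expect_equal(score_user_radicals(vb_structure(pairs = "1-2", unpaired = 4,
                                                doubly_occupied = 3), 4), 1)
  expect_equal(score_user_radicals(vb_structure(pairs = "1-2", unpaired = 3), c(4, 6)), 2)
  # singlet structure: no radicals, scores 1 by convention
  expect_equal(score_user_radicals(vb_structure(pairs = list(c(1, 2), c(3, 4))), 1), 1)
})

test_that("intra-atomic and symmetry scores count offending bonds + 1", {
  amap <- c("1" = "H1", "2" = "H2", "3" = "O", "4" = "O", "5" = "O")
  expect_equal(score_intra_atomic(vb_structure(pairs = "1-2", unpaired = c(3, 4),
                                               vacant = 5), amap), 1)
  expect_equal(score_intra_atomic(vb_structure(pairs = "4-5", unpaired = c(1, 2),
                                               vacant = 3), amap), 2)
  expect_equal(score_intra_atomic(vb_structure(pairs = list(c(3, 4)),
                                               doubly_occupied = 5,
                                               unpaired = c(1, 2)), amap), 2)

  labs <- c("1" = "sigma", "2" = "pi", "3" = "pi", "4" = NA)
  expect_equal(score_symmetry(vb_structure(pairs = "2-3", unpaired = c(1, 4)), labs), 1)
  expect_equal(score_symmetry(vb_structure(pairs = "1-3", unpaired = c(2, 4)), labs), 2)
  expect_equal(score_symmetry(vb_structure(unpaired = 1, vacant = c(2, 3, 4),
                                           doubly_occupied = integer()), labs), 1)
})

test_that("bond-length ranking orders by stretch with dense ties", {
  # linear A-B...C: short A-B bond, long A-C bond
  geom <- vbstruct:::make_geometry(data.frame(
    element = c("C", "C", "C"), x = c(0, 1.5, 4), y = 0, z = 0))
  amap <- c("1" = "C1", "2" = "C2", "3" = "C3", "4" = "C1")
  short <- vb_structure(pairs = "1-2", unpaired = c(3, 4))
  long <- vb_structure(pairs = "2-3", unpaired = c(1, 4))
  r <- rank_by_bond_length(list(short, long), geom, amap)
  expect_equal(r$scores, c(1, 2))
  expect_equal(r$d_nab[1], 0)  # 1.5 A within the 1.52 A covalent-radii sum
  # identical bond sets tie at rank 1
  r2 <- rank_by_bond_length(list(short, short), geom, amap)
  expect_equal(r2$scores, c(1, 1))
  # intra-atomic bonds contribute nothing
  intra <- vb_structure(pairs = "1-4", unpaired = c(2, 3))
  expect_equal(vbstruct:::bond_stretch(intra, geom, amap), 0)
})

test_that("pentagon geometry ranks all Kekule structures first", {
  sys <- builtin_system("c5h5")
  sts <- enumerate_structures(sys$space, subspace = vb_subspace())
  r <- rank_by_bond_length(sts, sys$geometry, sys$space)
  kek_keys <- vapply(kekule_c5h5(), pkg_struct_string, character(1))
  is_kek <- vapply(sts, pkg_struct_string, character(1)) %in% kek_keys
  expect_true(all(r$scores[is_kek] == 1))
  expect_true(all(r$scores[!is_kek] > 1))
})

test_that("merge_scores realizes lexicographic order", {
  expect_equal(merge_scores(list(c(3, 1, 2))), c(3, 1, 2))
  expect_equal(merge_scores(list(c(1, 2), c(2, 1))), c(2, 3))
  expect_equal(merge_scores(list(c(1, 1), c(3, 1))), c(3, 1))
  expect_error(merge_scores(list(1:2, 1:3)), "equal length")
  expect_error(merge_scores(list(c(0, 1))), ">= 1")

  set.seed(11)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    n <- sample(2:50, 1)
    tbl <- lapply(seq_len(k), function(i) sample(1:5, n, replace = TRUE))
    unified <- merge_scores(tbl)
    lex <- do.call(order, tbl)
    expect_identical(order(unified), lex,
                     info = sprintf("rep %d (k=%d n=%d)", rep, k, n))
  }
})

test_that("scores are permutation equivariant", {
  perm <- c(3, 1, 4, 2)  # orbital i -> perm[i]
  s <- vb_structure(pairs = list(c(1, 2)), unpaired = c(3, 4))
  s_p <- vb_structure(pairs = list(perm[c(1, 2)]), unpaired = perm[c(3, 4)])
  amap <- c("1" = "A", "2" = "A", "3" = "B", "4" = "B")
  amap_p <- stats::setNames(amap, perm[as.integer(names(amap))])
  expect_equal(score_intra_atomic(s, amap), score_intra_atomic(s_p, amap_p))
  expect_equal(score_user_bonds(s, list(c(1, 2))),
               score_user_bonds(s_p, list(perm[c(1, 2)])))
  expect_equal(score_user_radicals(s, c(3)),
               score_user_radicals(s_p, perm[3]))
})

test_that("criteria_config validates priorities and warns on bond_length first", {
  expect_error(criteria_config(priority = c("user_bonds")), "user_bonds")
  expect_error(criteria_config(priority = c("intra_atomic", "intra_atomic")),
               "repeat")
  expect_error(criteria_config(priority = "nonsense"), "unknown criterion")
  expect_warning(criteria_config(priority = "bond_length"), "not recommended")
  cfg <- criteria_config(user_bonds = list(c(1, 2)))
  expect_identical(cfg$priority[1], "user_bonds")
  expect_false("user_radicals" %in% cfg$priority)
})

test_that("rank_structures merges criteria in priority order", {
  sys <- builtin_system("h_oh_ts")
  sts <- enumerate_structures(sys$space, subspace = vb_subspace())
  tbl <- rank_structures(sts, sys$space, sys$config, geometry = sys$geometry)
  expect_equal(nrow(tbl), 6)
  expect_true(all(tbl$unified >= 1))
  # the intra-atomic O pairing is strictly worse than every other structure
  intra_row <- tbl$intra_atomic > 1
  expect_equal(sum(intra_row), 1)
  expect_true(all(tbl$unified[intra_row] > tbl$unified[!intra_row]))
  expect_error(rank_structures(sts, sys$space, sys$config), "geometry")
})
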