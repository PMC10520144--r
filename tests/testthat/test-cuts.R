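test_that("cut positions match the worked 3-region inversion example", {
  alpha <- alpha_example()
  expect_identical(cut_positions(alpha)$positions, c(1L, 4L))
  expect_identical(cut_positions_star(alpha), c(-4L, -1L, 1L, 4L))
  expect_identical(cut_positions(inversion(5, 1, 2))$positions, c(2L, 5L))
  expect_error(cut_positions(group_constants(5)$c), "sign rule")
})

test_that("the identity and every dihedral symmetry require no cuts", {
  for (n in c(3, 5)) {
    expect_length(cut_positions(identity_perm(n))$positions, 0)
    for (d in dihedral_group(n)) {
      expect_length(cut_positions(d)$positions, 0)
    }
  }
  expect_length(cut_positions_star(identity_perm(5)), 0)
})

test_that("cut sets transform dihedrally under pre/post symmetry", {
  gc <- group_constants(5)
  alpha <- alpha_example()

  # barred closure is rotation-equivariant
  shifted <- compose(alpha, gc$rotation)
  expect_setequal(cut_positions_star(shifted),
                  apply_perm(inverse(gc$rotation), cut_positions_star(alpha)))

  # the orientation-aware closure names each gap from both directions:
  # cuts {1, 4} are {-(2), -(5)} read the other way round
  expect_identical(signed_cut_closure(alpha), c(-5L, -2L, 1L, 4L))

  set.seed(13)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    alpha <- random_signed_perm(n)
    cp <- cut_positions(alpha)$positions
    expect_setequal(signed_cut_closure(alpha),
                    c(cp, -apply_perm(gc5 <- group_constants(n)$c, cp)))
    D <- dihedral_group(n)
    d1 <- D[[sample(2 * n, 1)]]
    d2 <- D[[sample(2 * n, 1)]]
    # left multiplication never changes the cut set
    expect_identical(cut_positions(compose(d1, alpha))$positions,
                     cut_positions(alpha)$positions)
    # full equivariance of the signed closure, and the induced law for CutPos
    moved <- compose(d1, compose(alpha, d2))
    law <- apply_perm(inverse(d2), signed_cut_closure(alpha))
    expect_setequal(signed_cut_closure(moved), law)
    expect_setequal(cut_positions(moved)$positions, law[law > 0])
    # rotation-equivariance of the barred closure
    rot <- D[[sample(n, 1)]]
    expect_setequal(cut_positions_star(compose(alpha, rot)),
                    apply_perm(inverse(rot), cut_positions_star(alpha)))
  }
})

test_that("no rearrangement requires exactly one cut (exhaustive small n)", {
  for (n in 2:4) {
    tab <- count_by_cuts(n, "cosets")
    expect_identical(unname(tab$counts["1"]), 0L)
  }
})

test_that("cut profiles and classification follow the cut count", {
  prof <- action_cut_profile(canonical_action(inversion(5, 3, 3)))
  expect_identical(prof$k, 2L)
  expect_identical(prof$segment_sizes, c(2L, 3L))

  id_prof <- action_cut_profile(canonical_action(identity_perm(5)))
  expect_identical(id_prof$k, 0L)
  expect_length(id_prof$segment_sizes, 0)

  expect_identical(classify_action(canonical_action(inversion(6, 1, 2)))$label,
                   "inversion")
  tr <- classify_action(canonical_action(parse_perm("(1 3 2)(-1 -3 -2)", 5)))
  expect_identical(tr$label, "transposition")
  expect_true(tr$block_interchange)
  idc <- classify_action(canonical_action(identity_perm(4)))
  expect_identical(idc$label, "identity_or_symmetry")
  expect_false(idc$block_interchange)

  # profiles are identical across instances of one action
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    alpha <- random_signed_perm(n)
    A <- canonical_action(alpha)
    expect_identical(action_cut_profile(A)$segment_sizes,
                     action_cut_profile(alpha)$segment_sizes)
  }
})

test_that("breakpoint counts agree with the direct adjacency oracle", {
  expect_identical(breakpoint_count(identity_perm(5)), 0L)
  expect_identical(breakpoint_count(make_perm(c(1, 2, -3, 4, 5))), 2L)
  expect_identical(breakpoint_count(sigma_example()), 4L)
  expect_identical(nrow(breakpoint_set(sigma_example())), 4L)
  expect_identical(nrow(breakpoint_set(identity_perm(4))), 0L)

  set.seed(15)
  for (rep in 1:40) {
    sigma <- random_signed_perm(5)
    expect_identical(breakpoint_count(sigma), breakpoints_by_adjacency(sigma))
  }
})

test_that("breakpoints are a genome invariant and paradigm-independent", {
  set.seed(16)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    sigma <- random_signed_perm(n)
    bp <- breakpoint_count(sigma)
    # same for all 2n instances
    d <- dihedral_group(n)[[sample(2 * n, 1)]]
    expect_identical(breakpoint_count(compose(d, sigma)), bp)
    # content-paradigm formula gives the same number
    expect_identical(breakpoint_count_content(position_to_content(sigma)), bp)
    # |Fix([sigma^-1, c])| = |Fix([sigma, c])|
    gc <- group_constants(n)
    expect_identical(length(fix_set(commutator(inverse(sigma), gc$c))),
                     length(fix_set(commutator(sigma, gc$c))))
  }
  expect_identical(
    breakpoint_count_content(position_to_content(identity_perm(5))), 0L)
})
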