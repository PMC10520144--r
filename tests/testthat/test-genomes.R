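# the ten printed instances of the running example genome
example_orbit_rows <- list(
  c(1, -3, -4, 2, 5), c(2, -4, -5, 3, 1), c(3, -5, -1, 4, 2),
  c(4, -1, -2, 5, 3), c(5, -2, -3, 1, 4), c(-1, 4, 3, -5, -2),
  c(-2, 5, 4, -1, -3), c(-3, 1, 5, -2, -4), c(-4, 2, 1, -3, -5),
  c(-5, 3, 2, -4, -1))

test_that("every instance of the example genome canonicalizes identically", {
  genomes <- lapply(example_orbit_rows,
                    function(r) canonical_genome(make_perm(r)))
  keys <- vapply(genomes, `[[`, numeric(1), "key")
  expect_identical(length(unique(keys)), 1L)

  # the canonical representative is the true lexicographic orbit minimum
  orbit <- genome_instances(genomes[[1]])
  expect_true(perm_equal(genomes[[1]]$rep, lex_min_instance(orbit)))

  # and the orbit is exactly the ten printed instances
  expect_setequal(
    vapply(orbit, format_perm, character(1), style = "one_row"),
    vapply(example_orbit_rows,
           function(r) format_perm(make_perm(r), "one_row"), character(1)))
})

test_that("genome orbits always have exactly 2n distinct instances", {
  expect_true(genome_equal(canonical_genome(identity_perm(4)),
                           canonical_genome(group_constants(4)$rotation)))
  set.seed(10)
  for (rep in 1:12) {
    n <- sample(2:6, 1)
    G <- canonical_genome(random_signed_perm(n))
    inst <- genome_instances(G)
    expect_identical(
      length(unique(vapply(inst, format_perm, character(1)))), 2L * n)
    expect_true(any(vapply(inst, perm_equal, logical(1), b = G$rep)))
  }
})

test_that("genome enumeration counts 2^(n-1) (n-1)! and refuses huge n", {
  expect_length(enumerate_genomes(2), 2)
  expect_length(enumerate_genomes(3), 8)
  expect_length(enumerate_genomes(4), 48)
  expect_length(enumerate_genomes(5), 384)
  keys5 <- vapply(enumerate_genomes(5), `[[`, numeric(1), "key")
  expect_false(is.unsorted(keys5))
  expect_error(enumerate_genomes(8), "645,120,\\d|genomes")
})

test_that("actions are double cosets: equivalent instances canonicalize together", {
  expect_true(action_equal(canonical_action(inversion(3, 1, 1)),
                           canonical_action(inversion(3, 1, 2))))
  expect_true(action_equal(canonical_action(inversion(6, 1, 2)),
                           canonical_action(inversion(6, 1, 4))))
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    alpha <- random_signed_perm(n)
    D <- dihedral_group(n)
    d1 <- D[[sample(2 * n, 1)]]
    d2 <- D[[sample(2 * n, 1)]]
    expect_true(action_equal(
      canonical_action(compose(d1, compose(alpha, d2))),
      canonical_action(alpha)))
  }
})

test_that("outcome distributions have the right supports and exact probabilities", {
  ref6 <- reference_genome(6)
  a3 <- canonical_action(inversion(6, 1, 3))
  out3 <- apply_action(a3, ref6)
  expect_length(out3$genomes, 3)
  a1 <- canonical_action(inversion(6, 1, 1))
  expect_length(apply_action(a1, ref6)$genomes, 6)
  expect_length(apply_action(canonical_action(inversion(6, 1, 2)),
                             ref6)$genomes, 6)

  expect_equal(sum(outcome_probabilities(out3)), 1)
  expect_identical(sum(out3$mult), out3$denom)

  # identity action: single outcome, probability one
  id_out <- apply_action(canonical_action(identity_perm(5)),
                         canonical_genome(sigma_example()))
  expect_length(id_out$genomes, 1)
  expect_identical(outcome_probabilities(id_out), 1)
})

test_that("outcome distributions are representative-independent", {
  set.seed(12)
  n <- 5
  alpha <- inversion(n, 2, 2)
  G <- canonical_genome(sigma_example())
  base <- apply_action(canonical_action(alpha), G)
  D <- dihedral_group(n)
  for (rep in 1:5) {
    alt_alpha <- compose(D[[sample(2 * n, 1)]],
                         compose(alpha, D[[sample(2 * n, 1)]]))
    alt_G <- compose(D[[sample(2 * n, 1)]], G$rep)
    alt <- apply_action(canonical_action(alt_alpha), canonical_genome(alt_G))
    expect_identical(vapply(alt$genomes, `[[`, numeric(1), "key"),
                     vapply(base$genomes, `[[`, numeric(1), "key"))
    expect_identical(alt$mult, base$mult)
  }
})

test_that("support size of an action is the same on every genome (small n sweep)", {
  for (n in 3:4) {
    acts <- inversion_actions(n)
    for (a in acts) {
      sizes <- vapply(enumerate_genomes(n),
                      function(g) length(apply_action(a, g)$genomes),
                      integer(1))
      expect_identical(length(unique(sizes)), 1L)
    }
  }
})
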