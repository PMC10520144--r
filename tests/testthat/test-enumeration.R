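test_that("the reconnection sequence starts 1, 0, 1, 4, 25, 208, 2121, 25828", {
  expect_equal(a061714(0:7), c(1, 0, 1, 4, 25, 208, 2121, 25828))
  expect_equal(per_cut_set_count(4), 25)
  expect_equal(per_cut_set_count(0), 1)
  expect_error(a061714(-1))
})

test_that("brute-force coset counts match the closed form for n <= 5", {
  t3 <- count_by_cuts(3, "cosets")
  expect_identical(unname(t3$counts), c(1L, 0L, 3L, 4L))
  expect_identical(t3$total, 8L)

  for (n in 2:5) {
    tab <- count_by_cuts(n, "cosets")
    expect_equal(unname(tab$counts), closed_form_R(n, 0:n))
    # total = |H_n| / 2n, the number of genomes
    expect_equal(tab$total, 2^n * factorial(n) / (2 * n))
    # per-cut-set quotients are integers independent of n
    for (k in 0:n) {
      expect_equal(tab$counts[[as.character(k)]] / choose(n, k),
                   per_cut_set_count(k))
    }
  }
  expect_equal(count_by_cuts(5, "cosets")$counts[["5"]], 208)
  expect_equal(closed_form_R(5, 5), 208)
  expect_equal(closed_form_R(6, 2), 15)
  expect_equal(closed_form_R(10, 1), 0)
  expect_error(closed_form_R(4, 5), "exceed")
  expect_error(count_by_cuts(8, "cosets"), "up to n = 7")
})

test_that("double-coset counts per cut number match the published table", {
  expect_identical(unname(count_by_cuts(3, "double_cosets")$counts),
                   c(1L, 0L, 1L, 2L))
  expect_identical(unname(count_by_cuts(4, "double_cosets")$counts),
                   c(1L, 0L, 2L, 3L, 7L))
  t5 <- count_by_cuts(5, "double_cosets")
  expect_identical(unname(t5$counts), c(1L, 0L, 2L, 6L, 15L, 32L))
  expect_identical(t5$total, 56L)
})

test_that("2- and 3-cut action counts follow the floor closed forms", {
  expect_equal(unname(action_counts_closed_form(5)), c(2, 6))
  expect_equal(unname(action_counts_closed_form(6)), c(3, 9))
  expect_equal(unname(action_counts_closed_form(3)), c(1, 2))
  for (n in 3:5) {
    tab <- count_by_cuts(n, "double_cosets")
    cf <- action_counts_closed_form(n)
    expect_equal(tab$counts[["2"]], unname(cf["2"]))
    expect_equal(tab$counts[["3"]], unname(cf["3"]))
  }
})

test_that("three-part partitions carry reconnection counts 2, 3, 4 by shape", {
  p6 <- three_cut_partitions(6)
  expect_identical(sum(p6$reconnections), 9L)
  expect_identical(p6$reconnections[p6$shape == "all_equal"], 2L)
  expect_setequal(p6$reconnections[p6$shape == "two_equal"], 3L)
  expect_identical(p6$reconnections[p6$a == 3 & p6$b == 2], 4L)

  p5 <- three_cut_partitions(5)
  expect_identical(sort(p5$reconnections), c(3L, 3L))
  expect_identical(sum(p5$reconnections), 6L)

  p3 <- three_cut_partitions(3)
  expect_identical(p3$shape, "all_equal")
  expect_identical(p3$reconnections, 2L)

  for (n in 3:12) {
    p <- three_cut_partitions(n)
    expect_equal(sum(p$reconnections),
                 unname(action_counts_closed_form(n)["3"]))
    # floor((n-1)/2) partitions a+a+b have a repeated part (the all-equal
    # partition, present iff 3 | n, is the case b = a)
    expect_identical(sum(p$shape %in% c("two_equal", "all_equal")),
                     (n - 1L) %/% 2L)
    expect_identical(any(p$shape == "all_equal"), n %% 3L == 0L)
    # number of partitions into exactly three parts: round(n^2 / 12)
    expect_identical(nrow(p), as.integer(round(n^2 / 12)))
  }
})

test_that("enumerated 3-cut actions group by segment partition as predicted", {
  seg5 <- count_actions_by_segments(5, 3)
  expect_identical(seg5$actions[seg5$segments == "3+1+1"], 3L)
  expect_identical(seg5$actions[seg5$segments == "2+2+1"], 3L)
  # 2-cut actions: one per segment pair {m, n-m}
  seg52 <- count_actions_by_segments(5, 2)
  expect_identical(nrow(seg52), 2L)
  expect_identical(unique(seg52$actions), 1L)
})
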