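# Exact counting over the full hyperoctahedral group: every element is a
# (unsigned permutation, sign vector) pair, held as one row of an integer
# matrix.  Coset and double-coset canonicalization is vectorized by
# encoding each one-row image as a single base-(2n+1) integer and taking
# parallel minima across the dihedral translates; n <= 7 (|H_7| = 645,120)
# keeps everything in memory.

perms_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms_matrix(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    out[[i]] <- cbind(rep(i, nrow(p)), q, deparse.level = 0)
  }
  do.call(rbind, out)
}

# all of H_n as an (2^n n!) x n integer matrix of one-row images
hyperoct_matrix <- function(n) {
  cached(paste0("hn", n), function() {
    P <- perms_matrix(n)
    S <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    M <- P[rep(seq_len(nrow(P)), each = nrow(S)), , drop = FALSE] *
      S[rep(seq_len(nrow(S)), times = nrow(P)), , drop = FALSE]
    storage.mode(M) <- "integer"
    dimnames(M) <- NULL
    M
  })
}

encode_rows <- function(M, n) {
  w <- (2 * n + 1)^((n - 1L):0)
  as.vector((M + n) %*% w)
}

# left-multiply every row of M (one-row images) by the full-image vector d
left_mult_rows <- function(M, dfull, n) {
  idx <- M
  neg <- M < 0L
  idx[neg] <- n - M[neg]
  matrix(dfull[idx], nrow = nrow(M))
}

# right-multiply: columns are permuted/signed by the positive row of d
right_mult_rows <- function(M, drow) {
  R <- M[, abs(drow), drop = FALSE]
  sweep(R, 2L, sign(drow), `*`)
}

min_left_keys <- function(M, n) {
  Dmat <- dihedral_image_matrix(n)
  best <- NULL
  for (r in seq_len(nrow(Dmat))) {
    k <- encode_rows(left_mult_rows(M, Dmat[r, ], n), n)
    best <- if (is.null(best)) k else pmin(best, k)
  }
  best
}

# number of cuts of every row of M, vectorized: |{i : c(a(i)) != a(c(i))}|
row_cut_counts <- function(M, n) {
  gc <- group_constants(n)
  ca <- left_mult_rows(M, gc$c$image, n)
  ac <- M[, c(seq_len(n)[-1L], 1L), drop = FALSE]
  as.integer(rowSums(ca != ac))
}

check_enum_n <- function(n) {
  if (n > 7L) {
    stop("refusing n = ", n, ": |H_n| = ",
         format(2^n * factorial(n), big.mark = ",", scientific = FALSE),
         " elements; brute-force enumeration is supported up to n = 7",
         call. = FALSE)
  }
  as.integer(n)
}

# canonical left-coset key and cut count for every element of H_n
hyperoct_coset_keys <- function(n) {
  n <- check_enum_n(n)
  cached(paste0("cosetkeys", n), function() {
    M <- hyperoct_matrix(n)
    list(keys = min_left_keys(M, n), cuts = row_cut_counts(M, n))
  })
}

# canonical double-coset key for every element of H_n
hyperoct_double_coset_keys <- function(n) {
  n <- check_enum_n(n)
  cached(paste0("dckeys", n), function() {
    M <- hyperoct_matrix(n)
    Dlist <- dihedral_group(n)
    best <- NULL
    for (d2 in Dlist) {
      k <- min_left_keys(right_mult_rows(M, d2$image[seq_len(n)]), n)
      best <- if (is.null(best)) k else pmin(best, k)
    }
    best
  })
}

#' Pure k-opt reconnection counts (OEIS A061714)
#'
#' The number of distinct rearrangements sharing one fixed cut set of size
#' k, from the closed form
#' \deqn{(-1)^k + \sum_{i=0}^{k-1} (-1)^{k-1+i} \binom{k}{i+1} i!\, 2^i.}
#' The sequence starts 1, 0, 1, 4, 25, 208, 2121, 25828 and is independent
#' of the number of regions.
#'
#' @param k number of cuts (>= 0).
#' @return integer-valued count.
#' @export
a061714 <- function(k) {
  stopifnot(k >= 0L)
  vapply(as.integer(k), function(kk) {
    if (kk == 0L) return(1)
    i <- 0:(kk - 1L)
    (-1)^kk + sum((-1)^(kk - 1L + i) * choose(kk, i + 1L) *
                    factorial(i) * 2^i)
  }, numeric(1))
}

#' Closed-form count of k-cut rearrangements
#'
#' \eqn{R(n, k) = \binom{n}{k} A061714(k)}: the number of distinct
#' rearrangements (left dihedral cosets) on n regions requiring exactly k
#' cuts — the choice of cut set times the reconnections per cut set.
#'
#' @param n number of regions.
#' @param k number of cuts, `0 <= k <= n`.
#' @return numeric count (exact integer value).
#' @export
closed_form_R <- function(n, k) {
  stopifnot(n >= 1L, k >= 0L)
  if (any(k > n)) stop("k must not exceed n", call. = FALSE)
  choose(n, k) * a061714(k)
}

#' Rearrangements per cut set
#'
#' `R(n, k) / choose(n, k)`, which is independent of n: the reconnection
#' count [a061714()].
#'
#' @param k number of cuts.
#' @return numeric count.
#' @export
per_cut_set_count <- function(k) a061714(k)

#' Count rearrangements or actions by number of cuts
#'
#' Brute-force enumeration of the full hyperoctahedral group, grouped into
#' left dihedral cosets (`mode = "cosets"`: distinct rearrangements) or
#' double cosets (`mode = "double_cosets"`: distinct rearrangement
#' actions), tallying the cut count of one representative per class (the
#' cut count is a class invariant).  Impossible cut numbers (such as k = 1)
#' are reported as explicit zeros.
#'
#' @param n number of regions, at most 7.
#' @param mode `"cosets"` or `"double_cosets"`.
#' @return object of class `count_table`: `n`, `mode`, `hn` (group order),
#'   `total` (number of classes), and `counts` named by k = 0..n.
#' @export
count_by_cuts <- function(n, mode = c("cosets", "double_cosets")) {
  mode <- match.arg(mode)
  n <- check_enum_n(n)
  ck <- hyperoct_coset_keys(n)
  keys <- if (mode == "cosets") ck$keys else hyperoct_double_coset_keys(n)
  pick <- !duplicated(keys)
  counts <- integer(n + 1L)
  tab <- table(ck$cuts[pick])
  counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
  names(counts) <- 0:n
  structure(list(n = n, mode = mode, hn = 2^n * factorial(n),
                 total = sum(counts), counts = counts),
            class = "count_table")
}

#' Count k-cut actions by segment-size multiset
#'
#' Enumerates the double cosets whose representatives require `k` cuts and
#' groups them by the multiset of circular segment sizes (an invariant of
#' the action).  For k = 3 this realizes, by brute force, the partition
#' counting of [three_cut_partitions()].
#'
#' @param n number of regions, at most 7.
#' @param k number of cuts.
#' @return data frame with columns `segments` (e.g. `"3+2+1"`, parts in
#'   decreasing order) and `actions`.
#' @export
count_actions_by_segments <- function(n, k) {
  n <- check_enum_n(n)
  stopifnot(k >= 0L, k <= n)
  ck <- hyperoct_coset_keys(n)
  dkeys <- hyperoct_double_coset_keys(n)
  pick <- !duplicated(dkeys) & ck$cuts == k
  M <- hyperoct_matrix(n)
  segs <- vapply(which(pick), function(i) {
    g <- action_cut_profile(make_perm(M[i, ]))$segment_sizes
    paste(sort(g, decreasing = TRUE), collapse = "+")
  }, character(1))
  tab <- table(segs)
  data.frame(segments = names(tab), actions = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Closed-form action counts for 2 and 3 cuts
#'
#' The number of distinct rearrangement actions requiring 2 cuts
#' (inversions) is `floor(n/2)`; requiring 3 cuts (transpositions) it is
#' `floor(n^2/3) - floor(n/2)`.
#'
#' @param n number of regions (>= 2; the 3-cut entry needs n >= 3).
#' @return named numeric vector with entries `"2"` and `"3"`.
#' @export
action_counts_closed_form <- function(n) {
  stopifnot(n >= 2L)
  out <- c(`2` = floor(n / 2), `3` = if (n >= 3L) floor(n^2 / 3) - floor(n / 2))
  out
}

#' Partitions of n into three segments and their reconnection counts
#'
#' Each 3-cut action determines a partition of n into the three circular
#' segment sizes.  A partition with all parts equal admits 2 distinct
#' reconnections, one with exactly two equal parts admits 3, and one with
#' all parts distinct admits 4; summing over all partitions gives the
#' 3-cut action count `floor(n^2/3) - floor(n/2)`.
#'
#' @param n number of regions (>= 3).
#' @return data frame with columns `a`, `b`, `c` (parts, decreasing),
#'   `shape` (`all_equal`, `two_equal`, `all_distinct`) and
#'   `reconnections`.
#' @export
three_cut_partitions <- function(n) {
  if (n < 3L) stop("need n >= 3 for three segments", call. = FALSE)
  n <- as.integer(n)
  parts <- list()
  for (a in seq_len(n - 2L)) {
    for (b in seq_len(min(a, n - a - 1L))) {
      cc <- n - a - b
      if (cc < 1L || cc > b) next
      parts[[length(parts) + 1L]] <- c(a, b, cc)
    }
  }
  P <- do.call(rbind, parts)
  neq <- apply(P, 1L, function(p) length(unique(p)))
  shape <- c("all_equal", "two_equal", "all_distinct")[neq]
  recon <- c(2L, 3L, 4L)[neq]
  data.frame(a = P[, 1], b = P[, 2], c = P[, 3], shape = shape,
             reconnections = recon, stringsAsFactors = FALSE)
}

#' @export
print.count_table <- function(x, ...) {
  what <- if (x$mode == "cosets") "rearrangements (left cosets)"
          else "rearrangement actions (double cosets)"
  cat("n = ", x$n, ", |H_n| = ",
      format(x$hn, big.mark = ",", scientific = FALSE),
      ", ", x$total, " distinct ", what, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
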