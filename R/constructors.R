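# Explicit instances of the biologically motivated event classes:
# inversions (in-place segment reversal), single-region moves, and small
# transpositions assembled from them.

wrap_pos <- function(x, n) {
  y <- x %% n
  y[y == 0L] <- n
  as.integer(y)
}

#' Inversion instance
#'
#' The signed permutation inverting `length` adjacent regions in place.
#' Odd lengths `2k+1` are centred on position `r`:
#' \deqn{(r, -r)\prod_{i=1}^{k} (r-i, -(r+i))(-(r-i), r+i),}
#' even lengths `2k` on the adjacent pair `r`, `r mod n + 1`:
#' \deqn{\prod_{i=1}^{k} (r-(i-1), -(r+i))(-(r-(i-1)), r+i),}
#' with position arithmetic mod n and zeros replaced by n (positions are
#' 1-based).  A length-n "inversion" is a reflection of the whole genome —
#' a symmetry, not a rearrangement — and is rejected.
#'
#' @param n number of regions.
#' @param r anchor position, `1 <= r <= n`.
#' @param length number of regions inverted, `1 <= length <= n - 1`.
#' @return a `signed_perm`; always an involution with two cuts.
#' @examples
#' format_perm(inversion(5, 3, 3), "cycles")  # (3 -3)(2 -4)(-2 4)
#' @export
inversion <- function(n, r, length) {
  stopifnot(n >= 1L, r >= 1L, r <= n)
  n <- as.integer(n); r <- as.integer(r); len <- as.integer(length)
  if (len < 1L || len >= n) {
    stop("inversion length must be in 1..(n-1); a length-", n,
         " inversion of an n-region circular genome is a dihedral symmetry,",
         " not a rearrangement", call. = FALSE)
  }
  image <- c(seq_len(n), -seq_len(n))
  swap <- function(x, y) {
    image[lab_index(x, n)] <<- y
    image[lab_index(y, n)] <<- x
  }
  if (len %% 2L == 1L) {
    k <- (len - 1L) %/% 2L
    swap(r, -r)
    for (i in seq_len(k)) {
      a <- wrap_pos(r - i, n)
      b <- wrap_pos(r + i, n)
      swap(a, -b)
      swap(-a, b)
    }
  } else {
    k <- len %/% 2L
    for (i in seq_len(k)) {
      a <- wrap_pos(r - (i - 1L), n)
      b <- wrap_pos(r + i, n)
      swap(a, -b)
      swap(-a, b)
    }
  }
  new_signed_map(n, image)
}

#' Move one region to the next position
#'
#' The transposition instance shifting the region at position `r` to
#' position `r + 1` with no net orientation change, assembled from
#' inversions as `Inv(r+1, 1) Inv(r, 1) Inv(r, 2)` (rightmost factor acts
#' first): invert the two-region segment, then re-invert each region.
#'
#' @param n number of regions (>= 3).
#' @param r source position.
#' @return a `signed_perm` with three cuts.
#' @export
move_one_region <- function(n, r) {
  stopifnot(r >= 1L, r <= n)
  if (n < 3L) stop("single-region moves need n >= 3", call. = FALSE)
  n <- as.integer(n); r <- as.integer(r)
  r2 <- wrap_pos(r + 1L, n)
  compose(inversion(n, r2, 1L),
          compose(inversion(n, r, 1L), inversion(n, r, 2L)))
}

#' The distinct inversion actions
#'
#' One action per segment length `m = 1..floor(n/2)`.  Inverting `n - m`
#' regions of a circular genome is the same action as inverting `m` (the
#' complement segment is what stays put), so longer lengths add nothing;
#' the returned actions are pairwise distinct.
#'
#' @param n number of regions (>= 2).
#' @return list of `action`s, ordered by segment length.
#' @export
inversion_actions <- function(n) {
  stopifnot(n >= 2L)
  lapply(seq_len(n %/% 2L), function(m) canonical_action(inversion(n, 1L, m)))
}

#' Example transposition instances
#'
#' Moves the region at position 1 forward by `shift` positions, by
#' composing single-region moves; `kind = "inverted"` additionally inverts
#' the moved region (composing the 1-region inversion at its destination,
#' equivalently inverting it at the source before moving).  Every result
#' requires exactly 3 cuts and classifies as a transposition.
#'
#' @param n number of regions (>= 3).
#' @param kind `"plain"` or `"inverted"`.
#' @param shift how many positions the region moves, `1 <= shift <= n - 2`.
#' @return a `signed_perm`.
#' @export
transposition_example <- function(n, kind = c("plain", "inverted"), shift = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 3L, shift >= 1L)
  n <- as.integer(n); shift <- as.integer(shift)
  if (shift > n - 2L) {
    stop("shift = ", shift, " is not realizable on ", n,
         " regions (max ", n - 2L, ")", call. = FALSE)
  }
  out <- identity_perm(n)
  for (j in seq_len(shift)) out <- compose(move_one_region(n, j), out)
  if (kind == "inverted") {
    out <- compose(inversion(n, wrap_pos(1L + shift, n), 1L), out)
  }
  out
}
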