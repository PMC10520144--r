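# Conversions between the position paradigm (regions -> signed positions)
# and the two content-paradigm representations: the conjugate of the
# successor cycle c (region -> following region) and the head/tail
# adjacency involution.

new_content_cycles <- function(n, map) {
  structure(list(n = n, map = map), class = "content_cycles")
}

validate_content_cycles <- function(pi) {
  stopifnot(inherits(pi, "content_cycles"))
  n <- pi$n
  map <- pi$map
  # conjugates of c satisfy map(-i) = -map^{-1}(i)
  inv <- inverse(map)
  if (!all(map$image[(n + 1):(2L * n)] == -inv$image[seq_len(n)])) {
    stop("not a content representation: map(-i) != -map^{-1}(i)",
         call. = FALSE)
  }
  # cycle through label 1 must traverse all n regions (cycle type (n, n))
  x <- 1L
  for (i in seq_len(n)) x <- apply_perm(map, x)
  if (x != 1L) stop("not a content representation: cycle through 1 shorter than n",
                    call. = FALSE)
  invisible(pi)
}

#' Convert a position-paradigm genome to content cycles
#'
#' Conjugates the successor cycle: \eqn{\sigma^{-1} c \sigma}.  The result
#' maps each signed region label to the region that follows it clockwise,
#' and is the same for every instance of the genome (the dihedral subgroup
#' commutes with `c`), so the content representation is coset-invariant.
#'
#' @param sigma a `signed_perm` (regions to signed positions).
#' @return an object of class `content_cycles` holding the conjugate map,
#'   a product of two n-cycles.
#' @export
position_to_content <- function(sigma) {
  stopifnot(is_signed_perm(sigma))
  gc <- group_constants(sigma$n)
  new_content_cycles(sigma$n,
                     compose(compose(inverse(sigma), gc$c), sigma))
}

#' Convert a position-paradigm genome to head/tail adjacencies
#'
#' \eqn{\sigma^{-1} c \sigma r} where `r` is the all-region orientation
#' flip: a fixed-point-free involution pairing the extremity of each region
#' with the extremity it touches.  Here the sign of a label means head
#' versus tail rather than orientation.
#'
#' @param sigma a `signed_perm`.
#' @return an object of class `adjacency_rep`.
#' @export
position_to_adjacencies <- function(sigma) {
  stopifnot(is_signed_perm(sigma))
  gc <- group_constants(sigma$n)
  map <- compose(position_to_content(sigma)$map, gc$flip_all)
  structure(list(n = sigma$n, map = map), class = "adjacency_rep")
}

#' Recover a position-paradigm instance from content cycles
#'
#' Anchors region 1 at position 1 with positive orientation: the returned
#' positions-to-regions map \eqn{\tau} has \eqn{\tau(1) = 1} and
#' \eqn{\tau(i) = \pi^{i-1}(1)}, extended by the sign rule.  The genome
#' instance (regions to positions) is `inverse(tau)`; the anchoring choice
#' resolves the 2n-fold dihedral ambiguity deterministically, so
#' `position_to_content(inverse(content_to_position(pi)))` returns `pi` and
#' the round trip lands in the same dihedral coset.
#'
#' @param pi a `content_cycles` object.
#' @return a `signed_perm` \eqn{\tau} mapping positions to regions.
#' @export
content_to_position <- function(pi) {
  validate_content_cycles(pi)
  n <- pi$n
  row <- integer(n)
  row[1L] <- 1L
  x <- 1L
  for (i in seq_len(n - 1L)) {
    x <- apply_perm(pi$map, x)
    row[i + 1L] <- x
  }
  make_perm(row)
}

#' @export
print.content_cycles <- function(x, ...) {
  cat("content-paradigm genome (cycles), n =", x$n, "\n")
  cat("  ", format_perm(x$map, "cycles"), "\n")
  invisible(x)
}

#' @export
print.adjacency_rep <- function(x, ...) {
  cat("content-paradigm genome (head/tail adjacencies), n =", x$n, "\n")
  cat("  ", format_perm(x$map, "cycles"), "\n")
  invisible(x)
}
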