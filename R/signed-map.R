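# Signed labels {1..n, -1..-n} are stored in a fixed index order:
# index j in 1..n is label j, index n+j is label -j.  A map is the integer
# vector of images in that order.  A bar in the literature is a minus sign.

lab_index <- function(x, n) {
  j <- x
  neg <- x < 0
  j[neg] <- n - x[neg]
  j
}

index_lab <- function(j, n) {
  x <- j
  hi <- j > n
  x[hi] <- n - j[hi]
  x
}

all_labels <- function(n) c(seq_len(n), -seq_len(n))

satisfies_sign_rule <- function(image, n) {
  all(image[(n + 1):(2L * n)] == -image[seq_len(n)])
}

new_signed_map <- function(n, image) {
  image <- as.integer(image)
  cls <- if (satisfies_sign_rule(image, n)) {
    c("signed_perm", "signed_map")
  } else {
    "signed_map"
  }
  structure(list(n = as.integer(n), image = image), class = cls)
}

validate_bijection <- function(image, n) {
  idx <- lab_index(image, n)
  if (anyNA(idx) || any(abs(image) < 1L) || any(abs(image) > n) ||
      anyDuplicated(idx)) {
    stop("image is not a bijection on the 2n signed labels", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a signed permutation from its one-row images
#'
#' Constructs the element of the hyperoctahedral group \eqn{H_n} whose image
#' on the positive labels \eqn{1..n} is `images`, extended to the negative
#' labels by the sign rule \eqn{\sigma(-i) = -\sigma(i)}.  This is the
#' position-paradigm encoding of a genome instance (regions to signed
#' positions) or of a rearrangement instance (positions to positions).
#'
#' @param images integer vector whose absolute values are a permutation of
#'   `1:length(images)`; a negative entry marks a reversed region.
#' @return an object of class `signed_perm` (also `signed_map`).
#' @examples
#' sigma <- make_perm(c(-1, 4, 3, -5, -2))
#' format_perm(sigma)
#' @export
make_perm <- function(images) {
  images <- as.integer(images)
  n <- length(images)
  if (n < 1L) stop("need at least one region", call. = FALSE)
  a <- abs(images)
  if (any(a < 1L) || any(a > n)) {
    bad <- images[a < 1L | a > n][1L]
    stop("label out of range: ", bad, call. = FALSE)
  }
  if (anyDuplicated(a)) {
    dup <- a[duplicated(a)][1L]
    stop("duplicate label: ", dup, call. = FALSE)
  }
  new_signed_map(n, c(images, -images))
}

#' Extend a map on positive labels to a signed permutation
#'
#' The unique extension of an injective map on `1..n` to an element of
#' \eqn{H_n} via \eqn{\sigma(-i) = -\sigma(i)}.  Unsigned permutations embed
#' into \eqn{H_n} through this rule.
#'
#' @param partial integer vector of signed images of `1..n`; absolute values
#'   must be distinct.
#' @return a `signed_perm`.
#' @export
extend_sign_rule <- function(partial) {
  partial <- as.integer(partial)
  if (anyDuplicated(abs(partial))) {
    stop("map on positive labels is not injective up to sign", call. = FALSE)
  }
  make_perm(partial)
}

#' Identity permutation
#' @param n number of regions.
#' @return the identity of \eqn{H_n}.
#' @export
identity_perm <- function(n) make_perm(seq_len(n))

#' Is an object a sign-rule-respecting permutation?
#' @param x object to test.
#' @return `TRUE` for elements of the hyperoctahedral group \eqn{H_n}.
#' @export
is_signed_perm <- function(x) inherits(x, "signed_perm")

#' Apply a signed map to labels
#' @param p a `signed_map`.
#' @param x vector of signed labels.
#' @return images of `x` under `p`.
#' @export
apply_perm <- function(p, x) {
  stopifnot(inherits(p, "signed_map"))
  if (any(x == 0L) || any(abs(x) > p$n)) {
    stop("labels must lie in {±1..±n}", call. = FALSE)
  }
  p$image[lab_index(as.integer(x), p$n)]
}

#' Compose two signed maps
#'
#' Returns the functional composite `a` after `b`: the rightmost factor acts
#' first, so `compose(a, b)` maps `x` to `a(b(x))`.  All printed products in
#' the package documentation follow this convention.
#'
#' @param a,b `signed_map` objects on the same number of regions.
#' @return their composite; a `signed_perm` whenever the composite respects
#'   the sign rule (always the case when both factors do).
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "signed_map"), inherits(b, "signed_map"))
  if (a$n != b$n) stop("size mismatch: ", a$n, " vs ", b$n, call. = FALSE)
  new_signed_map(a$n, a$image[lab_index(b$image, a$n)])
}

#' Invert a signed map
#' @param a a `signed_map`.
#' @return the inverse map: `compose(a, inverse(a))` is the identity.
#' @export
inverse <- function(a) UseMethod("inverse")

#' @export
inverse.signed_map <- function(a) {
  n <- a$n
  inv <- integer(2L * n)
  inv[lab_index(a$image, n)] <- index_lab(seq_len(2L * n), n)
  new_signed_map(n, inv)
}

#' Commutator of two signed maps
#'
#' `commutator(a, b)` is \eqn{a^{-1} b^{-1} a b} under the rightmost-first
#' composition convention.  The commutator with the region-successor map `c`
#' drives both the cut-set and breakpoint formulas.
#'
#' @param a,b `signed_map` objects on the same number of regions.
#' @return a `signed_map`.
#' @export
commutator <- function(a, b) {
  compose(compose(compose(inverse(a), inverse(b)), a), b)
}

#' Fixed labels of a signed map
#' @param a a `signed_map`.
#' @return the signed labels `x` (over all 2n of them) with `a(x) = x`.
#' @export
fix_set <- function(a) {
  stopifnot(inherits(a, "signed_map"))
  labs <- all_labels(a$n)
  labs[a$image == labs]
}

#' Test two signed maps for equality
#' @param a,b `signed_map` objects.
#' @return `TRUE` when they agree pointwise on all 2n labels.
#' @export
perm_equal <- function(a, b) {
  inherits(a, "signed_map") && inherits(b, "signed_map") &&
    a$n == b$n && identical(a$image, b$image)
}

# lexicographic key of the one-row image; natural integer order on values
perm_key <- function(image_row, n) {
  w <- (2 * n + 1)^((n - 1L):0)
  sum((image_row + n) * w)
}

key_to_row <- function(key, n) {
  base <- 2 * n + 1
  row <- integer(n)
  for (j in n:1) {
    d <- key %% base
    row[j] <- as.integer(d - n)
    key <- (key - d) / base
  }
  row
}

#' @export
print.signed_map <- function(x, ...) {
  kind <- if (is_signed_perm(x)) "signed permutation (H_n)" else
    "signed map (outside H_n)"
  cat(kind, " on n = ", x$n, " regions\n", sep = "")
  if (is_signed_perm(x)) {
    cat("  one-row: ", format_perm(x, "one_row"), "\n", sep = "")
  }
  cat("  cycles:  ", format_perm(x, "cycles"), "\n", sep = "")
  invisible(x)
}
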