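# Distinguished elements: the region-successor two-n-cycle c, the
# orientation flip of every region, and the dihedral subgroup generated by
# the single-position rotation and a reflection.  The literature uses the
# same symbol for flip_all and rotation; they are distinct elements and are
# kept apart here.

.circrearr_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .circrearr_cache, inherits = FALSE)) {
    assign(key, make(), envir = .circrearr_cache)
  }
  get(key, envir = .circrearr_cache, inherits = FALSE)
}

#' Distinguished group elements for n regions
#'
#' Returns the four special elements used throughout:
#' \describe{
#'   \item{c}{the two-n-cycle `(1...n)(-n...-1)` mapping each position to the
#'     next position clockwise.  It is *not* in \eqn{H_n} for `n > 2` (it
#'     violates the sign rule; instead `c(-i) = -c^{-1}(i)`).}
#'   \item{flip_all}{`(1 -1)(2 -2)...(n -n)`: reverses the orientation of
#'     every region in place; an involution in \eqn{H_n}.}
#'   \item{rotation}{`(1...n)(-1...-n)`: the one-position rotation, the
#'     sign-rule extension of the unsigned n-cycle.}
#'   \item{reflection}{the oriented reflection about the axis through
#'     position 1: `reflection(1) = -1` and
#'     `reflection(i) = -((n + 1 - i) mod n + 1)` for `i = 2..n`.  For n = 5
#'     this is `(2 -5)(-2 5)(3 -4)(-3 4)(1 -1)`.  Reflections of oriented
#'     regions flip orientations, so this is not the plain sign-rule
#'     extension of an unsigned reflection.}
#' }
#'
#' @param n number of regions (>= 1).
#' @return a list of class `group_constants` with elements `n`, `c`,
#'   `flip_all`, `rotation`, `reflection`.
#' @export
group_constants <- function(n) {
  stopifnot(n >= 1L)
  n <- as.integer(n)
  cached(paste0("gc", n), function() {
    pos <- seq_len(n)
    c_img <- c(pos %% n + 1L, -((pos - 2L) %% n + 1L))
    flip <- new_signed_map(n, c(-pos, pos))
    rot <- make_perm(pos %% n + 1L)
    refl_row <- c(-1L, if (n > 1L) -((n + 1L - 2:n) %% n + 1L))
    refl <- make_perm(refl_row)
    structure(
      list(n = n, c = new_signed_map(n, c_img), flip_all = flip,
           rotation = rot, reflection = refl),
      class = "group_constants")
  })
}

#' @export
print.group_constants <- function(x, ...) {
  cat("group constants, n =", x$n, "\n")
  cat("  c:          ", format_perm(x$c, "cycles"), "\n")
  cat("  flip_all:   ", format_perm(x$flip_all, "cycles"), "\n")
  cat("  rotation:   ", format_perm(x$rotation, "cycles"), "\n")
  cat("  reflection: ", format_perm(x$reflection, "cycles"), "\n")
  invisible(x)
}

#' The dihedral subgroup of circular symmetries
#'
#' The 2n rearrangements that leave every circular genome unchanged: the
#' group generated by the rotation and the reflection, isomorphic to the
#' dihedral group \eqn{D_n}.  Every element commutes with the successor map
#' `c`, which is what makes cut sets well defined on rearrangement actions.
#'
#' @param n number of regions.
#' @return list of `2n` distinct `signed_perm`s: the rotations
#'   `rotation^j` followed by the reflections `rotation^j * reflection`.
#' @export
dihedral_group <- function(n) {
  stopifnot(n >= 1L)
  n <- as.integer(n)
  cached(paste0("dih", n), function() {
    gc <- group_constants(n)
    rots <- vector("list", n)
    rots[[1L]] <- identity_perm(n)
    for (j in seq_len(n - 1L)) rots[[j + 1L]] <- compose(gc$rotation, rots[[j]])
    refls <- lapply(rots, compose, b = gc$reflection)
    c(rots, refls)
  })
}

# full-image matrix of the dihedral group, one row per element (internal)
dihedral_image_matrix <- function(n) {
  cached(paste0("dihmat", n), function() {
    do.call(rbind, lapply(dihedral_group(n), `[[`, "image"))
  })
}
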