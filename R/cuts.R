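# Cut sets: the positions where the genome must be physically cut for a
# rearrangement instance to act, computed from the commutator with the
# successor cycle c.  Breakpoints are the analogous genome-level notion.

#' Cut positions of a rearrangement instance
#'
#' A cut at position `i` means the genome is severed between positions `i`
#' and `i mod n + 1`.  Algebraically these are the positions moved by the
#' commutator with the successor cycle:
#' \eqn{CutPos(\alpha) = [n] - Fix(\alpha^{-1} c^{-1} \alpha c)},
#' equivalently the positions `i` with `c(alpha(i)) != alpha(c(i))`.  Left
#' dihedral multiplication does not change the cut set; right
#' multiplication permutes it (see [cut_positions_star()]).
#'
#' @param alpha a `signed_perm`.
#' @return object of class `cut_set`: `n` plus the sorted positions.
#' @examples
#' cut_positions(parse_perm("(3 -3)(2 -4)(-2 4)", 5))  # {1, 4}
#' @export
cut_positions <- function(alpha) {
  if (!is_signed_perm(alpha)) {
    stop("input violates the sign rule and is not a rearrangement instance",
         call. = FALSE)
  }
  n <- alpha$n
  gc <- group_constants(n)
  com <- commutator(alpha, gc$c)
  pos <- which(com$image[seq_len(n)] != seq_len(n))
  structure(list(n = n, positions = as.integer(pos)), class = "cut_set")
}

#' Signed closure of the cut set
#'
#' Both orientations of every cut position:
#' \eqn{CutPos^*(\alpha) = CutPos(\alpha) \cup -CutPos(\alpha)}.  This
#' barred closure transforms equivariantly under rotations:
#' \eqn{CutPos^*(\alpha r^j) = r^{-j} \cdot CutPos^*(\alpha)}.  Reflections
#' relabel the gaps between positions, not the positions themselves, so the
#' exact transformation law under the whole dihedral group is carried by
#' [signed_cut_closure()] instead.
#'
#' @param alpha a `signed_perm`.
#' @return sorted integer vector of signed labels.
#' @export
cut_positions_star <- function(alpha) {
  p <- cut_positions(alpha)$positions
  sort(c(p, -p))
}

#' Orientation-aware signed cut set
#'
#' The signed labels `x` (over all 2n of them) where the successor relation
#' breaks: \eqn{\{x : c\alpha(x) \ne \alpha c(x)\}}.  A cut between
#' positions `i` and `i + 1` appears once per reading direction: as `i`
#' read clockwise and as `-(i+1)` read counterclockwise, so the set equals
#' \eqn{CutPos(\alpha) \cup -c(CutPos(\alpha))}.  This is the set for which
#' the dihedral transformation law is exact for every pair of symmetries:
#' \deqn{SignedCuts(d_1 \alpha d_2) = d_2^{-1} \cdot SignedCuts(\alpha),}
#' and consequently
#' \eqn{CutPos(d_1 \alpha d_2) = (d_2^{-1} \cdot SignedCuts(\alpha)) \cap [n]}.
#'
#' @param alpha a `signed_perm`.
#' @return sorted integer vector of signed labels.
#' @export
signed_cut_closure <- function(alpha) {
  if (!is_signed_perm(alpha)) {
    stop("input violates the sign rule and is not a rearrangement instance",
         call. = FALSE)
  }
  n <- alpha$n
  gc <- group_constants(n)
  labs <- all_labels(n)
  broken <- apply_perm(gc$c, apply_perm(alpha, labs)) !=
    apply_perm(alpha, apply_perm(gc$c, labs))
  sort(labs[broken])
}

#' Cut profile of an action
#'
#' The number of cuts and the multiset of circular segment lengths between
#' consecutive cuts.  Instances of one action have dihedrally related cut
#' sets, so both are invariants of the double coset; the segment sizes sum
#' to n whenever there is at least one cut.
#'
#' @param A an `action` (a bare `signed_perm` instance is also accepted).
#' @return object of class `cut_profile`: `k` and sorted `segment_sizes`.
#' @export
action_cut_profile <- function(A) {
  rep <- if (inherits(A, "action")) A$rep else A
  cs <- cut_positions(rep)
  structure(list(k = length(cs$positions),
                 segment_sizes = circular_gaps(cs$positions, cs$n)),
            class = "cut_profile")
}

circular_gaps <- function(positions, n) {
  k <- length(positions)
  if (k == 0L) return(integer(0))
  p <- sort(positions)
  sort(as.integer(c(diff(p), n - p[k] + p[1L])))
}

#' Classify a rearrangement action by its cut count
#'
#' Two cuts are inversions, three are transpositions (possibly inverting
#' one moved segment), four cover the remaining block interchanges; zero
#' cuts means the identity or a pure symmetry.  Any action with 2-4 cuts
#' lies in the signed block-interchange class.
#'
#' @param A an `action` or a `signed_perm` instance.
#' @return list with `label`, `k`, and logical `block_interchange`.
#' @export
classify_action <- function(A) {
  prof <- action_cut_profile(A)
  k <- prof$k
  label <- switch(as.character(k),
                  "0" = "identity_or_symmetry",
                  "2" = "inversion",
                  "3" = "transposition",
                  "4" = "block_interchange_4cut",
                  paste0(k, "_cut"))
  list(label = label, k = k, block_interchange = k %in% 2:4)
}

#' Breakpoints of a genome
#'
#' Adjacencies of `sigma` that disagree with the reference genome: the
#' pairs \eqn{(\sigma^{-1}(i), \sigma^{-1}c(i))} over positions `i` where
#' \eqn{\sigma^{-1}c(i) \ne c\sigma^{-1}(i)}.  Entries keep the sign the
#' algebra produces.  The count satisfies
#' \eqn{bp(\sigma) = (2n - |Fix([\sigma^{-1}, c])|)/2} with the fix taken
#' over all 2n signed labels (so the reference itself has 0 breakpoints),
#' and is the same for every instance of the genome.
#'
#' @param sigma a `signed_perm` (regions to signed positions).
#' @return `breakpoint_set()`: a two-column integer matrix of region pairs;
#'   `breakpoint_count()`: the number of breakpoints.
#' @export
breakpoint_set <- function(sigma) {
  stopifnot(is_signed_perm(sigma))
  n <- sigma$n
  gc <- group_constants(n)
  si <- inverse(sigma)
  pos <- seq_len(n)
  nxt <- apply_perm(gc$c, pos)
  broken <- apply_perm(si, nxt) != apply_perm(gc$c, apply_perm(si, pos))
  cbind(from = apply_perm(si, pos)[broken],
        to = apply_perm(si, nxt)[broken])
}

#' @rdname breakpoint_set
#' @export
breakpoint_count <- function(sigma) {
  stopifnot(is_signed_perm(sigma))
  n <- sigma$n
  gc <- group_constants(n)
  com <- commutator(inverse(sigma), gc$c)
  as.integer((2L * n - length(fix_set(com))) / 2L)
}

#' Breakpoint count in the content paradigm
#'
#' For a genome given as content cycles \eqn{\rho}, the breakpoint count is
#' \eqn{(2n - |Fix(r \rho r c)|)/2} with `r` the all-region flip — the same
#' number as [breakpoint_count()] of any position-paradigm instance of the
#' same genome.
#'
#' @param rho a `content_cycles` object.
#' @return integer breakpoint count.
#' @export
breakpoint_count_content <- function(rho) {
  validate_content_cycles(rho)
  n <- rho$n
  gc <- group_constants(n)
  m <- compose(compose(compose(gc$flip_all, rho$map), gc$flip_all), gc$c)
  as.integer((2L * n - length(fix_set(m))) / 2L)
}

#' @export
print.cut_set <- function(x, ...) {
  cat("cut set, n = ", x$n, ": ", sep = "")
  if (length(x$positions) == 0L) cat("{} (no cuts)\n")
  else cat("{", paste(x$positions, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
print.cut_profile <- function(x, ...) {
  cat("k =", x$k, "cuts")
  if (x$k > 0L) {
    cat("; segment sizes {", paste(x$segment_sizes, collapse = ", "), "}")
  }
  cat("\n")
  invisible(x)
}
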