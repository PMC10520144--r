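# A rearrangement action is the double coset D_n * alpha * D_n: the set of
# instances differing by a flip/rotation applied before (choice of where on
# the circle the event happens) and after (physical symmetry of the result).
# Two instances in one double coset produce identical outcome distributions
# on every genome.

new_action <- function(rep) {
  structure(list(n = rep$n, rep = rep,
                 key = perm_key(rep$image[seq_len(rep$n)], rep$n)),
            class = "action")
}

#' Canonicalize a rearrangement instance to its action
#'
#' Minimizes the one-row image over all products `d1 * alpha * d2` with
#' `d1`, `d2` dihedral.  Two instances get the same action exactly when they
#' lie in the same double coset, i.e. when they induce the same outcome
#' distribution on every genome.
#'
#' @param alpha a `signed_perm` (positions to positions).
#' @return an object of class `action`.
#' @export
canonical_action <- function(alpha) {
  stopifnot(is_signed_perm(alpha))
  n <- alpha$n
  D <- dihedral_group(n)
  best <- NULL
  best_key <- Inf
  for (d2 in D) {
    ad2 <- compose(alpha, d2)
    for (d1 in D) {
      cand <- compose(d1, ad2)
      k <- perm_key(cand$image[seq_len(n)], n)
      if (k < best_key) {
        best_key <- k
        best <- cand
      }
    }
  }
  new_action(best)
}

action_equal <- function(a, b) a$n == b$n && a$key == b$key

#' Apply a rearrangement action to a genome
#'
#' The outcome distribution of the event: for each dihedral `d`, the
#' instance `rep(A) * d * rep(G)` is canonicalized, and each resulting
#' genome gets probability (its multiplicity)/2n.  The result does not
#' depend on which representatives of the action or the genome are used.
#'
#' @param A an `action`.
#' @param G a `genome` with the same number of regions.
#' @return an `outcome_distribution`: genomes with exact probabilities
#'   (integer multiplicities over the denominator 2n).
#' @export
apply_action <- function(A, G) {
  stopifnot(inherits(A, "action"), inherits(G, "genome"))
  if (A$n != G$n) stop("size mismatch: ", A$n, " vs ", G$n, call. = FALSE)
  n <- A$n
  D <- dihedral_group(n)
  outcomes <- lapply(D, function(d) {
    canonical_genome(compose(compose(A$rep, d), G$rep))
  })
  keys <- vapply(outcomes, `[[`, numeric(1), "key")
  ord <- order(keys)
  keys <- keys[ord]
  outcomes <- outcomes[ord]
  first <- !duplicated(keys)
  mult <- as.integer(tabulate(cumsum(first)))
  structure(list(n = n, genomes = outcomes[first], mult = mult,
                 denom = 2L * n),
            class = "outcome_distribution")
}

#' Probabilities of an outcome distribution
#' @param x an `outcome_distribution`.
#' @return numeric vector summing to 1, parallel to `x$genomes`.
#' @export
outcome_probabilities <- function(x) {
  stopifnot(inherits(x, "outcome_distribution"))
  x$mult / x$denom
}

#' @export
as.data.frame.outcome_distribution <- function(x, ...) {
  data.frame(
    genome = vapply(x$genomes, function(g) format_perm(g$rep, "one_row"),
                    character(1)),
    multiplicity = x$mult,
    probability = x$mult / x$denom,
    stringsAsFactors = FALSE)
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat("outcome distribution over", length(x$genomes),
      "genomes (denominator", paste0(x$denom, ")"), "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
print.action <- function(x, ...) {
  cat("rearrangement action (double coset), n =", x$n, "\n")
  cat("  canonical instance: ", format_perm(x$rep, "one_row"),
      " = ", format_perm(x$rep, "cycles"), "\n", sep = "")
  cp <- cut_positions(x$rep)
  cat("  cuts: k = ", length(cp$positions),
      if (length(cp$positions)) paste0(" at {",
                                       paste(cp$positions, collapse = ", "),
                                       "}"),
      "\n", sep = "")
  invisible(x)
}
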