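# A circular genome is the left coset D_n * sigma of an instance sigma: the
# 2n rotations/reflections of one signed permutation.  The canonical
# representative is the lexicographic minimum of the one-row image over the
# coset, under the natural integer order -n < ... < -1 < 1 < ... < n, so
# results are bit-reproducible.

new_genome <- function(rep) {
  structure(list(n = rep$n, rep = rep,
                 key = perm_key(rep$image[seq_len(rep$n)], rep$n)),
            class = "genome")
}

#' Canonicalize a genome instance
#'
#' Maps an instance to the genome it represents: the left coset of the
#' dihedral subgroup, named by its lexicographically minimal instance.  All
#' 2n instances of one circular genome canonicalize identically.
#'
#' @param sigma a `signed_perm` (regions to signed positions).
#' @return an object of class `genome`.
#' @export
canonical_genome <- function(sigma) {
  stopifnot(is_signed_perm(sigma))
  n <- sigma$n
  D <- dihedral_group(n)
  best <- NULL
  best_key <- Inf
  for (d in D) {
    inst <- compose(d, sigma)
    k <- perm_key(inst$image[seq_len(n)], n)
    if (k < best_key) {
      best_key <- k
      best <- inst
    }
  }
  new_genome(best)
}

#' The reference genome
#'
#' The genome of the identity permutation: regions 1..n in clockwise order,
#' all positively oriented.
#'
#' @param n number of regions.
#' @return a `genome`.
#' @export
reference_genome <- function(n) canonical_genome(identity_perm(n))

#' All instances of a genome
#'
#' The 2n pairwise-distinct signed permutations `d * rep` over the dihedral
#' subgroup: every rotation and reflection of the genome.  The left
#' stabilizer is trivial, so the orbit size is exactly 2n.
#'
#' @param G a `genome`.
#' @return list of 2n `signed_perm`s (contains `G$rep`).
#' @export
genome_instances <- function(G) {
  stopifnot(inherits(G, "genome"))
  lapply(dihedral_group(G$n), compose, b = G$rep)
}

#' Enumerate every genome with n regions
#'
#' All \eqn{2^{n-1}(n-1)!} distinct circular genomes, by brute-force
#' canonicalization of the full hyperoctahedral group, in increasing order
#' of canonical representative.
#'
#' @param n number of regions; at most 7 (the state space grows
#'   factorially).
#' @return list of `genome` objects.
#' @export
enumerate_genomes <- function(n) {
  stopifnot(n >= 1L)
  if (n > 7L) {
    stop("refusing n = ", n, ": there would be ",
         format(2^(n - 1) * factorial(n - 1), big.mark = ",",
                scientific = FALSE),
         " genomes; supported up to n = 7", call. = FALSE)
  }
  n <- as.integer(n)
  keys <- sort(unique(hyperoct_coset_keys(n)$keys))
  lapply(keys, function(k) new_genome(make_perm(key_to_row(k, n))))
}

#' @export
print.genome <- function(x, ...) {
  cat("circular genome, n = ", x$n, " (one of ", 2L * x$n,
      " instances)\n", sep = "")
  cat("  canonical instance: ", format_perm(x$rep, "one_row"), "\n", sep = "")
  invisible(x)
}

genome_equal <- function(a, b) a$n == b$n && a$key == b$key
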