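# Shared fixtures and independent oracles used across the suite.

# the running 5-region example genome instance (regions -> signed positions)
sigma_example <- function() make_perm(c(-1, 4, 3, -5, -2))

# the printed 3-region inversion instance on 5 regions
alpha_example <- function() parse_perm("(3 -3)(2 -4)(-2 4)", 5)

random_signed_perm <- function(n) {
  make_perm(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# oracle: dihedral subgroup by closure from the two generators, independent
# of the r^j / r^j f construction used in the package
dihedral_by_closure <- function(n) {
  gc <- group_constants(n)
  seen <- character(0)
  frontier <- list(identity_perm(n))
  seen <- format_perm(identity_perm(n))
  out <- frontier
  while (length(frontier) > 0) {
    nxt <- list()
    for (g in frontier) {
      for (h in list(gc$rotation, gc$reflection)) {
        cand <- compose(h, g)
        key <- format_perm(cand)
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          out[[length(out) + 1]] <- cand
          nxt[[length(nxt) + 1]] <- cand
        }
      }
    }
    frontier <- nxt
  }
  out
}

# oracle: breakpoints by reading the clockwise region sequence and checking
# each adjacency against the reference successor, with plain modular
# arithmetic (no group composition)
breakpoints_by_adjacency <- function(sigma) {
  n <- sigma$n
  seq_regions <- apply_perm(inverse(sigma), 1:n)  # region at each position
  succ <- function(a) {
    if (a > 0) a %% n + 1 else -((-a - 2) %% n + 1)
  }
  broken <- 0L
  for (i in 1:n) {
    a <- seq_regions[i]
    b <- seq_regions[i %% n + 1]
    if (b != succ(a)) broken <- broken + 1L
  }
  broken
}

# oracle: minimal genome over an orbit by explicit pairwise lexicographic
# comparison of one-row images (no integer encoding)
lex_min_instance <- function(perms) {
  rows <- lapply(perms, function(p) p$image[seq_len(p$n)])
  best <- 1L
  for (i in seq_along(rows)[-1L]) {
    a <- rows[[i]]; b <- rows[[best]]
    d <- which(a != b)
    if (length(d) > 0 && a[d[1]] < b[d[1]]) best <- i
  }
  perms[[best]]
}

# oracle: BFS shortest path from dense boolean reachability on a transition
# matrix (independent of the package's frontier search)
distance_by_matrix_powers <- function(tm, i, j) {
  if (i == j) return(0L)
  A <- tm$P > 0
  diag(A) <- FALSE
  reach <- A
  for (steps in seq_len(length(tm$states))) {
    if (reach[i, j]) return(steps)
    reach <- (reach %*% A) > 0
  }
  Inf
}
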