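# A rearrangement model is a set of distinct actions with probabilities
# summing to one.  Combined with the outcome distributions of the actions
# it induces a Markov chain whose states are the genomes themselves.

#' Build a rearrangement model
#'
#' Canonicalizes each instance to its action and attaches the weights.
#' Two instances lying in one double coset describe the same action; such
#' duplicates are rejected, as are weights that are nonpositive or do not
#' sum exactly to 1.  Weights may be fraction strings (`"2/5"`) or
#' numerics (rationalized exactly).
#'
#' @param n number of regions.
#' @param instances list of `signed_perm` rearrangement instances (or
#'   `action` objects).
#' @param weights vector (or list) of probabilities, one per instance.
#' @return object of class `rearr_model`.
#' @export
build_model <- function(n, instances, weights) {
  stopifnot(length(instances) == length(weights), length(instances) >= 1L)
  actions <- lapply(instances, function(a) {
    if (inherits(a, "action")) a else canonical_action(a)
  })
  if (any(vapply(actions, `[[`, integer(1), "n") != n)) {
    stop("all instances must act on n = ", n, " regions", call. = FALSE)
  }
  keys <- vapply(actions, `[[`, numeric(1), "key")
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1L]
    first <- which(keys == keys[d])[1L]
    stop("instances ", first, " and ", d, " lie in the same double coset (",
         format_perm(actions[[d]]$rep, "cycles"),
         "): they are the same rearrangement action", call. = FALSE)
  }
  w <- lapply(if (is.list(weights)) weights else as.list(weights), rat_parse)
  num <- vapply(w, `[`, numeric(1), 1L)
  den <- vapply(w, `[`, numeric(1), 2L)
  if (any(num <= 0)) stop("weights must be positive", call. = FALSE)
  L <- Reduce(lcm2, den)
  if (sum(num * (L / den)) != L) {
    stop("weights must sum to 1 exactly", call. = FALSE)
  }
  structure(list(n = as.integer(n), actions = actions,
                 w_num = num, w_den = den),
            class = "rearr_model")
}

#' Model weights as numerics
#' @param M a `rearr_model`.
#' @return numeric vector of action probabilities.
#' @export
model_weights <- function(M) {
  stopifnot(inherits(M, "rearr_model"))
  M$w_num / M$w_den
}

#' All inversions, all actions equally likely
#'
#' The `floor(n/2)` distinct inversion actions with equal probability —
#' the usual inversion-distance model.  Note that with equal *action*
#' weights the one-step outcome genomes are not all equally likely when
#' support sizes differ (see [uniform_outcome_inversion_model()]).
#'
#' @param n number of regions (>= 2).
#' @return a `rearr_model`.
#' @export
all_inversions_model <- function(n) {
  acts <- inversion_actions(n)
  m <- length(acts)
  build_model(n, acts, rep(paste0("1/", m), m))
}

#' Inversion model with uniform outcomes
#'
#' Weights each inversion action proportionally to the support size of its
#' outcome distribution on the reference genome, so that every genome
#' reachable in one step is equally likely.  For n = 6 this gives weights
#' 2/5, 2/5, 1/5 to the 1-, 2- and 3-region inversions (the 3-region
#' action has 3 outcomes where the others have 6).
#'
#' @param n number of regions (>= 2).
#' @return a `rearr_model`.
#' @export
uniform_outcome_inversion_model <- function(n) {
  acts <- inversion_actions(n)
  ref <- reference_genome(n)
  supp <- vapply(acts, function(a) length(apply_action(a, ref)$genomes),
                 integer(1))
  build_model(n, acts, paste0(supp, "/", sum(supp)))
}

#' Transition matrix of the induced Markov chain
#'
#' States are all genomes with n regions (in the deterministic order of
#' [enumerate_genomes()]); the transition probability from G to G' is the
#' weight-averaged outcome probability over the model's actions.  Entries
#' are exact rationals over a common denominator; every row sums to
#' exactly 1.  Outcomes equal to the source genome stay on the diagonal
#' (no renormalization).
#'
#' @param M a `rearr_model` with `n <= 6`.
#' @return object of class `transition_matrix`: `states` (list of
#'   genomes), `P` (numeric row-stochastic matrix), `num` (integer
#'   numerators) and `denom` (the common denominator).
#' @export
transition_matrix <- function(M) {
  stopifnot(inherits(M, "rearr_model"))
  n <- M$n
  if (n > 6L) {
    stop("refusing n = ", n, ": the chain would have ",
         format(2^(n - 1) * factorial(n - 1), big.mark = ",",
                scientific = FALSE),
         " states; supported up to n = 6", call. = FALSE)
  }
  states <- enumerate_genomes(n)
  keys <- vapply(states, `[[`, numeric(1), "key")
  L <- Reduce(lcm2, M$w_den)
  denom <- 2L * n * L
  N <- length(states)
  num <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (a in seq_along(M$actions)) {
      out <- apply_action(M$actions[[a]], states[[i]])
      j <- match(vapply(out$genomes, `[[`, numeric(1), "key"), keys)
      scale <- M$w_num[a] * (L / M$w_den[a])
      num[i, j] <- num[i, j] + scale * out$mult
    }
  }
  structure(list(states = states, keys = keys, P = num / denom,
                 num = num, denom = denom),
            class = "transition_matrix")
}

#' Minimum number of model steps between two genomes
#'
#' Breadth-first search over the support graph of the model's Markov chain
#' (edges are the nonzero off-diagonal transition probabilities; self
#' loops are ignored).  When every action's double coset contains its own
#' inverse — true for inversions, which are involutions — the distance is
#' symmetric.  Under the all-inversions model this is the inversion
#' distance.
#'
#' @param M a `rearr_model`.
#' @param G1,G2 `genome` objects with the model's n.
#' @return integer number of steps, or `Inf` if `G2` is unreachable.
#' @export
min_steps_distance <- function(M, G1, G2) {
  stopifnot(inherits(M, "rearr_model"),
            inherits(G1, "genome"), inherits(G2, "genome"))
  if (G1$n != M$n || G2$n != M$n) {
    stop("genomes must have the model's n = ", M$n, call. = FALSE)
  }
  if (genome_equal(G1, G2)) return(0L)
  visited <- G1$key
  frontier <- list(G1)
  dist <- 0L
  while (length(frontier) > 0L) {
    dist <- dist + 1L
    nxt <- list()
    for (g in frontier) {
      for (a in M$actions) {
        for (h in apply_action(a, g)$genomes) {
          if (h$key %in% visited) next
          if (h$key == G2$key) return(dist)
          visited <- c(visited, h$key)
          nxt[[length(nxt) + 1L]] <- h
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

#' @export
print.rearr_model <- function(x, ...) {
  cat("rearrangement model, n = ", x$n, ", ", length(x$actions),
      " actions\n", sep = "")
  for (i in seq_along(x$actions)) {
    cat(sprintf("  w = %d/%d  %s\n", x$w_num[i], x$w_den[i],
                format_perm(x$actions[[i]]$rep, "cycles")))
  }
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Markov chain on", length(x$states), "genomes; common denominator",
      x$denom, "\n")
  invisible(x)
}
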