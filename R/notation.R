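# Text notations: one-row "[1 -4 -3 -2 5]" and cycles "(3 -3)(2 -4)(-2 4)".
# Fixed points are omitted in cycle notation; "()" is the identity.

#' Parse a permutation from text
#'
#' Accepts one-row notation (`"[1 -4 3]"` or bare whitespace-separated signed
#' integers, one entry per region) or cycle notation
#' (`"(3 -3)(2 -4)(-2 4)"`, comma or whitespace separated, omitted labels
#' fixed).  A one-row string is extended to the negative labels by the sign
#' rule and always yields a `signed_perm`; a cycle string describes the map
#' literally and is tagged `signed_perm` only if it happens to respect the
#' sign rule.
#'
#' @param text character scalar.
#' @param n number of regions.
#' @return a `signed_map`, of class `signed_perm` when the sign rule holds.
#' @export
parse_perm <- function(text, n) {
  stopifnot(is.character(text), length(text) == 1L, n >= 1L)
  text <- trimws(text)
  if (grepl("(", text, fixed = TRUE)) {
    parse_cycles(text, n)
  } else {
    body <- gsub("[][,]", " ", text)
    vals <- suppressWarnings(as.integer(strsplit(trimws(body), "\\s+")[[1L]]))
    if (anyNA(vals) || length(vals) == 0L) {
      stop("malformed one-row permutation text: ", sQuote(text), call. = FALSE)
    }
    if (length(vals) != n) {
      stop("one-row notation needs exactly n = ", n, " entries, got ",
           length(vals), call. = FALSE)
    }
    make_perm(vals)
  }
}

parse_cycles <- function(text, n) {
  stripped <- gsub("\\([^()]*\\)", "", gsub("\\s", "", text))
  if (nzchar(stripped)) {
    stop("malformed cycle notation: ", sQuote(text), call. = FALSE)
  }
  m <- gregexpr("\\(([^()]*)\\)", text)[[1L]]
  bodies <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1L]]
  image <- c(seq_len(n), -seq_len(n))
  seen <- logical(2L * n)
  for (b in bodies) {
    inner <- trimws(gsub("[(),]", " ", b))
    if (!nzchar(inner)) next  # "()" = identity cycle
    labs <- suppressWarnings(as.integer(strsplit(inner, "\\s+")[[1L]]))
    if (anyNA(labs) || any(labs == 0L)) {
      stop("malformed cycle: ", sQuote(b), call. = FALSE)
    }
    if (any(abs(labs) > n)) {
      stop("label out of range in cycle ", sQuote(b), ": |label| > ", n,
           call. = FALSE)
    }
    idx <- lab_index(labs, n)
    if (any(seen[idx]) || anyDuplicated(idx)) {
      stop("label repeated across cycles in ", sQuote(text), call. = FALSE)
    }
    seen[idx] <- TRUE
    if (length(labs) > 1L) {
      image[idx] <- labs[c(seq_along(labs)[-1L], 1L)]
    }
  }
  validate_bijection(image, n)
  new_signed_map(n, image)
}

#' Format a permutation as text
#'
#' Inverse of [parse_perm()]: `parse_perm(format_perm(p, style), p$n)`
#' reproduces `p`.  One-row style is only defined for sign-rule-respecting
#' permutations (the positive row alone determines them); cycle style works
#' for any signed map.
#'
#' @param p a `signed_map`.
#' @param style `"one_row"` or `"cycles"`.
#' @return character scalar.
#' @export
format_perm <- function(p, style = c("one_row", "cycles")) {
  stopifnot(inherits(p, "signed_map"))
  style <- match.arg(style)
  n <- p$n
  if (style == "one_row") {
    if (!is_signed_perm(p)) {
      stop("one-row notation is only defined for sign-rule permutations; ",
           "use style = \"cycles\"", call. = FALSE)
    }
    return(paste0("[", paste(p$image[seq_len(n)], collapse = " "), "]"))
  }
  done <- logical(2L * n)
  out <- character(0)
  for (j in seq_len(2L * n)) {
    if (done[j]) next
    start <- index_lab(j, n)
    if (p$image[j] == start) {
      done[j] <- TRUE
      next
    }
    cyc <- start
    x <- p$image[j]
    done[j] <- TRUE
    while (x != start) {
      cyc <- c(cyc, x)
      xi <- lab_index(x, n)
      done[xi] <- TRUE
      x <- p$image[xi]
    }
    out <- c(out, paste0("(", paste(cyc, collapse = " "), ")"))
  }
  if (length(out) == 0L) "()" else paste(out, collapse = "")
}
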