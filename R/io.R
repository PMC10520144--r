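# GRIMM-style signed gene-order files: a ">name" header line followed by
# whitespace-separated signed integers; a "$" terminator (circular-genome
# marker) is tolerated and dropped.  Only circular, signed records are
# accepted.

#' Read signed genomes from a GRIMM-style file
#'
#' @param path file of records `>name` followed by n signed integers.
#' @return named list of `signed_perm`s, one per record; all records must
#'   share one n.
#' @export
read_genomes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty genome file: ", path, call. = FALSE)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("file must start with a '>' record header", call. = FALSE)
  rec_id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  out <- vector("list", length(names))
  for (i in seq_along(names)) {
    body <- paste(lines[rec_id == i & !hdr], collapse = " ")
    toks <- strsplit(trimws(body), "\\s+")[[1L]]
    toks <- toks[toks != "$"]
    vals <- suppressWarnings(as.integer(toks))
    if (length(vals) == 0L || anyNA(vals)) {
      stop("record ", sQuote(names[i]), ": malformed signed integers",
           call. = FALSE)
    }
    out[[i]] <- tryCatch(make_perm(vals), error = function(e) {
      stop("record ", sQuote(names[i]), ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ns <- vapply(out, `[[`, integer(1), "n")
  if (length(unique(ns)) > 1L) {
    stop("records disagree on the number of regions: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  }
  names(out) <- names
  out
}

#' Write signed genomes to a GRIMM-style file
#' @param genomes named list of `signed_perm`s.
#' @param path output file.
#' @export
write_genomes <- function(genomes, path) {
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)))
  lines <- unlist(lapply(names(genomes), function(nm) {
    p <- genomes[[nm]]
    c(paste0(">", nm), paste(c(p$image[seq_len(p$n)], "$"), collapse = " "))
  }))
  writeLines(lines, path)
}

#' Export a count table as text
#'
#' One row per table: columns `n`, `mode`, `hn` (group order), `total`,
#' then `k0..kn`, with explicit zeros for impossible cut numbers.
#'
#' @param table a `count_table` from [count_by_cuts()].
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return character scalar (csv/markdown: lines joined by newlines).
#' @export
export_counts <- function(table, format = c("csv", "json", "markdown")) {
  stopifnot(inherits(table, "count_table"))
  format <- match.arg(format)
  ks <- paste0("k", names(table$counts))
  if (format == "json") {
    obj <- list(n = table$n, mode = table$mode, hn = table$hn,
                total = table$total,
                counts = as.list(stats::setNames(as.numeric(table$counts),
                                                 ks)))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA)))
  }
  header <- c("n", "mode", "hn", "total", ks)
  row <- c(table$n, table$mode, table$hn, table$total,
           as.integer(table$counts))
  if (format == "csv") {
    return(paste(paste(header, collapse = ","),
                 paste(row, collapse = ","), sep = "\n"))
  }
  paste(paste0("| ", paste(header, collapse = " | "), " |"),
        paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
        paste0("| ", paste(row, collapse = " | "), " |"),
        sep = "\n")
}

#' Parse a count table back from exported text
#'
#' Inverse of [export_counts()] for the `"csv"` and `"json"` formats.
#'
#' @param text character scalar as produced by [export_counts()].
#' @param format `"csv"` or `"json"`.
#' @return a `count_table`.
#' @export
import_counts <- function(text, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::fromJSON(text)
    counts <- as.integer(unlist(obj$counts))
    names(counts) <- sub("^k", "", names(obj$counts))
    return(structure(list(n = as.integer(obj$n), mode = obj$mode,
                          hn = obj$hn, total = as.integer(obj$total),
                          counts = counts),
                     class = "count_table"))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  row <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  kcols <- grepl("^k[0-9]+$", header)
  counts <- as.integer(row[kcols])
  names(counts) <- sub("^k", "", header[kcols])
  structure(list(n = as.integer(row[header == "n"]),
                 mode = row[header == "mode"],
                 hn = as.numeric(row[header == "hn"]),
                 total = as.integer(row[header == "total"]),
                 counts = counts),
            class = "count_table")
}
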