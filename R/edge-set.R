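#' Construct a bipartite edge set
#'
#' An `edge_set` holds one bipartite relation of the heterogeneous network:
#' a set of undirected cross-edges between two node kinds (for example
#' miRNA--disease).  Duplicate pairs are collapsed, node names are
#' whitespace-trimmed, and empty names are rejected.
#'
#' @param left character vector of left-side node names.
#' @param right character vector of right-side node names (same length).
#' @param left_kind,right_kind node-kind labels, e.g. `"miRNA"`, `"disease"`.
#' @return An object of class `edge_set` with elements `left_kind`,
#'   `right_kind` and `edges` (a two-column character data frame with one row
#'   per distinct pair).
#' @examples
#' edge_set(c("m1", "m1"), c("d1", "d1"), "miRNA", "disease")  # 1 edge
#' @export
edge_set <- function(left = character(), right = character(),
                     left_kind, right_kind) {
  stopifnot(length(left) == length(right),
            is.character(left_kind), length(left_kind) == 1L,
            is.character(right_kind), length(right_kind) == 1L)
  left <- trimws(as.character(left))
  right <- trimws(as.character(right))
  if (any(!nzchar(left)) || any(!nzchar(right)))
    stop("edge_set: empty node name after whitespace trimming", call. = FALSE)
  keep <- !duplicated(paste(left, right, sep = "\r"))
  out <- list(left_kind = left_kind, right_kind = right_kind,
              edges = data.frame(left = left[keep], right = right[keep],
                                 stringsAsFactors = FALSE))
  class(out) <- "edge_set"
  out
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %s--%s: %d edges, %d %ss, %d %ss\n",
              x$left_kind, x$right_kind, nrow(x$edges),
              length(unique(x$edges$left)), x$left_kind,
              length(unique(x$edges$right)), x$right_kind))
  invisible(x)
}

#' @export
length.edge_set <- function(x) nrow(x$edges)

#' Read a two-column edge list from a TSV file
#'
#' Expects tab-separated lines `left<TAB>right`.  Lines starting with `#`
#' are comments; one optional header line (detected as the first
#' non-comment line whose fields repeat as no other line's -- in practice,
#' pass `header = TRUE`/`FALSE` to be explicit) is skipped.  Duplicate rows
#' are collapsed; the number collapsed is reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param left_kind,right_kind node-kind labels for validation downstream.
#' @param header `TRUE` to skip the first non-comment line, `FALSE` to read
#'   it as data, or `"auto"` (default) to skip it only when its two fields
#'   equal the kind labels (the header [write_edge_list()] emits), compared
#'   case-insensitively.  Files with other header conventions should pass
#'   `header = TRUE` explicitly.
#' @return An [edge_set()].
#' @export
read_edge_list <- function(path, left_kind, right_kind, header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]; lineno <- lineno[keep]
  if (identical(header, "auto") && length(raw)) {
    first <- trimws(strsplit(raw[[1L]], "\t", fixed = TRUE)[[1L]])
    header <- length(first) >= 2L &&
      identical(tolower(first[1:2]), tolower(c(left_kind, right_kind)))
  }
  if (isTRUE(header) && length(raw)) { raw <- raw[-1L]; lineno <- lineno[-1L] }
  if (!length(raw)) return(edge_set(left_kind = left_kind, right_kind = right_kind))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop(sprintf("parse error at line %d of %s: fewer than 2 tab-separated fields",
                 lineno[which(nf < 2L)[1L]], path), call. = FALSE)
  left <- trimws(vapply(parts, `[`, "", 1L))
  right <- trimws(vapply(parts, `[`, "", 2L))
  bad <- !nzchar(left) | !nzchar(right)
  if (any(bad))
    stop(sprintf("parse error at line %d of %s: empty node name",
                 lineno[which(bad)[1L]], path), call. = FALSE)
  n_dup <- sum(duplicated(paste(left, right, sep = "\r")))
  if (n_dup > 0L)
    message(sprintf("read_edge_list: collapsed %d duplicate line(s) in %s",
                    n_dup, path))
  edge_set(left, right, left_kind, right_kind)
}

#' Write an edge set as a two-column TSV
#'
#' @param x an [edge_set()].
#' @param path output path.
#' @param header write a `left_kind<TAB>right_kind` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, header = TRUE) {
  stopifnot(inherits(x, "edge_set"))
  lines <- paste(x$edges$left, x$edges$right, sep = "\t")
  if (header) lines <- c(paste(x$left_kind, x$right_kind, sep = "\t"), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
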