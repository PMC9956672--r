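## Line-oriented text serialization of admixture graphs and DOT export.
##
## Format: a header line `@outgroup <label> <c0>`, then one edge per line
## `child<TAB>parent<TAB>length[<TAB>w=<float><TAB>type={main|admix}]`;
## `#` starts a comment.

#' Write an admixture graph to a text file
#'
#' @param g an `admixture_graph`.
#' @param path output file path (or a connection).
#' @return `path`, invisibly. `read_graph(write_graph(g, p))` reproduces
#'   `g` exactly.
#' @export
write_graph <- function(g, path) {
  lines <- c(sprintf("@outgroup %s %.17g", g$outgroup, g$outgroup_length))
  for (e in seq_along(g$child)) {
    ln <- sprintf("%s\t%s\t%.17g", g$child[e], g$parent[e], g$length[e])
    if (g$type[e] %in% c("main", "admix"))
      ln <- sprintf("%s\tw=%.17g\ttype=%s", ln, g$prop[e], g$type[e])
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an admixture graph from a text file
#'
#' @param path file path written by [write_graph()].
#' @param validate check the parsed graph.
#' @return An `admixture_graph`.
#' @export
read_graph <- function(path, validate = TRUE) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^@outgroup\\b", lines)
  if (length(hdr) != 1L)
    stop("graph file needs exactly one '@outgroup <label> <c0>' line")
  hp <- strsplit(lines[hdr], "\\s+")[[1L]]
  if (length(hp) != 3L) stop("malformed @outgroup header")
  outgroup <- hp[2L]; c0 <- as.numeric(hp[3L])
  body <- lines[-hdr]
  child <- parent <- type <- character(length(body))
  len <- prop <- numeric(length(body))
  type[] <- "normal"; prop[] <- NA_real_
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L) f <- strsplit(body[i], "\\s+")[[1L]]
    if (!(length(f) %in% c(3L, 5L)))
      stop(sprintf("graph line %d: expected 3 or 5 fields, found %d",
                   i, length(f)))
    child[i] <- f[1L]; parent[i] <- f[2L]; len[i] <- as.numeric(f[3L])
    if (length(f) == 5L) {
      prop[i] <- as.numeric(sub("^w=", "", f[4L]))
      type[i] <- sub("^type=", "", f[5L])
    }
  }
  g <- new_graph(child, parent, len, type, prop, outgroup, c0)
  if (validate) {
    v <- validate_graph(g)
    if (length(v)) stop("invalid graph in ", path, ": ",
                        paste(v, collapse = "; "))
  }
  g
}

#' Export a graph or minimal topology as a DOT file
#'
#' Admixture ("admix"-typed) edges are dashed; for minimal topologies,
#' node posterior frequencies can be annotated inside the nodes.
#'
#' @param x an `admixture_graph` or `minimal_topology`.
#' @param path output file path.
#' @param frequencies optional named vector of node frequencies (names are
#'   set keys) displayed as percentages; defaults to the `frequencies`
#'   attribute, if any.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path, frequencies = attr(x, "frequencies")) {
  q <- function(s) paste0('"', s, '"')
  lines <- c("digraph admixture {", "  node [shape=box];")
  if (inherits(x, "admixture_graph")) {
    lines <- c(lines, sprintf("  %s -> %s;", q(x$outgroup),
                              q(graph_root(x))))
    for (e in seq_along(x$child)) {
      style <- if (x$type[e] == "admix")
        sprintf(" [style=dashed, label=\"w=%.2f\"]", x$prop[e]) else ""
      lines <- c(lines, sprintf("  %s -> %s%s;", q(x$parent[e]),
                                q(x$child[e]), style))
    }
  } else if (inherits(x, "minimal_topology")) {
    for (nd in x$nodes) {
      lab <- gsub(",", ", ", nd)
      if (!is.null(frequencies) && nd %in% names(frequencies))
        lab <- sprintf("%s (%.0f%%)", lab, 100 * frequencies[[nd]])
      lines <- c(lines, sprintf("  %s [label=%s];", q(nd), q(lab)))
    }
    for (i in seq_len(nrow(x$edges)))
      lines <- c(lines, sprintf("  %s -> %s;", q(x$edges$from[i]),
                                q(x$edges$to[i])))
  } else stop("cannot render this object as DOT")
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
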