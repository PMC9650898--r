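#' Export scaffold hierarchies
#'
#' `export_frequencies()` writes a TSV with columns `smiles`, `frequency`,
#' `virtual`, `level`, sorted by frequency (descending) then SMILES
#' (ascending, byte order) -- deterministic and byte-identical across
#' runs. `export_adjacency()` writes the 0/1 parent-of matrix as TSV with
#' the sorted keys as header and row names. `export_dot()` and
#' `export_graphml()` write the parent-to-child edge list with node
#' attributes (SMILES key, level, frequency, virtual flag).
#'
#' @param x a `scaffold_tree` or `scaffold_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_frequencies <- function(x, path) {
  df <- frequency_table(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(paste(df$smiles, df$frequency, tolower(df$virtual),
                     df$level, sep = "\t"), con)
  }
  invisible(path)
}

# frequency table used by exports and the snapshot protocol
frequency_table <- function(x) {
  if (inherits(x, "scaffold_forest")) {
    tabs <- lapply(x$trees, frequency_table)
    df <- do.call(rbind, tabs)
    if (is.null(df)) df <- data.frame(smiles = character(),
                                      frequency = integer(),
                                      virtual = logical(),
                                      level = integer())
    df <- stats::aggregate(cbind(frequency = df$frequency) ~ smiles +
                             virtual + level, data = df, FUN = sum)
    df <- df[, c("smiles", "frequency", "virtual", "level")]
  } else {
    keys <- node_keys(x)
    freq <- node_frequencies(x)
    lev <- node_levels(x)
    virt <- vapply(keys, function(k)
      is_virtual_node(x$nodes[[map_key(k)]]), logical(1))
    df <- data.frame(smiles = keys,
                     frequency = unname(freq[match(keys, names(freq))]),
                     virtual = unname(virt),
                     level = unname(lev[match(keys, names(lev))]),
                     stringsAsFactors = FALSE)
  }
  df[order(-df$frequency, df$smiles, method = "radix"), , drop = FALSE]
}

#' @rdname export_frequencies
#' @export
export_adjacency <- function(x, path) {
  adj <- to_adjacency(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("", adj$keys), collapse = "\t"), con)
  for (i in seq_along(adj$keys)) {
    writeLines(paste(c(adj$keys[i], adj$matrix[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

# igraph view with node attributes, shared by DOT and GraphML export
hierarchy_igraph <- function(x) {
  keys <- node_keys(x)
  freq <- node_frequencies(x)
  lev <- node_levels(x)
  virt <- vapply(keys, function(k)
    is_virtual_node(x$nodes[[map_key(k)]]), logical(1))
  edges <- character()
  for (node in x$nodes) {
    for (p in node$parent_keys) {
      edges <- c(edges, p, node$smiles_key)
    }
  }
  g <- igraph::make_empty_graph(n = length(keys), directed = TRUE)
  igraph::V(g)$name <- keys
  if (length(edges)) {
    g <- igraph::add_edges(g, match(edges, keys))
  }
  igraph::V(g)$smiles_key <- keys
  igraph::V(g)$level <- unname(lev[match(keys, names(lev))])
  igraph::V(g)$frequency <- unname(freq[match(keys, names(freq))])
  igraph::V(g)$virtual <- unname(virt)
  g
}

#' @rdname export_frequencies
#' @export
export_graphml <- function(x, path) {
  g <- hierarchy_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_frequencies
#' @export
export_dot <- function(x, path) {
  keys <- node_keys(x)
  freq <- node_frequencies(x)
  lev <- node_levels(x)
  esc <- function(s) gsub("\"", "\\\\\"", s)
  lines <- c("digraph scaffolds {")
  for (k in keys) {
    virt <- is_virtual_node(x$nodes[[map_key(k)]])
    i <- match(k, names(lev))
    j <- match(k, names(freq))
    lines <- c(lines, sprintf(
      "  \"%s\" [label=\"%s\" level=%d frequency=%d virtual=%s];",
      esc(k), esc(k), lev[[i]], freq[[j]], tolower(virt)))
  }
  for (node in x$nodes) {
    for (p in sort(node$parent_keys, method = "radix")) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", esc(p),
                                esc(node$smiles_key)))
    }
  }
  lines <- c(lines, "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
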