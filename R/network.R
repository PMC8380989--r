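#' Build the significant trait-trait correlation network
#'
#' Edges are exactly the correlation records with `q` below the cutoff;
#' the node set is the union of edge endpoints plus every measured
#' trait, so traits without a significant partner remain as flagged
#' isolated nodes (dropping them would hide negative results).
#'
#' @param records correlation records from [correlate_all()].
#' @param q_cutoff edge inclusion cutoff (default 0.01, the convention
#'   for trait-trait families).
#' @param nodes optional `data.frame` with columns `name` and `class`
#'   annotating all measured traits; defaults to the record endpoints.
#' @return A list of class `trait_network` with `nodes` (`name`,
#'   `class`, `isolated`) and `edges` (`from`, `to`, `gcc`, `q`,
#'   `sign`).
#' @export
build_network <- function(records, q_cutoff = 0.01, nodes = NULL) {
  sig <- !is.na(records$q) & records$q < q_cutoff
  edges <- data.frame(
    from = records$x_name[sig],
    to = records$y_name[sig],
    gcc = records$gcc[sig],
    q = records$q[sig],
    sign = ifelse(records$gcc[sig] >= 0, "pos", "neg"),
    stringsAsFactors = FALSE
  )
  keep <- edges$from != edges$to
  edges <- edges[keep, , drop = FALSE]
  pair_id <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(pair_id), , drop = FALSE]
  rownames(edges) <- NULL
  all_names <- unique(c(records$x_name, records$y_name))
  if (is.null(nodes)) {
    nodes <- data.frame(name = all_names, class = NA_character_,
                        stringsAsFactors = FALSE)
  }
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  extra <- setdiff(all_names, nodes$name)
  if (length(extra) > 0) {
    nodes <- rbind(nodes, data.frame(name = extra, class = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  nodes$isolated <- !(nodes$name %in% c(edges$from, edges$to))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, q_cutoff = q_cutoff),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat("trait_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$isolated), "isolated ),", nrow(x$edges),
      "edges at q <", x$q_cutoff, "\n")
  invisible(x)
}

#' Export a trait network for Cytoscape-style tools
#'
#' SIF output is the three-column simple interaction format with the
#' interaction type `pos` or `neg`; GraphML output carries `gcc`, `q`,
#' and `sign` edge attributes and the node `class`/`isolated`
#' attributes, and re-imports losslessly with [read_network_graphml()].
#'
#' @param net a `trait_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("usage error: unknown network format",
                            call. = FALSE))
  if (format == "sif") {
    lines <- if (nrow(net$edges) > 0) {
      sprintf("%s\t%s\t%s", net$edges$from, net$edges$sign, net$edges$to)
    } else character(0)
    lines <- c(lines, net$nodes$name[net$nodes$isolated])
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = net$nodes$name,
                            class = ifelse(is.na(net$nodes$class), "",
                                           net$nodes$class),
                            isolated = net$nodes$isolated,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return A list with `nodes` and `edges` data frames (edge attribute
#'   multiset matches the export).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  list(nodes = nodes, edges = edges)
}
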