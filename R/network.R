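#' Load a confidence-filtered interaction network
#'
#' Reads a STRING-flavoured edge list (`node_a<TAB>node_b<TAB>confidence`,
#' with header), drops edges below the confidence threshold, collapses
#' duplicate/reciprocal edges keeping the maximum confidence, and removes
#' self-loops with a warning. The confidence scale is never auto-detected:
#' scores are `[0, 1]` by default, or STRING's `[0, 1000]` (divided by
#' 1000) when `string_scale = TRUE`.
#'
#' @param edge_file Path to the edge-list TSV.
#' @param min_confidence Minimum confidence kept (default 0.15, the
#'   published STRING exploration default).
#' @param string_scale Interpret confidences on the 0--1000 STRING scale.
#' @param labels Optional node-label data frame (`protein`, `family`) or
#'   path to such a TSV.
#' @return Object of class `bhlh_network` wrapping an undirected
#'   [igraph::graph] with edge attribute `confidence` and optional vertex
#'   attribute `family`.
#' @export
load_network <- function(edge_file, min_confidence = 0.15,
                         string_scale = FALSE, labels = NULL) {
  edges <- read_checked_tsv(edge_file, c("node_a", "node_b", "confidence"))
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  build_network(edges, min_confidence, string_scale, labels)
}

#' @rdname load_network
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`.
#' @export
build_network <- function(edges, min_confidence = 0.15,
                          string_scale = FALSE, labels = NULL) {
  conf <- as.numeric(edges$confidence)
  hi <- if (string_scale) 1000 else 1
  if (any(is.na(conf)) || any(conf < 0 | conf > hi)) {
    stop("confidence outside [0, ", hi, "]",
         if (!string_scale) " (use string_scale = TRUE for 0-1000 scores)")
  }
  if (string_scale) conf <- conf / 1000
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    warning("removed ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
    conf <- conf[!loops]
  }
  keep <- conf >= min_confidence
  edges <- edges[keep, , drop = FALSE]
  conf <- conf[keep]
  # collapse duplicates (either orientation) keeping max confidence
  if (nrow(edges)) {
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b), sep = "\r")
    ord <- order(key, -conf)
    first <- !duplicated(key[ord])
    edges <- edges[ord[first], , drop = FALSE]
    conf <- conf[ord[first]]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$node_a, to = edges$node_b,
               confidence = conf, stringsAsFactors = FALSE),
    directed = FALSE)
  if (!is.null(labels)) {
    if (is.character(labels)) {
      labels <- read_checked_tsv(labels, c("protein", "family"))
    }
    fam <- as.character(labels$family[match(igraph::V(g)$name,
                                            labels$protein)])
    igraph::V(g)$family <- fam
  }
  structure(list(graph = g, min_confidence = min_confidence),
            class = "bhlh_network")
}

#' Hub proteins of a network
#'
#' Hubs are nodes with at least `hub_threshold` distinct interaction
#' partners (degree counts distinct neighbors, never multi-edges), the
#' published definition with threshold 5.
#'
#' @param net A [load_network()] object.
#' @param hub_threshold Minimum degree (default 5).
#' @return Data frame `protein`, `degree`, sorted by descending degree then
#'   protein id.
#' @export
find_hubs <- function(net, hub_threshold = 5) {
  deg <- igraph::degree(net$graph)
  hubs <- deg[deg >= hub_threshold]
  out <- data.frame(protein = names(hubs), degree = as.integer(hubs),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-family interaction modules
#'
#' For every family label, the connected components (>= 2 nodes) of the
#' subgraph induced by that family's nodes -- the "tight network or
#' functional module within their protein families" of the published
#' survey.
#'
#' @param net A [load_network()] object with a `family` vertex attribute,
#'   or supply `labels`.
#' @param labels Optional node-label data frame (`protein`, `family`).
#' @return Data frame `family`, `module` (index within family), `size`,
#'   `members` (comma-joined, sorted).
#' @export
family_modules <- function(net, labels = NULL) {
  g <- net$graph
  if (!is.null(labels)) {
    fam <- as.character(labels$family[match(igraph::V(g)$name,
                                            labels$protein)])
  } else {
    fam <- igraph::vertex_attr(g, "family")
  }
  out <- data.frame(family = character(0), module = integer(0),
                    size = integer(0), members = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(fam)) return(out)
  for (f in sort(unique(fam[!is.na(fam) & nzchar(fam)]))) {
    sub <- igraph::induced_subgraph(g, which(!is.na(fam) & fam == f))
    comp <- igraph::components(sub)
    m <- 0L
    for (cid in seq_len(comp$no)) {
      members <- sort(igraph::V(sub)$name[comp$membership == cid])
      if (length(members) < 2L) next
      m <- m + 1L
      out <- rbind(out, data.frame(
        family = f, module = m, size = length(members),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Network summary record
#'
#' @param net A [load_network()] object.
#' @param hub_threshold Passed to [find_hubs()].
#' @return List with `n_nodes`, `n_edges`, `n_hubs`, `n_modules` and
#'   `degree_histogram` (named integer vector, degree -> node count).
#' @export
network_summary <- function(net, hub_threshold = 5) {
  deg <- igraph::degree(net$graph)
  hist_ <- if (length(deg)) table(factor(deg, levels = 0:max(deg))) else
    table(integer(0))
  list(
    n_nodes = igraph::vcount(net$graph),
    n_edges = igraph::ecount(net$graph),
    n_hubs = nrow(find_hubs(net, hub_threshold)),
    n_modules = nrow(family_modules(net)),
    degree_histogram = stats::setNames(as.integer(hist_), names(hist_))
  )
}

#' @export
print.bhlh_network <- function(x, ...) {
  s <- network_summary(x)
  cat("Interaction network: ", s$n_nodes, " nodes, ", s$n_edges,
      " edges (confidence >= ", x$min_confidence, "), ", s$n_hubs,
      " hub(s)\n", sep = "")
  invisible(x)
}

#' Export a network for visualisation
#'
#' @param net A [load_network()] object.
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(net$graph, path, format = format)
  invisible(path)
}
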