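# Gene-network import (STRING edge-list dialect), PAI/DI annotation with a
# discrete colour scale, and export to TSV / GraphML / Cytoscape JSON.

#' Construct a gene network
#'
#' An undirected gene network: a node table with attribute columns and an
#' edge list with optional confidence weights in [0, 1] (STRING
#' \code{combined_score} semantics). Duplicate undirected edges are merged
#' keeping the maximum weight; self-loops are permitted but reported.
#'
#' @param edges Data frame with columns \code{node1}, \code{node2} and
#'   optionally \code{weight} (numeric in [0, 1], \code{NA} = unweighted).
#' @param nodes Optional data frame with a \code{gene} column plus attribute
#'   columns; defaults to the nodes inferred from edge endpoints, in first
#'   appearance order.
#' @return An object of class \code{gene_network} with components
#'   \code{nodes} and \code{edges}.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("node1", "node2") %in% names(edges)))
  if (!"weight" %in% names(edges))
    edges$weight <- rep(NA_real_, nrow(edges))
  edges <- edges[, c("node1", "node2", "weight")]
  edges$node1 <- as.character(edges$node1)
  edges$node2 <- as.character(edges$node2)
  edges$weight <- as.numeric(edges$weight)
  bad <- which(!is.na(edges$weight) &
                 (edges$weight < 0 | edges$weight > 1))
  if (length(bad))
    stop("edge weight ", edges$weight[bad[1L]], " (edge ", bad[1L],
         ") outside [0, 1]", call. = FALSE)
  loops <- sum(edges$node1 == edges$node2)
  if (loops) message(loops, " self-loop(s) in the network")
  # canonical orientation, then merge duplicates keeping the max weight
  flip <- edges$node1 > edges$node2
  tmp <- edges$node1[flip]
  edges$node1[flip] <- edges$node2[flip]
  edges$node2[flip] <- tmp
  key <- paste(edges$node1, edges$node2, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$node1, edges$node2,
                                       sep = "\r")])
  }
  rownames(edges) <- NULL
  inferred <- unique(c(rbind(edges$node1, edges$node2)))
  if (is.null(nodes)) {
    nodes <- data.frame(gene = inferred, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(nodes), "gene" %in% names(nodes))
    nodes$gene <- as.character(nodes$gene)
    if (anyDuplicated(nodes$gene))
      stop("duplicate gene in node table", call. = FALSE)
    missing <- setdiff(inferred, nodes$gene)
    if (length(missing))
      stop("edge endpoint(s) absent from node table: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (%d weighted)\n",
              nrow(x$nodes), nrow(x$edges), sum(!is.na(x$edges$weight))))
  invisible(x)
}

#' Parse a gene network from edge-list TSV
#'
#' Accepts the STRING export dialect (a header row containing \code{node1}
#' and \code{node2}, with an optional \code{combined_score} column mapped to
#' the edge weight) or a headerless two/three-column edge list. Weights must
#' lie in [0, 1]; the literal \code{NA} or an empty field denotes an
#' unweighted edge.
#'
#' @param file Path to the TSV file.
#' @return A \code{\link{gene_network}}.
#' @export
parse_network_tsv <- function(file) {
  tsv <- read_tsv_lines(file)
  fname <- if (is.character(file)) file else "connection"
  if (!length(tsv$lines))
    return(gene_network(data.frame(node1 = character(0),
                                   node2 = character(0))))
  fields <- split_tsv(tsv$lines)
  rows <- tsv$rows
  header <- fields[[1L]]
  i1 <- 1L; i2 <- 2L; iw <- NA_integer_
  if (all(c("node1", "node2") %in% header)) {
    i1 <- match("node1", header)
    i2 <- match("node2", header)
    iw <- match("combined_score", header)
    fields <- fields[-1L]; rows <- rows[-1L]
  } else if (any(lengths(fields) >= 3L)) {
    iw <- 3L
  }
  need <- max(i1, i2, if (is.na(iw)) 0L else 0L)
  parse_row <- function(f, row) {
    if (length(f) < max(i1, i2))
      stop_parse(fname, row, "fewer than 2 columns in edge row")
    w <- NA_real_
    if (!is.na(iw) && length(f) >= iw && nzchar(f[iw]) && f[iw] != "NA") {
      w <- suppressWarnings(as.numeric(f[iw]))
      if (is.na(w))
        stop_parse(fname, row, sprintf("non-numeric weight '%s'", f[iw]))
      if (w < 0 || w > 1)
        stop_parse(fname, row,
                   sprintf("combined_score %s outside [0, 1]", f[iw]))
    }
    data.frame(node1 = f[i1], node2 = f[i2], weight = w,
               stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, Map(parse_row, fields, rows))
  if (is.null(edges))
    edges <- data.frame(node1 = character(0), node2 = character(0),
                        weight = numeric(0))
  gene_network(edges)
}

# 10-entry colourblind-safe sequential palette (light to dark), used as the
# discrete stratum scale: low PAI (old) = light, high PAI (young) = dark.
PAI_PALETTE <- c("#FFFFE5", "#FFF7BC", "#FEE391", "#FEC44F", "#FE9929",
                 "#EC7014", "#CC4C02", "#993404", "#662506", "#3F1905")

#' Map a phylostratum to a palette colour
#'
#' Deterministic monotone mapping from PAI to a fixed 10-entry
#' colourblind-safe palette. When the stratum range exceeds the palette
#' size, strata are binned evenly; when it fits, distinct strata receive
#' distinct colours. A missing PAI maps to neutral white \code{"#FFFFFF"}.
#'
#' @param pai Integer PAI (or \code{NA} for the neutral colour).
#' @param pai_min,pai_max Stratum range used for scaling;
#'   \code{pai_min <= pai <= pai_max} is required.
#' @return Hex colour string.
#' @export
pai_color <- function(pai, pai_min, pai_max) {
  if (is.na(pai)) return("#FFFFFF")
  if (pai_min > pai_max)
    stop("pai_min must not exceed pai_max", call. = FALSE)
  if (pai < pai_min || pai > pai_max)
    stop("pai ", pai, " outside [", pai_min, ", ", pai_max, "]",
         call. = FALSE)
  range <- pai_max - pai_min + 1L
  npal <- length(PAI_PALETTE)
  idx <- if (range <= npal) pai - pai_min + 1L
         else floor((pai - pai_min) * npal / range) + 1L
  PAI_PALETTE[[min(idx, npal)]]
}

#' Annotate network nodes with PAI, DI and colour
#'
#' Adds \code{pai}, \code{di} and \code{color} attributes to the node table.
#' Nodes without a PAI get the neutral colour \code{"#FFFFFF"}; annotations
#' for genes absent from the network are ignored (and counted in a message).
#' Node and edge sets, and all edge weights, are unchanged.
#'
#' @param net A \code{\link{gene_network}}.
#' @param assignments Named vector of PAIs, or a list of
#'   \code{phylostratum_assignment} objects.
#' @param di Named vector of DIs, or a list of \code{divergence_index}
#'   objects. Optional.
#' @return The annotated \code{gene_network}.
#' @export
annotate_network <- function(net, assignments = NULL, di = NULL) {
  stopifnot(inherits(net, "gene_network"))
  pai_map <- as_index_map(assignments, "pai")
  di_map <- as_index_map(di, "di")
  genes <- net$nodes$gene
  extraneous <- setdiff(c(names(pai_map), names(di_map)), genes)
  if (length(extraneous))
    message("ignoring annotations for ", length(extraneous),
            " gene(s) not in the network")
  pai_vals <- unname(pai_map[genes])
  di_vals <- unname(di_map[genes])
  annotated <- sum(!is.na(pai_vals))
  if (annotated < length(genes))
    message(length(genes) - annotated, " node(s) without a PAI annotation")
  if (annotated > 0L) {
    rng <- range(pai_vals, na.rm = TRUE)
    colors <- vapply(pai_vals, pai_color, character(1L),
                     pai_min = rng[1L], pai_max = rng[2L])
  } else {
    colors <- rep("#FFFFFF", length(genes))
  }
  net$nodes$pai <- pai_vals
  net$nodes$di <- di_vals
  net$nodes$color <- colors
  net
}

# Accept a named numeric vector, a list of assignment/DI objects, or NULL.
as_index_map <- function(x, field) {
  if (is.null(x)) return(stats::setNames(numeric(0L), character(0L)))
  if (is.list(x) && !is.data.frame(x)) {
    vals <- vapply(x, function(el) as.numeric(el[[field]]), numeric(1L))
    ids <- vapply(x, function(el) el$gene_id, character(1L))
    return(stats::setNames(vals, ids))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a named numeric vector or a list of index objects",
       call. = FALSE)
}

#' Export a gene network
#'
#' \describe{
#'   \item{tsv}{STRING-dialect edge list (\code{node1}, \code{node2},
#'     \code{combined_score}); parsing it back recovers identical node and
#'     edge sets and weights (nodes are inferred from edge endpoints, so a
#'     network with isolated nodes is not representable in this format).}
#'   \item{graphml}{GraphML with node attributes (including \code{color})
#'     and edge weights.}
#'   \item{cytoscape_json}{Cytoscape.js JSON (\code{elements} with
#'     \code{nodes}/\code{edges} data maps).}
#' }
#'
#' @param net A \code{\link{gene_network}}.
#' @param file Output path.
#' @param format One of \code{"tsv"}, \code{"graphml"},
#'   \code{"cytoscape_json"}.
#' @return Invisibly, \code{file}.
#' @export
export_network <- function(net, file,
                           format = c("tsv", "graphml", "cytoscape_json")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  switch(format,
         tsv = export_network_tsv(net, file),
         graphml = export_network_graphml(net, file),
         cytoscape_json = export_network_json(net, file))
  invisible(file)
}

export_network_tsv <- function(net, file) {
  e <- net$edges
  lines <- c("node1\tnode2\tcombined_score",
             vapply(seq_len(nrow(e)), function(i)
               paste(e$node1[i], e$node2[i],
                     if (is.na(e$weight[i])) "NA"
                     else format(e$weight[i], scientific = FALSE,
                                 trim = TRUE),
                     sep = "\t"),
               character(1L)))
  writeLines(lines, file)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$node1, to = net$edges$node2,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = net$nodes)
  if (nrow(net$edges))
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
  g
}

export_network_graphml <- function(net, file) {
  g <- as_igraph(net)
  # GraphML writer rejects NA logical/numeric attributes on some backends;
  # igraph handles NA numerics, but colours must be characters throughout
  igraph::write_graph(g, file, format = "graphml")
}

export_network_json <- function(net, file) {
  node_el <- lapply(seq_len(nrow(net$nodes)), function(i) {
    data <- list(id = net$nodes$gene[i])
    for (col in setdiff(names(net$nodes), "gene")) {
      v <- net$nodes[[col]][i]
      data[[col]] <- if (is.na(v)) NULL else v
    }
    list(data = data)
  })
  edge_el <- lapply(seq_len(nrow(net$edges)), function(i) {
    data <- list(id = paste0("e", i),
                 source = net$edges$node1[i],
                 target = net$edges$node2[i])
    if (!is.na(net$edges$weight[i])) data$weight <- net$edges$weight[i]
    list(data = data)
  })
  jsonlite::write_json(list(elements = list(nodes = node_el,
                                            edges = edge_el)),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
}
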