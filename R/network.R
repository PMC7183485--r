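#' Build the signed differential correlation network
#'
#' Keeps edges with permutation p-value strictly below `alpha`; nodes are
#' the metabolites incident to a kept edge. Edge sign is the sign of the
#' differential statistic (positive = the pair is more positively
#' correlated in cases than controls), stored with a conventional color
#' (`red` = positive, `blue` = negative). Connected components are ordered
#' by node count, ties broken by edge count then by lexicographically
#' smallest member; the first is the central network.
#'
#' @param edges a [diff_edges()] table with `p_perm` filled in.
#' @param alpha significance threshold (strict inequality); default 0.01.
#' @return an object of class `diffcorr_network`: a list with `graph`
#'   (an [igraph][igraph::igraph-package] graph with node attributes
#'   `class`, `degree` and edge attributes `r_case`, `r_control`,
#'   `r_diff`, `p_perm`, `sign`, `color`), `components` (list of node-name
#'   vectors, largest first), `central_component`, `degrees`, `alpha`.
#' @export
build_network <- function(edges, alpha = 0.01) {
  stopifnot(is.data.frame(edges), !is.null(edges$p_perm))
  if (any(is.na(edges$p_perm)))
    stop("edges lack permutation p-values; run permutation_test() first")
  keep <- edges$p_perm < alpha
  if (!any(keep))
    warning("no edges significant at alpha = ", alpha, "; empty network")
  ed <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("metabolite_i", "metabolite_j", "r_case", "r_control",
           "r_diff", "p_perm", "sign")],
    directed = FALSE)
  igraph::E(g)$color <- ifelse(igraph::E(g)$sign == "positive", "red", "blue")
  igraph::V(g)$class <- metabolite_class(igraph::V(g)$name)
  igraph::V(g)$degree <- igraph::degree(g)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  if (length(comps)) {
    n_edges <- vapply(comps, function(nodes)
      igraph::ecount(igraph::induced_subgraph(g, nodes)), numeric(1))
    sizes <- lengths(comps)
    first <- vapply(comps, `[`, character(1), 1)
    comps <- comps[order(-sizes, -n_edges, first)]
    names(comps) <- NULL
  } else comps <- list()
  structure(list(graph = g,
                 components = comps,
                 central_component = if (length(comps)) comps[[1]] else character(),
                 degrees = setNames(igraph::V(g)$degree, igraph::V(g)$name),
                 alpha = alpha),
            class = "diffcorr_network")
}

#' @export
print.diffcorr_network <- function(x, ...) {
  cat(sprintf("<diffcorr_network> %d nodes, %d edges at p < %g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$alpha))
  if (length(x$components))
    cat("  component sizes:", paste(lengths(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Rank network nodes by degree
#'
#' @param net a [build_network()] result.
#' @return data frame with columns `metabolite`, `degree`, `tied` (is the
#'   node's degree shared with another node), sorted by degree descending
#'   then metabolite id.
#' @export
hub_nodes <- function(net) {
  stopifnot(inherits(net, "diffcorr_network"))
  d <- net$degrees
  if (!length(d))
    return(data.frame(metabolite = character(), degree = integer(),
                      tied = logical()))
  out <- data.frame(metabolite = names(d), degree = as.integer(d))
  out <- out[order(-out$degree, out$metabolite), , drop = FALSE]
  out$tied <- ave(out$degree, out$degree, FUN = length) > 1
  rownames(out) <- NULL
  out
}

#' Overlap between two differential networks
#'
#' @param net_a,net_b [build_network()] results at the same alpha.
#' @return a list with `shared_nodes` (metabolites present in both) and
#'   `shared_edges` (data frame of pairs significant in both networks
#'   with matching sign).
#' @export
network_overlap <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "diffcorr_network"),
            inherits(net_b, "diffcorr_network"))
  if (!isTRUE(all.equal(net_a$alpha, net_b$alpha)))
    warning("networks were built at different alpha levels")
  nodes_a <- igraph::V(net_a$graph)$name
  nodes_b <- igraph::V(net_b$graph)$name
  shared_nodes <- sort(intersect(nodes_a, nodes_b))
  ea <- edge_key_table(net_a)
  eb <- edge_key_table(net_b)
  keys <- intersect(paste(ea$key, ea$sign), paste(eb$key, eb$sign))
  shared <- ea[paste(ea$key, ea$sign) %in% keys,
               c("metabolite_i", "metabolite_j", "sign"), drop = FALSE]
  rownames(shared) <- NULL
  list(shared_nodes = shared_nodes, shared_edges = shared)
}

edge_key_table <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (!nrow(el))
    return(data.frame(metabolite_i = character(), metabolite_j = character(),
                      sign = character(), key = character()))
  i <- pmin(el[, 1], el[, 2]); j <- pmax(el[, 1], el[, 2])
  data.frame(metabolite_i = i, metabolite_j = j,
             sign = igraph::E(net$graph)$sign,
             key = paste(i, j, sep = "\r"), stringsAsFactors = FALSE)
}

#' Export a differential network
#'
#' `graphml` writes GraphML with the node attributes (metabolite class,
#' degree) and edge attributes (`r_case`, `r_control`, `r_diff`, `p_perm`,
#' `sign`, `color`); re-reading it reproduces the graph. `edge-list`
#' writes the tab-delimited edge schema of [diff_edges()].
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge-list")) {
  stopifnot(inherits(net, "diffcorr_network"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net$graph)
    df <- data.frame(metabolite_i = el[, 1], metabolite_j = el[, 2],
                     r_case = igraph::E(net$graph)$r_case,
                     r_control = igraph::E(net$graph)$r_control,
                     r_diff = igraph::E(net$graph)$r_diff,
                     p_perm = igraph::E(net$graph)$p_perm,
                     sign = igraph::E(net$graph)$sign)
    write_delim_num(df, path)
  }
  invisible(path)
}

#' Classify a metabolite identifier by Biocrates-style naming
#'
#' Identifier prefixes map to panel classes: `PC aa`/`PC ae` ->
#' glycerophospholipid, `lysoPC` -> lysoPC, `SM` -> sphingolipid, `C`
#' followed by a digit (acylcarnitine shorthand such as C0, C2, C14:2) ->
#' acylcarnitine, `H1`/hexose -> monosaccharide; common amino acid and
#' biogenic amine names are matched by name; anything else -> `other`.
#'
#' @param ids character vector of metabolite identifiers.
#' @return character vector of classes.
#' @export
metabolite_class <- function(ids) {
  amino <- c("alanine", "arginine", "asparagine", "aspartate", "citrulline",
             "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
             "leucine", "lysine", "methionine", "ornithine", "phenylalanine",
             "proline", "serine", "threonine", "tryptophan", "tyrosine",
             "valine", "ala", "arg", "asn", "asp", "cit", "glu", "gln", "gly",
             "his", "ile", "leu", "lys", "met", "orn", "phe", "pro", "ser",
             "thr", "trp", "tyr", "val")
  amine <- c("taurine", "kynurenine", "putrescine", "spermidine", "spermine",
             "serotonin", "sarcosine", "creatinine", "carnosine", "histamine",
             "dopamine", "adma", "sdma", "t4-oh-pro", "ac-orn", "alpha-aaa",
             "kynurenine", "met-so", "nitro-tyr", "ph-aa", "taurine")
  lo <- tolower(ids)
  out <- rep("other", length(ids))
  out[grepl("^lysoPC", ids, ignore.case = TRUE)] <- "lysoPC"
  out[grepl("^PC (aa|ae)", ids)] <- "glycerophospholipid"
  out[grepl("^SM", ids)] <- "sphingolipid"
  out[grepl("^C[0-9]", ids)] <- "acylcarnitine"
  out[lo %in% c("h1", "hexose", "glucose")] <- "monosaccharide"
  out[lo %in% amino] <- "amino acid"
  out[lo %in% amine] <- "biogenic amine"
  out
}
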