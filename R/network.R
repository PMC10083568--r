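#' Load a weighted chaperome PPI graph
#'
#' Reads a STRING-style tab-separated edge list (`protein1`, `protein2`,
#' `combined_score`) and optional protein annotations (`protein`, `family`,
#' `locations`, semicolon-separated) into an undirected weighted graph.
#' Scores on the 0--1000 STRING export scale are auto-detected and rescaled
#' to 0--1. Edges below `score_cutoff` are dropped (the default 0.9 is the
#' conventional highest-confidence band); self-loops are removed; duplicate
#' pairs collapse to the maximum score. Annotated proteins absent from the
#' edge list are retained as isolated nodes (they form singleton
#' communities). Symbols are upper-cased for the join.
#'
#' @param edge_file TSV edge list path.
#' @param annotation_file optional TSV annotation path.
#' @param score_cutoff minimum retained interaction score, in [0, 1].
#' @return An `igraph` object of class `chaperome_graph` with vertex
#'   attributes `family` and `locations` (if annotated) and edge attribute
#'   `weight`; metadata (source, cutoff) in the graph attributes.
#' @export
read_chaperome_graph <- function(edge_file, annotation_file = NULL,
                                 score_cutoff = 0.9) {
  ed <- utils::read.delim(edge_file, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(ed))) {
    # tolerate the proteinA/proteinB dialect
    alt <- c("proteinA", "proteinB", "combined_score")
    if (all(alt %in% names(ed))) {
      names(ed)[match(alt, names(ed))] <- need
    } else stop("edge list must have columns protein1/protein2/combined_score")
  }
  bad <- !stats::complete.cases(ed[, need]) |
    !is.finite(suppressWarnings(as.numeric(ed$combined_score)))
  if (any(bad)) {
    warning(sum(bad), " malformed edge rows skipped")
    ed <- ed[!bad, , drop = FALSE]
  }
  ed$combined_score <- as.numeric(ed$combined_score)
  if (any(ed$combined_score > 1)) ed$combined_score <- ed$combined_score / 1000
  ed$protein1 <- toupper(ed$protein1)
  ed$protein2 <- toupper(ed$protein2)
  ed <- ed[ed$protein1 != ed$protein2, , drop = FALSE]
  ed <- ed[ed$combined_score >= score_cutoff, , drop = FALSE]
  if (nrow(ed)) {
    key <- ifelse(ed$protein1 < ed$protein2,
                  paste(ed$protein1, ed$protein2),
                  paste(ed$protein2, ed$protein1))
    mx <- tapply(ed$combined_score, key, max)
    pairs <- do.call(rbind, strsplit(names(mx), " "))
    ed <- data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
                     weight = as.numeric(mx), stringsAsFactors = FALSE)
  }
  ann <- NULL
  if (!is.null(annotation_file)) {
    ann <- utils::read.delim(annotation_file, stringsAsFactors = FALSE)
    if (!"protein" %in% names(ann))
      stop("annotation file must have a 'protein' column")
    ann$protein <- toupper(ann$protein)
  }
  verts <- unique(c(ed$protein1, ed$protein2,
                    if (!is.null(ann)) ann$protein))
  if (!length(verts)) stop("empty graph after filtering")
  vdf <- data.frame(name = verts, stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    idx <- match(vdf$name, ann$protein)
    if ("family" %in% names(ann)) vdf$family <- ann$family[idx]
    if ("locations" %in% names(ann)) vdf$locations <- ann$locations[idx]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(ed)) ed else data.frame(protein1 = character(),
                                     protein2 = character(),
                                     weight = numeric()),
    directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "source", edge_file)
  g <- igraph::set_graph_attr(g, "score_cutoff", score_cutoff)
  class(g) <- c("chaperome_graph", class(g))
  g
}

#' Detect functional modules by weighted modularity maximisation
#'
#' Louvain-style greedy modularity maximisation on the weighted graph,
#' made reproducible by a fixed seed (node order is the vertex order of
#' the graph). Isolated nodes become singleton communities.
#'
#' @param graph a [read_chaperome_graph()] result (or any igraph).
#' @param resolution resolution parameter of the modularity objective.
#' @param seed integer seed fixing the algorithm's tie-breaking.
#' @return The graph with a `community` vertex attribute (integer labels
#'   forming a partition) and graph attributes `modularity`, `resolution`,
#'   `seed`.
#' @export
detect_communities <- function(graph, resolution = 1, seed = 1) {
  stopifnot(igraph::vcount(graph) > 0)
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  g <- igraph::set_vertex_attr(graph, "community", value = as.integer(memb))
  g <- igraph::set_graph_attr(g, "modularity",
                              igraph::modularity(graph, memb,
                                                 weights = igraph::E(graph)$weight,
                                                 resolution = resolution))
  g <- igraph::set_graph_attr(g, "resolution", resolution)
  g <- igraph::set_graph_attr(g, "seed", seed)
  class(g) <- unique(c("chaperome_graph", class(g)))
  g
}

#' Per-module membership, degree and localisation report
#'
#' Summarises a community-labelled chaperome graph: per-module size,
#' members, per-node degree (number of retained edges) and top hubs, plus
#' the distribution of subcellular localisations per module. Multi-location
#' proteins contribute one count per annotated location; percentages are
#' over all (node, location) pairs in the module and sum to 100.
#' Unannotated nodes count under `"unannotated"`.
#'
#' @param graph a graph with a `community` vertex attribute.
#' @param n_hubs number of top-degree members listed per module.
#' @return List with `modules` (one row per module: `community`, `size`,
#'   `members`, `hubs`), `degrees` (per node) and `localisation` (long
#'   format: `community`, `location`, `count`, `percent`).
#' @export
module_report <- function(graph, n_hubs = 3) {
  memb <- igraph::vertex_attr(graph, "community")
  if (is.null(memb)) stop("run detect_communities() first")
  nm <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  degrees <- data.frame(protein = nm, community = memb, degree = deg,
                        row.names = NULL, stringsAsFactors = FALSE)
  mods <- lapply(sort(unique(memb)), function(cm) {
    in_m <- memb == cm
    ord <- order(-deg[in_m], nm[in_m])
    mem <- nm[in_m][ord]
    data.frame(community = cm, size = sum(in_m),
               members = paste(mem, collapse = ";"),
               hubs = paste(utils::head(mem, n_hubs), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  locs <- igraph::vertex_attr(graph, "locations")
  if (is.null(locs)) locs <- rep(NA_character_, length(nm))
  loc_rows <- lapply(sort(unique(memb)), function(cm) {
    ll <- locs[memb == cm]
    ll[is.na(ll) | !nzchar(ll)] <- "unannotated"
    toks <- unlist(strsplit(ll, ";"))
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    tab <- table(toks)
    data.frame(community = cm, location = names(tab),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  list(modules = do.call(rbind, mods), degrees = degrees,
       localisation = do.call(rbind, loc_rows))
}

#' Write a labelled chaperome graph and module report to disk
#'
#' @param graph a community-labelled graph.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written: per-module CSV, per-node degree
#'   CSV, localisation CSV and a GraphML export of the labelled graph.
#' @export
write_network_report <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- module_report(graph)
  paths <- file.path(dir, c("modules.csv", "degrees.csv",
                            "localisation.csv", "graph.graphml"))
  utils::write.csv(rep$modules, paths[1], row.names = FALSE)
  utils::write.csv(rep$degrees, paths[2], row.names = FALSE)
  utils::write.csv(rep$localisation, paths[3], row.names = FALSE)
  igraph::write_graph(graph, paths[4], format = "graphml")
  invisible(paths)
}
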