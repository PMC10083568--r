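write_edge_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

test_that("edge loading: cutoff, dedup (max score), self-loops, rescaling", {
  f <- write_edge_file(data.frame(
    protein1 = c("a", "B", "a", "C", "D", "E"),
    protein2 = c("b", "A", "b", "c", "d", "F"),
    combined_score = c(0.91, 0.95, 0.95, 0.97, 0.99, 0.10)))
  g <- read_chaperome_graph(f, score_cutoff = 0.9)
  # A-B duplicated three times (case-insensitive, both orders) -> one edge;
  # self-loops (C-c, D-d) and the sub-cutoff E-F edge are dropped
  expect_equal(igraph::ecount(g), 1)
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("A", "B"))]
  expect_equal(w, 0.95)
  expect_false("F" %in% igraph::V(g)$name)

  f2 <- write_edge_file(data.frame(
    protein1 = c("A", "B"), protein2 = c("B", "C"),
    combined_score = c(950, 400)))
  g2 <- read_chaperome_graph(f2, score_cutoff = 0.9)
  expect_equal(igraph::ecount(g2), 1)  # 0-1000 scale auto-detected
  expect_equal(igraph::E(g2)$weight, 0.95)
})

test_that("toy graphs: pass-through and star degree", {
  f <- write_edge_file(data.frame(
    protein1 = c("A", "B", "C"), protein2 = c("B", "C", "D"),
    combined_score = c(0.95, 0.92, 0.99)))
  g <- read_chaperome_graph(f, score_cutoff = 0.9)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)

  star <- write_edge_file(data.frame(
    protein1 = "HUB", protein2 = paste0("L", 1:5),
    combined_score = rep(0.95, 5)))
  gs <- read_chaperome_graph(star, score_cutoff = 0.9)
  gs <- detect_communities(gs, seed = 1)
  rep <- module_report(gs)
  expect_equal(rep$degrees$degree[rep$degrees$protein == "HUB"], 5)
  # degree equals an independent recount from the retained edge list
  el <- igraph::as_data_frame(gs, what = "edges")
  for (i in seq_len(nrow(rep$degrees))) {
    nm <- rep$degrees$protein[i]
    expect_equal(rep$degrees$degree[i], sum(el$from == nm | el$to == nm))
  }
})

test_that("two disjoint cliques resolve into exactly two communities", {
  cl <- function(prefix) {
    pairs <- t(combn(paste0(prefix, 1:5), 2))
    data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
               combined_score = 0.95)
  }
  f <- write_edge_file(rbind(cl("a"), cl("b")))
  g <- detect_communities(read_chaperome_graph(f), seed = 3)
  memb <- igraph::vertex_attr(g, "community")
  expect_equal(length(unique(memb)), 2)
  names(memb) <- igraph::V(g)$name
  expect_equal(length(unique(memb[paste0("A", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("B", 1:5)])), 1)
})

test_that("planted-partition communities are recovered (NMI benchmark)", {
  hits <- vapply(1:5, function(sd) {
    cfg <- synth_config(seed = sd)
    gph <- synth_ppi_graph(cfg)
    f <- tempfile(fileext = ".tsv")
    write_edges_tsv(gph$edges, f)
    g <- detect_communities(read_chaperome_graph(f, score_cutoff = 0.9),
                            seed = sd)
    memb <- igraph::vertex_attr(g, "community")
    names(memb) <- igraph::V(g)$name
    truth <- gph$labels[names(memb)]
    igraph::compare(memb, truth, method = "nmi")
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})

test_that("partition is exhaustive and beats the all-singletons modularity", {
  cfg <- synth_config(seed = 9)
  gph <- synth_ppi_graph(cfg)
  f <- tempfile(fileext = ".tsv")
  write_edges_tsv(gph$edges, f)
  g0 <- read_chaperome_graph(f, score_cutoff = 0.9)
  g <- detect_communities(g0, seed = 2)
  memb <- igraph::vertex_attr(g, "community")
  expect_equal(length(memb), igraph::vcount(g))
  rep <- module_report(g)
  expect_equal(sum(rep$modules$size), igraph::vcount(g))
  q_single <- igraph::modularity(g0, seq_len(igraph::vcount(g0)),
                                 weights = igraph::E(g0)$weight)
  expect_gte(igraph::graph_attr(g, "modularity"), q_single)
})

test_that("localisation distributions are per-module percentages", {
  f <- write_edge_file(data.frame(
    protein1 = c("A", "B"), protein2 = c("B", "C"),
    combined_score = 0.95))
  ann <- tempfile(fileext = ".tsv")
  write.table(data.frame(protein = c("A", "B", "C", "LONER"),
                         family = "HSP70",
                         locations = c("Nucleus;Cytoplasm", "Cytoplasm",
                                       "", "Nucleus")),
              ann, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- detect_communities(read_chaperome_graph(f, ann), seed = 1)
  rep <- module_report(g)
  sums <- tapply(rep$localisation$percent, rep$localisation$community, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # isolated annotated protein forms a singleton with a 100% location
  loner_cm <- rep$degrees$community[rep$degrees$protein == "LONER"]
  expect_equal(sum(rep$degrees$community == loner_cm), 1)
  lr <- rep$localisation[rep$localisation$community == loner_cm, ]
  expect_equal(lr$location, "Nucleus")
  expect_equal(lr$percent, 100)
  # unannotated protein counted under "unannotated"
  expect_true("unannotated" %in% rep$localisation$location)
})

test_that("a constructed cytoskeletal-chaperonin-like module reports its
           planted 31% cytoplasm / 23% cytoskeleton split", {
  # 100 (protein, location) pairs by construction
  locs <- c(rep("Cytoplasm", 31), rep("Cytoskeleton", 23),
            rep("Nucleus", 25), rep("Membrane", 21))
  prot <- sprintf("CCT%02d", seq_along(locs))
  pairs <- cbind(prot[1:99], prot[2:100])
  f <- write_edge_file(data.frame(protein1 = pairs[, 1],
                                  protein2 = pairs[, 2],
                                  combined_score = 0.95))
  ann <- tempfile(fileext = ".tsv")
  write.table(data.frame(protein = prot, family = "CCT", locations = locs),
              ann, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- read_chaperome_graph(f, ann)
  g <- igraph::set_vertex_attr(g, "community", value = 1L)
  rep <- module_report(g)
  loc <- rep$localisation
  expect_equal(loc$percent[loc$location == "Cytoplasm"], 31)
  expect_equal(loc$percent[loc$location == "Cytoskeleton"], 23)
})

test_that("network report files are written", {
  cfg <- synth_config(seed = 4, n_blocks = 3, block_size = 10)
  gph <- synth_ppi_graph(cfg)
  f <- tempfile(fileext = ".tsv")
  write_edges_tsv(gph$edges, f)
  g <- detect_communities(read_chaperome_graph(f), seed = 1)
  d <- tempfile()
  paths <- write_network_report(g, d)
  expect_true(all(file.exists(paths)))
})
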