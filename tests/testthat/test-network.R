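mini_edges <- function(mi, mj, p, sign = "positive") {
  rc <- ifelse(sign == "positive", 0.5, 0.0)
  r0 <- ifelse(sign == "positive", 0.0, 0.5)
  data.frame(metabolite_i = mi, metabolite_j = mj,
             r_case = rc, r_control = r0,
             z_case = fisher_z(rc), z_control = fisher_z(r0),
             n_case = 50, n_control = 50,
             r_diff = differential_statistic(rc, r0, 50, 50),
             p_perm = p,
             sign = sign, stringsAsFactors = FALSE)
}

test_that("network keeps only edges strictly below alpha", {
  ed <- mini_edges(c("A", "C"), c("B", "D"), p = c(0.005, 0.02))
  net <- build_network(ed, alpha = 0.01)
  expect_identical(igraph::ecount(net$graph), 1)
  expect_identical(sort(igraph::V(net$graph)$name), c("A", "B"))
  # exactly at alpha is excluded
  at <- build_network(mini_edges("A", "B", 0.01), alpha = 0.01) |>
    suppressWarnings()
  expect_identical(igraph::ecount(at$graph), 0)
})

edge_keys <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (!nrow(el)) return(character())
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

test_that("lowering alpha never adds edges or nodes", {
  set.seed(30)
  d <- two_group_data(40, 40, 8, r_case = 0.8, seed = 30)
  ed <- permutation_test(d$x, d$is_case, n_permutations = 300, seed = 31)
  n05 <- suppressWarnings(build_network(ed, 0.05))
  n01 <- suppressWarnings(build_network(ed, 0.01))
  e05 <- edge_keys(n05); e01 <- edge_keys(n01)
  expect_true(all(e01 %in% e05))
  expect_true(all(igraph::V(n01$graph)$name %in% igraph::V(n05$graph)$name))
})

test_that("components agree with a union-find oracle on random graphs", {
  uf_components <- function(nodes, ei, ej) {
    parent <- setNames(nodes, nodes)
    find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
    for (k in seq_along(ei)) parent[[find(ei[k])]] <- find(ej[k])
    split(nodes, vapply(nodes, find, ""))
  }
  set.seed(33)
  for (trial in 1:5) {
    n_nodes <- sample(10:50, 1)
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    n_edges <- sample(5:40, 1)
    ei <- sample(nodes, n_edges, TRUE)
    ej <- sample(nodes, n_edges, TRUE)
    keep <- ei != ej
    ed <- mini_edges(ei[keep], ej[keep], p = 0.001)
    net <- build_network(ed, alpha = 0.01)
    got <- lapply(net$components, sort)
    want <- lapply(uf_components(unique(c(ei[keep], ej[keep])),
                                 ei[keep], ej[keep]), sort)
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(want, paste, "", collapse = "|"))
  }
})

test_that("hub ranking: a star graph hub has degree k and no tie", {
  leaves <- sprintf("L%d", 1:6)
  ed <- mini_edges(rep("HUB", 6), leaves, p = 0.001)
  net <- build_network(ed)
  h <- hub_nodes(net)
  expect_identical(h$metabolite[1], "HUB")
  expect_identical(h$degree[1], 6L)
  expect_false(h$tied[1])
  expect_true(all(h$tied[-1]))  # all leaves share degree 1
  expect_identical(net$central_component, sort(c("HUB", leaves)))
})

test_that("empty networks warn, print, and export cleanly", {
  ed <- mini_edges("A", "B", p = 0.5)
  expect_warning(net <- build_network(ed, 0.01), "empty network")
  expect_identical(igraph::ecount(net$graph), 0)
  expect_identical(hub_nodes(net)$metabolite, character())
  f <- tempfile(fileext = ".graphml")
  export_network(net, f)
  expect_true(file.exists(f))
  g <- igraph::read_graph(f, format = "graphml")
  expect_identical(igraph::vcount(g), 0)
})

test_that("GraphML and edge-list exports round-trip the graph", {
  net <- build_network(fixture_pain_edges(), 0.01)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_identical(igraph::vcount(g), igraph::vcount(net$graph))
  expect_identical(igraph::ecount(g), igraph::ecount(net$graph))
  expect_setequal(igraph::V(g)$name, igraph::V(net$graph)$name)
  expect_equal(sort(igraph::E(g)$r_diff), sort(igraph::E(net$graph)$r_diff),
               tolerance = 1e-9)
  expect_setequal(igraph::V(g)$class, igraph::V(net$graph)$class)

  f2 <- tempfile(fileext = ".tsv")
  export_network(net, f2, "edge-list")
  ed2 <- read_edges(f2)
  expect_identical(nrow(ed2), igraph::ecount(net$graph) |> as.integer())
  expect_setequal(paste(ed2$metabolite_i, ed2$metabolite_j, ed2$sign),
                  paste(igraph::as_edgelist(net$graph)[, 1],
                        igraph::as_edgelist(net$graph)[, 2],
                        igraph::E(net$graph)$sign))
})

test_that("network overlap finds shared nodes and signed shared edges", {
  a <- build_network(mini_edges(c("A", "C"), c("B", "D"), 0.001,
                                c("positive", "negative")))
  b <- build_network(mini_edges(c("A", "E"), c("B", "F"), 0.001,
                                c("positive", "positive")))
  ov <- network_overlap(a, b)
  expect_identical(ov$shared_nodes, c("A", "B"))
  expect_identical(nrow(ov$shared_edges), 1L)
  # same pair, opposite sign -> not a shared edge
  c2 <- build_network(mini_edges("A", "B", 0.001, "negative"))
  ov2 <- network_overlap(a, c2)
  expect_identical(ov2$shared_nodes, c("A", "B"))
  expect_identical(nrow(ov2$shared_edges), 0L)
  # disjoint and identical networks
  d2 <- build_network(mini_edges("X", "Y", 0.001))
  expect_length(network_overlap(a, d2)$shared_nodes, 0)
  self <- network_overlap(a, a)
  expect_identical(self$shared_nodes, c("A", "B", "C", "D"))
  expect_identical(nrow(self$shared_edges), 2L)
})

test_that("metabolite classes follow panel naming conventions", {
  expect_identical(
    metabolite_class(c("PC aa C38:6", "PC ae C40:6", "lysoPC a C18:2",
                       "SM C16:0", "C2", "C14:2", "C0", "Proline",
                       "Taurine", "H1", "XYZ")),
    c("glycerophospholipid", "glycerophospholipid", "lysoPC",
      "sphingolipid", "acylcarnitine", "acylcarnitine", "acylcarnitine",
      "amino acid", "biogenic amine", "monosaccharide", "other"))
})
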