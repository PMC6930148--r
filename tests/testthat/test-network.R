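test_that("network construction attaches labels and rejects bad edges", {
  net <- toy_network()
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  expect_setequal(igraph::vertex_attr(net, "group"),
                  c("bacteria", "bacteria", "small_eukaryote"))

  empty <- build_network(data.frame(taxon_a = character(0), taxon_b = character(0)))
  expect_equal(igraph::vcount(empty), 0)

  dup <- data.frame(taxon_a = c("x", "y"), taxon_b = c("y", "x"),
                    median = c(0.5, 0.5), sign = c("positive", "positive"))
  expect_warning(net_d <- build_network(dup), "deduplicated")
  expect_equal(igraph::ecount(net_d), 1)

  ann <- data.frame(taxon_id = "x", group = "bacteria", trophic = "unknown")
  expect_error(build_network(dup[1, ], ann), "absent from annotations")
  self <- data.frame(taxon_a = "x", taxon_b = "x", median = 1, sign = "positive")
  expect_error(build_network(self), "self-edges")
})

test_that("linkage density is edges per node, from a graph or printed counts", {
  expect_equal(linkage_density(toy_network()), 2 / 3)
  expect_equal(linkage_density(list(nodes = 0, edges = 0)), 0)
  expect_equal(round_half_up(linkage_density(list(nodes = 209, edges = 3481)), 1), 16.7)
  expect_equal(round_half_up(linkage_density(list(nodes = 96, edges = 452)), 1), 4.7)
})

test_that("network statistics tabulate signs, groups and photosynthetic microbes", {
  edges <- data.frame(
    taxon_a = c("b1", "b1", "e1", "b2"), taxon_b = c("b2", "e1", "b2", "f1"),
    median = c(0.4, 0.3, -0.2, -0.5),
    sign = c("positive", "positive", "negative", "negative"))
  ann <- data.frame(taxon_id = c("b1", "b2", "e1", "f1"),
                    group = c("bacteria", "bacteria", "small_eukaryote", "fungi"),
                    trophic = c("heterotrophic", "heterotrophic",
                                "photosynthetic", "heterotrophic"))
  net <- build_network(edges, ann)
  st <- network_stats(net)
  expect_equal(st$pct_positive, 50)
  expect_equal(st$n_bacteria, 2)
  expect_equal(st$n_fungi, 1)
  expect_equal(st$n_small_eukaryotes, 1)
  expect_equal(st$n_plants, 0)
  expect_equal(st$n_photosynthetic_microbes, 1)
  expect_equal(st$nodes, st$n_bacteria + st$n_fungi + st$n_small_eukaryotes +
                 st$n_microfauna + st$n_plants + st$n_unknown_group)

  # relabeling nodes leaves statistics unchanged
  edges2 <- edges
  edges2$taxon_a <- paste0("X", edges$taxon_a)
  edges2$taxon_b <- paste0("X", edges$taxon_b)
  ann2 <- ann; ann2$taxon_id <- paste0("X", ann$taxon_id)
  st2 <- network_stats(build_network(edges2, ann2))
  expect_identical(st2, network_stats(net))
})

test_that("cross-group edge counting is symmetric in its selectors", {
  edges <- data.frame(
    taxon_a = c("b1", "b1", "e1"), taxon_b = c("e1", "b2", "e2"),
    median = c(0.3, 0.2, 0.1), sign = "positive")
  ann <- data.frame(taxon_id = c("b1", "b2", "e1", "e2"),
                    group = c("bacteria", "bacteria", "small_eukaryote",
                              "small_eukaryote"),
                    trophic = c("heterotrophic", "heterotrophic",
                                "photosynthetic", "photosynthetic"))
  net <- build_network(edges, ann)
  het_bac <- list(group = "bacteria", trophic = "heterotrophic")
  photo <- list(trophic = "photosynthetic")
  expect_equal(cross_group_edge_count(net, het_bac, photo), 1)
  expect_equal(cross_group_edge_count(net, photo, het_bac), 1)
  expect_equal(cross_group_edge_count(net, list(group = "plant"), photo), 0)
})

test_that("degree ranking orders by degree with id tie-break", {
  star <- data.frame(taxon_a = "hub", taxon_b = c("a", "b", "c"),
                     median = 0.5, sign = "positive")
  rk <- degree_ranking(build_network(star))
  expect_equal(rk$taxon_id[1], "hub")
  expect_equal(nrow(rk), 4)
  # regular graph (triangle): all degrees equal, ranking = id order
  tri <- data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "a"),
                    median = 0.5, sign = "positive")
  expect_equal(degree_ranking(build_network(tri))$taxon_id, c("a", "b", "c"))
})
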