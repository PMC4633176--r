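mk_mirnas <- function(mirna, direction, tumor_type = "PTC",
                      status = "selected") {
  data.frame(mirna = mirna, tumor_type = tumor_type,
             n_up = ifelse(direction == "up", 3L, 0L),
             n_down = ifelse(direction == "down", 3L, 0L),
             n_reports = 3L, status = status, direction = direction,
             stringsAsFactors = FALSE)
}
mk_genes <- function(gene, direction, status = "consensus") {
  data.frame(gene = gene, status = status, direction = direction,
             n_sig_up = 0L, n_sig_down = 0L, n_measured = 3L,
             stringsAsFactors = FALSE)
}
mk_targets <- function(mirna, gene, votes = 6L) {
  data.frame(mirna = mirna, gene = gene, vote_count = votes,
             stringsAsFactors = FALSE)
}

test_that("anti-correlated consensus pairs become edges; concordant pairs are logged", {
  mirnas <- mk_mirnas(c("miR-146b-5p", "miR-221-3p"), c("up", "up"))
  genes <- mk_genes(c("SFRP1", "CITED1"), c("down", "up"))
  targets <- mk_targets(c("miR-146b-5p", "miR-221-3p", "miR-146b-5p"),
                        c("SFRP1", "SFRP1", "CITED1"))
  net <- build_network(mirnas, targets, genes, "PTC")
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(paste(net$edges$mirna, net$edges$gene) %in%
                    c("miR-146b-5p SFRP1", "miR-221-3p SFRP1")))
  expect_equal(net$discarded$gene, "CITED1")
  expect_equal(net$discarded$reason, "concordant")
  expect_equal(target_gene_list(net), "SFRP1")  # shared target listed once
})

test_that("no target/DE overlap or no selected miRNAs gives a valid empty network", {
  mirnas <- mk_mirnas("m1", "up")
  net <- build_network(mirnas, mk_targets("m1", "g1"),
                       mk_genes("g2", "down"), "PTC")
  expect_equal(nrow(net$edges), 0L)
  expect_length(target_gene_list(net), 0L)
  expect_warning(
    build_network(mk_mirnas("m1", "up", status = "inconsistent"),
                  mk_targets("m1", "g1"), mk_genes("g1", "down"), "PTC"),
    "no selected miRNAs")
})

test_that("every edge is anti-correlated, bipartite, and drawn from the target table", {
  set.seed(9)
  for (i in 1:10) {
    mirnas <- mk_mirnas(sprintf("m%d", 1:6),
                        sample(c("up", "down"), 6, replace = TRUE),
                        status = sample(c("selected", "inconsistent"), 6,
                                        replace = TRUE, prob = c(.8, .2)))
    genes <- mk_genes(sprintf("g%02d", 1:30),
                      sample(c("up", "down"), 30, replace = TRUE),
                      status = sample(c("consensus", "unsupported"), 30,
                                      replace = TRUE))
    pairs <- expand.grid(mirna = mirnas$mirna, gene = genes$gene,
                         stringsAsFactors = FALSE)
    pairs <- pairs[sample.int(nrow(pairs), 60), ]
    targets <- mk_targets(pairs$mirna, pairs$gene,
                          sample(5:8, 60, replace = TRUE))
    net <- suppressWarnings(build_network(mirnas, targets, genes, "PTC"))
    expect_true(all(net$edges$mirna_direction != net$edges$gene_direction))
    expect_true(all(net$edges$vote_count >= 5))
    expect_lte(nrow(net$edges), nrow(targets))
    expect_true(all(paste(net$edges$mirna, net$edges$gene) %in%
                      paste(targets$mirna, targets$gene)))
    expect_equal(sort(paste(net$edges$mirna, net$edges$gene)),
                 oracle_edges(mirnas, targets, genes, "PTC"))
    if (nrow(net$edges) > 0) {
      g <- as_igraph(net)
      expect_true(igraph::bipartite_mapping(g)$res)
      expect_setequal(igraph::V(g)$name,
                      c(net$mirna_nodes, net$gene_nodes))
    }
  }
})

test_that("swapping every direction leaves the edge set unchanged", {
  set.seed(10)
  mirnas <- mk_mirnas(sprintf("m%d", 1:4),
                      sample(c("up", "down"), 4, replace = TRUE))
  genes <- mk_genes(sprintf("g%d", 1:20),
                    sample(c("up", "down"), 20, replace = TRUE))
  pairs <- expand.grid(mirna = mirnas$mirna, gene = genes$gene,
                       stringsAsFactors = FALSE)
  targets <- mk_targets(pairs$mirna, pairs$gene)
  flip <- function(d) ifelse(d == "up", "down", "up")
  net1 <- build_network(mirnas, targets, genes, "PTC")
  mirnas$direction <- flip(mirnas$direction)
  mirnas$n_up <- 3L - mirnas$n_up
  mirnas$n_down <- 3L - mirnas$n_down
  genes$direction <- flip(genes$direction)
  net2 <- build_network(mirnas, targets, genes, "PTC")
  expect_equal(paste(net1$edges$mirna, net1$edges$gene),
               paste(net2$edges$mirna, net2$edges$gene))
})

test_that("SIF and GraphML exports round-trip the edge structure", {
  mirnas <- mk_mirnas("miR-1", "up")
  net <- build_network(mirnas, mk_targets("miR-1", c("g1", "g2")),
                       mk_genes(c("g1", "g2"), "down"), "PTC")
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(net, sif)
  expect_equal(readLines(sif),
               c("miR-1\trepresses\tg1", "miR-1\trepresses\tg2"))
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$type, c("mirna", "gene"))
})
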