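#' Anti-correlated miRNA:mRNA regulatory network
#'
#' Intersects the selected miRNA panel, the consensus predicted targets and
#' the consensus differentially expressed genes into a bipartite network
#' keeping only anti-correlated pairs (miRNA up with target down, or miRNA
#' down with target up). Concordant pairs are excluded and preserved in a
#' discard log.
#'
#' @name network
NULL

#' Build the bipartite anti-correlated regulatory network
#'
#' @param mirnas Output of [select_consensus()]; only rows with
#'   `status == "selected"` and the requested tumor type are used.
#' @param targets Output of [consensus_targets()].
#' @param genes Output of [call_consensus()]; only rows with
#'   `status == "consensus"` are used.
#' @param tumor_type `"PTC"` or `"ATC"`.
#' @return An object of class `regulatory_network`: a list with `tumor_type`,
#'   `edges` (`mirna`, `gene`, `mirna_direction`, `gene_direction`,
#'   `vote_count`), `discarded` (concordant pairs with a `reason` column),
#'   `mirna_nodes` and `gene_nodes`.
#' @export
build_network <- function(mirnas, targets, genes, tumor_type) {
  tumor_type <- match.arg(tumor_type, .valid_tumor_types)
  sel <- mirnas[mirnas$status == "selected" &
                  mirnas$tumor_type == tumor_type, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no selected miRNAs for tumor type ", tumor_type,
            "; returning an empty network")
  }
  cg <- genes[genes$status == "consensus", , drop = FALSE]

  idx_m <- match(targets$mirna, sel$mirna)
  idx_g <- match(targets$gene, cg$gene)
  cand <- !is.na(idx_m) & !is.na(idx_g)
  mdir <- sel$direction[idx_m[cand]]
  gdir <- cg$direction[idx_g[cand]]
  tab <- data.frame(mirna = targets$mirna[cand],
                    gene = targets$gene[cand],
                    mirna_direction = mdir,
                    gene_direction = gdir,
                    vote_count = targets$vote_count[cand],
                    stringsAsFactors = FALSE)
  anti <- tab$mirna_direction != tab$gene_direction
  edges <- tab[anti, , drop = FALSE]
  discarded <- tab[!anti, , drop = FALSE]
  if (nrow(discarded) > 0L) discarded$reason <- "concordant"
  ord <- order(edges$mirna, edges$gene, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  rownames(discarded) <- NULL
  structure(list(tumor_type = tumor_type,
                 edges = edges,
                 discarded = discarded,
                 mirna_nodes = sort(unique(edges$mirna)),
                 gene_nodes = sort(unique(edges$gene))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Anti-correlated miRNA:mRNA regulatory network (",
      x$tumor_type, ")\n", sep = "")
  cat("  ", length(x$mirna_nodes), " miRNAs, ", length(x$gene_nodes),
      " target genes, ", nrow(x$edges), " edges\n", sep = "")
  cat("  ", nrow(x$discarded),
      " predicted pair(s) discarded as concordant\n", sep = "")
  invisible(x)
}

#' De-duplicated target-gene list of a network
#'
#' @param network A `regulatory_network`.
#' @return Sorted character vector of the gene nodes, for hand-off to
#'   [enrich()].
#' @export
target_gene_list <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  network$gene_nodes
}

#' Convert a regulatory network to an igraph object
#'
#' Nodes carry attributes `type` (`"mirna"`/`"gene"`) and `direction`;
#' edges carry `vote_count`.
#'
#' @param network A `regulatory_network`.
#' @return An undirected bipartite [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  nodes <- data.frame(
    name = c(network$mirna_nodes, network$gene_nodes),
    type = c(rep("mirna", length(network$mirna_nodes)),
             rep("gene", length(network$gene_nodes))),
    direction = c(e$mirna_direction[match(network$mirna_nodes, e$mirna)],
                  e$gene_direction[match(network$gene_nodes, e$gene)]),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    e[, c("mirna", "gene", "vote_count")],
    directed = FALSE, vertices = nodes)
}

#' Write a network as SIF triples
#'
#' One `mirna  represses  gene` line per edge.
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  lines <- if (nrow(e) > 0L) {
    paste(e$mirna, "represses", e$gene, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
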