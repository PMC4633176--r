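#' End-to-end consensus network pipeline
#'
#' Chains the four upstream stages — literature vote counting, target
#' consensus, differential-expression concordance, anti-correlation
#' filtering — into one call.
#'
#' @param calls Normalized call-matrix data frame.
#' @param votes Prediction-vote data frame.
#' @param de Combined differential-expression data frame.
#' @param tumor_type `"PTC"` or `"ATC"`.
#' @param min_studies Consensus threshold for the literature stage.
#' @param min_algorithms,n_algorithms Target-consensus thresholds.
#' @param alpha,fraction DE-concordance thresholds.
#' @return A list with `tallies`, `mirnas` (selected panel rows), `targets`,
#'   `genes` (consensus rows) and `network`.
#' @export
run_pipeline <- function(calls, votes, de, tumor_type = "PTC",
                         min_studies = 3L, min_algorithms = 5L,
                         n_algorithms = 8L, alpha = 0.05, fraction = 0.5) {
  tallies <- select_consensus(tally_calls(calls), min_studies)
  targets <- consensus_targets(count_votes(votes), min_algorithms,
                               n_algorithms)
  genes <- call_consensus(de, alpha = alpha, fraction = fraction)
  network <- suppressWarnings(
    build_network(tallies, targets, genes, tumor_type))
  list(tallies = tallies,
       mirnas = tallies[tallies$status == "selected" &
                          tallies$tumor_type == tumor_type, , drop = FALSE],
       targets = targets, genes = genes, network = network)
}

#' Run the pipeline on synthetic inputs and score planted-structure recovery
#'
#' Generates a full synthetic input bundle from `config`, runs
#' [run_pipeline()], and compares the recovered selected-miRNA panel and
#' network edge set against the planted truth.
#'
#' @param config A [sim_config()].
#' @return A list with the pipeline `result`, the generated `truth`, and
#'   recovery metrics `mirna_precision`, `mirna_recall`, `edge_precision`,
#'   `edge_recall`.
#' @export
run_synthetic_pipeline <- function(config) {
  cm <- gen_call_matrix(config)
  panel <- cm$truth$mirna[cm$truth$status == "selected"]
  vt <- gen_votes(config, panel)
  planted_dir <- cm$truth$direction[match(vt$truth$mirna, cm$truth$mirna)]
  planted_genes <- data.frame(gene = vt$truth$gene,
                              direction = ifelse(planted_dir == "up",
                                                 "down", "up"),
                              stringsAsFactors = FALSE)
  de <- gen_de_tables(config, planted_genes)
  res <- run_pipeline(cm$calls, vt$votes, de$de,
                      tumor_type = config$tumor_type)

  true_mirnas <- panel
  got_mirnas <- res$mirnas$mirna
  true_edges <- paste(vt$truth$mirna, vt$truth$gene)
  got_edges <- paste(res$network$edges$mirna, res$network$edges$gene)
  prec <- function(got, truth) {
    if (length(got) == 0L) return(NA_real_)
    mean(got %in% truth)
  }
  rec <- function(got, truth) mean(truth %in% got)
  list(result = res,
       truth = list(mirnas = cm$truth, targets = vt$truth,
                    de_genes = de$truth),
       mirna_precision = prec(got_mirnas, true_mirnas),
       mirna_recall = rec(got_mirnas, true_mirnas),
       edge_precision = prec(got_edges, true_edges),
       edge_recall = rec(got_edges, true_edges))
}
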