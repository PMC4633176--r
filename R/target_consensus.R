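#' Multi-algorithm miRNA target prediction consensus
#'
#' Reduces per-algorithm miRNA-to-gene prediction votes (a miRWalk-style
#' eight-algorithm panel) to the set of pairs supported by at least
#' `min_algorithms` independent algorithms.
#'
#' @name target_consensus
NULL

#' Read a prediction-vote table
#'
#' Tab-separated with header `mirna  gene  algorithm`, one row per
#' (miRNA, gene, algorithm) prediction.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `mirna`, `gene`, `algorithm`.
#' @export
read_prediction_votes <- function(path) {
  votes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!all(c("mirna", "gene", "algorithm") %in% names(votes))) {
    stop("vote table must have columns 'mirna', 'gene', 'algorithm'")
  }
  votes
}

#' Count prediction votes per miRNA-gene pair
#'
#' @param votes A data frame with columns `mirna`, `gene`, `algorithm`.
#' @param algorithms Declared algorithm roster. Votes naming an algorithm
#'   outside the roster are rejected (protection against misjoined inputs).
#'   `NULL` (default) accepts the observed algorithms.
#' @return A data frame `mirna`, `gene`, `vote_count` with one row per voted
#'   pair, ordered by miRNA then gene. The total of `vote_count` equals the
#'   number of input votes.
#' @export
count_votes <- function(votes, algorithms = NULL) {
  stopifnot(is.data.frame(votes))
  if (!all(c("mirna", "gene", "algorithm") %in% names(votes))) {
    stop("vote table must have columns 'mirna', 'gene', 'algorithm'")
  }
  if (nrow(votes) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      vote_count = integer(), stringsAsFactors = FALSE))
  }
  if (!is.null(algorithms)) {
    bad <- setdiff(unique(votes$algorithm), algorithms)
    if (length(bad) > 0L) {
      stop("vote(s) from undeclared algorithm(s): ",
           paste(bad, collapse = ", "))
    }
  }
  key <- paste(votes$mirna, votes$gene, votes$algorithm, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (mirna, gene, algorithm) vote(s): ",
         paste(gsub("\r", "/", dup), collapse = "; "))
  }
  agg <- stats::aggregate(list(vote_count = votes$algorithm),
                          by = list(mirna = votes$mirna, gene = votes$gene),
                          FUN = length)
  agg$vote_count <- as.integer(agg$vote_count)
  agg <- agg[order(agg$mirna, agg$gene, method = "radix"), ]
  rownames(agg) <- NULL
  agg
}

#' Filter vote counts to consensus targets
#'
#' Retains exactly the miRNA-gene pairs predicted by at least
#' `min_algorithms` of the `n_algorithms` declared algorithms.
#'
#' @param vote_counts Output of [count_votes()].
#' @param min_algorithms Consensus threshold (default 5, inclusive).
#' @param n_algorithms Size of the algorithm roster (default 8).
#' @return The retained rows of `vote_counts`.
#' @export
consensus_targets <- function(vote_counts, min_algorithms = 5L,
                              n_algorithms = 8L) {
  if (!is.numeric(min_algorithms) || length(min_algorithms) != 1L ||
      is.na(min_algorithms) ||
      min_algorithms < 1 || min_algorithms > n_algorithms) {
    stop("min_algorithms must be a single integer in [1, n_algorithms]")
  }
  if (nrow(vote_counts) > 0L &&
      any(vote_counts$vote_count > n_algorithms)) {
    stop("vote_count exceeds the declared algorithm roster size")
  }
  out <- vote_counts[vote_counts$vote_count >= min_algorithms, , drop = FALSE]
  rownames(out) <- NULL
  out
}
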