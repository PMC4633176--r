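#' Gene-set over-representation analysis
#'
#' Scores a gene list against gene-set collections with the one-sided
#' hypergeometric test or DAVID's conservative EASE variant, reporting
#' overlap count, percent of the query, fold enrichment and p-value per set.
#'
#' @name enrichment
NULL

.check_hyper_args <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("impossible hypergeometric configuration: require 0 <= k <= ",
         "min(n, K), n <= N, K <= N")
  }
}

#' One-sided hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the overlap `X` between a query of size `n` drawn from a
#' background of size `N` containing `K` set members. Computed in log space
#' via [stats::phyper()].
#'
#' @param k Observed overlap.
#' @param n Query-list size.
#' @param K Set size within the background.
#' @param N Background size.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, n, K, N) {
  .check_hyper_args(k, n, K, N)
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score
#'
#' DAVID's conservative variant of the hypergeometric enrichment p-value:
#' one overlapping gene is removed before computing the tail, i.e.
#' `hypergeom_p(max(k - 1, 0), n, K, N)`. Equals 1 whenever `k <= 1`.
#'
#' @inheritParams hypergeom_p
#' @return The penalized tail probability in (0, 1].
#' @export
ease_p <- function(k, n, K, N) {
  .check_hyper_args(k, n, K, N)
  hypergeom_p(max(k - 1, 0), n, K, N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted values (via [stats::p.adjust()]), each at least the raw
#'   p and at most 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) > 0L &&
      (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated name, description and
#' member genes.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L || any(lengths(sets) == 0L)) {
    stop("GMT file contains an empty gene set")
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation of a gene list in gene sets
#'
#' For each set, counts the overlap `k` with the query list, and reports
#' `percent = 100 k / n`, `fold = (k/n) / (K/N)` (0 when `k = 0`) and the
#' one-sided enrichment p-value. Query genes outside the background are
#' dropped with a message; set members are intersected with the background.
#'
#' @param query Character vector of gene symbols.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param method `"ease"` (default, DAVID-style) or `"hypergeom"`.
#' @param correct `"none"` (default) or `"BH"` to add adjusted p-values.
#' @param alpha Significance level for the `significant` flag (applied to
#'   the adjusted p when `correct = "BH"`).
#' @return A data frame with one row per set (`set_name`, `k`, `n`, `K`,
#'   `N`, `percent`, `fold`, `p`, optionally `adj_p`, `significant`),
#'   sorted by ascending p then set name.
#' @export
enrich <- function(query, sets, background,
                   method = c("ease", "hypergeom"),
                   correct = c("none", "BH"), alpha = 0.05) {
  method <- match.arg(method)
  correct <- match.arg(correct)
  background <- unique(background)
  if (length(background) == 0L) stop("background gene universe is empty")
  if (length(sets) == 0L) stop("no gene sets supplied")
  query <- unique(query)
  dropped <- setdiff(query, background)
  if (length(dropped) > 0L) {
    message(length(dropped), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  n <- length(query)
  N <- length(background)
  pfun <- if (method == "ease") ease_p else hypergeom_p
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), background)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (n == 0L || K == 0L) 1 else pfun(k, n, K, N)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               percent = if (n > 0L) 100 * k / n else 0,
               fold = if (k > 0L) (k / n) / (K / N) else 0,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (correct == "BH") {
    res$adj_p <- bh_adjust(res$p)
    res$significant <- res$adj_p < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res <- res[order(res$p, res$set_name, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
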