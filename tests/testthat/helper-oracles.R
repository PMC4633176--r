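# Independent brute-force oracles used to cross-check the implementation.
# Each recomputes its quantity directly from raw tuples or by exhaustive
# enumeration, never through the package's own code path.

# Vote-counting selection by direct tuple filtering.
oracle_select <- function(calls, m) {
  combos <- unique(calls[, c("mirna", "tumor_type")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- calls[calls$mirna == combos$mirna[i] &
                   calls$tumor_type == combos$tumor_type[i], , drop = FALSE]
    ups <- unique(sub$study_id[sub$direction == "up"])
    downs <- unique(sub$study_id[sub$direction == "down"])
    n <- length(ups) + length(downs)
    status <- if (n < m) "insufficient"
      else if (length(ups) > 0 && length(downs) > 0) "inconsistent"
      else "selected"
    data.frame(mirna = combos$mirna[i], tumor_type = combos$tumor_type[i],
               n_up = length(ups), n_down = length(downs), status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Hypergeometric upper tail by direct summation of the mass function.
oracle_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Exact two-sided Mann-Whitney p by enumeration of every labeling, with the
# U statistic computed by direct pair counting (not ranks).
oracle_mw_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    aa <- x[idx]; bb <- x[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  u_all <- apply(utils::combn(length(x), na), 2, u_of)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Consensus targets by direct filtering of raw vote tuples.
oracle_consensus_targets <- function(votes, a) {
  key <- paste(votes$mirna, votes$gene, sep = "\r")
  counts <- table(key)
  sort(names(counts)[counts >= a])
}

# Per-gene DE consensus status by direct tuple filtering.
oracle_de_status <- function(de, alpha, f) {
  genes <- sort(unique(de$gene))
  vapply(genes, function(g) {
    sub <- de[de$gene == g, , drop = FALSE]
    up <- sum(sub$adj_p < alpha & sub$log_fc > 0)
    down <- sum(sub$adj_p < alpha & sub$log_fc < 0)
    if (up > 0 && down > 0) return("conflicting")
    if (max(up, down) / nrow(sub) >= f && (up + down) > 0) return("consensus")
    "unsupported"
  }, character(1))
}

# Anti-correlated edges by a three-way nested loop.
oracle_edges <- function(mirnas, targets, genes, tumor_type) {
  out <- character()
  for (i in seq_len(nrow(mirnas))) {
    if (mirnas$status[i] != "selected" ||
        mirnas$tumor_type[i] != tumor_type) next
    for (j in seq_len(nrow(targets))) {
      if (targets$mirna[j] != mirnas$mirna[i]) next
      for (l in seq_len(nrow(genes))) {
        if (genes$gene[l] != targets$gene[j]) next
        if (genes$status[l] == "consensus" &&
            genes$direction[l] != mirnas$direction[i]) {
          out <- c(out, paste(targets$mirna[j], targets$gene[j]))
        }
      }
    }
  }
  sort(out)
}

# Small random fixtures.
rand_calls <- function(n_studies = 6, n_mirnas = 20, n_calls = 60) {
  studies <- sprintf("s%02d", seq_len(n_studies))
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  grid <- expand.grid(study_id = studies,
                      tumor_type = c("PTC", "ATC"),
                      mirna = mirnas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- grid[sample.int(nrow(grid), min(n_calls, nrow(grid))), ]
  pick$direction <- sample(c("up", "down"), nrow(pick), replace = TRUE)
  rownames(pick) <- NULL
  pick
}

rand_votes <- function(n_mirnas = 5, n_genes = 40, n_algorithms = 8,
                       p = 0.3) {
  grid <- expand.grid(mirna = sprintf("m%d", seq_len(n_mirnas)),
                      gene = sprintf("g%02d", seq_len(n_genes)),
                      algorithm = sprintf("alg%d", seq_len(n_algorithms)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
}

rand_de <- function(n_datasets = 4, n_genes = 50) {
  do.call(rbind, lapply(seq_len(n_datasets), function(d) {
    data.frame(dataset_id = sprintf("d%d", d),
               gene = sprintf("g%02d", seq_len(n_genes)),
               log_fc = stats::rnorm(n_genes, 0, 1.5),
               adj_p = stats::runif(n_genes),
               stringsAsFactors = FALSE)
  }))
}
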