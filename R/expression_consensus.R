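#' Cross-dataset differential-expression concordance
#'
#' Combines per-dataset tumor-vs-normal differential-expression tables
#' (GEO2R-style: gene, log2 fold-change, adjusted p) into per-gene consensus
#' calls: a gene reaches consensus when significant calls with one sign are
#' observed in at least a fraction `fraction` of the datasets measuring it
#' and no significant call with the opposite sign exists.
#'
#' @name expression_consensus
NULL

#' Read one per-dataset differential-expression table
#'
#' Tab-separated with columns `gene`, `logFC` (or `log_fc`) and `adj.P.Val`
#' (or `adj_p`), the column names GEO2R emits. One row per gene; duplicated
#' genes are rejected.
#'
#' @param path Path to a TSV file.
#' @param dataset_id Identifier attached to every row.
#' @return A data frame `dataset_id`, `gene`, `log_fc`, `adj_p`.
#' @export
read_de_table <- function(path, dataset_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(tab))
    if (length(hit) == 0L) {
      stop("differential-expression table lacks a column named one of: ",
           paste(cands, collapse = ", "))
    }
    tab[[hit[1L]]]
  }
  out <- data.frame(dataset_id = dataset_id,
                    gene = as.character(pick(c("gene", "Gene.symbol", "ID"))),
                    log_fc = as.numeric(pick(c("log_fc", "logFC"))),
                    adj_p = as.numeric(pick(c("adj_p", "adj.P.Val"))),
                    stringsAsFactors = FALSE)
  validate_de(out)
}

validate_de <- function(de) {
  stopifnot(is.data.frame(de))
  required <- c("dataset_id", "gene", "log_fc", "adj_p")
  missing <- setdiff(required, names(de))
  if (length(missing) > 0L) {
    stop("DE table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(de) > 0L) {
    if (any(!is.na(de$adj_p) & (de$adj_p < 0 | de$adj_p > 1))) {
      stop("adjusted p-values must lie in [0, 1]")
    }
    key <- paste(de$dataset_id, de$gene, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (dataset, gene) row(s); collapse probes to one row ",
           "per gene per dataset before loading")
    }
  }
  invisible(de)
}

#' Read a dataset manifest
#'
#' Tab-separated with header `dataset_id  tumor_type  path`; paths are
#' resolved relative to the manifest's directory when not absolute.
#'
#' @param path Path to the manifest.
#' @return A data frame with the manifest columns and absolute paths.
#' @export
read_de_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("dataset_id", "tumor_type", "path") %in% names(man))) {
    stop("manifest must have columns 'dataset_id', 'tumor_type', 'path'")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Load and stack all datasets of a manifest
#'
#' @param manifest Output of [read_de_manifest()].
#' @param tumor_type Optional filter (`"PTC"` or `"ATC"`).
#' @return A combined DE data frame (see [read_de_table()]).
#' @export
read_de_tables <- function(manifest, tumor_type = NULL) {
  if (!is.null(tumor_type)) {
    manifest <- manifest[manifest$tumor_type == tumor_type, , drop = FALSE]
  }
  if (nrow(manifest) == 0L) stop("manifest selects no datasets")
  do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    read_de_table(manifest$path[i], manifest$dataset_id[i])
  }))
}

#' Call per-gene consensus differential expression across datasets
#'
#' A dataset supports a direction for a gene iff `adj_p < alpha` and the
#' log fold-change has the matching sign; `log_fc == 0` with a significant
#' adjusted p is directionless and never supports either side. Status is
#' `consensus` when the supporting fraction reaches `fraction` with no
#' significant opposite support and the gene is measured in at least
#' `min_datasets` datasets; `conflicting` when both directions have
#' significant support; `unsupported` otherwise.
#'
#' @param de Combined DE data frame (`dataset_id`, `gene`, `log_fc`, `adj_p`).
#' @param alpha Significance cutoff on the adjusted p (default 0.05, strict
#'   inequality).
#' @param fraction Minimum supporting fraction of datasets (default 0.5).
#' @param min_datasets Minimum datasets a gene must be measured in to reach
#'   consensus (default 1).
#' @param denominator `"measured"` (default) computes the fraction over the
#'   datasets in which the gene appears; `"all"` over all datasets in `de`.
#' @return A data frame `gene`, `status`, `direction`, `n_sig_up`,
#'   `n_sig_down`, `n_measured`, ordered by gene name.
#' @export
call_consensus <- function(de, alpha = 0.05, fraction = 0.5,
                           min_datasets = 1L,
                           denominator = c("measured", "all")) {
  validate_de(de)
  denominator <- match.arg(denominator)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  if (nrow(de) == 0L) {
    return(data.frame(gene = character(), status = character(),
                      direction = character(), n_sig_up = integer(),
                      n_sig_down = integer(), n_measured = integer(),
                      stringsAsFactors = FALSE))
  }
  sig <- !is.na(de$adj_p) & de$adj_p < alpha
  n_directionless <- sum(sig & de$log_fc == 0)
  if (n_directionless > 0L) {
    message(n_directionless,
            " significant call(s) with log_fc == 0 treated as non-supporting")
  }
  agg <- stats::aggregate(
    cbind(n_sig_up = sig & de$log_fc > 0,
          n_sig_down = sig & de$log_fc < 0,
          n_measured = rep(1L, nrow(de))),
    by = list(gene = de$gene), FUN = sum)
  agg$n_sig_up <- as.integer(agg$n_sig_up)
  agg$n_sig_down <- as.integer(agg$n_sig_down)
  agg$n_measured <- as.integer(agg$n_measured)
  denom <- if (denominator == "all") {
    length(unique(de$dataset_id))
  } else {
    agg$n_measured
  }
  support <- pmax(agg$n_sig_up, agg$n_sig_down) / denom
  both <- agg$n_sig_up > 0L & agg$n_sig_down > 0L
  status <- rep("unsupported", nrow(agg))
  status[both] <- "conflicting"
  ok <- !both & support >= fraction & agg$n_measured >= min_datasets &
    (agg$n_sig_up + agg$n_sig_down) > 0L
  status[ok] <- "consensus"
  agg$status <- status
  agg$direction <- ifelse(status == "consensus",
                          ifelse(agg$n_sig_up > 0L, "up", "down"),
                          NA_character_)
  agg <- agg[order(agg$gene, method = "radix"),
             c("gene", "status", "direction", "n_sig_up", "n_sig_down",
               "n_measured")]
  rownames(agg) <- NULL
  agg
}
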