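#' Synthetic input generation with planted, recoverable structure
#'
#' Emulates all input kinds the pipeline consumes — a literature call
#' matrix, per-algorithm target-prediction votes, per-dataset
#' differential-expression tables, gene-set collections, and a clinical
#' cohort with survival — each carrying planted signal whose ground truth is
#' returned alongside. Every generator is a pure function of its
#' configuration: the configuration's `seed` plus a fixed per-generator
#' offset seeds the RNG, so e.g. changing the cohort size never perturbs the
#' call matrix.
#'
#' @name synthetic_data
NULL

.seed_offsets <- c(calls = 101L, votes = 202L, de = 303L, sets = 404L,
                   cohort = 505L)

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic-data generators.
#' Defaults are the package's reference study conditions (documented in the
#' methods vignette): 20 planted miRNAs among 200 over 10 studies with a 5%
#' noise call rate, an 8-algorithm vote panel, 5 expression datasets, and a
#' 388-sample cohort with hazard ratio 3 between altered and unaltered
#' samples.
#'
#' @param seed Integer master seed.
#' @param n_studies,n_mirnas,n_planted_mirnas,planted_report_count,noise_call_rate,inconsistent_fraction
#'   Call-matrix stage: number of study columns, miRNA universe size, number
#'   of planted miRNAs, unanimous reports each planted miRNA receives,
#'   per-(study, miRNA) probability of a spurious call on non-planted
#'   miRNAs, and the fraction of planted miRNAs that additionally receive
#'   one opposite-direction call (planted inconsistents).
#' @param tumor_type Tumor-type label stamped on generated calls.
#' @param n_algorithms,n_genes,planted_targets_per_mirna,background_vote_prob
#'   Vote stage: roster size, gene universe size, planted targets per
#'   miRNA (each planted pair receives at least `min_algorithms` votes), and
#'   the per-algorithm vote probability for background pairs.
#' @param n_datasets,de_effect_lfc,de_alpha_planted,planted_support
#'   Expression stage: number of datasets, planted absolute log2
#'   fold-change, upper bound on planted adjusted p-values, and the number
#'   of datasets in which each planted gene is significant.
#' @param n_gene_sets,gene_set_size,planted_set_overlap Gene-set stage.
#' @param cohort_n,cohort_n_genes,altered_fraction,expression_shift_sd,hazard_ratio,censoring_rate,baseline_event_rate
#'   Cohort stage: sample count, scored gene count, fraction of altered
#'   samples, minimum shift (in reference sd) planted in one gene of each
#'   altered sample, hazard ratio of altered vs unaltered, censoring
#'   probability, and the baseline exponential event rate (per month).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_studies = 10L, n_mirnas = 200L,
                       n_planted_mirnas = 20L, planted_report_count = 4L,
                       noise_call_rate = 0.05, inconsistent_fraction = 0.1,
                       tumor_type = "PTC",
                       n_algorithms = 8L, n_genes = 2000L,
                       planted_targets_per_mirna = 10L,
                       background_vote_prob = 0.1,
                       n_datasets = 5L, de_effect_lfc = 2,
                       de_alpha_planted = 0.01, planted_support = 3L,
                       n_gene_sets = 20L, gene_set_size = 50L,
                       planted_set_overlap = 25L,
                       cohort_n = 388L, cohort_n_genes = 10L,
                       altered_fraction = 0.33,
                       expression_shift_sd = 3,
                       hazard_ratio = 3, censoring_rate = 0.2,
                       baseline_event_rate = 0.01) {
  cfg <- list(seed = as.integer(seed), n_studies = as.integer(n_studies),
              n_mirnas = as.integer(n_mirnas),
              n_planted_mirnas = as.integer(n_planted_mirnas),
              planted_report_count = as.integer(planted_report_count),
              noise_call_rate = noise_call_rate,
              inconsistent_fraction = inconsistent_fraction,
              tumor_type = match.arg(tumor_type, .valid_tumor_types),
              n_algorithms = as.integer(n_algorithms),
              n_genes = as.integer(n_genes),
              planted_targets_per_mirna =
                as.integer(planted_targets_per_mirna),
              background_vote_prob = background_vote_prob,
              n_datasets = as.integer(n_datasets),
              de_effect_lfc = de_effect_lfc,
              de_alpha_planted = de_alpha_planted,
              planted_support = as.integer(planted_support),
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size = as.integer(gene_set_size),
              planted_set_overlap = as.integer(planted_set_overlap),
              cohort_n = as.integer(cohort_n),
              cohort_n_genes = as.integer(cohort_n_genes),
              altered_fraction = altered_fraction,
              expression_shift_sd = expression_shift_sd,
              hazard_ratio = hazard_ratio,
              censoring_rate = censoring_rate,
              baseline_event_rate = baseline_event_rate)
  counts <- c("n_studies", "n_mirnas", "n_planted_mirnas",
              "planted_report_count", "n_algorithms", "n_genes",
              "planted_targets_per_mirna", "n_datasets", "planted_support",
              "n_gene_sets", "gene_set_size", "planted_set_overlap",
              "cohort_n", "cohort_n_genes")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) stop(nm, " must be positive")
  }
  probs <- c("noise_call_rate", "inconsistent_fraction",
             "background_vote_prob", "altered_fraction", "censoring_rate")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$n_planted_mirnas > cfg$n_mirnas) {
    stop("n_planted_mirnas exceeds n_mirnas")
  }
  if (cfg$planted_report_count > cfg$n_studies) {
    stop("planted_report_count exceeds n_studies")
  }
  if (cfg$inconsistent_fraction > 0 &&
      cfg$planted_report_count + 1L > cfg$n_studies) {
    stop("planted inconsistents need planted_report_count + 1 studies")
  }
  if (cfg$planted_targets_per_mirna * cfg$n_planted_mirnas > cfg$n_genes) {
    stop("not enough genes for disjoint planted target sets")
  }
  if (cfg$planted_support > cfg$n_datasets) {
    stop("planted_support exceeds n_datasets")
  }
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (cfg$de_alpha_planted <= 0 || cfg$de_alpha_planted >= 1) {
    stop("de_alpha_planted must lie in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

.sim_mirna_names <- function(cfg) sprintf("mir-%03d", seq_len(cfg$n_mirnas))
.sim_gene_names <- function(cfg) sprintf("GENE%05d", seq_len(cfg$n_genes))
.sim_study_names <- function(cfg) sprintf("study%02d", seq_len(cfg$n_studies))

#' Generate a literature call matrix with planted consensus miRNAs
#'
#' Planted miRNAs receive `planted_report_count` unanimous calls from
#' randomly chosen studies; a fraction of them receive one additional
#' opposite-direction call (planted inconsistents). Non-planted miRNAs
#' receive sparse Binomial(`n_studies`, `noise_call_rate`) calls with random
#' directions.
#'
#' @param config A [sim_config()].
#' @return A list: `calls` (call-matrix data frame) and `truth` (data frame
#'   `mirna`, `planted`, `status`, `direction`).
#' @export
gen_call_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["calls"]])
  mirnas <- .sim_mirna_names(config)
  studies <- .sim_study_names(config)
  planted <- sort(sample(mirnas, config$n_planted_mirnas))
  n_inc <- round(config$inconsistent_fraction * config$n_planted_mirnas)
  inconsistent <- if (n_inc > 0L) sort(sample(planted, n_inc)) else character()
  dirs <- sample(c("up", "down"), length(planted), replace = TRUE)
  names(dirs) <- planted

  rows <- vector("list", config$n_mirnas)
  i <- 0L
  for (m in planted) {
    extra <- m %in% inconsistent
    st <- sample(studies, config$planted_report_count + extra)
    dir_calls <- rep(dirs[[m]], config$planted_report_count)
    if (extra) dir_calls <- c(dir_calls, setdiff(c("up", "down"), dirs[[m]]))
    i <- i + 1L
    rows[[i]] <- data.frame(study_id = st, tumor_type = config$tumor_type,
                            mirna = m, direction = dir_calls,
                            stringsAsFactors = FALSE)
  }
  for (m in setdiff(mirnas, planted)) {
    k <- stats::rbinom(1L, config$n_studies, config$noise_call_rate)
    if (k == 0L) next
    i <- i + 1L
    rows[[i]] <- data.frame(study_id = sample(studies, k),
                            tumor_type = config$tumor_type, mirna = m,
                            direction = sample(c("up", "down"), k,
                                               replace = TRUE),
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[seq_len(i)])
  calls <- calls[order(calls$study_id, calls$mirna, method = "radix"), ]
  rownames(calls) <- NULL
  truth <- data.frame(mirna = planted, planted = TRUE,
                      status = ifelse(planted %in% inconsistent,
                                      "inconsistent", "selected"),
                      direction = unname(dirs), stringsAsFactors = FALSE)
  list(calls = validate_calls(calls), truth = truth)
}

#' Generate per-algorithm prediction votes with planted consensus targets
#'
#' Each planted (miRNA, gene) pair receives between 5 and `n_algorithms`
#' votes from distinct algorithms; every other pair of the panel x gene
#' universe receives Binomial(`n_algorithms`, `background_vote_prob`) votes.
#' Planted target sets are disjoint across miRNAs.
#'
#' @param config A [sim_config()].
#' @param panel_mirnas Character vector: the miRNA panel to predict targets
#'   for (typically the planted consensus miRNAs).
#' @return A list: `votes` (data frame `mirna`, `gene`, `algorithm`) and
#'   `truth` (data frame `mirna`, `gene` of planted pairs).
#' @export
gen_votes <- function(config, panel_mirnas) {
  stopifnot(inherits(config, "sim_config"), length(panel_mirnas) > 0L)
  set.seed(config$seed + .seed_offsets[["votes"]])
  genes <- .sim_gene_names(config)
  algs <- sprintf("alg%d", seq_len(config$n_algorithms))
  n_t <- config$planted_targets_per_mirna
  if (n_t * length(panel_mirnas) > config$n_genes) {
    stop("not enough genes for disjoint planted target sets")
  }
  planted_genes <- sample(genes, n_t * length(panel_mirnas))
  truth <- data.frame(mirna = rep(panel_mirnas, each = n_t),
                      gene = planted_genes, stringsAsFactors = FALSE)

  pairs <- expand.grid(gene = genes, mirna = panel_mirnas,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(pairs$mirna, pairs$gene)
  is_planted <- key %in% paste(truth$mirna, truth$gene)
  nv <- integer(nrow(pairs))
  nv[!is_planted] <- stats::rbinom(sum(!is_planted), config$n_algorithms,
                                   config$background_vote_prob)
  nv[is_planted] <- sample(5:config$n_algorithms, sum(is_planted),
                           replace = TRUE)
  keep <- nv > 0L
  # one random algorithm ordering per voted pair; take the first nv votes
  ord <- t(vapply(seq_len(sum(keep)), function(i) sample.int(length(algs)),
                  integer(length(algs))))
  votes <- data.frame(
    mirna = rep(pairs$mirna[keep], nv[keep]),
    gene = rep(pairs$gene[keep], nv[keep]),
    algorithm = algs[ord[cbind(rep(seq_len(sum(keep)), nv[keep]),
                               sequence(nv[keep]))]],
    stringsAsFactors = FALSE)
  votes <- votes[order(votes$mirna, votes$gene, votes$algorithm,
                       method = "radix"), ]
  rownames(votes) <- NULL
  truth <- truth[order(truth$mirna, truth$gene, method = "radix"), ]
  rownames(truth) <- NULL
  list(votes = votes, truth = truth)
}

#' Generate per-dataset differential-expression tables with planted signal
#'
#' Planted genes are significant (`adj_p < de_alpha_planted`) with the
#' planted sign in exactly `planted_support` randomly chosen datasets and
#' clearly non-significant elsewhere; null genes receive uniform adjusted
#' p-values and small symmetric log fold-changes.
#'
#' @param config A [sim_config()].
#' @param planted_genes Data frame `gene`, `direction` giving each planted
#'   gene's differential-expression direction (opposite to its regulating
#'   miRNA).
#' @return A list: `de` (combined data frame `dataset_id`, `gene`, `log_fc`,
#'   `adj_p`) and `truth` (the `planted_genes` input).
#' @export
gen_de_tables <- function(config, planted_genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["de"]])
  genes <- .sim_gene_names(config)
  datasets <- sprintf("dataset%d", seq_len(config$n_datasets))
  n_g <- length(genes)
  tabs <- vector("list", config$n_datasets)
  support <- matrix(FALSE, nrow(planted_genes), config$n_datasets)
  for (i in seq_len(nrow(planted_genes))) {
    support[i, sample.int(config$n_datasets, config$planted_support)] <- TRUE
  }
  sign_of <- ifelse(planted_genes$direction == "up", 1, -1)
  for (d in seq_len(config$n_datasets)) {
    adj_p <- stats::runif(n_g)
    log_fc <- stats::rnorm(n_g, 0, 0.3)
    idx <- match(planted_genes$gene, genes)
    sup <- support[, d]
    # supported planted rows: significant with the planted sign
    adj_p[idx[sup]] <- stats::runif(sum(sup), 0, config$de_alpha_planted)
    log_fc[idx[sup]] <- sign_of[sup] *
      pmax(0.25, config$de_effect_lfc + stats::rnorm(sum(sup), 0, 0.25))
    # unsupported planted rows: kept clearly non-significant
    adj_p[idx[!sup]] <- stats::runif(sum(!sup), 0.1, 1)
    log_fc[idx[!sup]] <- stats::rnorm(sum(!sup), 0, 0.3)
    tabs[[d]] <- data.frame(dataset_id = datasets[d], gene = genes,
                            log_fc = log_fc, adj_p = adj_p,
                            stringsAsFactors = FALSE)
  }
  list(de = do.call(rbind, tabs), truth = planted_genes)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The planted set contains `planted_set_overlap` genes drawn from the
#' query gene list, padded to `gene_set_size` with background genes; the
#' remaining sets are uniform draws from the background.
#'
#' @param config A [sim_config()].
#' @param target_genes Character vector: the gene list the planted set is
#'   enriched in.
#' @param background Character vector: gene universe to draw from.
#' @return A list: `sets` (named list of gene sets, the planted one named
#'   `"planted_set"`) and `planted` (its name).
#' @export
gen_gene_sets <- function(config, target_genes, background) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .seed_offsets[["sets"]])
  if (config$planted_set_overlap > length(target_genes)) {
    stop("planted_set_overlap exceeds the target-gene list size")
  }
  filler_pool <- setdiff(background, target_genes)
  n_fill <- config$gene_set_size - config$planted_set_overlap
  if (n_fill < 0L) stop("planted_set_overlap exceeds gene_set_size")
  planted_set <- c(sample(target_genes, config$planted_set_overlap),
                   sample(filler_pool, min(n_fill, length(filler_pool))))
  sets <- list(planted_set = sort(planted_set))
  for (i in seq_len(config$n_gene_sets - 1L)) {
    sets[[sprintf("random_set%02d", i)]] <-
      sort(sample(background, config$gene_set_size))
  }
  list(sets = sets, planted = "planted_set")
}

#' Generate a clinical cohort with planted altered samples
#'
#' Baseline expression is standard normal. Each altered sample has one
#' scored gene replaced by a value at least `expression_shift_sd` reference
#' standard deviations from the mean (random sign). Survival is exponential
#' with rate `baseline_event_rate` for unaltered and `hazard_ratio *
#' baseline_event_rate` for altered samples; with probability
#' `censoring_rate` a record is censored at a uniform fraction of its event
#' time. Risk group and nodal/extension flags are drawn with probabilities
#' that enrich aggressive labels among altered samples.
#'
#' @param config A [sim_config()].
#' @return A list: `expression` (samples x genes matrix), `clinical` (data
#'   frame `sample_id`, `risk_group`, `ete`, `lnm`, `os_time`, `os_event`),
#'   `genes` (scored gene names) and `truth` (data frame `sample_id`,
#'   `altered`, `shifted_gene`).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  set.seed(config$seed + .seed_offsets[["cohort"]])
  n <- config$cohort_n
  genes <- sprintf("TG%02d", seq_len(config$cohort_n_genes))
  samples <- sprintf("S%04d", seq_len(n))
  expr <- matrix(stats::rnorm(n * length(genes)), nrow = n,
                 dimnames = list(samples, genes))
  altered <- stats::runif(n) < config$altered_fraction
  shifted_gene <- rep(NA_character_, n)
  for (i in which(altered)) {
    g <- sample(genes, 1L)
    shifted_gene[i] <- g
    expr[i, g] <- sample(c(-1, 1), 1L) *
      (config$expression_shift_sd + abs(stats::rnorm(1L)))
  }
  rate <- config$baseline_event_rate *
    ifelse(altered, config$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < config$censoring_rate
  os_time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  clinical <- data.frame(
    sample_id = samples,
    risk_group = ifelse(stats::runif(n) < ifelse(altered, 0.7, 0.25),
                        "high", "low"),
    ete = stats::runif(n) < ifelse(altered, 0.5, 0.15),
    lnm = stats::runif(n) < ifelse(altered, 0.5, 0.2),
    os_time = os_time,
    os_event = as.integer(!censored),
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = samples, altered = altered,
                      shifted_gene = shifted_gene, stringsAsFactors = FALSE)
  list(expression = expr, clinical = clinical, genes = genes, truth = truth)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every file kind the analysis functions (and the command-line
#' interface) read: call matrix, alias table, vote table, per-dataset
#' differential-expression tables plus manifest, GMT gene sets, background
#' list, cohort expression and clinical tables, target gene list, and a
#' `truth.json` with all planted labels.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_inputs <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  cm <- gen_call_matrix(config)
  utils::write.table(cm$calls, p("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  aliases <- data.frame(alias = sort(unique(cm$calls$mirna)))
  aliases$canonical <- aliases$alias
  utils::write.table(aliases, p("aliases.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel <- cm$truth$mirna[cm$truth$status == "selected"]
  vt <- gen_votes(config, panel)
  utils::write.table(vt$votes, p("votes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  planted_dir <- cm$truth$direction[match(vt$truth$mirna, cm$truth$mirna)]
  planted_genes <- data.frame(gene = vt$truth$gene,
                              direction = ifelse(planted_dir == "up",
                                                 "down", "up"),
                              stringsAsFactors = FALSE)
  de <- gen_de_tables(config, planted_genes)
  man <- data.frame(dataset_id = unique(de$de$dataset_id),
                    tumor_type = config$tumor_type, stringsAsFactors = FALSE)
  man$path <- paste0(man$dataset_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    d <- de$de[de$de$dataset_id == man$dataset_id[i],
               c("gene", "log_fc", "adj_p")]
    utils::write.table(d, p(man$path[i]), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(man, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gs <- gen_gene_sets(config, vt$truth$gene, .sim_gene_names(config))
  write_gmt(gs$sets, p("gene_sets.gmt"))
  writeLines(.sim_gene_names(config), p("background.txt"))
  co <- gen_cohort(config)
  expr_out <- data.frame(sample_id = rownames(co$expression),
                         co$expression, check.names = FALSE)
  utils::write.table(expr_out, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(co$clinical, p("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(co$genes, p("cohort_genes.txt"))
  truth <- list(planted_mirnas = cm$truth,
                planted_targets = vt$truth,
                planted_de_genes = de$truth,
                planted_gene_set = gs$planted,
                cohort = co$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(list(calls = p("calls.tsv"), aliases = p("aliases.tsv"),
                 votes = p("votes.tsv"), manifest = p("manifest.tsv"),
                 gene_sets = p("gene_sets.gmt"),
                 background = p("background.txt"),
                 expression = p("expression.tsv"),
                 clinical = p("clinical.tsv"),
                 cohort_genes = p("cohort_genes.txt"),
                 truth = p("truth.json")))
}
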