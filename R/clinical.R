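#' Clinical association of target-gene alteration
#'
#' TCGA/cBioPortal-style downstream stage: Z-score classification of samples
#' as altered in a target-gene list, normality-gated two-group comparison
#' (Kolmogorov-Smirnov, then Student's t or Mann-Whitney), and Kaplan-Meier /
#' log-rank overall-survival contrast between altered and unaltered samples.
#'
#' @name clinical
NULL

#' Read an expression matrix (samples x genes)
#'
#' Tab-separated; first column holds sample identifiers, remaining columns
#' one gene each.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with sample ids as row names.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' Read a clinical attribute table
#'
#' Tab-separated with header
#' `sample_id  risk_group  ete  lnm  os_time  os_event`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with those columns.
#' @export
read_clinical_table <- function(path) {
  clin <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "risk_group", "ete", "lnm",
                "os_time", "os_event")
  missing <- setdiff(required, names(clin))
  if (length(missing) > 0L) {
    stop("clinical table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (any(clin$os_time < 0)) stop("survival times must be >= 0")
  clin
}

#' Classify samples as altered by expression Z-score
#'
#' Per gene, `z = (x - mean) / sd` over all samples of the reference
#' population (the whole cohort); a sample is altered when `|z| >= z_star`
#' for at least one gene in the list (inclusive threshold). Genes absent
#' from the matrix or with zero variance are skipped with a warning.
#'
#' @param expr Numeric samples x genes matrix with sample ids as row names.
#' @param genes Character vector of gene symbols to score.
#' @param z_star Z-score threshold (default 2.0).
#' @return A data frame `sample_id`, `altered`, `n_genes_altered` plus a
#'   list column `triggering_genes`; attributes `fraction_altered` and
#'   `skipped_genes`.
#' @export
zscore_classify <- function(expr, genes, z_star = 2.0) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("sample", seq_len(nrow(expr)))
  }
  missing <- setdiff(genes, colnames(expr))
  if (length(missing) > 0L) {
    warning("gene(s) absent from the expression matrix skipped: ",
            paste(missing, collapse = ", "))
  }
  genes <- intersect(genes, colnames(expr))
  sds <- apply(expr[, genes, drop = FALSE], 2, stats::sd)
  flat <- genes[is.na(sds) | sds == 0]
  if (length(flat) > 0L) {
    warning("zero-variance gene(s) skipped: ", paste(flat, collapse = ", "))
  }
  genes <- setdiff(genes, flat)
  hits <- matrix(FALSE, nrow(expr), length(genes),
                 dimnames = list(rownames(expr), genes))
  if (length(genes) > 0L) {
    z <- scale(expr[, genes, drop = FALSE])
    hits <- abs(z) >= z_star
  }
  triggering <- apply(hits, 1, function(h) genes[h], simplify = FALSE)
  out <- data.frame(sample_id = rownames(expr),
                    altered = rowSums(hits) > 0,
                    n_genes_altered = as.integer(rowSums(hits)),
                    stringsAsFactors = FALSE)
  out$triggering_genes <- I(unname(triggering))
  attr(out, "fraction_altered") <- mean(out$altered)
  attr(out, "skipped_genes") <- c(missing, flat)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p by complete enumeration of all labelings when the
#' combined sample size is at most `exact_max` (ties handled through
#' average ranks); otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b Numeric vectors.
#' @param exact_max Largest combined size for exact enumeration (default 12).
#' @return A list with `statistic` (U for the first sample), `p`, and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
mann_whitney_test <- function(a, b, exact_max = 12L) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_max) {
    idx <- utils::combn(na + nb, na)
    rsums <- colSums(matrix(r[idx], nrow = na))
    u_all <- rsums - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    list(statistic = u_obs, p = p, method = "exact")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(statistic = u_obs, p = wt$p.value,
         method = "normal_approximation")
  }
}

#' Significance star code
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` for p < 0.001, `**` for p < 0.01,
#'   `*` for p < 0.05, `ns` otherwise.
#' @export
p_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "ns"), right = FALSE))
}

#' Normality-gated two-group comparison
#'
#' Each group is checked for normality with a Kolmogorov-Smirnov test
#' against a normal with the group's sample mean and sd (Lilliefors
#' correction behind a flag). If both groups pass (p >= `alpha_normal`) a
#' two-sided Student's t-test is used; otherwise a two-sided Mann-Whitney
#' test.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @param alpha_normal Normality-rejection level (default 0.05).
#' @param lilliefors Use [nortest::lillie.test()] instead of the plain KS
#'   check (default `FALSE`).
#' @return A list with `test_used` (`"t_test"` or `"mann_whitney"`),
#'   `statistic`, `p`, `stars` and `normality_p` (length 2).
#' @export
compare_groups <- function(a, b, alpha_normal = 0.05, lilliefors = FALSE) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group must contain at least 3 values")
  }
  norm_p <- vapply(list(a, b), function(x) {
    if (lilliefors) {
      nortest::lillie.test(x)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
  }, numeric(1))
  if (all(norm_p >= alpha_normal)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_used = "t_test",
                statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    mw <- mann_whitney_test(a, b)
    res <- list(test_used = "mann_whitney",
                statistic = mw$statistic, p = mw$p)
  }
  res$stars <- p_stars(res$p)
  res$normality_p <- norm_p
  res
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; the returned step function starts at
#' `(time = 0, survival = 1)` and is non-increasing, stepping only at event
#' times.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event observed, 0 = censored).
#' @return A data frame `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("survival times must be >= 0")
  stopifnot(length(time) == length(event), length(time) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Wraps [survival::survdiff()] (observed minus expected events over
#' distinct event times, hypergeometric variance, 1 df chi-square). When no
#' event is observed anywhere the contrast is undefined and `p = 1` is
#' returned with a warning.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group A two-level grouping vector.
#' @return A list with `chisq`, `df`, `p` and `km_curves` (a per-group list
#'   of [km_estimate()] data frames).
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop("survival times must be >= 0")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("exactly two non-empty groups are required")
  }
  km <- lapply(split(seq_along(time), group), function(i) {
    km_estimate(time[i], event[i])
  })
  if (sum(event) == 0L) {
    warning("no events observed in either group; log-rank is undefined")
    return(list(chisq = 0, df = 1L, p = 1, km_curves = km))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_fit$n) - 1L
  list(chisq = unname(sd_fit$chisq), df = df,
       p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       km_curves = km)
}
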