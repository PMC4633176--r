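#' Literature vote-counting of miRNA deregulation
#'
#' Functions to normalize miRNA nomenclature, tally per-study deregulation
#' calls and apply the consensus selection rule (reported with a unanimous
#' direction by at least `min_studies` independent studies within a tumor
#' type).
#'
#' @name literature_consensus
NULL

.valid_directions <- c("up", "down")
.valid_tumor_types <- c("PTC", "ATC")

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  required <- c("study_id", "tumor_type", "mirna", "direction")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0L) {
    stop("call matrix is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(calls) > 0L) {
    bad_dir <- setdiff(unique(calls$direction), .valid_directions)
    if (length(bad_dir) > 0L) {
      stop("invalid direction value(s): ", paste(bad_dir, collapse = ", "))
    }
    bad_tt <- setdiff(unique(calls$tumor_type), .valid_tumor_types)
    if (length(bad_tt) > 0L) {
      stop("invalid tumor_type value(s): ", paste(bad_tt, collapse = ", "))
    }
    key <- paste(calls$study_id, calls$tumor_type, calls$mirna, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop("duplicate (study, tumor_type, miRNA) call(s): ",
           paste(gsub("\r", "/", dup), collapse = "; "))
    }
  }
  invisible(calls)
}

#' Read a study-level miRNA deregulation call table
#'
#' Expects a tab-separated file with header
#' `study_id  tumor_type  mirna  direction`, one row per (study, tumor type,
#' miRNA) deregulation call with direction `up` or `down`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `study_id`, `tumor_type`, `mirna`,
#'   `direction`.
#' @export
read_call_matrix <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_calls(calls)
}

#' Packaged literature survey of miRNA deregulation in thyroid cancer
#'
#' A digitized compilation of published miRNA profiling studies comparing
#' papillary (PTC) and anaplastic (ATC) thyroid carcinoma against non-tumor
#' thyroid tissue: 15 study columns (11 PTC, 4 ATC), 53 miRNAs, one row per
#' reported deregulation call.
#'
#' @return A call-matrix data frame (see [read_call_matrix()]).
#' @export
thyroid_mirna_calls <- function() {
  read_call_matrix(system.file("extdata", "thyroid_mirna_calls.tsv",
                               package = "mirconsensus", mustWork = TRUE))
}

#' Read a miRNA alias table
#'
#' Two-column TSV (`alias`, `canonical`) mapping reported miRNA names to
#' canonical miRBase-style names. Canonical names map to themselves.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `alias` and `canonical`.
#' @export
read_alias_table <- function(path) {
  aliases <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  if (!all(c("alias", "canonical") %in% names(aliases))) {
    stop("alias table must have columns 'alias' and 'canonical'")
  }
  if (anyDuplicated(aliases$alias)) {
    stop("alias table maps a name more than once: ",
         paste(unique(aliases$alias[duplicated(aliases$alias)]),
               collapse = ", "))
  }
  # canonical names must be known aliases of themselves
  self <- setdiff(aliases$canonical, aliases$alias)
  if (length(self) > 0L) {
    aliases <- rbind(aliases,
                     data.frame(alias = self, canonical = self,
                                stringsAsFactors = FALSE))
  }
  aliases
}

#' Packaged miRNA alias table
#'
#' Covers the names appearing in the packaged literature survey plus common
#' arm-less shorthand (e.g. `miR-146b` for `miR-146b-5p`), following miRBase
#' naming conventions.
#'
#' @return A data frame with columns `alias` and `canonical`.
#' @export
mirna_alias_table <- function() {
  read_alias_table(system.file("extdata", "mirna_aliases.tsv",
                               package = "mirconsensus", mustWork = TRUE))
}

#' Normalize miRNA names in a call matrix
#'
#' Replaces every reported miRNA name by its canonical form from the alias
#' table. Calls that become duplicates after renaming are collapsed when
#' their directions agree and rejected with an error when they disagree.
#'
#' @param calls A call-matrix data frame.
#' @param aliases An alias table (see [read_alias_table()]).
#' @param strict If `TRUE` (default) an unknown miRNA name is an error; if
#'   `FALSE` unknown names pass through unchanged with a warning.
#' @return The normalized call matrix.
#' @export
normalize_mirna_names <- function(calls, aliases = mirna_alias_table(),
                                  strict = TRUE) {
  validate_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  idx <- match(calls$mirna, aliases$alias)
  unknown <- unique(calls$mirna[is.na(idx)])
  if (length(unknown) > 0L) {
    if (strict) {
      stop("unknown miRNA name(s): ", paste(unknown, collapse = ", "))
    }
    warning("unknown miRNA name(s) passed through unchanged: ",
            paste(unknown, collapse = ", "))
  }
  canon <- ifelse(is.na(idx), calls$mirna, aliases$canonical[idx])
  calls$mirna <- canon
  key <- paste(calls$study_id, calls$tumor_type, calls$mirna, sep = "\r")
  if (anyDuplicated(key)) {
    dirs_per_key <- tapply(calls$direction, key,
                           function(d) length(unique(d)))
    conflict <- names(dirs_per_key)[dirs_per_key > 1L]
    if (length(conflict) > 0L) {
      stop("direction conflict after name normalization for: ",
           paste(gsub("\r", "/", conflict), collapse = "; "))
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Tally deregulation calls per miRNA and tumor type
#'
#' Counts, over distinct studies, how many report each miRNA up- and
#' downregulated within each tumor type.
#'
#' @param calls A normalized call-matrix data frame.
#' @return A data frame with one row per (miRNA, tumor type) and columns
#'   `mirna`, `tumor_type`, `n_up`, `n_down`, `n_reports`, ordered by
#'   tumor type, then descending `n_reports`, then miRNA name.
#' @export
tally_calls <- function(calls) {
  validate_calls(calls)
  if (nrow(calls) == 0L) {
    return(data.frame(mirna = character(), tumor_type = character(),
                      n_up = integer(), n_down = integer(),
                      n_reports = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    cbind(n_up = calls$direction == "up",
          n_down = calls$direction == "down"),
    by = list(mirna = calls$mirna, tumor_type = calls$tumor_type),
    FUN = sum)
  agg$n_up <- as.integer(agg$n_up)
  agg$n_down <- as.integer(agg$n_down)
  agg$n_reports <- agg$n_up + agg$n_down
  ord <- order(agg$tumor_type, -agg$n_reports, agg$mirna, method = "radix")
  agg <- agg[ord, c("mirna", "tumor_type", "n_up", "n_down", "n_reports")]
  rownames(agg) <- NULL
  agg
}

#' Select consensus miRNAs by vote counting
#'
#' Assigns each tallied (miRNA, tumor type) a status: `selected` when
#' reported by at least `min_studies` studies with a unanimous direction,
#' `inconsistent` when reported by at least `min_studies` studies but with
#' conflicting directions, `insufficient` otherwise. `direction` is filled
#' only for selected rows.
#'
#' @param tallies Output of [tally_calls()].
#' @param min_studies Minimum number of concordant studies (default 3).
#' @return The tallies with `status` and `direction` columns added, in the
#'   same stable order.
#' @export
select_consensus <- function(tallies, min_studies = 3L) {
  if (!is.numeric(min_studies) || length(min_studies) != 1L ||
      is.na(min_studies) || min_studies < 1) {
    stop("min_studies must be a single integer >= 1")
  }
  min_studies <- as.integer(min_studies)
  status <- rep("insufficient", nrow(tallies))
  enough <- tallies$n_reports >= min_studies
  mixed <- tallies$n_up > 0L & tallies$n_down > 0L
  status[enough & !mixed] <- "selected"
  status[enough & mixed] <- "inconsistent"
  tallies$status <- status
  tallies$direction <- ifelse(status == "selected",
                              ifelse(tallies$n_up > 0L, "up", "down"),
                              NA_character_)
  tallies
}

#' miRNAs reported in both tumor types
#'
#' @param tallies Output of [tally_calls()] (or [select_consensus()]) covering
#'   both tumor types.
#' @return Sorted character vector of miRNA names with at least one report in
#'   PTC and at least one in ATC.
#' @export
shared_mirnas <- function(tallies) {
  ptc <- tallies$mirna[tallies$tumor_type == "PTC" & tallies$n_reports >= 1L]
  atc <- tallies$mirna[tallies$tumor_type == "ATC" & tallies$n_reports >= 1L]
  sort(intersect(ptc, atc))
}

#' Write a consensus tally to TSV
#'
#' @param tallies Output of [select_consensus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tallies, path) {
  cols <- c("mirna", "tumor_type", "n_up", "n_down", "n_reports",
            "status", "direction")
  utils::write.table(tallies[, intersect(cols, names(tallies))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
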