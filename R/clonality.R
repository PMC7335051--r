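# Conserved CDR3/FR4 junction motif in the J region: Phe or Trp, Gly, any,
# Gly.
J_MOTIF <- "[FW]G.G"

#' Filter a per-read CDR3 annotation table
#'
#' Record-level filters, applied first: CDR3 must be found
#' (`cdr3_found != "NOT_FOUND"`), the VDJ frame and top D gene must be
#' annotated (not `"N/A"`/missing), the CDR3 peptide must be at least 5 amino
#' acids, and the J-region translation must contain the conserved
#' Phe/Trp-Gly-X-Gly motif. Clonotypes whose total retained read count is 1
#' (singletons) are then removed. The filter is idempotent.
#'
#' @param records data.frame with columns `cdr3_peptide`, `cdr3_found`,
#'   `vdj_frame`, `top_d_gene`, `j_region_aa` (plus any identifiers).
#' @return filtered data.frame (possibly empty).
#' @export
filter_cdr3 <- function(records) {
  bad <- is.na(records$cdr3_found) | records$cdr3_found == "NOT_FOUND" |
    is.na(records$vdj_frame) | records$vdj_frame == "N/A" |
    is.na(records$top_d_gene) | records$top_d_gene == "N/A" |
    is.na(records$cdr3_peptide) | nchar(records$cdr3_peptide) < 5 |
    is.na(records$j_region_aa) | !grepl(J_MOTIF, records$j_region_aa)
  out <- records[!bad, , drop = FALSE]
  counts <- table(out$cdr3_peptide)
  singletons <- names(counts)[counts == 1]
  out <- out[!(out$cdr3_peptide %in% singletons), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clonotype table with representativities
#'
#' Counts retained reads per unique CDR3 peptide; representativity is the
#' percentage of retained reads carrying that peptide (sums to 100).
#'
#' @param records filtered read table ([filter_cdr3()] output, >= 1 row).
#' @return data.frame of class `clonotype_table`: `cdr3_peptide`, `count`,
#'   `representativity` (percent), sorted by decreasing count.
#' @export
representativity <- function(records) {
  if (!nrow(records)) stop("representativity: no retained reads")
  counts <- sort(table(records$cdr3_peptide), decreasing = TRUE)
  out <- data.frame(cdr3_peptide = names(counts),
                    count = as.integer(counts),
                    representativity = 100 * as.integer(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' Clonality verdict from a clonotype table
#'
#' Applies the representativity rules in order: if two or more CDR3
#' sequences reach 20% representativity the sample is polyclonal; otherwise
#' if the major clone reaches 80% it is monoclonal; otherwise the data are
#' inconclusive. Thresholds are inclusive.
#'
#' @param table [representativity()] output.
#' @param poly_threshold,mono_threshold representativity thresholds (percent).
#' @return list of class `clonality_call`: `verdict` ("monoclonal" /
#'   "polyclonal" / "inconclusive"), `major_clone` (peptide of the most
#'   represented clone, or `NA`), `sequences_over_20pct`.
#' @export
classify_clonality <- function(table, poly_threshold = 20, mono_threshold = 80) {
  if (!nrow(table)) stop("classify_clonality: empty clonotype table")
  over <- table$cdr3_peptide[table$representativity >= poly_threshold]
  major_i <- which.max(table$representativity)
  verdict <- if (length(over) >= 2) "polyclonal"
  else if (table$representativity[major_i] >= mono_threshold) "monoclonal"
  else "inconclusive"
  structure(list(verdict = verdict,
                 major_clone = if (verdict == "monoclonal")
                   table$cdr3_peptide[major_i] else NA_character_,
                 sequences_over_20pct = over),
            class = "clonality_call")
}

#' @export
print.clonality_call <- function(x, ...) {
  cat(sprintf("clonality_call: %s (%d sequence(s) >= 20%%%s)\n", x$verdict,
              length(x$sequences_over_20pct),
              if (!is.na(x$major_clone)) paste0("; major clone ", x$major_clone)
              else ""))
  invisible(x)
}

#' Reconcile two technical replicates of a clonality assay
#'
#' A clonotype reaching the 20% threshold in only one of the two replicates
#' is flagged as suspect (e.g. an amplicon contamination) and excluded from
#' the consensus, which is recomputed on the concordant clonotypes of the
#' pooled reads. If the recomputed per-replicate verdicts still disagree the
#' consensus is inconclusive, with both calls reported.
#'
#' @param tableA,tableB [representativity()] tables of the two replicates
#'   (`tableB = NULL` passes the single-replicate call through, flagged
#'   `unreplicated`).
#' @param poly_threshold representativity threshold (percent).
#' @return list of class `clonality_consensus`: `verdict`, `calls` (the two
#'   per-replicate calls), `suspect_clonotypes`, `unreplicated`.
#' @export
reconcile_replicates <- function(tableA, tableB = NULL, poly_threshold = 20) {
  if (is.null(tableB)) {
    call <- classify_clonality(tableA, poly_threshold = poly_threshold)
    return(structure(list(verdict = call$verdict, calls = list(call),
                          suspect_clonotypes = character(0),
                          unreplicated = TRUE),
                     class = "clonality_consensus"))
  }
  overA <- tableA$cdr3_peptide[tableA$representativity >= poly_threshold]
  overB <- tableB$cdr3_peptide[tableB$representativity >= poly_threshold]
  suspect <- c(setdiff(overA, overB), setdiff(overB, overA))
  strip <- function(tab) {
    out <- tab[!(tab$cdr3_peptide %in% suspect), , drop = FALSE]
    if (!nrow(out)) return(NULL)
    out$representativity <- 100 * out$count / sum(out$count)
    out
  }
  a2 <- strip(tableA); b2 <- strip(tableB)
  calls <- lapply(list(a2, b2), function(t)
    if (is.null(t)) NULL else classify_clonality(t, poly_threshold = poly_threshold))
  verdicts <- unique(vapply(Filter(Negate(is.null), calls),
                            `[[`, character(1), "verdict"))
  verdict <- if (length(verdicts) == 1) verdicts else "inconclusive"
  if (!length(verdicts)) verdict <- "inconclusive"
  structure(list(verdict = verdict, calls = calls,
                 suspect_clonotypes = suspect, unreplicated = FALSE),
            class = "clonality_consensus")
}

#' @export
print.clonality_consensus <- function(x, ...) {
  cat(sprintf("clonality consensus: %s%s%s\n", x$verdict,
              if (x$unreplicated) " (unreplicated)" else "",
              if (length(x$suspect_clonotypes))
                paste0("; suspect clonotypes: ",
                       paste(x$suspect_clonotypes, collapse = ", ")) else ""))
  invisible(x)
}

#' Run the clonality pipeline on a per-read annotation table
#'
#' Filters reads, builds per-replicate clonotype tables, reconciles technical
#' replicates per sample, and returns a per-sample verdict table.
#'
#' @param reads data.frame with `sample_id`, `replicate` and the
#'   [filter_cdr3()] columns (e.g. from [read_cdr3_tsv()]).
#' @return list with `verdicts` (data.frame: sample_id, n_sequences_over_20,
#'   verdict, unreplicated) and `details` (per-sample
#'   `clonality_consensus` objects).
#' @export
run_clonality <- function(reads) {
  verdicts <- list(); details <- list()
  for (sid in unique(reads$sample_id)) {
    sub <- reads[reads$sample_id == sid, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    tabs <- lapply(reps, function(r) {
      f <- filter_cdr3(sub[sub$replicate == r, , drop = FALSE])
      if (!nrow(f)) NULL else representativity(f)
    })
    tabs <- Filter(Negate(is.null), tabs)
    if (!length(tabs)) {
      cons <- structure(list(verdict = "inconclusive", calls = list(),
                             suspect_clonotypes = character(0),
                             unreplicated = TRUE),
                        class = "clonality_consensus")
    } else if (length(tabs) == 1) {
      cons <- reconcile_replicates(tabs[[1]], NULL)
    } else {
      cons <- reconcile_replicates(tabs[[1]], tabs[[2]])
    }
    details[[sid]] <- cons
    n20 <- if (length(tabs))
      length(unique(unlist(lapply(tabs, function(t)
        t$cdr3_peptide[t$representativity >= 20])))) else 0L
    verdicts[[sid]] <- data.frame(sample_id = sid,
                                  n_sequences_over_20 = n20,
                                  verdict = cons$verdict,
                                  unreplicated = cons$unreplicated,
                                  stringsAsFactors = FALSE)
  }
  list(verdicts = do.call(rbind, verdicts), details = details)
}

#' Read / write per-read CDR3 annotation tables as TSV
#'
#' @param path TSV file with columns `sample_id`, `replicate`,
#'   `cdr3_peptide`, `cdr3_found`, `vdj_frame`, `top_d_gene`, `j_region_aa`.
#' @return data.frame of reads.
#' @export
read_cdr3_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
}

#' @param reads data.frame of reads.
#' @rdname read_cdr3_tsv
#' @export
write_cdr3_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
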