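#' Construct a taxa count table
#'
#' The common input container of the pipeline: a samples-by-taxa matrix of
#' non-negative integer counts with unique sample and taxon identifiers and a
#' per-sample study label (several 16S studies may be pooled into one table).
#'
#' @param counts Numeric matrix, samples in rows and taxa in columns, with
#'   row and column names. All entries must be non-negative integers.
#' @param study Character vector of study labels, one per sample (recycled if
#'   length one). Defaults to a single study `"study1"`.
#' @return An object of class `taxa_count_table`: a list with elements
#'   `counts` (integer matrix), `sample_ids`, `taxon_ids` and `study`.
#' @details All-zero samples are rejected: every sample must retain a positive
#'   total count, since a sample without reads carries no compositional
#'   information for the topic model.
#' @export
taxa_count_table <- function(counts, study = "study1") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts))) stop("`counts` contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("all-zero samples not allowed: ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  study <- rep_len(as.character(study), nrow(counts))
  structure(list(counts = counts,
                 sample_ids = rownames(counts),
                 taxon_ids = colnames(counts),
                 study = setNames(study, rownames(counts))),
            class = "taxa_count_table")
}

#' @export
print.taxa_count_table <- function(x, ...) {
  cat(sprintf("taxa_count_table: %d samples x %d taxa (%d stud%s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$study)),
              if (length(unique(x$study)) == 1L) "y" else "ies"))
  cat(sprintf("  total reads: %.0f; median library size: %.0f\n",
              sum(as.numeric(x$counts)), median(rowSums(x$counts))))
  invisible(x)
}

#' @export
dim.taxa_count_table <- function(x) dim(x$counts)

#' Read a taxa count table from TSV
#'
#' Reads a tab-separated count file in either orientation and returns a
#' validated, samples-by-taxa [taxa_count_table]. The first column holds row
#' identifiers; the header holds column identifiers.
#'
#' @param path Path to a TSV file.
#' @param dialect `"taxa_by_samples"` (rows are taxa, as conventionally
#'   written by amplicon pipelines) or `"samples_by_taxa"`.
#' @param study Study label(s) for the samples, see [taxa_count_table()].
#' @return A `taxa_count_table`.
#' @export
load_count_table <- function(path,
                             dialect = c("taxa_by_samples", "samples_by_taxa"),
                             study = "study1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE,
                    colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
                               dimnames = dimnames(raw)))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("cannot parse count at row '%s', column '%s' (value '%s')",
                 rownames(m)[bad[1]], colnames(m)[bad[2]],
                 as.matrix(raw)[bad[1], bad[2]]))
  }
  if (dialect == "taxa_by_samples") m <- t(m)
  taxa_count_table(m, study = study)
}

#' Write a taxa count table to TSV
#'
#' @param table A [taxa_count_table].
#' @param path Output file path.
#' @param dialect Orientation to write, see [load_count_table()].
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path,
                              dialect = c("taxa_by_samples", "samples_by_taxa")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "taxa_count_table"))
  m <- table$counts
  if (dialect == "taxa_by_samples") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (dialect == "taxa_by_samples") "taxon_id" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimum-abundance filter
#'
#' Removes suspiciously rare taxa: within each study, a taxon whose total
#' count summed over that study's samples falls below `threshold` has its
#' counts zeroed for those samples. Taxa left with zero counts everywhere are
#' dropped from the table. The cut is inclusive: a taxon is kept for a study
#' when its per-study total is greater than or equal to the threshold.
#'
#' @param table A [taxa_count_table].
#' @param threshold Non-negative integer; default 100.
#' @return A filtered `taxa_count_table`. The attribute `"filter_log"` holds
#'   a data frame of removed (taxon, study) pairs with their totals.
#' @export
min_abundance_filter <- function(table, threshold = 100) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("`threshold` must be a single non-negative number")
  m <- table$counts
  log_rows <- list()
  for (s in unique(table$study)) {
    idx <- which(table$study == s)
    tot <- colSums(m[idx, , drop = FALSE])
    rm_tax <- which(tot < threshold & tot > 0L)
    if (length(rm_tax)) {
      log_rows[[s]] <- data.frame(taxon = colnames(m)[rm_tax], study = s,
                                  total = as.integer(tot[rm_tax]),
                                  row.names = NULL)
      m[idx, rm_tax] <- 0L
    }
  }
  keep <- colSums(m) > 0L
  if (!any(keep)) {
    tot_all <- colSums(table$counts)
    stop("filter removed all taxa; per-taxon totals were: ",
         paste(sprintf("%s=%d", names(tot_all), tot_all), collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("filter left samples with zero counts: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  out <- taxa_count_table(m, study = table$study)
  attr(out, "filter_log") <- if (length(log_rows))
    do.call(rbind, unname(log_rows)) else
    data.frame(taxon = character(), study = character(), total = integer())
  out
}

#' Aggregate taxa to genus or species level
#'
#' Taxon identifiers are expected in the form `"Genus"`, `"Genus species"` or
#' `"Genus species subsp. name"`. Genus-level aggregation sums counts over
#' the first whitespace-separated token; species level over the first two
#' (identifiers with a single token are kept as-is at species level).
#'
#' @param table A [taxa_count_table].
#' @param level `"genus"` or `"species"`.
#' @return An aggregated `taxa_count_table`; column order follows first
#'   appearance of each label. Sample totals are conserved exactly.
#' @export
aggregate_taxa <- function(table, level = c("species", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "taxa_count_table"))
  toks <- strsplit(table$taxon_ids, "\\s+")
  labels <- vapply(toks, function(t) {
    n <- if (level == "genus") 1L else 2L
    paste(t[seq_len(min(n, length(t)))], collapse = " ")
  }, character(1))
  uniq <- unique(labels)
  agg <- sapply(uniq, function(lab)
    rowSums(table$counts[, labels == lab, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(table$counts),
                dimnames = list(table$sample_ids, uniq))
  taxa_count_table(agg, study = table$study)
}

#' Merge two count tables over the union of their vocabularies
#'
#' Missing taxa are zero-filled. Sample ids must not collide.
#'
#' @param x,y `taxa_count_table` objects.
#' @return A combined `taxa_count_table`.
#' @export
merge_count_tables <- function(x, y) {
  stopifnot(inherits(x, "taxa_count_table"), inherits(y, "taxa_count_table"))
  if (length(intersect(x$sample_ids, y$sample_ids)))
    stop("sample ids occur in both tables: ",
         paste(intersect(x$sample_ids, y$sample_ids), collapse = ", "))
  vocab <- union(x$taxon_ids, y$taxon_ids)
  pad <- function(t) {
    m <- matrix(0L, nrow(t$counts), length(vocab),
                dimnames = list(t$sample_ids, vocab))
    m[, t$taxon_ids] <- t$counts
    m
  }
  taxa_count_table(rbind(pad(x), pad(y)), study = c(x$study, y$study))
}

#' Subset a count table to selected samples
#'
#' @param table A [taxa_count_table].
#' @param sample_ids Character vector of sample ids to keep (order preserved).
#' @param drop_empty_taxa Drop taxa with zero counts in the subset
#'   (default `FALSE`).
#' @return A `taxa_count_table`.
#' @export
subset_samples <- function(table, sample_ids, drop_empty_taxa = FALSE) {
  stopifnot(inherits(table, "taxa_count_table"))
  missing_ids <- setdiff(sample_ids, table$sample_ids)
  if (length(missing_ids))
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
  m <- table$counts[sample_ids, , drop = FALSE]
  if (drop_empty_taxa) m <- m[, colSums(m) > 0L, drop = FALSE]
  taxa_count_table(m, study = table$study[sample_ids])
}
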