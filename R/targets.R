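#' Read a miRNA target-score table
#'
#' Parses a TSV of predicted miRNA/mRNA target pairs with mirSVR-style
#' scores (more negative = stronger predicted repression).  The same
#' miRNA-gene pair may appear on several lines when a 3'UTR carries
#' several predicted sites.
#'
#' @param path TSV with columns \code{mirna_id}, \code{target_gene_id},
#'   \code{score} (header optional if in that order).
#' @return data frame with those three columns.
#' @export
read_target_scores <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(mirna_id = character(), target_gene_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (identical(tolower(fields[[1L]][1:3]),
                c("mirna_id", "target_gene_id", "score"))) start <- 2L
  rows <- lapply(seq.int(start, length.out = length(lines) - start + 1L), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop_mirsig("malformed target record at line ", i, ": expected 3 fields, got ",
                  length(f), class = "mirsig_format_error")
    score <- suppressWarnings(as.numeric(f[3L]))
    if (!is.finite(score))
      stop_mirsig("malformed target record at line ", i, ": score '", f[3L],
                  "' is not a finite number", class = "mirsig_format_error")
    data.frame(mirna_id = f[1L], target_gene_id = f[2L], score = score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter target predictions by mirSVR-style score
#'
#' Retains records with a score strictly below the threshold (default
#' -1.25, the conventional cut for confident mirSVR predictions), then
#' deduplicates genes within each miRNA keeping the most negative score,
#' since downstream pathway analysis operates on gene sets.
#'
#' @param records data frame as returned by \code{\link{read_target_scores}}.
#' @param threshold retain scores strictly less than this (default -1.25).
#' @return list of class \code{target_filter_result}: \code{records}
#'   (filtered, deduplicated, ordered by miRNA then score) and
#'   \code{counts} (named integer vector of genes per miRNA).
#' @export
filter_target_scores <- function(records, threshold = -1.25) {
  stopifnot(is.data.frame(records))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop_mirsig("threshold must be a single finite number",
                class = "mirsig_validation_error")
  need <- c("mirna_id", "target_gene_id", "score")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_mirsig("records lack column(s): ", paste(missing, collapse = ", "),
                class = "mirsig_format_error")
  kept <- records[records$score < threshold, need, drop = FALSE]
  if (nrow(kept)) {
    # best (most negative) score per miRNA-gene pair
    kept <- kept[order(kept$mirna_id, kept$target_gene_id, kept$score), , drop = FALSE]
    kept <- kept[!duplicated(kept[, c("mirna_id", "target_gene_id")]), , drop = FALSE]
    kept <- kept[order(kept$mirna_id, kept$score, kept$target_gene_id), , drop = FALSE]
    rownames(kept) <- NULL
    counts <- table(kept$mirna_id)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    rownames(kept) <- NULL
    counts <- stats::setNames(integer(), character())
  }
  structure(list(records = kept, counts = counts, threshold = threshold),
            class = "target_filter_result")
}

#' @export
print.target_filter_result <- function(x, ...) {
  cat(sprintf("Target filter (score < %g): %d records across %d miRNA(s)\n",
              x$threshold, nrow(x$records), length(x$counts)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Write per-miRNA gene sets in GMT format
#'
#' One line per miRNA: set name, description, then its predicted target
#' genes — the plain format enrichment tools consume.
#'
#' @param result a \code{target_filter_result} from
#'   \code{\link{filter_target_scores}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_target_gmt <- function(result, path) {
  stopifnot(inherits(result, "target_filter_result"))
  sets <- split(result$records$target_gene_id, result$records$mirna_id)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sprintf("targets_below_%g", result$threshold), sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
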