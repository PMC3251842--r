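#' Construct a signature set
#'
#' An ordered set of distinct probe identifiers used jointly as a
#' predictor, together with its provenance (\code{"fixed"} for a published
#' list, \code{"searched"} for a data-driven reduction, \code{"planted"}
#' for a simulated ground truth) and any selection metrics.
#'
#' @param probe_ids character vector of distinct probe ids, ordered.
#' @param provenance one of \code{"fixed"}, \code{"searched"},
#'   \code{"planted"}.
#' @param metrics optional named list (e.g. loocv_accuracy,
#'   validation_accuracy).
#' @return an object of class \code{signature_set}.
#' @export
signature_set <- function(probe_ids, provenance = c("fixed", "searched", "planted"),
                          metrics = list()) {
  provenance <- match.arg(provenance)
  probe_ids <- as.character(probe_ids)
  if (!length(probe_ids))
    stop_mirsig("a signature needs at least one probe",
                class = "mirsig_validation_error")
  if (anyDuplicated(probe_ids))
    stop_mirsig("duplicate probe id(s) in signature: ",
                paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
                class = "mirsig_validation_error")
  structure(list(probe_ids = probe_ids, k = length(probe_ids),
                 provenance = provenance, metrics = metrics),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("%d-probe signature (%s)\n", x$k, x$provenance))
  cat("  ", paste(x$probe_ids, collapse = ", "), "\n", sep = "")
  for (nm in intersect(names(x$metrics), c("loocv_accuracy", "validation_accuracy")))
    cat(sprintf("  %s: %.3f\n", nm, x$metrics[[nm]]))
  invisible(x)
}

#' The published 13-miRNA erlotinib-sensitivity signature
#'
#' Returns the fixed 13-miRNA signature reported to predict erlotinib
#' (EGFR-inhibitor) sensitivity in lung and pancreatic cancer: eleven
#' miRNAs up-regulated and two down-regulated in sensitive samples,
#' dominated by the mir-200 family / EMT axis.  Use it with user-supplied
#' delta-Ct data; the identifiers follow the hsa-mir naming of the TaqMan
#' array annotation.
#'
#' @return a \code{\link{signature_set}} with \code{provenance = "fixed"}
#'   and k = 13.
#' @export
erlotinib_signature <- function() {
  ids <- paste0("hsa-mir-", c("140-3p", "628-5p", "518f", "636", "301a",
                              "34c", "224", "197", "205", "135b",
                              "200b", "200c", "141"))
  signature_set(ids, provenance = "fixed")
}

#' Reduce a candidate probe list to the best small signature
#'
#' Evaluates nested prefixes of the candidate list (which
#' \code{\link{filter_significant}} orders by ascending p-value) at every
#' size k in 1..\code{k_max}, scoring each prefix by leave-one-out
#' cross-validated accuracy on the training data.  The k maximizing LOOCV
#' accuracy wins; ties are broken by accuracy on an optional external
#' validation set (which never participates in fitting), then by smaller k.
#'
#' Exhaustive subset search is deliberately avoided: nested p-ranked
#' prefixes are deterministic, reproducible and feasible, where
#' \eqn{\binom{38}{13} \approx 10^{10}} subsets are not.
#'
#' @param candidates ordered character vector of candidate probe ids
#'   (ascending screen p-value).
#' @param train a \code{delta_ct_matrix}/matrix of training samples.
#' @param labels training class labels.
#' @param validation optional \code{delta_ct_matrix}/matrix of external
#'   validation samples used only for tie-breaking.
#' @param validation_labels labels for \code{validation}.
#' @param k_max largest prefix size to evaluate (default: all candidates).
#' @param ... passed to \code{\link{dlda}} / \code{\link{loocv}}.
#' @return a \code{\link{signature_set}} with \code{provenance =
#'   "searched"}; its \code{metrics} record the winning LOOCV accuracy,
#'   validation accuracy (if available) and the full per-k evaluation
#'   table.
#' @export
reduce_signature <- function(candidates, train, labels, validation = NULL,
                             validation_labels = NULL,
                             k_max = length(candidates), ...) {
  candidates <- as.character(candidates)
  if (!length(candidates))
    stop_mirsig("empty candidate list", class = "mirsig_validation_error")
  if (k_max < 1L || k_max > length(candidates))
    stop_mirsig("k_max must lie in 1..", length(candidates),
                class = "mirsig_validation_error")
  has_val <- !is.null(validation)
  if (has_val && is.null(validation_labels))
    stop_mirsig("validation data supplied without validation_labels",
                class = "mirsig_validation_error")
  eval_tab <- data.frame(k = seq_len(k_max), loocv_accuracy = NA_real_,
                         validation_accuracy = NA_real_)
  for (k in seq_len(k_max)) {
    probes <- candidates[seq_len(k)]
    eval_tab$loocv_accuracy[k] <- loocv(train, labels, probes = probes, ...)$accuracy
    if (has_val) {
      fit <- dlda(train, labels, probes = probes, ...)
      eval_tab$validation_accuracy[k] <-
        prediction_accuracy(predict(fit, validation), validation_labels)
    }
  }
  best <- eval_tab$loocv_accuracy == max(eval_tab$loocv_accuracy)
  if (has_val) {
    va <- eval_tab$validation_accuracy
    best <- best & va == max(va[best])
  }
  k_sel <- eval_tab$k[best][1L]
  signature_set(candidates[seq_len(k_sel)], provenance = "searched",
                metrics = list(loocv_accuracy = eval_tab$loocv_accuracy[k_sel],
                               validation_accuracy =
                                 if (has_val) eval_tab$validation_accuracy[k_sel] else NULL,
                               evaluations = eval_tab))
}

# accuracy of a dlda_prediction against known labels; samples whose label
# is not sensitive/resistant are excluded
prediction_accuracy <- function(prediction, labels) {
  labels <- align_labels(labels, prediction$sample_id)
  use <- labels %in% c("sensitive", "resistant")
  if (!any(use))
    stop_mirsig("no labelled samples to compute accuracy on",
                class = "mirsig_validation_error")
  mean(prediction$call[use] == labels[use])
}

#' Write a signature to a plain-text file
#'
#' One probe id per line; lines starting with \code{#} are comments.
#'
#' @param signature a \code{\link{signature_set}} or character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signature_file <- function(signature, path) {
  ids <- if (inherits(signature, "signature_set")) signature$probe_ids
         else as.character(signature)
  prov <- if (inherits(signature, "signature_set")) signature$provenance else "fixed"
  writeLines(c(sprintf("# %d-probe signature (%s)", length(ids), prov), ids), path)
  invisible(path)
}

#' Read a signature file written by \code{\link{write_signature_file}}
#'
#' @param path input path.
#' @param provenance provenance to record (default \code{"fixed"}).
#' @return a \code{\link{signature_set}}.
#' @export
read_signature_file <- function(path, provenance = "fixed") {
  lines <- trimws(readLines(path))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  signature_set(ids, provenance = provenance)
}
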