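#' Impute undetected wells at the detection ceiling
#'
#' Wells reported as \code{"Undetermined"} never crossed the fluorescence
#' threshold; they are assigned the maximum cycle of the run (Ct = 40 by
#' default) so that downstream statistics can treat the matrix as complete.
#' Imputed wells keep a provenance flag so reports can count them, because
#' fold changes computed from ceiling-imputed wells can be inflated.
#'
#' @param x a \code{\link{ct_matrix}}.
#' @param ceiling maximum cycle of the PCR run (default 40).
#' @return a fully detected \code{ct_matrix}; idempotent.
#' @export
impute_undetected <- function(x, ceiling = 40) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!is.numeric(ceiling) || length(ceiling) != 1L || !is.finite(ceiling))
    stop_mirsig("ceiling must be a single finite cycle count",
                class = "mirsig_validation_error")
  mx <- suppressWarnings(max(x$values[x$detected], -Inf))
  if (is.finite(mx) && ceiling < mx)
    stop_mirsig(sprintf("ceiling %g is below the largest detected Ct (%g)",
                        ceiling, mx),
                class = "mirsig_validation_error")
  fill <- !x$detected
  x$values[fill] <- ceiling
  x$imputed <- x$imputed | fill
  x$detected[fill] <- TRUE
  x
}

#' Normalize a Ct matrix to delta-Ct
#'
#' Subtracts the endogenous-control signal, yielding the delta-Ct feature
#' space every downstream statistic operates on.  Two conventions are
#' offered: \code{"per_sample"} (the standard comparative-Ct convention)
#' subtracts, within each sample, the mean Ct of that sample's control
#' wells, so sample-loading differences cancel; \code{"global"} subtracts
#' one scalar, the mean of all control wells across all samples.
#'
#' @param x a fully imputed \code{\link{ct_matrix}} (no undetected wells;
#'   run \code{\link{impute_undetected}} first).
#' @param mode \code{"per_sample"} (default) or \code{"global"}.
#' @param keep_controls keep the control-probe rows in the output
#'   (default \code{TRUE}); in per-sample mode their per-sample mean is 0.
#' @return a numeric matrix of class \code{delta_ct_matrix} with attributes
#'   \code{normalization_mode}, \code{control_probes} and \code{imputed}.
#' @export
normalize_delta_ct <- function(x, mode = c("per_sample", "global"),
                               keep_controls = TRUE) {
  stopifnot(inherits(x, "ct_matrix"))
  mode <- match.arg(mode)
  if (any(!x$detected))
    stop_mirsig("matrix still holds undetected wells; run impute_undetected() first",
                class = "mirsig_stage_error")
  ctrl <- x$control_probes
  if (!length(ctrl))
    stop_mirsig("no endogenous-control probes recorded; cannot normalize",
                class = "mirsig_validation_error")
  ctrl_vals <- x$values[ctrl, , drop = FALSE]
  vals <- x$values
  if (mode == "per_sample") {
    vals <- sweep(vals, 2L, colMeans(ctrl_vals), "-")
  } else {
    vals <- vals - mean(ctrl_vals)
  }
  imputed <- x$imputed
  if (!keep_controls) {
    keep <- setdiff(rownames(vals), ctrl)
    vals <- vals[keep, , drop = FALSE]
    imputed <- imputed[keep, , drop = FALSE]
  }
  delta_ct_matrix(vals, mode = mode, control_probes = ctrl, imputed = imputed)
}

delta_ct_matrix <- function(values, mode, control_probes, imputed = NULL) {
  structure(values,
            normalization_mode = mode,
            control_probes = control_probes,
            imputed = imputed,
            class = c("delta_ct_matrix", "matrix", "array"))
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("delta-Ct matrix: %d probes x %d samples (%s normalization, %d controls)\n",
              nrow(x), ncol(x), attr(x, "normalization_mode"),
              length(attr(x, "control_probes"))))
  invisible(x)
}

# subsetting keeps the class and normalization metadata when the result
# is still a matrix
#' @export
`[.delta_ct_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    imp <- attr(x, "imputed")
    if (!is.null(imp)) imp <- imp[rownames(out), colnames(out), drop = FALSE]
    out <- delta_ct_matrix(out, attr(x, "normalization_mode"),
                           attr(x, "control_probes"), imp)
  }
  out
}

# assay (non-control) probe ids of a delta-Ct or Ct matrix
assay_probes <- function(x) {
  if (inherits(x, "ct_matrix"))
    return(setdiff(rownames(x$values), x$control_probes))
  setdiff(rownames(x), attr(x, "control_probes"))
}

#' Comparative-Ct fold change (2^-ddCt)
#'
#' Computes the fold change between a case and a reference condition from
#' their delta-Ct values by the comparative Ct method:
#' \eqn{2^{-(\Delta Ct_{case} - \Delta Ct_{ref})}}.  Technical replicates
#' (e.g. triplicate wells) are averaged on the delta-Ct scale before
#' exponentiation.
#'
#' @param delta_ct_case numeric vector of case delta-Ct replicates.
#' @param delta_ct_reference numeric vector of reference delta-Ct replicates.
#' @param imputed set \code{TRUE} if any contributing well was
#'   ceiling-imputed; a warning is raised because such fold changes can be
#'   inflated.
#' @return positive scalar fold change.
#' @examples
#' fold_change_ddct(c(5.1, 4.9, 5.0), c(6.0, 6.2, 5.8))  # = 2
#' @export
fold_change_ddct <- function(delta_ct_case, delta_ct_reference, imputed = FALSE) {
  if (!length(delta_ct_case) || !length(delta_ct_reference) ||
      !all(is.finite(delta_ct_case)) || !all(is.finite(delta_ct_reference)))
    stop_mirsig("delta-Ct inputs must be non-empty and finite",
                class = "mirsig_validation_error")
  if (isTRUE(any(imputed)))
    warning("fold change involves ceiling-imputed well(s); value may be inflated",
            call. = FALSE)
  2^-(mean(delta_ct_case) - mean(delta_ct_reference))
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @param x a \code{delta_ct_matrix} or plain numeric matrix with dimnames.
#' @param path output path.
#' @param descriptions optional per-probe Description column (defaults to
#'   the probe ids).
#' @return \code{path}, invisibly.
#' @export
write_gct <- function(x, path, descriptions = NULL) {
  m <- as_value_matrix(x)
  if (is.null(descriptions)) descriptions <- rownames(m)
  lines <- c("#1.2",
             paste(nrow(m), ncol(m), sep = "\t"),
             paste(c("NAME", "Description", colnames(m)), collapse = "\t"),
             paste(rownames(m), descriptions,
                   apply(matrix(fmt_num(m), nrow(m)), 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GCT 1.2 expression matrix
#'
#' @param path a GCT file written by \code{\link{write_gct}} or a
#'   GenePattern-style tool.
#' @return numeric matrix (probes x samples).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
    stop_mirsig("not a GCT 1.2 file: ", path, class = "mirsig_format_error")
  dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]])
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (length(body) != dims[1L])
    stop_mirsig("GCT row count mismatch: header says ", dims[1L],
                ", found ", length(body), class = "mirsig_format_error")
  vals <- t(vapply(body, function(f) as.numeric(f[-(1:2)]), numeric(dims[2L])))
  if (dims[2L] == 1L) vals <- matrix(vals, ncol = 1L)
  rownames(vals) <- vapply(body, `[[`, character(1L), 1L)
  colnames(vals) <- header[-(1:2)]
  vals
}
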