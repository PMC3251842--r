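#' Construct a raw Ct matrix
#'
#' Container for TaqMan-array style cycle-threshold (Ct) readouts:
#' a probes x samples matrix of cycles together with a detected flag per
#' well and the identities of the endogenous-control probes.  Undetected
#' wells ("Undetermined" on the instrument) are stored as \code{NA} until
#' they are imputed with \code{\link{impute_undetected}}.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).  \code{NA} marks an
#'   undetected well.
#' @param detected optional logical matrix of the same shape; defaults to
#'   \code{!is.na(values)}.
#' @param control_probes character vector of probe ids acting as
#'   endogenous controls (e.g. U6 snRNA wells).
#' @param imputed optional logical matrix flagging wells whose value was
#'   filled in at the detection ceiling.
#' @return an object of class \code{ct_matrix}.
#' @seealso \code{\link{load_ct_table}}, \code{\link{impute_undetected}},
#'   \code{\link{normalize_delta_ct}}
#' @export
ct_matrix <- function(values, detected = NULL, control_probes = character(),
                      imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_mirsig("values must be a numeric matrix", class = "mirsig_validation_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_mirsig("values must have probe rownames and sample colnames",
                class = "mirsig_validation_error")
  if (anyDuplicated(rownames(values)))
    stop_mirsig("duplicate probe id(s): ",
                paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
                class = "mirsig_format_error")
  if (anyDuplicated(colnames(values)))
    stop_mirsig("duplicate sample id(s): ",
                paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
                class = "mirsig_format_error")
  if (is.null(detected)) detected <- !is.na(values)
  stopifnot(is.logical(detected), dim(detected) == dim(values))
  dimnames(detected) <- dimnames(values)
  if (any(detected & !is.finite(values)))
    stop_mirsig("detected wells must hold finite Ct values",
                class = "mirsig_validation_error")
  if (any(values[detected] < 0))
    stop_mirsig("negative Ct value encountered", class = "mirsig_validation_error")
  values[!detected] <- NA_real_
  control_probes <- as.character(control_probes)
  missing_ctrl <- setdiff(control_probes, rownames(values))
  if (length(missing_ctrl))
    stop_mirsig("control probe(s) absent from matrix: ",
                paste(missing_ctrl, collapse = ", "),
                class = "mirsig_validation_error")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  structure(list(values = values, detected = detected,
                 control_probes = control_probes, imputed = imputed),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Ct matrix: %d probes x %d samples (%d control probes)\n",
              nrow(x$values), ncol(x$values), length(x$control_probes)))
  n_undet <- sum(!x$detected)
  cat(sprintf("  undetected wells: %d (%.1f%%); imputed wells: %d\n",
              n_undet, 100 * n_undet / length(x$detected), sum(x$imputed)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

# tokens the loader treats as an undetected well (case-insensitive)
UNDETECTED_TOKENS <- c("undetermined", "undetected", "na", "")

#' Read a delimited Ct table
#'
#' Parses a probes x samples Ct table as exported from SDS-style qPCR
#' software: first column probe id, remaining columns one per sample.
#' Cells holding \code{"Undetermined"}, \code{"undetected"}, \code{"NA"}
#' or nothing are flagged as undetected wells.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; \code{NULL} (default) auto-detects tab
#'   versus comma from the header line.
#' @param control_probes probe ids to mark as endogenous controls, or
#'   \code{NULL} to auto-detect ids matching \code{control_pattern}.
#' @param control_pattern regular expression used for auto-detection
#'   (default matches U6/RNU-style normalizer names).
#' @return a \code{\link{ct_matrix}}.
#' @export
load_ct_table <- function(path, sep = NULL, control_probes = NULL,
                          control_pattern = "^(U6|RNU)") {
  if (!file.exists(path))
    stop_mirsig("file not found: ", path, class = "mirsig_io_error")
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop_mirsig("Ct table needs a probe id column plus at least one sample column",
                class = "mirsig_format_error")
  probe_ids <- raw[[1L]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop_mirsig("duplicate probe id(s): ", paste(dup, collapse = ", "),
                class = "mirsig_format_error")
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  token <- tolower(trimws(cells))
  undet <- matrix(token %in% UNDETECTED_TOKENS, nrow(cells), ncol(cells))
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(!undet & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop_mirsig(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                        cells[bad[1L, 1L], bad[1L, 2L]],
                        probe_ids[bad[1L, 1L]],
                        colnames(cells)[bad[1L, 2L]]),
                class = "mirsig_format_error")
  num[undet] <- NA_real_
  dimnames(num) <- list(probe_ids, colnames(cells))
  if (is.null(control_probes))
    control_probes <- probe_ids[grepl(control_pattern, probe_ids)]
  ct_matrix(num, detected = !undet, control_probes = control_probes)
}

#' Write a Ct matrix to a delimited file
#'
#' Inverse of \code{\link{load_ct_table}}: undetected wells are written as
#' the literal token \code{"Undetermined"}; detected values are written
#' with enough digits to round-trip exactly.
#'
#' @param x a \code{\link{ct_matrix}}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_ct_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "ct_matrix"))
  cells <- matrix("Undetermined", nrow(x$values), ncol(x$values))
  cells[x$detected] <- fmt_num(x$values[x$detected])
  lines <- c(paste(c("probe_id", colnames(x$values)), collapse = sep),
             paste(rownames(x$values), apply(cells, 1L, paste, collapse = sep),
                   sep = sep))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok))
    stop_mirsig("cannot write Ct table to ", path, ": ", conditionMessage(ok),
                class = "mirsig_io_error")
  invisible(path)
}
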