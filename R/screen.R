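#' Per-probe two-sample t-test between sensitive and resistant samples
#'
#' Screens every assay probe of a delta-Ct matrix with a classical
#' two-sample Student's t-test (pooled variance) between the sensitive and
#' resistant training samples.  Endogenous-control probes are excluded.
#' Because up-regulation means lower Ct, a probe up-regulated in sensitive
#' samples has a negative difference (sensitive minus resistant).
#'
#' Probes with zero pooled variance (e.g. rows fully imputed at the
#' ceiling in both classes) would yield an infinite statistic; their pooled
#' standard deviation is floored at \code{variance_floor} cycles and the
#' probe is flagged.
#'
#' @param x a \code{delta_ct_matrix} (or plain probes x samples matrix).
#' @param labels class per sample: \code{"sensitive"} or
#'   \code{"resistant"}, named by sample id or aligned with columns.
#'   Samples with other labels (e.g. \code{"unknown"}) are dropped.
#' @param method \code{"student"} (pooled variance, default) or
#'   \code{"welch"}.
#' @param variance_floor lower bound for the pooled standard deviation,
#'   cycles (default 1e-8).
#' @return data frame of class \code{probe_stats}: probe_id,
#'   mean_delta_ct_sensitive, mean_delta_ct_resistant, difference,
#'   t_statistic, p_value, direction, variance_floored.
#' @seealso \code{\link{filter_significant}}
#' @export
probe_t_test <- function(x, labels, method = c("student", "welch"),
                         variance_floor = 1e-8) {
  method <- match.arg(method)
  m <- as_value_matrix(x)
  labels <- align_labels(labels, colnames(m))
  use <- labels %in% c("sensitive", "resistant")
  m <- m[, use, drop = FALSE]
  labels <- labels[use]
  probes <- if (inherits(x, "delta_ct_matrix")) assay_probes(x) else rownames(m)
  m <- m[probes, , drop = FALSE]
  s <- labels == "sensitive"
  n1 <- sum(s); n2 <- sum(!s)
  if (n1 < 2L || n2 < 2L)
    stop_mirsig("need at least 2 samples per class (got ", n1, " sensitive, ",
                n2, " resistant)", class = "mirsig_validation_error")
  xs <- m[, s, drop = FALSE]; xr <- m[, !s, drop = FALSE]
  m1 <- rowMeans(xs); m2 <- rowMeans(xr)
  v1 <- rowSums((xs - m1)^2) / (n1 - 1L)
  v2 <- rowSums((xr - m2)^2) / (n2 - 1L)
  if (method == "student") {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    floored <- sp2 < variance_floor^2
    sp2[floored] <- variance_floor^2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep_len(n1 + n2 - 2L, length(se))
  } else {
    floored <- (v1 + v2) < variance_floor^2
    v1[floored] <- pmax(v1[floored], variance_floor^2 / 2)
    v2[floored] <- pmax(v2[floored], variance_floor^2 / 2)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  diff <- m1 - m2
  tstat <- diff / se
  tstat[diff == 0] <- 0          # identical groups: t = 0 even at the floor
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(probe_id = probes,
                    mean_delta_ct_sensitive = m1,
                    mean_delta_ct_resistant = m2,
                    difference = diff,
                    t_statistic = tstat,
                    p_value = p,
                    direction = ifelse(diff < 0, "up_in_sensitive", "down_in_sensitive"),
                    variance_floored = floored,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Filter a probe screen by significance
#'
#' Retains probes with p-value strictly below \code{alpha}, ordered by
#' ascending p-value; ties are broken by descending absolute t-statistic,
#' then probe id.  The resulting ordered candidate list feeds
#' \code{\link{reduce_signature}}.
#'
#' @param stats a \code{probe_stats} data frame from
#'   \code{\link{probe_t_test}}.
#' @param alpha significance threshold in (0, 1] (default 0.1, the
#'   threshold tied to the candidate-screen stage of the workflow).
#' @return character vector of probe ids (possibly empty), ordered.
#' @export
filter_significant <- function(stats, alpha = 0.1) {
  stopifnot(inherits(stats, "data.frame"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop_mirsig("alpha must lie in (0, 1]", class = "mirsig_validation_error")
  keep <- stats[stats$p_value < alpha, , drop = FALSE]
  ord <- order(keep$p_value, -abs(keep$t_statistic), keep$probe_id)
  keep$probe_id[ord]
}

#' Write a probe screen to TSV
#'
#' @param stats a \code{probe_stats} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_probe_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
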