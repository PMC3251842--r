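#' Draw random same-size signatures from a probe pool
#'
#' Each signature is k distinct probes drawn uniformly without replacement
#' from the pool; signatures are drawn independently of one another, so
#' the same probe (or an identical signature) may recur across draws.
#'
#' @param probe_pool character vector of probe ids to draw from.
#' @param k signature size.
#' @param n number of signatures.
#' @param seed RNG seed for reproducibility (optional).
#' @return list of \code{n} character vectors of length \code{k}.
#' @export
draw_random_signatures <- function(probe_pool, k, n, seed = NULL) {
  probe_pool <- as.character(probe_pool)
  if (k > length(probe_pool))
    stop_mirsig("k = ", k, " exceeds the pool size ", length(probe_pool),
                class = "mirsig_validation_error")
  if (n < 1L)
    stop_mirsig("n must be at least 1", class = "mirsig_validation_error")
  with_seed(seed,
            lapply(seq_len(n), function(i) sample(probe_pool, k)))
}

#' Summarize a permutation comparison
#'
#' Builds the result record of a random-signature calibration from its
#' counts.  The empirical adjusted p-value is the fraction of random
#' signatures the candidate failed to outperform:
#' \deqn{p = (n_{random} - n_{outperformed}) / n_{random},}
#' where outperforming means the random signature's metric is
#' \emph{strictly} below the candidate's — ties count against the
#' candidate.  With \code{continuity = TRUE} the positively biased
#' \eqn{(b + 1)/(n + 1)} estimator is used instead (b = non-wins).
#'
#' @param n_random number of random signatures evaluated.
#' @param n_outperformed how many had a metric strictly below the
#'   candidate's.
#' @param k signature size.
#' @param candidate_metric the candidate signature's metric value.
#' @param metric_name \code{"validation_accuracy"} or
#'   \code{"loocv_accuracy"}.
#' @param random_metrics optional numeric vector of the random signatures'
#'   metric values.
#' @param seed seed used for the draws, if any.
#' @param continuity use the (b+1)/(n+1) estimator (default \code{FALSE}).
#' @return an object of class \code{permutation_result}.
#' @examples
#' # a candidate that outperforms 9510 of 10,000 random signatures
#' permutation_result(10000, 9510)$empirical_p   # 0.049
#' @export
permutation_result <- function(n_random, n_outperformed, k = NA_integer_,
                               candidate_metric = NA_real_,
                               metric_name = "validation_accuracy",
                               random_metrics = NULL, seed = NULL,
                               continuity = FALSE) {
  if (n_outperformed < 0 || n_outperformed > n_random)
    stop_mirsig("n_outperformed must lie in 0..n_random",
                class = "mirsig_validation_error")
  b <- n_random - n_outperformed
  p <- if (continuity) (b + 1) / (n_random + 1) else b / n_random
  structure(list(n_random = n_random, k = k,
                 candidate_metric = candidate_metric,
                 n_outperformed = n_outperformed,
                 empirical_p = p, continuity = continuity,
                 metric_name = metric_name,
                 random_metrics = random_metrics, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Random-signature calibration (%s, k = %s): candidate outperformed %d/%d draws\n",
              x$metric_name, ifelse(is.na(x$k), "?", x$k),
              x$n_outperformed, x$n_random))
  if (!is.na(x$candidate_metric))
    cat(sprintf("  candidate metric: %.4f\n", x$candidate_metric))
  cat(sprintf("  empirical adjusted p-value: %.4g%s\n", x$empirical_p,
              if (x$continuity) " (with (b+1)/(n+1) continuity)" else ""))
  invisible(x)
}

#' Compare a signature against random same-size signatures
#'
#' The selected signature's claim to predict sensitivity is calibrated
#' against chance: \code{n} random signatures of the same size are drawn
#' from the probe pool, a DLDA model is fitted to the training data for
#' each, every model is evaluated with the chosen metric, and the
#' candidate's metric is compared against the resulting null distribution.
#' The empirical adjusted p-value is the fraction of random signatures the
#' candidate did not strictly outperform (see
#' \code{\link{permutation_result}}).
#'
#' Because DLDA treats probes independently, each random signature's model
#' is assembled from per-probe statistics computed once on the training
#' data; this is algebraically identical to refitting per signature and
#' makes \code{n = 10000} draws essentially free.
#'
#' @param candidate a \code{\link{signature_set}} or character vector of
#'   probe ids.
#' @param train training \code{delta_ct_matrix}/matrix.
#' @param train_labels training class labels.
#' @param evaluation external evaluation matrix (required for the
#'   \code{"validation_accuracy"} metric).
#' @param eval_labels labels for the evaluation samples.
#' @param pool probe pool to draw from; default all assay (non-control)
#'   probes of \code{train}.
#' @param n number of random signatures (default 10000).
#' @param seed RNG seed for the draws.
#' @param metric \code{"validation_accuracy"} (default) or
#'   \code{"loocv_accuracy"} when no external set exists.
#' @param continuity use the (b+1)/(n+1) p-value estimator.
#' @param variance_floor passed to the DLDA fits.
#' @return a \code{\link{permutation_result}}; its \code{random_metrics}
#'   component holds the full null distribution.
#' @export
permutation_test <- function(candidate, train, train_labels,
                             evaluation = NULL, eval_labels = NULL,
                             pool = NULL, n = 10000, seed = NULL,
                             metric = c("validation_accuracy", "loocv_accuracy"),
                             continuity = FALSE, variance_floor = 1e-8) {
  metric <- match.arg(metric)
  cand_ids <- if (inherits(candidate, "signature_set")) candidate$probe_ids
              else as.character(candidate)
  k <- length(cand_ids)
  tr <- as_value_matrix(train)
  if (is.null(pool))
    pool <- if (inherits(train, "delta_ct_matrix")) assay_probes(train)
            else rownames(tr)
  missing <- setdiff(cand_ids, union(pool, rownames(tr)))
  if (length(missing))
    stop_mirsig("candidate probe(s) not in pool or training matrix: ",
                paste(missing, collapse = ", "),
                class = "mirsig_validation_error")
  if (metric == "validation_accuracy") {
    if (is.null(evaluation) || is.null(eval_labels))
      stop_mirsig("validation_accuracy metric needs an evaluation matrix and labels",
                  class = "mirsig_validation_error")
    ev <- as_value_matrix(evaluation)
    ev_labels <- align_labels(eval_labels, colnames(ev))
    use <- ev_labels %in% c("sensitive", "resistant")
    if (!any(use))
      stop_mirsig("evaluation set has no labelled samples",
                  class = "mirsig_validation_error")
    ev <- ev[, use, drop = FALSE]
    ev_labels <- ev_labels[use]
    all_probes <- union(pool, cand_ids)
    fit <- dlda(tr, train_labels, probes = all_probes,
                variance_floor = variance_floor)
    # per-probe, per-sample margin contributions on the evaluation set
    contrib <- margin_contributions(fit, ev[all_probes, , drop = FALSE])
    truth <- ev_labels == "sensitive"
    acc_of <- function(ids) {
      margins <- colSums(contrib[ids, , drop = FALSE])
      mean((margins > 0) == truth)
    }
    candidate_metric <- acc_of(cand_ids)
    sigs <- draw_random_signatures(pool, k, n, seed = seed)
    ind <- matrix(0L, n, length(all_probes),
                  dimnames = list(NULL, all_probes))
    idx <- cbind(rep(seq_len(n), each = k), match(unlist(sigs), all_probes))
    ind[idx] <- 1L
    margins <- ind %*% contrib
    random_metrics <- rowMeans(sweep(margins > 0, 2L, truth, "=="))
  } else {
    tr_labels <- align_labels(train_labels, colnames(tr))
    keep <- tr_labels %in% c("sensitive", "resistant")
    trm <- tr[, keep, drop = FALSE]
    tr_labels <- tr_labels[keep]
    all_probes <- union(pool, cand_ids)
    truth <- tr_labels == "sensitive"
    # per-fold margin contributions for each held-out training sample
    contrib <- vapply(seq_len(ncol(trm)), function(i) {
      fit <- dlda(trm[, -i, drop = FALSE], tr_labels[-i], probes = all_probes,
                  variance_floor = variance_floor)
      margin_contributions(fit, trm[all_probes, i, drop = FALSE])[, 1L]
    }, numeric(length(all_probes)))
    rownames(contrib) <- all_probes
    acc_of <- function(ids) {
      margins <- colSums(contrib[ids, , drop = FALSE])
      mean((margins > 0) == truth)
    }
    candidate_metric <- acc_of(cand_ids)
    sigs <- draw_random_signatures(pool, k, n, seed = seed)
    ind <- matrix(0L, n, length(all_probes),
                  dimnames = list(NULL, all_probes))
    idx <- cbind(rep(seq_len(n), each = k), match(unlist(sigs), all_probes))
    ind[idx] <- 1L
    margins <- ind %*% contrib
    random_metrics <- rowMeans(sweep(margins > 0, 2L, truth, "=="))
  }
  permutation_result(n_random = n,
                     n_outperformed = sum(random_metrics < candidate_metric),
                     k = k, candidate_metric = candidate_metric,
                     metric_name = metric,
                     random_metrics = as.numeric(random_metrics),
                     seed = seed, continuity = continuity)
}

# per-probe additive contribution of each probe to the (sensitive -
# resistant) score margin of each sample; rows = model probes
margin_contributions <- function(fit, m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  v <- fit$variances
  ((m - fit$means["resistant", ])^2 - (m - fit$means["sensitive", ])^2) / (2 * v)
}

#' Write the random-signature metric distribution to TSV
#'
#' @param result a \code{\link{permutation_result}} carrying
#'   \code{random_metrics}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_permutation_distribution <- function(result, path) {
  stopifnot(inherits(result, "permutation_result"))
  if (is.null(result$random_metrics))
    stop_mirsig("result carries no random-signature metrics",
                class = "mirsig_validation_error")
  utils::write.table(data.frame(draw = seq_along(result$random_metrics),
                                metric = result$random_metrics),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
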