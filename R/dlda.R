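#' Fit a diagonal linear discriminant (DLDA) classifier
#'
#' Fits the diagonal-covariance Gaussian discriminant used throughout the
#' signature workflow: per-class per-probe means \eqn{\mu_{kj}} and a
#' pooled within-class variance \eqn{\sigma_j^2} per probe,
#' \deqn{\sigma_j^2 = \sum_k \sum_i (x_{ij} - \mu_{kj})^2 / (n - 2),}
#' floored at \code{variance_floor}.  Classification of an unknown sample
#' produces one likelihood score per class (see \code{\link{predict.dlda}});
#' a sample is called sensitive when its sensitive score exceeds its
#' resistant score, i.e. when the point (resistant score, sensitive score)
#' lies above the identity line.
#'
#' @param x a \code{delta_ct_matrix} (probes x samples) or plain numeric
#'   matrix with dimnames; the delta-Ct feature space.
#' @param labels class per sample, \code{"sensitive"}/\code{"resistant"}
#'   (named by sample id or aligned with columns); at least two samples per
#'   class.  Samples with other labels are dropped.
#' @param probes signature probe ids to restrict the model to (default: all
#'   assay probes of \code{x}).  Order is preserved and fixed in the model.
#' @param variance_floor lower bound for each pooled variance, cycles^2
#'   (default 1e-8); floored probes are flagged.
#' @param per_class_variance use class-specific instead of pooled
#'   variances (non-standard variant, default \code{FALSE}).
#' @param prior class prior probabilities (resistant, sensitive); the
#'   default equal priors add no offset to the scores.
#' @return an object of class \code{dlda} with components \code{probes},
#'   \code{classes}, \code{means} (class x probe), \code{variances},
#'   \code{variance_floor}, \code{floored}, \code{n_train}, \code{prior}.
#' @examples
#' x <- matrix(c(0, 2, 4, 6), 1, dimnames = list("p1", paste0("s", 1:4)))
#' fit <- dlda(x, c(s1 = "resistant", s2 = "resistant",
#'                  s3 = "sensitive", s4 = "sensitive"))
#' coef(fit)   # means 1 and 5, pooled variance 2
#' @export
dlda <- function(x, labels, probes = NULL, variance_floor = 1e-8,
                 per_class_variance = FALSE, prior = c(resistant = 0.5, sensitive = 0.5)) {
  m <- as_value_matrix(x)
  labels <- align_labels(labels, colnames(m))
  use <- labels %in% c("sensitive", "resistant")
  m <- m[, use, drop = FALSE]
  labels <- labels[use]
  if (is.null(probes)) {
    probes <- if (inherits(x, "delta_ct_matrix")) assay_probes(x) else rownames(m)
  } else {
    probes <- as.character(probes)
    missing <- setdiff(probes, rownames(m))
    if (length(missing))
      stop_mirsig("signature probe(s) absent from matrix: ",
                  paste(missing, collapse = ", "),
                  class = "mirsig_validation_error")
  }
  m <- m[probes, , drop = FALSE]
  s <- labels == "sensitive"
  n_s <- sum(s); n_r <- sum(!s)
  if (n_s < 2L || n_r < 2L)
    stop_mirsig("need at least 2 training samples per class (got ", n_s,
                " sensitive, ", n_r, " resistant)",
                class = "mirsig_validation_error")
  mu_s <- rowMeans(m[, s, drop = FALSE])
  mu_r <- rowMeans(m[, !s, drop = FALSE])
  ss_s <- rowSums((m[, s, drop = FALSE] - mu_s)^2)
  ss_r <- rowSums((m[, !s, drop = FALSE] - mu_r)^2)
  if (per_class_variance) {
    variances <- rbind(resistant = ss_r / (n_r - 1L), sensitive = ss_s / (n_s - 1L))
    floored <- apply(variances < variance_floor, 2L, any)
    variances[variances < variance_floor] <- variance_floor
  } else {
    variances <- (ss_s + ss_r) / (n_s + n_r - 2L)
    floored <- variances < variance_floor
    variances[floored] <- variance_floor
  }
  stopifnot(length(prior) == 2L, all(prior > 0))
  prior <- prior / sum(prior)
  if (is.null(names(prior))) names(prior) <- c("resistant", "sensitive")
  structure(list(probes = probes, classes = c("resistant", "sensitive"),
                 means = rbind(resistant = mu_r, sensitive = mu_s),
                 variances = variances, variance_floor = variance_floor,
                 floored = floored,
                 n_train = c(resistant = n_r, sensitive = n_s),
                 prior = prior, per_class_variance = per_class_variance,
                 call = match.call()),
            class = "dlda")
}

#' @export
print.dlda <- function(x, ...) {
  cat(sprintf("Diagonal linear discriminant model: %d probes, trained on %d resistant / %d sensitive samples\n",
              length(x$probes), x$n_train[["resistant"]], x$n_train[["sensitive"]]))
  if (any(x$floored))
    cat(sprintf("  %d probe(s) at the variance floor (%g)\n",
                sum(x$floored), x$variance_floor))
  cat("  decision rule: sensitive iff sensitive score > resistant score (identity line)\n")
  invisible(x)
}

#' @export
summary.dlda <- function(object, ...) {
  v <- if (object$per_class_variance) colMeans(object$variances) else object$variances
  tab <- data.frame(probe_id = object$probes,
                    mean_resistant = object$means["resistant", ],
                    mean_sensitive = object$means["sensitive", ],
                    separation = (object$means["sensitive", ] - object$means["resistant", ]) / sqrt(v),
                    pooled_variance = v,
                    floored = object$floored,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = object, probes = tab), class = "summary.dlda")
}

#' @export
print.summary.dlda <- function(x, ...) {
  print(x$model)
  print(x$probes, digits = 3)
  invisible(x)
}

#' @export
coef.dlda <- function(object, ...) {
  rbind(object$means,
        pooled_variance = if (object$per_class_variance)
          colMeans(object$variances) else object$variances)
}

# per-sample class scores for a probes x samples value matrix aligned to
# the model's probe order
dlda_scores <- function(object, m) {
  v <- object$variances
  if (object$per_class_variance) {
    vr <- v["resistant", ]; vs <- v["sensitive", ]
  } else {
    vr <- vs <- v
  }
  score_r <- -0.5 * colSums((m - object$means["resistant", ])^2 / vr)
  score_s <- -0.5 * colSums((m - object$means["sensitive", ])^2 / vs)
  if (diff(range(object$prior)) > 0) {
    score_r <- score_r + log(object$prior[["resistant"]])
    score_s <- score_s + log(object$prior[["sensitive"]])
  }
  cbind(resistant = score_r, sensitive = score_s)
}

#' Score unknown samples with a DLDA model
#'
#' For each sample the discriminant emits two scores, the diagonal-Gaussian
#' log-likelihood (up to a constant shared by both classes) that the sample
#' was drawn from the resistant or the sensitive training distribution:
#' \deqn{score_k = -\tfrac12 \sum_j (x_j - \mu_{kj})^2 / \sigma_j^2.}
#' Plotting sensitive score against resistant score, samples above the
#' identity line (positive margin) are called sensitive; on or below it,
#' resistant.  A zero margin is deliberately called resistant — the
#' conservative direction for a borderline tumour.
#'
#' @param object a fitted \code{\link{dlda}} model.
#' @param newdata a \code{delta_ct_matrix}/matrix (probes x samples)
#'   containing all model probes, or a numeric vector over the model's
#'   probes for a single sample.
#' @param actual optional known labels, recycled into the output table.
#' @param ... unused.
#' @return data frame of class \code{dlda_prediction}: sample_id,
#'   score_resistant, score_sensitive, margin, call (and actual if given).
#' @export
predict.dlda <- function(object, newdata, actual = NULL, ...) {
  if (is.null(dim(newdata))) {
    if (!is.null(names(newdata))) {
      missing <- setdiff(object$probes, names(newdata))
      if (length(missing))
        stop_mirsig("sample lacks probe(s): ", paste(missing, collapse = ", "),
                    class = "mirsig_validation_error")
      newdata <- newdata[object$probes]
    } else if (length(newdata) != length(object$probes)) {
      stop_mirsig("sample vector length ", length(newdata),
                  " does not match the ", length(object$probes), "-probe model",
                  class = "mirsig_validation_error")
    }
    m <- matrix(newdata, ncol = 1L, dimnames = list(object$probes, "sample"))
  } else {
    vals <- as_value_matrix(newdata)
    missing <- setdiff(object$probes, rownames(vals))
    if (length(missing))
      stop_mirsig("matrix lacks model probe(s): ", paste(missing, collapse = ", "),
                  class = "mirsig_validation_error")
    m <- vals[object$probes, , drop = FALSE]
  }
  if (!all(is.finite(m)))
    stop_mirsig("non-finite value in sample(s) to score",
                class = "mirsig_validation_error")
  sc <- dlda_scores(object, m)
  out <- data.frame(sample_id = colnames(m),
                    score_resistant = unname(sc[, "resistant"]),
                    score_sensitive = unname(sc[, "sensitive"]),
                    margin = unname(sc[, "sensitive"] - sc[, "resistant"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$call <- ifelse(out$margin > 0, "sensitive", "resistant")
  if (!is.null(actual)) out$actual <- as.character(actual)
  class(out) <- c("dlda_prediction", "data.frame")
  out
}

#' Score a single sample
#'
#' Convenience wrapper around \code{\link{predict.dlda}} for one delta-Ct
#' vector aligned to the model's probes.
#'
#' @param model a fitted \code{\link{dlda}} model.
#' @param x numeric vector over the model's signature probes.
#' @return one-row \code{dlda_prediction} data frame.
#' @export
score_sample <- function(model, x) {
  stopifnot(inherits(model, "dlda"))
  predict(model, x)
}

#' Plot DLDA prediction scores against the identity line
#'
#' Reproduces the two-score decision plot: resistant score on the x axis,
#' sensitive score on the y axis, with samples above the dashed identity
#' line called sensitive.
#'
#' @param x a \code{dlda_prediction} data frame.
#' @param ... further arguments passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.dlda_prediction <- function(x, ...) {
  col <- ifelse(x$call == "sensitive", "firebrick", "navy")
  lim <- range(c(x$score_resistant, x$score_sensitive))
  graphics::plot(x$score_resistant, x$score_sensitive, col = col, pch = 19,
                 xlim = lim, ylim = lim,
                 xlab = "resistant score", ylab = "sensitive score", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("called sensitive", "called resistant"),
                   col = c("firebrick", "navy"), pch = 19, bty = "n")
  invisible(x)
}

#' Leave-one-out cross-validation of a DLDA signature
#'
#' Internal validation of a signature: each training sample in turn is
#' held out, the model is refit on the remainder, and the held-out sample
#' is scored.  Reports per-sample held-out calls and the overall accuracy
#' fraction.
#'
#' @param x a \code{delta_ct_matrix}/matrix (probes x samples).
#' @param labels class per sample (\code{"sensitive"}/\code{"resistant"});
#'   at least 3 samples per class so every fold retains 2.
#' @param probes signature probe ids (default: all assay probes).
#' @param ... further arguments passed to \code{\link{dlda}}.
#' @return list of class \code{dlda_loocv} with \code{results} (data frame:
#'   sample_id, actual, call, margin, correct) and \code{accuracy}.
#' @export
loocv <- function(x, labels, probes = NULL, ...) {
  m <- as_value_matrix(x)
  labels <- align_labels(labels, colnames(m))
  use <- labels %in% c("sensitive", "resistant")
  m2 <- m[, use, drop = FALSE]
  labels <- labels[use]
  counts <- table(factor(labels, c("resistant", "sensitive")))
  if (any(counts < 3L))
    stop_mirsig("leave-one-out needs at least 3 samples per class so every fold keeps 2",
                class = "mirsig_validation_error")
  if (is.null(probes))
    probes <- if (inherits(x, "delta_ct_matrix")) assay_probes(x) else rownames(m2)
  rows <- lapply(seq_len(ncol(m2)), function(i) {
    fit <- dlda(m2[, -i, drop = FALSE], labels[-i], probes = probes, ...)
    pr <- predict(fit, m2[, i, drop = FALSE])
    data.frame(sample_id = colnames(m2)[i], actual = unname(labels[i]),
               call = pr$call, margin = pr$margin,
               correct = pr$call == unname(labels[i]),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 accuracy = mean(results$correct),
                 probes = probes),
            class = "dlda_loocv")
}

#' @export
print.dlda_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation over %d probes: %d/%d correct (accuracy %.3f)\n",
              length(x$probes), sum(x$results$correct), nrow(x$results), x$accuracy))
  miss <- x$results$sample_id[!x$results$correct]
  if (length(miss)) cat("  misclassified:", paste(miss, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a DLDA model to JSON
#'
#' @param object a \code{\link{dlda}} model.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dlda <- function(object, path) {
  stopifnot(inherits(object, "dlda"))
  payload <- list(format = "mirsig-dlda", version = 1L,
                  probes = object$probes,
                  classes = object$classes,
                  means = list(resistant = unname(object$means["resistant", ]),
                               sensitive = unname(object$means["sensitive", ])),
                  variances = if (object$per_class_variance)
                    list(resistant = unname(object$variances["resistant", ]),
                         sensitive = unname(object$variances["sensitive", ]))
                  else unname(object$variances),
                  variance_floor = object$variance_floor,
                  per_class_variance = object$per_class_variance,
                  n_train = as.list(object$n_train),
                  prior = as.list(object$prior))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a DLDA model serialized with \code{\link{write_dlda}}
#'
#' @param path JSON file path.
#' @return a \code{\link{dlda}} model.
#' @export
read_dlda <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mirsig-dlda"))
    stop_mirsig("not a serialized DLDA model: ", path,
                class = "mirsig_format_error")
  variances <- if (isTRUE(p$per_class_variance))
    rbind(resistant = p$variances$resistant, sensitive = p$variances$sensitive)
  else as.numeric(p$variances)
  if (!isTRUE(p$per_class_variance)) names(variances) <- p$probes
  means <- rbind(resistant = p$means$resistant, sensitive = p$means$sensitive)
  colnames(means) <- p$probes
  structure(list(probes = p$probes, classes = p$classes, means = means,
                 variances = variances, variance_floor = p$variance_floor,
                 floored = if (is.matrix(variances))
                   apply(variances <= p$variance_floor, 2L, any)
                 else variances <= p$variance_floor,
                 n_train = unlist(p$n_train), prior = unlist(p$prior),
                 per_class_variance = isTRUE(p$per_class_variance),
                 call = NULL),
            class = "dlda")
}
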