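#' Hierarchical clustering of signature expression
#'
#' Unsupervised agglomerative clustering of samples or probes from
#' delta-Ct expression values, as used for signature heatmaps.  The
#' default distance is Pearson correlation distance (1 - r) with average
#' linkage, the conventional choice for expression heatmap viewers;
#' Euclidean distance and complete/single linkage are available.  Items
#' are sorted lexicographically by label before clustering so the result
#' does not depend on input order, and leaf-order ties resolve to
#' alphabetical order.
#'
#' @param x a \code{delta_ct_matrix}/matrix (probes x samples), free of
#'   missing values.
#' @param axis cluster \code{"samples"} (columns, default) or
#'   \code{"probes"} (rows).
#' @param probes optional signature probe ids to restrict to before
#'   clustering.
#' @param distance \code{"pearson"} (1 - correlation, default) or
#'   \code{"euclidean"}.
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @return an object of class \code{signature_dendrogram}: the underlying
#'   \code{\link[stats]{hclust}} tree plus \code{axis},
#'   \code{distance_name}, \code{linkage_name} and \code{leaf_order}.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "probes"), probes = NULL,
                                 distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as_value_matrix(x)
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(m))
    if (length(missing))
      stop_mirsig("probe(s) absent from matrix: ", paste(missing, collapse = ", "),
                  class = "mirsig_validation_error")
    m <- m[probes, , drop = FALSE]
  }
  if (anyNA(m))
    stop_mirsig("matrix holds missing values; impute before clustering",
                class = "mirsig_stage_error")
  items <- if (axis == "samples") m else t(m)   # columns = items
  items <- items[, order(colnames(items)), drop = FALSE]
  if (ncol(items) < 2L)
    stop_mirsig("need at least 2 ", axis, " to cluster",
                class = "mirsig_validation_error")
  if (distance == "pearson") {
    sds <- apply(items, 2L, stats::sd)
    if (any(sds == 0))
      stop_mirsig("constant ", sub("s$", "", axis), "(s) under correlation distance: ",
                  paste(colnames(items)[sds == 0], collapse = ", "),
                  class = "mirsig_validation_error")
    d <- stats::as.dist(1 - stats::cor(items))
  } else {
    d <- stats::dist(t(items))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, axis = axis, distance_name = distance,
                 linkage_name = linkage,
                 leaf_order = hc$labels[hc$order]),
            class = "signature_dendrogram")
}

#' @export
print.signature_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram over %d %s (%s distance, %s linkage)\n",
              length(x$leaf_order), x$axis, x$distance_name, x$linkage_name))
  invisible(x)
}

#' Cut a dendrogram into flat groups
#'
#' @param dendrogram a \code{signature_dendrogram}.
#' @param k number of groups (default 2, the top split).
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(dendrogram, k = 2) {
  stopifnot(inherits(dendrogram, "signature_dendrogram"))
  stats::cutree(dendrogram$hclust, k = k)
}

#' Render a blue-to-red expression heatmap
#'
#' Writes a PNG heatmap of signature expression in the convention of
#' expression viewers: blue denotes low and red high expression.  Because
#' the matrix holds delta-Ct values (where \emph{lower} means more
#' transcript), the colour scale maps negated delta-Ct; the sign
#' convention is printed in the figure margin.
#'
#' @param x a \code{delta_ct_matrix}/matrix (probes x samples).
#' @param path output PNG path.
#' @param probe_order,sample_order permutations of the row/column names
#'   fixing the display order (default: current order).  Supply
#'   \code{leaf_order} from \code{\link{hierarchical_cluster}} to match a
#'   dendrogram.
#' @param width,height device size in pixels.
#' @return \code{path}, invisibly; output is deterministic for fixed input.
#' @export
render_heatmap <- function(x, path, probe_order = NULL, sample_order = NULL,
                           width = 900, height = 700) {
  m <- as_value_matrix(x)
  probe_order <- check_permutation(probe_order, rownames(m), "probe_order")
  sample_order <- check_permutation(sample_order, colnames(m), "sample_order")
  m <- m[probe_order, sample_order, drop = FALSE]
  expr <- -m   # high expression (low delta-Ct) = red
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(6, 2, 2, 8))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  # image() draws rows of the input along x; transpose so probes are rows
  graphics::image(x = seq_len(ncol(expr)), y = seq_len(nrow(expr)),
                  z = t(expr), col = pal,
                  zlim = range(expr), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(expr)), labels = colnames(expr),
                 las = 2, cex.axis = 0.8, tick = FALSE)
  graphics::axis(4, at = seq_len(nrow(expr)), labels = rownames(expr),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::mtext("colour = -ΔCt: red high expression, blue low", side = 1,
                  line = 4.5, cex = 0.8)
  invisible(path)
}

check_permutation <- function(ord, labels, what) {
  if (is.null(ord)) return(labels)
  if (!setequal(ord, labels) || length(ord) != length(labels))
    stop_mirsig(what, " is not a permutation of the axis labels",
                class = "mirsig_validation_error")
  ord
}

#' Export a clustered matrix as GCT plus CDT/GTR/ATR files
#'
#' Writes the delta-Ct matrix in GCT 1.2 and in the clustered-data-table
#' family of formats consumed by GenePattern-style heatmap viewers: a CDT
#' with rows and columns permuted to the dendrogram leaf orders, a GTR
#' (probe tree) and an ATR (sample tree) describing the merge history.
#'
#' @param x a \code{delta_ct_matrix}/matrix.
#' @param dendrograms list with optional elements \code{probes} and
#'   \code{samples}, each a \code{signature_dendrogram} over the matching
#'   axis of \code{x}.
#' @param directory output directory (created if needed).
#' @param name basename for the files (default \code{"expression"}).
#' @return named character vector of the written paths.
#' @export
write_gct_cdt <- function(x, dendrograms = list(), directory, name = "expression") {
  m <- as_value_matrix(x)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_mirsig("cannot create directory ", directory, class = "mirsig_io_error")
  probe_order <- if (!is.null(dendrograms$probes)) dendrograms$probes$leaf_order
                 else rownames(m)
  sample_order <- if (!is.null(dendrograms$samples)) dendrograms$samples$leaf_order
                  else colnames(m)
  probe_order <- check_permutation(probe_order, rownames(m), "probe dendrogram leaves")
  sample_order <- check_permutation(sample_order, colnames(m), "sample dendrogram leaves")
  paths <- c(gct = file.path(directory, paste0(name, ".gct")),
             cdt = file.path(directory, paste0(name, ".cdt")))
  write_gct(m, paths[["gct"]])
  mo <- m[probe_order, sample_order, drop = FALSE]
  gid <- paste0("GENE", seq_len(nrow(mo)), "X")
  aid <- paste0("ARRY", seq_len(ncol(mo)), "X")
  header <- paste(c("GID", "NAME", "GWEIGHT", sample_order), collapse = "\t")
  aid_line <- paste(c("AID", "", "", aid), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", rep("1", ncol(mo))), collapse = "\t")
  body <- paste(gid, probe_order, "1",
                apply(matrix(fmt_num(mo), nrow(mo)), 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, aid_line, eweight, body), paths[["cdt"]])
  if (!is.null(dendrograms$probes)) {
    paths[["gtr"]] <- file.path(directory, paste0(name, ".gtr"))
    write_tree_file(dendrograms$probes$hclust, gid, probe_order,
                    "NODE", paths[["gtr"]])
  }
  if (!is.null(dendrograms$samples)) {
    paths[["atr"]] <- file.path(directory, paste0(name, ".atr"))
    write_tree_file(dendrograms$samples$hclust, aid, sample_order,
                    "ANODE", paths[["atr"]])
  }
  paths
}

# serialize an hclust merge history in the GTR/ATR convention: one line
# per merge, node id, two children, score = 1 - height
write_tree_file <- function(hc, leaf_ids, leaf_labels, node_prefix, path) {
  id_of_leaf <- stats::setNames(leaf_ids, leaf_labels)
  child_id <- function(v, node_ids) {
    ifelse(v < 0, id_of_leaf[hc$labels[-v]], node_ids[v])
  }
  node_ids <- paste0(node_prefix, seq_len(nrow(hc$merge)), "X")
  lines <- vapply(seq_len(nrow(hc$merge)), function(i) {
    paste(node_ids[i],
          child_id(hc$merge[i, 1L], node_ids),
          child_id(hc$merge[i, 2L], node_ids),
          fmt_num(1 - hc$height[i]),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
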