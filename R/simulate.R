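#' Configuration for a simulated miRNA array experiment
#'
#' Describes the design of a synthetic TaqMan low-density-array study:
#' a card of assay probes plus endogenous-control wells, a small training
#' panel of drug-sensitive and drug-resistant cell lines, validation cell
#' lines and primary/metastatic tumours, and a planted expression
#' signature separating the two classes on the Ct scale.
#'
#' Conventions: all effects are stated in PCR cycles on the Ct scale, and
#' up-regulation means a \emph{lower} Ct (more transcript).  Up-regulated
#' signature probes are shifted by \code{-effect_cycles} in sensitive
#' samples, down-regulated probes by \code{+effect_cycles}.
#'
#' @param n_probes number of assay probes on the card (default 381).
#' @param n_controls number of endogenous-control wells (default 3).
#' @param n_sensitive_train,n_resistant_train training samples per class
#'   (default 4 and 4).
#' @param n_validation named counts of validation samples per specimen
#'   category: \code{cell_line}, \code{primary}, \code{metastatic}.
#' @param signature_size number of planted signature probes (default 13).
#' @param n_up_in_sensitive,n_down_in_sensitive split of the signature into
#'   probes up- (11) and down-regulated (2) in sensitive samples; must sum
#'   to \code{signature_size}.
#' @param effect_cycles Ct-scale class shift of signature probes (default 3).
#' @param noise_sd per-well Gaussian noise, cycles (default 0.75).
#' @param sample_offset_sd per-sample loading offset, cycles (default 0.5);
#'   cancelled by per-sample delta-Ct normalization.
#' @param baseline_ct_range interval within [15, 38] from which per-probe
#'   baseline Ct values are drawn (default c(20, 32)).
#' @param dropout_ceiling maximum cycle; wells at or beyond it are
#'   undetected (default 40).
#' @param dropout_slope probability-per-cycle of an undetected call near the
#'   ceiling: a well with true value v is undetected with probability
#'   \code{max(0, 1 - (ceiling - v) * dropout_slope)} (default 0.25).
#' @param discordant_sample if \code{TRUE}, the last resistant training
#'   cell line keeps its resistant label but expresses the sensitive
#'   signature profile, emulating a biologically discordant line that a
#'   leave-one-out validation should flag.
#' @param seed default RNG seed used by \code{\link{simulate_card_experiment}}.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_probes = 381, n_controls = 3,
                       n_sensitive_train = 4, n_resistant_train = 4,
                       n_validation = c(cell_line = 8, primary = 4, metastatic = 4),
                       signature_size = 13, n_up_in_sensitive = 11,
                       n_down_in_sensitive = 2, effect_cycles = 3.0,
                       noise_sd = 0.75, sample_offset_sd = 0.5,
                       baseline_ct_range = c(20, 32), dropout_ceiling = 40,
                       dropout_slope = 0.25, discordant_sample = FALSE,
                       seed = NULL) {
  cfg <- list(n_probes = n_probes, n_controls = n_controls,
              n_sensitive_train = n_sensitive_train,
              n_resistant_train = n_resistant_train,
              n_validation = n_validation, signature_size = signature_size,
              n_up_in_sensitive = n_up_in_sensitive,
              n_down_in_sensitive = n_down_in_sensitive,
              effect_cycles = effect_cycles, noise_sd = noise_sd,
              sample_offset_sd = sample_offset_sd,
              baseline_ct_range = baseline_ct_range,
              dropout_ceiling = dropout_ceiling, dropout_slope = dropout_slope,
              discordant_sample = isTRUE(discordant_sample), seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, what)
    if (!ok) stop_mirsig("invalid simulation config: ", what,
                         class = "mirsig_config_error")
  counts <- c("n_probes", "n_controls", "n_sensitive_train", "n_resistant_train",
              "signature_size", "n_up_in_sensitive", "n_down_in_sensitive")
  for (f in counts)
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] >= 0 &&
          cfg[[f]] == round(cfg[[f]]), paste(f, "must be a count >= 0"))
  chk(all(c("cell_line", "primary", "metastatic") %in% names(cfg$n_validation)) &&
        all(cfg$n_validation >= 0),
      "n_validation must name counts for cell_line, primary, metastatic")
  chk(cfg$n_up_in_sensitive + cfg$n_down_in_sensitive == cfg$signature_size,
      "n_up_in_sensitive + n_down_in_sensitive must equal signature_size")
  chk(cfg$signature_size <= cfg$n_probes, "signature_size must not exceed n_probes")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd > 0, "noise_sd must be > 0")
  chk(is.numeric(cfg$effect_cycles) && cfg$effect_cycles >= 0,
      "effect_cycles must be >= 0")
  chk(is.numeric(cfg$sample_offset_sd) && cfg$sample_offset_sd >= 0,
      "sample_offset_sd must be >= 0")
  chk(length(cfg$baseline_ct_range) == 2L &&
        cfg$baseline_ct_range[1L] <= cfg$baseline_ct_range[2L] &&
        cfg$baseline_ct_range[1L] >= 15 && cfg$baseline_ct_range[2L] <= 38,
      "baseline_ct_range must be an interval within [15, 38]")
  chk(is.numeric(cfg$dropout_ceiling) && cfg$dropout_ceiling > cfg$baseline_ct_range[2L],
      "dropout_ceiling must exceed the baseline range")
  chk(is.numeric(cfg$dropout_slope) && cfg$dropout_slope >= 0,
      "dropout_slope must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulated card design: %d assay probes + %d controls; ",
                     "training %dS/%dR; validation %s;\n",
                     "  signature %d (%d up / %d down in sensitive), effect %.2g cycles, ",
                     "noise sd %.2g\n"),
              x$n_probes, x$n_controls, x$n_sensitive_train, x$n_resistant_train,
              paste(names(x$n_validation), x$n_validation, sep = "=", collapse = " "),
              x$signature_size, x$n_up_in_sensitive, x$n_down_in_sensitive,
              x$effect_cycles, x$noise_sd))
  invisible(x)
}

#' Simulate a complete miRNA qPCR array experiment
#'
#' Generates a Ct matrix with the statistical structure the signature
#' workflow assumes: per-probe baselines drawn once from
#' \code{baseline_ct_range}, a planted signature shifted between classes by
#' \code{effect_cycles} (up-regulated probes have lower Ct in sensitive
#' samples), per-sample loading offsets, Gaussian well noise, and
#' undetected wells near the detection ceiling.  Control probes carry no
#' class effect.  Metastatic tumours are drawn from the resistant profile;
#' primary tumours follow the profile matching their label.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed RNG seed; defaults to \code{config$seed}.  The same config
#'   and seed reproduce the experiment bit-exactly.
#' @return a list of class \code{card_experiment} with elements
#'   \code{ct} (a \code{\link{ct_matrix}}), \code{annotation} (data frame
#'   with sample_id, label, tissue, specimen, role), \code{signature}
#'   (the planted \code{\link{signature_set}}) and \code{config}.
#' @export
simulate_card_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(seed, {
    probe_ids <- sprintf("hsa-mir-%04d", seq_len(config$n_probes))
    ctrl_ids <- if (config$n_controls > 0)
      sprintf("U6-snRNA-%d", seq_len(config$n_controls)) else character()
    all_ids <- c(probe_ids, ctrl_ids)

    nv <- config$n_validation
    ann <- rbind(
      sample_block("SEN", config$n_sensitive_train, "sensitive", "cell_line", "train"),
      sample_block("RES", config$n_resistant_train, "resistant", "cell_line", "train"),
      sample_block("VAL-CL", nv[["cell_line"]],
                   rep_len(c("sensitive", "resistant"), nv[["cell_line"]]),
                   "cell_line", "validation"),
      sample_block("TUM-P", nv[["primary"]],
                   rep_len(c("sensitive", "resistant"), nv[["primary"]]),
                   "primary", "validation"),
      sample_block("TUM-M", nv[["metastatic"]], "resistant", "metastatic",
                   "validation"))

    baseline <- stats::runif(length(all_ids), config$baseline_ct_range[1L],
                             config$baseline_ct_range[2L])
    names(baseline) <- all_ids

    sig_ids <- sort(sample(probe_ids, config$signature_size))
    up_ids <- sig_ids[seq_len(config$n_up_in_sensitive)]
    down_ids <- setdiff(sig_ids, up_ids)

    # Ct shift applied to *sensitive-profile* samples
    shift <- stats::setNames(numeric(length(all_ids)), all_ids)
    shift[up_ids] <- -config$effect_cycles
    shift[down_ids] <- +config$effect_cycles

    # expression profile (sensitive/resistant) each sample follows
    profile <- ann$label
    if (config$discordant_sample && config$n_resistant_train > 0) {
      disc <- paste0("RES-", config$n_resistant_train)
      profile[ann$sample_id == disc] <- "sensitive"
    }
    profile[ann$specimen == "metastatic"] <- "resistant"

    n_s <- nrow(ann)
    offsets <- stats::rnorm(n_s, 0, config$sample_offset_sd)
    mu <- matrix(baseline, length(all_ids), n_s,
                 dimnames = list(all_ids, ann$sample_id))
    sens <- profile == "sensitive"
    if (any(sens)) mu[, sens] <- mu[, sens] + shift
    mu <- sweep(mu, 2L, offsets, "+")
    vals <- mu + stats::rnorm(length(mu), 0, config$noise_sd)

    p_drop <- pmin(1, pmax(0, 1 - (config$dropout_ceiling - vals) * config$dropout_slope))
    undet <- matrix(stats::runif(length(vals)) < p_drop, nrow(vals), ncol(vals))
    vals[undet] <- NA_real_
    vals[!undet] <- pmax(vals[!undet], 0)

    ct <- ct_matrix(vals, detected = !undet, control_probes = ctrl_ids)
    sig <- signature_set(sig_ids, provenance = "planted",
                         metrics = list(up_in_sensitive = up_ids,
                                        down_in_sensitive = down_ids))
    structure(list(ct = ct, annotation = ann, signature = sig, config = config),
              class = "card_experiment")
  })
}

sample_block <- function(prefix, n, label, specimen, role) {
  if (n == 0) {
    return(data.frame(sample_id = character(), label = character(),
                      tissue = character(), specimen = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  data.frame(sample_id = paste0(prefix, "-", seq_len(n)),
             label = rep_len(label, n), tissue = "lung",
             specimen = specimen, role = role, stringsAsFactors = FALSE)
}

#' @export
print.card_experiment <- function(x, ...) {
  cat("Simulated miRNA card experiment\n")
  print(x$ct)
  tab <- table(x$annotation$role, x$annotation$label)
  cat("  samples:\n")
  print(tab)
  cat(sprintf("  planted signature: %d probes\n", x$signature$k))
  invisible(x)
}

#' Write a simulated experiment as plain-text fixture files
#'
#' Serializes a \code{\link{simulate_card_experiment}} result into the
#' formats the Ct-processing stage consumes: the Ct table (undetected wells
#' as the literal token \code{"Undetermined"}), the sample annotation table
#' and the planted signature list.  The round trip through
#' \code{\link{load_ct_table}} is lossless.
#'
#' @param experiment a \code{card_experiment}.
#' @param directory output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_fixture_bundle <- function(experiment, directory) {
  stopifnot(inherits(experiment, "card_experiment"))
  ok <- tryCatch({ dir.create(directory, recursive = TRUE, showWarnings = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok) || !dir.exists(directory))
    stop_mirsig("cannot create fixture directory ", directory,
                class = "mirsig_io_error")
  paths <- c(ct_table = file.path(directory, "ct_table.tsv"),
             annotation = file.path(directory, "annotation.tsv"),
             signature = file.path(directory, "signature.txt"))
  write_ct_table(experiment$ct, paths[["ct_table"]])
  utils::write.table(experiment$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_signature_file(experiment$signature, paths[["signature"]])
  paths
}

#' Read a sample annotation table
#'
#' @param path TSV with columns sample_id, label, tissue, specimen (and
#'   optionally role) as written by \code{\link{write_fixture_bundle}}.
#' @return data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "tissue", "specimen")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop_mirsig("annotation file lacks column(s): ", paste(missing, collapse = ", "),
                class = "mirsig_format_error")
  ann
}
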