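# shared fixture builders and independent oracles

# small toy Ct matrix with named probes/samples
toy_ct <- function(values, controls = character()) {
  ct_matrix(values, control_probes = controls)
}

# a small, fast simulation design for property-style loops
small_config <- function(..., effect_cycles = 2.5, seed = NULL) {
  sim_config(n_probes = 40, n_controls = 3,
             n_validation = c(cell_line = 4, primary = 2, metastatic = 2),
             signature_size = 3, n_up_in_sensitive = 2, n_down_in_sensitive = 1,
             effect_cycles = effect_cycles, seed = seed, ...)
}

# default-config experiment processed to the delta-Ct stage
processed_experiment <- function(cfg) {
  e <- simulate_card_experiment(cfg)
  dct <- normalize_delta_ct(impute_undetected(e$ct, cfg$dropout_ceiling))
  labels <- stats::setNames(e$annotation$label, e$annotation$sample_id)
  list(exp = e, dct = dct, labels = labels,
       train = e$annotation$sample_id[e$annotation$role == "train"],
       validation = e$annotation$sample_id[e$annotation$role == "validation"])
}

# --- independent oracles ------------------------------------------------

# full diagonal-Gaussian log-density classifier, including the log-variance
# term the packaged score drops as class-invariant
oracle_dlda_call <- function(x, mu_r, mu_s, v) {
  ll_r <- sum(stats::dnorm(x, mu_r, sqrt(v), log = TRUE))
  ll_s <- sum(stats::dnorm(x, mu_s, sqrt(v), log = TRUE))
  if (ll_s > ll_r) "sensitive" else "resistant"
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# naive O(n^3) average-linkage agglomeration over a dissimilarity matrix;
# returns successive merge heights and member sets
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    merges <- c(merges, list(sort(c(clusters[[best[2]]], clusters[[best[3]]]))))
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  list(heights = heights, merges = merges)
}
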