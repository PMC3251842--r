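# internal helpers shared across the package

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_mirsig <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mirsig_error")))
}

# coerce a labels argument (named or positional) to a character vector
# aligned with `sample_ids`; every sample must be covered
align_labels <- function(labels, sample_ids, allowed = NULL) {
  labels <- as.character(if (is.factor(labels)) as.character(labels) else labels)
  nm <- names(labels)
  if (!is.null(nm) && all(nzchar(nm))) {
    missing <- setdiff(sample_ids, nm)
    if (length(missing))
      stop_mirsig("labels missing for sample(s): ", paste(missing, collapse = ", "),
                  class = "mirsig_validation_error")
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop_mirsig("labels must be named by sample or have length ", length(sample_ids),
                class = "mirsig_validation_error")
  }
  names(labels) <- sample_ids
  if (!is.null(allowed)) {
    bad <- setdiff(unique(labels), allowed)
    if (length(bad))
      stop_mirsig("unknown label(s): ", paste(bad, collapse = ", "),
                  " (expected ", paste(allowed, collapse = "/"), ")",
                  class = "mirsig_validation_error")
  }
  labels
}

# values matrix from either a plain matrix or one of the package's
# matrix-like classes
as_value_matrix <- function(x) {
  if (inherits(x, "ct_matrix")) return(x$values)
  m <- unclass(x)
  if (!is.matrix(m) || !is.numeric(m))
    stop_mirsig("expected a numeric matrix of probes x samples",
                class = "mirsig_validation_error")
  m
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to shortest representation that round-trips
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}
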