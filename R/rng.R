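# Hierarchical seed derivation: one user-facing seed, split deterministically
# per plate / well / purpose so any subset of the synthetic screen can be
# regenerated in isolation. Plain multiply-add hash over a prime below 2^31;
# collisions across the handful of streams a screen uses are irrelevant, only
# determinism and decorrelation matter.

derive_seed <- function(seed, ...) {
  parts <- c(as.double(seed), unlist(lapply(list(...), function(p) {
    if (is.character(p)) {
      v <- utf8ToInt(p)
      sum(v * seq_along(v))
    } else {
      as.double(p)
    }
  }), use.names = FALSE))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483629
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
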