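#' Differential protein test and regulated-protein filter
#'
#' Per-protein two-sided two-sample t-test on the log2 intensities of
#' treated versus control replicates, Benjamini-Hochberg adjustment over
#' all tested proteins, and the regulated flag at the stated raw-p plus
#' fold-change rule: `p < p_thr` and `|log2fc| > lfc_thr` (strict
#' inequalities; the adjusted q-value is reported alongside). The default
#' is the pooled-variance Student t-test, which is exact for
#' equal-variance triplicate designs; at n = 3 per group the Welch variant
#' (`var_equal = FALSE`) is markedly conservative (empirical size ~0.03 at
#' nominal 0.05), so it is offered as an option and the choice is recorded
#' in the `test` attribute of the result. Proteins with zero variance in
#' both groups get `p = 1` when the group means are equal and `p = 0`
#' otherwise (degenerate-evidence convention, noted in the `note` column).
#'
#' @param quant data.frame with `protein_id` and the replicate columns
#'   `treated_1..k`, `control_1..k` (k >= 2), e.g. from
#'   [generate_proteomics()] or [read_protein_quant()].
#' @param p_thr raw p-value threshold (default 0.05).
#' @param lfc_thr absolute log2 fold-change threshold (default 0.3).
#' @param var_equal pool the within-group variances (default `TRUE`);
#'   `FALSE` uses the Welch test.
#' @return data.frame: `protein_id`, `log2fc` (treated mean minus control
#'   mean), `p_value`, `q_value`, `regulated`, `note`; attribute `test`
#'   names the test applied.
#' @export
differential_proteins <- function(quant, p_thr = 0.05, lfc_thr = 0.3,
                                  var_equal = TRUE) {
  tcols <- grep("^treated_", names(quant), value = TRUE)
  ccols <- grep("^control_", names(quant), value = TRUE)
  if (length(tcols) < 2 || length(ccols) < 2) {
    stop("need at least 2 replicates per group")
  }
  tm <- as.matrix(quant[, tcols])
  cm <- as.matrix(quant[, ccols])
  if (!all(is.finite(tm)) || !all(is.finite(cm))) stop("intensities must be finite")
  n <- nrow(quant)
  lfc <- rowMeans(tm) - rowMeans(cm)
  p <- numeric(n)
  note <- character(n)
  for (i in seq_len(n)) {
    a <- tm[i, ]; b <- cm[i, ]
    if (sd(a) == 0 && sd(b) == 0) {
      p[i] <- if (mean(a) == mean(b)) 1 else 0
      note[i] <- "zero_variance"
    } else {
      p[i] <- t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  q <- p.adjust(p, method = "BH")
  out <- data.frame(protein_id = quant$protein_id, log2fc = lfc, p_value = p,
                    q_value = q, regulated = p < p_thr & abs(lfc) > lfc_thr,
                    note = note)
  attr(out, "test") <- if (var_equal) "student_t" else "welch_t"
  out
}

#' Rank proteins by log2 fold change
#'
#' Descending log2 ratio with a deterministic lexicographic tie-break on
#' the protein id — the ranking the preranked enrichment stage consumes.
#'
#' @param results data.frame with `protein_id` and `log2fc` (e.g. from
#'   [differential_proteins()]).
#' @return the rows reordered, with a `rank` column prepended.
#' @export
rank_proteins <- function(results) {
  if (!all(is.finite(results$log2fc))) stop("log2fc must be finite")
  o <- order(-results$log2fc, results$protein_id)
  out <- results[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: set name, description, members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

# Running-sum enrichment score of one set over a ranked metric.
# hit: logical vector aligned with metric (descending order). Hits advance
# the sum by |metric|^p normalized by the total over set members, misses
# retreat by 1/(N - Nh). ES is the extremum of larger magnitude (signed);
# an exact positive/negative tie scores 0 — the standard convention, so
# the statistic agrees with reference implementations on small universes
# where the miss decrements make such ties attainable.
gsea_es <- function(metric, hit, weight_p = 1) {
  N <- length(metric)
  nh <- sum(hit)
  if (nh == 0 || nh == N) stop("set must be a proper nonempty subset")
  w <- abs(metric)^weight_p
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, N)
  run <- cumsum(ifelse(hit, inc, -1 / (N - nh)))
  max_p <- max(run)
  min_p <- min(run)
  if (max_p > -min_p) max_p else if (max_p < -min_p) min_p else 0
}

#' Preranked gene-set enrichment with the weighted statistic
#'
#' Walks the ranked list accumulating `|metric|^weight_p` (normalized by the
#' sum over set members) at each set member and `-1/(N - N_set)` at each
#' non-member; the enrichment score (ES) is the signed extremum of the
#' running sum, so `weight_p = 0` recovers the classic Kolmogorov-Smirnov
#' style statistic and `weight_p = 1` the standard weighted form. The null
#' distribution comes from random gene-label memberships of the same size
#' (fixed seed, or exhaustive enumeration of all memberships when feasible);
#' NES divides ES by the mean magnitude of same-sign null scores, the
#' permutation p-value is the same-sign tail fraction, and FDR q follows the
#' pooled-null procedure across all scored sets.
#'
#' @param ranked output of [rank_proteins()], or a named numeric vector of
#'   metrics sorted in descending order.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param weight_p exponent on the ranking metric (default 1, "weighted").
#' @param n_perm permutations per set (default 1000).
#' @param seed integer seed (mandatory) for the permutation draws.
#' @param min_size sets with fewer members in the ranked universe are
#'   skipped with a warning.
#' @param exhaustive if `TRUE` and `choose(N, N_set) <= max_exhaustive`,
#'   enumerate every membership instead of sampling.
#' @param max_exhaustive enumeration cap.
#' @return data.frame: `gene_set_id`, `size`, `es`, `nes`, `p_value`,
#'   `fdr_q`, `n_perm`, `seed`.
#' @export
gsea_preranked <- function(ranked, gene_sets, weight_p = 1, n_perm = 1000,
                           seed, min_size = 3, exhaustive = FALSE,
                           max_exhaustive = 100000) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.data.frame(ranked)) {
    metric <- setNames(ranked$log2fc, ranked$protein_id)
  } else {
    metric <- ranked
  }
  if (is.unsorted(rev(metric))) {
    o <- order(-metric, names(metric))
    metric <- metric[o]
  }
  N <- length(metric)
  universe <- names(metric)
  prep <- lapply(names(gene_sets), function(gs) {
    members <- intersect(gene_sets[[gs]], universe)
    list(id = gs, members = members, size = length(members))
  })
  skipped <- vapply(prep, function(x) x$size < min_size || x$size >= N, logical(1))
  if (any(skipped)) {
    warning("skipping sets below min_size or covering the universe: ",
            paste(vapply(prep[skipped], `[[`, "", "id"), collapse = ", "))
    prep <- prep[!skipped]
  }
  if (!length(prep)) {
    return(data.frame(gene_set_id = character(), size = integer(),
                      es = numeric(), nes = numeric(), p_value = numeric(),
                      fdr_q = numeric(), n_perm = integer(), seed = integer()))
  }
  res <- with_seed(derive_seed(seed, "gsea"), lapply(prep, function(x) {
    hit <- universe %in% x$members
    es <- gsea_es(metric, hit, weight_p)
    nulls <- if (exhaustive && choose(N, x$size) <= max_exhaustive) {
      combos <- utils::combn(N, x$size)
      apply(combos, 2, function(ix) {
        h <- logical(N); h[ix] <- TRUE
        gsea_es(metric, h, weight_p)
      })
    } else {
      vapply(seq_len(n_perm), function(k) {
        h <- logical(N); h[sample.int(N, x$size)] <- TRUE
        gsea_es(metric, h, weight_p)
      }, numeric(1))
    }
    same <- nulls[sign(nulls) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    pval <- if (length(same)) mean(abs(same) >= abs(es)) else NA_real_
    null_nes <- c(if (any(nulls > 0)) nulls[nulls > 0] / mean(nulls[nulls > 0]),
                  if (any(nulls < 0)) nulls[nulls < 0] / mean(abs(nulls[nulls < 0])))
    list(id = x$id, size = x$size, es = es, nes = nes, p = pval,
         n_null = length(nulls), null_nes = null_nes)
  }))
  nes_obs <- vapply(res, `[[`, numeric(1), "nes")
  null_pool <- unlist(lapply(res, `[[`, "null_nes"))
  fdr <- vapply(seq_along(res), function(i) {
    v <- nes_obs[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(null_pool[null_pool >= 0] >= v)
      den <- mean(nes_obs[!is.na(nes_obs) & nes_obs >= 0] >= v)
    } else {
      num <- mean(null_pool[null_pool <= 0] <= v)
      den <- mean(nes_obs[!is.na(nes_obs) & nes_obs <= 0] <= v)
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, numeric(1))
  data.frame(
    gene_set_id = vapply(res, `[[`, "", "id"),
    size = vapply(res, function(x) as.integer(x$size), integer(1)),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = nes_obs,
    p_value = vapply(res, `[[`, numeric(1), "p"),
    fdr_q = fdr,
    n_perm = vapply(res, function(x) as.integer(x$n_null), integer(1)),
    seed = as.integer(seed))
}
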