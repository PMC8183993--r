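#' Generate a synthetic 3-vs-3 proteomics quantification table
#'
#' Per-protein log2 intensities for three treated and three control
#' replicates. The first `n_regulated` proteins are shifted in the treated
#' group by `effect_log2fc`, alternating up/down (odd indices up, even
#' down); the rest share the group mean (global null). Replicate values are
#' Gaussian around the group mean with SD `within_group_sd`.
#'
#' @param n_proteins total proteins.
#' @param n_regulated planted regulated proteins (`<= n_proteins`).
#' @param effect_log2fc absolute log2 fold change of regulated proteins.
#' @param within_group_sd replicate SD on the log2 scale (must be positive).
#' @param seed integer seed; identical seeds give identical tables.
#' @param base_mean,base_sd distribution of per-protein baseline log2
#'   intensity.
#' @return list with `quant` (data.frame: `protein_id`, `treated_1..3`,
#'   `control_1..3`) and `truth` (`protein_id`, `regulated`, `direction`,
#'   `true_log2fc`).
#' @export
generate_proteomics <- function(n_proteins, n_regulated, effect_log2fc,
                                within_group_sd, seed,
                                base_mean = 25, base_sd = 2) {
  if (n_regulated > n_proteins) stop("n_regulated must not exceed n_proteins")
  if (within_group_sd <= 0) stop("within_group_sd must be positive")
  with_seed(derive_seed(seed, "proteomics"), {
    id <- sprintf("PROT%05d", seq_len(n_proteins))
    base <- rnorm(n_proteins, base_mean, base_sd)
    dir <- rep(0, n_proteins)
    if (n_regulated > 0) {
      dir[seq_len(n_regulated)] <- ifelse(seq_len(n_regulated) %% 2 == 1, 1, -1)
    }
    shift <- dir * effect_log2fc
    treated <- vapply(1:3, function(i) rnorm(n_proteins, base + shift, within_group_sd),
                      numeric(n_proteins))
    control <- vapply(1:3, function(i) rnorm(n_proteins, base, within_group_sd),
                      numeric(n_proteins))
    quant <- data.frame(protein_id = id,
                        treated_1 = treated[, 1], treated_2 = treated[, 2],
                        treated_3 = treated[, 3],
                        control_1 = control[, 1], control_2 = control[, 2],
                        control_3 = control[, 3])
    truth <- data.frame(protein_id = id, regulated = dir != 0,
                        direction = c("null", "up", "down")[1 + (dir == 1) + 2 * (dir == -1)],
                        true_log2fc = shift)
    list(quant = quant, truth = truth)
  })
}
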