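#' Evaluate dose-response validation series
#'
#' Validation-screen rule for hits re-tested at a dose ladder (default
#' 1, 3, 10 uM) in two independent plates and two orthogonal labeling
#' assays (OPP and HPG). For a down-regulator, a single series passes when
#' the top-dose response shows at least `min_effect` reduction
#' (`response(max dose) <= 1 - min_effect`) and the responses are
#' non-increasing in dose within an additive tolerance `mono_tol`
#' (`response[d+1] <= response[d] + mono_tol`); the rule is mirrored for
#' up-regulators. A compound is `validated` when every (assay x plate)
#' series passes in strict mode, or when at least one assay passes on both
#' plates in lenient mode. Compounds with an incomplete dose grid are
#' flagged and never validated.
#'
#' @param records data.frame with columns `compound_id`, `assay`,
#'   `replicate_plate`, `dose_uM`, `response` (fraction of vehicle).
#' @param min_effect minimum top-dose effect as a fraction (default 0.25).
#' @param mono_tol additive monotonicity tolerance (default 0.05).
#' @param direction `"down"` or `"up"`.
#' @param require_both_assays strict mode (default `TRUE`): all assays must
#'   pass; `FALSE`: one assay passing on all its plates suffices.
#' @return data.frame: per compound, `validated`, `complete`, per-assay
#'   pass flags (`pass_OPP`, `pass_HPG`, ... one per assay present) and
#'   top-dose responses (`top_OPP`, ...).
#' @export
evaluate_dose_response <- function(records, min_effect = 0.25,
                                   mono_tol = 0.05,
                                   direction = c("down", "up"),
                                   require_both_assays = TRUE) {
  direction <- match.arg(direction)
  if (any(records$response < 0)) stop("responses must be nonnegative")
  assays <- sort(unique(records$assay))
  doses <- sort(unique(records$dose_uM))
  series_pass <- function(resp) {
    if (direction == "down") {
      resp[length(resp)] <= 1 - min_effect &&
        all(diff(resp) <= mono_tol)
    } else {
      resp[length(resp)] >= 1 + min_effect &&
        all(diff(resp) >= -mono_tol)
    }
  }
  rows <- lapply(split(records, records$compound_id), function(g) {
    out <- data.frame(compound_id = g$compound_id[1], validated = FALSE,
                      complete = TRUE)
    assay_pass <- setNames(rep(NA, length(assays)), assays)
    assay_top <- setNames(rep(NA_real_, length(assays)), assays)
    for (a in assays) {
      ga <- g[g$assay == a, ]
      plates <- sort(unique(ga$replicate_plate))
      pass <- logical(0)
      tops <- numeric(0)
      for (p in plates) {
        s <- ga[ga$replicate_plate == p, ]
        s <- s[order(s$dose_uM), ]
        if (!identical(s$dose_uM, doses)) {
          out$complete <- FALSE
          next
        }
        pass <- c(pass, series_pass(s$response))
        tops <- c(tops, s$response[length(doses)])
      }
      if (length(plates) < 2) out$complete <- FALSE
      assay_pass[a] <- length(pass) > 0 && all(pass)
      assay_top[a] <- if (length(tops)) mean(tops) else NA_real_
    }
    out$validated <- out$complete && if (require_both_assays) {
      all(assay_pass)
    } else {
      any(assay_pass)
    }
    for (a in assays) {
      out[[paste0("pass_", a)]] <- assay_pass[[a]]
      out[[paste0("top_", a)]] <- assay_top[[a]]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
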