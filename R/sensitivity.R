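#' Sensitivity of hazard ratios to assumed population incidence
#'
#' Re-derives the case/control sample weights under each multiple of the
#' baseline incidence curve, refits the Cox model, and recomputes every
#' percentile hazard-ratio contrast. A factor of 1 reproduces the baseline
#' analysis exactly. Factors that push the scaled population case fraction
#' to 1 are flagged in the output rather than failing the sweep.
#'
#' @param data survival `data.frame` with `time`, `event`, `phs` (any
#'   existing `sample_weight` column is replaced per factor).
#' @param incidence baseline [incidence_curve()].
#' @param ref percentile reference for group assignment.
#' @param factors positive multipliers of the incidence curve; default a
#'   9-point geometric grid spanning 0.25-4.
#' @return `data.frame` sorted by factor with columns `factor`, `flagged`,
#'   `z`, and one `hr_<a>_<b>` column per contrast.
#' @export
sweep_incidence <- function(data, incidence, ref,
                            factors = 4^seq(-1, 1, length.out = 9)) {
  stopifnot(all(factors > 0))
  factors <- sort(factors)
  rows <- lapply(factors, function(f) {
    flagged <- FALSE
    w <- withCallingHandlers(
      compute_sample_weights(data$event, data$time, incidence,
                             scale_factor = f),
      warning = function(wn) {
        if (grepl("capped", conditionMessage(wn))) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    d <- data
    d$sample_weight <- as.numeric(w)
    rep <- hr_report(d, ref, stratum = sprintf("factor_%g", f))
    cbind(data.frame(factor = f, flagged = flagged),
          rep[, setdiff(names(rep), c("stratum", "n", "n_events"))])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum relative deviation of a contrast across an incidence sweep
#'
#' Convenience summary of [sweep_incidence()]: the largest
#' `|HR(factor) / HR(1) - 1|` over the grid for one contrast.
#'
#' @param sweep output of [sweep_incidence()]; the grid must contain
#'   factor 1.
#' @param contrast contrast column suffix, default `"80_20"`.
#' @return numeric scalar (relative deviation).
#' @export
sweep_max_deviation <- function(sweep, contrast = "80_20") {
  col <- paste0("hr_", contrast)
  stopifnot(col %in% names(sweep))
  base <- sweep[[col]][sweep$factor == 1]
  if (length(base) != 1)
    stop("sweep grid must contain factor 1 exactly once")
  max(abs(sweep[[col]] / base - 1))
}
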