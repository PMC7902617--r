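#' Assign continental ancestry labels from admixture proportions
#'
#' Threshold rules on named admixture components, evaluated in fixed order:
#' European if the European proportion exceeds 0.80, else Asian if the
#' Asian proportion exceeds 0.40, else African if the African proportion
#' exceeds 0.20, else "other". Thresholds are strict (>), matching the
#' "greater than" phrasing of the array-defined grouping they implement.
#'
#' @param profiles `data.frame` (or matrix) with columns `european`,
#'   `asian`, `african`; rows are individuals, each row summing to 1 within
#'   1e-6.
#' @return character vector of labels in
#'   `{"European", "Asian", "African", "other"}`.
#' @export
assign_oncoarray_label <- function(profiles) {
  profiles <- as.data.frame(profiles)
  names(profiles) <- tolower(names(profiles))
  need <- c("european", "asian", "african")
  if (!all(need %in% names(profiles)))
    stop("admixture profile must have components: ",
         paste(need, collapse = ", "))
  p <- as.matrix(profiles[, need])
  check_simplex(p)
  unname(ifelse(p[, "european"] > 0.80, "European",
    ifelse(p[, "asian"] > 0.40, "Asian",
      ifelse(p[, "african"] > 0.20, "African", "other"))))
}

#' Assign agnostic cluster labels from admixture proportions
#'
#' For model-free (e.g. fastSTRUCTURE-style) admixture output with K
#' components: an individual is placed in the cluster of its maximum
#' admixture proportion if that proportion is at least `threshold`
#' (boundary inclusive), otherwise labelled `"admixed"`. A tie at the
#' maximum is resolved to the lowest-index component with a warning.
#'
#' @param profiles numeric matrix or `data.frame`, individuals x K >= 2
#'   components, rows summing to 1 within 1e-6.
#' @param threshold minimum maximum-proportion for a hard assignment
#'   (default 0.8).
#' @return character vector: the assigned column name (or `"cluster<k>"`
#'   when columns are unnamed) or `"admixed"`.
#' @export
assign_cluster_label <- function(profiles, threshold = 0.8) {
  p <- as.matrix(profiles)
  if (ncol(p) < 2) stop("need at least 2 admixture components")
  check_simplex(p)
  if (is.null(colnames(p))) colnames(p) <- paste0("cluster", seq_len(ncol(p)))
  mx <- apply(p, 1, max)
  amax <- apply(p, 1, which.max)  # which.max takes the lowest index on ties
  ties <- rowSums(p == mx) > 1 & mx >= threshold
  if (any(ties))
    warning(sum(ties), " individual(s) tied at the maximum proportion; ",
            "assigned to the lowest-index cluster")
  unname(ifelse(mx >= threshold, colnames(p)[amax], "admixed"))
}

check_simplex <- function(p, tol = 1e-6) {
  if (any(p < -tol) || any(p > 1 + tol))
    stop("admixture proportions must lie in [0, 1]")
  bad <- abs(rowSums(p) - 1) > tol
  if (any(bad))
    stop(sum(bad), " profile(s) do not sum to 1 within ", tol)
  invisible(p)
}
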