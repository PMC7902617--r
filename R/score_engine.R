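#' Construct a SNP weight table
#'
#' The weight table defines a polygenic hazard score (PHS): for each variant
#' it records which allele is counted (the effect allele), the opposite
#' allele, and the per-allele log-hazard weight. The PHS of an individual is
#' the sum over variants of effect-allele dosage times weight.
#'
#' @param snp_id character vector of unique variant identifiers.
#' @param effect_allele character vector of single bases (A/C/G/T); the
#'   allele whose dosage is multiplied by the weight.
#' @param other_allele character vector of single bases, distinct from
#'   `effect_allele` at every variant.
#' @param weight numeric vector of finite per-allele log-hazard weights.
#' @return A `data.frame` of class `snp_weight_table` with the four columns
#'   above.
#' @export
snp_weight_table <- function(snp_id, effect_allele, other_allele, weight) {
  tab <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  validate_snp_weight_table(tab)
  class(tab) <- c("snp_weight_table", "data.frame")
  tab
}

validate_snp_weight_table <- function(tab) {
  stopifnot(all(c("snp_id", "effect_allele", "other_allele", "weight") %in%
                  names(tab)))
  if (anyDuplicated(tab$snp_id))
    stop("duplicate snp_id in weight table: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  if (!all(tab$effect_allele %in% bases) || !all(tab$other_allele %in% bases))
    stop("alleles must be one of A/C/G/T")
  if (any(tab$effect_allele == tab$other_allele))
    stop("effect_allele must differ from other_allele")
  if (any(!is.finite(tab$weight)))
    stop("weights must be finite")
  invisible(tab)
}

#' Construct a genotype dosage matrix
#'
#' Holds effect-allele dosages (reals in \[0, 2\], `NA` allowed) for a set of
#' individuals by variants, together with the allele each column counts.
#' The counted allele is required for [harmonize_alleles()]; purely numeric
#' workflows (e.g. simulated data already oriented to the score's effect
#' alleles) may omit the allele annotations.
#'
#' @param dosage numeric matrix, individuals in rows, variants in columns;
#'   `rownames` are individual ids and `colnames` are variant ids.
#' @param counted_allele optional named character vector (names = variant
#'   ids) giving the allele counted by each dosage column.
#' @param other_allele optional named character vector, the opposite allele.
#' @return A list of class `genotype_matrix` with elements `dosage`,
#'   `counted_allele`, `other_allele`.
#' @export
genotype_matrix <- function(dosage, counted_allele = NULL, other_allele = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind_", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have variant ids as colnames")
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("individual and variant ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; found range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  for (nm in c("counted_allele", "other_allele")) {
    al <- get(nm)
    if (!is.null(al)) {
      if (is.null(names(al)) || !all(colnames(dosage) %in% names(al)))
        stop(nm, " must be named by every variant id in the dosage matrix")
      assign(nm, toupper(al[colnames(dosage)]))
    }
  }
  structure(list(dosage = dosage,
                 counted_allele = counted_allele,
                 other_allele = other_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants;",
      if (is.null(x$counted_allele)) "no allele annotation"
      else "allele-annotated", "\n")
  invisible(x)
}

#' Compute the polygenic hazard score
#'
#' PHS is the weighted sum of effect-allele dosages,
#' `phs_j = sum_i dosage_ji * weight_i`. Dosage columns must already count
#' the weight table's effect allele (see [harmonize_alleles()]).
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights a [snp_weight_table()]; every `snp_id` must be present as
#'   a column of `genotypes`.
#' @param missing_policy how to handle missing dosages: `"mean_impute"`
#'   (default) replaces a missing value by twice the effect-allele frequency
#'   estimated from the non-missing values of the same column, `"zero"`
#'   replaces it by 0, `"error"` fails on any missing value.
#' @return named numeric vector of scores, one per individual.
#' @export
compute_phs <- function(genotypes, weights,
                        missing_policy = c("mean_impute", "zero", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_snp_weight_table(weights)
  absent <- setdiff(weights$snp_id, colnames(genotypes$dosage))
  if (length(absent))
    stop("weight-table SNPs missing from genotypes: ",
         paste(absent, collapse = ", "))
  X <- genotypes$dosage[, weights$snp_id, drop = FALSE]
  if (anyNA(X)) {
    if (missing_policy == "error")
      stop("missing dosages present and missing_policy = 'error'")
    if (missing_policy == "zero") {
      X[is.na(X)] <- 0
    } else {
      fill <- colMeans(X, na.rm = TRUE)  # = 2 * effect-allele frequency
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- fill[idx[, 2]]
    }
  }
  drop(X %*% weights$weight)
}

#' Orient genotype dosages to a weight table's effect alleles
#'
#' Where a genotype column counts the weight table's `other_allele`, the
#' dosage is flipped to `2 - d` so that every column counts the effect
#' allele. Strand-ambiguous variants (A/T or C/G allele pairs) cannot be
#' oriented reliably from unphased dosage data and are rejected by default.
#'
#' @param genotypes a [genotype_matrix()] with allele annotations.
#' @param weights a [snp_weight_table()].
#' @param ambiguous `"error"` (default) to reject strand-ambiguous variants,
#'   `"keep"` to orient them by literal allele match.
#' @return a `genotype_matrix` whose columns named in `weights` count the
#'   effect allele.
#' @export
harmonize_alleles <- function(genotypes, weights,
                              ambiguous = c("error", "keep")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  validate_snp_weight_table(weights)
  if (is.null(genotypes$counted_allele) || is.null(genotypes$other_allele))
    stop("genotypes carry no allele annotation; cannot harmonize")
  shared <- intersect(weights$snp_id, colnames(genotypes$dosage))
  w <- weights[match(shared, weights$snp_id), ]
  ca <- genotypes$counted_allele[shared]
  oa <- genotypes$other_allele[shared]
  amb <- (w$effect_allele == comp_base(w$other_allele))
  if (any(amb) && ambiguous == "error")
    stop("strand-ambiguous variants (A/T or C/G): ",
         paste(shared[amb], collapse = ", "))
  same <- ca == w$effect_allele & oa == w$other_allele
  flip <- ca == w$other_allele & oa == w$effect_allele
  bad <- !(same | flip)
  if (any(bad))
    stop("allele pair mismatches weight table for: ",
         paste(shared[bad], collapse = ", "))
  out <- genotypes
  if (any(flip)) {
    cols <- shared[flip]
    out$dosage[, cols] <- 2 - out$dosage[, cols]
    out$counted_allele[cols] <- w$effect_allele[flip]
    out$other_allele[cols] <- w$other_allele[flip]
  }
  out
}

comp_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Linkage disequilibrium between two dosage columns
#'
#' Returns r-squared, the squared Pearson correlation of the two dosage
#' vectors over pairwise-complete individuals. This genotype-level LD is
#' computable from unphased data and coincides with haplotype r-squared
#' under Hardy-Weinberg and random mating.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
compute_ld <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined: zero variance over pairwise-complete individuals")
  stats::cor(a, b)^2
}

#' Find LD proxies for score SNPs absent from a genotyping platform
#'
#' Targets directly genotyped on the platform map to themselves with
#' `ld_r2 = 1`. For each remaining target, LD with every platform variant
#' is estimated in the reference panel; the candidate with the largest
#' r-squared is selected if it reaches `min_r2`, otherwise the target is
#' left unmapped (`proxy_snp = NA`). Ties are broken by larger r-squared,
#' then lexicographic candidate id, so the map is reproducible.
#'
#' @param targets a [snp_weight_table()] of score SNPs to place.
#' @param platform a [genotype_matrix()] for the destination platform (its
#'   column set defines which variants are available).
#' @param reference a [genotype_matrix()] containing both target and
#'   platform variants, used to estimate LD.
#' @param min_r2 minimum r-squared for an acceptable proxy (default 0.94).
#' @return `data.frame` with columns `target_snp`, `proxy_snp`, `ld_r2`;
#'   one row per target.
#' @export
find_proxies <- function(targets, platform, reference, min_r2 = 0.94) {
  validate_snp_weight_table(targets)
  stopifnot(inherits(platform, "genotype_matrix"),
            inherits(reference, "genotype_matrix"),
            min_r2 >= 0, min_r2 <= 1)
  plat_snps <- colnames(platform$dosage)
  ref <- reference$dosage
  out <- data.frame(target_snp = targets$snp_id,
                    proxy_snp = NA_character_,
                    ld_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  on_platform <- targets$snp_id %in% plat_snps
  out$proxy_snp[on_platform] <- targets$snp_id[on_platform]
  out$ld_r2[on_platform] <- 1
  candidates <- sort(intersect(plat_snps, colnames(ref)))
  for (i in which(!on_platform)) {
    tgt <- targets$snp_id[i]
    if (!tgt %in% colnames(ref)) {
      warning("target ", tgt, " absent from reference panel; left unmapped")
      next
    }
    cand <- setdiff(candidates, tgt)
    if (!length(cand)) next
    r2 <- vapply(cand, function(s) {
      tryCatch(compute_ld(ref[, tgt], ref[, s]), error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(r2))) next
    best <- which(r2 == max(r2, na.rm = TRUE))[1]  # cand sorted: lexicographic tie-break
    if (!is.na(r2[best]) && r2[best] >= min_r2) {
      out$proxy_snp[i] <- cand[best]
      out$ld_r2[i] <- r2[best]
    }
  }
  out
}

#' Re-estimate SNP weights by a joint weighted Cox fit
#'
#' Fits one multivariable weighted Cox proportional hazards model of age at
#' diagnosis on all SNP dosage columns simultaneously; the coefficient
#' vector becomes the new weight table. Used after proxy substitution so
#' that weights reflect the adapted variant panel.
#'
#' @param genotypes a [genotype_matrix()] of the adapted panel, oriented to
#'   the counted alleles the new weights will refer to.
#' @param training a `data.frame` with columns `time` (age), `event` (0/1)
#'   and optionally `sample_weight`; rows align with `genotypes` rows.
#' @param effect_allele,other_allele optional named allele vectors for the
#'   output table; taken from `genotypes` annotations when present,
#'   otherwise filled with placeholder A/G.
#' @param ties tie-handling method passed to the Cox engine.
#' @return a [snp_weight_table()] with the refitted weights.
#' @export
adapt_weights <- function(genotypes, training,
                          effect_allele = NULL, other_allele = NULL,
                          ties = "efron") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosage
  stopifnot(nrow(X) == nrow(training))
  dat <- cbind(training[, intersect(c("time", "event", "sample_weight"),
                                    names(training)), drop = FALSE],
               as.data.frame(X))
  fit <- fit_weighted_cox(dat, covariates = colnames(X), ties = ties)
  if (!fit$converged)
    stop("weight re-estimation did not converge after ", fit$iter,
         " iterations")
  ea <- effect_allele %||% genotypes$counted_allele %||%
    stats::setNames(rep("A", ncol(X)), colnames(X))
  oa <- other_allele %||% genotypes$other_allele %||%
    stats::setNames(rep("G", ncol(X)), colnames(X))
  snp_weight_table(colnames(X), ea[colnames(X)], oa[colnames(X)],
                   fit$coefficients[colnames(X)])
}

#' Adapt a polygenic hazard score to a new genotyping platform
#'
#' Runs the full platform-adaptation procedure: map every score SNP to the
#' destination platform ([find_proxies()]), restrict to mapped variants,
#' and re-estimate all weights jointly on a training cohort
#' ([adapt_weights()]).
#'
#' @inheritParams find_proxies
#' @param training_genotypes a [genotype_matrix()] of platform variants for
#'   the training cohort.
#' @param training a survival `data.frame` (`time`, `event`, optional
#'   `sample_weight`) aligned with `training_genotypes`.
#' @return list with `weights` (the adapted [snp_weight_table()]),
#'   `proxy_map` (the [find_proxies()] table) and `n_mapped`.
#' @export
adapt_score <- function(targets, platform, reference,
                        training_genotypes, training, min_r2 = 0.94) {
  pm <- find_proxies(targets, platform, reference, min_r2 = min_r2)
  mapped <- pm[!is.na(pm$proxy_snp), ]
  if (!nrow(mapped)) stop("no score SNP could be placed on the platform")
  sub <- training_genotypes
  sub$dosage <- sub$dosage[, mapped$proxy_snp, drop = FALSE]
  if (!is.null(sub$counted_allele))
    sub$counted_allele <- sub$counted_allele[mapped$proxy_snp]
  if (!is.null(sub$other_allele))
    sub$other_allele <- sub$other_allele[mapped$proxy_snp]
  w <- adapt_weights(sub, training)
  list(weights = w, proxy_map = pm, n_mapped = nrow(mapped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
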