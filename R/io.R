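#' Read / write a SNP weight table (tab-separated)
#'
#' Columns: `snp_id`, `effect_allele`, `other_allele`, `weight`, with
#' header.
#'
#' @param path file path.
#' @return a [snp_weight_table()].
#' @export
read_weight_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  snp_weight_table(tab$snp_id, tab$effect_allele, tab$other_allele,
                   tab$weight)
}

#' @rdname read_weight_table
#' @param weights a [snp_weight_table()].
#' @export
write_weight_table <- function(weights, path) {
  validate_snp_weight_table(weights)
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a rectangular dosage table (tab-separated)
#'
#' Individuals as rows (first column `individual_id`), variants as the
#' remaining columns. Allele annotations, if any, are supplied separately
#' via [genotype_matrix()].
#'
#' @param path file path.
#' @param counted_allele,other_allele optional named allele vectors passed
#'   to [genotype_matrix()].
#' @return a [genotype_matrix()].
#' @export
read_dosage_table <- function(path, counted_allele = NULL,
                              other_allele = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  genotype_matrix(m, counted_allele = counted_allele,
                  other_allele = other_allele)
}

#' @rdname read_dosage_table
#' @param genotypes a [genotype_matrix()].
#' @export
write_dosage_table <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  df <- data.frame(individual_id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Uses the `DS` FORMAT field when present, otherwise counts ALT alleles in
#' `GT`. The returned dosages count the ALT allele; REF/ALT become the
#' counted/other allele annotations for [harmonize_alleles()].
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix()] (individuals x variants).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  fmt <- v@gt[1, "FORMAT"]
  if (grepl("\\bDS\\b", fmt)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  m <- t(ds)  # individuals x variants
  colnames(m) <- ids
  genotype_matrix(m,
                  counted_allele = stats::setNames(toupper(alt), ids),
                  other_allele = stats::setNames(toupper(ref), ids))
}

#' Read / write a phenotype table (CSV)
#'
#' @param path file path.
#' @return `data.frame` phenotype table.
#' @export
read_phenotype_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_phenotype_table
#' @param phenotypes phenotype `data.frame`.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Read a population incidence curve (two-column CSV: age, cum_incidence)
#'
#' @param path file path.
#' @return an [incidence_curve()].
#' @export
read_incidence_curve <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  incidence_curve(tab[[1]], tab[[2]])
}

#' Read an admixture-proportion matrix (whitespace-delimited, one row per
#' individual, K columns), the common layout of admixture-inference output
#'
#' @param path file path.
#' @param components optional component names for the columns.
#' @return numeric matrix of proportions.
#' @export
read_admixture_matrix <- function(path, components = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.null(components)) {
    stopifnot(length(components) == ncol(m))
    colnames(m) <- components
  } else colnames(m) <- paste0("cluster", seq_len(ncol(m)))
  check_simplex(m)
  m
}

#' Write a proxy map (tab-separated: target_snp, proxy_snp, ld_r2)
#'
#' @param proxy_map output of [find_proxies()].
#' @param path file path.
#' @export
write_proxy_map <- function(proxy_map, path) {
  utils::write.table(proxy_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a Cox fit to JSON
#'
#' @param fit a `phs_coxfit`.
#' @param path file path.
#' @export
write_coxfit_json <- function(fit, path) {
  stopifnot(inherits(fit, "phs_coxfit"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), z = as.list(fit$z),
         log10_p = as.list(fit$log10_p),
         loglik = fit$loglik, loglik_null = fit$loglik_null,
         n = fit$n, n_events = fit$n_events, ties = fit$ties),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
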