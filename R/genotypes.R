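#' Genotype matrix with population labels
#'
#' Container for a cohort of diploid individuals typed at biallelic SNPs.
#' Calls count copies of a designated counted allele per SNP (0, 1, 2 or
#' `NA` for missing); missingness is a distinct state, never conflated
#' with the zero genotype.
#'
#' @param calls Integer matrix, individuals in rows (rownames are
#'   individual ids), SNPs in columns (colnames are SNP ids). Values in
#'   `{0, 1, 2, NA}`.
#' @param population Named character vector mapping every individual to
#'   exactly one population label.
#' @param counted_allele Named character vector mapping every SNP to the
#'   allele whose copies `calls` counts. Defaults to `"A"` for all SNPs.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, population, counted_allele = NULL) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` needs individual rownames and SNP colnames")
  }
  if (anyDuplicated(colnames(calls))) abort("duplicate SNP ids")
  if (anyDuplicated(rownames(calls))) {
    abort(paste0("duplicate individual id: ",
                 rownames(calls)[duplicated(rownames(calls))][1]))
  }
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or NA")
  miss <- setdiff(rownames(calls), names(population))
  if (length(miss) > 0) {
    abort(paste0("no population label for individual(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  population <- population[rownames(calls)]
  if (is.null(counted_allele)) {
    counted_allele <- setNames(rep("A", ncol(calls)), colnames(calls))
  }
  structure(
    list(calls = calls, population = population,
         counted_allele = counted_allele[colnames(calls)]),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d populations, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$population)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Pooled frequency of the counted allele per SNP
#'
#' Sample allele frequency over all called genotypes in the whole cohort
#' (the "global" frequency in a worldwide cohort).
#'
#' @param genotypes A [genotype_matrix()].
#' @return Named numeric vector, one frequency per SNP.
#' @export
pooled_frequency <- function(genotypes) {
  colMeans(genotypes$calls, na.rm = TRUE) / 2
}

#' @describeIn genotype_matrix Long-format view: one row per individual/SNP
#'   call, with columns `individual`, `population`, `snp_id`, `call`.
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$calls), times = ncol(x$calls)),
    population = rep(unname(x$population), times = ncol(x$calls)),
    snp_id = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.integer(x$calls)
  )
}
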