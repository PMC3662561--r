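# Readers and writers for the file formats the pipeline consumes and emits:
# genotype tables (TSV and PLINK .ped/.map text), Newick population trees,
# association and annotation tables, and branch-result TSVs with a
# machine-readable run summary.

#' Read a genotype matrix
#'
#' Two text dialects are supported. `"tsv"` is a rectangular table with
#' columns `individual`, `population`, then one column per SNP holding
#' risk/counted-allele copy counts (0/1/2, `NA` for missing); optional
#' leading comment lines `#counted_allele<TAB><snp><TAB><allele>` record
#' which allele is counted. `"plink-text"` is a `.ped`/`.map` pair; the
#' counted allele is the file-wide minor allele of each SNP (ties broken
#' alphabetically) and `0` alleles are missing.
#'
#' @param path For `"tsv"`, the file; for `"plink-text"`, the `.ped` file
#'   or the common prefix of the pair.
#' @param dialect `"tsv"` or `"plink-text"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink-text")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    "tsv" = read_genotypes_tsv(path),
    "plink-text" = read_genotypes_ped(path)
  )
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  if (length(body) < 2) abort("no individuals in genotype file")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "individual" || header[2] != "population") {
    abort("genotype TSV must start with columns `individual`, `population`")
  }
  snp_ids <- header[-(1:2)]
  n_unknown <- 0L
  rows <- lapply(seq_along(body[-1]), function(i) {
    fields <- strsplit(body[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      abort(sprintf("malformed genotype row at line %d: %d fields, expected %d",
                    i + 1L, length(fields), length(header)))
    }
    fields
  })
  ids <- vapply(rows, `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) abort(paste0("duplicate individual id: ", dup[1]))
  pops <- vapply(rows, `[`, character(1), 2)
  raw <- vapply(rows, function(f) f[-(1:2)], character(length(snp_ids)))
  raw <- matrix(raw, nrow = length(snp_ids))          # SNPs x individuals
  known <- raw %in% c("0", "1", "2", "NA", "")
  n_unknown <- sum(!known)
  raw[!known] <- NA
  calls <- suppressWarnings(matrix(as.integer(raw), nrow = length(snp_ids)))
  calls <- t(calls)
  dimnames(calls) <- list(ids, snp_ids)
  if (n_unknown > 0) {
    inform(sprintf("read_genotypes: %d unrecognised genotype symbols set to missing",
                   n_unknown))
  }
  counted <- setNames(rep("A", length(snp_ids)), snp_ids)
  for (m in meta) {
    f <- strsplit(sub("^#", "", m), "\t", fixed = TRUE)[[1]]
    if (length(f) == 3 && f[1] == "counted_allele" && f[2] %in% snp_ids) {
      counted[f[2]] <- f[3]
    }
  }
  genotype_matrix(calls, setNames(pops, ids), counted)
}

read_genotypes_ped <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) abort(paste0("file not found: ", ped_path))
  if (!file.exists(map_path)) abort(paste0("file not found: ", map_path))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 2) abort("malformed .map: expected >= 2 columns")
  snp_ids <- map[[2]]
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("no individuals in .ped file")
  n_expect <- 6 + 2 * length(snp_ids)
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != n_expect) {
      abort(sprintf("malformed .ped row at line %d: %d fields, expected %d",
                    i, length(f), n_expect))
    }
    f
  })
  ids <- vapply(parsed, `[`, character(1), 2)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) abort(paste0("duplicate individual id: ", dup[1]))
  pops <- vapply(parsed, `[`, character(1), 1)
  a1 <- t(vapply(parsed, function(f) f[seq(7, n_expect, by = 2)],
                 character(length(snp_ids))))
  a2 <- t(vapply(parsed, function(f) f[seq(8, n_expect, by = 2)],
                 character(length(snp_ids))))
  if (length(snp_ids) == 1) { a1 <- t(a1); a2 <- t(a2) }
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = length(snp_ids),
                  dimnames = list(ids, snp_ids))
  counted <- setNames(character(length(snp_ids)), snp_ids)
  for (j in seq_along(snp_ids)) {
    alleles <- c(a1[, j], a2[, j])
    alleles <- alleles[alleles != "0"]
    if (length(alleles) == 0) {
      counted[j] <- "A"
      next
    }
    tab <- sort(table(alleles))
    # counted allele = minor allele (alphabetical on ties)
    minors <- names(tab)[tab == tab[1]]
    counted[j] <- sort(minors)[1]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    calls[ok, j] <- (a1[ok, j] == counted[j]) + (a2[ok, j] == counted[j])
  }
  genotype_matrix(calls, setNames(pops, ids), counted)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of `read_genotypes(dialect = "tsv")`, including the
#' `#counted_allele` header comments.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  meta <- sprintf("#counted_allele\t%s\t%s",
                  names(genotypes$counted_allele), genotypes$counted_allele)
  header <- paste(c("individual", "population", colnames(genotypes$calls)),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(genotypes$calls)), function(i) {
    paste(c(rownames(genotypes$calls)[i], genotypes$population[i],
            ifelse(is.na(genotypes$calls[i, ]), "NA", genotypes$calls[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Read a rooted population phylogeny
#'
#' Reads a Newick tree and checks it is usable as a population tree:
#' rooted, unique leaf names, and (when `populations` is supplied) leaves
#' matching the cohort's population labels one to one.
#'
#' @param path Newick file.
#' @param populations Optional character vector of population labels the
#'   leaves must cover.
#' @param resolve_root If `TRUE`, a multifurcating root is resolved
#'   arbitrarily (via [ape::multi2di()]); otherwise it is an error.
#' @return An [ape::phylo] object.
#' @export
read_population_tree <- function(path, populations = NULL, resolve_root = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick in ", path))
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf names in tree")
  if (!ape::is.rooted(tree)) {
    if (resolve_root) {
      tree <- ape::multi2di(tree)
    } else {
      abort("tree is unrooted (or multifurcating at the root); set `resolve_root = TRUE` to resolve arbitrarily")
    }
  }
  if (!is.null(populations)) {
    extra <- setdiff(tree$tip.label, populations)
    if (length(extra) > 0) {
      abort(paste0("tree leaves absent from genotype populations: ",
                   paste(extra, collapse = ", ")))
    }
  }
  tree
}

#' Read an association table
#'
#' One row per (SNP, disease, study). Effect sizes come either as direct
#' per-genotype likelihood ratios (`lr_hom_risk`, `lr_het`,
#' `lr_hom_protective`) or as case/control genotype probabilities
#' (`case_*` / `control_*` triplets); [combine_likelihood_ratios()]
#' accepts both.
#'
#' @param path TSV file with columns `snp_id`, `disease`,
#'   `study_population`, `sample_size`, `p_value`, `risk_allele` and the
#'   effect-size columns described above.
#' @return A tibble.
#' @export
read_associations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp_id", "disease", "study_population", "sample_size", "p_value",
            "risk_allele")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("association table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(x$sample_size < 1)) abort("sample_size must be >= 1")
  if (any(x$p_value <= 0 | x$p_value > 1)) abort("p_value must be in (0, 1]")
  x
}

#' Read a genome-wide SNP annotation table
#'
#' Defines the resampling pool: for every genotyped SNP, its global minor
#' allele frequency, functional category (one of the eight matched
#' categories) and whether it has been reported associated with any
#' phenotype.
#'
#' @param path TSV with columns `snp_id`, `global_maf`,
#'   `functional_category`, `phenotype_associated`.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp_id", "global_maf", "functional_category", "phenotype_associated")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("annotation table missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(x$functional_category), functional_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown functional category: ", paste(bad, collapse = ", ")))
  }
  if (any(x$global_maf < 0 | x$global_maf > 0.5)) {
    abort("global_maf must be in [0, 0.5]")
  }
  x$phenotype_associated <- as.logical(x$phenotype_associated)
  x
}

#' Write branch results and a run summary
#'
#' Writes one TSV row per tested unit (branch or population) and a JSON
#' run summary carrying everything needed to reproduce the run: seed,
#' number of draws K, matching configuration and the panel SNP ids.
#' Reruns with the same seed and configuration produce byte-identical
#' files.
#'
#' @param test A result of [test_differentiation()] or
#'   [population_vs_rest()].
#' @param path Output TSV path; the summary goes to
#'   `<path without extension>_summary.json`.
#' @param events Optional [infer_events()] result to record in the
#'   summary.
#' @return `path`, invisibly.
#' @export
write_results <- function(test, path, events = NULL) {
  res <- tidy(test)
  # 17 significant digits round-trip IEEE doubles exactly
  res <- dplyr::mutate(res, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  readr::write_tsv(res, path, progress = FALSE)
  summary <- list(
    seed = test$seed,
    K = test$K,
    mode = test$mode,
    alternative = test$alternative,
    maf_bin = test$maf_bin,
    panel_snps = test$panel$snp_id,
    disease = attr(test$panel, "disease")
  )
  if (!is.null(events)) {
    summary$events <- list(
      chosen_n = events$chosen_n,
      event_branches = events$models$events[[max(1L, events$chosen_n)]],
      alpha = events$alpha
    )
  }
  jsonlite::write_json(summary, summary_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

summary_path <- function(path) {
  sub("\\.[^.]+$", "", path) |> paste0("_summary.json")
}

#' Read back a results TSV and its run summary
#'
#' @param path Path given to [write_results()].
#' @return A list with elements `results` (tibble) and `summary` (list).
#' @export
read_results <- function(path) {
  # read as character and convert with base R's correctly-rounded parser,
  # so stored doubles round-trip bit-exactly
  results <- readr::read_tsv(path, progress = FALSE,
                             col_types = readr::cols(.default = "c"))
  results <- tibble::as_tibble(
    utils::type.convert(as.data.frame(results), as.is = TRUE)
  )
  sp <- summary_path(path)
  summary <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
  list(results = results, summary = summary)
}
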