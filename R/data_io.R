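# Readers and writers for the delimited tables the pipeline touches.
# Delimiter: tab by default; a comma-delimited file is auto-detected from its
# header line. Missing markers "NA", "" and "." are accepted everywhere.

detect_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

read_table_auto <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_delim(path, delim = detect_delim(path),
                    na = c("NA", "", "."), comment = "#",
                    show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a per-individual cohort table
#'
#' Reads a delimited phenotype/covariate table (id, raw phenotype, sex, and
#' arbitrary covariate columns such as age, centre and principal components).
#' Unparseable phenotype cells become missing values and are counted; a
#' missing mandatory column or a duplicated id is a hard error.
#'
#' @param path Delimited text file with a header (tab default, comma
#'   auto-detected).
#' @param id_col,phenotype_col,sex_col Column names in the file for the
#'   individual identifier, the raw phenotype, and sex (set `sex_col = NULL`
#'   if absent).
#' @param covariate_cols Character vector of covariate column names to carry
#'   along; default: every remaining column.
#' @return A tibble of class `cohort` with columns `id`, `phenotype`, `sex`
#'   (factor male/female/unknown) and the covariates; attribute
#'   `n_missing_phenotype`.
#' @export
read_cohort <- function(path, id_col = "id", phenotype_col = "phenotype",
                        sex_col = "sex", covariate_cols = NULL) {
  raw <- read_table_auto(path, col_types = readr::cols(.default = readr::col_guess()))
  for (col in c(id_col, phenotype_col, sex_col)) {
    if (!is.null(col) && !col %in% names(raw)) {
      abort(paste0("Mandatory column `", col, "` not found in ", path))
    }
  }
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids) > 0) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicated id(s) in cohort: ",
                 paste(head(dups, 5), collapse = ", ")))
  }
  pheno <- suppressWarnings(as.numeric(raw[[phenotype_col]]))
  if (any(is.infinite(pheno))) abort("Phenotype contains infinite values.")
  n_missing <- sum(is.na(pheno) & !is.na(raw[[phenotype_col]])) + sum(is.na(raw[[phenotype_col]]))
  if (n_missing > 0) {
    inform(sprintf("%d phenotype value(s) missing or unparseable.", n_missing))
  }
  sex <- if (is.null(sex_col)) {
    factor(rep("unknown", length(ids)), levels = c("male", "female", "unknown"))
  } else {
    sx <- tolower(as.character(raw[[sex_col]]))
    sx[sx %in% c("m", "male", "1")] <- "male"
    sx[sx %in% c("f", "female", "2")] <- "female"
    sx[!sx %in% c("male", "female")] <- "unknown"
    factor(sx, levels = c("male", "female", "unknown"))
  }
  covariate_cols <- covariate_cols %||%
    setdiff(names(raw), c(id_col, phenotype_col, sex_col))
  miss <- setdiff(covariate_cols, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Covariate column(s) not found: ", paste(miss, collapse = ", ")))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(id = ids, phenotype = pheno, sex = sex),
    raw[covariate_cols]
  )
  attr(out, "n_missing_phenotype") <- n_missing
  class(out) <- c("cohort", class(out))
  out
}

#' Read a variant-weights table
#'
#' Reads GWAS summary-statistic style per-variant weights: variant id, effect
#' allele, other allele, per-effect-allele effect size.
#'
#' @param path Delimited text file.
#' @param id_col,effect_col,other_col,beta_col Column names in the file.
#' @return Tibble with `variant_id`, `effect_allele`, `other_allele`, `beta`.
#' @export
read_weights <- function(path, id_col = "variant_id",
                         effect_col = "effect_allele",
                         other_col = "other_allele", beta_col = "beta") {
  raw <- read_table_auto(path)
  for (col in c(id_col, effect_col, other_col, beta_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("Mandatory column `", col, "` not found in ", path))
    }
  }
  out <- tibble::tibble(
    variant_id = as.character(raw[[id_col]]),
    effect_allele = toupper(as.character(raw[[effect_col]])),
    other_allele = toupper(as.character(raw[[other_col]])),
    beta = as.numeric(raw[[beta_col]])
  )
  if (anyDuplicated(out$variant_id) > 0) {
    abort("Duplicated variant_id in weights table.")
  }
  if (any(out$effect_allele == out$other_allele)) {
    abort("effect_allele must differ from other_allele.")
  }
  if (any(!is.finite(out$beta))) abort("Non-finite beta in weights table.")
  out
}

#' Read a genotype dosage matrix
#'
#' Reads an individuals x variants dosage matrix either from delimited text
#' (first column = individual id, remaining columns = variants, entries in
#' `[0, 2]` or missing) or from a VCF with per-sample dosages (`DS` format
#' field preferred; hard `GT` genotypes converted to 0/1/2 as a fallback).
#' Multi-allelic VCF records are rejected. The allele counted by each dosage
#' column is recorded so scoring can reconcile allele orientation.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param effect_alleles For `format = "tsv"`: named character vector giving
#'   the counted allele per variant (names = variant ids). Optional; unnamed
#'   dosages then reconcile by variant id only, assuming the weights'
#'   effect-allele orientation.
#' @return A list of class `genotype_matrix`: `dosages` (numeric matrix with
#'   id rownames and variant colnames) and `effect_allele` (named vector).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           effect_alleles = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- read_table_auto(path)
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids) > 0) abort("Duplicated individual ids in genotype file.")
    mat <- as.matrix(raw[-1])
    storage.mode(mat) <- "double"
    rownames(mat) <- ids
    if (anyDuplicated(colnames(mat)) > 0) abort("Duplicated variant ids in genotype file.")
    rng <- range(mat, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) abort("Dosages must lie in [0, 2].")
    eff <- effect_alleles %||% setNames(rep(NA_character_, ncol(mat)), colnames(mat))
    out <- list(dosages = mat, effect_allele = eff[colnames(mat)])
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))
    alt <- fix[, "ALT"]
    if (any(grepl(",", alt))) {
      abort("Multi-allelic VCF records are not supported; split or filter them first.")
    }
    vids <- fix[, "ID"]
    no_id <- is.na(vids) | vids == "."
    vids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
    if (anyDuplicated(vids) > 0) abort("Duplicated variant ids in VCF.")
    fmt_fields <- unique(unlist(strsplit(fix_format <- vcf@gt[, "FORMAT"], ":")))
    if ("DS" %in% fmt_fields) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- matrix(count_alt_alleles(gt), nrow = nrow(gt), dimnames = dimnames(gt))
    }
    mat <- t(ds)  # individuals x variants
    colnames(mat) <- vids
    rng <- range(mat, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
      abort("VCF dosages must lie in [0, 2].")
    }
    out <- list(dosages = mat, effect_allele = setNames(alt, vids))
  }
  structure(out, class = "genotype_matrix")
}

# "0/1", "1|1", "./." -> alt-allele counts 1, 2, NA
count_alt_alleles <- function(gt) {
  vapply(as.vector(gt), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a variant annotation table
#'
#' Per-variant gene symbol, consequence class and minor-allele frequency,
#' used to define rare loss-of-function carrier sets.
#'
#' @param path Delimited text file with columns `variant_id`, `gene`,
#'   `consequence`, `maf`.
#' @return Tibble with those columns; `maf` validated to `[0, 0.5]`.
#' @export
read_annotations <- function(path) {
  raw <- read_table_auto(path)
  need <- c("variant_id", "gene", "consequence", "maf")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Mandatory column(s) missing: ", paste(miss, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[need])
  out$maf <- as.numeric(out$maf)
  if (any(out$maf < 0 | out$maf > 0.5, na.rm = TRUE)) {
    abort("`maf` must lie in [0, 0.5].")
  }
  out
}

#' Write / read classification results
#'
#' Classification tables round-trip losslessly (labels exact, numeric columns
#' to full double precision) through tab-delimited text. A manifest of the
#' thresholds applied is written as `#`-prefixed header comments.
#'
#' @param results A `pgs_classification` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(results, path) {
  spec <- attr(results, "threshold_spec")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec)) {
    writeLines(paste0("# threshold_spec: ",
                      gsub("\n", " ", yaml::as.yaml(spec))), con)
  }
  out <- dplyr::mutate(results, label = as.character(.data$label))
  writeLines(paste(names(out), collapse = "\t"), con)
  # numeric columns at full double precision so the round-trip is lossless
  cols <- lapply(out, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  out <- readr::read_tsv(path, comment = "#", na = "NA",
                         show_col_types = FALSE, progress = FALSE)
  out$label <- factor(out$label,
                      levels = c("lower", "concordant", "higher",
                                 "indeterminate"))
  class(out) <- c("pgs_classification", class(out))
  out
}

#' Write any result tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_result <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
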