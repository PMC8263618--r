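## On-disk formats: phenotype/feature TSVs, VCF 4.2 with per-sample DS
## dosages and an INFO R2 imputation-quality key, and a plain dosage-TSV
## dialect (subjects as rows, SNPs as columns). Reading VCF goes through
## vcfR; validation (class labels, dosage bounds) is done here so parse
## errors name the offending record.

.num_fmt <- "%.10g"  # round-trips doubles on [0,2] and MFI scales to < 1e-9

#' Write / read a cohort as TSV files
#'
#' `write_cohort()` writes `phenotypes.tsv` (`subject_id vte_class age
#' sex`), `features.tsv` (subject_id plus one named column per feature)
#' and, when generator metadata is present, `meta.json`. `read_cohort()`
#' rebuilds the `pe_cohort`; numeric round-trip error is below 1e-9.
#'
#' @param cohort a `pe_cohort`.
#' @param dir directory to write into (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `pe_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pe_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$subjects, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fmt <- matrix(sprintf("%.17g", cohort$features), nrow(cohort$features),
                dimnames = dimnames(cohort$features))
  feat <- data.frame(subject_id = rownames(cohort$features), fmt,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(feat, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$meta)) {
    meta <- cohort$meta
    meta$spec <- unclass(meta$spec)
    meta$interaction_pairs <- as.data.frame(meta$interaction_pairs)
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pheno_path <- file.path(dir, "phenotypes.tsv")
  feat_path <- file.path(dir, "features.tsv")
  if (!file.exists(pheno_path) || !file.exists(feat_path))
    stop("cohort directory must contain phenotypes.tsv and features.tsv",
         call. = FALSE)
  subjects <- utils::read.table(pheno_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  need <- c("subject_id", "vte_class", "age", "sex")
  if (!identical(names(subjects)[1:4], need))
    stop("malformed phenotype header: expected '",
         paste(need, collapse = " "), "'", call. = FALSE)
  bad <- which(!subjects$vte_class %in% c("DVT", "PE", "DVT_PE"))
  if (length(bad))
    stop(sprintf("unknown vte_class '%s' at %s line %d",
                 subjects$vte_class[bad[1]], pheno_path, bad[1] + 1L),
         call. = FALSE)
  feat <- utils::read.table(feat_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  features <- as.matrix(feat[, -1, drop = FALSE])
  rownames(features) <- feat$subject_id
  if (!identical(rownames(features), subjects$subject_id))
    stop("feature and phenotype tables disagree on subject ids",
         call. = FALSE)
  if (anyNA(features))
    stop("missing feature values in ", feat_path, call. = FALSE)
  meta <- NULL
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta$interaction_pairs <- as.matrix(meta$interaction_pairs)
    if (!is.null(meta$spec)) meta$spec <- do.call(cohort_spec, meta$spec)
  }
  structure(list(subjects = subjects, features = features, meta = meta),
            class = "pe_cohort")
}

#' Write / read genotype dosages
#'
#' The VCF dialect is VCF 4.2 with one sample column per subject, a `DS`
#' FORMAT field carrying the effect-allele dosage and an `R2` INFO key
#' carrying imputation quality; ALT is the effect allele. The TSV dialect
#' stores the dosage matrix (subjects as rows, SNP ids as the header) plus
#' a `<stem>.snps.tsv` sidecar with the per-SNP metadata.
#'
#' @param geno a `genotype_data`.
#' @param path output file (`.vcf` or `.tsv`; `format` is inferred from
#'   the extension when `NULL`).
#' @param format `"vcf"` or `"tsv"`.
#' @return `write_genotypes()` the path, invisibly; `read_genotypes()` a
#'   `genotype_data`.
#' @export
write_genotypes <- function(geno, path, format = NULL) {
  stopifnot(inherits(geno, "genotype_data"))
  format <- format %||%
    switch(tolower(tools::file_ext(path)), vcf = "vcf", tsv = "tsv",
           stop("cannot infer genotype format from '", path, "'",
                call. = FALSE))
  if (format == "vcf") {
    info <- geno$info
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality r-squared\">",
      "##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description=\"Generator-designated causal SNP\">",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect (ALT) allele dosage\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", rownames(geno$dosage)), collapse = "\t"))
    body <- vapply(seq_len(nrow(info)), function(j) {
      paste(c(info$chrom[j], info$pos[j], info$snp_id[j], info$ref[j],
              info$alt[j], ".", "PASS",
              paste0("R2=", sprintf("%.4g", info$imput_r2[j]),
                     if (isTRUE(info$causal[j])) ";CAUSAL"),
              "DS", sprintf(.num_fmt, geno$dosage[, j])),
            collapse = "\t")
    }, "")
    writeLines(c(hdr, body), path)
  } else {
    dos <- data.frame(subject_id = rownames(geno$dosage),
                      matrix(sprintf("%.17g", geno$dosage),
                             nrow(geno$dosage),
                             dimnames = dimnames(geno$dosage)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dos, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(geno$info, .snp_sidecar(path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.snp_sidecar <- function(path)
  paste0(tools::file_path_sans_ext(path), ".snps.tsv")

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, format = NULL) {
  format <- format %||%
    switch(tolower(tools::file_ext(path)), vcf = "vcf", tsv = "tsv",
           stop("cannot infer genotype format from '", path, "'",
                call. = FALSE))
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.empty_genotypes <- function(subject_ids = character(0)) {
  structure(list(
    info = data.frame(snp_id = character(0), chrom = integer(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), imput_r2 = numeric(0),
                      causal = logical(0), stringsAsFactors = FALSE),
    dosage = matrix(numeric(0), length(subject_ids), 0,
                    dimnames = list(subject_ids, NULL))),
    class = "genotype_data")
}

.read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF header in ", path, call. = FALSE)
  n_rec <- sum(!startsWith(lines, "#"))
  chrom_line <- grep("^#CHROM", lines, value = TRUE)
  if (!length(chrom_line))
    stop("malformed VCF: missing #CHROM line in ", path, call. = FALSE)
  if (n_rec == 0L) {
    samples <- utils::tail(strsplit(chrom_line[1], "\t")[[1]], -9L)
    return(.empty_genotypes(samples))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- matrix(fix, nrow = n_rec, dimnames = list(NULL, colnames(fix)))
  r2 <- vcfR::extract.info(v, "R2", as.numeric = TRUE)
  causal <- grepl("(^|;)CAUSAL(;|$)", fix[, "INFO"])
  if (nrow(v@gt) > 0 && !all(v@gt[, "FORMAT"] == "DS"))
    stop("expected a DS-only FORMAT field in ", path, call. = FALSE)
  ds <- vcfR::extract.gt(v, "DS")
  dosage <- t(matrix(suppressWarnings(as.numeric(ds)), nrow = n_rec,
                     dimnames = dimnames(ds)))
  bad <- which(is.na(dosage) | dosage < 0 | dosage > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage outside [0,2] (or unparsable) for record '%s', sample '%s' in %s",
                 fix[bad[1, 2], "ID"], rownames(dosage)[bad[1, 1]], path),
         call. = FALSE)
  info <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], imput_r2 = r2,
                     causal = causal, stringsAsFactors = FALSE)
  if (anyNA(info$imput_r2))
    stop("missing R2 INFO value for record '",
         info$snp_id[which(is.na(info$imput_r2))[1]], "' in ", path,
         call. = FALSE)
  colnames(dosage) <- info$snp_id
  structure(list(info = info, dosage = dosage), class = "genotype_data")
}

.read_genotypes_tsv <- function(path) {
  dos <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(dos) && ncol(dos) <= 1L) return(.empty_genotypes())
  if (names(dos)[1] != "subject_id")
    stop("malformed dosage TSV: first column must be 'subject_id' in ",
         path, call. = FALSE)
  dosage <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dosage) <- dos$subject_id
  bad <- which(is.na(dosage) | dosage < 0 | dosage > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage outside [0,2] for SNP '%s' at %s line %d",
                 colnames(dosage)[bad[1, 2]], path, bad[1, 1] + 1L),
         call. = FALSE)
  sidecar <- .snp_sidecar(path)
  if (file.exists(sidecar)) {
    info <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  } else {
    info <- data.frame(snp_id = colnames(dosage), chrom = NA_integer_,
                       pos = NA_integer_, ref = NA_character_,
                       alt = NA_character_, imput_r2 = NA_real_,
                       causal = NA, stringsAsFactors = FALSE)
  }
  if (!identical(info$snp_id, colnames(dosage)))
    stop("SNP sidecar and dosage header disagree for ", path, call. = FALSE)
  structure(list(info = info, dosage = dosage), class = "genotype_data")
}
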