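# Readers/writers: native genotype TSV pair, VCF import, model and report
# serialisation, run configuration.
#
# Native format: a tab-separated genotype file whose header row is
# "snp_id" followed by the subject ids, one row per SNP, cells in
# {1, 2, 3, .} ("." = missing call); and a companion label file with
# header "subject_id<TAB>label", label in {case, control}. Gzip-compressed
# files (.gz) are read and written transparently.

open_in <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read the native genotype + label file pair
#'
#' @param genotype_path tab-separated genotype file (SNPs in rows, subjects
#'   in columns; see package README for the exact layout).
#' @param label_path tab-separated label file (`subject_id`, `label`).
#' @return list with `genotypes` (subjects x SNPs integer matrix, `NA` for
#'   ".") and `labels` (factor aligned to the matrix rows).
#' @export
read_native <- function(genotype_path, label_path) {
  gm <- read_genotypes(genotype_path)
  labels <- read_labels(label_path)
  if (!setequal(names(labels), rownames(gm))) {
    stop("label file subjects do not match genotype file subjects")
  }
  labels <- labels[rownames(gm)]
  list(genotypes = gm, labels = labels)
}

#' @rdname read_native
#' @export
read_genotypes <- function(genotype_path) {
  con <- open_in(genotype_path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1) stop("empty genotype file: ", genotype_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "snp_id") {
    stop("genotype file must start with a 'snp_id' header column")
  }
  subject_ids <- header[-1]
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject id(s) in genotype header: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  n_sub <- length(subject_ids)
  body <- lines[-1]
  snp_ids <- character(length(body))
  gm <- matrix(NA_integer_, n_sub, length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_sub + 1) {
      stop("line ", i + 1, ": expected ", n_sub + 1, " fields, got ",
           length(fields))
    }
    snp_ids[i] <- fields[1]
    cells <- fields[-1]
    bad <- !cells %in% c("1", "2", "3", ".")
    if (any(bad)) {
      j <- which(bad)[1]
      stop("line ", i + 1, ", subject '", subject_ids[j],
           "': invalid genotype cell '", cells[j],
           "' (expected 1, 2, 3 or .)")
    }
    v <- suppressWarnings(as.integer(cells))
    gm[, i] <- v
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP id(s): ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  dimnames(gm) <- list(subject_ids, snp_ids)
  check_genotypes(gm)
  gm
}

#' @rdname read_native
#' @export
read_labels <- function(label_path) {
  con <- open_in(label_path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("label file needs 'subject_id' and 'label' columns")
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject id in label file")
  as_labels(df$label, df$subject_id)
}

#' Write the native genotype + label file pair
#'
#' @param gm subjects x SNPs genotype matrix.
#' @param labels per-subject phenotype (optional; skipped if `NULL`).
#' @param genotype_path,label_path output paths (`.gz` for compression).
#' @return invisibly, the genotype path.
#' @export
write_native <- function(gm, labels = NULL, genotype_path,
                         label_path = NULL) {
  check_genotypes(gm)
  con <- open_out(genotype_path)
  cells <- t(gm)                       # SNPs in rows on disk
  storage <- ifelse(is.na(cells), ".", as.character(cells))
  writeLines(paste(c("snp_id", rownames(gm)), collapse = "\t"), con)
  writeLines(paste(colnames(gm),
                   apply(storage, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  close(con)
  if (!is.null(labels) && !is.null(label_path)) {
    labels <- as_labels(labels, names(labels))
    con2 <- open_out(label_path)
    writeLines(c("subject_id\tlabel",
                 paste(names(labels), as.character(labels), sep = "\t")),
               con2)
    close(con2)
  }
  invisible(genotype_path)
}

#' Import genotypes from a VCF file
#'
#' Biallelic records with a GT field are mapped to the package's additive
#' genotype coding: `0/0 -> 1`, `0/1` or `1/0 -> 2`, `1/1 -> 3`,
#' `./. -> NA`; phased separators (`|`) are treated identically to `/`.
#' Multiallelic records and records containing half-missing calls (e.g.
#' `./1`) are skipped, and the skip count is reported. Note that code 3
#' here means the ALT homozygote regardless of which allele is minor (the
#' simulator, by contrast, orients code 3 to the minor allele); the
#' convention is fixed so that import never depends on estimated allele
#' frequencies.
#'
#' @param vcf_path a VCF (v4.x) file, optionally gzipped.
#' @param label_path optional companion label file (see [read_labels()]).
#' @return list with `genotypes`, `labels` (NULL if no label file) and
#'   `skipped` (count of excluded records).
#' @export
import_vcf <- function(vcf_path, label_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0 || !"FORMAT" %in% colnames(vcf@gt)) {
    stop("VCF has no genotype (GT) data")
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF records lack a GT field")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # drop phasing distinction
  gt_core <- gsub("|", "/", gt, fixed = TRUE)

  alt <- fix[, "ALT"]
  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  code_of <- c("0/0" = 1L, "0/1" = 2L, "1/0" = 2L, "1/1" = 3L)
  codes <- matrix(code_of[gt_core], nrow = nrow(gt_core))
  full_missing <- is.na(gt_core) | gt_core == "./." | gt_core == "."
  half_missing <- !full_missing & is.na(codes)
  codes[full_missing] <- NA_integer_
  drop <- multi | apply(half_missing, 1, any)

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste(fix[no_id, "CHROM"], fix[no_id, "POS"],
                      fix[no_id, "REF"], fix[no_id, "ALT"], sep = ":")
  keep <- !drop
  gm <- t(codes[keep, , drop = FALSE])
  dimnames(gm) <- list(colnames(gt), ids[keep])
  check_genotypes(gm)
  labels <- NULL
  if (!is.null(label_path)) {
    labels <- read_labels(label_path)
    if (!setequal(names(labels), rownames(gm))) {
      stop("label file subjects do not match VCF samples")
    }
    labels <- labels[rownames(gm)]
  }
  list(genotypes = gm, labels = labels, skipped = sum(drop))
}

#' Write a simulated dataset to disk
#'
#' Writes the native genotype/label pair plus a `truth.json` sidecar
#' naming the planted effect, HWE-violating, low-MAF and missing-call
#' SNPs and echoing the configuration.
#'
#' @param dataset a [simulate_genotypes()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_native(dataset$genotypes, dataset$labels,
               file.path(dir, "genotypes.tsv"),
               file.path(dir, "labels.tsv"))
  truth <- dataset$truth
  truth$q_control <- NULL
  truth$q_case <- NULL
  jsonlite::write_json(list(truth = truth,
                            config = unclass(dataset$config)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a QC report as TSV
#'
#' @param qc an [apply_qc()] result.
#' @param path output file.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_result"))
  utils::write.table(qc$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a fitted KNN classifier
#'
#' The model is stored as `model.json` (selected SNP ids, k, labels,
#' training majority class) plus `train.tsv` (the reduced training matrix
#' in the native genotype layout).
#'
#' @param model a [knn_fit()] object.
#' @param dir model directory.
#' @return `save_knn` invisibly returns `dir`; `load_knn` returns the
#'   restored `knn_model`.
#' @export
save_knn <- function(model, dir) {
  stopifnot(inherits(model, "knn_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(snp_ids = model$snp_ids,
                            k = model$k,
                            majority = model$majority,
                            labels = as.character(model$labels),
                            subject_ids = rownames(model$x)),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  write_native(model$x, NULL, file.path(dir, "train.tsv"))
  invisible(dir)
}

#' @rdname save_knn
#' @export
load_knn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  x <- read_genotypes(file.path(dir, "train.tsv"))
  x <- x[meta$subject_ids, meta$snp_ids, drop = FALSE]
  knn_fit(x, as_labels(meta$labels, meta$subject_ids), meta$k)
}

#' Validated pipeline run configuration
#'
#' Bundles every tunable pipeline parameter with its default: m = 500
#' MeanDiff-selected SNPs, k grid \{1,3,5,7\}, r = 10 internal folds,
#' MAF minimum 0.05, HWE alpha 0.001, B = 100 permutations.
#'
#' @param m,k_grid,r,maf_min,hwe_alpha,B,seed see the individual pipeline
#'   functions.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(m = 500, k_grid = c(1, 3, 5, 7), r = 10,
                       maf_min = 0.05, hwe_alpha = 0.001, B = 100,
                       seed = 1) {
  stopifnot(m >= 1, length(k_grid) >= 1, all(k_grid >= 1), r >= 2,
            maf_min >= 0, maf_min <= 0.5, hwe_alpha > 0, hwe_alpha <= 1,
            B >= 1)
  structure(list(m = as.integer(m), k_grid = as.integer(k_grid),
                 r = as.integer(r), maf_min = maf_min,
                 hwe_alpha = hwe_alpha, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "run_config")
}
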