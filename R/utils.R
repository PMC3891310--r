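# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All exported functions that consume randomness route through this, so a
# gwps call never perturbs the user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Draw `n` sub-seeds (< 2^31) from a master seed, for nested procedures that
# need independent, reproducible random streams per fold / permutation.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

LABEL_LEVELS <- c("control", "case")

#' Coerce a phenotype vector to the package's label representation
#'
#' Labels are stored as a factor with levels `control`, `case`; `case` is the
#' positive class in every derived metric (sensitivity, precision).
#'
#' @param x character, factor or logical (`TRUE` = case) vector.
#' @param subject_ids optional subject identifiers attached as names.
#' @return a factor with levels `control`, `case`.
#' @export
as_labels <- function(x, subject_ids = names(x)) {
  if (is.logical(x)) x <- ifelse(x, "case", "control")
  x <- as.character(x)
  bad <- !x %in% LABEL_LEVELS
  if (any(bad)) {
    stop("invalid label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected 'case' or 'control')")
  }
  out <- factor(x, levels = LABEL_LEVELS)
  if (!is.null(subject_ids)) names(out) <- subject_ids
  out
}

# Validate a genotype matrix: integer codes 1/2/3 with NA for missing calls,
# unique subject (row) and SNP (column) identifiers.
check_genotypes <- function(gm, require_ids = TRUE) {
  if (!is.matrix(gm)) stop("genotypes must be a subjects x SNPs matrix")
  v <- gm[!is.na(gm)]
  if (length(v) && (!all(v %in% c(1L, 2L, 3L)))) {
    stop("genotype codes must be 1, 2 or 3 (NA for missing calls)")
  }
  if (require_ids) {
    if (is.null(rownames(gm)) || is.null(colnames(gm))) {
      stop("genotype matrix must carry subject rownames and SNP colnames")
    }
    if (anyDuplicated(rownames(gm))) stop("duplicate subject ids")
    if (anyDuplicated(colnames(gm))) stop("duplicate SNP ids")
  }
  invisible(gm)
}

check_aligned <- function(gm, labels) {
  if (length(labels) != nrow(gm)) {
    stop("labels (", length(labels), ") do not align with subjects (",
         nrow(gm), ")")
  }
  if (!is.null(names(labels)) && !is.null(rownames(gm)) &&
      !identical(names(labels), rownames(gm))) {
    stop("label subject ids do not match genotype matrix subject ids")
  }
  invisible(TRUE)
}

# Round half up (never banker's rounding) -- used for reported percentages.
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Express a proportion as a percentage rounded to two decimals
#'
#' Rounding is half-up, so 0.59550... prints as 59.55 and 0.51525 as 51.53.
#'
#' @param p proportion(s) in `[0, 1]` (NA allowed).
#' @return numeric percentage(s).
#' @export
as_percent <- function(p) round_half_up(100 * p, 2)
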