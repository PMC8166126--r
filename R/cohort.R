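#' Construct a cohort of paired tumor/normal allelic counts
#'
#' An `ai_cohort` holds, for a grid of SNP loci x samples, the tumor and
#' normal reference (A) and alternate (B) allele read depths, a heterozygote
#' mask, and per-sample coverage normalization factors. By convention the A
#' allele is the reference allele and the B allele the alternate.
#'
#' @param loci data frame with columns `snp_id`, `chrom`, `pos`, `arm`,
#'   `ref`, `alt` and optionally `gene`, `maf`.
#' @param samples character vector of sample identifiers.
#' @param tumor_a,tumor_b,normal_a,normal_b integer matrices
#'   (loci x samples) of allele read depths; `NA` marks missing entries.
#' @param is_het logical matrix of heterozygote calls; if `NULL`, computed
#'   from the normal counts via [call_heterozygote()].
#' @return Object of class `ai_cohort`.
#' @export
ai_cohort <- function(loci, samples, tumor_a, tumor_b, normal_a, normal_b,
                      is_het = NULL) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "arm", "ref", "alt")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(loci$gene)) loci$gene <- NA_character_
  if (is.null(loci$maf)) loci$maf <- NA_real_
  loci$ref <- toupper(loci$ref)
  loci$alt <- toupper(loci$alt)
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  if (any(loci$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (anyDuplicated(loci$snp_id)) stop("duplicated snp_id in loci")
  rownames(loci) <- NULL
  samples <- as.character(samples)
  dims <- c(nrow(loci), length(samples))
  mats <- list(tumor_a = tumor_a, tumor_b = tumor_b,
               normal_a = normal_a, normal_b = normal_b)
  dn <- list(loci$snp_id, samples)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop(nm, " must be a ", dims[1], " x ", dims[2], " matrix")
    if (any(m < 0, na.rm = TRUE)) stop(nm, " contains negative counts")
    if (any(m != floor(m), na.rm = TRUE)) stop(nm, " contains non-integer counts")
    storage.mode(m) <- "integer"
    dimnames(m) <- dn
    mats[[nm]] <- m
  }
  tumor_a <- mats$tumor_a; tumor_b <- mats$tumor_b
  normal_a <- mats$normal_a; normal_b <- mats$normal_b
  if (is.null(is_het)) {
    is_het <- call_heterozygote(normal_a, normal_b)
    is_het[is.na(is_het)] <- FALSE
  }
  dimnames(is_het) <- dn
  obj <- structure(list(loci = loci, samples = samples,
                        tumor_a = tumor_a, tumor_b = tumor_b,
                        normal_a = normal_a, normal_b = normal_b,
                        is_het = is_het, norm_factor = NULL),
                   class = "ai_cohort")
  obj$norm_factor <- coverage_norm_factors(obj)
  obj
}

# Per-sample coverage scale: global median normal depth over sample median
# depth. Inert for the estimator (the depth scale cancels in the expected
# allele fractions); retained for reporting.
coverage_norm_factors <- function(cohort) {
  tot <- cohort$normal_a + cohort$normal_b
  med <- apply(tot, 2, median, na.rm = TRUE)
  med[!is.finite(med) | med <= 0] <- NA_real_
  glob <- median(tot, na.rm = TRUE)
  nf <- glob / med
  nf[!is.finite(nf)] <- 1
  setNames(nf, cohort$samples)
}

#' @export
print.ai_cohort <- function(x, ...) {
  cat("ai_cohort:", nrow(x$loci), "SNPs x", length(x$samples), "samples\n")
  cat("  heterozygous entries:", sum(x$is_het, na.rm = TRUE), "\n")
  cat("  arms:", length(unique(x$loci$arm)), " median normal depth:",
      round(median(x$normal_a + x$normal_b, na.rm = TRUE), 1), "\n")
  invisible(x)
}

#' B-allele frequency
#'
#' `BAF = n_b / (n_a + n_b)` — the fraction of reads carrying the alternate
#' (B) allele.
#'
#' @param n_a,n_b reference and alternate read counts (vectorized).
#' @return Numeric BAF; an error if any total is zero.
#' @examples
#' compute_baf(15, 10) # 0.4
#' @export
compute_baf <- function(n_a, n_b) {
  if (any(n_a < 0 | n_b < 0, na.rm = TRUE)) stop("counts must be non-negative")
  tot <- n_a + n_b
  if (any(tot == 0, na.rm = TRUE))
    stop("BAF undefined where both allele counts are zero")
  n_b / tot
}

#' Call a heterozygous genotype from normal-tissue counts
#'
#' A locus-sample pair is heterozygous when the normal total coverage is
#' strictly greater than 20 and the normal BAF lies within \[0.2, 0.8\]
#' (endpoints included).
#'
#' @param normal_a,normal_b normal-tissue reference and alternate counts
#'   (vectorized; matrices allowed).
#' @return Logical, same shape as the inputs.
#' @examples
#' call_heterozygote(12, 13) # TRUE:  coverage 25, BAF 0.52
#' call_heterozygote(10, 10) # FALSE: coverage exactly 20 fails
#' @export
call_heterozygote <- function(normal_a, normal_b) {
  tot <- normal_a + normal_b
  baf <- ifelse(tot > 0, normal_b / tot, NA_real_)
  out <- tot > 20 & !is.na(baf) & baf >= 0.2 & baf <= 0.8
  out & !is.na(out)
}

count_table_columns <- function() {
  c("snp_id", "chrom", "pos", "arm", "ref", "alt", "sample_id",
    "tumor_ref_count", "tumor_alt_count", "normal_ref_count",
    "normal_alt_count")
}

#' Read a cohort count table
#'
#' Reads the canonical tab-separated dialect (one row per SNP x sample):
#' `snp_id`, `chrom`, `pos`, `arm`, `ref`, `alt`, `sample_id`,
#' `tumor_ref_count`, `tumor_alt_count`, `normal_ref_count`,
#' `normal_alt_count`. Heterozygote flags are set from the normal counts on
#' load. Gene symbols and population MAFs live in the separate annotation
#' table; see [annotate_cohort()].
#'
#' @param path file path.
#' @return An `ai_cohort`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  miss <- setdiff(count_table_columns(), names(df))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  cnt_cols <- c("tumor_ref_count", "tumor_alt_count",
                "normal_ref_count", "normal_alt_count")
  for (cc in cnt_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop("column ", cc, ": invalid count '", df[[cc]][bad[1]],
           "' at line ", bad[1] + 1L)  # +1 for the header line
    df[[cc]] <- as.integer(v)
  }
  df$pos <- as.integer(df$pos)
  loci <- unique(df[, c("snp_id", "chrom", "pos", "arm", "ref", "alt")])
  if (anyDuplicated(loci$snp_id))
    stop("inconsistent locus metadata for a snp_id")
  samples <- sort(unique(df$sample_id))
  idx <- cbind(match(df$snp_id, loci$snp_id), match(df$sample_id, samples))
  mk <- function(col) {
    m <- matrix(NA_integer_, nrow(loci), length(samples))
    m[idx] <- df[[col]]
    m
  }
  ai_cohort(loci, samples, mk("tumor_ref_count"), mk("tumor_alt_count"),
            mk("normal_ref_count"), mk("normal_alt_count"))
}

#' Write a cohort count table
#'
#' Emits the canonical dialect read by [read_count_table()], rows ordered by
#' snp_id then sample so that rewriting is byte-identical.
#'
#' @param cohort an `ai_cohort`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_count_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "ai_cohort"))
  loci <- cohort$loci
  ord <- order(loci$snp_id)
  samp_ord <- order(cohort$samples)
  # locus-major ordering: all samples of a locus together
  li <- rep(ord, each = length(samp_ord))
  si <- rep(samp_ord, times = length(ord))
  keep <- !(is.na(cohort$tumor_a[cbind(li, si)]) |
              is.na(cohort$tumor_b[cbind(li, si)]) |
              is.na(cohort$normal_a[cbind(li, si)]) |
              is.na(cohort$normal_b[cbind(li, si)]))
  li <- li[keep]; si <- si[keep]
  df <- data.frame(snp_id = loci$snp_id[li], chrom = loci$chrom[li],
                   pos = loci$pos[li], arm = loci$arm[li],
                   ref = loci$ref[li], alt = loci$alt[li],
                   sample_id = cohort$samples[si],
                   tumor_ref_count = cohort$tumor_a[cbind(li, si)],
                   tumor_alt_count = cohort$tumor_b[cbind(li, si)],
                   normal_ref_count = cohort$normal_a[cbind(li, si)],
                   normal_alt_count = cohort$normal_b[cbind(li, si)],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-SNP annotation and per-gene dependency tables
#'
#' Annotation dialect: `snp_id`, `gene`, `maf`, `cadd`, `control_af`.
#' Dependency dialect: `gene`, `dependency_score`.
#'
#' @param path file path.
#' @return A data frame in the respective dialect.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("snp_id", "gene", "maf", "cadd", "control_af"), names(df))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_annotation_table
#' @export
read_dependency_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "dependency_score"), names(df))
  if (length(miss))
    stop("dependency table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Attach annotation fields to a cohort's loci
#'
#' Fills the `gene` and `maf` locus columns from an annotation table (needed
#' before [filter_loci()] when the cohort came from a bare count table).
#'
#' @param cohort an `ai_cohort`.
#' @param annotations data frame with `snp_id`, `gene`, `maf`.
#' @return The cohort with updated loci.
#' @export
annotate_cohort <- function(cohort, annotations) {
  stopifnot(inherits(cohort, "ai_cohort"))
  i <- match(cohort$loci$snp_id, annotations$snp_id)
  cohort$loci$gene <- annotations$gene[i]
  cohort$loci$maf <- annotations$maf[i]
  cohort
}

#' Apply the SNP inclusion filters
#'
#' Two ordered stages: remove loci with population minor-allele frequency
#' below `maf_min`, then loci with fewer than `min_het` heterozygous samples.
#' Variants with few heterozygotes in the cohort carry little information
#' about allelic preference, hence the second stage (its threshold is a
#' configurable stand-in for the quality filter; see the vignette).
#'
#' @param cohort an `ai_cohort` with het flags set and `maf` populated.
#' @param maf_min minimum population MAF (loci with `maf < maf_min` are
#'   removed); must lie in \[0, 0.5\].
#' @param min_het minimum number of heterozygous samples.
#' @return List with the filtered `cohort` and a `report` data frame of loci
#'   counts surviving each stage (`input`, `maf`, `het_count`), monotone
#'   non-increasing.
#' @export
filter_loci <- function(cohort, maf_min = 0.005, min_het = 10L) {
  stopifnot(inherits(cohort, "ai_cohort"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  n0 <- nrow(cohort$loci)
  if (maf_min > 0 && anyNA(cohort$loci$maf))
    stop("loci have missing maf; annotate the cohort before MAF filtering")
  keep_maf <- if (maf_min > 0) cohort$loci$maf >= maf_min else rep(TRUE, n0)
  cohort <- subset_cohort(cohort, keep_maf)
  n1 <- nrow(cohort$loci)
  het_n <- rowSums(cohort$is_het, na.rm = TRUE)
  cohort <- subset_cohort(cohort, het_n >= min_het)
  n2 <- nrow(cohort$loci)
  report <- data.frame(stage = c("input", "maf", "het_count"),
                       n_loci = c(n0, n1, n2), stringsAsFactors = FALSE)
  list(cohort = cohort, report = report)
}

subset_cohort <- function(cohort, keep) {
  cohort$loci <- cohort$loci[keep, , drop = FALSE]
  rownames(cohort$loci) <- NULL
  for (nm in c("tumor_a", "tumor_b", "normal_a", "normal_b", "is_het"))
    cohort[[nm]] <- cohort[[nm]][keep, , drop = FALSE]
  cohort
}
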