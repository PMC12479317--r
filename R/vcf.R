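#' Read genotype categories and dosages from a VCF
#'
#' Converts biallelic sites into genotype categories (allele-string labels
#' such as `TT`, `TC`, `CC`, ordered by alternate-allele count) and a dosage
#' matrix in \{0, 1, 2\}. Phased and unphased GT separators are treated
#' alike; missing GT becomes `NA`. Requires the `VariantAnnotation` package.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param variant_ids Optional variant id filter (VCF ID column).
#' @param sample_ids Optional sample filter; VCF samples not listed are
#'   excluded with a warning (cohort alignment).
#' @return List with `genotypes` (data.frame of ordered factors, one column
#'   per variant, named by ID), `dosages` (samples x variants integer
#'   matrix) and `samples`.
#' @export
read_genotypes_vcf <- function(path, variant_ids = NULL, sample_ids = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_genotypes_vcf requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  if (!is.null(variant_ids)) {
    missing_v <- setdiff(variant_ids, ids)
    if (length(missing_v))
      stop("variant(s) not in VCF: ", paste(missing_v, collapse = ", "),
           call. = FALSE)
    vcf <- vcf[match(variant_ids, ids), ]
    ids <- variant_ids
  }
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L))
    stop("unsupported site: multi-allelic variant(s) ",
         paste(ids[lengths(alt) != 1L], collapse = ", "), call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  samples <- colnames(gt)
  if (!is.null(sample_ids)) {
    extra <- setdiff(samples, sample_ids)
    if (length(extra))
      warning(length(extra), " VCF sample(s) absent from cohort excluded",
              call. = FALSE)
    keep <- samples %in% sample_ids
    gt <- gt[, keep, drop = FALSE]
    samples <- samples[keep]
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  altc <- as.character(unlist(alt))
  dosage_of <- function(g) {
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (any(a == ".") || length(a) != 2L) return(NA_integer_)
      sum(a == "1")
    }, NA_integer_)
  }
  dos <- t(apply(gt, 1L, dosage_of))
  dos <- matrix(as.integer(dos), nrow = nrow(gt),
                dimnames = list(ids, samples))
  genos <- as.data.frame(lapply(seq_along(ids), function(v) {
    labels <- c(paste0(ref[v], ref[v]), paste0(ref[v], altc[v]),
                paste0(altc[v], altc[v]))
    factor(labels[dos[v, ] + 1L], levels = labels)
  }), col.names = ids, check.names = FALSE)
  rownames(genos) <- samples
  list(genotypes = genos, dosages = t(dos), samples = samples)
}
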