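# Sieve-plateau variance correction for genetic relatedness. The GRM entry
# for individuals i, j over R variants with sample reference-allele
# frequencies p_k is
#   G_ij = 1/(R-1) sum_k (s_ik - 2 p_k)(s_jk - 2 p_k) / (2 p_k (1 - p_k)),
# genetic dissimilarity is d(i, j) = 1 - G_ij (clamped at 0 from below for
# sample GRMs, with d(i, i) := 0 by convention so the tau = 0 estimator is
# the iid one), and the sieve variance estimator at cut-off tau is
#   sigma2(tau) = 1/n sum_ij 1{d(i, j) <= tau} D_i D_j.

#' Genetic relationship matrix from a dosage matrix
#'
#' @param dosages n x R matrix of allele counts in \{0, 1, 2\} (individuals
#'   by variants). Monomorphic variants are excluded with a warning.
#' @param ids Optional individual ids (defaults to rownames or 1..n).
#' @return A `grm` object: `$G` (n x n, diagonal included as computed),
#'   `$diag`, `$ids`, `$p` (reference-allele frequencies), `$R`.
#' @export
compute_grm <- function(dosages, ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) ids <- rownames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosages)))
  p <- colMeans(dosages) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) excluded from the GRM",
            call. = FALSE)
    dosages <- dosages[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  R <- ncol(dosages)
  if (R < 2L) stop("need at least 2 polymorphic variants", call. = FALSE)
  z <- sweep(sweep(dosages, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(z) / (R - 1)
  structure(list(G = G, diag = diag(G), ids = ids, p = p, R = R),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm>", length(x$ids), "individuals,", x$R, "variants\n")
  invisible(x)
}

#' Sieve variance curve over dissimilarity thresholds
#'
#' For each tau in the grid, accumulates `(1/n) sum_ij 1{d(i,j) <= tau}
#' D_i D_j` where `d = 1 - G` off the diagonal (negative values clamped to
#' 0) and `d(i, i) = 0` by convention, so `sigma2(0)` includes all
#' self-pairs and recovers the iid estimator. The selected plateau value is
#' the grid argmax (the most conservative estimate). Pair contributions are
#' accumulated in row chunks so the n x n dissimilarity matrix is never
#' materialized whole.
#'
#' @param eif EIF vector (see [eif_values()]), same individuals/order as the
#'   GRM.
#' @param grm A [compute_grm()] object (or a plain n x n relatedness
#'   matrix).
#' @param taus Threshold grid in `[0, 2]`; default 100 equally spaced values
#'   in `[0, 1]`, stopping before the degenerate all-pairs region.
#' @param chunk Rows per accumulation chunk.
#' @return A `sieve_curve`: `$taus`, `$sigma2` (variance per threshold),
#'   `$tau0` and `$sigma2_selected` (the plateau argmax).
#' @export
sieve_curve <- function(eif, grm, taus = seq(0, 1, length.out = 100L),
                        chunk = 512L) {
  if (length(taus) == 0L) stop("invalid config: empty tau grid", call. = FALSE)
  taus <- sort(taus)
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  n <- length(eif)
  if (nrow(G) != n)
    stop("eif and grm must cover the same individuals", call. = FALSE)
  base <- sum(eif^2)  # self-pairs, always included
  acc <- numeric(length(taus))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- 1 - G[idx, , drop = FALSE]
    d[d < 0] <- 0
    # keep strictly off-diagonal pairs; each unordered pair appears twice
    # across the full loop, which is exactly the double sum's count
    d[cbind(seq_along(idx), idx)] <- Inf
    prod <- eif[idx] %o% eif
    for (t in seq_along(taus))
      acc[t] <- acc[t] + sum(prod[d <= taus[t]])
  }
  sigma2 <- (base + acc) / n
  sel <- which.max(sigma2)
  structure(list(taus = taus, sigma2 = sigma2, tau0 = taus[sel],
                 sigma2_selected = sigma2[sel]),
            class = "sieve_curve")
}

#' @export
print.sieve_curve <- function(x, ...) {
  cat("<sieve_curve>", length(x$taus), "thresholds; plateau at tau0 =",
      format(x$tau0, digits = 3), "with sigma2 =",
      format(x$sigma2_selected, digits = 5), "\n")
  invisible(x)
}

#' Replace the iid variance of a record by the sieve-plateau value
#'
#' Swaps `sigma2(tau0)` into the Wald interval and p-value of an
#' `estimate_record` and flags it as SVP-corrected. Because the grid
#' contains tau = 0, the corrected p-value is never smaller than the iid
#' one.
#'
#' @param record An `estimate_record`.
#' @param curve A [sieve_curve()] computed from the record's EIF.
#' @return The corrected `estimate_record`.
#' @export
corrected_inference <- function(record, curve) {
  record$sigma2_iid <- record$sigma2
  record$sigma2 <- curve$sigma2_selected
  w <- wald_ci(record$psi, record$sigma2, record$n, record$alpha)
  record$se <- w$se; record$ci <- w$ci; record$p <- w$p
  record$svp <- TRUE
  record$tau0 <- curve$tau0
  record
}

#' Optional Hardy-Weinberg pre-filter for GRM variants
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the genotype counts
#' against Hardy-Weinberg proportions; columns with p below `alpha` are
#' dropped.
#'
#' @param dosages n x R dosage matrix.
#' @param alpha Exclusion threshold (default 1e-6, the conventional GWAS QC
#'   cut).
#' @return The filtered dosage matrix.
#' @export
hwe_filter <- function(dosages, alpha = 1e-6) {
  keep <- apply(dosages, 2L, function(s) {
    n <- length(s)
    p <- mean(s) / 2
    if (p <= 0 || p >= 1) return(FALSE)
    obs <- c(sum(s == 0), sum(s == 1), sum(s == 2))
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((obs - expd)^2 / expd)
    stats::pchisq(x2, df = 1, lower.tail = FALSE) >= alpha
  })
  dosages[, keep, drop = FALSE]
}

# ---- GRM persistence --------------------------------------------------------

#' Write / read a GRM in the GCTA-style lower-triangle layout
#'
#' `write_grm()` persists `<prefix>.grm.gz` (tab-separated `i j R G`, lower
#' triangle including the diagonal, 1-based indices) and `<prefix>.grm.id`
#' (family/individual id pairs). `read_grm()` reads that text dialect and
#' the GCTA binary dialect (`<prefix>.grm.bin`: little-endian float32 lower
#' triangle, plus `<prefix>.grm.id`), whichever is present.
#'
#' @param grm A [compute_grm()] object.
#' @param prefix Path prefix for the `.grm.gz` / `.grm.id` (or `.grm.bin`)
#'   pair.
#' @return `write_grm()` the prefix, invisibly; `read_grm()` a `grm` object
#'   (with `$R` the per-pair variant count when available).
#' @export
write_grm <- function(grm, prefix) {
  n <- length(grm$ids)
  lower <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  lower <- lower[order(lower[, 1L], lower[, 2L]), , drop = FALSE]
  tab <- data.frame(i = lower[, 1L], j = lower[, 2L], R = grm$R,
                    G = grm$G[lower])
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  utils::write.table(data.frame(fid = grm$ids, iid = grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  idf <- utils::read.table(paste0(prefix, ".grm.id"),
                           col.names = c("fid", "iid"),
                           colClasses = "character")
  n <- nrow(idf)
  G <- matrix(0, n, n)
  npairs <- n * (n + 1) / 2
  binpath <- paste0(prefix, ".grm.bin")
  if (file.exists(binpath)) {
    con <- file(binpath, "rb")
    vals <- readBin(con, "numeric", n = npairs, size = 4L,
                    endian = "little")
    close(con)
    lower <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    lower <- lower[order(lower[, 1L], lower[, 2L]), , drop = FALSE]
    G[lower] <- vals
    R <- NA_integer_
  } else {
    tab <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")),
                             col.names = c("i", "j", "R", "G"))
    G[cbind(tab$i, tab$j)] <- tab$G
    R <- as.integer(stats::median(tab$R))
  }
  G[upper.tri(G)] <- t(G)[upper.tri(G)]
  structure(list(G = G, diag = diag(G), ids = idf$iid, p = NULL, R = R),
            class = "grm")
}

#' Export a sieve curve as TSV
#'
#' Two columns, `tau` and `sigma2`, one row per threshold.
#'
#' @param curve A [sieve_curve()].
#' @param path Output file.
#' @export
write_sieve_curve <- function(curve, path) {
  utils::write.table(data.frame(tau = curve$taus, sigma2 = curve$sigma2),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
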