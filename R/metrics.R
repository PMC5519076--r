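# Split a canonical genotype-class code into its allele symbols. Two-letter
# calls split into characters, separator calls on "/"; any other code (e.g. a
# numeric zygosity string taken verbatim) is treated as homozygous for a
# symbol of its own.
.parse_alleles <- function(code) {
  if (grepl("/", code, fixed = TRUE)) strsplit(code, "/", fixed = TRUE)[[1]]
  else if (grepl("^[A-Z]{2}$", code)) strsplit(code, "")[[1]]
  else c(code, code)
}

#' Per-marker allele decomposition and reference-allele dosages
#'
#' Decomposes every genotype class into alleles and stores, per sample and
#' marker, the relative allele frequencies `p_xij` (0, 0.5 or 1 for diploids:
#' allele dosage / ploidy). Designates a reference allele per marker — by
#' default the major allele of the entire collection; for VCF-derived
#' matrices `ref = "vcf"` uses allele index `"0"` where present.
#'
#' @param G A [genotype_matrix()].
#' @param table Optional precomputed [class_table()] of `G`.
#' @param ref `"major"`, `"vcf"`, or a character vector of allele symbols
#'   named by marker ID (unnamed markers fall back to the major allele).
#' @return An object of class `allele_freq_table`: list with `sample_ids`,
#'   `marker_ids`, `alleles` (per-marker symbols), `allele_marker` (marker
#'   index of every dosage column), `P` (samples x allele-columns dosage
#'   matrix, `NA` where the call is missing), `nonmiss` (samples x markers
#'   logical), `informative`, `ref_allele`, and `ref_dosage` (samples x
#'   markers reference-allele dosage).
#' @export
allele_freq_table <- function(G, table = NULL, ref = "major") {
  T <- if (is.null(table)) class_table(G) else table
  n <- nrow(G$calls)
  m <- ncol(G$calls)
  alleles <- vector("list", m)
  for (i in which(T$informative))
    alleles[[i]] <- sort(unique(unlist(lapply(T$classes[[i]], .parse_alleles))))
  n_all <- lengths(alleles)
  aoff <- cumsum(c(0L, n_all))[seq_len(m)]
  P <- matrix(NA_real_, n, sum(n_all))
  ref_allele <- rep(NA_character_, m)
  ref_dosage <- matrix(NA_real_, n, m)
  named_ref <- is.character(ref) && !identical(ref, "major") &&
    !identical(ref, "vcf")
  for (i in which(T$informative)) {
    als <- alleles[[i]]
    cls <- T$classes[[i]]
    D <- matrix(0, length(cls), length(als), dimnames = list(cls, als))
    for (k in seq_along(cls)) {
      pa <- .parse_alleles(cls[k])
      for (a in pa) D[k, a] <- D[k, a] + 1 / length(pa)
    }
    ci <- match(G$calls[, i], cls)
    block <- D[ci, , drop = FALSE]            # NA row index -> NA dosages
    P[, aoff[i] + seq_along(als)] <- block
    pop <- as.numeric(T$freq[[i]] %*% D)      # collection allele frequencies
    r <- NULL
    if (named_ref) r <- unname(ref[G$marker_ids[i]])
    if (identical(ref, "vcf") && "0" %in% als) r <- "0"
    if (is.null(r) || is.na(r) || !r %in% als) r <- als[which.max(pop)]
    ref_allele[i] <- r
    ref_dosage[, i] <- block[, match(r, als)]
  }
  structure(
    list(sample_ids = G$sample_ids, marker_ids = G$marker_ids,
         alleles = alleles, allele_marker = rep.int(seq_len(m), n_all),
         P = P, nonmiss = !is.na(G$calls), informative = T$informative,
         ref_allele = ref_allele, ref_dosage = ref_dosage),
    class = "allele_freq_table"
  )
}

#' Genotype-class coverage of a sample subset
#'
#' `CV = 100/m' * sum_i GC_i / GE_i` over the `m'` informative markers, where
#' `GE_i` is the number of genotype classes at marker `i` in the entire
#' collection and `GC_i` the number of those classes present (non-missing) in
#' the subset.
#'
#' @param subset Sample IDs or indices (the empty subset scores 0).
#' @param G A [genotype_matrix()].
#' @param table Optional precomputed [class_table()].
#' @return CV in percent.
#' @export
cv_coverage <- function(subset, G, table = NULL) {
  T <- if (is.null(table)) class_table(G) else table
  if (!length(subset)) return(0)
  idx <- .resolve_samples(G$sample_ids, subset)
  inf <- which(T$informative)
  gc <- vapply(inf, function(i) {
    col <- G$calls[idx, i]
    length(unique(col[!is.na(col)]))
  }, integer(1))
  100 * mean(gc / T$ge[inf])
}

#' Shannon diversity index of a sample subset
#'
#' `SH = -sum_i p_i * ln(p_i)` over informative markers, where `p_i` is the
#' relative reference-allele frequency at marker `i` computed within the
#' subset from non-missing calls. Markers with `p_i = 0` contribute 0 (limit
#' convention); markers with no call inside the subset are skipped.
#'
#' @param subset Non-empty sample IDs or indices.
#' @param aft An [allele_freq_table()].
#' @return SH, a non-negative real.
#' @export
shannon_index <- function(subset, aft) {
  idx <- .resolve_samples(aft$sample_ids, subset)
  if (!length(idx)) stop("subset must be non-empty")
  p <- colMeans(aft$ref_dosage[idx, , drop = FALSE], na.rm = TRUE)
  p <- p[aft$informative & !is.nan(p)]
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Modified Rogers distance between two samples
#'
#' `MR(x, y) = sqrt( 1/(2 m'') * sum_{i shared} sum_j (p_xij - p_yij)^2 )`,
#' where the sum runs over the `m''` markers at which both samples have a
#' non-missing call and `j` over that marker's alleles. MR lies in `[0, 1]`,
#' is symmetric, and is 0 for identical genotypes.
#'
#' @param x,y Sample IDs or indices.
#' @param aft An [allele_freq_table()].
#' @return MR, or `NA` with a warning when the pair shares no non-missing
#'   marker.
#' @export
modified_rogers <- function(x, y, aft) {
  i <- .resolve_samples(aft$sample_ids, x)[1L]
  j <- .resolve_samples(aft$sample_ids, y)[1L]
  shared <- aft$nonmiss[i, ] & aft$nonmiss[j, ]
  mpp <- sum(shared)
  if (mpp == 0L) {
    warning("samples share no non-missing marker; MR undefined")
    return(NA_real_)
  }
  d <- aft$P[i, ] - aft$P[j, ]
  sqrt(sum(d * d, na.rm = TRUE) / (2 * mpp))
}

#' Pairwise modified Rogers distances for a subset
#'
#' Matrix-product formulation of [modified_rogers()] over all pairs of the
#' subset, with pairwise-complete markers per pair.
#'
#' @param subset Sample IDs or indices (length >= 1).
#' @param aft An [allele_freq_table()].
#' @return Symmetric matrix of MR distances (`NA` where a pair shares no
#'   marker), with subset sample IDs as dimnames.
#' @export
mr_matrix <- function(subset, aft) {
  idx <- .resolve_samples(aft$sample_ids, subset)
  P0 <- aft$P[idx, , drop = FALSE]
  P0[is.na(P0)] <- 0
  M <- aft$nonmiss[idx, , drop = FALSE] * 1
  MA <- M[, aft$allele_marker, drop = FALSE]
  S <- (P0 * P0) %*% t(MA)     # S[x, y] = sum_c P0[x,c]^2 * nonmiss[y, marker(c)]
  XY <- tcrossprod(P0)
  MM <- tcrossprod(M)
  MR2 <- (S + t(S) - 2 * XY) / (2 * MM)
  MR2[MM == 0] <- NA
  out <- sqrt(pmax(MR2, 0))
  diag(out) <- 0
  dimnames(out) <- list(aft$sample_ids[idx], aft$sample_ids[idx])
  out
}

#' Evaluation statistics for a sample subset
#'
#' Assembles the standard core-collection report: subset size, mean and
#' minimum pairwise modified Rogers distance, Shannon diversity, and coverage
#' CV. MR fields are `NA` for singleton subsets.
#'
#' @param subset Sample IDs or indices; duplicates are dropped with a
#'   warning.
#' @param G A [genotype_matrix()].
#' @param table Optional precomputed [class_table()].
#' @param aft Optional precomputed [allele_freq_table()].
#' @return An object of class `core_metrics`: list with `n_samples`,
#'   `mr_mean`, `mr_min`, `sh`, `cv_percent`. `as.data.frame()` renders it as
#'   a one-row table in the order (# samples, MR, Min. MR, SH, CV).
#' @export
evaluate_core <- function(subset, G, table = NULL, aft = NULL) {
  T <- if (is.null(table)) class_table(G) else table
  A <- if (is.null(aft)) allele_freq_table(G, table = T) else aft
  idx <- .resolve_samples(G$sample_ids, subset)
  if (anyDuplicated(idx)) {
    warning("duplicate sample IDs in subset; deduplicated")
    idx <- unique(idx)
  }
  n <- length(idx)
  if (!n) stop("subset must be non-empty")
  cvp <- cv_coverage(idx, G, table = T)
  sh <- shannon_index(idx, A)
  mr_mean <- mr_min <- NA_real_
  if (n >= 2L) {
    mm <- mr_matrix(idx, A)
    ut <- mm[upper.tri(mm)]
    mr_mean <- mean(ut, na.rm = TRUE)
    mr_min <- suppressWarnings(min(ut, na.rm = TRUE))
    if (!is.finite(mr_min)) mr_min <- NA_real_
  }
  structure(list(n_samples = n, mr_mean = mr_mean, mr_min = mr_min, sh = sh,
                 cv_percent = cvp),
            class = "core_metrics")
}

#' @export
as.data.frame.core_metrics <- function(x, ...) {
  data.frame(n_samples = x$n_samples, MR = x$mr_mean, Min.MR = x$mr_min,
             SH = x$sh, CV = x$cv_percent)
}

#' @export
print.core_metrics <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Reference-allele frequency spectrum of a subset
#'
#' Bins the per-marker reference-allele frequencies computed within the
#' subset. `spectrum_max_diff()` gives the maximum absolute difference
#' between the normalized spectra of two subsets — the summary used to check
#' that a core preserves the allele-frequency distribution of the entire
#' collection.
#'
#' @param subset,subset1,subset2 Sample IDs or indices.
#' @param aft An [allele_freq_table()].
#' @param bin_width Bin width in (0, 1].
#' @return `allele_spectrum()`: list with `breaks`, `counts`, `proportion`
#'   and `n_markers`; `spectrum_max_diff()`: a single number in `[0, 1]`.
#' @export
allele_spectrum <- function(subset, aft, bin_width = 0.05) {
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 1)
    stop("`bin_width` must lie in (0, 1]")
  idx <- .resolve_samples(aft$sample_ids, subset)
  p <- colMeans(aft$ref_dosage[idx, , drop = FALSE], na.rm = TRUE)
  p <- p[aft$informative & !is.nan(p)]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- graphics::hist(p, breaks = breaks, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  list(breaks = breaks, counts = h$counts,
       proportion = h$counts / sum(h$counts), n_markers = length(p))
}

#' @rdname allele_spectrum
#' @export
spectrum_max_diff <- function(subset1, subset2, aft, bin_width = 0.05) {
  s1 <- allele_spectrum(subset1, aft, bin_width)
  s2 <- allele_spectrum(subset2, aft, bin_width)
  max(abs(s1$proportion - s2$proportion))
}
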