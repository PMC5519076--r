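#' Simulate a genotype collection with founder structure
#'
#' Emulates a germplasm collection: `n_founders` distinct diploid genotype
#' prototypes, each duplicated `dups_per_founder` times. Per marker, two
#' distinct nucleotide alleles are chosen and the reference-allele frequency
#' is drawn from a Beta distribution (`maf_beta`); founder genotypes follow
#' Hardy-Weinberg proportions at that frequency. Duplicate copies can be
#' perturbed per call at `mutation_rate` (creating near-duplicates).
#' Missingness defaults to the founder-prototype level (`missing_level =
#' "founder"`): missing cells are drawn once per founder and inherited by its
#' duplicates, so unmutated duplicates are byte-identical clones — the regime
#' the selection algorithm's identical-sample removal targets.
#' `missing_level = "sample"` instead applies independent per-call
#' missingness after duplication. Either way each call is missing with
#' marginal probability `missing_rate`. A fraction of markers can be made
#' triallelic (`multiallelic_rate`) to exercise genotype-class logic beyond
#' biallelic markers.
#'
#' @param n_founders Number of distinct genotype prototypes (>= 1).
#' @param dups_per_founder Copies per founder (>= 1).
#' @param n_markers Marker count (>= 1).
#' @param maf_beta Shape pair of the Beta distribution the reference-allele
#'   frequency is drawn from.
#' @param missing_rate Per-call missingness probability in [0, 1).
#' @param mutation_rate Per-call probability that a duplicate's call is
#'   redrawn from the marker's genotype model, in [0, 1).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param missing_level `"founder"` (default) or `"sample"`; see above.
#' @param multiallelic_rate Fraction of markers drawn with three alleles.
#'
#' @return A list with `geno` (a [genotype_matrix()]), `founders` (factor of
#'   ground-truth founder labels named by sample ID), `p_ref` (per-marker
#'   reference-allele frequency used by the model) and `ref_allele`
#'   (per-marker reference allele symbol).
#'
#' @examples
#' sim <- simulate_geno(n_founders = 3, dups_per_founder = 5, n_markers = 20,
#'                      missing_rate = 0, seed = 1)
#' table(sim$founders)
#' @export
simulate_geno <- function(n_founders = 25, dups_per_founder = 20,
                          n_markers = 2000, maf_beta = c(0.8, 0.8),
                          missing_rate = 0.02, mutation_rate = 0,
                          seed = 1L, missing_level = c("founder", "sample"),
                          multiallelic_rate = 0) {
  missing_level <- match.arg(missing_level)
  if (n_founders < 1 || dups_per_founder < 1 || n_markers < 1)
    stop("`n_founders`, `dups_per_founder` and `n_markers` must be >= 1")
  for (r in c(missing_rate, mutation_rate, multiallelic_rate))
    if (!is.numeric(r) || r < 0 || r >= 1)
      stop("rates must lie in [0, 1)")
  if (length(maf_beta) != 2 || any(maf_beta <= 0))
    stop("`maf_beta` must be two positive shape parameters")
  k <- as.integer(n_founders)
  m <- as.integer(n_markers)
  bases <- c("A", "C", "G", "T")

  out <- .with_seed(seed, {
    p <- stats::rbeta(m, maf_beta[1], maf_beta[2])
    a1 <- sample.int(4L, m, replace = TRUE)
    a2 <- ((a1 - 1L + sample.int(3L, m, replace = TRUE)) %% 4L) + 1L
    ref_al <- bases[a1]
    alt_al <- bases[a2]
    hom_r <- paste0(ref_al, ref_al)
    hom_a <- paste0(alt_al, alt_al)
    het <- ifelse(ref_al < alt_al, paste0(ref_al, alt_al),
                  paste0(alt_al, ref_al))

    # founder dosage of the reference allele under Hardy-Weinberg
    draw_dosage <- function(nr, cols) {
      u <- matrix(stats::runif(nr * length(cols)), nr, length(cols))
      p2 <- matrix(rep(p[cols]^2, each = nr), nr)
      p1 <- matrix(rep(p[cols]^2 + 2 * p[cols] * (1 - p[cols]), each = nr), nr)
      d <- matrix(0L, nr, length(cols))
      d[u < p1] <- 1L
      d[u < p2] <- 2L
      d
    }
    d <- draw_dosage(k, seq_len(m))
    F <- matrix(rep(hom_a, each = k), k, m)
    F[d == 1L] <- matrix(rep(het, each = k), k, m)[d == 1L]
    F[d == 2L] <- matrix(rep(hom_r, each = k), k, m)[d == 2L]

    tri <- integer(0)
    tri_alleles <- list()
    tri_freq <- list()
    if (multiallelic_rate > 0) {
      tri <- which(stats::runif(m) < multiallelic_rate)
      for (i in tri) {
        als <- sort(sample(bases, 3L))
        w <- stats::rgamma(3L, 1)
        w <- w / sum(w)
        gt <- matrix(als[sample.int(3L, 2L * k, replace = TRUE, prob = w)],
                     ncol = 2L)
        F[, i] <- paste0(pmin(gt[, 1], gt[, 2]), pmax(gt[, 1], gt[, 2]))
        ref_al[i] <- als[which.max(w)]
        p[i] <- w[which.max(w)]
        tri_alleles[[as.character(i)]] <- als
        tri_freq[[as.character(i)]] <- w
      }
    }

    if (missing_level == "founder" && missing_rate > 0)
      F[matrix(stats::runif(k * m) < missing_rate, k, m)] <- NA

    rows <- rep(seq_len(k), each = dups_per_founder)
    calls <- F[rows, , drop = FALSE]
    n <- k * dups_per_founder

    if (mutation_rate > 0) {
      hit <- which(stats::runif(n * m) < mutation_rate)
      for (cell in hit) {
        i <- ((cell - 1L) %/% n) + 1L
        r <- ((cell - 1L) %% n) + 1L
        if (i %in% tri) {
          als <- tri_alleles[[as.character(i)]]
          w <- tri_freq[[as.character(i)]]
          gt <- sort(als[sample.int(3L, 2L, replace = TRUE, prob = w)])
          calls[r, i] <- paste0(gt[1], gt[2])
        } else {
          dd <- draw_dosage(1L, i)[1L, 1L]
          calls[r, i] <- c(hom_a[i], het[i], hom_r[i])[dd + 1L]
        }
      }
    }

    if (missing_level == "sample" && missing_rate > 0)
      calls[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA

    copy_no <- stats::ave(rows, rows, FUN = seq_along)
    ids <- sprintf("F%03d_%02d", rows, copy_no)
    marker_ids <- sprintf("M%05d", seq_len(m))
    G <- genotype_matrix(calls, ids, marker_ids)
    list(geno = G,
         founders = stats::setNames(factor(sprintf("F%03d", rows)), ids),
         p_ref = stats::setNames(p, marker_ids),
         ref_allele = stats::setNames(ref_al, marker_ids))
  })
  out
}
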