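#' Per-marker genotype-class frequency table
#'
#' Tabulates, for every marker, the distinct non-missing genotype classes
#' observed in the entire collection, their relative frequencies
#' `f[i, c] = count(c at i) / (non-missing calls at i)`, and the class count
#' `GE_i`. Markers whose calls are all missing are flagged uninformative and
#' excluded from every statistic downstream.
#'
#' @param G A [genotype_matrix()].
#' @return An object of class `marker_class_table`: a list with `classes`
#'   (per-marker character vectors), `freq` (per-marker named numeric vectors
#'   summing to 1), `ge` (integer `GE_i`), `informative` (logical), plus
#'   internal indexing fields (`offset`, `n_classes`, `class_marker`,
#'   `f_global`) that give every (marker, class) pair a global index.
#' @export
class_table <- function(G) {
  calls <- G$calls
  m <- ncol(calls)
  classes <- vector("list", m)
  freq <- vector("list", m)
  ge <- integer(m)
  informative <- logical(m)
  for (i in seq_len(m)) {
    tab <- table(calls[, i])          # drops NA
    if (length(tab)) {
      informative[i] <- TRUE
      classes[[i]] <- names(tab)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      freq[[i]] <- f
      ge[i] <- length(tab)
    }
  }
  offset <- cumsum(c(0L, ge))[seq_len(m)]
  structure(
    list(marker_ids = G$marker_ids, classes = classes, freq = freq, ge = ge,
         informative = informative, offset = offset, n_classes = sum(ge),
         class_marker = rep.int(seq_len(m), ge),
         f_global = if (sum(ge)) unlist(freq, use.names = FALSE) else numeric(0)),
    class = "marker_class_table"
  )
}

#' @export
print.marker_class_table <- function(x, ...) {
  cat(sprintf("marker_class_table: %d markers (%d informative), %d classes\n",
              length(x$ge), sum(x$informative), x$n_classes))
  invisible(x)
}

#' Coverage state over (marker, class) pairs
#'
#' Tracks which entire-collection genotype classes are already carried by the
#' selected core. `covered` flags are monotone within a selection run: once a
#' class is covered it is never reset. `gc` holds the per-marker covered-class
#' count `GC_i`.
#'
#' @param table A [class_table()].
#' @return An object of class `coverage_state` with elements `covered`
#'   (logical over global class indices) and `gc` (integer per marker).
#' @export
coverage_state <- function(table) {
  structure(list(covered = logical(table$n_classes),
                 gc = integer(length(table$ge))),
            class = "coverage_state")
}

#' Mark every class carried by a sample as covered
#'
#' @param state A [coverage_state()].
#' @param G,table The matrix and its [class_table()].
#' @param sample Sample ID or row index.
#' @return The updated `coverage_state`.
#' @export
cover_sample <- function(state, G, table, sample) {
  j <- .resolve_samples(G$sample_ids, sample)[1L]
  gi <- .sample_class_index(G, table, j)
  new <- gi[!state$covered[gi]]
  if (length(new)) {
    state$covered[new] <- TRUE
    state$gc <- state$gc + tabulate(table$class_marker[new],
                                    nbins = length(table$ge))
  }
  state
}

#' Coverage percentage implied by a coverage state
#'
#' `CV = 100/m' * sum_i GC_i / GE_i` over the `m'` informative markers.
#'
#' @param state A [coverage_state()].
#' @param table A [class_table()].
#' @return CV in percent.
#' @export
state_cv <- function(state, table) {
  inf <- table$informative
  100 * mean(state$gc[inf] / table$ge[inf])
}

# Global class indices of a sample's non-missing calls.
.sample_class_index <- function(G, table, j) {
  idx <- which(!is.na(G$calls[j, ]) & table$informative)
  vapply(idx, function(i)
    table$offset[i] + match(G$calls[j, i], table$classes[[i]]), integer(1))
}

# Masked per-marker frequency terms for sample j: f[i, g_ij] for non-missing
# markers, zeroed where the (marker, class) pair is already covered.
.masked_terms <- function(G, table, state, j) {
  idx <- which(!is.na(G$calls[j, ]) & table$informative)
  f <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    pos <- match(G$calls[j, i], table$classes[[i]])
    gi <- table$offset[i] + pos
    f[k] <- if (!is.null(state) && state$covered[gi]) 0 else table$freq[[i]][[pos]]
  }
  list(f = f, n_called = length(idx))
}

#' Coverage score of a candidate sample
#'
#' `C_j = (1 / n(N_j)) * sum_{i in N_j} f[i, g_ij]`, where `N_j` is the set of
#' markers with a non-missing call in sample `j` and `f` is the
#' entire-collection genotype-class frequency. Terms whose (marker, class)
#' pair is already covered in `state` contribute 0, so with an empty state
#' this is exactly the first-iteration score. The denominator `n(N_j)` depends
#' only on missingness and is not reduced by masking.
#'
#' @param G A [genotype_matrix()].
#' @param table Its [class_table()].
#' @param state A [coverage_state()], or `NULL` for the unmasked score.
#' @param sample Sample ID or row index.
#' @return `C_j` in `[0, 1]`. A sample with no non-missing call scores 0 with
#'   a warning.
#' @export
coverage_score <- function(G, table, state = NULL, sample) {
  j <- .resolve_samples(G$sample_ids, sample)[1L]
  t <- .masked_terms(G, table, state, j)
  if (t$n_called == 0L) {
    warning("sample ", G$sample_ids[j],
            " has no non-missing call; coverage score set to 0")
    return(0)
  }
  sum(t$f) / t$n_called
}

#' Diversity score of a candidate sample
#'
#' `D_j = (1 / n(N_j)) * sum_{i in N_j} (f[i, g_ij] - C_j)^2`: the mean
#' squared deviation of the sample's (masked) per-marker frequency terms
#' around its coverage score. Used as the tie-break (minimum preferred) among
#' samples with equal `C_j`; the same covered-class masking as in
#' [coverage_score()] is applied so the deviation is measured around the
#' score actually used.
#'
#' @inheritParams coverage_score
#' @param c_score The sample's coverage score from the same iteration.
#' @return `D_j >= 0`; 0 with a warning when the sample has no non-missing
#'   call.
#' @export
diversity_score <- function(G, table, state = NULL, sample, c_score) {
  j <- .resolve_samples(G$sample_ids, sample)[1L]
  t <- .masked_terms(G, table, state, j)
  if (t$n_called == 0L) {
    warning("sample ", G$sample_ids[j],
            " has no non-missing call; diversity score set to 0")
    return(0)
  }
  sum((t$f - c_score)^2) / t$n_called
}

# Vectorized per-sample code/frequency matrices used by the selection loop.
# gidx: n x m integer matrix of global class indices (NA where missing);
# fmat: n x m matrix of f[i, g_ij]; n_called: per-sample |N_j|.
.geno_codes <- function(G, table) {
  n <- nrow(G$calls)
  m <- ncol(G$calls)
  gidx <- matrix(NA_integer_, n, m)
  for (i in which(table$informative))
    gidx[, i] <- table$offset[i] + match(G$calls[, i], table$classes[[i]])
  fmat <- matrix(table$f_global[gidx], n, m)
  list(gidx = gidx, fmat = fmat, n_called = rowSums(!is.na(gidx)))
}
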