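# Run expr with a private, seeded RNG stream; the caller's RNG state is
# restored on exit.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Duplicate-detection keys: byte-identical call vectors (missing positions
# included) collapse to one key.
.dup_keys <- function(calls) {
  calls[is.na(calls)] <- "\x01"
  apply(calls, 1L, paste, collapse = "\x1f")
}

#' Greedy core-collection selection
#'
#' Iteratively builds a core subset that maximizes genotype-class coverage.
#' Each step: (1) the candidate pool is restricted to remaining samples whose
#' missing-call count equals the minimum among remaining samples — if that
#' pool adds no new class while other remaining samples would, the pool is
#' widened to all remaining samples for that step; (2) the
#' masked coverage score `C_j` (see [coverage_score()]) is computed for every
#' candidate; (3) the argmax is picked — ties (equality after rounding to 12
#' decimals) are broken by minimum diversity score `D_j`, residual ties by
#' `tie_break`; (4) the pick's (marker, class)
#' pairs are marked covered and the pick plus all remaining samples with
#' byte-identical call vectors are removed; (5) the cumulative coverage CV%
#' is recomputed. Selection stops when CV reaches `target_cv`, when the CV
#' gain of the step just taken falls below `delta`, when no candidate adds
#' coverage, when the pool is exhausted, or when `max_core_size` is hit.
#'
#' @param G A [genotype_matrix()] with at least one sample and one
#'   informative marker.
#' @param target_cv Target coverage in percent, in (0, 100]; default 99.
#' @param delta Minimum coverage gain per step in percentage points;
#'   default 0.01.
#' @param seed Integer seed; consumed only when `tie_break = "random"`.
#' @param max_core_size Optional cap on the core size.
#' @param table Optionally, a precomputed [class_table()] of `G` (reused
#'   across repeated runs on the same matrix).
#' @param tie_break How residual ties (equal `C_j` and equal `D_j`) are
#'   resolved. `"first"` (default) takes the tied sample earliest in input
#'   order, which keeps the selected IDs identical across runs and seeds —
#'   residual ties arise almost exclusively among genetically identical
#'   samples, where any member is an equivalent representative. `"random"`
#'   draws uniformly from a seeded stream instead.
#'
#' @return An object of class `core_selection`: list with `core_ids` (ordered
#'   selected sample IDs), `trace` (data frame: `step`, `sample_id`,
#'   `coverage_score`, `diversity_score`, `cumulative_cv_percent`,
#'   `n_removed_duplicates`), `duplicates` (per-step list of removed IDs),
#'   `stop_reason` (one of `target_reached`, `delta_below_threshold`,
#'   `no_gain`, `samples_exhausted`, `size_cap`), `final_cv`, `seed`,
#'   `target_cv`, `delta`.
#'
#' @examples
#' sim <- simulate_geno(n_founders = 3, dups_per_founder = 5, n_markers = 50,
#'                      missing_rate = 0, seed = 7)
#' res <- select_core(sim$geno, target_cv = 100, delta = 0)
#' res$core_ids
#' @export
select_core <- function(G, target_cv = 99, delta = 0.01, seed = 1L,
                        max_core_size = Inf, table = NULL,
                        tie_break = c("first", "random")) {
  tie_break <- match.arg(tie_break)
  if (!inherits(G, "genotype_matrix")) stop("`G` must be a genotype_matrix")
  n <- nrow(G$calls)
  if (n < 1L || ncol(G$calls) < 1L) stop("empty genotype matrix")
  if (!is.numeric(target_cv) || target_cv <= 0 || target_cv > 100)
    stop("`target_cv` must lie in (0, 100]")
  if (!is.numeric(delta) || delta < 0) stop("`delta` must be >= 0")
  T <- if (is.null(table)) class_table(G) else table
  if (!any(T$informative))
    stop("all markers are uninformative (every call missing)")
  m <- length(T$ge)
  inf <- T$informative
  ge_inf <- T$ge[inf]
  pr <- .geno_codes(G, T)
  key <- .dup_keys(G$calls)

  covered <- logical(T$n_classes)
  gc <- integer(m)
  remaining <- seq_len(n)
  core <- integer(0)
  tr_id <- character(0); tr_c <- numeric(0); tr_d <- numeric(0)
  tr_cv <- numeric(0); tr_nd <- integer(0)
  dup_list <- list()
  cv_prev <- 0
  stop_reason <- NULL

  .with_seed(seed, {
    repeat {
      if (!length(remaining)) { stop_reason <- "samples_exhausted"; break }
      mc <- G$missing_counts[remaining]
      cand <- remaining[mc == min(mc)]
      score_pool <- function(cand) {
        val <- pr$fmat[cand, , drop = FALSE]
        val[which(covered[pr$gidx[cand, , drop = FALSE]])] <- 0
        nc <- pr$n_called[cand]
        list(val = val, nc = nc,
             Cs = ifelse(nc > 0L, rowSums(val, na.rm = TRUE) / pmax(nc, 1L), 0))
      }
      sc <- score_pool(cand)
      if (max(sc$Cs) <= 0 && length(cand) < length(remaining)) {
        # min-missing pool adds no new class: widen to all remaining samples
        cand <- remaining
        sc <- score_pool(cand)
      }
      val <- sc$val; nc <- sc$nc; Cs <- sc$Cs
      if (max(Cs) <= 0) { stop_reason <- "no_gain"; break }
      Cr <- round(Cs, 12)
      best <- which(Cr == max(Cr))
      d_val <- NA_real_
      if (length(best) > 1L) {
        vb <- val[best, , drop = FALSE]
        D <- rowSums((vb - Cs[best])^2, na.rm = TRUE) / pmax(nc[best], 1L)
        Dr <- round(D, 12)
        tie <- which(Dr == min(Dr))
        pick_in_best <- if (length(tie) == 1L) tie
                        else if (tie_break == "random")
                          tie[sample.int(length(tie), 1L)]
                        else tie[1L]
        d_val <- D[pick_in_best]
        pick <- best[pick_in_best]
      } else pick <- best
      chosen <- cand[pick]

      gi <- pr$gidx[chosen, ]
      gi <- gi[!is.na(gi)]
      new <- gi[!covered[gi]]
      covered[new] <- TRUE
      gc <- gc + tabulate(T$class_marker[new], nbins = m)
      cv_now <- 100 * mean(gc[inf] / ge_inf)

      dups <- remaining[key[remaining] == key[chosen] & remaining != chosen]
      remaining <- setdiff(remaining, c(chosen, dups))
      core <- c(core, chosen)
      step <- length(core)
      tr_id[step] <- G$sample_ids[chosen]
      tr_c[step] <- Cs[pick]
      tr_d[step] <- d_val
      tr_cv[step] <- cv_now
      tr_nd[step] <- length(dups)
      dup_list[[step]] <- G$sample_ids[dups]
      gain <- cv_now - cv_prev
      cv_prev <- cv_now

      if (cv_now >= target_cv - 1e-9) { stop_reason <- "target_reached"; break }
      if (gain < delta) { stop_reason <- "delta_below_threshold"; break }
      if (length(core) >= max_core_size) { stop_reason <- "size_cap"; break }
    }
  })

  trace <- data.frame(step = seq_along(core), sample_id = tr_id,
                      coverage_score = tr_c, diversity_score = tr_d,
                      cumulative_cv_percent = tr_cv,
                      n_removed_duplicates = tr_nd,
                      stringsAsFactors = FALSE)
  names(dup_list) <- tr_id
  structure(list(core_ids = G$sample_ids[core], trace = trace,
                 duplicates = dup_list, stop_reason = stop_reason,
                 final_cv = cv_prev, seed = seed, target_cv = target_cv,
                 delta = delta, tie_break = tie_break),
            class = "core_selection")
}

#' Random baseline core of a given size
#'
#' Draws `k` distinct samples uniformly at random (the baseline the greedy
#' method is compared against) and records the cumulative coverage CV% per
#' added sample.
#'
#' @param G A [genotype_matrix()].
#' @param k Core size, `1 <= k <= n_samples`.
#' @param seed Integer seed.
#' @param table Optional precomputed [class_table()].
#' @return A `core_selection` object (coverage/diversity scores are `NA` in
#'   the trace; `stop_reason` is `size_cap`).
#' @export
random_core <- function(G, k, seed = 1L, table = NULL) {
  n <- nrow(G$calls)
  if (!is.numeric(k) || k < 1 || k > n)
    stop("`k` must lie between 1 and ", n)
  k <- as.integer(k)
  T <- if (is.null(table)) class_table(G) else table
  if (!any(T$informative))
    stop("all markers are uninformative (every call missing)")
  m <- length(T$ge)
  inf <- T$informative
  pr <- .geno_codes(G, T)
  picks <- .with_seed(seed, sample.int(n, k))
  covered <- logical(T$n_classes)
  gc <- integer(m)
  cv <- numeric(k)
  for (s in seq_len(k)) {
    gi <- pr$gidx[picks[s], ]
    gi <- gi[!is.na(gi)]
    new <- gi[!covered[gi]]
    covered[new] <- TRUE
    gc <- gc + tabulate(T$class_marker[new], nbins = m)
    cv[s] <- 100 * mean(gc[inf] / T$ge[inf])
  }
  trace <- data.frame(step = seq_len(k), sample_id = G$sample_ids[picks],
                      coverage_score = NA_real_, diversity_score = NA_real_,
                      cumulative_cv_percent = cv,
                      n_removed_duplicates = 0L, stringsAsFactors = FALSE)
  structure(list(core_ids = G$sample_ids[picks], trace = trace,
                 duplicates = stats::setNames(list(), character(0)),
                 stop_reason = "size_cap", final_cv = cv[k], seed = seed,
                 target_cv = NA_real_, delta = NA_real_),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection: %d samples, final CV %.3f%% (%s)\n",
              length(x$core_ids), x$final_cv, x$stop_reason))
  n_dup <- sum(lengths(x$duplicates))
  if (n_dup) cat(sprintf("  duplicates removed along the way: %d\n", n_dup))
  invisible(x)
}
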