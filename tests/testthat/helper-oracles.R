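# Independent naive-loop oracles and small random fixtures. These share no
# code with the package internals: plain loops, per-marker tables, explicit
# allele parsing.

rand_geno <- function(n, m, miss = 0.15, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  calls <- matrix(NA_character_, n, m)
  for (i in seq_len(m)) {
    al <- sort(sample(bases, 2))
    cls <- c(paste0(al[1], al[1]), paste0(al[1], al[2]), paste0(al[2], al[2]))
    calls[, i] <- sample(cls, n, replace = TRUE)
  }
  if (miss > 0) calls[matrix(stats::runif(n * m) < miss, n, m)] <- NA
  genotype_matrix(calls, sprintf("s%03d", seq_len(n)),
                  sprintf("m%03d", seq_len(m)))
}

naive_freq <- function(G) {
  lapply(seq_len(ncol(G$calls)), function(i) {
    col <- G$calls[, i]
    col <- col[!is.na(col)]
    if (!length(col)) return(numeric(0))
    tab <- table(col)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    f
  })
}

# covered: list per marker of covered class codes (character vectors)
naive_C <- function(G, covered, j) {
  f <- naive_freq(G)
  tot <- 0
  nn <- 0
  for (i in seq_len(ncol(G$calls))) {
    g <- G$calls[j, i]
    if (is.na(g)) next
    nn <- nn + 1
    if (!(g %in% covered[[i]])) tot <- tot + f[[i]][[g]]
  }
  if (nn == 0) 0 else tot / nn
}

naive_D <- function(G, covered, j, cj) {
  f <- naive_freq(G)
  s <- 0
  nn <- 0
  for (i in seq_len(ncol(G$calls))) {
    g <- G$calls[j, i]
    if (is.na(g)) next
    nn <- nn + 1
    term <- if (g %in% covered[[i]]) 0 else f[[i]][[g]]
    s <- s + (term - cj)^2
  }
  if (nn == 0) 0 else s / nn
}

naive_CV <- function(G, subset) {
  idx <- if (is.numeric(subset)) subset else match(subset, G$sample_ids)
  ratios <- c()
  for (i in seq_len(ncol(G$calls))) {
    all_cls <- unique(G$calls[, i][!is.na(G$calls[, i])])
    if (!length(all_cls)) next
    sub <- G$calls[idx, i]
    sub_cls <- unique(sub[!is.na(sub)])
    ratios <- c(ratios, length(sub_cls) / length(all_cls))
  }
  100 * mean(ratios)
}

naive_alleles <- function(code) {
  if (grepl("/", code, fixed = TRUE)) strsplit(code, "/", fixed = TRUE)[[1]]
  else if (nchar(code) == 2 && grepl("^[A-Z]{2}$", code))
    strsplit(code, "")[[1]]
  else c(code, code)
}

# major allele of the entire collection, ties to the alphabetically first
naive_ref <- function(G) {
  vapply(seq_len(ncol(G$calls)), function(i) {
    col <- G$calls[, i][!is.na(G$calls[, i])]
    if (!length(col)) return(NA_character_)
    cnt <- table(unlist(lapply(col, naive_alleles)))
    names(cnt)[which.max(cnt)]
  }, character(1))
}

naive_SH <- function(G, subset) {
  idx <- if (is.numeric(subset)) subset else match(subset, G$sample_ids)
  ref <- naive_ref(G)
  sh <- 0
  for (i in seq_len(ncol(G$calls))) {
    if (is.na(ref[i])) next
    sub <- G$calls[idx, i]
    sub <- sub[!is.na(sub)]
    if (!length(sub)) next
    dos <- vapply(sub, function(g) mean(naive_alleles(g) == ref[i]), numeric(1))
    p <- mean(dos)
    if (p > 0) sh <- sh - p * log(p)
  }
  sh
}

naive_MR <- function(G, x, y) {
  i1 <- if (is.numeric(x)) x else match(x, G$sample_ids)
  i2 <- if (is.numeric(y)) y else match(y, G$sample_ids)
  s <- 0
  mpp <- 0
  for (i in seq_len(ncol(G$calls))) {
    gx <- G$calls[i1, i]
    gy <- G$calls[i2, i]
    if (is.na(gx) || is.na(gy)) next
    mpp <- mpp + 1
    ax <- naive_alleles(gx)
    ay <- naive_alleles(gy)
    for (a in unique(c(ax, ay)))
      s <- s + (mean(ax == a) - mean(ay == a))^2
  }
  if (mpp == 0) return(NA_real_)
  sqrt(s / (2 * mpp))
}

# Full greedy run re-implemented with loops: min-missing candidate filter
# (widened when it adds nothing), argmax C, min-D tie-break, first-in-order
# residual tie-break, identical-vector removal, target/delta stops.
naive_greedy <- function(G, target = 100, delta = 0) {
  n <- nrow(G$calls)
  m <- ncol(G$calls)
  covered <- rep(list(character(0)), m)
  remaining <- seq_len(n)
  ids <- character(0)
  cvs <- numeric(0)
  cv_prev <- 0
  repeat {
    if (!length(remaining)) break
    miss <- rowSums(is.na(G$calls[remaining, , drop = FALSE]))
    cand <- remaining[miss == min(miss)]
    Cs <- vapply(cand, function(j) naive_C(G, covered, j), numeric(1))
    if (max(Cs) <= 0 && length(cand) < length(remaining)) {
      cand <- remaining
      Cs <- vapply(cand, function(j) naive_C(G, covered, j), numeric(1))
    }
    if (max(Cs) <= 0) break
    best <- which(round(Cs, 12) == max(round(Cs, 12)))
    if (length(best) > 1) {
      Ds <- vapply(best, function(b) naive_D(G, covered, cand[b], Cs[b]),
                   numeric(1))
      best <- best[round(Ds, 12) == min(round(Ds, 12))]
    }
    pick <- cand[best[1]]
    for (i in seq_len(m)) {
      g <- G$calls[pick, i]
      if (!is.na(g) && !(g %in% covered[[i]]))
        covered[[i]] <- c(covered[[i]], g)
    }
    ratios <- c()
    for (i in seq_len(m)) {
      tot <- unique(G$calls[, i][!is.na(G$calls[, i])])
      if (length(tot))
        ratios <- c(ratios, length(covered[[i]]) / length(tot))
    }
    cv <- 100 * mean(ratios)
    same <- remaining[vapply(remaining, function(r)
      identical(unname(G$calls[r, ]), unname(G$calls[pick, ])), logical(1))]
    remaining <- setdiff(remaining, same)
    ids <- c(ids, G$sample_ids[pick])
    cvs <- c(cvs, cv)
    gain <- cv - cv_prev
    cv_prev <- cv
    if (cv >= target - 1e-9) break
    if (gain < delta) break
  }
  list(ids = ids, cvs = cvs)
}

# random covered mask over a class table, as both the package state and the
# oracle's per-marker code list
rand_state <- function(G, frac = 0.4, seed = 1) {
  set.seed(seed)
  T <- class_table(G)
  st <- coverage_state(T)
  cov_list <- rep(list(character(0)), length(T$ge))
  for (i in which(T$informative)) {
    hit <- stats::runif(T$ge[i]) < frac
    if (any(hit)) {
      st$covered[T$offset[i] + which(hit)] <- TRUE
      st$gc[i] <- sum(hit)
      cov_list[[i]] <- T$classes[[i]][hit]
    }
  }
  list(state = st, covered = cov_list, table = T)
}
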