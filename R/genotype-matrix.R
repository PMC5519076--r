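#' Genotype matrix container
#'
#' Holds a samples x markers grid of canonical genotype-class codes. A
#' genotype class is a distinct genotype value observed at a marker across
#' the collection (e.g. `"AG"`, `"0/1"`, or a numeric zygosity code taken
#' verbatim); missing calls are stored as `NA` and are never classes.
#' Unphased heterozygotes are order-normalized before they reach this
#' container, so the class for alleles \{A, G\} has exactly one spelling.
#'
#' @param calls Character matrix (samples in rows, markers in columns) of
#'   genotype-class codes; missing calls as `NA`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(calls)`.
#' @param marker_ids Character vector of unique marker identifiers; defaults
#'   to `colnames(calls)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `marker_ids`, `calls` (the dimnamed character matrix) and
#'   `missing_counts` (per-sample count of `NA` calls).
#'
#' @examples
#' calls <- matrix(c("AA", "AG", "AA", NA), nrow = 2, byrow = TRUE)
#' g <- genotype_matrix(calls, c("s1", "s2"), c("m1", "m2"))
#' g$missing_counts
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            marker_ids = colnames(calls)) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix (samples x markers)")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(calls))
    stop("length(sample_ids) must equal nrow(calls)")
  if (length(marker_ids) != ncol(calls))
    stop("length(marker_ids) must equal ncol(calls)")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(marker_ids[duplicated(marker_ids)])
  if (length(dup))
    stop("duplicate marker ID(s): ", paste(dup, collapse = ", "))
  dimnames(calls) <- list(sample_ids, marker_ids)
  structure(
    list(sample_ids = sample_ids, marker_ids = marker_ids, calls = calls,
         missing_counts = unname(rowSums(is.na(calls)))),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers\n",
              nrow(x$calls), ncol(x$calls)))
  miss <- sum(x$missing_counts)
  cat(sprintf("  missing calls: %d (%.2f%%)\n", miss,
              100 * miss / length(x$calls)))
  invisible(x)
}

#' Normalize raw genotype call strings to canonical class codes
#'
#' Upper-cases calls, maps any code in `missing_codes` to `NA`, and
#' canonicalizes heterozygote spellings: two-letter calls have their allele
#' symbols sorted (`"GA"` -> `"AG"`), and separator-style calls (`"1|0"`,
#' `"G/A"`) have their alleles sorted and joined with `/` (`"0/1"`). Any
#' allele spelled `.` (half-calls such as `"0/."`) renders the whole call
#' missing. Other strings (e.g. numeric zygosity codes `"0"`, `"1"`, `"2"`)
#' pass through verbatim.
#'
#' @param x Character vector of raw calls.
#' @param missing_codes Character vector of codes to treat as missing
#'   (case-insensitive).
#' @return Character vector of canonical class codes with `NA` for missing.
#' @export
normalize_calls <- function(x, missing_codes = c("NA", "--", "NN", "./.", "")) {
  x <- toupper(trimws(x))
  u <- unique(x)
  mc <- toupper(missing_codes)
  norm <- vapply(u, function(s) {
    if (is.na(s) || s %in% mc) return(NA_character_)
    if (grepl("[/|]", s)) {
      al <- strsplit(s, "[/|]")[[1]]
      if (!length(al) || any(al %in% c(".", ""))) return(NA_character_)
      al <- if (all(grepl("^[0-9]+$", al))) al[order(as.integer(al))] else sort(al)
      return(paste(al, collapse = "/"))
    }
    if (grepl("^[A-Z]{2}$", s))
      return(paste(sort(strsplit(s, "")[[1]]), collapse = ""))
    s
  }, character(1), USE.NAMES = FALSE)
  norm[match(x, u)]
}

# Resolve sample identifiers or indices to row indices; errors name unknowns.
.resolve_samples <- function(sample_ids, subset) {
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > length(sample_ids)))
      stop("sample index out of range")
    return(idx)
  }
  idx <- match(as.character(subset), sample_ids)
  if (anyNA(idx))
    stop("unknown sample ID(s): ",
         paste(unique(subset[is.na(idx)]), collapse = ", "))
  idx
}
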