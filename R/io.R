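#' Read a delimited sample x marker genotype matrix
#'
#' The dialect is a UTF-8 text table: a header row whose fields after the
#' first are marker IDs, then one row per sample whose first field is the
#' sample ID and remaining fields are genotype calls. The delimiter is
#' auto-detected (tab vs comma) from the header unless given. Calls matching
#' `missing_codes` become missing; heterozygote spellings are canonicalized
#' (see [normalize_calls()]).
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `"\t"` or `","`; `NULL` auto-detects.
#' @param missing_codes Codes treated as missing calls.
#' @return A [genotype_matrix()].
#' @export
read_geno_matrix <- function(path, delim = NULL,
                             missing_codes = c("NA", "--", "NN", "./.", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L)
    stop("file must hold a header row and at least one sample row: ", path)
  if (is.null(delim)) {
    n_tab <- nchar(gsub("[^\t]", "", lines[1L]))
    n_com <- nchar(gsub("[^,]", "", lines[1L]))
    delim <- if (n_tab >= n_com) "\t" else ","
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  header <- parts[[1L]]
  m <- length(header) - 1L
  if (m < 1L) stop("header row holds no marker IDs")
  body <- parts[-1L]
  # strsplit drops a trailing empty field; restore it
  nf <- lengths(body)
  body[nf == m] <- lapply(body[nf == m], function(p) c(p, ""))
  nf <- lengths(body)
  bad <- which(nf != m + 1L)
  if (length(bad))
    stop(sprintf("ragged row %d: %d field(s), expected %d",
                 bad[1L] + 1L, nf[bad[1L]], m + 1L))
  sample_ids <- trimws(vapply(body, `[[`, character(1), 1L))
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  calls <- matrix(normalize_calls(cells, missing_codes),
                  nrow = length(body), ncol = m, byrow = TRUE)
  genotype_matrix(calls, sample_ids, trimws(header[-1L]))
}

#' Write a genotype matrix in the delimited dialect
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @param missing_code String written for missing calls.
#' @return Invisibly, `path`.
#' @export
write_geno_matrix <- function(G, path, delim = "\t", missing_code = "NA") {
  out <- G$calls
  out[is.na(out)] <- missing_code
  lines <- c(paste(c("sample_id", G$marker_ids), collapse = delim),
             paste(G$sample_ids, apply(out, 1L, paste, collapse = delim),
                   sep = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Each VCF record becomes one marker; the per-sample GT field is mapped to an
#' unordered multiset of allele indices rendered canonically (`0/1`, `1/0` and
#' `0|1` all become the class `"0/1"`). `./.` and half-calls map to missing.
#' Multi-allelic sites yield one class per observed allele pair. INFO and
#' FILTER columns are ignored. Marker IDs come from the ID column, falling
#' back to `CHROM:POS` when absent or duplicated.
#'
#' @param path Path to a VCF (4.x) file.
#' @return A [genotype_matrix()].
#' @export
read_geno_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L) stop("VCF holds no variant records: ", path)
  if (ncol(v@gt) < 2L) stop("VCF holds no sample columns: ", path)
  has_gt <- vapply(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (!all(has_gt))
    stop("every VCF record must carry a GT FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  ids <- fix[, "ID"]
  pos_ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- pos_ids[blank]
  if (anyDuplicated(ids)) ids <- pos_ids
  if (anyDuplicated(ids))
    stop("duplicate marker identifiers in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  calls <- t(gt)
  calls[] <- normalize_calls(as.character(calls),
                             missing_codes = c("NA", "--", "NN", "./.", "", "."))
  genotype_matrix(calls, colnames(gt), ids)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Only supported for two-letter genotype calls (e.g. `"AG"`). Per marker the
#' most frequent allele becomes REF, the rest ALT; genotypes are written as
#' sorted GT index pairs and missing calls as `./.`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @param chrom Chromosome label used for every record.
#' @return Invisibly, `path`.
#' @export
write_geno_vcf <- function(G, path, chrom = "1") {
  m <- length(G$marker_ids)
  recs <- character(m)
  for (i in seq_len(m)) {
    col <- G$calls[, i]
    obs <- col[!is.na(col)]
    cls <- sort(unique(obs))
    if (length(cls) && !all(grepl("^[A-Z]{2}$", cls)))
      stop("VCF export requires two-letter genotype calls; offending marker: ",
           G$marker_ids[i])
    if (!length(cls)) {
      gt_str <- rep("./.", length(col))
      ref <- "N"; alt <- "."
    } else {
      counts <- table(obs)
      al_list <- strsplit(cls, "")
      alleles <- sort(unique(unlist(al_list)))
      cnt <- stats::setNames(numeric(length(alleles)), alleles)
      for (k in seq_along(cls))
        for (a in al_list[[k]]) cnt[a] <- cnt[a] + counts[[cls[k]]]
      ref <- names(cnt)[which.max(cnt)]
      alt_al <- setdiff(alleles, ref)
      alt <- if (length(alt_al)) paste(alt_al, collapse = ",") else "."
      code <- stats::setNames(seq_along(c(ref, alt_al)) - 1L, c(ref, alt_al))
      gt_by_class <- vapply(al_list, function(a)
        paste(sort(code[a]), collapse = "/"), character(1))
      names(gt_by_class) <- cls
      gt_str <- ifelse(is.na(col), "./.", gt_by_class[col])
    }
    recs[i] <- paste(c(chrom, i, G$marker_ids[i], ref, alt, ".", ".", ".",
                       "GT", gt_str), collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write and read core sample lists and selection traces
#'
#' `write_core_list()` writes one sample ID per line in selection order;
#' `read_core_list()` reads such a file back. `write_trace()` writes the
#' per-step selection trace as CSV with columns `step`, `sample_id`,
#' `coverage_score`, `diversity_score`, `cumulative_cv_percent`,
#' `n_removed_duplicates`.
#'
#' @param result A `core_selection` object from [select_core()] or
#'   [random_core()].
#' @param path Output (or input) path.
#' @return Invisibly, `path`; `read_core_list()` returns a character vector.
#' @export
write_core_list <- function(result, path) {
  if (!length(result$core_ids)) stop("selection result holds no core samples")
  writeLines(result$core_ids, path)
  invisible(path)
}

#' @rdname write_core_list
#' @export
read_core_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' @rdname write_core_list
#' @export
write_trace <- function(result, path) {
  if (!nrow(result$trace)) stop("selection result holds an empty trace")
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
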