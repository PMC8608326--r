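#' Partition a genome into fixed-width windows
#'
#' Windows are contiguous, non-overlapping, half-open `[start, end)` in
#' 0-based coordinates; the last window of a chromosome may be short.
#'
#' @param chrom_sizes Either a two-column data frame (`chrom`, `length`),
#'   or the path to a two-column TSV / FAI file (first two columns used).
#' @param width Window width in bp.
#' @return A `genome_windows` data frame with columns `chrom`, `start`,
#'   `end`, `index_on_chrom` and a `width` attribute.
#' @export
make_windows <- function(chrom_sizes, width) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    tab <- utils::read.delim(chrom_sizes, header = FALSE, stringsAsFactors = FALSE)
    chrom_sizes <- data.frame(chrom = tab[[1]], length = as.numeric(tab[[2]]))
  }
  stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
  if (width <= 0) stop_user("window width must be positive")
  if (any(chrom_sizes$length <= 0)) stop_user("chromosome lengths must be positive")
  if (anyDuplicated(chrom_sizes$chrom)) stop_user("duplicate chromosome labels")
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + width, len),
               index_on_chrom = seq_along(starts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, width = width,
            chrom_lengths = stats::setNames(chrom_sizes$length, chrom_sizes$chrom),
            class = c("genome_windows", "data.frame"))
}

#' Window keys of the form "chrom:start-end"
#' @param windows A `genome_windows` data frame.
#' @return Character vector of keys.
#' @export
window_keys <- function(windows) {
  sprintf("%s:%d-%d", windows$chrom, as.integer(windows$start), as.integer(windows$end))
}

#' Per-site parental similarity mark
#'
#' Scores one site of a parent pair: identical nucleotides in both
#' parents mark 2; exactly one parent matching the reference while the
#' other differs marks 1; both parents differing from the reference and
#' from each other mark 0. Identical non-reference nucleotides count as
#' 2 (the identity rule takes precedence).
#'
#' @param p1_allele,p2_allele,ref_allele Nucleotide character vectors.
#' @return Integer vector of marks in \{0, 1, 2\}.
#' @export
site_mark <- function(p1_allele, p2_allele, ref_allele) {
  if (anyNA(p1_allele) || anyNA(p2_allele))
    stop("missing alleles must be excluded before marking")
  ifelse(p1_allele == p2_allele, 2L,
         ifelse(p1_allele == ref_allele | p2_allele == ref_allele, 1L, 0L))
}

#' PGSI of one window from its site marks
#'
#' Default (normalized) convention: `sum(marks) / (2 * n)`, mapping
#' identical parents to 1 and maximal divergence to 0. The literal
#' convention `2 * sum(marks) / n` (range \[0, 4\]) is available behind
#' `literal = TRUE` for auditability.
#'
#' @param marks Integer marks in \{0, 1, 2\}.
#' @param literal Use the unnormalized convention.
#' @return A similarity value, or `NA` for an empty mark set.
#' @export
block_pgsi <- function(marks, literal = FALSE) {
  n <- length(marks)
  if (n == 0) return(NA_real_)
  if (literal) 2 * sum(marks) / n else sum(marks) / (2 * n)
}

#' Compute the PGSI matrix (crosses x windows)
#'
#' For each cross and window, marks are accumulated over the sites in
#' the window where both parents have non-missing (inbred-resolved)
#' calls; sites missing in either parent enter neither numerator nor
#' denominator. PGSI is strictly a parent-pair quantity; hybrid
#' genotypes are never involved.
#'
#' @param parents A [parent_geno] of inbred parents.
#' @param plan Cross-plan data frame.
#' @param windows A `genome_windows` object from [make_windows].
#' @param literal Use the unnormalized mark convention (see [block_pgsi]).
#' @param empty `"one"` (default) scores windows with no informative
#'   locus as 1 (no observed divergence among called SNPs), `"missing"`
#'   leaves them `NA`; either way the affected cells are flagged.
#' @return A `pgsi_matrix`: numeric matrix (crosses x windows) with
#'   attributes `n_loci` (informative locus counts), `windows`,
#'   `empty_cells` and `width`.
#' @export
compute_pgsi_matrix <- function(parents, plan, windows,
                                literal = FALSE, empty = c("one", "missing")) {
  empty <- match.arg(empty)
  plan <- validate_cross_plan(plan)
  unknown <- setdiff(c(plan$female_id, plan$male_id), parents$samples)
  if (length(unknown) > 0)
    stop_user("cross plan references unknown parent(s): ",
              paste(unique(unknown), collapse = ", "))
  parents <- resolve_inbred(parents)
  wchrom <- unique(windows$chrom)
  if (!any(parents$chrom %in% wchrom))
    stop_user("window set and genotype chromosomes are disjoint")
  width <- attr(windows, "width")
  # map each site to its window row (0-based half-open; uniform width)
  chrom_offset <- c(0, cumsum(tapply(windows$index_on_chrom, windows$chrom, max)[wchrom]))
  names(chrom_offset) <- c(wchrom, "..end")
  wmax <- tapply(windows$index_on_chrom, windows$chrom, max)[wchrom]
  site_chrom_i <- match(parents$chrom, wchrom)
  widx_on_chrom <- (parents$pos - 1L) %/% width + 1L
  in_range <- !is.na(site_chrom_i) & widx_on_chrom <= wmax[site_chrom_i]
  if (any(!in_range))
    warning(sprintf("%d site(s) outside the window set were dropped", sum(!in_range)))
  site_win <- chrom_offset[site_chrom_i[in_range]] + widx_on_chrom[in_range]
  # sanity: window keys align with computed rows
  stopifnot(max(site_win) <= nrow(windows))
  a <- parents$a1[in_range, , drop = FALSE]  # inbred: a1 == a2
  n_cross <- nrow(plan); n_win <- nrow(windows)
  values <- matrix(NA_real_, n_cross, n_win,
                   dimnames = list(plan$hybrid_id, window_keys(windows)))
  n_loci <- matrix(0L, n_cross, n_win, dimnames = dimnames(values))
  fwin <- factor(site_win, levels = seq_len(n_win))
  for (i in seq_len(n_cross)) {
    p1 <- a[, plan$female_id[i]]
    p2 <- a[, plan$male_id[i]]
    ok <- !is.na(p1) & !is.na(p2)
    mark <- ifelse(p1[ok] == p2[ok], 2L,
                   ifelse(p1[ok] == 0L | p2[ok] == 0L, 1L, 0L))
    msum <- tapply(mark, fwin[ok], sum)
    cnt <- tapply(rep(1L, sum(ok)), fwin[ok], sum)
    cnt[is.na(cnt)] <- 0L; msum[is.na(msum)] <- 0
    n_loci[i, ] <- cnt
    vals <- if (literal) 2 * msum / cnt else msum / (2 * cnt)
    values[i, ] <- ifelse(cnt > 0, vals, NA_real_)
  }
  empty_cells <- n_loci == 0L
  if (empty == "one") values[empty_cells] <- 1
  structure(values, n_loci = n_loci, windows = windows,
            empty_cells = empty_cells, width = width, literal = literal,
            class = c("pgsi_matrix", "matrix", "array"))
}

#' @export
print.pgsi_matrix <- function(x, ...) {
  cat(sprintf("pgsi_matrix: %d crosses x %d windows (width %s bp), %d empty cell(s)\n",
              nrow(x), ncol(x), format(attr(x, "width"), big.mark = ","),
              sum(attr(x, "empty_cells"))))
  invisible(x)
}

#' Export a PGSI matrix as TSV
#'
#' Rows are crosses (column `cross_id`), columns are windows keyed
#' "chrom:start-end" (BED-convention 0-based half-open intervals).
#'
#' @param pgsi A `pgsi_matrix`.
#' @param path Output path.
#' @export
write_pgsi_tsv <- function(pgsi, path) {
  df <- data.frame(cross_id = rownames(pgsi), as.data.frame(unclass(pgsi)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PGSI matrix written by [write_pgsi_tsv]
#' @param path TSV path.
#' @return A numeric matrix with cross IDs as row names.
#' @export
read_pgsi_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export genome windows as BED
#' @param windows A `genome_windows` object.
#' @param path Output path.
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(data.frame(windows$chrom, as.integer(windows$start),
                                as.integer(windows$end), window_keys(windows)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
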