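#' Per-window correlations between PGSI and heterosis
#'
#' @param pgsi A `pgsi_matrix` (crosses x windows).
#' @param heterosis Output of [compute_heterosis].
#' @param trait Trait ID.
#' @param which `"HPH"` or `"MPH"`.
#' @return Data frame: `window`, `chrom`, `start`, `end`, `trait`,
#'   `heterosis_type`, `r`, `n`. `r` is `NA` where either column is
#'   constant over the paired crosses.
#' @export
window_heterosis_correlations <- function(pgsi, heterosis, trait,
                                          which = c("HPH", "MPH")) {
  which <- match.arg(which)
  h <- heterosis_vector(heterosis, trait, which)
  h <- h[!is.na(h)]
  common <- intersect(names(h), rownames(pgsi))
  if (length(common) < 3)
    stop_user("fewer than 3 crosses shared between PGSI matrix and heterosis table")
  P <- unclass(pgsi)[common, , drop = FALSE]
  hv <- h[common]
  r <- suppressWarnings(as.numeric(stats::cor(P, hv, use = "pairwise.complete.obs")))
  n <- colSums(!is.na(P))
  win <- attr(pgsi, "windows")
  data.frame(window = colnames(pgsi),
             chrom = win$chrom, start = win$start, end = win$end,
             trait = trait, heterosis_type = which, r = r, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome influence on heterosis
#'
#' The influence of a chromosome is the sum of the absolute values of
#' its window-level PGSI-heterosis correlations (missing correlations
#' contribute zero). Subgenome aggregates are formed from the leading
#' letter of the chromosome name (A vs C).
#'
#' @param correlations Output of [window_heterosis_correlations].
#' @return Data frame (`chrom`, `influence`, `n_windows`) sorted by
#'   decreasing influence, with a `subgenome` attribute.
#' @export
chromosome_influence <- function(correlations) {
  ab <- abs(correlations$r)
  ab[is.na(ab)] <- 0
  infl <- tapply(ab, correlations$chrom, sum)
  out <- data.frame(chrom = names(infl), influence = as.numeric(infl),
                    n_windows = as.integer(table(correlations$chrom)[names(infl)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$influence), ]
  rownames(out) <- NULL
  sub <- toupper(substr(out$chrom, 1, 1))
  attr(out, "subgenome") <- c(tapply(out$influence, sub, sum))
  out
}

#' Extract h-QTLs from a window-feature LASSO fit
#'
#' Every selected window becomes an h-QTL record carrying its
#' re-estimated coefficient. High-impact h-QTLs are the top and bottom
#' 10% of coefficients (ceiling counts; boundary ties broken by larger
#' |coefficient|, then earlier genomic position). The effect label
#' follows the convention that a "positive" effect means the smaller
#' the PGSI the greater the heterosis, i.e. a negative coefficient on
#' PGSI; both the raw coefficient and the label are kept. Windows on
#' chromosomes not matching the A/C nomenclature are retained but
#' flagged unmappable.
#'
#' @param fit A `lasso_fit` built on window features.
#' @param windows The `genome_windows` the features came from.
#' @param trait Trait ID (annotation only).
#' @param which Heterosis type (annotation only).
#' @return Data frame of h-QTL records (possibly empty), columns:
#'   `name` (filled by [name_hqtls]), `chrom`, `start`, `end`,
#'   `coefficient`, `effect`, `impact`, `mappable`, `trait`,
#'   `heterosis_type`.
#' @export
extract_hqtls <- function(fit, windows, trait = NA, which = NA) {
  keys <- window_keys(windows)
  if (length(fit$selected) == 0) {
    message("extract_hqtls: intercept-only fit, no h-QTLs")
    return(data.frame(name = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      coefficient = numeric(0), effect = character(0),
                      impact = character(0), mappable = logical(0),
                      trait = character(0), heterosis_type = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- match(fit$selected, keys)
  if (anyNA(idx))
    stop_user("fit features are not windows of the given window set")
  coefs <- as.numeric(fit$coef)
  k <- length(coefs)
  n_top <- ceiling(0.1 * k)
  # rank with tie-breaks: coefficient, then |coefficient|, then position
  ord_desc <- order(-coefs, -abs(coefs), windows$chrom[idx], windows$start[idx])
  ord_asc <- order(coefs, -abs(coefs), windows$chrom[idx], windows$start[idx])
  impact <- rep("regular", k)
  impact[ord_desc[seq_len(n_top)]] <- "high"
  impact[ord_asc[seq_len(n_top)]] <- "high"
  out <- data.frame(name = NA_character_,
                    chrom = windows$chrom[idx],
                    start = windows$start[idx], end = windows$end[idx],
                    coefficient = coefs,
                    effect = ifelse(coefs < 0, "positive", "negative"),
                    impact = impact,
                    mappable = grepl("^[AC][0-9]+$", windows$chrom[idx]),
                    trait = trait, heterosis_type = which,
                    stringsAsFactors = FALSE)
  name_hqtls(out)
}

#' Name h-QTLs by chromosome and top-to-bottom rank
#'
#' Per chromosome, records are sorted by start position and numbered
#' from the chromosome top; the name is "Chr.<chrom>-<NN>" with the
#' number zero-padded to at least two digits (more when a chromosome
#' carries over 99 records). Naming is stable under record shuffling.
#'
#' @param records h-QTL data frame with `chrom` and `start` columns.
#' @return The records with the `name` column filled, in genomic order.
#' @export
name_hqtls <- function(records) {
  if (nrow(records) == 0) return(records)
  ord <- order(match(records$chrom, unique(sort(records$chrom))), records$start)
  records <- records[ord, ]
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    pad <- max(2L, nchar(length(i)))
    records$name[i] <- sprintf("Chr.%s-%0*d", ch, pad, seq_along(i))
  }
  rownames(records) <- NULL
  records
}

#' Genes intersecting h-QTL windows
#'
#' Intersects each record's half-open window `[start, end)` with the
#' gene features of a GFF3 annotation.
#'
#' @param records h-QTL data frame ([extract_hqtls]).
#' @param annotation Path to a GFF3 file, or a `GRanges` of genes.
#' @param feature_type GFF3 feature type to use (default `"gene"`).
#' @param id_field Attribute holding the gene identifier (default
#'   `"ID"`).
#' @return Named list (h-QTL name -> character vector of gene IDs).
#' @export
genes_in_windows <- function(records, annotation, feature_type = "gene",
                             id_field = "ID") {
  genes <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3", feature.type = feature_type)
  } else annotation
  if (nrow(records) == 0) return(stats::setNames(list(), character(0)))
  shared <- intersect(records$chrom, as.character(GenomicRanges::seqnames(genes)))
  n_unmatched <- sum(!records$chrom %in% shared)
  if (n_unmatched > 0)
    warning(sprintf("%d record(s) on chromosomes absent from the annotation",
                    n_unmatched))
  # half-open [start, end) 0-based -> closed 1-based [start+1, end]
  qry <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$start + 1, records$end))
  hits <- GenomicRanges::findOverlaps(qry, genes)
  ids <- if (id_field %in% names(GenomicRanges::mcols(genes))) {
    as.character(GenomicRanges::mcols(genes)[[id_field]])
  } else as.character(seq_along(genes))
  out <- stats::setNames(vector("list", nrow(records)), records$name)
  for (i in seq_len(nrow(records))) out[[i]] <- character(0)
  for (j in seq_along(hits))
    out[[S4Vectors::queryHits(hits)[j]]] <-
      c(out[[S4Vectors::queryHits(hits)[j]]], ids[S4Vectors::subjectHits(hits)[j]])
  out
}

#' Export h-QTL records as TSV and BED
#'
#' @param records h-QTL data frame.
#' @param path Output TSV path; a BED track is written next to it with
#'   extension `.bed` unless `bed = FALSE`.
#' @param bed Also write the BED track.
#' @export
write_hqtl_tsv <- function(records, path, bed = TRUE) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed && nrow(records) > 0) {
    bed_path <- sub("\\.tsv$", "", path)
    bed_path <- paste0(bed_path, ".bed")
    mp <- records[records$mappable, ]
    utils::write.table(data.frame(mp$chrom, as.integer(mp$start),
                                  as.integer(mp$end), mp$name,
                                  round(mp$coefficient, 6)),
                       bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
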