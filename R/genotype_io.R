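#' Parental genotype container
#'
#' Holds biallelic-or-multiallelic SNP calls for a set of samples as two
#' allele-index matrices (`a1`, `a2`; sites x samples). Allele index 0 is
#' the reference allele, 1.. index into `alt`; `NA` is a missing call.
#' Sites are sorted by (chromosome, position); positions are 1-based as
#' in VCF.
#'
#' @param chrom Character vector of chromosome labels per site.
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference nucleotides.
#' @param alt List of character vectors of alternate nucleotides.
#' @param a1,a2 Integer matrices (sites x samples) of allele indices.
#' @param samples Character vector of sample IDs (column names).
#' @return An object of class `parent_geno`.
#' @export
parent_geno <- function(chrom, pos, ref, alt, a1, a2, samples) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            nrow(a1) == n, nrow(a2) == n,
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  if (any(pos < 1)) stop("positions must be >= 1")
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate (chrom, pos) sites")
  if (!all(lengths(alt) >= 1)) stop("every site needs at least one alt allele")
  ord <- order(match(chrom, unique(chrom)), pos)
  colnames(a1) <- colnames(a2) <- samples
  structure(list(chrom = chrom[ord], pos = as.integer(pos[ord]),
                 ref = ref[ord], alt = alt[ord],
                 a1 = a1[ord, , drop = FALSE], a2 = a2[ord, , drop = FALSE],
                 samples = samples),
            class = "parent_geno")
}

#' @export
print.parent_geno <- function(x, ...) {
  cat(sprintf("parent_geno: %d sites x %d samples (%d chromosome(s))\n",
              length(x$pos), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.parent_geno <- function(x) c(length(x$pos), length(x$samples))

#' Read parental SNP genotypes from a VCF file
#'
#' Keeps SNP records (single-nucleotide REF and all single-nucleotide
#' ALTs); indels and other variant types are skipped with a message
#' giving the count. Only the GT FORMAT field is used.
#'
#' @param path Path to a VCF (optionally gzipped) with GT fields.
#' @param sample_ids Optional character vector selecting and ordering
#'   samples; all must be present in the file.
#' @return A [parent_geno] object.
#' @export
read_parent_vcf <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop_user("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  is_snp <- nchar(fix[, "REF"]) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L & a != "*"), logical(1))
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message(sprintf("read_parent_vcf: skipped %d non-SNP record(s)", n_skip))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  vcf_samples <- colnames(gt)
  if (is.null(sample_ids)) sample_ids <- vcf_samples
  missing_ids <- setdiff(sample_ids, vcf_samples)
  if (length(missing_ids) > 0)
    stop_user("sample(s) not in VCF: ", paste(missing_ids, collapse = ", "))
  gt <- gt[is_snp, sample_ids, drop = FALSE]
  # GT strings: "0/1", "0|1", "0", ".", "./."
  first <- sub("[/|].*$", "", gt)
  second <- sub("^[^/|]*[/|]?", "", gt)
  a1 <- suppressWarnings(matrix(as.integer(first), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(second), nrow = nrow(gt)))
  a2[is.na(a2) & !is.na(a1)] <- a1[is.na(a2) & !is.na(a1)]  # haploid calls
  both <- !is.na(a1) & !is.na(a2)
  a1[!both] <- NA_integer_; a2[!both] <- NA_integer_
  parent_geno(chrom = fix[is_snp, "CHROM"],
              pos = as.integer(fix[is_snp, "POS"]),
              ref = fix[is_snp, "REF"], alt = alt_list[is_snp],
              a1 = a1, a2 = a2, samples = sample_ids)
}

#' Write a parental genotype matrix as a plain-text VCF
#'
#' @param geno A [parent_geno] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parent_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pgsihet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples), collapse = "\t")), con)
  gt <- matrix(paste0(geno$a1, "/", geno$a2), nrow = nrow(geno$a1))
  gt[is.na(geno$a1)] <- "./."
  body <- cbind(geno$chrom, geno$pos, ".", geno$ref,
                vapply(geno$alt, paste, "", collapse = ","),
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Resolve heterozygous calls in nominally inbred parents
#'
#' Parents are assumed fully inbred; a heterozygous call is treated as
#' missing at that site (with a message giving the count), or raises an
#' error in strict mode.
#'
#' @param geno A [parent_geno] object.
#' @param strict Error instead of masking heterozygous calls.
#' @return A [parent_geno] with all non-missing calls homozygous.
#' @export
resolve_inbred <- function(geno, strict = FALSE) {
  het <- !is.na(geno$a1) & !is.na(geno$a2) & geno$a1 != geno$a2
  n_het <- sum(het)
  if (n_het > 0) {
    if (strict)
      stop_user(sprintf("%d heterozygous call(s) in inbred parents (strict mode)", n_het))
    message(sprintf("resolve_inbred: masked %d heterozygous call(s)", n_het))
    geno$a1[het] <- NA_integer_
    geno$a2[het] <- NA_integer_
  }
  geno
}

#' Cross plan accessors
#'
#' A cross plan is a data frame with columns `female_id`, `male_id`,
#' `hybrid_id` (one row per planned F1).
#'
#' @param path Path to a headered TSV with those columns.
#' @return A validated cross-plan data frame.
#' @export
read_cross_plan <- function(path) {
  plan <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cross_plan(plan)
}

#' @rdname read_cross_plan
#' @param plan A data frame to validate.
#' @export
validate_cross_plan <- function(plan) {
  need <- c("female_id", "male_id", "hybrid_id")
  if (!all(need %in% names(plan)))
    stop_user("cross plan needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(plan$hybrid_id)) stop_user("hybrid_id values must be unique")
  plan[, need]
}

#' Infer F1 hybrid genotypes from inbred parents
#'
#' Each hybrid receives one allele from each parent; a site missing in
#' either parent is missing in the hybrid.
#'
#' @param parents A [parent_geno] of inbred parents.
#' @param plan Cross-plan data frame (see [read_cross_plan]).
#' @param strict Passed to [resolve_inbred].
#' @return A [parent_geno] whose samples are the hybrids.
#' @export
infer_f1_genotypes <- function(parents, plan, strict = FALSE) {
  plan <- validate_cross_plan(plan)
  unknown <- setdiff(c(plan$female_id, plan$male_id), parents$samples)
  if (length(unknown) > 0)
    stop_user("cross plan references unknown parent(s): ",
              paste(unique(unknown), collapse = ", "))
  parents <- resolve_inbred(parents, strict = strict)
  fa <- parents$a1[, plan$female_id, drop = FALSE]
  ma <- parents$a1[, plan$male_id, drop = FALSE]
  miss <- is.na(fa) | is.na(ma)
  fa[miss] <- NA_integer_; ma[miss] <- NA_integer_
  parent_geno(parents$chrom, parents$pos, parents$ref, parents$alt,
              a1 = fa, a2 = ma, samples = plan$hybrid_id)
}

# Reduce a site to reference + most frequent alt (others -> missing).
# Returns list(a1, a2) with alt index recoded to 1.
.reduce_biallelic <- function(geno) {
  multi <- which(lengths(geno$alt) > 1)
  a1 <- geno$a1; a2 <- geno$a2
  for (i in multi) {
    counts <- tabulate(c(a1[i, ], a2[i, ]), nbins = length(geno$alt[[i]]))
    major_alt <- which.max(counts)  # ties -> lowest index
    keep1 <- is.na(a1[i, ]) | a1[i, ] %in% c(0L, major_alt)
    keep2 <- is.na(a2[i, ]) | a2[i, ] %in% c(0L, major_alt)
    keep <- keep1 & keep2
    a1[i, !keep] <- NA_integer_; a2[i, !keep] <- NA_integer_
    a1[i, which(a1[i, ] == major_alt)] <- 1L
    a2[i, which(a2[i, ] == major_alt)] <- 1L
  }
  list(a1 = a1, a2 = a2)
}

#' Additive marker coding (1 / 0 / -1)
#'
#' Codes each marker 1 for the minor-allele homozygote, 0 for the
#' heterozygote, and -1 for the major-allele homozygote. The minor
#' allele is the less frequent allele among the coded individuals; a
#' 50/50 tie designates the alternate allele as minor. Multiallelic
#' sites are first reduced to the reference plus the most frequent
#' alternate (remaining calls set missing). Missing calls stay missing.
#'
#' @param geno A [parent_geno] object (parents or inferred F1s).
#' @return A `coded_markers` object: list with `values` (individuals x
#'   markers), `coding`, `marker_keys` (chrom/pos data frame),
#'   `minor_allele`, and `monomorphic` flags.
#' @export
code_additive <- function(geno) {
  red <- .reduce_biallelic(geno)
  dos <- red$a1 + red$a2                     # alt-allele dosage 0/1/2
  n_called <- rowSums(!is.na(dos))
  alt_freq <- rowSums(dos, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  minor_is_alt <- alt_freq <= 0.5            # tie -> alt minor
  code <- ifelse(rep(minor_is_alt, ncol(dos)), dos - 1, 1 - dos)
  values <- t(matrix(code, nrow = nrow(dos), dimnames = dimnames(dos)))
  rownames(values) <- geno$samples
  alt1 <- vapply(geno$alt, `[`, "", 1L)
  structure(list(values = values, coding = "additive",
                 marker_keys = data.frame(chrom = geno$chrom, pos = geno$pos,
                                          stringsAsFactors = FALSE),
                 minor_allele = ifelse(minor_is_alt, alt1, geno$ref),
                 monomorphic = alt_freq %in% c(0, 1)),
            class = "coded_markers")
}

#' Dominance marker coding (heterozygosity indicator, mean-centered)
#'
#' Heterozygote -> 1, either homozygote -> 0, then per-marker mean
#' centering. Dominance kinships are built from these codes exactly as
#' additive ones are from additive codes.
#'
#' @inheritParams code_additive
#' @return A `coded_markers` object with `coding = "dominance"`.
#' @export
code_dominance <- function(geno) {
  red <- .reduce_biallelic(geno)
  het <- (red$a1 != red$a2) * 1
  values <- t(het)
  rownames(values) <- geno$samples
  values <- scale(values, center = TRUE, scale = FALSE)
  attr(values, "scaled:center") <- NULL
  structure(list(values = values, coding = "dominance",
                 marker_keys = data.frame(chrom = geno$chrom, pos = geno$pos,
                                          stringsAsFactors = FALSE),
                 minor_allele = NA_character_,
                 monomorphic = apply(het, 1, function(z) length(unique(z[!is.na(z)])) <= 1)),
            class = "coded_markers")
}

#' @export
print.coded_markers <- function(x, ...) {
  cat(sprintf("coded_markers (%s): %d individuals x %d markers\n",
              x$coding, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Randomly subsample markers
#'
#' Uniform sample without replacement of `round(fraction * m)` markers,
#' keeping genomic order. The same seed always selects the same markers.
#'
#' @param codes A `coded_markers` object.
#' @param fraction Proportion of markers to keep (0 < fraction <= 1).
#' @param seed Integer seed.
#' @return A `coded_markers` object restricted to the sampled markers.
#' @export
subsample_markers <- function(codes, fraction, seed) {
  m <- ncol(codes$values)
  if (!(fraction > 0 && fraction <= 1)) stop_user("fraction must be in (0, 1]")
  n_keep <- round(fraction * m)
  if (n_keep < 1) stop_user("fraction selects zero markers (m = ", m, ")")
  sel <- sort(with_seed(seed, sample.int(m, n_keep)))
  codes$values <- codes$values[, sel, drop = FALSE]
  codes$marker_keys <- codes$marker_keys[sel, , drop = FALSE]
  codes$minor_allele <- codes$minor_allele[sel]
  codes$monomorphic <- codes$monomorphic[sel]
  codes
}
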