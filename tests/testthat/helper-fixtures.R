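# Fixtures and independent oracles, built in code at test time.

NTS <- c("A", "C", "G", "T")

# Hand-written toy VCF: 5 SNPs (one optionally replaced by an indel), 3 samples.
write_toy_vcf <- function(path, samples = c("P1", "P2", "P3"),
                          with_indel = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- list(
    c("A01", "100", ".", "A", "G", ".", "PASS", ".", "GT", "0/0", "1/1", "0/0"),
    c("A01", "250", ".", "C", "T", ".", "PASS", ".", "GT", "1/1", "1/1", "./."),
    c("A01", "900", ".", "G", "A,T", ".", "PASS", ".", "GT", "0/0", "1/1", "2/2"),
    c("C01", "40",  ".", "T", "C", ".", "PASS", ".", "GT", "0/0", "0/0", "1/1"),
    c("C01", "77",  ".", "A", "C", ".", "PASS", ".", "GT", "1/1", "0/0", "0/0"))
  if (with_indel)
    rows[[2]] <- c("A01", "250", ".", "CT", "C", ".", "PASS", ".", "GT",
                   "1/1", "1/1", "./.")
  writeLines(c(hdr, vapply(rows, paste, "", collapse = "\t")), path)
  path
}

# Random inbred parent panel on a small genome.
random_parent_geno <- function(n_samples, n_sites, seed,
                               chroms = c("A01", "C01"),
                               chrom_len = 1000, miss_rate = 0.05,
                               multi_rate = 0) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n_sites, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(chrom_len, sum(chrom == ch)))))
  ref <- sample(NTS, n_sites, replace = TRUE)
  alt <- lapply(seq_len(n_sites), function(i) {
    k <- if (stats::runif(1) < multi_rate) 2 else 1
    sample(setdiff(NTS, ref[i]), k)
  })
  n_alleles <- lengths(alt)
  a <- matrix(NA_integer_, n_sites, n_samples)
  for (i in seq_len(n_sites))
    a[i, ] <- sample(0:n_alleles[i], n_samples, replace = TRUE)
  a[matrix(stats::runif(n_sites * n_samples) < miss_rate,
           n_sites, n_samples)] <- NA_integer_
  ids <- sprintf("S%02d", seq_len(n_samples))
  parent_geno(chrom, pos, ref, alt, a1 = a, a2 = a, samples = ids)
}

random_plan <- function(geno, n_cross, seed) {
  set.seed(seed)
  f <- sample(geno$samples, n_cross, replace = TRUE)
  m <- sample(geno$samples, n_cross, replace = TRUE)
  data.frame(female_id = f, male_id = m,
             hybrid_id = sprintf("H%02d", seq_len(n_cross)),
             stringsAsFactors = FALSE)
}

# Brute-force PGSI oracle: per cross, per window, per site, marking on
# NUCLEOTIDES via site_mark (the implementation works on allele indices).
pgsi_oracle <- function(geno, plan, windows, literal = FALSE, empty = "one") {
  nt_of <- function(i, idx) ifelse(idx == 0, geno$ref[i], geno$alt[[i]][idx])
  vals <- matrix(NA_real_, nrow(plan), nrow(windows),
                 dimnames = list(plan$hybrid_id, window_keys(windows)))
  for (ci in seq_len(nrow(plan))) {
    j1 <- match(plan$female_id[ci], geno$samples)
    j2 <- match(plan$male_id[ci], geno$samples)
    for (wi in seq_len(nrow(windows))) {
      marks <- integer(0)
      for (i in seq_along(geno$pos)) {
        if (geno$chrom[i] != windows$chrom[wi]) next
        if (geno$pos[i] <= windows$start[wi] || geno$pos[i] > windows$end[wi]) next
        a1 <- geno$a1[i, j1]; a2 <- geno$a1[i, j2]
        if (is.na(a1) || is.na(a2)) next
        marks <- c(marks, site_mark(nt_of(i, a1), nt_of(i, a2), geno$ref[i]))
      }
      v <- block_pgsi(marks, literal = literal)
      vals[ci, wi] <- if (length(marks) == 0 && empty == "one") 1 else v
    }
  }
  vals
}

# Long phenotype records from a genotype-value table.
make_records <- function(values, environments = "E1", reps = 1:3,
                         trait = "T1", env_offset = 0, noise = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sample_id = names(values), environment = environments,
                      replicate = reps, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  off <- stats::setNames(rep_len(env_offset, length(environments)), environments)
  grid$trait <- trait
  grid$value <- values[grid$sample_id] + off[grid$environment] +
    stats::rnorm(nrow(grid), 0, noise)
  grid
}

write_toy_gff3 <- function(path, genes) {
  # genes: data.frame(chrom, start1, end1, id) in 1-based closed coords
  lines <- c("##gff-version 3",
             sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start1, genes$end1, genes$id))
  writeLines(lines, path)
  path
}
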