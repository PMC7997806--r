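#' Write genotypes as minimal VCFv4.2
#'
#' Emits one bi-allelic record per variant with a GT FORMAT field only.
#' Dosages 0/1/2 map to `0/0`, `0/1`, `1/1`; missing dosages to `./.`.
#'
#' @param genotypes n x m dosage matrix (rownames = sample ids).
#' @param variants data.frame with columns chrom, pos, id, ref, alt.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)), collapse = "\t")),
             con)
  gt <- matrix("./.", nrow(variants), nrow(genotypes))
  ok <- !is.na(t(genotypes))
  gt[ok] <- gt_codes[as.character(t(genotypes))[ok]]
  lines <- paste(variants$chrom, format(variants$pos, scientific = FALSE, trim = TRUE),
                 variants$id, variants$ref, variants$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses GT fields into dosages in \{0, 1, 2\} (`NA` for missing calls such
#' as `./.`). Multi-allelic records are rejected. Phased separators (`|`)
#' are accepted. Parsing is delegated to \pkg{vcfR}.
#'
#' @param path a VCF file.
#' @return list with `genotypes` (n x m dosage matrix, samples in rows),
#'   `variants` (data.frame: chrom, pos, id, ref, alt, maf, missingness).
#' @export
read_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic record at ",
         fix$ID[grepl(",", fix$ALT, fixed = TRUE)][1],
         "; only bi-allelic sites are supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  unknown <- !is.na(clean) & is.na(dos) & clean != "./."
  if (any(unknown)) stop("unrecognized GT value '", clean[unknown][1], "'")
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- fix$ID
  maf <- apply(geno, 2, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    if (is.nan(f)) NA_real_ else min(f, 1 - f)
  })
  variants <- data.frame(chrom = fix$CHROM,
                         pos = as.numeric(fix$POS),
                         id = fix$ID,
                         ref = fix$REF,
                         alt = fix$ALT,
                         maf = unname(maf),
                         missingness = unname(colMeans(is.na(geno))),
                         stringsAsFactors = FALSE)
  list(genotypes = geno, variants = variants)
}

#' Dosage-matrix alternative to VCF
#'
#' Writes/reads the dosage matrix as TSV: columns chrom, pos, id, ref, alt,
#' then one column per sample. Missing dosages are written as `NA`.
#'
#' @param genotypes n x m dosage matrix (rownames = sample ids).
#' @param variants variant table (chrom, pos, id, ref, alt).
#' @param path a TSV file.
#' @return `write_dosage_matrix`: `path`, invisibly. `read_dosage_matrix`:
#'   list with `genotypes` and `variants` as in [read_genotypes()].
#' @export
write_dosage_matrix <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  out <- cbind(variants[, c("chrom", "pos", "id", "ref", "alt")],
               as.data.frame(t(genotypes)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("chrom", "pos", "id", "ref", "alt")
  missing <- setdiff(meta, names(x))
  if (length(missing))
    stop("dosage matrix: missing column(s) ", paste(missing, collapse = ", "))
  geno <- t(as.matrix(x[, setdiff(names(x), meta), drop = FALSE]))
  colnames(geno) <- x$id
  storage.mode(geno) <- "integer"
  list(genotypes = geno,
       variants = x[, meta])
}
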