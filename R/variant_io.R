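# VCF ingestion and the haploid genotype matrix.
#
# The Y chromosome of males is hemizygous, so genotypes collapse to three
# states: 0 (REF allele), 1 (ALT allele), NA (no-call). Heterozygous diploid
# encodings ("0/1") cannot occur at a clean hemizygous locus and are treated
# as no-calls (mapping artifacts), never resolved to a majority allele.

MISSING <- NA_integer_

#' Read a multi-sample VCF into a light record table
#'
#' Thin wrapper around \code{VariantAnnotation::readVcf}; only CHROM, POS, ID,
#' REF, ALT and the GT subfield are retained. Works for plain or bgzipped
#' VCF v4.2+.
#'
#' @param path VCF file path.
#' @return an object of class \code{vcf_table}: \code{records} data.frame
#'   (chrom, pos, id, ref, list-column alts) aligned with a character
#'   \code{gt} matrix (records x samples).
#' @export
read_vcf_table <- function(path) {
  if (!file.exists(path)) yis_parse_error("VCF not found: %s", path)
  vcf <- tryCatch(VariantAnnotation::readVcf(path, genome = "unknown"),
                  error = function(e) yis_parse_error("failed to parse VCF %s: %s",
                                                      path, conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  nm <- names(rr)
  # readVcf substitutes "chrom:pos_ref/alt" names for records with no ID
  auto <- paste0(chrom, ":", pos, "_", ref, "/",
                 vapply(alts, paste, character(1), collapse = ","))
  id <- ifelse(is.null(nm) | nm == auto, NA_character_, nm)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) yis_format_error("VCF carries no GT FORMAT field: %s", path)
  gt <- matrix(as.character(gt), nrow = length(ref),
               dimnames = list(NULL, colnames(gt)))
  rec <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                    stringsAsFactors = FALSE)
  rec$alts <- unname(alts)
  new_vcf_table(rec, gt)
}

new_vcf_table <- function(records, gt) {
  stopifnot(nrow(records) == nrow(gt))
  structure(list(records = records, gt = gt, samples = colnames(gt)),
            class = "vcf_table")
}

#' @export
print.vcf_table <- function(x, ...) {
  cat(sprintf("<vcf_table> %d records x %d samples\n",
              nrow(x$records), length(x$samples)))
  invisible(x)
}

#' Classify variant records
#'
#' Partition of all records into five classes. \code{biallelic_indel}: exactly
#' one ALT, both alleles pure ACGT, unequal lengths. \code{snp}: one ALT, both
#' length 1. \code{mnp}: one ALT, equal lengths > 1. \code{multiallelic}:
#' more than one ALT. \code{symbolic_or_other}: breakends, symbolic alleles,
#' \code{*} or any non-ACGT character.
#'
#' @param ref character vector of REF alleles (uppercase).
#' @param alts list of character vectors of ALT alleles, one per record.
#' @return character vector of classes, one per record.
#' @export
classify_variant <- function(ref, alts) {
  if (!is.list(alts)) alts <- as.list(alts)
  if (length(ref) != length(alts))
    yis_contract_error("ref and alts lengths differ")
  n_alt <- lengths(alts)
  alt1 <- vapply(alts, function(a) if (length(a) >= 1) a[1] else "", character(1))
  if (any(ref == "") || any(alt1 == "" & n_alt > 0) || any(n_alt == 0))
    yis_contract_error("empty allele string in variant record")
  cls <- rep("symbolic_or_other", length(ref))
  multi <- n_alt > 1
  acgt <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt1)
  cls[multi] <- "multiallelic"
  one <- !multi & acgt
  cls[one & nchar(ref) == 1 & nchar(alt1) == 1] <- "snp"
  cls[one & nchar(ref) == nchar(alt1) & nchar(ref) > 1] <- "mnp"
  cls[one & nchar(ref) != nchar(alt1)] <- "biallelic_indel"
  cls
}

#' Collapse raw GT strings to haploid 0/1/NA codes
#'
#' \code{"0"}/\code{"0/0"}/\code{"0|0"} -> 0; \code{"1"}/\code{"1/1"}/
#' \code{"1|1"} -> 1; heterozygous diploid encodings and anything containing
#' \code{"."} -> \code{NA}. An allele index >= 2 is a contract violation: the
#' record was not bi-allelic.
#'
#' @param gt character vector of raw GT fields.
#' @return integer vector over \{0, 1, NA\}.
#' @export
collapse_genotype <- function(gt) {
  vapply(strsplit(as.character(gt), "[/|]"), function(al) {
    if (any(al == ".") || length(al) == 0) return(MISSING)
    if (any(!al %in% c("0", "1")))
      yis_contract_error("allele index >= 2 in GT '%s' on a record passed as bi-allelic",
                         paste(al, collapse = "/"))
    u <- unique(al)
    if (length(u) > 1) return(MISSING)  # heterozygous: impossible on clean chrY
    as.integer(u)
  }, integer(1))
}

#' Build the haploid genotype matrix
#'
#' Retains records of the requested class(es), optionally drops records whose
#' reference span overlaps a BED mask, and collapses GT fields to 0/1/NA.
#' Input order is preserved. Counts of records seen / retained / masked are
#' logged to stderr and attached as the \code{"counts"} attribute.
#'
#' @param vt a \code{vcf_table}.
#' @param keep_class character vector of classes to retain
#'   (default \code{"biallelic_indel"}).
#' @param mask optional BED file path or \code{GRanges} of intervals to
#'   exclude (BED is 0-based half-open; handled by \code{rtracklayer}).
#'   Masking requires position-sorted input.
#' @return an object of class \code{geno_matrix}: \code{variants} data.frame
#'   (key, chrom, pos, id, ref, alt, class), \code{samples}, and an integer
#'   \code{calls} matrix (variants x samples) over \{0, 1, NA\}.
#' @export
build_genotype_matrix <- function(vt, keep_class = "biallelic_indel", mask = NULL) {
  stopifnot(inherits(vt, "vcf_table"))
  rec <- vt$records
  if (nrow(rec) > 0 && length(unique(rec$chrom)) > 1)
    yis_format_error("all records must share one contig; saw: %s",
                     paste(unique(rec$chrom), collapse = ", "))
  cls <- classify_variant(rec$ref, rec$alts)
  keep <- cls %in% keep_class
  n_masked <- 0L
  if (!is.null(mask) && nrow(rec) > 0) {
    if (is.unsorted(rec$pos))
      yis_format_error("masking requires position-sorted input")
    if (is.character(mask)) mask <- rtracklayer::import(mask, format = "BED")
    span <- GenomicRanges::GRanges(rec$chrom,
                                   IRanges::IRanges(rec$pos, rec$pos + nchar(rec$ref) - 1L))
    hit <- IRanges::overlapsAny(span, mask)
    n_masked <- sum(keep & hit)
    keep <- keep & !hit
  }
  idx <- which(keep)
  alt1 <- vapply(rec$alts, function(a) a[1], character(1))
  variants <- data.frame(
    key = paste(rec$chrom, rec$pos, rec$ref, alt1, sep = ":")[idx],
    chrom = rec$chrom[idx], pos = rec$pos[idx], id = rec$id[idx],
    ref = rec$ref[idx], alt = alt1[idx], class = cls[idx],
    stringsAsFactors = FALSE)
  calls <- matrix(MISSING, nrow = length(idx), ncol = length(vt$samples),
                  dimnames = list(variants$key, vt$samples))
  if (length(idx) > 0)
    calls[] <- collapse_genotype(vt$gt[idx, , drop = FALSE])
  # indels whose REF/ALT share no leading anchor base hint at non-normalized input
  ind <- variants$class == "biallelic_indel"
  unanchored <- ind & substr(variants$ref, 1, 1) != substr(variants$alt, 1, 1)
  if (any(unanchored))
    warning(sprintf("%d indel record(s) lack a shared leading anchor base (input may not be left-normalized): %s",
                    sum(unanchored), paste(utils::head(variants$key[unanchored], 5), collapse = ", ")))
  counts <- list(seen = nrow(rec), kept = length(idx), masked = n_masked,
                 by_class = table(factor(cls, levels = c("snp", "biallelic_indel",
                                                         "multiallelic", "mnp",
                                                         "symbolic_or_other"))))
  yis_log("build_genotype_matrix: %d seen, %d retained (%s), %d masked",
          counts$seen, counts$kept, paste(keep_class, collapse = "+"), n_masked)
  gm <- structure(list(variants = variants, samples = vt$samples, calls = calls),
                  class = "geno_matrix")
  attr(gm, "counts") <- counts
  gm
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d variants x %d samples (%.1f%% called)\n",
              nrow(x$variants), length(x$samples),
              if (length(x$calls) > 0) 100 * mean(!is.na(x$calls)) else 100))
  invisible(x)
}

#' Export a genotype matrix as TSV
#'
#' One row per variant: the variant key, then one 0/1/. column per sample.
#'
#' @param gm a \code{geno_matrix}.
#' @param path output file.
#' @export
write_genotype_matrix <- function(gm, path) {
  m <- gm$calls
  chr <- ifelse(is.na(m), ".", as.character(m))
  out <- data.frame(variant_key = gm$variants$key, chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("variant_key", gm$samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
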