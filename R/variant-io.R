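#' Hard-filter thresholds for variant records
#'
#' Mirrors the GATK VariantFiltration expressions used in heavy-ion
#' mutagenesis resequencing: records with `QD < 2.0 || FS > 60.0 ||
#' MQ < 40.0` or sample `GQ < 20` are removed; InDels longer than
#' `indel_len_max` bp are excluded downstream.
#'
#' @param qd_min,fs_max,mq_min,gq_min site/genotype thresholds.
#' @param indel_len_max maximum InDel length retained (bp).
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                              gq_min = 20, indel_len_max = 50) {
  vals <- c(qd_min, fs_max, mq_min, gq_min, indel_len_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_badarg("all thresholds must be finite and positive")
  }
  structure(list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 gq_min = gq_min, indel_len_max = indel_len_max),
            class = "filter_thresholds")
}

#' Read a single-sample VCF into a flat record table
#'
#' Backed by [VariantAnnotation::readVcf()]; multi-allelic records are split
#' into one record per ALT allele (`expand`), coordinates stay 1-based, and
#' INFO QD/FS/MQ and the sample's GT/GQ are extracted (absent annotations
#' become `NA`).
#'
#' @param path VCF 4.x file.
#' @param line_id line identifier attached to every record.
#' @return data.frame with columns line_id, chrom, pos, ref, alt, qd, fs,
#'   mq, gq, gt.
#' @export
read_vcf <- function(path, line_id) {
  if (!file.exists(path)) stop_badarg("VCF not found: ", path)
  v <- tryCatch(VariantAnnotation::readVcf(path),
                error = function(e) stop_badarg("malformed VCF ", path, ": ",
                                                conditionMessage(e)))
  if (ncol(v) < 1) stop_badarg("VCF has no sample column: ", path)
  ve <- VariantAnnotation::expand(v)
  n <- length(ve)
  get_info <- function(field) {
    x <- VariantAnnotation::info(ve)[[field]]
    if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  }
  geno <- VariantAnnotation::geno(ve)
  gq <- if ("GQ" %in% names(geno)) as.integer(geno$GQ[, 1]) else rep(NA_integer_, n)
  gt <- if ("GT" %in% names(geno)) as.character(geno$GT[, 1]) else rep(NA_character_, n)
  rr <- SummarizedExperiment::rowRanges(ve)
  data.frame(line_id = rep(line_id, n),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(ve)),
             alt = as.character(VariantAnnotation::alt(ve)),
             qd = get_info("QD"), fs = get_info("FS"), mq = get_info("MQ"),
             gq = gq, gt = gt, stringsAsFactors = FALSE)
}

#' Apply GATK-style hard filters to variant records
#'
#' Removes records breaching any threshold in `thresholds`; missing (`NA`)
#' annotations pass their filter (the GATK convention for absent
#' annotations). Record order is preserved, and applying the filter twice
#' equals applying it once.
#'
#' @param records record table from [read_vcf()].
#' @param thresholds a [filter_thresholds()].
#' @return the retained records, with attribute `n_removed`.
#' @export
apply_hard_filters <- function(records, thresholds = filter_thresholds()) {
  fail <- (!is.na(records$qd) & records$qd < thresholds$qd_min) |
    (!is.na(records$fs) & records$fs > thresholds$fs_max) |
    (!is.na(records$mq) & records$mq < thresholds$mq_min) |
    (!is.na(records$gq) & records$gq < thresholds$gq_min)
  out <- records[!fail, , drop = FALSE]
  attr(out, "n_removed") <- sum(fail)
  out
}

#' Classify ref/alt allele pairs into SBS / INS / DEL / other
#'
#' VCF-style anchored representation is assumed for InDels. Equal-length
#' multi-base pairs (MNVs) fall outside the two-class SBS/InDel scheme and
#' are labelled `"other"`.
#'
#' @param ref,alt uppercase ACGT allele vectors.
#' @return data.frame with columns `mclass` (`SBS`/`INS`/`DEL`/`other`) and
#'   `indel_len` (`|len(ref) - len(alt)|`; 0 for SBS and other).
#' @export
classify_mutation <- function(ref, alt) {
  check_bases(ref); check_bases(alt)
  if (any(ref == alt)) stop_badarg("ref and alt must differ")
  lr <- nchar(ref); la <- nchar(alt)
  mclass <- ifelse(lr == 1 & la == 1, "SBS",
                   ifelse(la > lr, "INS", ifelse(lr > la, "DEL", "other")))
  indel_len <- ifelse(mclass %in% c("INS", "DEL"), abs(la - lr), 0L)
  data.frame(mclass = mclass, indel_len = as.integer(indel_len),
             stringsAsFactors = FALSE)
}

#' Derive induced mutations by mutant-vs-wild-type subtraction
#'
#' Keeps mutant records whose exact (chrom, pos, ref, alt) key is absent
#' from the wild-type set, classifies them, assigns zygosity from the
#' genotype (1/1 hom, 0/1 het, else unknown), drops MNVs and InDels longer
#' than `thresholds$indel_len_max`, and logs every exclusion class.
#' Duplicate keys within either input are deduplicated with a warning.
#'
#' @param mutant_records,wildtype_records record tables from [read_vcf()]
#'   (typically already hard-filtered).
#' @param thresholds a [filter_thresholds()] (only `indel_len_max` is used).
#' @return data.frame of induced mutations (line_id, chrom, pos, ref, alt,
#'   mclass, indel_len, zygosity) with attribute `log`, a named count
#'   vector: n_mutant, n_shared, n_dedup, n_mnv, n_len_excluded, n_induced.
#' @export
derive_induced <- function(mutant_records, wildtype_records,
                           thresholds = filter_thresholds()) {
  mk <- variant_key(mutant_records$chrom, mutant_records$pos,
                    mutant_records$ref, mutant_records$alt)
  wk <- variant_key(wildtype_records$chrom, wildtype_records$pos,
                    wildtype_records$ref, wildtype_records$alt)
  n_dedup <- sum(duplicated(mk)) + sum(duplicated(wk))
  if (n_dedup > 0) warning(n_dedup, " duplicate variant keys deduplicated")
  mutant_records <- mutant_records[!duplicated(mk), , drop = FALSE]
  mk <- mk[!duplicated(mk)]
  wk <- unique(wk)
  shared <- mk %in% wk
  ind <- mutant_records[!shared, , drop = FALSE]
  cls <- classify_mutation(ind$ref, ind$alt)
  is_mnv <- cls$mclass == "other"
  too_long <- cls$indel_len > thresholds$indel_len_max
  keep <- !is_mnv & !too_long
  out <- data.frame(line_id = ind$line_id, chrom = ind$chrom, pos = ind$pos,
                    ref = ind$ref, alt = ind$alt, mclass = cls$mclass,
                    indel_len = cls$indel_len,
                    zygosity = ifelse(ind$gt %in% "1/1", "hom",
                                      ifelse(ind$gt %in% "0/1", "het", "unknown")),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- c(n_mutant = length(mk), n_shared = sum(shared),
                        n_dedup = n_dedup, n_mnv = sum(is_mnv),
                        n_len_excluded = sum(too_long), n_induced = nrow(out))
  out
}

#' Write / read an induced-mutation TSV
#' @param mutations induced-mutation data.frame from [derive_induced()].
#' @param path TSV path.
#' @return the path ([write_mutations()]) or a data.frame ([read_mutations()]).
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations
#' @export
read_mutations <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
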