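# VCF reading/writing for structural-variant and small-variant callsets.
#
# Internal coordinates are uniformly 0-based half-open; the 1-based VCF
# convention is applied only here, at the file boundary. Writers emit a
# deterministic dialect (fixed header, fixed column and line order) so that
# write -> read -> write is byte-identical, which the synthetic generator
# and the round-trip tests rely on.

SV_CALL_COLUMNS <- c("call_id", "contig", "start", "end", "svtype", "length",
                     "sequence", "support", "depth", "filter", "genotype",
                     "gq", "vaf", "sample_id", "cell_id")

#' Construct a structural-variant call table
#'
#' Builds the canonical SV call data.frame used throughout the package:
#' one row per call, 0-based half-open coordinates (`end == start` for
#' insertion points, `end = start + length` for deletions), supporting-read
#' count and locus depth, genotype, genotype quality and variant allele
#' frequency.
#'
#' @param ... column vectors; any subset of the canonical columns. Missing
#'   columns are filled with `NA` of the right type.
#' @return data.frame with the canonical column set and order.
#' @export
sv_calls <- function(...) {
  args <- list(...)
  n <- if (length(args)) max(vapply(args, length, 1L)) else 0L
  template <- list(call_id = NA_character_, contig = NA_character_,
                   start = NA_integer_, end = NA_integer_,
                   svtype = NA_character_, length = NA_integer_,
                   sequence = NA_character_, support = NA_integer_,
                   depth = NA_integer_, filter = NA_character_,
                   genotype = NA_character_, gq = NA_integer_,
                   vaf = NA_real_, sample_id = NA_character_,
                   cell_id = NA_character_)
  unknown <- setdiff(names(args), names(template))
  if (length(unknown)) stop("unknown SV call column(s): ",
                            paste(unknown, collapse = ", "))
  cols <- lapply(names(template), function(nm) {
    if (nm %in% names(args)) rep_len(args[[nm]], n) else rep(template[[nm]], n)
  })
  names(cols) <- names(template)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

empty_sv_calls <- function() sv_calls()

#' Write structural-variant calls as VCF v4.2
#'
#' One sample per file. `SVTYPE`, `SVLEN` (negative for deletions, per the
#' long-read caller convention), `END`, the supporting-read count and the
#' insertion sequence go in INFO; `GT`, `GQ`, locus depth `DP` and variant
#' allele frequency `AF` go in FORMAT. ALT alleles are symbolic. Records
#' are written sorted by contig order in `layout` (or alphabetically when
#' no layout is given), then start.
#'
#' @param calls SV call table (see [sv_calls()]); must carry a single
#'   `sample_id`.
#' @param path output file.
#' @param layout optional [genome_layout()] used for `##contig` header
#'   lines and contig sort order.
#' @param support_key INFO key used for the supporting-read count.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, layout = NULL, support_key = "SUPPORT") {
  calls <- sv_calls_check(calls)
  sample_id <- unique(calls$sample_id[!is.na(calls$sample_id)])
  if (length(sample_id) > 1L) stop("one sample per VCF; got: ",
                                   paste(sample_id, collapse = ", "))
  if (length(sample_id) == 0L) sample_id <- "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicSV",
    contig_header_lines(calls, layout),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Number of reads supporting the call\">", support_key),
    "##INFO=<ID=SVSEQ,Number=1,Type=String,Description=\"Resolved variant sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the locus\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  calls <- sort_calls(calls, layout)
  body <- character(0)
  if (nrow(calls) > 0L) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      r <- calls[i, ]
      parts <- paste0("SVTYPE=", r$svtype)
      if (!is.na(r$length) && r$svtype != "BND") {
        svlen <- if (r$svtype == "DEL") -r$length else r$length
        parts <- c(parts, paste0("SVLEN=", svlen),
                   paste0("END=", vcf_end(r)))
      }
      if (!is.na(r$support)) parts <- c(parts, paste0(support_key, "=", r$support))
      if (!is.na(r$sequence)) parts <- c(parts, paste0("SVSEQ=", r$sequence))
      paste(parts, collapse = ";")
    }, character(1))
    fmt <- sprintf("%s:%s:%s:%s",
                   ifelse(is.na(calls$genotype), "./.", calls$genotype),
                   ifelse(is.na(calls$gq), ".", as.character(calls$gq)),
                   ifelse(is.na(calls$depth), ".", as.character(calls$depth)),
                   ifelse(is.na(calls$vaf), ".", sprintf("%.6f", calls$vaf)))
    body <- paste(calls$contig, calls$start + 1L, calls$call_id, "N",
                  paste0("<", calls$svtype, ">"), ".",
                  ifelse(is.na(calls$filter), ".", calls$filter),
                  info, "GT:GQ:DP:AF", fmt, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

vcf_end <- function(r) {
  # VCF END is the 1-based inclusive last affected base; for point
  # insertions it equals POS.
  if (r$svtype == "INS") r$start + 1L else r$end
}

contig_header_lines <- function(calls, layout) {
  if (!is.null(layout)) {
    sprintf("##contig=<ID=%s,length=%d>",
            layout$contigs$name, layout$contigs$length)
  } else {
    ctg <- sort(unique(calls$contig[!is.na(calls$contig)]))
    sprintf("##contig=<ID=%s>", ctg)
  }
}

sort_calls <- function(calls, layout = NULL) {
  if (nrow(calls) == 0L) return(calls)
  if (!is.null(layout)) {
    key <- match(calls$contig, layout$contigs$name)
  } else {
    key <- calls$contig
  }
  calls[order(key, calls$start, calls$end, calls$call_id), , drop = FALSE]
}

sv_calls_check <- function(calls) {
  missing <- setdiff(SV_CALL_COLUMNS, names(calls))
  if (length(missing)) stop("SV call table lacks column(s): ",
                            paste(missing, collapse = ", "))
  calls[, SV_CALL_COLUMNS, drop = FALSE]
}

#' Read a structural-variant VCF
#'
#' Parses a VCF v4.2 with SVTYPE-annotated records into the canonical SV
#' call table, converting 1-based positions to the package's 0-based
#' half-open convention. Non-BND records lacking `SVTYPE` or `SVLEN` are
#' skipped with a warning and counted in the parse report attached as the
#' `"parse_report"` attribute.
#'
#' @param path VCF file.
#' @param support_key INFO key holding the supporting-read count
#'   (default `"SUPPORT"`, the dialect of long-read SV callers).
#' @param cell_id optional cell identifier to stamp on every call.
#' @return SV call table with attribute `parse_report` (list with
#'   `n_records`, `n_kept`, `n_skipped`).
#' @export
read_sv_vcf <- function(path, support_key = "SUPPORT", cell_id = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single records come back as a vector
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- empty_sv_calls()
    attr(out, "parse_report") <- list(n_records = 0L, n_kept = 0L, n_skipped = 0L)
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "SVLEN")))
  support <- suppressWarnings(as.integer(vcfR::extract.info(vcf, support_key)))
  svseq <- vcfR::extract.info(vcf, "SVSEQ")
  gt <- vcfR::extract.gt(vcf, "GT")[, 1L]
  gq <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "GQ")[, 1L]))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "DP")[, 1L]))
  af <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "AF")[, 1L]))
  sample_id <- colnames(vcf@gt)[2L]

  bad <- is.na(svtype) | (svtype != "BND" & is.na(svlen))
  if (any(bad)) {
    warning(sum(bad), " record(s) missing SVTYPE or SVLEN skipped in ", path)
  }
  keep <- which(!bad)
  pos <- as.integer(fix$POS[keep])
  type <- svtype[keep]
  len <- abs(svlen[keep])
  start <- pos - 1L
  end <- ifelse(type %in% c("DEL", "INV", "DUP"), start + len, start)
  out <- sv_calls(
    call_id = fix$ID[keep], contig = fix$CHROM[keep],
    start = start, end = as.integer(end), svtype = type,
    length = ifelse(type == "BND", NA_integer_, len),
    sequence = svseq[keep], support = support[keep], depth = dp[keep],
    filter = fix$FILTER[keep], genotype = gt[keep], gq = gq[keep],
    vaf = af[keep], sample_id = sample_id, cell_id = cell_id)
  attr(out, "parse_report") <- list(n_records = nrow(fix),
                                    n_kept = length(keep),
                                    n_skipped = sum(bad))
  out
}

SMALL_VARIANT_COLUMNS <- c("variant_id", "contig", "pos", "ref", "alt",
                           "filter", "genotype", "gq", "depth", "alt_support",
                           "sample_id", "cell_id")

#' Construct a small-variant (SNV/indel) table
#'
#' `pos` is 1-based (VCF convention kept for point variants); alleles are
#' literal sequences shorter than 50 bp, the conventional boundary with
#' structural variants.
#'
#' @param ... column vectors (subset of the canonical columns).
#' @return data.frame with the canonical small-variant columns.
#' @export
small_variants <- function(...) {
  args <- list(...)
  n <- if (length(args)) max(vapply(args, length, 1L)) else 0L
  template <- list(variant_id = NA_character_, contig = NA_character_,
                   pos = NA_integer_, ref = NA_character_,
                   alt = NA_character_, filter = NA_character_,
                   genotype = NA_character_, gq = NA_integer_,
                   depth = NA_integer_, alt_support = NA_integer_,
                   sample_id = NA_character_, cell_id = NA_character_)
  unknown <- setdiff(names(args), names(template))
  if (length(unknown)) stop("unknown small-variant column(s): ",
                            paste(unknown, collapse = ", "))
  cols <- lapply(names(template), function(nm) {
    if (nm %in% names(args)) rep_len(args[[nm]], n) else rep(template[[nm]], n)
  })
  names(cols) <- names(template)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write small variants as VCF v4.2
#' @param calls small-variant table (see [small_variants()]).
#' @param path output file.
#' @param layout optional [genome_layout()] for contig headers and order.
#' @return `path`, invisibly.
#' @export
write_small_vcf <- function(calls, path, layout = NULL) {
  stopifnot(all(SMALL_VARIANT_COLUMNS %in% names(calls)))
  sample_id <- unique(calls$sample_id[!is.na(calls$sample_id)])
  if (length(sample_id) > 1L) stop("one sample per VCF")
  if (length(sample_id) == 0L) sample_id <- "SAMPLE"
  fake <- data.frame(contig = calls$contig, start = calls$pos - 1L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicSV",
    if (!is.null(layout)) sprintf("##contig=<ID=%s,length=%d>",
                                  layout$contigs$name, layout$contigs$length)
    else sprintf("##contig=<ID=%s>", sort(unique(calls$contig))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the locus\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Reads supporting the alternate allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  ord <- order(if (!is.null(layout)) match(calls$contig, layout$contigs$name)
               else calls$contig, calls$pos, calls$variant_id)
  calls <- calls[ord, , drop = FALSE]
  body <- character(0)
  if (nrow(calls) > 0L) {
    fmt <- sprintf("%s:%s:%s:%s",
                   ifelse(is.na(calls$genotype), "./.", calls$genotype),
                   ifelse(is.na(calls$gq), ".", as.character(calls$gq)),
                   ifelse(is.na(calls$depth), ".", as.character(calls$depth)),
                   ifelse(is.na(calls$alt_support), ".",
                          as.character(calls$alt_support)))
    body <- paste(calls$contig, calls$pos, calls$variant_id, calls$ref,
                  calls$alt, ".",
                  ifelse(is.na(calls$filter), ".", calls$filter),
                  ".", "GT:GQ:DP:AD", fmt, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a small-variant VCF written by [write_small_vcf()] or compatible
#' @param path VCF file.
#' @param cell_id optional cell identifier to stamp on every record.
#' @return small-variant table.
#' @export
read_small_vcf <- function(path, cell_id = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)
  if (is.null(fix) || nrow(fix) == 0L) return(small_variants())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, "GT")[, 1L]
  gq <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "GQ")[, 1L]))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "DP")[, 1L]))
  ad <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, "AD")[, 1L]))
  small_variants(variant_id = fix$ID, contig = fix$CHROM,
                 pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                 filter = fix$FILTER, genotype = gt, gq = gq, depth = dp,
                 alt_support = ad, sample_id = colnames(vcf@gt)[2L],
                 cell_id = cell_id)
}
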