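#' @include profiles.R
NULL

#' Write a sample profile as single-sample VCF 4.2
#'
#' Genomic coordinates come from the gene model; indels are left-anchored
#' with a padding base prepended, the VCF 4.2 representation. Each record
#' carries the originating HGVS c. label in \code{INFO/HGVSC} so that
#' notation round-trips exactly (including bracketed repeat insertions that
#' genomic coordinates alone cannot express). When a reference sequence is
#' supplied, padding and deleted bases are taken from it; otherwise \code{N}
#' is used for bases the HGVS label does not state.
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param model a \linkS4class{GeneModel} with genomic anchoring.
#' @param path output file path.
#' @param reference optional reference sequence (as accepted by
#'   \code{\link{insilicoPcr}}) on the model's contig.
#' @return invisibly, the path.
#' @export
writeProfileVcf <- function(profile, model, path, reference = NULL) {
  refSeq <- if (!is.null(reference)) .asDNAString(reference) else NULL
  baseAt <- function(g, n = 1L) {
    if (is.null(refSeq)) return(strrep("N", n))
    as.character(Biostrings::subseq(refSeq, g, g + n - 1L))
  }
  k <- profile@calls
  rows <- lapply(seq_len(nrow(k)), function(i) {
    r <- k[i, ]
    v <- parseHgvsC(r$hgvs_c)
    gStart <- cToGenomic(.posLabel(v$anchor, v$offset), model)
    gEnd <- cToGenomic(.posLabel(v$anchor2, v$offset2), model)
    if (v$kind == "substitution") {
      pos <- gStart; ref <- v$ref; alt <- v$alt
    } else if (v$kind == "deletion") {
      pos <- gStart - 1L
      del <- if (nzchar(v$ref)) v$ref else baseAt(gStart, gEnd - gStart + 1L)
      pad <- baseAt(pos)
      ref <- paste0(pad, del); alt <- pad
    } else if (v$kind == "insertion") {
      pos <- gStart
      pad <- baseAt(pos)
      ref <- pad; alt <- paste0(pad, v$alt)
    } else if (v$kind == "duplication") {
      pos <- gStart
      ref <- if (nzchar(v$ref)) v$ref else baseAt(gStart, gEnd - gStart + 1L)
      alt <- paste0(ref, ref)
    } else {                                   # delins
      pos <- gStart - 1L
      pad <- baseAt(pos)
      ref <- paste0(pad, baseAt(gStart, gEnd - gStart + 1L))
      alt <- paste0(pad, v$alt)
    }
    gt <- switch(r$zygosity, hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 ambiguous = "./.")
    data.frame(pos = pos, ref = ref, alt = alt,
               info = paste0("HGVSC=", r$hgvs_c),
               gt = gt, dp = r$depth, af = r$alt_fraction)
  })
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               info = character(0), gt = character(0), dp = integer(0),
               af = numeric(0))
  rec <- rec[order(rec$pos, rec$ref, rec$alt), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=aboseq",
    paste0("##contig=<ID=", model@contig,
           if (!is.null(refSeq)) paste0(",length=", length(refSeq)) else "",
           ">"),
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS c. notation of the call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate read fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", profile@sampleId, sep = "\t"))
  body <- if (nrow(rec)) paste(model@contig, rec$pos, ".", rec$ref, rec$alt,
                               ".", "PASS", rec$info, "GT:DP:AF",
                               paste(rec$gt, rec$dp, rec$af, sep = ":"),
                               sep = "\t") else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-sample VCF 4.2 into a SampleProfile
#'
#' Records must lie on the model's contig; genomic coordinates are converted
#' back to HGVS c. notation (the \code{INFO/HGVSC} annotation written by
#' \code{\link{writeProfileVcf}} is trusted when present, after a positional
#' consistency check). Multi-sample files and multiallelic records are
#' rejected.
#'
#' @param path VCF file path.
#' @param model a \linkS4class{GeneModel}.
#' @param minDepth see \code{\link{SampleProfile}}.
#' @return a \linkS4class{SampleProfile}.
#' @export
readProfileVcf <- function(path, model, minDepth = 50L) {
  hdr <- VariantAnnotation::scanVcfHeader(path)
  smp <- VariantAnnotation::samples(hdr)
  if (length(smp) != 1L)
    stop("expected a single-sample VCF, found ", length(smp), " samples")
  sc <- VariantAnnotation::scanVcf(path)[[1]]
  gr <- as.data.frame(sc$rowRanges)
  n <- nrow(gr)
  if (n == 0L)
    return(SampleProfile(smp, data.frame(hgvs_c = character(0),
                                         zygosity = character(0),
                                         depth = integer(0),
                                         alt_fraction = numeric(0)),
                         minDepth = minDepth))
  chrom <- as.character(gr$seqnames)
  if (any(chrom != model@contig))
    stop("contig mismatch: VCF has '", unique(chrom[chrom != model@contig])[1],
         "', model expects '", model@contig, "'")
  nAlt <- vapply(sc$ALT, length, integer(1))
  if (any(nAlt != 1L))
    stop("multiallelic record(s) at POS ",
         paste(gr$start[nAlt != 1L], collapse = ", "),
         "; split records are not accepted")
  ref <- as.character(sc$REF)
  alt <- vapply(sc$ALT, function(a) as.character(a)[1], character(1))
  hgvsInfo <- sc$INFO$HGVSC
  hgvs <- character(n)
  for (i in seq_len(n)) {
    lab <- if (!is.null(hgvsInfo)) as.character(hgvsInfo[[i]])[1] else NA_character_
    if (!is.na(lab) && nzchar(lab)) {
      hgvs[i] <- lab
    } else {
      hgvs[i] <- .hgvsFromRecord(gr$start[i], ref[i], alt[i], model)
    }
  }
  gt <- as.character(sc$GENO$GT[, 1])
  zyg <- vapply(gt, function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/")[[1]]
    if (any(a == ".")) return("ambiguous")
    nAltA <- sum(a != "0")
    if (nAltA == 0L) "hom_ref" else if (nAltA == length(a)) "hom_alt" else "het"
  }, character(1))
  dp <- if (!is.null(sc$GENO$DP)) as.integer(sc$GENO$DP[, 1]) else rep(NA_integer_, n)
  af <- if (!is.null(sc$GENO$AF)) as.numeric(sc$GENO$AF[, 1]) else rep(NA_real_, n)
  dp[is.na(dp)] <- 0L
  af[is.na(af)] <- ifelse(zyg[is.na(af)] == "hom_alt", 1, 0.5)
  SampleProfile(smp,
                data.frame(hgvs_c = hgvs, zygosity = unname(zyg),
                           depth = dp, alt_fraction = af,
                           stringsAsFactors = FALSE),
                minDepth = minDepth)
}

# Reconstruct an HGVS c. label from a left-anchored VCF record.
.hgvsFromRecord <- function(pos, ref, alt, model) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    p <- genomicToC(pos, model)
    return(paste0("c.", .fmtPos(p$anchor, p$offset), ref, ">", alt))
  }
  if (nchar(ref) > 1L && nchar(alt) == 1L && startsWith(ref, alt)) {
    del <- substring(ref, 2L)
    p1 <- genomicToC(pos + 1L, model)
    if (nchar(del) == 1L)
      return(paste0("c.", .fmtPos(p1$anchor, p1$offset), "del",
                    if (del != "N") del else ""))
    p2 <- genomicToC(pos + nchar(ref) - 1L, model)
    return(paste0("c.", .fmtPos(p1$anchor, p1$offset), "_",
                  .fmtPos(p2$anchor, p2$offset), "del"))
  }
  if (nchar(alt) > 1L && nchar(ref) == 1L && startsWith(alt, ref)) {
    ins <- substring(alt, 2L)
    p1 <- genomicToC(pos, model)
    p2 <- genomicToC(pos + 1L, model)
    return(paste0("c.", .fmtPos(p1$anchor, p1$offset), "_",
                  .fmtPos(p2$anchor, p2$offset), "ins", ins))
  }
  # general delins
  p1 <- genomicToC(pos + 1L, model)
  p2 <- genomicToC(pos + nchar(ref) - 1L, model)
  span <- if (nchar(ref) == 2L) .fmtPos(p1$anchor, p1$offset) else
    paste0(.fmtPos(p1$anchor, p1$offset), "_", .fmtPos(p2$anchor, p2$offset))
  paste0("c.", span, "delins", substring(alt, 2L))
}
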