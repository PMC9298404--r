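#' @include hgvs.R
NULL

#' Construct a GeneModel
#'
#' @param exonEnds integer vector of cumulative cDNA exon end coordinates
#'   (exons are contiguous in cDNA space, the first starts at c.1).
#' @param intronLengths integer vector of intron lengths in bp (one per
#'   inter-exon gap).
#' @param contig working contig name for genomic coordinates.
#' @param cdsGenomicStart 1-based plus-strand genomic coordinate of c.1.
#' @return a validated \linkS4class{GeneModel}.
#' @export
GeneModel <- function(exonEnds, intronLengths, contig = "ABO_ref",
                      cdsGenomicStart = 1L) {
  new("GeneModel",
      exonEnds = as.integer(exonEnds),
      intronLengths = as.integer(intronLengths),
      contig = as.character(contig),
      cdsGenomicStart = as.integer(cdsGenomicStart))
}

#' The bundled ABO gene model
#'
#' Seven exons with cDNA spans 1-28, 29-98, 99-155, 156-203, 204-239,
#' 240-374 and 375-1065 (1062 bp of coding sequence plus the stop codon,
#' following ISBT numbering practice). The intron lengths are fixture
#' values for the synthetic reference: each is long enough that every
#' bundled intronic variant is nearer its own anchor exon than the opposite
#' one, so c.-to-genomic conversion round-trips exactly; intron 1 is 13 kb,
#' in line with the real gene where intron 1 dominates the ~20 kb span.
#' Substitute a model read from \code{\link{readGeneModel}} to work against
#' a real reference assembly.
#'
#' @return a \linkS4class{GeneModel}.
#' @examples
#' defaultGeneModel()
#' @export
defaultGeneModel <- function() {
  GeneModel(
    exonEnds = c(28L, 98L, 155L, 203L, 239L, 374L, 1065L),
    intronLengths = c(13000L, 760L, 1200L, 1480L, 600L, 1000L),
    contig = "ABO_ref",
    cdsGenomicStart = 501L
  )
}

#' Read a GeneModel from a YAML/JSON config file
#'
#' The config must provide \code{exon_ends} (or \code{exon_spans} as a list
#' of [start, end] pairs), \code{intron_lengths}, \code{contig} and
#' \code{cds_genomic_start}.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return a validated \linkS4class{GeneModel}.
#' @export
readGeneModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  ends <- if (!is.null(cfg$exon_ends)) {
    as.integer(unlist(cfg$exon_ends))
  } else if (!is.null(cfg$exon_spans)) {
    spans <- do.call(rbind, lapply(cfg$exon_spans, as.integer))
    if (spans[1, 1] != 1L || any(spans[-1, 1] != head(spans[, 2], -1L) + 1L))
      stop("exon spans must be contiguous in cDNA space and start at 1")
    spans[, 2]
  } else stop("config must provide exon_ends or exon_spans")
  GeneModel(ends, as.integer(unlist(cfg$intron_lengths)),
            contig = cfg$contig %||% "ABO_ref",
            cdsGenomicStart = cfg$cds_genomic_start %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a model can place a set of variants
#'
#' Verifies that every intron used by the variants is longer than the sum of
#' the largest plus offset and the largest minus offset occurring in it, the
#' condition for the model-free gene-axis order to agree with genomic order.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param hgvs character vector of HGVS c. labels.
#' @return invisibly TRUE; errors otherwise.
#' @export
validateModelForVariants <- function(model, hgvs) {
  v <- parseHgvsC(hgvs)
  region <- classifyRegion(v, model)
  intronic <- grepl("^intron", region)
  if (any(intronic)) {
    idx <- as.integer(sub("intron ", "", region[intronic]))
    off <- v$offset[intronic]
    for (i in unique(idx)) {
      plus <- max(c(0L, off[idx == i & off > 0]))
      minus <- max(c(0L, -off[idx == i & off < 0]))
      if (model@intronLengths[i] <= plus + minus)
        stop("intron ", i, " length (", model@intronLengths[i],
             ") cannot hold offsets +", plus, " and -", minus)
    }
  }
  invisible(TRUE)
}
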