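#' @include aboseq-package.R
NULL

#' GeneModel: exon/intron structure of the ABO transcript
#'
#' Anchors all HGVS c. arithmetic. Exons are contiguous in cDNA space
#' (span k+1 starts one base after span k ends; the first span starts at
#' c.1), so the structure is fully described by the exon end coordinates.
#' Intron lengths are in genomic bp, one per inter-exon gap; they must be
#' long enough that no plus-offset and minus-offset position used in the
#' same intron can collide.
#'
#' @slot exonEnds integer, cumulative cDNA end coordinate of each exon.
#' @slot intronLengths integer, genomic length (bp) of each intron.
#' @slot contig character, name of the working contig for genomic output.
#' @slot cdsGenomicStart integer, 1-based plus-strand genomic coordinate of
#'   c.1 on the working contig.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    exonEnds = "integer",
    intronLengths = "integer",
    contig = "character",
    cdsGenomicStart = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  e <- object@exonEnds
  i <- object@intronLengths
  if (length(e) < 2L) msg <- c(msg, "need at least two exons")
  if (any(diff(e) <= 0L)) msg <- c(msg, "exon ends must strictly increase")
  if (any(e < 1L)) msg <- c(msg, "exon ends must be positive")
  if (length(i) != length(e) - 1L)
    msg <- c(msg, "number of intron lengths must equal number of exons - 1")
  if (any(i <= 0L)) msg <- c(msg, "intron lengths must be positive")
  if (length(object@contig) != 1L || !nzchar(object@contig))
    msg <- c(msg, "contig must be a single non-empty string")
  if (length(object@cdsGenomicStart) != 1L || object@cdsGenomicStart < 1L)
    msg <- c(msg, "cdsGenomicStart must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' SampleProfile: per-variant zygosity calls for one specimen
#'
#' The pipeline's primary input: an ordered collection of zygosity calls
#' (hom_ref / het / hom_alt with read depth and alt-read fraction), keyed
#' by the canonical HGVS c. label and sorted along the gene axis.
#'
#' @slot sampleId character scalar.
#' @slot calls data.frame with columns \code{hgvs_c}, \code{zygosity},
#'   \code{depth}, \code{alt_fraction}, \code{low_coverage} plus parsed
#'   position columns \code{anchor}, \code{offset}, \code{kind} and the
#'   gene-axis sort key \code{key}.
#' @slot metadata list of free-form key/value annotations (phenotype label,
#'   cohort group, truth flags from the simulator).
#' @exportClass SampleProfile
setClass("SampleProfile",
  representation(
    sampleId = "character",
    calls = "data.frame",
    metadata = "list"
  )
)

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be scalar")
  need <- c("hgvs_c", "zygosity", "depth", "alt_fraction", "low_coverage", "key")
  miss <- setdiff(need, names(object@calls))
  if (length(miss))
    msg <- c(msg, paste0("calls is missing columns: ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(object@calls$hgvs_c))
      msg <- c(msg, "duplicate variant rows in calls")
    if (is.unsorted(object@calls$key))
      msg <- c(msg, "calls must be sorted by gene-axis position")
    bad <- setdiff(unique(object@calls$zygosity),
                   c("hom_ref", "het", "hom_alt", "ambiguous"))
    if (length(bad))
      msg <- c(msg, paste0("unknown zygosity token(s): ", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' AlleleDefinition: one named ABO allele
#'
#' Defining coding variants plus (optionally) intronic haplotype variants,
#' both as canonical HGVS c. labels. Subtype alleles are expressed as deltas
#' on a parent allele (e.g. ABO*B3.10 = ABO*B.01 + c.28G>A); parent chains
#' are resolved by the accessors and must be acyclic.
#'
#' @slot name character, ISBT-style allele label.
#' @slot coding character vector of HGVS c. labels (exonic).
#' @slot intronic character vector of HGVS c. labels (intronic).
#' @slot parent character, name of the base allele or NA.
#' @slot subtype logical, whether the allele defines a weak/subtype phenotype.
#' @exportClass AlleleDefinition
setClass("AlleleDefinition",
  representation(
    name = "character",
    coding = "character",
    intronic = "character",
    parent = "character",
    subtype = "logical"
  ),
  prototype(parent = NA_character_, subtype = FALSE)
)

#' AlleleTable: collection of allele definitions
#'
#' @slot alleles named list of \linkS4class{AlleleDefinition}.
#' @slot reference character, name of the mapping reference allele; its
#'   variant sets must be empty (all variants are expressed relative to it).
#' @exportClass AlleleTable
setClass("AlleleTable",
  representation(alleles = "list", reference = "character")
)

setValidity("AlleleTable", function(object) {
  msg <- character()
  nm <- vapply(object@alleles, function(a) a@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "allele names must be unique")
  if (!identical(names(object@alleles), unname(nm)))
    msg <- c(msg, "alleles list must be named by allele name")
  if (!(object@reference %in% nm))
    msg <- c(msg, "reference allele not present in table")
  else {
    ref <- object@alleles[[object@reference]]
    if (length(ref@coding) || length(ref@intronic))
      msg <- c(msg, "reference allele must have empty variant sets")
  }
  for (a in object@alleles) {
    seen <- a@name; p <- a@parent
    while (!is.na(p)) {
      if (p %in% seen) { msg <- c(msg, paste0("cyclic parent chain at ", a@name)); break }
      if (!(p %in% nm)) { msg <- c(msg, paste0("unknown parent '", p, "' of ", a@name)); break }
      seen <- c(seen, p); p <- object@alleles[[p]]@parent
    }
  }
  if (length(msg)) msg else TRUE
})

#' MarkerCatalog: allele-specific intronic SNV sets
#'
#' One marker set per allele lineage, derived from a homozygote panel (or
#' bundled from the published catalog). Marker sets are pairwise disjoint by
#' construction: a marker is a variant present on every haplotype of one
#' lineage and absent from all others in the panel.
#'
#' @slot markers named list, allele name -> character vector of HGVS c. labels.
#' @slot provenance data.frame with columns \code{allele}, \code{hgvs_c},
#'   \code{n_support}, \code{n_refute} (supporting/refuting sample counts).
#' @slot qualityWarnings data.frame naming samples with heterozygous calls at
#'   candidate marker positions (columns \code{sample_id}, \code{hgvs_c}).
#' @exportClass MarkerCatalog
setClass("MarkerCatalog",
  representation(
    markers = "list",
    provenance = "data.frame",
    qualityWarnings = "data.frame"
  )
)

setValidity("MarkerCatalog", function(object) {
  msg <- character()
  all_m <- unlist(object@markers, use.names = FALSE)
  if (anyDuplicated(all_m))
    msg <- c(msg, "marker sets must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' RecombinationEvent: an inferred intragenic recombination
#'
#' One maximal run of discordant marker zygosity explained by substituting a
#' single donor allele onto one haplotype. The breakpoint interval is the gap
#' between the last informative variant inside the donor segment and the
#' first informative variant outside it (NA on a side where the segment runs
#' to the end of the modeled gene).
#'
#' @slot sampleId character.
#' @slot status character, one of \code{ok}, \code{low_confidence},
#'   \code{untypical}.
#' @slot donor character, donor allele name(s) consistent with the segment
#'   (empty for untypical reports).
#' @slot replaced character, which called allele the donor substitutes.
#' @slot segments data.frame with columns \code{from}, \code{to} (HGVS c.
#'   labels of the first/last informative position) and \code{donor}.
#' @slot breakpointInterval character of length 2: (5' flank, 3' flank)
#'   HGVS labels, NA where the segment reaches a gene end.
#' @slot runLength integer, number of informative discordant positions
#'   supporting the donor segment.
#' @slot notes character, diagnostic messages (offending positions for
#'   untypical patterns).
#' @exportClass RecombinationEvent
setClass("RecombinationEvent",
  representation(
    sampleId = "character",
    status = "character",
    donor = "character",
    replaced = "character",
    segments = "data.frame",
    breakpointInterval = "character",
    runLength = "integer",
    notes = "character"
  )
)

setValidity("RecombinationEvent", function(object) {
  msg <- character()
  if (!object@status %in% c("ok", "low_confidence", "untypical"))
    msg <- c(msg, "status must be ok, low_confidence or untypical")
  if (length(object@breakpointInterval) != 2L)
    msg <- c(msg, "breakpointInterval must have length 2")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  spans <- exonSpans(object)
  cat("GeneModel on contig '", object@contig, "': ",
      nrow(spans), " exons, cDNA length ", max(spans$end),
      ", c.1 at g.", object@cdsGenomicStart, "\n", sep = "")
  cat("  intron lengths: ", paste(object@intronLengths, collapse = ", "),
      " bp\n", sep = "")
})

setMethod("show", "SampleProfile", function(object) {
  z <- table(factor(object@calls$zygosity,
                    levels = c("hom_ref", "het", "hom_alt", "ambiguous")))
  cat("SampleProfile '", object@sampleId, "': ", nrow(object@calls),
      " calls (", paste(paste0(names(z), "=", as.integer(z)), collapse = ", "),
      ")\n", sep = "")
})

setMethod("show", "AlleleTable", function(object) {
  cat("AlleleTable: ", length(object@alleles), " alleles, reference ",
      object@reference, "\n", sep = "")
  for (a in object@alleles)
    cat("  ", a@name, ": ", length(a@coding), " coding / ",
        length(a@intronic), " intronic",
        if (!is.na(a@parent)) paste0(" (parent ", a@parent, ")") else "",
        if (a@subtype) " [subtype]" else "", "\n", sep = "")
})

setMethod("show", "MarkerCatalog", function(object) {
  cat("MarkerCatalog:",
      paste(names(object@markers),
            vapply(object@markers, length, integer(1)),
            sep = "=", collapse = ", "), "\n")
  if (nrow(object@qualityWarnings))
    cat("  quality warnings for sample(s):",
        paste(unique(object@qualityWarnings$sample_id), collapse = ", "), "\n")
})

setMethod("show", "RecombinationEvent", function(object) {
  cat("RecombinationEvent [", object@status, "] sample ", object@sampleId,
      "\n", sep = "")
  if (object@status != "untypical") {
    cat("  donor ", paste(object@donor, collapse = "|"),
        " replacing ", object@replaced,
        ", ", object@runLength, " informative positions\n", sep = "")
    cat("  breakpoint interval: (",
        object@breakpointInterval[1], ", ",
        object@breakpointInterval[2], ")\n", sep = "")
  } else if (length(object@notes)) {
    cat("  ", object@notes[1], "\n", sep = "")
  }
})
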