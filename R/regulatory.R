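#' @include genotype.R
NULL

#' Known regulatory-element variant associations
#'
#' Bundled association table for the erythroid cell-specific regulatory
#' element in intron 1 (the +5.8 kb enhancer window carrying GATA and RUNX1
#' motifs): variant, associated subtype phenotype, and whether the variant
#' was first described in the study cohort this package models.
#'
#' @return data.frame with columns \code{hgvs_c}, \code{phenotype},
#'   \code{novel_in_study}, \code{note}.
#' @export
regulatoryAssociations <- function() {
  read.delim(system.file("extdata", "regulatory_associations.tsv",
                         package = "aboseq"),
             stringsAsFactors = FALSE)
}

#' Annotate variants in the intron-1 erythroid regulatory element
#'
#' Flags every observed variant whose position lies in the configured
#' element window and attaches the known phenotype association where one is
#' bundled; in-window variants without an entry are labeled
#' \code{"element, unknown effect"}.
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param window character of length 2, element bounds as c. positions
#'   (default \code{c("c.28+5856", "c.28+5958")}).
#' @param associations association table, defaulting to
#'   \code{\link{regulatoryAssociations}}.
#' @return data.frame with one row per observed non-reference variant:
#'   \code{hgvs_c}, \code{zygosity}, \code{in_element}, \code{association},
#'   \code{novel_association}.
#' @export
annotateRegulatory <- function(profile,
                               window = c("c.28+5856", "c.28+5958"),
                               associations = regulatoryAssociations()) {
  obs <- .nonRefCalls(profile)
  lo <- positionKey(window[1]); hi <- positionKey(window[2])
  inEl <- obs$key >= lo & obs$key <= hi
  idx <- match(obs$hgvs_c, associations$hgvs_c)
  assoc <- ifelse(inEl,
                  ifelse(is.na(idx), "element, unknown effect",
                         associations$phenotype[idx]),
                  NA_character_)
  data.frame(hgvs_c = obs$hgvs_c,
             zygosity = obs$zygosity,
             in_element = inEl,
             association = assoc,
             novel_association = inEl & !is.na(idx) &
               as.logical(associations$novel_in_study[idx]),
             stringsAsFactors = FALSE)
}
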