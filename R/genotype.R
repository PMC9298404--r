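#' @include allele-table.R
NULL

#' GenotypeCall: a diploid ABO allele assignment
#'
#' @slot sampleId character.
#' @slot allelePair character of length 2, allele names (unordered pair,
#'   stored case-insensitively sorted).
#' @slot novelVariants character, observed coding variants not explained by
#'   the pair (attached to the background they extend).
#' @slot zygosityConsistent logical, TRUE when the pair reproduces every
#'   observed coding zygosity exactly.
#' @slot alternatives data.frame of all consistent pairs ranked by (zygosity
#'   mismatches, number of novel variants, name), columns \code{allele1},
#'   \code{allele2}, \code{n_mismatch}, \code{n_novel}.
#' @exportClass GenotypeCall
setClass("GenotypeCall",
  representation(
    sampleId = "character",
    allelePair = "character",
    novelVariants = "character",
    zygosityConsistent = "logical",
    alternatives = "data.frame"
  )
)

setMethod("show", "GenotypeCall", function(object) {
  cat("GenotypeCall ", object@sampleId, ": ", genotypeLabel(object),
      if (length(object@novelVariants))
        paste0(" + novel ", paste(object@novelVariants, collapse = ",")),
      if (!object@zygosityConsistent) " [inconsistent]",
      "\n", sep = "")
  if (nrow(object@alternatives) > 1L)
    cat("  ", nrow(object@alternatives) - 1L, " alternative pair(s)\n")
})

#' Genotype string of a call
#'
#' @param call a \linkS4class{GenotypeCall}.
#' @return character like \code{"ABO*B.01/ABO*O.01.01"}.
#' @export
genotypeLabel <- function(call) {
  paste(call@allelePair, collapse = "/")
}

#' @rdname accessors
#' @param call a \linkS4class{GenotypeCall}.
#' @export
allelePair <- function(call) call@allelePair

#' @rdname accessors
#' @export
novelVariants <- function(call) call@novelVariants

#' Assign a diploid ABO genotype from coding-region calls
#'
#' Enumerates every unordered allele pair from the table and scores it
#' against the observed coding zygosity pattern: a pair predicts hom_alt at
#' variants carried by both alleles, het at variants carried by exactly one,
#' and hom_ref elsewhere; observed coding variants carried by neither allele
#' are candidate novel variants on the pair's background. Consistent pairs
#' (no zygosity contradiction) are ranked by fewest novel variants, then by
#' name; the best pair is returned with all alternatives. With
#' \code{tolerant = TRUE} pairs with zygosity mismatches are also ranked
#' (by mismatches first), which keeps the caller usable on noisy calls.
#'
#' Intronic calls are ignored at this stage; they drive marker derivation
#' and recombination analysis instead.
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param table an \linkS4class{AlleleTable}.
#' @param model a \linkS4class{GeneModel}.
#' @param tolerant logical; allow and rank zygosity mismatches.
#' @return a \linkS4class{GenotypeCall}.
#' @examples
#' tab <- defaultAlleleTable()
#' p <- SampleProfile("s1", data.frame(hgvs_c = "c.261delG",
#'   zygosity = "hom_alt", depth = 200, alt_fraction = 0.99))
#' genotypeLabel(callGenotype(p, tab))   # homozygous deletion-allele pair
#' @export
callGenotype <- function(profile, table, model = defaultGeneModel(),
                         tolerant = FALSE) {
  if (nrow(profile@calls) == 0L)
    stop("empty profile for sample '", profile@sampleId, "'")
  obs <- .nonRefCalls(profile)
  keep <- isCoding(obs$hgvs_c, model) | isSpliceSite(obs$hgvs_c)
  obs <- obs[keep, , drop = FALSE]
  obsZyg <- setNames(obs$zygosity, obs$hgvs_c)

  alleles <- alleleNames(table)
  coding <- lapply(alleles, function(a) codingVariants(table, a))
  names(coding) <- alleles

  nA <- length(alleles)
  ii <- rep(seq_len(nA), times = nA); jj <- rep(seq_len(nA), each = nA)
  keepPair <- ii <= jj
  ii <- ii[keepPair]; jj <- jj[keepPair]
  nP <- length(ii)
  allele1 <- character(nP); allele2 <- character(nP)
  nMis <- integer(nP); nNov <- integer(nP); novelTxt <- character(nP)
  for (r in seq_len(nP)) {
    a1 <- alleles[ii[r]]; a2 <- alleles[jj[r]]
    c1 <- coding[[a1]]; c2 <- coding[[a2]]
    pairVars <- union(c1, c2)
    expZyg <- ifelse(pairVars %in% c1 & pairVars %in% c2, "hom_alt", "het")
    got <- obsZyg[pairVars]; got[is.na(got)] <- "hom_ref"
    novel <- setdiff(names(obsZyg), pairVars)
    pair <- c(a1, a2)[order(tolower(c(a1, a2)))]
    allele1[r] <- pair[1]; allele2[r] <- pair[2]
    nMis[r] <- sum(got != expZyg); nNov[r] <- length(novel)
    novelTxt[r] <- paste(novel, collapse = ",")
  }
  res <- data.frame(allele1 = allele1, allele2 = allele2, n_mismatch = nMis,
                    n_novel = nNov, novel = novelTxt, stringsAsFactors = FALSE)
  if (!tolerant) res <- res[res$n_mismatch == 0L, , drop = FALSE]
  if (nrow(res) == 0L)
    stop("no allele pair is consistent with the coding zygosity pattern of '",
         profile@sampleId, "'; offending positions: ",
         paste(names(obsZyg), collapse = ", "))
  # rank by total unexplained observations (zygosity contradictions plus
  # novel variants), preferring explanations through known alleles
  res <- res[order(res$n_mismatch + res$n_novel, res$n_mismatch,
                   tolower(res$allele1), tolower(res$allele2)), , drop = FALSE]
  rownames(res) <- NULL
  best <- res[1, ]
  novel <- if (nzchar(best$novel)) strsplit(best$novel, ",")[[1]] else character(0)
  new("GenotypeCall",
      sampleId = profile@sampleId,
      allelePair = c(best$allele1, best$allele2),
      novelVariants = novel,
      zygosityConsistent = best$n_mismatch == 0L,
      alternatives = res[, c("allele1", "allele2", "n_mismatch", "n_novel")])
}

#' Classify the mechanism behind a subtype phenotype
#'
#' \code{coding_variant} when the assigned pair contains a subtype-defining
#' allele or the call carries novel coding/splice-site variants;
#' \code{regulatory_variant} when the coding region is clean but a variant
#' lies in the erythroid regulatory element of intron 1;
#' \code{unexplained} otherwise.
#'
#' @param call a \linkS4class{GenotypeCall}.
#' @param regulatory annotation data.frame from
#'   \code{\link{annotateRegulatory}} for the same sample.
#' @param table an \linkS4class{AlleleTable}.
#' @param model a \linkS4class{GeneModel}.
#' @param spliceWindow intron offset magnitude counted as a splice site.
#' @return character scalar mechanism label.
#' @export
classifySubtypeMechanism <- function(call, regulatory, table,
                                     model = defaultGeneModel(),
                                     spliceWindow = 2L) {
  subtypePair <- any(vapply(call@allelePair,
                            function(a) isSubtypeAllele(table, a), logical(1)))
  novel <- call@novelVariants
  novelCoding <- length(novel) &&
    any(isCoding(novel, model) | isSpliceSite(novel, spliceWindow))
  if (subtypePair || novelCoding) return("coding_variant")
  if (nrow(regulatory) && any(regulatory$in_element)) return("regulatory_variant")
  "unexplained"
}
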