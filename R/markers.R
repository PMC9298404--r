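#' @include regulatory.R
NULL

#' The bundled allele-specific intronic marker catalog
#'
#' The published catalog of intronic SNVs specific to the B.01, O.01.01 and
#' O.01.02 lineages (12, 10 and 35 markers), as derived from a 47-strong
#' homozygote panel after excluding one recombinant B/B specimen. Used by
#' the synthetic-cohort generator as ground truth; \code{\link{deriveMarkers}}
#' re-derives it from profiles.
#'
#' @return a \linkS4class{MarkerCatalog}.
#' @export
bundledMarkerCatalog <- function() {
  tab <- read.delim(system.file("extdata", "intronic_marker_catalog.tsv",
                                package = "aboseq"),
                    stringsAsFactors = FALSE)
  new("MarkerCatalog",
      markers = split(tab$hgvs_c, tab$allele),
      provenance = data.frame(allele = character(0), hgvs_c = character(0),
                              n_support = integer(0), n_refute = integer(0)),
      qualityWarnings = data.frame(sample_id = character(0),
                                   hgvs_c = character(0)))
}

#' Derive allele-specific intronic markers from a homozygote panel
#'
#' A variant is a marker for allele X when it is called homozygous-alt in
#' every retained X/X sample and absent (hom_ref or uncalled) from every
#' retained Y/Y sample of all other lineages. A heterozygous call inside a
#' supposedly homozygous sample disqualifies that variant and raises a
#' sample-quality warning naming the sample — the signature by which a
#' recombinant hiding in the panel is caught (see
#' \code{\link{deriveMarkerCatalog}} for the two-pass workflow).
#'
#' With \code{delta > 0} the unanimity rule is relaxed: a marker needs a
#' non-reference call in at least a fraction (1 - delta) of X samples and at
#' most a fraction delta of each other lineage, which restores marker
#' recovery on noisy panels.
#'
#' @param profiles list of \linkS4class{SampleProfile}.
#' @param genotypes character vector of homozygous genotype assignments,
#'   one per profile (allele name, or \code{"X/X"}), named by sample id or
#'   in profile order.
#' @param model a \linkS4class{GeneModel}.
#' @param delta tolerance fraction in [0, 0.5); 0 (default) = strict
#'   unanimity.
#' @param exclude sample ids to drop before derivation (e.g. flagged
#'   recombinants).
#' @return a \linkS4class{MarkerCatalog} with provenance counts and quality
#'   warnings.
#' @export
deriveMarkers <- function(profiles, genotypes, model = defaultGeneModel(),
                          delta = 0, exclude = character(0)) {
  stopifnot(length(profiles) == length(genotypes), delta >= 0, delta < 0.5)
  ids <- vapply(profiles, sampleId, character(1))
  if (is.null(names(genotypes))) names(genotypes) <- ids
  genotypes <- genotypes[ids]
  # accept "X/X" pair notation; reject heterozygous assignments
  allele <- vapply(seq_along(genotypes), function(i) {
    g <- strsplit(genotypes[i], "/", fixed = TRUE)[[1]]
    if (length(g) == 2L && g[1] != g[2])
      stop("sample '", ids[i], "' has a heterozygous genotype (", genotypes[i],
           "); marker derivation needs a homozygote panel")
    g[1]
  }, character(1))
  keep <- !(ids %in% exclude)
  profiles <- profiles[keep]; allele <- allele[keep]; ids <- ids[keep]
  if (length(unique(allele)) < 2L)
    stop("need at least two distinct allele lineages to derive specificity (",
         "got: ", paste(unique(allele), collapse = ", "), ")")

  intronicOf <- function(p) {
    k <- .nonRefCalls(p)
    k[!(isCoding(k$hgvs_c, model)), , drop = FALSE]
  }
  obs <- lapply(profiles, intronicOf)
  allVars <- unique(unlist(lapply(obs, function(k) k$hgvs_c), use.names = FALSE))
  if (length(allVars))
    allVars <- allVars[order(parseHgvsC(allVars)$key)]

  # per-sample zygosity matrix over candidate variants ("" = no call)
  zyg <- vapply(obs, function(k) {
    z <- k$zygosity[match(allVars, k$hgvs_c)]
    z[is.na(z)] <- ""
    z
  }, character(length(allVars)))
  zyg <- matrix(zyg, nrow = length(allVars),
                dimnames = list(allVars, ids))

  warnIdx <- which(zyg == "het", arr.ind = TRUE)
  warnings <- data.frame(
    sample_id = ids[warnIdx[, 2]],
    hgvs_c = allVars[warnIdx[, 1]],
    stringsAsFactors = FALSE)

  lineages <- sort(unique(allele))
  markers <- setNames(vector("list", length(lineages)), lineages)
  prov <- list()
  for (X in lineages) {
    inX <- allele == X
    nX <- sum(inX)
    sel <- logical(length(allVars))
    nSupport <- integer(length(allVars)); nRefute <- integer(length(allVars))
    for (vi in seq_along(allVars)) {
      zX <- zyg[vi, inX]; zO <- zyg[vi, !inX]
      presX <- sum(zX %in% c("hom_alt", "het"))
      presO <- sum(zO %in% c("hom_alt", "het"))
      nSupport[vi] <- presX; nRefute[vi] <- presO
      if (delta == 0) {
        sel[vi] <- all(zX == "hom_alt") && presO == 0L
      } else {
        sel[vi] <- presX >= (1 - delta) * nX &&
          all(tapply(zO %in% c("hom_alt", "het"), allele[!inX], mean) <= delta)
      }
    }
    markers[[X]] <- allVars[sel]
    if (any(sel))
      prov[[X]] <- data.frame(allele = X, hgvs_c = allVars[sel],
                              n_support = nSupport[sel],
                              n_refute = nRefute[sel],
                              stringsAsFactors = FALSE)
  }
  new("MarkerCatalog",
      markers = markers,
      provenance = if (length(prov)) do.call(rbind, c(prov, make.row.names = FALSE))
                   else data.frame(allele = character(0), hgvs_c = character(0),
                                   n_support = integer(0), n_refute = integer(0)),
      qualityWarnings = warnings)
}

#' Two-pass marker derivation from a mixed cohort
#'
#' Runs the genotype caller over the cohort, selects the clean homozygous
#' samples (identical named pair, no novel variants), derives markers, and
#' — when the first pass raises sample-quality warnings (heterozygous calls
#' inside supposed homozygotes, the footprint of an allele recombinant) —
#' excludes the warned samples and re-derives. This mirrors the published
#' workflow in which one recombinant B/B specimen was excluded from the
#' homozygote panel.
#'
#' @param profiles list of \linkS4class{SampleProfile} (the whole cohort;
#'   non-homozygous samples are ignored).
#' @param table an \linkS4class{AlleleTable}.
#' @param model a \linkS4class{GeneModel}.
#' @param delta tolerance passed to \code{\link{deriveMarkers}}.
#' @param twoPass logical; exclude quality-flagged samples and re-derive.
#' @param tolerant logical; passed to \code{\link{callGenotype}}.
#' @return a \linkS4class{MarkerCatalog}; quality warnings are those of the
#'   first pass, so excluded samples remain visible.
#' @export
deriveMarkerCatalog <- function(profiles, table, model = defaultGeneModel(),
                                delta = 0, twoPass = TRUE, tolerant = FALSE) {
  callsList <- lapply(profiles, callGenotype, table = table, model = model,
                      tolerant = tolerant)
  hom <- vapply(callsList, function(cl) {
    cl@allelePair[1] == cl@allelePair[2] && length(cl@novelVariants) == 0L
  }, logical(1))
  panel <- profiles[hom]
  genotypes <- vapply(callsList[hom], function(cl) cl@allelePair[1], character(1))
  names(genotypes) <- vapply(panel, sampleId, character(1))
  cat1 <- deriveMarkers(panel, genotypes, model = model, delta = delta)
  flagged <- unique(cat1@qualityWarnings$sample_id)
  if (!twoPass || length(flagged) == 0L) return(cat1)
  cat2 <- deriveMarkers(panel, genotypes, model = model, delta = delta,
                        exclude = flagged)
  cat2@qualityWarnings <- cat1@qualityWarnings
  cat2
}

#' Count non-reference variant positions of a profile against the mapping
#' reference
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param region one of \code{"intronic"}, \code{"coding"}, \code{"all"}.
#' @param model a \linkS4class{GeneModel}.
#' @return integer count of distinct non-reference variants passing the
#'   region filter.
#' @export
countDiffsVsReference <- function(profile,
                                  region = c("intronic", "coding", "all"),
                                  model = defaultGeneModel()) {
  region <- match.arg(region)
  k <- .nonRefCalls(profile)
  if (nrow(k) == 0L) return(0L)
  coding <- isCoding(k$hgvs_c, model)
  n <- switch(region,
              intronic = sum(!coding),
              coding = sum(coding),
              all = nrow(k))
  as.integer(n)
}
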