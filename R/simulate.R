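#' @include phasing.R
NULL

# Novel variants used by the bundled cohort presets (not part of any named
# allele definition).
.presetNovelVariants <- function() {
  c("c.964G>A", "c.106delG", "c.389T>C", "c.410C>T")
}

#' Build the variant content of an allele haplotype
#'
#' Union of the allele's resolved coding and intronic table content and the
#' marker set of its lineage root.
#'
#' @param allele allele name.
#' @param table an \linkS4class{AlleleTable}.
#' @param catalog a \linkS4class{MarkerCatalog}.
#' @return character vector of HGVS c. labels, sorted along the gene axis.
#' @examples
#' length(buildHaplotype("ABO*B.01", defaultAlleleTable()))  # 7 coding + 12 markers
#' @export
buildHaplotype <- function(allele, table, catalog = bundledMarkerCatalog()) {
  root <- lineageRoot(table, allele)
  mk <- if (root %in% names(catalog@markers)) catalog@markers[[root]] else character(0)
  v <- unique(c(codingVariants(table, allele),
                intronicVariants(table, allele), mk))
  if (length(v)) v[order(parseHgvsC(v)$key)] else v
}

#' Build a recombinant haplotype from two donor alleles
#'
#' Takes the 5' donor's variants at gene-axis positions before the
#' breakpoint and the 3' donor's variants after it; deterministic given the
#' specification. \code{extra} variants are always retained (e.g. a
#' subtype-defining coding change carried by the recombinant irrespective
#' of the crossover).
#'
#' @param donor5,donor3 allele names for the 5' and 3' segments.
#' @param breakpoint c. position string strictly between the flanking
#'   variants.
#' @param table an \linkS4class{AlleleTable}.
#' @param catalog a \linkS4class{MarkerCatalog}.
#' @param flanks optional character of length 2: HGVS labels of the
#'   variants that must flank the breakpoint (checked strictly).
#' @param extra HGVS labels appended regardless of position.
#' @return character vector of HGVS c. labels.
#' @export
makeRecombinant <- function(donor5, donor3, breakpoint, table,
                            catalog = bundledMarkerCatalog(),
                            flanks = NULL, extra = character(0)) {
  bp <- positionKey(breakpoint)
  if (!is.null(flanks)) {
    k <- positionKey(parseHgvsC(flanks))
    if (!(bp > k[1] && bp < k[2]))
      stop("breakpoint ", breakpoint, " is not strictly between ",
           flanks[1], " and ", flanks[2])
  }
  h5 <- buildHaplotype(donor5, table, catalog)
  h3 <- buildHaplotype(donor3, table, catalog)
  k5 <- if (length(h5)) positionKey(parseHgvsC(h5)) else numeric(0)
  k3 <- if (length(h3)) positionKey(parseHgvsC(h3)) else numeric(0)
  if (any(k5 == bp) || any(k3 == bp))
    stop("breakpoint ", breakpoint, " coincides with a variant position")
  v <- unique(c(h5[k5 < bp], h3[k3 > bp], extra))
  v[order(parseHgvsC(v)$key)]
}

# Double recombinant used for the untypical-pattern specimens: a subtype-B
# backbone whose introns 3-5 carry O.01.01 characteristics (two crossovers,
# which the single-donor walk reports as an untypical pattern).
.doubleRecombinant <- function(backbone, zoneDonor, table, catalog) {
  zone <- c(positionKey("c.155+1"), positionKey("c.240-1"))
  inZone <- function(v) {
    if (length(v) == 0L) return(logical(0))
    p <- parseHgvsC(v)
    intronic <- p$offset != 0L
    k <- p$key
    intronic & k >= zone[1] & k <= zone[2]
  }
  b <- buildHaplotype(backbone, table, catalog)
  o <- buildHaplotype(zoneDonor, table, catalog)
  v <- unique(c(b[!inZone(b)], o[inZone(o)]))
  v[order(parseHgvsC(v)$key)]
}

#' Simulate a diploid zygosity profile from two haplotypes
#'
#' The union of the two haplotypes' variant positions is called hom_alt
#' where both carry the variant and het where one does. Each call is
#' independently flipped to one of the other two zygosity states with
#' probability \code{noise}; depths are negative-binomial and alt-read
#' fractions are drawn consistently with the (possibly flipped) zygosity.
#'
#' @param h1,h2 character vectors of HGVS c. labels (haplotype contents).
#' @param sampleId sample identifier.
#' @param noise per-call flip probability in [0, 0.5).
#' @param depthMean,depthSize negative-binomial depth model (mu, size).
#' @param minDepth coverage floor for flagging, see
#'   \code{\link{SampleProfile}}.
#' @param metadata list stored in the profile.
#' @param seed optional integer; when supplied the draw is made on a local
#'   seeded stream, making the profile reproducible in isolation.
#' @return a \linkS4class{SampleProfile}.
#' @export
makeSample <- function(h1, h2, sampleId = "sim", noise = 0,
                       depthMean = 500, depthSize = 10, minDepth = 50L,
                       metadata = list(), seed = NULL) {
  stopifnot(noise >= 0, noise < 0.5)
  rs <- if (!is.null(seed)) .seededRNG(seed)
  vars <- union(h1, h2)
  if (length(vars)) vars <- vars[order(parseHgvsC(vars)$key)]
  zyg <- ifelse(vars %in% h1 & vars %in% h2, "hom_alt", "het")
  if (noise > 0 && length(vars)) {
    flip <- runif(length(vars)) < noise
    if (any(flip)) {
      zyg[flip] <- vapply(zyg[flip], function(z) {
        sample(setdiff(.ZYGOSITY, z), 1L)
      }, character(1))
    }
  }
  n <- length(vars)
  depth <- if (n) rnbinom(n, mu = depthMean, size = depthSize) else integer(0)
  af <- if (n) {
    ifelse(zyg == "hom_alt", runif(n, 0.93, 1.0),
      ifelse(zyg == "het", runif(n, 0.40, 0.60), runif(n, 0.0, 0.07)))
  } else numeric(0)
  if (!is.null(seed)) .restoreRNG(rs)
  SampleProfile(sampleId,
                data.frame(hgvs_c = vars, zygosity = zyg,
                           depth = depth, alt_fraction = af,
                           stringsAsFactors = FALSE),
                metadata = metadata, minDepth = minDepth)
}

# ---- cohort presets ---------------------------------------------------------

# Descriptor columns: a1, a2 (underlying named alleles; for recombinants the
# pair the caller should assign), extra1/extra2 (novel variants on one
# haplotype), recomb (NA, "Brec1", "Brec2", "double"), mechanism
# (NA, "coding_variant", "regulatory_variant").
.presetRows <- function(preset) {
  row <- function(a1, a2, n = 1L, extra1 = "", extra2 = "",
                  recomb = NA_character_, mechanism = NA_character_,
                  id = NA_character_) {
    data.frame(a1 = a1, a2 = a2, n = n, extra1 = extra1, extra2 = extra2,
               recomb = recomb, mechanism = mechanism, id = id,
               stringsAsFactors = FALSE)
  }
  table2 <- rbind(
    row("ABO*A1.02", "ABO*A1.02", 12L),
    row("ABO*B.01", "ABO*B.01", 14L),
    row("ABO*B.01", "ABO*B.01", 1L, recomb = "Brec1"),
    row("ABO*O.01.01", "ABO*O.01.01", 13L),
    row("ABO*O.01.02", "ABO*O.01.02", 8L),
    row("ABO*O.01.01", "ABO*O.01.01", 1L, extra2 = "c.964G>A"),
    row("ABO*A1.02", "ABO*O.01.01", 8L),
    row("ABO*A1.02", "ABO*O.01.02", 6L),
    row("ABO*A1.01", "ABO*A1.02", 1L),
    row("ABO*A1.01", "ABO*O.01.01", 2L),
    row("ABO*B.01", "ABO*O.01.01", 5L),
    row("ABO*B.01", "ABO*O.01.02", 6L),
    row("ABO*O.01.01", "ABO*O.01.02", 6L),
    row("ABO*A1.02", "ABO*B.01", 5L))
  subtypes <- rbind(
    row("ABO*A1.02", "ABO*O.01.01", extra1 = "c.106delG",
        mechanism = "coding_variant", id = "19001"),
    row("ABO*A1.02", "ABO*O.01.02", extra1 = "c.106delG",
        mechanism = "coding_variant", id = "19014"),
    row("ABO*A1.02", "ABO*O.01.01", extra1 = "c.389T>C",
        mechanism = "coding_variant", id = "19007"),
    row("ABO*A1.02", "ABO*O.01.01", extra1 = "c.410C>T",
        mechanism = "coding_variant", id = "19046"),
    row("ABO*AW.37", "ABO*B.01", mechanism = "coding_variant", id = "19035"),
    row("ABO*BW.03", "ABO*O.01.02", mechanism = "coding_variant", id = "19041"),
    row("ABO*BW.28", "ABO*O.01.01", mechanism = "coding_variant", id = "19005"),
    row("ABO*A2.08", "ABO*B.01", mechanism = "coding_variant", id = "19026"),
    row("ABO*A2.07", "ABO*B.01", mechanism = "coding_variant", id = "19039"),
    row("ABO*BA.02", "ABO*O.01.02", mechanism = "coding_variant", id = "19011"),
    row("ABO*BA.07", "ABO*O.01.02", mechanism = "coding_variant", id = "19019"),
    row("ABO*cisAB.01", "ABO*O.01.02", mechanism = "coding_variant", id = "19034"),
    row("ABO*O.01.02", "ABO*B3.10", recomb = "double",
        mechanism = "coding_variant", id = "19048"),
    row("ABO*O.01.02", "ABO*B3.10", recomb = "double",
        mechanism = "coding_variant", id = "19008"),
    row("ABO*O.01.01", "ABO*B3.10", recomb = "Brec2",
        mechanism = "coding_variant", id = "19047"),
    row("ABO*O.01.01", "ABO*B3.10", recomb = "Brec2",
        mechanism = "coding_variant", id = "19004"),
    row("ABO*A1.02", "ABO*B3.10", recomb = "double",
        mechanism = "coding_variant", id = "19032"),
    row("ABO*A1.02", "ABO*O.01.02", extra1 = "c.28+5956T>A",
        mechanism = "regulatory_variant", id = "19053"),
    row("ABO*B.01", "ABO*O.01.01", extra1 = "c.28+5872C>T",
        mechanism = "regulatory_variant", id = "18121"),
    row("ABO*A1.02", "ABO*B.01", extra2 = "c.28+5872C>T",
        mechanism = "regulatory_variant", id = "18103"),
    row("ABO*B.01", "ABO*O.01.01", extra1 = "c.28+5882C>T",
        mechanism = "regulatory_variant", id = "19010"),
    row("ABO*A1.02", "ABO*B.01", extra2 = "c.28+5882C>T",
        mechanism = "regulatory_variant", id = "19013"))
  switch(preset,
         table2 = table2,
         subtypes = subtypes,
         full = rbind(table2, subtypes),
         stop("unknown preset '", preset, "'"))
}

#' Simulate a cohort of zygosity profiles with a truth sidecar
#'
#' Bundled presets reproduce the study conditions at the variant-call
#' level: \code{"table2"} — 88 donors with common phenotypes (48 clean
#' homozygotes, one recombinant B/B, one novel-allele carrier, 38 further
#' heterozygotes); \code{"subtypes"} — the 22 subtype specimens (17 with
#' coding variants, of which five carry recombinant haplotypes, plus 5
#' carrying only regulatory-element variants); \code{"full"} — both (110
#' samples). A custom descriptor data.frame with the same columns as the
#' presets may be supplied instead.
#'
#' @param preset \code{"table2"}, \code{"subtypes"}, \code{"full"}, or a
#'   descriptor data.frame.
#' @param table an \linkS4class{AlleleTable}; by default the bundled table
#'   augmented with \code{nShared} seeded shared-lineage intronic variants.
#' @param catalog a \linkS4class{MarkerCatalog} (ground-truth marker
#'   content).
#' @param noise per-call zygosity flip probability.
#' @param seed integer; all randomness (shared-variant placement, depths,
#'   noise) derives from it.
#' @param model a \linkS4class{GeneModel}.
#' @param nShared number of shared-lineage background variants.
#' @return list with \code{profiles} (list of \linkS4class{SampleProfile}),
#'   \code{truth} (data.frame: \code{sample_id}, \code{allele1},
#'   \code{allele2}, \code{novel}, \code{recombinant}, \code{mechanism}),
#'   \code{table} (the augmented allele table) and \code{catalog}.
#' @examples
#' coh <- makeCohort("table2", seed = 7)
#' length(coh$profiles)  # 88
#' @export
makeCohort <- function(preset = "table2", table = NULL,
                       catalog = bundledMarkerCatalog(), noise = 0,
                       seed = 1L, model = defaultGeneModel(), nShared = 20L) {
  rows <- if (is.data.frame(preset)) preset else .presetRows(preset)
  if (is.null(table))
    table <- addSharedLineageVariants(defaultAlleleTable(), n = nShared,
                                      seed = seed, model = model,
                                      catalog = catalog)
  rs <- .seededRNG(seed + 1L)
  on.exit(.restoreRNG(rs))

  profiles <- list(); truth <- list()
  counter <- 0L
  for (r in seq_len(nrow(rows))) {
    spec <- rows[r, ]
    for (k in seq_len(spec$n)) {
      counter <- counter + 1L
      id <- if (!is.na(spec$id)) spec$id else sprintf("D%03d", counter)
      h1 <- buildHaplotype(spec$a1, table, catalog)
      h2 <- if (is.na(spec$recomb)) {
        buildHaplotype(spec$a2, table, catalog)
      } else if (spec$recomb == "Brec1") {
        makeRecombinant("ABO*O.01.01", "ABO*B.01", "c.29-1000", table, catalog,
                        flanks = c("c.29-1053_29-1037del", "c.29-86G>A"))
      } else if (spec$recomb == "Brec2") {
        makeRecombinant("ABO*O.01.01", "ABO*B.01", "c.240-100", table, catalog,
                        flanks = c("c.240-219G>A", "c.240-25A>G"),
                        extra = "c.28G>A")
      } else if (spec$recomb == "double") {
        .doubleRecombinant(spec$a2, "ABO*O.01.01", table, catalog)
      } else stop("unknown recombinant spec '", spec$recomb, "'")
      if (nzchar(spec$extra1)) h1 <- c(h1, spec$extra1)
      if (nzchar(spec$extra2)) h2 <- c(h2, spec$extra2)
      novel <- c(spec$extra1, spec$extra2)
      novel <- novel[nzchar(novel)]
      novel <- novel[isCoding(novel, model)]   # element variants are not novel coding
      meta <- list(
        true_pair = sort(c(spec$a1, spec$a2)),
        recombinant = spec$recomb,
        mechanism = spec$mechanism)
      profiles[[counter]] <- makeSample(h1, h2, sampleId = id, noise = noise,
                                        metadata = meta)
      truth[[counter]] <- data.frame(
        sample_id = id,
        allele1 = sort(c(spec$a1, spec$a2))[1],
        allele2 = sort(c(spec$a1, spec$a2))[2],
        novel = paste(novel, collapse = ","),
        recombinant = if (is.na(spec$recomb)) NA_character_
                      else if (spec$recomb == "double") "untypical"
                      else spec$recomb,
        mechanism = spec$mechanism,
        stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       table = table, catalog = catalog)
}

#' Write a simulated cohort to disk
#'
#' One TSV profile per sample (optionally also VCF when the model carries
#' genomic anchoring) plus a machine-readable \code{truth.json} sidecar.
#'
#' @param cohort result of \code{\link{makeCohort}}.
#' @param dir output directory (created if needed).
#' @param model a \linkS4class{GeneModel}.
#' @param vcf logical; also write per-sample VCFs.
#' @param reference optional reference sequence for VCF ref/padding bases.
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir, model = defaultGeneModel(),
                        vcf = FALSE, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$profiles) {
    writeProfileTsv(p, file.path(dir, paste0(sampleId(p), ".tsv")))
    if (vcf)
      writeProfileVcf(p, model, file.path(dir, paste0(sampleId(p), ".vcf")),
                      reference = reference)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Simulate read fragments over a region of a diploid sample
#'
#' Each fragment samples one haplotype (fair coin unless forced), starts
#' uniformly within the region, spans \code{fragmentSpan} bp of genomic
#' sequence, and reports \code{"ref"}/\code{"alt"} at every covered variant
#' position — the co-occurrence signal read-backed phasing consumes.
#'
#' @param h1,h2 haplotype contents (HGVS c. labels).
#' @param region character of length 2: c. positions bounding the region.
#' @param nFragments number of fragments.
#' @param fragmentSpan fragment length in genomic bp.
#' @param model a \linkS4class{GeneModel}.
#' @param haplotype NULL for fair-coin sampling, or 1/2 to force one
#'   haplotype.
#' @param seed optional integer for a local reproducible stream.
#' @return list of fragments (each a list with \code{fragment_id},
#'   \code{haplotype} and \code{obs}).
#' @export
makeReadFragments <- function(h1, h2, region, nFragments, fragmentSpan = 300L,
                              model = defaultGeneModel(), haplotype = NULL,
                              seed = NULL) {
  g1 <- cToGenomic(region[1], model); g2 <- cToGenomic(region[2], model)
  stopifnot(g1 < g2)
  vars <- union(h1, h2)
  gv <- if (length(vars)) vapply(vars, function(v) {
    p <- parseHgvsC(v)
    cToGenomic(.posLabel(p$anchor, p$offset), model)
  }, integer(1)) else integer(0)
  inRegion <- gv >= g1 & gv <= g2
  if (!any(inRegion))
    stop("region [", region[1], ", ", region[2],
         "] contains no variant positions")
  vars <- vars[inRegion]; gv <- gv[inRegion]
  rs <- if (!is.null(seed)) .seededRNG(seed)
  out <- lapply(seq_len(nFragments), function(i) {
    hap <- if (is.null(haplotype)) sample(1:2, 1L) else as.integer(haplotype)
    start <- floor(runif(1, g1, max(g1, g2 - fragmentSpan) + 1))
    covered <- gv >= start & gv <= start + fragmentSpan - 1L
    content <- if (hap == 1L) h1 else h2
    obs <- setNames(ifelse(vars[covered] %in% content, "alt", "ref"),
                    vars[covered])
    list(fragment_id = sprintf("frag%04d", i), haplotype = hap, obs = obs)
  })
  if (!is.null(seed)) .restoreRNG(rs)
  out
}

#' Apply a haplotype's variants to a reference sequence
#'
#' Interoperability helper: materialises a haplotype as sequence (e.g. for
#' alignment-based tools). Variants are applied 3' to 5' so coordinates
#' stay valid.
#'
#' @param variants character vector of HGVS c. labels.
#' @param reference reference sequence (as accepted by
#'   \code{\link{insilicoPcr}}).
#' @param model a \linkS4class{GeneModel}.
#' @return a \code{Biostrings::DNAString} of the haplotype sequence.
#' @export
haplotypeSequence <- function(variants, reference, model = defaultGeneModel()) {
  refSeq <- .asDNAString(reference)
  s <- strsplit(as.character(refSeq), "")[[1]]
  if (length(variants) == 0L) return(Biostrings::DNAString(paste(s, collapse = "")))
  v <- parseHgvsC(variants)
  g <- vapply(seq_len(nrow(v)), function(i)
    cToGenomic(.posLabel(v$anchor[i], v$offset[i]), model), integer(1))
  g2 <- vapply(seq_len(nrow(v)), function(i)
    cToGenomic(.posLabel(v$anchor2[i], v$offset2[i]), model), integer(1))
  ord <- order(g, decreasing = TRUE)
  for (i in ord) {
    kind <- v$kind[i]
    if (kind == "substitution") {
      s[g[i]] <- v$alt[i]
    } else if (kind == "deletion") {
      s <- s[-(g[i]:g2[i])]
    } else if (kind == "insertion") {
      s <- append(s, strsplit(v$alt[i], "")[[1]], after = g[i])
    } else if (kind == "duplication") {
      s <- append(s, s[g[i]:g2[i]], after = g2[i])
    } else {  # delins
      s <- append(s[-(g[i]:g2[i])], strsplit(v$alt[i], "")[[1]],
                  after = g[i] - 1L)
    }
  }
  Biostrings::DNAString(paste(s, collapse = ""))
}
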