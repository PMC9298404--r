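# Shared fixtures, cached across test files (cohort generation is cheap but
# not free, and several files exercise the same presets).
.fixtures <- new.env(parent = emptyenv())

fixtureCohort <- function(preset = "full", seed = 101L, noise = 0) {
  key <- paste(preset, seed, noise)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- makeCohort(preset, seed = seed, noise = noise)
  .fixtures[[key]]
}

fixtureReference <- function() {
  if (is.null(.fixtures[["ref"]]))
    .fixtures[["ref"]] <- syntheticReference(defaultGeneModel(), seed = 1L)
  .fixtures[["ref"]]
}

publishedCatalog <- function() bundledMarkerCatalog()

catalogMarkerLabels <- function() {
  unlist(bundledMarkerCatalog()@markers, use.names = FALSE)
}

# every variant string printed in the study tables (intronic catalog,
# subtype coding variants, regulatory element variants, recombination flank)
printedVariantLabels <- function() {
  unique(c(
    catalogMarkerLabels(),
    "c.106delG", "c.389T>C", "c.410C>T", "c.940A>G", "c.721C>T", "c.541T>C",
    "c.467C>T", "c.539G>C", "c.700C>G", "c.701C>T", "c.803G>C", "c.28G>A",
    "c.964G>A", "c.261delG",
    "c.28+5872C>T", "c.28+5882C>T", "c.28+5956T>A",
    "c.29-1053_29-1037del"))
}

# independent brute-force marker oracle: test the all-X-and-no-Y predicate
# for every observed intronic variant by exhaustive iteration
bruteForceMarkers <- function(panel, gt) {
  obsOf <- function(p) {
    k <- calls(p)
    k[k$zygosity %in% c("het", "hom_alt") & k$offset != 0, "hgvs_c"]
  }
  zygAt <- function(p, v) {
    k <- calls(p)
    z <- k$zygosity[match(v, k$hgvs_c)]
    if (is.na(z)) "hom_ref" else z
  }
  allVars <- unique(unlist(lapply(panel, obsOf)))
  out <- list()
  for (X in unique(gt)) {
    mk <- character(0)
    for (v in allVars) {
      ok <- TRUE
      for (i in seq_along(panel)) {
        z <- zygAt(panel[[i]], v)
        if (gt[i] == X && z != "hom_alt") { ok <- FALSE; break }
        if (gt[i] != X && z != "hom_ref") { ok <- FALSE; break }
      }
      if (ok) mk <- c(mk, v)
    }
    out[[X]] <- mk
  }
  out
}

# quick profile builder: het/hom_alt calls with clean depth/fraction
mkProfile <- function(hgvs, zygosity, sampleId = "t", depth = 200L) {
  af <- ifelse(zygosity == "hom_alt", 0.98,
               ifelse(zygosity == "het", 0.5, 0.02))
  SampleProfile(sampleId,
                data.frame(hgvs_c = hgvs, zygosity = zygosity,
                           depth = depth, alt_fraction = af,
                           stringsAsFactors = FALSE))
}
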