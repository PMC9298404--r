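test_that("the homozygote panel reproduces the published marker catalog row for row", {
  coh <- fixtureCohort("table2")
  cat2 <- deriveMarkerCatalog(coh$profiles, coh$table)
  sizes <- vapply(cat2@markers, length, integer(1))
  expect_equal(sizes[["ABO*B.01"]], 12L)
  expect_equal(sizes[["ABO*O.01.01"]], 10L)
  expect_equal(sizes[["ABO*O.01.02"]], 35L)
  expect_equal(sizes[["ABO*A1.02"]], 0L)
  truthCat <- publishedCatalog()
  for (al in c("ABO*B.01", "ABO*O.01.01", "ABO*O.01.02"))
    expect_setequal(markerSet(cat2, al), markerSet(truthCat, al))
  expect_true("c.29-86G>A" %in% markerSet(cat2, "ABO*B.01"))
  # exactly one sample (the hidden recombinant) raises quality warnings
  expect_length(unique(cat2@qualityWarnings$sample_id), 1L)
  # marker sets are pairwise disjoint
  allm <- unlist(cat2@markers, use.names = FALSE)
  expect_false(anyDuplicated(allm) > 0)
})

test_that("derivation demands a contrast group and homozygous input", {
  coh <- fixtureCohort("table2")
  bOnly <- coh$profiles[2:5]
  g <- setNames(rep("ABO*B.01", 4), vapply(bOnly, sampleId, character(1)))
  expect_error(deriveMarkers(bOnly, g), "at least two distinct allele")
  g2 <- g; g2[2] <- "ABO*B.01/ABO*O.01.01"
  expect_error(deriveMarkers(bOnly, g2), "heterozygous genotype")
})

test_that("brute-force specificity enumeration agrees with the derivation", {
  coh <- fixtureCohort("table2")
  cl <- lapply(coh$profiles[1:45], callGenotype, table = coh$table)
  hom <- vapply(cl, function(x) x@allelePair[1] == x@allelePair[2] &&
                  length(x@novelVariants) == 0, logical(1))
  panel <- coh$profiles[1:45][hom]
  gt <- vapply(cl[hom], function(x) x@allelePair[1], character(1))
  names(gt) <- vapply(panel, sampleId, character(1))
  flagged <- unique(deriveMarkers(panel, gt)@qualityWarnings$sample_id)
  panel <- panel[!names(gt) %in% flagged]
  gt <- gt[!names(gt) %in% flagged]
  got <- deriveMarkers(panel, gt)

  # oracle: for every observed intronic variant test the all-X-no-Y
  # predicate by exhaustive iteration over samples
  m <- defaultGeneModel()
  obsOf <- function(p) {
    k <- calls(p)
    k[k$zygosity %in% c("het", "hom_alt") & k$offset != 0, ]
  }
  allVars <- unique(unlist(lapply(panel, function(p) obsOf(p)$hgvs_c)))
  oracle <- setNames(vector("list", length(unique(gt))), unique(gt))
  for (X in unique(gt)) {
    mk <- character(0)
    for (v in allVars) {
      ok <- TRUE
      for (i in seq_along(panel)) {
        k <- calls(panel[[i]])
        z <- k$zygosity[match(v, k$hgvs_c)]
        if (is.na(z)) z <- "hom_ref"
        if (gt[i] == X && z != "hom_alt") { ok <- FALSE; break }
        if (gt[i] != X && z != "hom_ref") { ok <- FALSE; break }
      }
      if (ok) mk <- c(mk, v)
    }
    oracle[[X]] <- mk
  }
  for (X in names(oracle))
    expect_setequal(markerSet(got, X), oracle[[X]])
})

test_that("adding a contrast sample can only shrink or preserve marker sets", {
  coh <- fixtureCohort("table2")
  cl <- lapply(coh$profiles, callGenotype, table = coh$table)
  hom <- vapply(cl, function(x) x@allelePair[1] == x@allelePair[2] &&
                  length(x@novelVariants) == 0, logical(1))
  panel <- coh$profiles[hom]
  gt <- vapply(cl[hom], function(x) x@allelePair[1], character(1))
  names(gt) <- vapply(panel, sampleId, character(1))
  flagged <- unique(deriveMarkers(panel, gt)@qualityWarnings$sample_id)
  keep <- !(names(gt) %in% flagged)
  panel <- panel[keep]; gt <- gt[keep]
  base <- which(gt != "ABO*O.01.02")[1:20]
  small <- deriveMarkers(panel[base], gt[base])
  extraIdx <- c(base, which(gt == "ABO*O.01.02")[1])
  bigger <- deriveMarkers(panel[extraIdx], gt[extraIdx])
  for (X in unique(gt[base]))
    expect_true(all(markerSet(bigger, X) %in% markerSet(small, X)))
})

test_that("tolerant derivation recovers the catalog under zygosity noise", {
  spec <- data.frame(
    a1 = c("ABO*A1.02", "ABO*B.01", "ABO*O.01.01", "ABO*O.01.02"),
    a2 = c("ABO*A1.02", "ABO*B.01", "ABO*O.01.01", "ABO*O.01.02"),
    n = 30L, extra1 = "", extra2 = "", recomb = NA_character_,
    mechanism = NA_character_, id = NA_character_,
    stringsAsFactors = FALSE)
  coh <- makeCohort(spec, noise = 0.02, seed = 202L)
  gt <- setNames(coh$truth$allele1, coh$truth$sample_id)
  tolerant <- deriveMarkers(coh$profiles, gt, delta = 0.1)
  truthCat <- publishedCatalog()
  for (al in c("ABO*B.01", "ABO*O.01.01", "ABO*O.01.02"))
    expect_setequal(markerSet(tolerant, al), markerSet(truthCat, al))
  # the strict rule loses markers on the same noisy panel
  strict <- deriveMarkers(coh$profiles, gt, delta = 0)
  expect_lt(length(unlist(strict@markers)), length(unlist(tolerant@markers)))
})

test_that("variant counts against the reference respect the region filter", {
  tab <- defaultAlleleTable()
  cat3 <- publishedCatalog()
  ref <- makeSample(character(0), character(0), seed = 9L)
  expect_equal(countDiffsVsReference(ref, "intronic"), 0L)
  bb <- makeSample(markerSet(cat3, "ABO*B.01"), markerSet(cat3, "ABO*B.01"),
                   seed = 9L)
  expect_equal(countDiffsVsReference(bb, "intronic"), 12L)
  oo <- makeSample(markerSet(cat3, "ABO*O.01.02"),
                   markerSet(cat3, "ABO*O.01.02"), seed = 9L)
  expect_equal(countDiffsVsReference(oo, "intronic"), 35L)
  mixed <- makeSample(buildHaplotype("ABO*O.01.02", tab),
                      buildHaplotype("ABO*O.01.02", tab), seed = 9L)
  expect_equal(countDiffsVsReference(mixed, "coding"), 10L)
  expect_equal(countDiffsVsReference(mixed, "all"),
               countDiffsVsReference(mixed, "coding") +
                 countDiffsVsReference(mixed, "intronic"))
})
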