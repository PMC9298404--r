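test_that("substitutions, deletions and repeat insertions parse to the right fields", {
  v <- parseHgvsC("c.28+5956T>A")
  expect_equal(v$kind, "substitution")
  expect_equal(v$anchor, 28L)
  expect_equal(v$offset, 5956L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "A")

  d <- parseHgvsC("c.261delG")
  expect_equal(d$kind, "deletion")
  expect_equal(d$anchor, 261L)
  expect_equal(d$offset, 0L)
  expect_equal(d$ref, "G")

  ins <- parseHgvsC("c.239+103_239+105insC[3]")
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$alt, "CCC")          # repeat unit expanded
  expect_equal(ins$ins_unit, "C")
  expect_equal(ins$ins_rep, 3L)
  expect_equal(ins$anchor2, 239L)
  expect_equal(ins$offset2, 105L)

  di <- parseHgvsC("c.29-780delinsGG")
  expect_equal(di$kind, "delins")
  expect_equal(di$alt, "GG")

  dup <- parseHgvsC("c.204-61dupC")
  expect_equal(dup$kind, "duplication")
  expect_equal(dup$ref, "C")

  del <- parseHgvsC("c.29-1053_29-1037del")
  expect_equal(del$kind, "deletion")
  expect_equal(del$offset, -1053L)
  expect_equal(del$offset2, -1037L)
})

test_that("malformed HGVS strings fail with the offending token named", {
  expect_error(parseHgvsC("c.28+0T>A"), "zero intron offset")
  expect_error(parseHgvsC("28G>A"), "begin with 'c\\.'")
  expect_error(parseHgvsC("c.28X>A"), "malformed")
  expect_error(parseHgvsC("c.28G>"), "malformed")
  expect_error(parseHgvsC("c.30_10del"), "start position after end")
  expect_error(parseHgvsC("c.28ins"), "ins requires")
  expect_error(parseHgvsC("c.28delinsXX"), "malformed")
  expect_error(parseHgvsC("c.261_262delG"), "length does not match span")
})

test_that("parse/format round-trips every printed variant string", {
  labs <- printedVariantLabels()
  expect_gt(length(labs), 70)
  expect_identical(formatHgvsC(parseHgvsC(labs)), labs)
})

test_that("gene-axis ordering follows the intron offset convention", {
  expect_equal(comparePositions("c.29-1053", "c.29-86"), "before")
  expect_equal(comparePositions("c.240-219", "c.240-25"), "before")
  expect_equal(comparePositions("c.374+89", "c.375-336"), "before")
  expect_equal(comparePositions("c.964", "c.964"), "equal")
  expect_equal(comparePositions("c.375-336", "c.374+89"), "after")
})

test_that("position order is total, antisymmetric and transitive on the fixture set", {
  labs <- printedVariantLabels()
  k <- positionKey(parseHgvsC(labs))
  pos <- paste0("c.", sub("^c\\.", "", labs))
  # totality + antisymmetry over all ordered pairs
  set.seed(11)
  idx <- cbind(sample(length(k), 400, replace = TRUE),
               sample(length(k), 400, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ab <- sign(k[i] - k[j])
    ba <- sign(k[j] - k[i])
    expect_identical(ab, -ba)
  }
  # transitivity: sort keys and verify pairwise order is consistent
  o <- order(k)
  expect_true(all(diff(k[o]) >= 0))
})

test_that("regions classify to the model's exons and introns", {
  m <- defaultGeneModel()
  expect_equal(classifyRegion("c.28+4282", m), "intron 1")
  expect_equal(classifyRegion("c.964", m), "exon 7")
  expect_equal(classifyRegion("c.240-25", m), "intron 5")
  # the published catalog labels these two rows intron 1, but exon 2 ends at
  # c.98 so the model places them in intron 2 (documented discrepancy)
  expect_equal(classifyRegion("c.98+362", m), "intron 2")
  expect_equal(classifyRegion("c.99-186", m), "intron 2")
  expect_error(classifyRegion("c.100+5", m), "non-boundary anchor")
  expect_error(classifyRegion("c.2000", m), "beyond the modeled cDNA")
})

test_that("the marker catalog's location column agrees with classifyRegion", {
  m <- defaultGeneModel()
  tab <- read.delim(system.file("extdata", "intronic_marker_catalog.tsv",
                                package = "aboseq"))
  got <- classifyRegion(parseHgvsC(tab$hgvs_c), m)
  printed <- tolower(gsub("intron(\\d)", "intron \\1", tab$location))
  flagged <- tab$hgvs_c %in% c("c.98+362C>T", "c.99-186C>A")
  expect_identical(got[!flagged], printed[!flagged])
  expect_true(all(got[flagged] == "intron 2"))
})

test_that("c-to-genomic conversion anchors, offsets and round-trips", {
  m <- defaultGeneModel()
  expect_equal(cToGenomic("c.1", m), m@cdsGenomicStart)
  expect_equal(cToGenomic("c.28+5", m), cToGenomic("c.28", m) + 5L)
  expect_equal(cToGenomic("c.29-86", m), cToGenomic("c.29", m) - 86L)
  # bijective over all printed positions
  v <- parseHgvsC(printedVariantLabels())
  g <- cToGenomic(v, m)
  back <- genomicToC(g, m)
  expect_identical(back$anchor, v$anchor)
  expect_identical(back$offset, v$offset)
  expect_error(cToGenomic("c.28+20000", m), "exceeds intron")
  expect_error(genomicToC(1L, m), "outside the modeled span")
})

test_that("genomic coordinates are strictly monotone in the gene-axis order", {
  m <- defaultGeneModel()
  v <- parseHgvsC(printedVariantLabels())
  k <- positionKey(v)
  g <- cToGenomic(v, m)
  o <- order(k)
  dk <- diff(k[o]); dg <- diff(g[o])
  expect_true(all(dg[dk > 0] > 0))
  expect_true(all(dg[dk == 0] == 0))
})

test_that("model validity and variant-capacity checks fail loudly", {
  expect_error(GeneModel(c(28L, 20L), 100L), "strictly increase")
  expect_error(GeneModel(c(28L, 98L), c(100L, 100L)), "intron lengths")
  m <- GeneModel(c(28L, 98L), 50L)
  expect_error(validateModelForVariants(m, c("c.28+30A>G", "c.29-30G>A")),
               "cannot hold offsets")
  expect_silent(validateModelForVariants(defaultGeneModel(),
                                         printedVariantLabels()))
})

test_that("a gene model reads back from a YAML config", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "contig: ABO_ref",
    "cds_genomic_start: 501",
    "exon_ends: [28, 98, 155, 203, 239, 374, 1065]",
    "intron_lengths: [13000, 760, 1200, 1480, 600, 1000]"), cfg)
  m <- readGeneModel(cfg)
  expect_equal(m@exonEnds, defaultGeneModel()@exonEnds)
  expect_equal(m@intronLengths, defaultGeneModel()@intronLengths)
  expect_equal(exonSpans(m)$start, c(1L, 29L, 99L, 156L, 204L, 240L, 375L))
})
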