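test_that("expected zygosity counts carrier alleles", {
  tab <- defaultAlleleTable(); cat3 <- publishedCatalog()
  expect_equal(expectedZygosity(c("ABO*B.01", "ABO*B.01"), "c.29-86G>A",
                                tab, cat3), "hom_alt")
  expect_equal(expectedZygosity(c("ABO*B.01", "ABO*O.01.01"), "c.29-86G>A",
                                tab, cat3), "het")
  # shared O-lineage variant configured on both O backgrounds
  expect_equal(expectedZygosity(c("ABO*O.01.01", "ABO*O.01.02"),
                                "c.29-1053_29-1037del", tab, cat3), "hom_alt")
  expect_equal(expectedZygosity(c("ABO*A1.02", "ABO*B3.10"), "c.29-86G>A",
                                tab, cat3), "het")   # via the B lineage root
  expect_error(expectedZygosity(c("ABO*B.01", "ABO*B.01"), "c.500X",
                                tab, cat3), "unknown variant|malformed")
})

test_that("the intron-1 recombinant yields the published breakpoint interval", {
  coh <- fixtureCohort("full")
  ids <- vapply(coh$profiles, sampleId, character(1))
  rec <- coh$truth$sample_id[!is.na(coh$truth$recombinant) &
                             coh$truth$recombinant == "Brec1"]
  p <- coh$profiles[[match(rec, ids)]]
  cl <- callGenotype(p, coh$table)
  expect_equal(genotypeLabel(cl), "ABO*B.01/ABO*B.01")
  ev <- detectRecombination(p, cl, coh$table, coh$catalog)
  expect_length(ev, 1)
  expect_equal(ev[[1]]@status, "ok")
  expect_equal(ev[[1]]@donor, "ABO*O.01.01")
  expect_equal(breakpointInterval(ev[[1]]),
               c("c.29-1053_29-1037del", "c.29-86G>A"))
})

test_that("the intron-5 recombinants yield the published breakpoint interval", {
  coh <- fixtureCohort("full")
  ids <- vapply(coh$profiles, sampleId, character(1))
  for (id in c("19047", "19004")) {
    p <- coh$profiles[[match(id, ids)]]
    cl <- callGenotype(p, coh$table)
    expect_equal(genotypeLabel(cl), "ABO*B3.10/ABO*O.01.01", info = id)
    ev <- detectRecombination(p, cl, coh$table, coh$catalog)
    expect_length(ev, 1)
    expect_equal(ev[[1]]@donor, "ABO*O.01.01", info = id)
    expect_equal(breakpointInterval(ev[[1]]),
                 c("c.240-219G>A", "c.240-25A>G"), info = id)
  }
})

test_that("double-crossover patterns route to the untypical report", {
  coh <- fixtureCohort("full")
  ids <- vapply(coh$profiles, sampleId, character(1))
  for (id in c("19048", "19008", "19032")) {
    p <- coh$profiles[[match(id, ids)]]
    cl <- callGenotype(p, coh$table)
    ev <- detectRecombination(p, cl, coh$table, coh$catalog)
    expect_length(ev, 1)
    expect_equal(ev[[1]]@status, "untypical", info = id)
    expect_true(all(is.na(breakpointInterval(ev[[1]]))))
    expect_gt(length(ev[[1]]@notes), 1)
  }
})

test_that("no recombination is reported for any non-recombinant fixture sample", {
  coh <- fixtureCohort("full")
  clean <- is.na(coh$truth$recombinant)
  for (i in which(clean)) {
    p <- coh$profiles[[i]]
    cl <- callGenotype(p, coh$table)
    ev <- detectRecombination(p, cl, coh$table, coh$catalog)
    expect_length(ev, 0)
  }
})

test_that("random single-crossover recombinants are bounded by the flanking informative markers", {
  coh <- fixtureCohort("table2")   # provides the augmented table
  tab <- coh$table; cat3 <- coh$catalog
  m <- defaultGeneModel()
  hapB <- buildHaplotype("ABO*B.01", tab, cat3)
  hapO <- buildHaplotype("ABO*O.01.01", tab, cat3)
  isIntronic <- function(v) parseHgvsC(v)$offset != 0
  axis <- sort(union(hapB[isIntronic(hapB)], hapO[isIntronic(hapO)]))
  keys <- positionKey(parseHgvsC(axis))
  axis <- axis[order(keys)]; keys <- sort(keys)
  # stay 5' of the coding exon 6 so the coding genotype remains B/B
  axis <- axis[keys < positionKey("c.239+1")]
  v <- parseHgvsC(axis)
  gEnd2 <- vapply(seq_len(nrow(v)), function(i)
    cToGenomic(paste0("c.", v$anchor2[i],
                      ifelse(v$offset2[i] == 0, "",
                             sprintf("%+d", v$offset2[i]))), m), integer(1))
  gStart <- cToGenomic(v, m)

  set.seed(303)
  nTrial <- 200
  executed <- 0; contained <- 0; tight <- 0
  for (t in seq_len(nTrial)) {
    gap <- sample(length(axis) - 1L, 1L)
    gLo <- max(gEnd2[gap], gStart[gap]) + 1L
    gHi <- gStart[gap + 1L] - 1L
    if (gLo > gHi) next
    bpG <- if (gLo == gHi) gLo else sample(gLo:gHi, 1L)
    bp <- genomicToC(bpG, m)$position
    bpKey <- positionKey(bp)
    if (!(bpKey > positionKey(parseHgvsC(axis[gap])) &&
          bpKey < positionKey(parseHgvsC(axis[gap + 1L])))) next
    executed <- executed + 1
    rec <- makeRecombinant("ABO*O.01.01", "ABO*B.01", bp, tab, cat3)
    p <- makeSample(hapB, rec, sampleId = paste0("trial", t))
    cl <- callGenotype(p, tab)
    ev <- detectRecombination(p, cl, tab, cat3)
    expect_length(ev, 1)
    expect_true(ev[[1]]@status %in% c("ok", "low_confidence"))
    iv <- breakpointInterval(ev[[1]])
    ivKeys <- positionKey(parseHgvsC(iv))
    if (ivKeys[1] < bpKey && bpKey < ivKeys[2]) contained <- contained + 1

    # tightness oracle (unambiguous-donor trials): the flanks must be the
    # adjacent observed positions that distinguish the two haplotype
    # hypotheses, i.e. the symmetric difference of the donor contents
    # restricted to positions with observable signal
    if (identical(ev[[1]]@donor, "ABO*O.01.01")) {
      symdiff <- union(setdiff(hapB, hapO), setdiff(hapO, hapB))
      symdiff <- symdiff[isIntronic(symdiff)]
      w <- union(hapB[isIntronic(hapB)], rec[isIntronic(rec)])
      dPos <- intersect(symdiff, w)
      dKeys <- positionKey(parseHgvsC(dPos))
      dPos <- dPos[order(dKeys)]; dKeys <- sort(dKeys)
      lf <- dPos[max(which(dKeys < bpKey))]
      rf <- dPos[min(which(dKeys > bpKey))]
      tight <- tight + 1
      expect_identical(unname(iv), c(lf, rf))
    }
  }
  expect_gt(executed, 150)           # most draws land in usable gaps
  expect_equal(contained, executed)  # containment holds in every trial
  expect_gt(tight, 100)              # donor usually resolves uniquely
})

test_that("read-backed phasing separates cis from trans and is label-symmetric", {
  frag <- function(tv, av) list(fragment_id = "f", haplotype = 1L,
                                obs = c("c.28+5956T>A" = tv, "c.29-86G>A" = av))
  cis <- c(replicate(5, frag("alt", "alt"), simplify = FALSE),
           replicate(5, frag("ref", "ref"), simplify = FALSE))
  out <- phaseByReads(cis, "c.28+5956T>A", "c.29-86G>A")
  expect_equal(out$verdict, "cis")
  expect_equal(out$n_informative, 5L)

  trans <- c(replicate(5, frag("alt", "ref"), simplify = FALSE),
             replicate(5, frag("ref", "alt"), simplify = FALSE))
  out2 <- phaseByReads(trans, "c.28+5956T>A", "c.29-86G>A")
  expect_equal(out2$verdict, "trans")

  # swapping the anchor's ref/alt labels flips the verdict
  flip <- lapply(cis, function(f) {
    f$obs[["c.29-86G>A"]] <- ifelse(f$obs[["c.29-86G>A"]] == "alt", "ref", "alt")
    f
  })
  expect_equal(phaseByReads(flip, "c.28+5956T>A", "c.29-86G>A")$verdict, "trans")

  # too few informative fragments -> unknown
  out3 <- phaseByReads(cis[1:2], "c.28+5956T>A", "c.29-86G>A")
  expect_equal(out3$verdict, "unknown")
  expect_equal(phaseByReads(list(), "c.28+5956T>A", "c.29-86G>A")$verdict,
               "unknown")
})

test_that("a novel element variant phases trans to the other haplotype's markers", {
  coh <- fixtureCohort("table2")
  tab <- coh$table; cat3 <- coh$catalog
  h1 <- c(buildHaplotype("ABO*A1.02", tab, cat3), "c.28+5956T>A")
  h2 <- buildHaplotype("ABO*O.01.02", tab, cat3)
  frags <- makeReadFragments(h1, h2, region = c("c.28+1", "c.29-1"),
                             nFragments = 120, fragmentSpan = 13000,
                             seed = 17L)
  anchors <- intersect(markerSet(cat3, "ABO*O.01.02"),
                       h2[parseHgvsC(h2)$offset != 0])
  anchors <- anchors[parseHgvsC(anchors)$anchor <= 29]   # intron-1 anchors
  out <- phaseByReads(frags, "c.28+5956T>A", anchors)
  expect_true(all(out$verdict == "trans"))

  # forced single-haplotype sampling is consistent with that haplotype
  f1 <- makeReadFragments(h1, h2, region = c("c.28+1", "c.29-1"),
                          nFragments = 10, fragmentSpan = 13000,
                          haplotype = 1L, seed = 18L)
  expect_true(all(vapply(f1, function(f) {
    alts <- names(f$obs)[f$obs == "alt"]
    all(alts %in% h1)
  }, logical(1))))

  expect_equal(length(makeReadFragments(h1, h2, region = c("c.28+1", "c.29-1"),
                                        nFragments = 0, seed = 1L)), 0L)
  expect_error(makeReadFragments("c.964G>A", character(0),
                                 region = c("c.28+1", "c.28+100"),
                                 nFragments = 5),
               "no variant positions")
})
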