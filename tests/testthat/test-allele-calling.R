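tab <- defaultAlleleTable()

test_that("allele table resolves parent chains and lineage roots", {
  expect_setequal(codingVariants(tab, "ABO*B3.10"),
                  c("c.28G>A", codingVariants(tab, "ABO*B.01")))
  expect_equal(lineageRoot(tab, "ABO*B3.10"), "ABO*B.01")
  expect_equal(lineageRoot(tab, "ABO*cisAB.01"), "ABO*A1.02")
  expect_setequal(baseAlleles(tab),
                  c("ABO*A1.01", "ABO*A1.02", "ABO*B.01",
                    "ABO*O.01.01", "ABO*O.01.02"))
  expect_true(isSubtypeAllele(tab, "ABO*BW.28"))
  expect_false(isSubtypeAllele(tab, "ABO*B.01"))
  expect_error(codingVariants(tab, "ABO*nope"), "unknown allele")
})

test_that("textbook genotypes are called from coding zygosity patterns", {
  # homozygous O: the single-base deletion alone
  p <- mkProfile("c.261delG", "hom_alt")
  cl <- callGenotype(p, tab)
  expect_equal(genotypeLabel(cl), "ABO*O.01.01/ABO*O.01.01")
  expect_length(novelVariants(cl), 0)
  expect_true(cl@zygosityConsistent)

  # novel O allele: hom deletion plus het exon-7 substitution
  p2 <- mkProfile(c("c.261delG", "c.964G>A"), c("hom_alt", "het"))
  cl2 <- callGenotype(p2, tab)
  expect_equal(genotypeLabel(cl2), "ABO*O.01.01/ABO*O.01.01")
  expect_identical(novelVariants(cl2), "c.964G>A")

  # B/O heterozygote: het at the deletion and the whole B coding set
  bset <- codingVariants(tab, "ABO*B.01")
  p3 <- mkProfile(c("c.261delG", bset), rep("het", 1 + length(bset)))
  cl3 <- callGenotype(p3, tab)
  expect_equal(genotypeLabel(cl3), "ABO*B.01/ABO*O.01.01")

  # all coding positions reference -> reference pair
  p4 <- mkProfile("c.29-86G>A", "het")   # intronic only
  cl4 <- callGenotype(p4, tab)
  expect_equal(genotypeLabel(cl4), "ABO*A1.01/ABO*A1.01")

  expect_error(callGenotype(SampleProfile("e", data.frame(
    hgvs_c = character(0), zygosity = character(0), depth = integer(0),
    alt_fraction = numeric(0))), tab), "empty profile")
})

test_that("noise-free samples from every common-allele pair are recovered exactly", {
  common <- c("ABO*A1.01", "ABO*A1.02", "ABO*B.01", "ABO*O.01.01", "ABO*O.01.02")
  for (i in seq_along(common)) for (j in i:length(common)) {
    a1 <- common[i]; a2 <- common[j]
    h1 <- buildHaplotype(a1, tab); h2 <- buildHaplotype(a2, tab)
    p <- if (length(h1) + length(h2) == 0) {
      # reference homozygote: coding positions called reference-homozygous
      mkProfile("c.467C>T", "hom_ref", sampleId = paste(a1, a2))
    } else {
      makeSample(h1, h2, sampleId = paste(a1, a2), seed = 5L)
    }
    cl <- callGenotype(p, tab)
    expect_identical(allelePair(cl), sort(c(a1, a2)),
                     info = paste(a1, a2))
    expect_length(novelVariants(cl), 0)

    # brute-force oracle: enumerate pairs and compare predicted coding
    # patterns to the observed ones directly
    obs <- calls(p)
    obs <- obs[obs$offset == 0 & obs$zygosity != "hom_ref", ]
    obsMap <- setNames(obs$zygosity, obs$hgvs_c)
    consistent <- character(0)
    for (x in common) for (y in common[match(x, common):length(common)]) {
      cx <- codingVariants(tab, x); cy <- codingVariants(tab, y)
      u <- union(cx, cy)
      pred <- setNames(ifelse(u %in% cx & u %in% cy, "hom_alt", "het"), u)
      got <- obsMap[u]; got[is.na(got)] <- "hom_ref"
      if (all(got == pred) && all(names(obsMap) %in% u))
        consistent <- c(consistent, paste(sort(c(x, y)), collapse = "/"))
    }
    expect_true(genotypeLabel(cl) %in% consistent)
    alt <- cl@alternatives
    alt <- alt[alt$n_mismatch == 0 & alt$n_novel == 0 &
               alt$allele1 %in% common & alt$allele2 %in% common, ]
    expect_setequal(paste(alt$allele1, alt$allele2, sep = "/"), consistent)
  }
})

test_that("a single novel coding variant never changes the recovered pair", {
  spare <- c("c.350A>G", "c.600G>T", "c.900C>A")  # unused exonic positions
  common <- c("ABO*A1.02", "ABO*B.01", "ABO*O.01.01", "ABO*O.01.02")
  k <- 0
  for (i in seq_along(common)) for (j in i:length(common)) {
    k <- k + 1
    nv <- spare[(k %% length(spare)) + 1]
    h1 <- c(buildHaplotype(common[i], tab), nv)
    h2 <- buildHaplotype(common[j], tab)
    p <- makeSample(h1, h2, seed = 6L)
    cl <- callGenotype(p, tab)
    expect_identical(allelePair(cl), sort(c(common[i], common[j])))
    expect_identical(novelVariants(cl), nv)
  }
})

test_that("all 17 coding-variant subtype profiles reproduce the published genotype strings", {
  coh <- fixtureCohort("subtypes")
  expected <- c(
    "19001" = "ABO*A1.02/ABO*O.01.01",
    "19014" = "ABO*A1.02/ABO*O.01.02",
    "19007" = "ABO*A1.02/ABO*O.01.01",
    "19046" = "ABO*A1.02/ABO*O.01.01",
    "19035" = "ABO*AW.37/ABO*B.01",
    "19041" = "ABO*BW.03/ABO*O.01.02",
    "19005" = "ABO*BW.28/ABO*O.01.01",
    "19026" = "ABO*A2.08/ABO*B.01",
    "19039" = "ABO*A2.07/ABO*B.01",
    "19011" = "ABO*BA.02/ABO*O.01.02",
    "19019" = "ABO*BA.07/ABO*O.01.02",
    "19034" = "ABO*cisAB.01/ABO*O.01.02",
    "19048" = "ABO*B3.10/ABO*O.01.02",
    "19008" = "ABO*B3.10/ABO*O.01.02",
    "19047" = "ABO*B3.10/ABO*O.01.01",
    "19004" = "ABO*B3.10/ABO*O.01.01",
    "19032" = "ABO*A1.02/ABO*B3.10")
  ids <- vapply(coh$profiles, sampleId, character(1))
  for (id in names(expected)) {
    p <- coh$profiles[[match(id, ids)]]
    expect_equal(genotypeLabel(callGenotype(p, coh$table)), expected[[id]],
                 info = id)
  }
})

test_that("regulatory-element annotation matches the bundled associations", {
  p <- mkProfile(c("c.28+5872C>T", "c.28+4282A>G"), c("het", "het"))
  a <- annotateRegulatory(p)
  row <- a[a$hgvs_c == "c.28+5872C>T", ]
  expect_true(row$in_element)
  expect_equal(row$association, "B3/AB3")
  expect_false(row$novel_association)
  expect_false(a[a$hgvs_c == "c.28+4282A>G", "in_element"])

  p2 <- mkProfile("c.28+5956T>A", "het")
  a2 <- annotateRegulatory(p2)
  expect_true(a2$in_element)
  expect_equal(a2$association, "A3")
  expect_true(a2$novel_association)

  # in-window variant without a bundled association
  p3 <- mkProfile("c.28+5900G>A", "het")
  a3 <- annotateRegulatory(p3)
  expect_equal(a3$association, "element, unknown effect")
})

test_that("subtype mechanisms split into coding, regulatory and unexplained", {
  # coding: named subtype pair (Ael-like c.410C>T is carried as novel)
  p <- mkProfile(c("c.467C>T", "c.410C>T", "c.261delG"),
                 c("het", "het", "het"))
  cl <- callGenotype(p, tab)
  expect_equal(genotypeLabel(cl), "ABO*A1.02/ABO*O.01.01")
  expect_identical(novelVariants(cl), "c.410C>T")
  expect_equal(classifySubtypeMechanism(cl, annotateRegulatory(p), tab),
               "coding_variant")

  # regulatory: clean coding genotype, element variant present
  p2 <- mkProfile(c("c.467C>T", "c.261delG", "c.28+5956T>A"),
                  c("het", "het", "het"))
  cl2 <- callGenotype(p2, tab)
  expect_length(novelVariants(cl2), 0)
  expect_equal(classifySubtypeMechanism(cl2, annotateRegulatory(p2), tab),
               "regulatory_variant")

  # neither -> unexplained
  p3 <- mkProfile(c("c.467C>T", "c.261delG"), c("het", "het"))
  cl3 <- callGenotype(p3, tab)
  expect_equal(classifySubtypeMechanism(cl3, annotateRegulatory(p3), tab),
               "unexplained")
})
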