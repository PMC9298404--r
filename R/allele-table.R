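#' @include vcf.R
NULL

#' Construct an AlleleDefinition
#'
#' @param name ISBT-style allele label (e.g. \code{"ABO*O.01.01"}).
#' @param coding,intronic character vectors of HGVS c. labels.
#' @param parent optional base-allele name the definition extends.
#' @param subtype logical, whether the allele defines a subtype phenotype.
#' @return an \linkS4class{AlleleDefinition}.
#' @export
AlleleDefinition <- function(name, coding = character(0),
                             intronic = character(0), parent = NA_character_,
                             subtype = FALSE) {
  if (length(coding)) parseHgvsC(coding)     # validate labels
  if (length(intronic)) parseHgvsC(intronic)
  new("AlleleDefinition", name = name, coding = as.character(coding),
      intronic = as.character(intronic), parent = as.character(parent),
      subtype = isTRUE(subtype))
}

#' Construct an AlleleTable
#'
#' @param alleles list of \linkS4class{AlleleDefinition}.
#' @param reference name of the mapping reference allele (empty variant
#'   sets; all variants are relative to it).
#' @return a validated \linkS4class{AlleleTable}.
#' @export
AlleleTable <- function(alleles, reference = "ABO*A1.01") {
  names(alleles) <- vapply(alleles, function(a) a@name, character(1))
  new("AlleleTable", alleles = alleles, reference = reference)
}

#' Read an allele-definition table from YAML/JSON
#'
#' The config has a \code{reference} name and an \code{alleles} list whose
#' entries give \code{name} and optional \code{coding}, \code{intronic},
#' \code{parent}, \code{subtype} fields.
#'
#' @param path config file path.
#' @return an \linkS4class{AlleleTable}.
#' @export
readAlleleTable <- function(path) {
  cfg <- yaml::read_yaml(path)
  alleles <- lapply(cfg$alleles, function(a) {
    AlleleDefinition(a$name,
                     coding = unlist(a$coding) %||% character(0),
                     intronic = unlist(a$intronic) %||% character(0),
                     parent = a$parent %||% NA_character_,
                     subtype = isTRUE(a$subtype))
  })
  AlleleTable(alleles, reference = cfg$reference %||% "ABO*A1.01")
}

#' The bundled fixture allele table
#'
#' Common alleles A1.01 (reference), A1.02, B.01, O.01.01, O.01.02 plus the
#' subtype alleles of the bundled cohort presets, with coding contents
#' following ISBT convention. A fixture: swap in
#' \code{\link{readAlleleTable}} with the full ISBT catalog for production
#' use.
#'
#' @return an \linkS4class{AlleleTable}.
#' @export
defaultAlleleTable <- function() {
  readAlleleTable(system.file("extdata", "alleles.yaml", package = "aboseq"))
}

#' Resolved variant content of an allele
#'
#' Resolves the parent chain and returns the union of the allele's own and
#' all ancestors' variants.
#'
#' @param table an \linkS4class{AlleleTable}.
#' @param allele allele name.
#' @return character vector of HGVS c. labels.
#' @export
codingVariants <- function(table, allele) {
  .resolvedContent(table, allele, "coding")
}

#' @rdname codingVariants
#' @export
intronicVariants <- function(table, allele) {
  .resolvedContent(table, allele, "intronic")
}

.resolvedContent <- function(table, allele, what) {
  if (!allele %in% names(table@alleles))
    stop("unknown allele '", allele, "'")
  out <- character(0)
  a <- table@alleles[[allele]]
  repeat {
    out <- union(out, slot(a, what))
    if (is.na(a@parent)) break
    a <- table@alleles[[a@parent]]
  }
  out
}

#' Base lineage of an allele
#'
#' The top ancestor of the parent chain; marker catalogs are keyed by these
#' lineage roots.
#'
#' @param table an \linkS4class{AlleleTable}.
#' @param allele allele name.
#' @return allele name of the lineage root.
#' @export
lineageRoot <- function(table, allele) {
  if (!allele %in% names(table@alleles))
    stop("unknown allele '", allele, "'")
  a <- table@alleles[[allele]]
  while (!is.na(a@parent)) a <- table@alleles[[a@parent]]
  a@name
}

#' @rdname lineageRoot
#' @export
baseAlleles <- function(table) {
  nm <- names(table@alleles)
  nm[vapply(table@alleles, function(a) is.na(a@parent), logical(1))]
}

#' Is an allele flagged as a subtype allele?
#'
#' @param table an \linkS4class{AlleleTable}.
#' @param allele allele name.
#' @return logical.
#' @export
isSubtypeAllele <- function(table, allele) {
  if (!allele %in% names(table@alleles))
    stop("unknown allele '", allele, "'")
  table@alleles[[allele]]@subtype
}

#' Add seeded shared-lineage intronic background variants
#'
#' Real haplotypes carry many intronic variants shared across allele
#' lineages, which are exactly what an allele-specific marker derivation
#' must reject. This augments a table with \code{n} synthetic intronic SNVs,
#' each assigned to a deterministic multi-lineage carrier group, at seeded
#' intronic positions that avoid the bundled marker/regulatory/crossover
#' regions and are nearer their own anchor exon (so genomic round-trips
#' hold).
#'
#' @param table an \linkS4class{AlleleTable}.
#' @param n number of shared variants (default 20).
#' @param seed integer seed.
#' @param model a \linkS4class{GeneModel}.
#' @param catalog marker catalog whose positions must be avoided.
#' @return the augmented \linkS4class{AlleleTable}.
#' @export
addSharedLineageVariants <- function(table, n = 20L, seed = 1L,
                                     model = defaultGeneModel(),
                                     catalog = bundledMarkerCatalog()) {
  groups <- list(
    c("ABO*A1.02", "ABO*B.01"),
    c("ABO*O.01.01", "ABO*O.01.02"),
    c("ABO*B.01", "ABO*O.01.01", "ABO*O.01.02"),
    c("ABO*B.01", "ABO*O.01.02"))
  # group sizes: 4 A/B-shared (giving A1.02 its intronic background), the
  # rest split over O-lineage and B-containing groups
  sizes <- c(4L, max(0L, n - 12L), 4L, 4L)
  if (n < 12L) sizes <- c(min(4L, n), max(0L, n - 4L), 0L, 0L)
  groupOf <- rep(seq_along(groups), times = sizes)

  avoid <- .avoidedGenomicSpans(table, model, catalog)
  ends <- model@exonEnds
  starts <- c(1L, head(ends, -1L) + 1L)
  rs <- .seededRNG(seed)
  labels <- character(0)
  keysSeen <- numeric(0)
  while (length(labels) < n) {
    i <- sample(seq_along(model@intronLengths), 1L)
    len <- model@intronLengths[i]
    half <- (len - 1L) %/% 2L
    usePlus <- runif(1) < 0.5
    off <- sample(half, 1L)
    pos <- if (usePlus) .fmtPos(ends[i], off) else .fmtPos(starts[i + 1L], -off)
    g <- cToGenomic(paste0("c.", pos), model)
    if (any(g >= avoid$from & g <= avoid$to)) next
    key <- positionKey(paste0("c.", pos))
    if (key %in% keysSeen) next
    ref <- sample(c("A", "C", "G", "T"), 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    labels <- c(labels, paste0("c.", pos, ref, ">", alt))
    keysSeen <- c(keysSeen, key)
    avoid <- rbind(avoid, data.frame(from = g, to = g))
  }
  .restoreRNG(rs)

  for (k in seq_len(n)) {
    for (al in groups[[groupOf[k]]]) {
      a <- table@alleles[[al]]
      a@intronic <- union(a@intronic, labels[k])
      table@alleles[[al]] <- a
    }
  }
  validObject(table)
  table
}

# Genomic spans that seeded background variants must not enter: every
# bundled variant span (markers, allele content, regulatory associations),
# the regulatory element window, the primer landing sites, and the two
# modeled crossover windows.
.avoidedGenomicSpans <- function(table, model, catalog) {
  labs <- unique(c(unlist(catalog@markers, use.names = FALSE),
                   unlist(lapply(table@alleles,
                                 function(a) c(a@coding, a@intronic)),
                          use.names = FALSE),
                   regulatoryAssociations()$hgvs_c))
  v <- parseHgvsC(labs)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(v))) {
    g1 <- cToGenomic(.posLabel(v$anchor[i], v$offset[i]), model)
    g2 <- cToGenomic(.posLabel(v$anchor2[i], v$offset2[i]), model)
    from <- c(from, g1); to <- c(to, max(g1, g2))
  }
  extras <- rbind(
    c(cToGenomic("c.28+5856", model), cToGenomic("c.28+5958", model)),
    c(cToGenomic("c.29-1053", model), cToGenomic("c.29-86", model)),
    c(cToGenomic("c.240-219", model), cToGenomic("c.240-25", model)),
    c(model@cdsGenomicStart - 350L, model@cdsGenomicStart - 331L))
  data.frame(from = c(from, extras[, 1]), to = c(to, extras[, 2]))
}
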