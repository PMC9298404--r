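#' @include markers.R
NULL

# Does an allele carry a variant? Union of its resolved table content and
# the marker set of its lineage root.
.alleleCarries <- function(table, catalog, allele, hgvs) {
  root <- lineageRoot(table, allele)
  mk <- if (root %in% names(catalog@markers)) catalog@markers[[root]] else character(0)
  hgvs %in% c(codingVariants(table, allele),
              intronicVariants(table, allele), mk)
}

# Every variant the table + catalog know about.
.knownVariants <- function(table, catalog) {
  unique(c(unlist(lapply(table@alleles, function(a) c(a@coding, a@intronic)),
                  use.names = FALSE),
           unlist(catalog@markers, use.names = FALSE)))
}

#' Expected zygosity of a variant under a diploid allele pair
#'
#' hom_alt when both alleles carry the variant, het when exactly one does,
#' hom_ref otherwise. Carriage resolves parent chains and includes the
#' lineage's catalog markers.
#'
#' @param pair character of length 2, allele names.
#' @param hgvs HGVS c. label(s).
#' @param table an \linkS4class{AlleleTable}.
#' @param catalog a \linkS4class{MarkerCatalog}.
#' @return character vector of zygosity tokens.
#' @examples
#' tab <- defaultAlleleTable(); cat3 <- bundledMarkerCatalog()
#' expectedZygosity(c("ABO*B.01", "ABO*B.01"), "c.29-86G>A", tab, cat3)
#' @export
expectedZygosity <- function(pair, hgvs, table, catalog) {
  stopifnot(length(pair) == 2L)
  known <- .knownVariants(table, catalog)
  bad <- setdiff(hgvs, known)
  if (length(bad))
    stop("unknown variant(s): ", paste(bad, collapse = ", "))
  n <- .alleleCarries(table, catalog, pair[1], hgvs) +
       .alleleCarries(table, catalog, pair[2], hgvs)
  c("hom_ref", "het", "hom_alt")[n + 1L]
}

#' Detect intragenic allele recombination from marker zygosity patterns
#'
#' Walks the informative intronic positions in gene-axis order. Informative
#' positions are those known to the allele table or marker catalog where
#' either the called pair predicts a non-reference zygosity or a
#' non-reference call was observed (positions reference-homozygous on both
#' counts carry no signal in call-level data). A maximal run of discordant
#' zygosity that starts at one end of the gene and is fully explained by
#' substituting a single donor allele onto one haplotype is reported as a
#' recombination event; its breakpoint interval is the gap between the last
#' discordant position and the adjacent concordant informative position.
#' Donor identification additionally uses absence evidence: a candidate
#' donor predicting variants that are missing from the segment span is
#' refuted.
#'
#' Discordance that does not fit a single-crossover, single-donor
#' substitution — multiple discordant runs, a discordant block flanked by
#' concordant markers on both sides, or no consistent donor — is reported
#' as an \code{untypical} pattern without asserting an interval.
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param call the sample's \linkS4class{GenotypeCall}.
#' @param table an \linkS4class{AlleleTable}.
#' @param catalog a \linkS4class{MarkerCatalog}.
#' @param model a \linkS4class{GeneModel}.
#' @param minRun minimum number of informative discordant positions for a
#'   full-confidence segment (shorter runs are reported
#'   \code{low_confidence}).
#' @return list of \linkS4class{RecombinationEvent} (empty when every
#'   informative position is concordant).
#' @export
detectRecombination <- function(profile, call, table, catalog,
                                model = defaultGeneModel(), minRun = 2L) {
  pair <- call@allelePair
  known <- .knownVariants(table, catalog)
  known <- known[!isCoding(known, model)]
  keys <- positionKey(parseHgvsC(known))
  ord <- order(keys)
  known <- known[ord]; keys <- keys[ord]

  expZ <- expectedZygosity(pair, known, table, catalog)
  obsZ <- .observedZygosity(profile, known)
  usable <- obsZ != "ambiguous"
  known <- known[usable]; keys <- keys[usable]
  expZ <- expZ[usable]; obsZ <- obsZ[usable]

  # observed-informative walk: positions with signal in call-level data
  walk <- expZ != "hom_ref" | obsZ != "hom_ref"
  disc <- walk & (obsZ != expZ)
  if (!any(disc)) return(list())

  untypical <- function(msg) {
    list(new("RecombinationEvent",
             sampleId = profile@sampleId, status = "untypical",
             donor = character(0), replaced = NA_character_,
             segments = data.frame(),
             breakpointInterval = c(NA_character_, NA_character_),
             runLength = sum(disc), notes = c(msg, known[disc])))
  }

  # Single-crossover hypothesis scan. For donor substituted on the 5' side
  # up to some breakpoint: every position before the breakpoint must match
  # the substituted pair's expectation (including predicted variants that
  # are absent, the refuting evidence), every position after it the called
  # pair's. Feasible iff the last called-discordant position precedes the
  # first substitution-violating position; mirrored for a 3' donor side.
  maxD <- max(keys[disc]); minD <- min(keys[disc])
  hyps <- list()
  for (replaced in unique(pair)) {
    other <- if (pair[1] == replaced) pair[2] else pair[1]
    for (donor in baseAlleles(table)) {
      subPair <- c(other, donor)
      if (identical(sort(subPair), sort(pair))) next
      subExp <- expectedZygosity(subPair, known, table, catalog)
      badSub <- (subExp != "hom_ref" | obsZ != "hom_ref") & (obsZ != subExp)
      # observed positions that discriminate the called pair from the
      # substituted pair: only these can flank the crossover (positions
      # carried identically under both hypotheses are silent, and
      # reference-homozygous positions carry no signal in call-level data)
      discrim <- walk & (expZ != subExp)
      # 5' donor segment
      bKey <- if (any(badSub)) min(keys[badSub]) else Inf
      if (maxD < bKey) {
        after <- discrim & keys > maxD
        rightFlank <- if (any(after)) known[which(after)[1]] else NA_character_
        hyps[[length(hyps) + 1L]] <- list(
          side = "5'", donor = donor, replaced = replaced,
          interval = c(known[which(keys == maxD & disc)[1]], rightFlank))
      }
      # 3' donor segment
      bKey2 <- if (any(badSub)) max(keys[badSub]) else -Inf
      if (bKey2 < minD) {
        before <- discrim & keys < minD
        leftFlank <- if (any(before)) known[tail(which(before), 1L)] else NA_character_
        hyps[[length(hyps) + 1L]] <- list(
          side = "3'", donor = donor, replaced = replaced,
          interval = c(leftFlank, known[which(keys == minD & disc)[1]]))
      }
    }
  }
  if (length(hyps) == 0L)
    return(untypical("no single-crossover donor substitution explains the zygosity pattern"))
  sides <- unique(vapply(hyps, `[[`, character(1), "side"))
  if (length(sides) > 1L)
    return(untypical("ambiguous crossover orientation"))
  side <- sides[1]
  ivs <- lapply(hyps, `[[`, "interval")
  if (any(vapply(ivs, anyNA, logical(1))))
    return(untypical("donor segment not bounded inside the modeled gene"))
  # with several feasible donors the crossover region is the union of the
  # per-donor feasible ranges: shared inner flank, outermost outer flank
  if (side == "5'") {
    outer <- vapply(ivs, `[`, character(1), 2)
    interval <- c(ivs[[1]][1], outer[which.max(positionKey(parseHgvsC(outer)))])
  } else {
    outer <- vapply(ivs, `[`, character(1), 1)
    interval <- c(outer[which.min(positionKey(parseHgvsC(outer)))], ivs[[1]][2])
  }
  donors <- unique(vapply(hyps, `[[`, character(1), "donor"))
  replaced <- unique(vapply(hyps, `[[`, character(1), "replaced"))
  wlab <- known[walk]
  donorTxt <- paste(donors, collapse = "|")
  calledTxt <- paste(pair, collapse = "/")
  segs <- if (side == "5'") {
    data.frame(from = c(wlab[1], interval[2]),
               to = c(interval[1], wlab[length(wlab)]),
               donor = c(donorTxt, calledTxt), stringsAsFactors = FALSE)
  } else {
    data.frame(from = c(wlab[1], interval[2]),
               to = c(interval[1], wlab[length(wlab)]),
               donor = c(calledTxt, donorTxt), stringsAsFactors = FALSE)
  }
  runLen <- sum(disc)
  list(new("RecombinationEvent",
           sampleId = profile@sampleId,
           status = if (runLen < minRun) "low_confidence" else "ok",
           donor = donors,
           replaced = paste(replaced, collapse = "|"),
           segments = segs,
           breakpointInterval = interval,
           runLength = as.integer(runLen),
           notes = character(0)))
}

#' Tabulate recombination events over a cohort
#'
#' Convenience wrapper: genotype each profile, run
#' \code{\link{detectRecombination}}, and return one row per reported event.
#'
#' @param profiles list of \linkS4class{SampleProfile}.
#' @param table an \linkS4class{AlleleTable}.
#' @param catalog a \linkS4class{MarkerCatalog}.
#' @param model a \linkS4class{GeneModel}.
#' @param minRun see \code{\link{detectRecombination}}.
#' @return data.frame with columns \code{sample_id}, \code{status},
#'   \code{donor}, \code{interval_left}, \code{interval_right},
#'   \code{run_length}.
#' @export
screenRecombination <- function(profiles, table, catalog,
                                model = defaultGeneModel(), minRun = 2L) {
  rows <- lapply(profiles, function(p) {
    cl <- callGenotype(p, table, model)
    ev <- detectRecombination(p, cl, table, catalog, model, minRun)
    if (length(ev) == 0L) return(NULL)
    do.call(rbind, lapply(ev, function(e) data.frame(
      sample_id = e@sampleId, status = e@status,
      donor = paste(e@donor, collapse = "|"),
      interval_left = e@breakpointInterval[1],
      interval_right = e@breakpointInterval[2],
      run_length = e@runLength, stringsAsFactors = FALSE)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(0), status = character(0),
                      donor = character(0), interval_left = character(0),
                      interval_right = character(0), run_length = integer(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
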