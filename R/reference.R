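#' @include gene-model.R
NULL

# Primer set used for the two overlapping long-range amplicons that tile the
# gene from upstream of the start codon into the 3'UTR.
.lrPcrPrimers <- function() {
  read.delim(system.file("extdata", "lr_pcr_primers.tsv", package = "aboseq"),
             stringsAsFactors = FALSE)
}

#' Bundled long-range PCR primers
#'
#' The two primer pairs for overlap-amplicon coverage of the ABO gene
#' (5'UTR~intron 1 and intron 1~3'UTR) with their published amplicon sizes.
#'
#' @return data.frame with columns \code{name}, \code{sequence},
#'   \code{coverage}, \code{size_kb}.
#' @export
lrPcrPrimers <- function() .lrPcrPrimers()

# All HGVS labels the package bundles (marker catalog, allele definitions,
# regulatory element variants, preset novel variants); used to patch the
# synthetic reference so stated ref alleles agree with the sequence.
.bundledVariantLabels <- function() {
  cat3 <- bundledMarkerCatalog()
  tab <- defaultAlleleTable()
  content <- unlist(lapply(tab@alleles,
                           function(a) c(a@coding, a@intronic)),
                    use.names = FALSE)
  unique(c(unlist(cat3@markers, use.names = FALSE),
           content,
           regulatoryAssociations()$hgvs_c,
           .presetNovelVariants()))
}

#' Deterministic synthetic reference sequence for the bundled gene model
#'
#' Builds a synthetic stand-in for the RefSeqGene genomic record: a random
#' plus-strand sequence spanning 500 bp of 5' flank, the modeled gene and a
#' 500 bp 3' flank, with (i) the reference base(s) of every bundled variant
#' patched in at its genomic coordinate, so HGVS ref alleles agree with the
#' sequence, and (ii) the two long-range PCR primer pairs embedded so the
#' amplicons have the published sizes (12.8 kb and 8.7 kb, overlapping in
#' intron 1). It is a synthetic fixture, not the real accession; all
#' coordinate and PCR machinery applies unchanged to a user-supplied genomic
#' FASTA.
#'
#' @param model a \linkS4class{GeneModel}; must be the bundled model layout
#'   (the primer geometry is defined relative to it).
#' @param seed integer seed for the random background sequence.
#' @return a \code{Biostrings::DNAStringSet} of length 1 named after the
#'   model's contig.
#' @export
syntheticReference <- function(model = defaultGeneModel(), seed = 1L) {
  gEnd <- cToGenomic(paste0("c.", max(model@exonEnds)), model)
  totalLen <- gEnd + 500L
  if (model@cdsGenomicStart <= 370L)
    stop("synthetic reference needs >= 370 bp of 5' flank before c.1")
  rs <- .seededRNG(seed)
  base <- sample(c("A", "C", "G", "T"), totalLen, replace = TRUE)
  .restoreRNG(rs)

  # patch reference alleles of bundled variants; refuse conflicting patches
  v <- parseHgvsC(.bundledVariantLabels())
  at <- integer(0); nt <- character(0)
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    if (!nzchar(r$ref)) next
    g <- cToGenomic(.posLabel(r$anchor, r$offset), model)
    at <- c(at, g:(g + nchar(r$ref) - 1L))
    nt <- c(nt, strsplit(r$ref, "")[[1]])
  }
  if (length(at)) {
    agg <- tapply(nt, at, function(x) length(unique(x)))
    if (any(agg > 1L))
      stop("conflicting reference bases among bundled variants at g.",
           paste(names(agg)[agg > 1L], collapse = ", "))
    base[at] <- nt
  }

  # embed primers: amplicon 1 = 12800 bp starting 350 bp upstream of c.1,
  # amplicon 2 = 8700 bp ending in the 3' flank, overlapping in intron 1
  pr <- .lrPcrPrimers()
  f1 <- pr$sequence[pr$name == "ABO1longF"]
  r1 <- pr$sequence[pr$name == "ABO1longR"]
  f2 <- pr$sequence[pr$name == "ABOe27longF"]
  r2 <- pr$sequence[pr$name == "ABOe27longR"]
  a1_start <- model@cdsGenomicStart - 350L
  a1_end <- a1_start + 12800L - 1L
  a2_end <- totalLen - 206L
  a2_start <- a2_end - 8700L + 1L
  stopifnot(a1_end > a2_start, a2_end <= totalLen)
  .put <- function(base, seqs, at) {
    base[at:(at + nchar(seqs) - 1L)] <- strsplit(seqs, "")[[1]]
    base
  }
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  base <- .put(base, f1, a1_start)
  base <- .put(base, rc(r1), a1_end - nchar(r1) + 1L)
  base <- .put(base, f2, a2_start)
  base <- .put(base, rc(r2), a2_end - nchar(r2) + 1L)

  out <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(out) <- model@contig
  out
}

.posLabel <- function(anchor, offset) paste0("c.", .fmtPos(anchor, offset))

# Seed handling: temporarily install a local RNG state so simulation
# functions are reproducible without clobbering the caller's stream.
.seededRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
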