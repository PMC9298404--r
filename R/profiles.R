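#' @include insilico-pcr.R
NULL

.ZYGOSITY <- c("hom_ref", "het", "hom_alt")

#' Construct a SampleProfile from zygosity calls
#'
#' Parses and validates the HGVS labels, flags calls below the minimum read
#' depth, and sorts calls along the gene axis. Duplicate variant rows are an
#' error.
#'
#' @param sampleId sample identifier.
#' @param callTable data.frame with columns \code{hgvs_c}, \code{zygosity}
#'   (\code{hom_ref}/\code{het}/\code{hom_alt}, or \code{ambiguous}),
#'   \code{depth}, \code{alt_fraction}.
#' @param metadata list of free-form annotations.
#' @param minDepth minimum read depth for a full-confidence call; calls
#'   below it are retained but flagged \code{low_coverage}. Default 50, the
#'   coverage floor used for variant review.
#' @return a \linkS4class{SampleProfile}.
#' @export
SampleProfile <- function(sampleId, callTable, metadata = list(),
                          minDepth = 50L) {
  stopifnot(is.data.frame(callTable))
  need <- c("hgvs_c", "zygosity", "depth", "alt_fraction")
  miss <- setdiff(need, names(callTable))
  if (length(miss))
    stop("call table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(callTable$zygosity), c(.ZYGOSITY, "ambiguous"))
  if (length(bad))
    stop("unknown zygosity token(s): ", paste(bad, collapse = ", "))
  dup <- callTable$hgvs_c[duplicated(callTable$hgvs_c)]
  if (length(dup))
    stop("duplicate variant row(s): ", paste(unique(dup), collapse = ", "))
  if (nrow(callTable)) {
    v <- parseHgvsC(callTable$hgvs_c)
    callTable$anchor <- v$anchor
    callTable$offset <- v$offset
    callTable$kind <- v$kind
    callTable$key <- v$key
  } else {
    callTable$anchor <- integer(0); callTable$offset <- integer(0)
    callTable$kind <- character(0); callTable$key <- numeric(0)
  }
  callTable$depth <- as.integer(callTable$depth)
  callTable$alt_fraction <- as.numeric(callTable$alt_fraction)
  callTable$low_coverage <- callTable$depth < minDepth
  callTable <- callTable[order(callTable$key), , drop = FALSE]
  rownames(callTable) <- NULL
  new("SampleProfile", sampleId = as.character(sampleId),
      calls = callTable, metadata = metadata)
}

#' Derive a diploid zygosity call from an alt-read fraction
#'
#' Standard diploid thresholds, exposed as configuration: fractions below
#' \code{homRefMax} call hom_ref, within \code{[hetMin, hetMax]} het, above
#' \code{homAltMin} hom_alt; fractions in the gaps are flagged
#' \code{ambiguous}.
#'
#' @param altFraction numeric vector in [0, 1].
#' @param homRefMax,hetMin,hetMax,homAltMin thresholds (defaults 0.15,
#'   0.30, 0.70, 0.85).
#' @return character vector of zygosity tokens.
#' @export
zygosityFromFraction <- function(altFraction, homRefMax = 0.15,
                                 hetMin = 0.30, hetMax = 0.70,
                                 homAltMin = 0.85) {
  stopifnot(all(altFraction >= 0 & altFraction <= 1))
  ifelse(altFraction < homRefMax, "hom_ref",
    ifelse(altFraction >= hetMin & altFraction <= hetMax, "het",
      ifelse(altFraction > homAltMin, "hom_alt", "ambiguous")))
}

#' Read a sample profile from the c.-notation TSV dialect
#'
#' Expects a header with columns \code{hgvs_c}, \code{zygosity},
#' \code{depth}, \code{alt_fraction}.
#'
#' @param path TSV file path.
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @param minDepth see \code{\link{SampleProfile}}.
#' @return a \linkS4class{SampleProfile}.
#' @export
readProfileTsv <- function(path, sampleId = NULL, minDepth = 50L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  SampleProfile(sampleId, tab, minDepth = minDepth)
}

#' Write a sample profile to the c.-notation TSV dialect
#'
#' @param profile a \linkS4class{SampleProfile}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeProfileTsv <- function(profile, path) {
  tab <- profile@calls[, c("hgvs_c", "zygosity", "depth", "alt_fraction")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Non-reference calls of a profile (the variant content actually observed).
.nonRefCalls <- function(profile) {
  k <- profile@calls
  k[k$zygosity %in% c("het", "hom_alt"), , drop = FALSE]
}

# Observed zygosity at a set of labels; positions absent from the profile
# are hom_ref (variant calling reports non-reference sites only).
.observedZygosity <- function(profile, hgvs) {
  k <- profile@calls
  z <- k$zygosity[match(hgvs, k$hgvs_c)]
  z[is.na(z)] <- "hom_ref"
  z
}
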