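#' @include reference.R
NULL

#' In-silico PCR: locate an amplicon by exact primer matching
#'
#' Exact-match search of the forward primer on the plus strand and of the
#' reverse primer as its reverse complement on the plus strand; both must
#' hit exactly once and in amplifiable orientation. The amplicon is reported
#' 5'-end to 5'-end, the span a polymerase would copy.
#'
#' @param forward,reverse primer sequences (5'-3'), character or
#'   \code{DNAString}.
#' @param reference the template: a \code{Biostrings::DNAStringSet} (first
#'   sequence used), a \code{DNAString}, a bare character sequence, or a
#'   path to a FASTA file.
#' @return list with \code{start}, \code{end} (1-based, inclusive),
#'   \code{length_bp} and \code{length_kb} (rounded to 0.1 kb).
#' @examples
#' ref <- syntheticReference()
#' pr <- lrPcrPrimers()
#' insilicoPcr(pr$sequence[pr$name == "ABO1longF"],
#'             pr$sequence[pr$name == "ABO1longR"], ref)$length_kb
#' @export
insilicoPcr <- function(forward, reverse, reference) {
  subject <- .asDNAString(reference)
  fwd <- Biostrings::DNAString(toupper(as.character(forward)))
  rev <- Biostrings::DNAString(toupper(as.character(reverse)))
  fHits <- Biostrings::matchPattern(fwd, subject)
  rHits <- Biostrings::matchPattern(Biostrings::reverseComplement(rev), subject)
  .assertUnique(fHits, "forward primer")
  .assertUnique(rHits, "reverse primer")
  fStart <- Biostrings::start(fHits)[1]
  rEnd <- Biostrings::end(rHits)[1]
  if (rEnd <= fStart)
    stop("orientation error: reverse-primer site (ending at ", rEnd,
         ") lies upstream of the forward-primer site (starting at ", fStart,
         ")")
  len <- rEnd - fStart + 1L
  list(start = fStart, end = rEnd,
       length_bp = len, length_kb = round(len / 1000, 1))
}

.assertUnique <- function(hits, what) {
  n <- length(hits)
  if (n == 0L) stop("no binding site found for the ", what)
  if (n > 1L) stop(n, " binding sites found for the ", what,
                   "; amplicon would be ambiguous")
  invisible(TRUE)
}

.asDNAString <- function(reference) {
  if (is(reference, "DNAStringSet")) return(reference[[1]])
  if (is(reference, "DNAString")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    if (file.exists(reference))
      return(Biostrings::readDNAStringSet(reference)[[1]])
    return(Biostrings::DNAString(toupper(reference)))
  }
  stop("reference must be a DNAString(Set), a sequence string, or a FASTA path")
}
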