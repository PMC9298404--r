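#' @include recombination.R
NULL

#' Read-backed phasing of a target variant against anchor variants
#'
#' For each anchor, fragments jointly covering the target and the anchor
#' and carrying the alternate allele at either position are informative;
#' the verdict is \code{cis} when the target's alternate co-occurs with the
#' anchor's alternate in at least \code{cisMin} of informative fragments,
#' \code{trans} when in at most \code{transMax}, and \code{unknown}
#' otherwise or below \code{minFrags} informative fragments. A novel
#' variant trans to every marker of the other haplotype's lineage is
#' thereby assigned to the remaining haplotype.
#'
#' @param fragments list of read fragments as produced by
#'   \code{\link{makeReadFragments}}: each a list with \code{fragment_id}
#'   and \code{obs}, a named character vector of \code{"ref"}/\code{"alt"}
#'   observations keyed by HGVS c. label.
#' @param target HGVS c. label of the variant to phase.
#' @param anchors character vector of anchor variant labels.
#' @param minFrags minimum informative fragments per anchor (default 3).
#' @param cisMin,transMax co-occurrence thresholds (defaults 0.9 / 0.1).
#' @return data.frame with columns \code{anchor}, \code{n_informative},
#'   \code{cooccurrence}, \code{verdict}.
#' @export
phaseByReads <- function(fragments, target, anchors, minFrags = 3L,
                         cisMin = 0.9, transMax = 0.1) {
  rows <- lapply(anchors, function(anchor) {
    covered <- Filter(function(f) {
      all(c(target, anchor) %in% names(f$obs))
    }, fragments)
    informative <- Filter(function(f) {
      f$obs[[target]] == "alt" || f$obs[[anchor]] == "alt"
    }, covered)
    n <- length(informative)
    if (n < minFrags)
      return(data.frame(anchor = anchor, n_informative = n,
                        cooccurrence = NA_real_, verdict = "unknown",
                        stringsAsFactors = FALSE))
    co <- mean(vapply(informative, function(f) {
      f$obs[[target]] == "alt" && f$obs[[anchor]] == "alt"
    }, logical(1)))
    verdict <- if (co >= cisMin) "cis" else if (co <= transMax) "trans"
               else "unknown"
    data.frame(anchor = anchor, n_informative = n, cooccurrence = co,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
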