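#' @include AllGenerics.R
NULL

# Gene-axis sort key. Model-free total order over c. positions:
# exonic positions order by anchor; within an intron every plus-offset
# position precedes every minus-offset position; plus offsets ascend,
# minus offsets descend by magnitude (c.29-1053 < c.29-86). Offsets are
# bounded well below the 5e6 branch constant for any realistic intron, and
# the composite stays far inside exact double-integer range.
.axisKey <- function(anchor, offset) {
  ifelse(offset >= 0,
         anchor * 1e7 + offset,
         (anchor - 1) * 1e7 + 5e6 + offset)
}

.fmtPos <- function(anchor, offset) {
  paste0(anchor, ifelse(offset == 0, "",
                        ifelse(offset > 0, paste0("+", offset),
                               as.character(offset))))
}

# label-keyed caches: the same few HGVS labels recur across thousands of
# calls in cohort work, so parses and region lookups are memoized
.hgvsCache <- new.env(parent = emptyenv())
.regionCache <- new.env(parent = emptyenv())

.parsePos <- function(tok, context = tok) {
  m <- regmatches(tok, regexec("^([0-9]+)([+-][0-9]+)?$", tok))[[1]]
  if (length(m) == 0L)
    stop("malformed HGVS position '", tok, "' in '", context, "'")
  anchor <- as.integer(m[2])
  offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  if (anchor < 1L)
    stop("coding position must be >= 1 in '", context, "'")
  if (nzchar(m[3]) && offset == 0L)
    stop("zero intron offset in '", context,
         "' (offset 0 is exonic by definition)")
  c(anchor = anchor, offset = offset)
}

#' Parse HGVS c.-notation variant descriptions
#'
#' Supported forms: substitutions (\code{c.28+5956T>A}), deletions with or
#' without the deleted sequence (\code{c.261delG},
#' \code{c.29-1053_29-1037del}), duplications (\code{c.204-61dupC}),
#' insertions over an explicit span (\code{c.203+72_203+73insGTGTGGACAGAAG}),
#' deletion-insertions (\code{c.29-780delinsGG}) and repeated-unit
#' insertions (\code{c.239+103_239+105insC[3]}, expanded at parse time while
#' the bracketed form is retained for round-trip output). Intronic positions
#' carry signed anchor offsets; parsing is model-free, region validation
#' against a \linkS4class{GeneModel} happens in \code{\link{classifyRegion}}.
#'
#' @param x character vector of HGVS c. strings (each starting with "c.").
#' @return data.frame with one row per variant: \code{hgvs_c} (the canonical
#'   label), \code{anchor}, \code{offset}, \code{anchor2}, \code{offset2}
#'   (end position; equal to the start for single-base changes), \code{kind}
#'   (substitution/deletion/insertion/duplication/delins), \code{ref},
#'   \code{alt} (nucleotide strings, possibly empty), and the gene-axis sort
#'   \code{key}.
#' @examples
#' parseHgvsC(c("c.28+5956T>A", "c.261delG", "c.239+103_239+105insC[3]"))
#' @export
parseHgvsC <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L)
    return(data.frame(hgvs_c = character(0), anchor = integer(0),
                      offset = integer(0), anchor2 = integer(0),
                      offset2 = integer(0), kind = character(0),
                      ref = character(0), alt = character(0),
                      ins_unit = character(0), ins_rep = integer(0),
                      ranged = logical(0), key = numeric(0)))
  rows <- lapply(x, .parseOneCached)
  data.frame(
    hgvs_c = x,
    anchor = vapply(rows, `[[`, integer(1), "anchor"),
    offset = vapply(rows, `[[`, integer(1), "offset"),
    anchor2 = vapply(rows, `[[`, integer(1), "anchor2"),
    offset2 = vapply(rows, `[[`, integer(1), "offset2"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    ins_unit = vapply(rows, `[[`, character(1), "ins_unit"),
    ins_rep = vapply(rows, `[[`, integer(1), "ins_rep"),
    ranged = vapply(rows, `[[`, logical(1), "ranged"),
    key = vapply(rows, `[[`, numeric(1), "key"),
    stringsAsFactors = FALSE)
}

.parseOneCached <- function(s) {
  hit <- .hgvsCache[[s]]
  if (!is.null(hit)) return(hit)
  out <- .parseOne(s)
  .hgvsCache[[s]] <- out
  out
}

.parseOne <- function(s) {
  if (is.na(s) || !startsWith(s, "c."))
    stop("HGVS string must begin with 'c.': '", s, "'")
  body <- substring(s, 3L)
  # split off the operator tail; positions are everything before the first
  # letter that starts an operator token
  m <- regexec(
    "^([0-9+-]+(?:_[0-9+-]+)?)(?:([ACGTacgt])>([ACGTacgt])|(delins|del|dup|ins)([ACGTacgt]*)(?:\\[([0-9]+)\\])?)$",
    body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0L)
    stop("malformed HGVS string '", s, "'")
  posTok <- g[2]
  toks <- strsplit(posTok, "_", fixed = TRUE)[[1]]
  p1 <- .parsePos(toks[1], s)
  p2 <- if (length(toks) == 2L) .parsePos(toks[2], s) else p1
  if (length(toks) > 2L) stop("malformed position range in '", s, "'")
  k1 <- .axisKey(p1["anchor"], p1["offset"])
  k2 <- .axisKey(p2["anchor"], p2["offset"])
  if (k1 > k2)
    stop("start position after end position in '", s, "'")
  ref <- ""; alt <- ""; kind <- NULL; rep <- NA_integer_; unit <- NA_character_
  if (nzchar(g[3])) {                      # substitution
    if (length(toks) != 1L)
      stop("substitution cannot span a range in '", s, "'")
    kind <- "substitution"; ref <- toupper(g[3]); alt <- toupper(g[4])
  } else {
    op <- g[5]; seqTok <- toupper(g[6])
    rep <- if (nzchar(g[7])) as.integer(g[7]) else NA_integer_
    if (!is.na(rep) && op != "ins")
      stop("repeat count only supported for insertions in '", s, "'")
    if (op == "del") {
      kind <- "deletion"; ref <- seqTok
      span <- (k2 - k1) + 1
      if (nzchar(ref) && nchar(ref) != span)
        stop("deleted sequence length does not match span in '", s, "'")
    } else if (op == "dup") {
      kind <- "duplication"; ref <- seqTok; alt <- seqTok
    } else if (op == "delins") {
      if (!nzchar(seqTok))
        stop("delins requires an inserted sequence in '", s, "'")
      kind <- "delins"; alt <- seqTok
    } else if (op == "ins") {
      if (!nzchar(seqTok))
        stop("ins requires an inserted sequence in '", s, "'")
      kind <- "insertion"
      alt <- if (!is.na(rep)) paste(rep(seqTok, rep), collapse = "") else seqTok
    }
    if (is.null(kind)) stop("unknown operator in '", s, "'")
  }
  list(
    anchor = as.integer(p1[["anchor"]]), offset = as.integer(p1[["offset"]]),
    anchor2 = as.integer(p2[["anchor"]]), offset2 = as.integer(p2[["offset"]]),
    kind = kind, ref = ref, alt = alt,
    ins_unit = if (kind == "insertion" && !is.na(rep)) toupper(g[6]) else NA_character_,
    ins_rep = if (kind == "insertion") rep else NA_integer_,
    ranged = length(toks) == 2L,
    key = unname(k1)
  )
}

#' Format parsed variants back to HGVS c. strings
#'
#' Inverse of \code{\link{parseHgvsC}}: \code{formatHgvsC(parseHgvsC(x))}
#' reproduces \code{x} for every supported form, including bracketed
#' repeated-unit insertions.
#'
#' @param v data.frame as returned by \code{\link{parseHgvsC}}.
#' @return character vector of HGVS c. strings.
#' @export
formatHgvsC <- function(v) {
  vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    pos <- .fmtPos(r$anchor, r$offset)
    if (r$ranged)
      pos <- paste0(pos, "_", .fmtPos(r$anchor2, r$offset2))
    tail <- switch(r$kind,
      substitution = paste0(r$ref, ">", r$alt),
      deletion = paste0("del", r$ref),
      duplication = paste0("dup", r$ref),
      delins = paste0("delins", r$alt),
      insertion = if (!is.na(r$ins_rep))
        paste0("ins", r$ins_unit, "[", r$ins_rep, "]")
      else paste0("ins", r$alt)
    )
    paste0("c.", pos, tail)
  }, character(1))
}

#' Order two c. positions along the gene axis
#'
#' Total order used throughout the package: exonic positions order by
#' coding coordinate; within an intron, plus-offset positions (counted from
#' the 5' exon end) precede minus-offset positions (counted back from the 3'
#' exon start), plus offsets ascend and minus offsets descend, matching the
#' genomic order whenever the intron is long enough for the offsets used.
#'
#' @param a,b character, positions like \code{"c.29-86"} (the \code{"c."}
#'   prefix is optional); recycled to a common length.
#' @return character vector: \code{"before"}, \code{"equal"} or
#'   \code{"after"} (ordering of \code{a} relative to \code{b}).
#' @examples
#' comparePositions("c.29-1053", "c.29-86")   # "before"
#' comparePositions("c.374+89", "c.375-336")  # "before"
#' @export
comparePositions <- function(a, b) {
  ka <- positionKey(a); kb <- positionKey(b)
  ifelse(ka < kb, "before", ifelse(ka > kb, "after", "equal"))
}

#' Gene-axis sort key of a c. position
#'
#' @param x character vector of positions (\code{"29-86"} or
#'   \code{"c.29-86"}), or a data.frame from \code{\link{parseHgvsC}}.
#' @return numeric sort key; comparing keys realises the package's total
#'   order on positions.
#' @export
positionKey <- function(x) {
  if (is.data.frame(x)) return(.axisKey(x$anchor, x$offset))
  x <- sub("^c\\.", "", x)
  p <- vapply(x, .parsePos, numeric(2))
  .axisKey(p["anchor", ], p["offset", ])
}

#' Classify a c. position as exonic or intronic
#'
#' Exonic positions map to the exon containing the anchor; plus-offset
#' positions map to the intron following the anchor exon, minus-offset
#' positions to the intron preceding it. Offsets are only legal on exon
#' boundary anchors (last base of an exon for \code{+}, first base for
#' \code{-}).
#'
#' @param pos character vector of positions or a data.frame from
#'   \code{\link{parseHgvsC}} (the start position is classified).
#' @param model a \linkS4class{GeneModel}.
#' @return character vector like \code{"exon 7"} / \code{"intron 1"}.
#' @examples
#' classifyRegion("c.28+4282", defaultGeneModel())  # "intron 1"
#' classifyRegion("c.964", defaultGeneModel())      # "exon 7"
#' @export
classifyRegion <- function(pos, model) {
  if (is.data.frame(pos)) {
    anchor <- pos$anchor; offset <- pos$offset; lab <- pos$hgvs_c
  } else {
    x <- sub("^c\\.", "", pos)
    p <- vapply(x, .parsePos, numeric(2))
    anchor <- as.integer(p["anchor", ]); offset <- as.integer(p["offset", ])
    lab <- pos
  }
  ends <- model@exonEnds
  starts <- c(1L, head(ends, -1L) + 1L)
  sig <- paste(ends, collapse = "_")
  out <- character(length(anchor))
  for (i in seq_along(anchor)) {
    a <- anchor[i]; o <- offset[i]
    ck <- paste0(sig, ":", a, ":", o)
    hit <- .regionCache[[ck]]
    if (!is.null(hit)) { out[i] <- hit; next }
    if (a > max(ends))
      stop("position '", lab[i], "' beyond the modeled cDNA (length ",
           max(ends), ")")
    ex <- which(a <= ends)[1]
    if (o == 0) {
      out[i] <- paste("exon", ex)
    } else if (o > 0) {
      if (a != ends[ex])
        stop("plus offset on non-boundary anchor in '", lab[i],
             "' (exon ", ex, " ends at c.", ends[ex], ")")
      if (ex == length(ends))
        stop("no intron after the last exon for '", lab[i], "'")
      out[i] <- paste("intron", ex)
    } else {
      if (a != starts[ex])
        stop("minus offset on non-boundary anchor in '", lab[i],
             "' (exon ", ex, " starts at c.", starts[ex], ")")
      if (ex == 1L)
        stop("no intron before the first exon for '", lab[i], "'")
      out[i] <- paste("intron", ex - 1L)
    }
    .regionCache[[ck]] <- out[i]
  }
  out
}

#' Convert c. positions to 1-based genomic coordinates
#'
#' Plus-strand arithmetic on the model's contig: exonic positions shift by
#' the cumulative length of upstream introns; intronic offsets add to (or
#' subtract from) the genomic coordinate of their anchor. Fails loudly when
#' an offset exceeds its intron's modeled length.
#'
#' @param pos positions as in \code{\link{classifyRegion}}.
#' @param model a \linkS4class{GeneModel} with genomic anchoring.
#' @return integer vector of genomic coordinates.
#' @seealso \code{\link{genomicToC}} for the inverse.
#' @export
cToGenomic <- function(pos, model) {
  if (is.data.frame(pos)) {
    anchor <- pos$anchor; offset <- pos$offset; lab <- pos$hgvs_c
  } else {
    x <- sub("^c\\.", "", pos)
    p <- vapply(x, .parsePos, numeric(2))
    anchor <- as.integer(p["anchor", ]); offset <- as.integer(p["offset", ])
    lab <- pos
  }
  region <- classifyRegion(if (is.data.frame(pos)) pos else pos, model)
  ends <- model@exonEnds
  cumIntron <- c(0L, cumsum(model@intronLengths))
  out <- integer(length(anchor))
  for (i in seq_along(anchor)) {
    a <- anchor[i]; o <- offset[i]
    ex <- which(a <= ends)[1]
    g_anchor <- model@cdsGenomicStart - 1L + a + cumIntron[ex]
    if (o != 0) {
      intron <- as.integer(sub("intron ", "", region[i]))
      if (abs(o) > model@intronLengths[intron])
        stop("offset ", o, " exceeds intron ", intron, " length (",
             model@intronLengths[intron], ") for '", lab[i], "'")
    }
    out[i] <- g_anchor + o
  }
  out
}

#' Convert genomic coordinates back to c. positions
#'
#' Inverse of \code{\link{cToGenomic}} on the modeled span. Intronic
#' positions take the nearest-exon anchor (ties to the plus side), the
#' standard HGVS convention; the fixture model's intron lengths are chosen
#' so that every bundled variant position is nearer its own anchor, making
#' the conversion a bijection over them.
#'
#' @param g integer vector of 1-based genomic coordinates.
#' @param model a \linkS4class{GeneModel}.
#' @return data.frame with columns \code{anchor}, \code{offset},
#'   \code{position} (formatted, with \code{"c."} prefix).
#' @export
genomicToC <- function(g, model) {
  ends <- model@exonEnds
  starts <- c(1L, head(ends, -1L) + 1L)
  cumIntron <- c(0L, cumsum(model@intronLengths))
  gStart <- model@cdsGenomicStart - 1L + starts + cumIntron[seq_along(starts)]
  gEnd <- model@cdsGenomicStart - 1L + ends + cumIntron[seq_along(ends)]
  anchor <- integer(length(g)); offset <- integer(length(g))
  for (i in seq_along(g)) {
    gi <- g[i]
    if (gi < gStart[1] || gi > gEnd[length(gEnd)])
      stop("genomic position ", gi, " outside the modeled span [",
           gStart[1], ", ", gEnd[length(gEnd)], "]")
    ex <- which(gi <= gEnd)[1]
    if (gi >= gStart[ex]) {
      anchor[i] <- starts[ex] + (gi - gStart[ex]); offset[i] <- 0L
    } else {
      d1 <- gi - gEnd[ex - 1L]          # distance into intron from 5' exon
      d2 <- gStart[ex] - gi             # distance back from 3' exon
      if (d1 <= d2) { anchor[i] <- ends[ex - 1L]; offset[i] <- d1 }
      else { anchor[i] <- starts[ex]; offset[i] <- -d2 }
    }
  }
  data.frame(anchor = anchor, offset = offset,
             position = paste0("c.", .fmtPos(anchor, offset)))
}

# Reconstruct the HGVS label of a variant row after coordinate round-trip;
# used by the VCF reader when no HGVSC annotation is present.
.variantRegion <- function(hgvs, model) {
  classifyRegion(parseHgvsC(hgvs), model)
}

#' Test whether variants are coding (exonic) under a model
#'
#' @param hgvs character vector of HGVS c. labels.
#' @param model a \linkS4class{GeneModel}.
#' @return logical vector; TRUE where the start position is exonic.
#' @export
isCoding <- function(hgvs, model) {
  grepl("^exon", .variantRegion(hgvs, model))
}

#' Test whether variants lie in or near a splice site
#'
#' Positions with intron offset magnitude of at most \code{window} count as
#' splice-site variants; they are grouped with coding variants when
#' classifying the mechanism behind a subtype phenotype.
#'
#' @param hgvs character vector of HGVS c. labels.
#' @param window integer, maximum offset magnitude (default 2).
#' @return logical vector.
#' @export
isSpliceSite <- function(hgvs, window = 2L) {
  v <- parseHgvsC(hgvs)
  v$offset != 0L & abs(v$offset) <= window
}
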