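## Pairing/non-pairing region mapping: the best local alignment between the
## sense transcript and the reverse complement of the antisense transcript
## defines the sense-antisense overlap (the role BLAST played in the original
## analysis).  BLASTN-like scoring: match +2, mismatch -3, gap open 5,
## gap extend 2 (a gap of length k costs open + k*extend).

## Substitution matrix over A,C,G,T,N; N scores as mismatch against
## everything, including N.
overlap_submat <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

#' Find the pairing (overlap) region of a sense-antisense transcript pair
#'
#' Computes the best local alignment of the sense sequence against the
#' reverse complement of the antisense sequence and partitions both
#' transcripts into a pairing segment (the aligned span) and non-pairing
#' remainder segments.  Gaps are tolerated inside the overlap alignment;
#' `overlap_len` is the aligned span length on the sense transcript.  If the
#' best alignment scores below `min_score` the pair has no overlap
#' (`overlap_len = 0`, both transcripts entirely non-pairing).
#'
#' @param sense,antisense single-row sequence records (or plain named lists
#'   with `id` and `seq`).
#' @param pair_id identifier for the pair (defaults to `<sense>|<antisense>`).
#' @param min_overlap minimum overlap length (nt) for `passes_filter`
#'   (default 25, the study's inclusion threshold).
#' @param match,mismatch,gap_open,gap_extend local-alignment scores/costs
#'   (costs positive).
#' @param min_score minimum alignment score for an overlap call.
#' @return an object of class `region_partition`: a list with `pair_id`,
#'   `sense_id`, `antisense_id`, `pairing` and `nonpairing` segment
#'   data.frames (`transcript_id`, `start`, `end` 0-based half-open, `seq`),
#'   `overlap_len`, `score`, and `passes_filter`.
#' @export
find_overlap <- function(sense, antisense, pair_id = NULL, min_overlap = 25L,
                         match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2, min_score = 40) {
  s_id <- sense$id; a_id <- antisense$id
  s <- toupper(sense$seq); a <- toupper(antisense$seq)
  stopifnot(nzchar(s), nzchar(a))
  pair_id <- pair_id %||% paste0(s_id, "|", a_id)
  a_rc <- revcomp(a)
  aln <- Biostrings::pairwiseAlignment(
    s, a_rc, type = "local",
    substitutionMatrix = overlap_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- BiocGenerics::score(aln)

  seg <- function(id, seqstr, start, end) {
    if (end <= start) return(NULL)
    data.frame(transcript_id = id, start = start, end = end,
               seq = substr(seqstr, start + 1L, end), stringsAsFactors = FALSE)
  }
  empty_part <- function() {
    list(pair_id = pair_id, sense_id = s_id, antisense_id = a_id,
         pairing = data.frame(transcript_id = character(0), start = integer(0),
                              end = integer(0), seq = character(0),
                              stringsAsFactors = FALSE),
         nonpairing = do.call(rbind, Filter(Negate(is.null), list(
           seg(s_id, s, 0L, nchar(s)), seg(a_id, a, 0L, nchar(a))))),
         overlap_len = 0L, score = sc, passes_filter = FALSE)
  }
  if (sc < min_score) return(structure(empty_part(),
                                       class = "region_partition"))

  ## aligned span: sense coords direct; subject coords are on revcomp(anti)
  ## and map back to antisense coords by reflection
  p <- Biostrings::pattern(aln); q <- Biostrings::subject(aln)
  s0 <- BiocGenerics::start(p) - 1L; s1 <- BiocGenerics::end(p)   # [s0, s1)
  r0 <- BiocGenerics::start(q) - 1L; r1 <- BiocGenerics::end(q)
  la <- nchar(a)
  a0 <- la - r1; a1 <- la - r0                                    # [a0, a1)

  pairing <- rbind(seg(s_id, s, s0, s1), seg(a_id, a, a0, a1))
  nonpairing <- do.call(rbind, Filter(Negate(is.null), list(
    seg(s_id, s, 0L, s0), seg(s_id, s, s1, nchar(s)),
    seg(a_id, a, 0L, a0), seg(a_id, a, a1, la))))
  if (is.null(nonpairing))
    nonpairing <- data.frame(transcript_id = character(0), start = integer(0),
                             end = integer(0), seq = character(0),
                             stringsAsFactors = FALSE)
  overlap_len <- s1 - s0
  structure(list(pair_id = pair_id, sense_id = s_id, antisense_id = a_id,
                 pairing = pairing, nonpairing = nonpairing,
                 overlap_len = overlap_len, score = sc,
                 passes_filter = overlap_len >= min_overlap),
            class = "region_partition")
}

#' Partition every pair in a pair table
#'
#' @param records sequence-record data.frame holding all transcripts.
#' @param pairs pair table (`sense_id`, `antisense_id`, optional `pair_id`).
#' @param ... passed to [find_overlap()].
#' @return list of `region_partition` objects, one per pair, in table order.
#' @export
partition_pairs <- function(records, pairs, ...) {
  idx <- setNames(seq_len(nrow(records)), records$id)
  missing <- setdiff(unique(c(pairs$sense_id, pairs$antisense_id)),
                     records$id)
  if (length(missing))
    stop("pair table id(s) absent from sequences: ",
         paste(head(missing, 5), collapse = ", "))
  lapply(seq_len(nrow(pairs)), function(i) {
    find_overlap(records[idx[[pairs$sense_id[i]]], ],
                 records[idx[[pairs$antisense_id[i]]], ],
                 pair_id = if ("pair_id" %in% names(pairs))
                   pairs$pair_id[i] else NULL,
                 ...)
  })
}

#' Apply the minimum-overlap filter to computed partitions
#'
#' Retains partitions whose `overlap_len` is at least `min_overlap`
#' (inclusive, matching the study's ">= 25 nt" rule) and logs the filter
#' accounting.
#'
#' @param partitions list of `region_partition` objects.
#' @param min_overlap minimum overlap length in nt (default 25).
#' @return list with `retained` and `dropped` partition lists and the counts
#'   `n_retained`, `n_dropped`, `pct_retained`.
#' @export
filter_pairs <- function(partitions, min_overlap = 25L) {
  keep <- vapply(partitions, function(p) p$overlap_len >= min_overlap, TRUE)
  pct <- if (length(keep)) round(100 * sum(keep) / length(keep), 1) else NA_real_
  as_log("filter_pairs: ", length(keep), " partition(s); ", sum(keep),
         " retained (overlap >= ", min_overlap, " nt, ", pct, "%); ",
         sum(!keep), " dropped")
  list(retained = partitions[keep], dropped = partitions[!keep],
       n_retained = sum(keep), n_dropped = sum(!keep), pct_retained = pct)
}

#' @export
print.region_partition <- function(x, ...) {
  cat("Sense-antisense region partition:", x$pair_id, "\n")
  cat("  sense:", x$sense_id, " antisense:", x$antisense_id, "\n")
  cat("  overlap:", x$overlap_len, "nt (alignment score", x$score, ")\n")
  cat("  passes >= filter:", x$passes_filter, "\n")
  np <- if (is.null(x$nonpairing)) 0L else nrow(x$nonpairing)
  cat("  segments:", if (is.null(x$pairing)) 0L else nrow(x$pairing),
      "pairing,", np, "non-pairing\n")
  invisible(x)
}

## Total scanned length per region class for one partition under a strand
## convention (see scan_regions for the convention).
partition_lengths <- function(partition, strands = c("both", "sense")) {
  strands <- match.arg(strands)
  segs <- partition_segments(partition, strands)
  c(pairing = sum(segs$len[segs$region_class == "pairing"]),
    nonpairing = sum(segs$len[segs$region_class == "nonpairing"]))
}

## Enumerate the segments a scan will visit.  Pairing is scanned once, on the
## sense transcript's aligned span (one physical duplex); non-pairing covers
## the remainder of the sense transcript and, with strands = "both", also the
## antisense transcript's non-pairing segments.
partition_segments <- function(partition, strands = c("both", "sense")) {
  strands <- match.arg(strands)
  p <- partition
  rows <- list()
  if (!is.null(p$pairing) && nrow(p$pairing)) {
    sp <- p$pairing[p$pairing$transcript_id == p$sense_id, , drop = FALSE]
    if (nrow(sp))
      rows <- c(rows, list(cbind(sp, region_class = "pairing",
                                 stringsAsFactors = FALSE)))
  }
  np <- p$nonpairing
  if (!is.null(np) && nrow(np)) {
    if (strands == "sense")
      np <- np[np$transcript_id == p$sense_id, , drop = FALSE]
    if (nrow(np))
      rows <- c(rows, list(cbind(np, region_class = "nonpairing",
                                 stringsAsFactors = FALSE)))
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      region_class = character(0), len = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$len <- out$end - out$start
  out
}
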