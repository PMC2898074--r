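## miRanda-style two-phase site prediction: seed-weighted complementarity
## Smith-Waterman (phase 1, in C++), then a nearest-neighbor duplex
## free-energy filter (phase 2, R/energy.R).  The numeric defaults are this
## package's explicit approximation of the published miRanda scheme (the
## original study names the tool but not its settings); all are exposed here
## and the region-class comparison is designed to be robust to them.

#' Scanner scoring parameters
#'
#' @param match,wobble,mismatch per-position complementarity scores (A:T and
#'   G:C pair as match; G:U wobble is directional-symmetric: target G vs
#'   miRNA U and target U vs miRNA G both score `wobble`; `N` always scores
#'   as mismatch).
#' @param gap_open,gap_extend affine gap scores (negative); a gap of length k
#'   scores `gap_open + k * gap_extend`.
#' @param seed_scale multiplier applied to per-position pairing scores at
#'   miRNA seed positions (`seed_start`..`seed_end` from the miRNA 5' end).
#' @param seed_start,seed_end seed window, default positions 2-8.
#' @param score_threshold minimum alignment score for a candidate site.
#' @param energy_threshold maximum (most positive) duplex free energy in
#'   kcal/mol for an emitted site.
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(match = 5, wobble = 1, mismatch = -3,
                        gap_open = -8, gap_extend = -2,
                        seed_scale = 4.0, seed_start = 2L, seed_end = 8L,
                        score_threshold = 90, energy_threshold = -17) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            seed_scale >= 1, seed_start >= 1, seed_end >= seed_start,
            is.finite(score_threshold), is.finite(energy_threshold))
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_scale = seed_scale, seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 score_threshold = score_threshold,
                 energy_threshold = energy_threshold),
            class = "scan_params")
}

#' Align one miRNA against a target sequence (phase 1)
#'
#' Local dynamic-programming alignment of the reversed miRNA against the
#' target, scoring complementarity (see [scan_params()]).  All local optima
#' scoring at least `params$score_threshold` are returned, selected greedily
#' best-first with previously used target spans masked, so the reported
#' sites of one miRNA never overlap.  No energy filtering is applied here.
#'
#' @param mirna single-row sequence record (or list with `id`, `seq`).
#' @param target a target nucleotide string (DNA alphabet).
#' @param params a [scan_params()] object.
#' @return data.frame with one row per candidate: `mirna_id`, `score`,
#'   `t_start`/`t_end` (0-based half-open target coordinates),
#'   `q_start`/`q_end` (miRNA positions covered, 1-based from the 5' end),
#'   and the gapped alignment strings `aln_target` (5'->3') and `aln_mirna`
#'   (3'->5', column-aligned).
#' @export
align_mirna <- function(mirna, target, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"), nzchar(target))
  mseq <- toupper(if (is.list(mirna) || is.data.frame(mirna)) mirna$seq
                  else mirna)
  mid <- if (is.list(mirna) || is.data.frame(mirna)) mirna$id else "mirna"
  mseq <- chartr("U", "T", mseq)
  ml <- nchar(mseq)
  if (ml < 7L) stop("miRNA '", mid, "' is shorter than 7 nt: no seed region")
  if (ml < 16L) warning("miRNA '", mid, "' is shorter than 16 nt (", ml,
                        " nt); scores may be unreliable")
  hits <- .sw_scan_cpp(toupper(chartr("U", "T", target)), mseq,
                       params$match, params$wobble, params$mismatch,
                       params$gap_open, params$gap_extend, params$seed_scale,
                       params$seed_start, params$seed_end,
                       params$score_threshold)
  if (nrow(hits)) hits <- cbind(mirna_id = mid, hits, stringsAsFactors = FALSE)
  else hits <- cbind(mirna_id = character(0), hits)
  hits
}

#' Scan the regions of a partition against a miRNA panel (both phases)
#'
#' Every segment of the partition is scanned against every miRNA; candidates
#' above the score threshold are kept only if their nearest-neighbor duplex
#' free energy is at or below `params$energy_threshold`.  Each emitted site
#' is labeled with its region class.  Sites of different miRNAs may overlap
#' and all count; sites of one miRNA never overlap (phase-1 masking).
#'
#' Strand convention: the pairing region is one physical sense-antisense
#' duplex and is scanned once, on the sense transcript's aligned span.  With
#' `strands = "both"` (default) the non-pairing segments of both transcripts
#' are scanned; `strands = "sense"` restricts the scan to the sense
#' transcript.  Scanned lengths per region class follow the same convention
#' (see [region_lengths()]).
#'
#' @param mirnas sequence-record data.frame of mature miRNAs.
#' @param partition a `region_partition` (or list of them).
#' @param params a [scan_params()] object.
#' @param strands `"both"` or `"sense"`.
#' @return data.frame of predicted sites: `pair_id`, `transcript_id`,
#'   `region_class`, `start`, `end` (0-based half-open transcript
#'   coordinates), `strand_scanned`, `mirna_id`, `score`, `energy`,
#'   `aln_target`, `aln_mirna`.
#' @export
scan_regions <- function(mirnas, partition, params = scan_params(),
                         strands = c("both", "sense")) {
  strands <- match.arg(strands)
  if (!inherits(partition, "region_partition") && is.list(partition)) {
    out <- lapply(partition, scan_regions, mirnas = mirnas, params = params,
                  strands = strands)
    return(do.call(rbind, out))
  }
  segs <- partition_segments(partition, strands)
  rows <- list()
  for (si in seq_len(nrow(segs))) {
    if (segs$len[si] < 7L) {
      as_log("scan_regions: segment ", segs$transcript_id[si], ":",
             segs$start[si], "-", segs$end[si], " shorter than 7 nt, skipped",
             level = "debug")
      next
    }
    for (mi in seq_len(nrow(mirnas))) {
      hits <- align_mirna(mirnas[mi, ], segs$seq[si], params)
      if (!nrow(hits)) next
      energies <- vapply(seq_len(nrow(hits)), function(k)
        duplex_energy(list(target = hits$aln_target[k],
                           mirna = hits$aln_mirna[k])), 0)
      keep <- energies <= params$energy_threshold
      if (!any(keep)) next
      hits <- hits[keep, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = partition$pair_id,
        transcript_id = segs$transcript_id[si],
        region_class = segs$region_class[si],
        start = segs$start[si] + hits$t_start,
        end = segs$start[si] + hits$t_end,
        strand_scanned = "+",
        mirna_id = hits$mirna_id,
        score = hits$score,
        energy = energies[keep],
        aln_target = hits$aln_target,
        aln_mirna = hits$aln_mirna,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pair_id = character(0), transcript_id = character(0),
                      region_class = character(0), start = integer(0),
                      end = integer(0), strand_scanned = character(0),
                      mirna_id = character(0), score = numeric(0),
                      energy = numeric(0), aln_target = character(0),
                      aln_mirna = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Scanned length per pair and region class
#'
#' @param partitions list of `region_partition` objects (or a single one).
#' @param strands `"both"` or `"sense"`, as in [scan_regions()].
#' @return data.frame with `pair_id`, `region_class`, `length_nt`.
#' @export
region_lengths <- function(partitions, strands = c("both", "sense")) {
  strands <- match.arg(strands)
  if (inherits(partitions, "region_partition")) partitions <- list(partitions)
  do.call(rbind, lapply(partitions, function(p) {
    L <- partition_lengths(p, strands)
    data.frame(pair_id = p$pair_id,
               region_class = c("pairing", "nonpairing"),
               length_nt = as.integer(L[c("pairing", "nonpairing")]),
               stringsAsFactors = FALSE)
  }))
}
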