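## Synthetic sense-antisense pair sets with known overlap geometry and
## planted miRNA complements at controlled per-nucleotide rates, plus the
## mono-/dinucleotide sequence shufflers shared with the randomization module.
##
## Planted-site model: for each region the number of site events is an exact
## Poisson(rate x region length) draw, recorded in the ground truth and used
## for density statistics.  Physical insertion of the reverse-complement
## 22-mers is done without overlap, so at rates above the packing limit of
## disjoint sites (1/mirna_len per nt; the study-scale non-pairing rate
## 0.0708 exceeds it because real predicted sites overlap across miRNAs)
## only as many sites as fit are actually written into the sequence; the
## `placed` flag in the ground truth distinguishes them.

#' Configuration for the synthetic pair-set generator
#'
#' Defaults state the study-scale world: 391 pairs (the number of conserved
#' NAT pairs with a >= 25-nt overlap in the original study), overlap lengths
#' 400-1400 nt, four non-pairing flanks of 500-1500 nt each (total non-pairing
#' 2000-6000 nt per pair), and planted per-nucleotide site rates 0.0521
#' (pairing) / 0.0708 (non-pairing), the study's aggregate densities.
#'
#' @param n_pairs number of sense-antisense pairs.
#' @param overlap_len_range integer `(min, max)` of the exact
#'   reverse-complement overlap, in nt.  The default minimum respects the
#'   >= 25-nt overlap filter.
#' @param flank_len_range integer `(min, max)` of each of the four non-pairing
#'   flanks (sense left/right, antisense left/right), in nt.
#' @param rate_pairing planted site events per nt of overlap.
#' @param rate_nonpairing planted site events per nt of flank.
#' @param mirna_panel_size number of synthetic mature miRNAs.
#' @param mirna_len mature miRNA length in nt (default 22).
#' @param gc_content background GC fraction, in (0, 1).
#' @param mismatch_rate per-nucleotide probability of mutating a planted
#'   complement (default 0: planted sites are perfect complements, so the
#'   scanner detects them at any sensible threshold).
#' @param seed RNG seed making the generator fully deterministic.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_pairs = 391L,
                             overlap_len_range = c(400L, 1400L),
                             flank_len_range = c(500L, 1500L),
                             rate_pairing = 0.0521,
                             rate_nonpairing = 0.0708,
                             mirna_panel_size = 20L,
                             mirna_len = 22L,
                             gc_content = 0.5,
                             mismatch_rate = 0,
                             seed = 1L) {
  stopifnot(n_pairs >= 1, length(overlap_len_range) == 2L,
            length(flank_len_range) == 2L,
            all(overlap_len_range >= 1), all(flank_len_range >= 1),
            overlap_len_range[1] <= overlap_len_range[2],
            flank_len_range[1] <= flank_len_range[2],
            rate_pairing >= 0, rate_nonpairing >= 0,
            mirna_panel_size >= 1, mirna_len >= 7,
            gc_content > 0, gc_content < 1,
            mismatch_rate >= 0, mismatch_rate < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 overlap_len_range = as.integer(overlap_len_range),
                 flank_len_range = as.integer(flank_len_range),
                 rate_pairing = rate_pairing,
                 rate_nonpairing = rate_nonpairing,
                 mirna_panel_size = as.integer(mirna_panel_size),
                 mirna_len = as.integer(mirna_len),
                 gc_content = gc_content,
                 mismatch_rate = mismatch_rate,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a panel of synthetic mature miRNA sequences
#'
#' Stands in for a miRBase mature-miRNA download: i.i.d. sequences at the
#' requested GC content, deterministic under `seed`.
#'
#' @param size panel size (>= 1).
#' @param length miRNA length in nt.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return sequence-record data.frame (`id`, `seq`, `source_alphabet`).
#' @export
generate_mirna_panel <- function(size, length = 22L, gc = 0.5, seed = 1L) {
  stopifnot(size >= 1, length >= 7)
  with_seed(seed, {
    data.frame(
      id = sprintf("syn-mir-%03d", seq_len(size)),
      seq = vapply(seq_len(size), function(i) random_seq(length, gc), ""),
      source_alphabet = "RNA",
      stringsAsFactors = FALSE)
  })
}

## Uniform integer draw on [lo, hi], safe when lo == hi (avoids the
## sample(x, ...) scalar expansion).
runif_int <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

## Draw non-overlapping placements of `n` sites of length `len` uniformly in
## [lo, hi) (0-based, site must fit wholly).  Up to 100 tries per site; sites
## that do not fit are returned with NA start (placed = FALSE).
place_sites <- function(n, len, lo, hi) {
  starts <- rep(NA_integer_, n)
  if (n == 0L) return(starts)
  span <- hi - lo - len
  occupied <- integer(0)  # starts of placed sites
  for (k in seq_len(n)) {
    if (span < 0) break
    for (try in seq_len(100L)) {
      s <- lo + sample.int(span + 1L, 1L) - 1L
      if (!any(abs(occupied - s) < len)) {  # equal lengths: overlap iff |ds|<len
        starts[k] <- s
        occupied <- c(occupied, s)
        break
      }
    }
  }
  starts
}

## Mutate a planted complement at per-nt probability `rate`.
mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(BASES, b), 1L), "")
  chars
}

#' Generate a synthetic sense-antisense pair set with planted miRNA sites
#'
#' Each pair is built as `sense = left_flank + core + right_flank` and
#' `antisense = left_flank' + revcomp(core) + right_flank'`, so the core is an
#' exact reverse-complement overlap of known coordinates.  Reverse complements
#' of panel miRNAs are planted as a Poisson process at
#' `rate_pairing`/`rate_nonpairing` per nt (see the module comment above for
#' how counts and physical placements are kept distinct at saturating rates).
#' Twelve deliberate mismatch positions flank each core end so that local
#' alignment cannot extend the overlap into the flanks and the planted core
#' coordinates are recovered exactly.
#'
#' @param cfg a [synthetic_config()].
#' @param seed optional RNG seed overriding `cfg$seed`.
#' @return list of class `synthetic_pair_set` with elements
#'   `records` (sequence-record data.frame for all transcripts),
#'   `pairs` (pair table: `pair_id`, `sense_id`, `antisense_id`),
#'   `mirnas` (the miRNA panel),
#'   `truth` (list: `sites` data.frame with per-event coordinates, region
#'   class and `placed` flag; `geometry` data.frame with core coordinates and
#'   region lengths per pair), and `config`.
#' @export
generate_pair_set <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    ml <- cfg$mirna_len
    panel <- generate_mirna_panel(cfg$mirna_panel_size, ml, cfg$gc_content,
                                  seed = sample.int(.Machine$integer.max, 1L))
    panel_rc <- revcomp(panel$seq)

    rec_id <- character(0); rec_seq <- character(0)
    pair_rows <- vector("list", cfg$n_pairs)
    geom_rows <- vector("list", cfg$n_pairs)
    site_rows <- vector("list", cfg$n_pairs)
    unplaced_regions <- 0L

    for (i in seq_len(cfg$n_pairs)) {
      pid <- sprintf("pair%04d", i)
      sid <- paste0(pid, "_s"); aid <- paste0(pid, "_as")
      ov <- runif_int(cfg$overlap_len_range[1], cfg$overlap_len_range[2])
      fl <- runif_int(cfg$flank_len_range[1], cfg$flank_len_range[2],
                      4L)  # sense L, sense R, anti L, anti R
      core <- strsplit(random_seq(ov, cfg$gc_content), "")[[1]]
      Ls <- strsplit(random_seq(fl[1], cfg$gc_content), "")[[1]]
      Rs <- strsplit(random_seq(fl[2], cfg$gc_content), "")[[1]]
      La <- strsplit(random_seq(fl[3], cfg$gc_content), "")[[1]]
      Ra <- strsplit(random_seq(fl[4], cfg$gc_content), "")[[1]]

      ins <- 12L  # insulator width at each core boundary
      plant_region <- function(chars, n_events, lo, hi, transcript_len) {
        ## returns list(chars, df) — df rows in region-local coordinates
        starts <- place_sites(n_events, ml, lo, hi)
        mir_idx <- if (n_events) sample.int(nrow(panel), n_events,
                                            replace = TRUE) else integer(0)
        for (k in seq_len(n_events)) {
          if (is.na(starts[k])) next
          site <- mutate_seq(strsplit(panel_rc[mir_idx[k]], "")[[1]],
                             cfg$mismatch_rate)
          chars[(starts[k] + 1L):(starts[k] + ml)] <- site
        }
        list(chars = chars,
             df = data.frame(mirna_id = panel$id[mir_idx],
                             start = starts, end = starts + ml,
                             placed = !is.na(starts),
                             stringsAsFactors = FALSE))
      }

      ## pairing sites go into the core (the one physical duplex region)
      n_core <- rpois(1L, cfg$rate_pairing * ov)
      pr <- plant_region(core, n_core, 0L, ov, ov)
      core <- pr$chars
      core_df <- pr$df

      ## non-pairing sites: all four flanks, core-adjacent insulator zones
      ## excluded so planting cannot undo the extension barrier
      n_fl <- rpois(4L, cfg$rate_nonpairing * fl)
      fr <- list(
        plant_region(Ls, n_fl[1], 0L, max(0L, fl[1] - ins), fl[1]),
        plant_region(Rs, n_fl[2], min(fl[2], ins), fl[2], fl[2]),
        plant_region(La, n_fl[3], 0L, max(0L, fl[3] - ins), fl[3]),
        plant_region(Ra, n_fl[4], min(fl[4], ins), fl[4], fl[4]))
      Ls <- fr[[1]]$chars; Rs <- fr[[2]]$chars
      La <- fr[[3]]$chars; Ra <- fr[[4]]$chars

      ## insulators: disjoint-alphabet barrier zones just outside the core so
      ## local alignment cannot extend the overlap under any gap shift.  On
      ## the sense transcript the 12 nt flanking the core read 'A'; on the
      ## reverse complement of the antisense the corresponding 12 nt read
      ## 'C' (i.e. 'G' on the antisense itself), so every cross-zone column
      ## is a mismatch.
      if (length(Rs) >= 1) Rs[seq_len(min(ins, length(Rs)))] <- "A"
      if (length(Ls) >= 1)
        Ls[(length(Ls) - min(ins, length(Ls)) + 1L):length(Ls)] <- "A"
      if (length(Ra) >= 1) Ra[seq_len(min(ins, length(Ra)))] <- "G"
      if (length(La) >= 1)
        La[(length(La) - min(ins, length(La)) + 1L):length(La)] <- "G"

      sense <- paste(c(Ls, core, Rs), collapse = "")
      antisense <- paste(c(La, strsplit(revcomp(paste(core, collapse = "")),
                                        "")[[1]], Ra), collapse = "")

      ## assemble ground-truth site rows in transcript coordinates
      off <- function(df, offset, transcript, class) {
        if (nrow(df) == 0L) return(NULL)
        data.frame(pair_id = pid, transcript_id = transcript,
                   region_class = class, mirna_id = df$mirna_id,
                   start = df$start + offset, end = df$end + offset,
                   placed = df$placed, stringsAsFactors = FALSE)
      }
      site_rows[[i]] <- do.call(rbind, Filter(Negate(is.null), list(
        off(core_df, fl[1], sid, "pairing"),
        off(fr[[1]]$df, 0L, sid, "nonpairing"),
        off(fr[[2]]$df, fl[1] + ov, sid, "nonpairing"),
        off(fr[[3]]$df, 0L, aid, "nonpairing"),
        off(fr[[4]]$df, fl[3] + ov, aid, "nonpairing"))))
      unplaced_regions <- unplaced_regions +
        sum(!core_df$placed, !fr[[1]]$df$placed, !fr[[2]]$df$placed,
            !fr[[3]]$df$placed, !fr[[4]]$df$placed)

      rec_id <- c(rec_id, sid, aid)
      rec_seq <- c(rec_seq, sense, antisense)
      pair_rows[[i]] <- data.frame(pair_id = pid, sense_id = sid,
                                   antisense_id = aid, stringsAsFactors = FALSE)
      geom_rows[[i]] <- data.frame(
        pair_id = pid, sense_id = sid, antisense_id = aid,
        overlap_len = ov,
        core_start_sense = fl[1], core_start_antisense = fl[3],
        n_pairing = n_core, n_nonpairing = sum(n_fl),
        pairing_len = ov, nonpairing_len = sum(fl),
        stringsAsFactors = FALSE)
    }

    if (unplaced_regions > 0L)
      warning(unplaced_regions, " planted site event(s) could not be placed ",
              "without overlap (rate above the disjoint-site packing limit); ",
              "they are counted in the ground truth with placed = FALSE")

    sites <- do.call(rbind, Filter(Negate(is.null), site_rows))
    if (is.null(sites))
      sites <- data.frame(pair_id = character(0), transcript_id = character(0),
                          region_class = character(0), mirna_id = character(0),
                          start = integer(0), end = integer(0),
                          placed = logical(0), stringsAsFactors = FALSE)
    as_log("generate_pair_set: ", cfg$n_pairs, " pair(s), ",
           nrow(sites), " planted site event(s), seed ", seed)
    structure(list(
      records = data.frame(id = rec_id, seq = rec_seq,
                           source_alphabet = "DNA", stringsAsFactors = FALSE),
      pairs = do.call(rbind, pair_rows),
      mirnas = panel,
      truth = list(sites = sites, geometry = do.call(rbind, geom_rows)),
      config = cfg, seed = seed),
      class = "synthetic_pair_set")
  })
}

#' Per-pair density records from a synthetic set's ground truth
#'
#' Converts the planted Poisson site counts into the same per-pair,
#' per-region-class density records the scanner pipeline produces, using the
#' known region lengths (pairing = overlap length; non-pairing = total flank
#' length of both transcripts).
#'
#' @param ps a `synthetic_pair_set` from [generate_pair_set()].
#' @return density-record data.frame with columns `pair_id`, `sense_id`,
#'   `antisense_id`, `region_class`, `site_count`, `length_nt`, `density`.
#' @export
truth_densities <- function(ps) {
  stopifnot(inherits(ps, "synthetic_pair_set"))
  g <- ps$truth$geometry
  out <- rbind(
    data.frame(pair_id = g$pair_id, sense_id = g$sense_id,
               antisense_id = g$antisense_id, region_class = "pairing",
               site_count = g$n_pairing, length_nt = g$pairing_len,
               stringsAsFactors = FALSE),
    data.frame(pair_id = g$pair_id, sense_id = g$sense_id,
               antisense_id = g$antisense_id, region_class = "nonpairing",
               site_count = g$n_nonpairing, length_nt = g$nonpairing_len,
               stringsAsFactors = FALSE))
  out$density <- out$site_count / out$length_nt
  out
}

#' Shuffle a nucleotide sequence
#'
#' `mode = "mono"` permutes the letters uniformly, preserving base
#' composition exactly.  `mode = "dinucleotide"` performs an Euler-path
#' (Altschul-Erikson) shuffle preserving the full dinucleotide count vector
#' (and hence also composition and the first/last base).
#'
#' @param seq a single nucleotide string.
#' @param mode `"mono"` or `"dinucleotide"`.
#' @param seed optional RNG seed for determinism.
#' @return the shuffled string.
#' @export
shuffle_sequence <- function(seq, mode = c("mono", "dinucleotide"),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    if (mode == "mono") return(paste(sample(chars), collapse = ""))
    if (n <= 3L || length(unique(chars)) == 1L) return(seq)
    euler_shuffle(chars)
  })
}

## Altschul-Erikson dinucleotide shuffle: pick a random "last exit" edge per
## vertex forming an arborescence into the terminal vertex, randomize the
## order of the remaining exits, then walk the Euler path from the first base.
euler_shuffle <- function(chars) {
  n <- length(chars)
  from <- chars[-n]; to <- chars[-1]
  s1 <- chars[1]; sn <- chars[n]
  out_edges <- split(to, from)           # multiset of exits per vertex
  vs <- names(out_edges)
  need_tree <- setdiff(vs, sn)
  repeat {
    last_exit <- vapply(need_tree,
                        function(v) out_edges[[v]][
                          sample.int(length(out_edges[[v]]), 1L)], "")
    ok <- vapply(need_tree, function(v) {
      seen <- character(0)
      while (v != sn) {
        if (v %in% seen || !(v %in% need_tree)) return(FALSE)
        seen <- c(seen, v)
        v <- last_exit[[v]]
      }
      TRUE
    }, TRUE)
    if (all(ok)) break
  }
  ordered <- lapply(vs, function(v) {
    exits <- out_edges[[v]]
    if (v %in% need_tree) {
      drop <- match(last_exit[[v]], exits)
      rest <- exits[-drop]
      c(rest[sample.int(length(rest))], last_exit[[v]])
    } else exits[sample.int(length(exits))]
  })
  names(ordered) <- vs
  ptr <- setNames(rep(1L, length(vs)), vs)
  res <- character(n)
  res[1] <- s1
  cur <- s1
  for (k in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[k] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}
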