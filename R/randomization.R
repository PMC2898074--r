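## Monte Carlo randomization null: reassign (or shuffle and re-scan) the
## pooled region observations into simulated pairing and non-pairing data
## sets of the real class sizes, recompute the Wilcoxon comparison for each
## randomization, and report P = x / n_reps, where x counts randomizations
## whose statistic is strictly smaller than the real data's.

## The pooled observation unit is one pair in one region class: its cached
## (site_count, length_nt) record in label mode, its segment sequences in
## shuffle mode.
pool_from_records <- function(records) {
  stopifnot(all(c("region_class", "site_count", "length_nt") %in%
                  names(records)))
  list(count = records$site_count, length = records$length_nt,
       class = records$region_class,
       n_pairing = sum(records$region_class == "pairing"),
       n_nonpairing = sum(records$region_class == "nonpairing"))
}

#' One randomization of the region pool
#'
#' `mode = "label"`: reassign the cached per-observation (count, length)
#' records to simulated pairing / non-pairing classes uniformly at random,
#' class sizes equal to the real ones, without re-scanning — no record's
#' count or length ever changes, only its class.  `mode = "shuffle"`: shuffle
#' the nucleotides of every segment sequence (mono- or dinucleotide-
#' preserving), reassign observations to classes at random, re-run the
#' scanner on the shuffled sequences and recompute densities.
#'
#' @param records density-record data.frame of the real data (label mode and
#'   class sizes).
#' @param mode `"label"` or `"shuffle"`.
#' @param shuffle_mode `"mono"` or `"dinucleotide"` (shuffle mode only).
#' @param partitions,mirnas,params scan context, required for
#'   `mode = "shuffle"`: the partitions whose segments form the pool, the
#'   miRNA panel, and the [scan_params()].
#' @param strands strand convention for shuffle-mode re-scanning.
#' @param seed optional RNG seed (scoped; the caller's RNG is untouched).
#' @return list with the simulated `W`, `U`, `p`, `assignment` (the simulated
#'   class vector over the pooled observations) and `densities` (the
#'   per-observation densities entering the simulated comparison; in label
#'   mode these are the unchanged real densities).
#' @export
randomize_once <- function(records, mode = c("label", "shuffle"),
                           shuffle_mode = c("mono", "dinucleotide"),
                           partitions = NULL, mirnas = NULL,
                           params = scan_params(),
                           strands = c("both", "sense"), seed = NULL) {
  mode <- match.arg(mode)
  shuffle_mode <- match.arg(shuffle_mode)
  strands <- match.arg(strands)
  pool <- pool_from_records(records)
  n <- length(pool$count)
  stopifnot(pool$n_pairing >= 1, pool$n_nonpairing >= 1,
            pool$n_pairing + pool$n_nonpairing == n)
  with_seed(seed, {
    sim_class <- rep("nonpairing", n)
    sim_class[sample.int(n, pool$n_pairing)] <- "pairing"
    if (mode == "label") {
      d <- pool$count / pool$length
    } else {
      stopifnot(!is.null(partitions), !is.null(mirnas))
      if (inherits(partitions, "region_partition"))
        partitions <- list(partitions)
      names(partitions) <- vapply(partitions, `[[`, "", "pair_id")
      key <- paste(records$pair_id, records$region_class)
      d <- vapply(seq_len(n), function(i) {
        p <- partitions[[records$pair_id[i]]]
        segs <- partition_segments(p, strands)
        segs <- segs[segs$region_class == records$region_class[i], ,
                     drop = FALSE]
        cnt <- 0L
        for (k in seq_len(nrow(segs))) {
          shuf <- shuffle_sequence(segs$seq[k], mode = shuffle_mode)
          if (nchar(shuf) < 7L) next
          for (mi in seq_len(nrow(mirnas))) {
            hits <- align_mirna(mirnas[mi, ], shuf, params)
            if (!nrow(hits)) next
            en <- vapply(seq_len(nrow(hits)), function(h)
              duplex_energy(list(target = hits$aln_target[h],
                                 mirna = hits$aln_mirna[h])), 0)
            cnt <- cnt + sum(en <= params$energy_threshold)
          }
        }
        cnt / sum(segs$len)
      }, 0)
    }
    wt <- wilcoxon_rank_sum(d[sim_class == "pairing"],
                            d[sim_class == "nonpairing"])
    list(W = wt$W, U = wt$U, p = wt$p, assignment = sim_class, densities = d)
  })
}

#' Monte Carlo randomization test (P = x / n_reps)
#'
#' Runs [randomize_once()] `n_reps` times (default 1,000) and counts the
#' randomizations `x` whose Wilcoxon statistic (p-value or W, per `metric`)
#' is strictly smaller than the real data's; ties count as not smaller.  The
#' randomization p-value is exactly `x / n_reps`.
#'
#' @param real an `enrichment_result` for the real data (from
#'   [compare_regions()] on `records`).
#' @param records density-record data.frame of the real data.
#' @param n_reps number of randomizations (>= 1; default 1000).
#' @param mode,shuffle_mode,partitions,mirnas,params,strands see
#'   [randomize_once()].
#' @param seed RNG seed; the full test is deterministic under it.
#' @param metric `"p"` (default) or `"W"`.
#' @return an object of class `randomization_result`: list with `n_reps`,
#'   `x`, `p_randomization` (= x/n_reps), `mode`, `comparison_metric`,
#'   `real_value`, `sim_values`, `seed`.
#' @export
randomization_test <- function(real, records, n_reps = 1000L,
                               mode = c("label", "shuffle"),
                               shuffle_mode = c("mono", "dinucleotide"),
                               partitions = NULL, mirnas = NULL,
                               params = scan_params(),
                               strands = c("both", "sense"),
                               seed = 1L, metric = c("p", "W")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  stopifnot(inherits(real, "enrichment_result"), n_reps >= 1)
  real_value <- switch(metric, p = real$p_two_sided, W = real$wilcoxon_W)
  sims <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      s <- randomize_once(records, mode = mode, shuffle_mode = shuffle_mode,
                          partitions = partitions, mirnas = mirnas,
                          params = params, strands = strands, seed = NULL)
      switch(metric, p = s$p, W = s$W)
    }, 0)
  })
  x <- sum(sims < real_value)
  as_log("randomization_test: mode=", mode, " metric=", metric, " reps=",
         n_reps, " x=", x, " p=", x / n_reps, " seed=", seed)
  structure(list(n_reps = as.integer(n_reps), x = x,
                 p_randomization = x / n_reps, mode = mode,
                 comparison_metric = metric, real_value = real_value,
                 sim_values = sims, seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("Monte Carlo randomization test (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  x = %d of %d randomizations with simulated %s < real (%.4g)\n",
              x$x, x$n_reps, x$comparison_metric, x$real_value))
  cat(sprintf("  P(randomization) = x/%d = %.4g\n", x$n_reps,
              x$p_randomization))
  invisible(x)
}
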