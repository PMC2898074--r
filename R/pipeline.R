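## End-to-end driver: resolve pairs -> map overlaps -> apply the >= 25-nt
## filter -> scan retained pairs -> per-pair densities -> Wilcoxon
## comparison, returning one classed result object.

#' Run the sense-antisense miRNA-site depletion analysis
#'
#' Executes the full pipeline on transcript sequences, a sense-antisense
#' pair table and a mature-miRNA panel: pairs are resolved against the
#' sequences, each pair's overlap is mapped by local alignment
#' ([find_overlap()]), pairs with an overlap of at least `min_overlap` nt
#' are retained ([filter_pairs()]), retained pairs are scanned for miRNA
#' binding sites ([scan_regions()]), site counts are normalized to per-pair
#' per-nucleotide densities, and pairing vs non-pairing densities are
#' compared ([compare_regions()]).  Optionally a Monte Carlo randomization
#' test is run on the resulting density records.
#'
#' @param transcripts sequence-record data.frame (see [read_fasta()]).
#' @param pairs pair table (`sense_id`, `antisense_id`, optional `pair_id`).
#' @param mirnas mature-miRNA sequence-record data.frame.
#' @param params [scan_params()] for the scanner.
#' @param min_overlap minimum overlap length in nt (default 25).
#' @param strands strand convention, see [scan_regions()].
#' @param n_reps randomizations for the Monte Carlo test; 0 skips it.
#' @param mode randomization mode, see [randomization_test()].
#' @param seed RNG seed for the randomization test.
#' @param ... further arguments to [find_overlap()] (alignment scores,
#'   `min_score`).
#' @return an object of class `nat_enrichment`: list with `accounting`
#'   (input/usable/retained pair counts and the retained percentage),
#'   `partitions` (retained), `sites`, `densities`, `result` (an
#'   `enrichment_result`), and `randomization` (a `randomization_result` or
#'   `NULL`).
#' @export
nat_enrichment <- function(transcripts, pairs, mirnas,
                           params = scan_params(), min_overlap = 25L,
                           strands = c("both", "sense"), n_reps = 0L,
                           mode = c("label", "shuffle"), seed = 1L, ...) {
  strands <- match.arg(strands)
  mode <- match.arg(mode)
  res <- resolve_pairs(pairs, transcripts)
  parts <- partition_pairs(transcripts, res$usable,
                           min_overlap = min_overlap, ...)
  flt <- filter_pairs(parts, min_overlap)
  if (flt$n_retained == 0L)
    stop("no pair passes the >= ", min_overlap, "-nt overlap filter")
  sites <- scan_regions(mirnas, flt$retained, params = params,
                        strands = strands)
  dens <- density_records(sites, flt$retained, strands = strands)
  result <- compare_regions(dens)
  rand <- NULL
  if (n_reps > 0L)
    rand <- randomization_test(result, dens, n_reps = n_reps, mode = mode,
                               partitions = flt$retained, mirnas = mirnas,
                               params = params, strands = strands,
                               seed = seed)
  structure(list(
    accounting = list(n_input = nrow(pairs), n_usable = nrow(res$usable),
                      n_unresolved = nrow(res$dropped),
                      n_retained = flt$n_retained, n_dropped = flt$n_dropped,
                      pct_retained = flt$pct_retained,
                      min_overlap = min_overlap, strands = strands),
    partitions = flt$retained, sites = sites, densities = dens,
    result = result, randomization = rand, params = params),
    class = "nat_enrichment")
}

#' @export
print.nat_enrichment <- function(x, ...) {
  a <- x$accounting
  cat("Sense-antisense miRNA binding-site depletion analysis\n")
  cat(sprintf("  pairs: %d input, %d usable (%d unresolved), %d retained with overlap >= %d nt (%.1f%%)\n",
              a$n_input, a$n_usable, a$n_unresolved, a$n_retained,
              a$min_overlap, a$pct_retained))
  cat(sprintf("  predicted sites: %d (strands = %s)\n", nrow(x$sites),
              a$strands))
  print(x$result)
  if (!is.null(x$randomization)) print(x$randomization)
  invisible(x)
}

#' @export
summary.nat_enrichment <- function(object, ...) {
  print(object)
  d <- object$densities
  agg <- stats::aggregate(cbind(site_count, length_nt) ~ region_class,
                          data = d, FUN = sum)
  cat("\nAggregate totals:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-11s %d sites / %d nt = %.2f per 100 nt\n",
                agg$region_class[i], agg$site_count[i], agg$length_nt[i],
                100 * agg$site_count[i] / agg$length_nt[i]))
  invisible(object)
}

#' Boxplot of per-pair site densities by region class
#'
#' The analysis-level figure: per-pair predicted miRNA binding sites per 100
#' nt in pairing (overlap) vs non-pairing regions.
#'
#' @param x a `nat_enrichment` object.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.nat_enrichment <- function(x, ...) {
  d <- x$densities
  per100 <- 100 * d$site_count / d$length_nt
  cls <- factor(d$region_class, levels = c("pairing", "nonpairing"),
                labels = c("pairing\n(overlap)", "non-pairing"))
  boxplot(per100 ~ cls,
          ylab = "predicted miRNA binding sites per 100 nt",
          xlab = "region class",
          main = sprintf("Wilcoxon two-sided p = %.3g", x$result$p_two_sided),
          ...)
  invisible(x)
}
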