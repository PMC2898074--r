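## Independent oracles used across the suite.  These deliberately use naive
## formulations (gap-length enumeration, full permutation enumeration,
## direct counting) so they share no code path with the implementation.

options(asmirmask.log_level = "quiet")

## Brute-force best local complementarity alignment score: gap transitions
## enumerate every gap length explicitly (cost gap_open + k * gap_extend),
## no affine E/F bookkeeping.
oracle_local_score <- function(target, mirna, p) {
  tc <- strsplit(chartr("U", "T", toupper(target)), "")[[1]]
  mc <- rev(strsplit(chartr("U", "T", toupper(mirna)), "")[[1]])  # 3'->5'
  n <- length(tc); m <- length(mc); ml <- m
  sub <- function(i, j) {
    t <- tc[i]; mm <- mc[j]
    s <- if ((t == "A" && mm == "T") || (t == "T" && mm == "A") ||
             (t == "G" && mm == "C") || (t == "C" && mm == "G")) p$match
         else if ((t == "G" && mm == "T") || (t == "T" && mm == "G")) p$wobble
         else p$mismatch
    pos5 <- ml - j + 1
    if (pos5 >= p$seed_start && pos5 <= p$seed_end) s * p$seed_scale else s
  }
  H <- matrix(0, n + 1, m + 1); best <- 0
  for (i in 1:n) for (j in 1:m) {
    v <- max(0, H[i, j] + sub(i, j))
    if (i > 1) {
      k <- 1:(i - 1)
      v <- max(v, max(H[i - k + 1, j + 1] + p$gap_open + k * p$gap_extend))
    }
    if (j > 1) {
      k <- 1:(j - 1)
      v <- max(v, max(H[i + 1, j - k + 1] + p$gap_open + k * p$gap_extend))
    }
    H[i + 1, j + 1] <- v
    best <- max(best, v)
  }
  best
}

## Brute-force best local identity-match alignment (match/mismatch/affine
## gap), for the overlap mapper; same naive gap enumeration.  Costs given
## positive (subtracted), matching the BLAST-like convention.
oracle_overlap_score <- function(x, y, match = 2, mismatch = -3,
                                 gap_open = 5, gap_extend = 2) {
  xc <- strsplit(x, "")[[1]]; yc <- strsplit(y, "")[[1]]
  n <- length(xc); m <- length(yc)
  H <- matrix(0, n + 1, m + 1); best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (xc[i] == yc[j] && xc[i] != "N") match else mismatch
    v <- max(0, H[i, j] + s)
    if (i > 1) {
      k <- 1:(i - 1)
      v <- max(v, max(H[i - k + 1, j + 1] - gap_open - k * gap_extend))
    }
    if (j > 1) {
      k <- 1:(j - 1)
      v <- max(v, max(H[i + 1, j - k + 1] - gap_open - k * gap_extend))
    }
    H[i + 1, j + 1] <- v
    best <- max(best, v)
  }
  best
}

## Exact two-sided rank-sum p by full enumeration of all C(n+m, n)
## assignments of the pooled values to group A.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); N <- length(pooled)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n)])
  Ws <- apply(utils::combn(N, n), 2, function(ix) sum(rk[ix]))
  min(1, 2 * min(mean(Ws <= w), mean(Ws >= w)))
}

## Direct dinucleotide count vector of one sequence.
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

## Small random DNA string helper for fixtures.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
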