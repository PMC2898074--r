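## Small shared helpers: alphabet handling, seeded RNG scoping, logging.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA-alphabet string
#'
#' Operates on plain character strings over the internal alphabet
#' \code{A,C,G,T,N}.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All generators in the package route their randomness through this, so a
## (config, seed) pair is fully deterministic and never disturbs the session.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## One log line per pipeline stage; controlled by options(asmirmask.log_level).
## Levels: "quiet" < "info" < "debug".
as_log <- function(..., level = "info") {
  opt <- getOption("asmirmask.log_level", "info")
  ord <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ord[[level]] <= ord[[match.arg(opt, names(ord))]])
    message("[asmirmask] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw n i.i.d. bases at the given GC fraction; returns one string.
random_seq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}
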