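## Readers/writers for the external formats: FASTA sequences, the
## sense-antisense pair table, the predicted-site table and the density table.
## Internal conventions: DNA alphabet (U -> T on read), 0-based half-open
## coordinates in memory, 1-based inclusive coordinates in every written file.

#' Read sequences from a FASTA file into a sequence-record table
#'
#' Parses transcript or mature-miRNA FASTA (miRBase-style headers are fine:
#' the token before the first whitespace becomes the id).  RNA input is
#' normalized to the internal DNA alphabet (`U`/`u` to `T`), case is folded to
#' upper, and IUPAC ambiguity codes other than `N` are converted to `N` with a
#' warning.  `N` never pairs and always scores as a mismatch downstream.
#'
#' @param path path to a FASTA file.
#' @param alphabet_policy `"auto"` (default) records `"RNA"` when a record
#'   contains `U`, `"DNA"` otherwise; `"DNA"`/`"RNA"` force the flag (with
#'   `"DNA"`, a `U` is an error).
#' @return a data.frame with columns `id`, `seq`, `source_alphabet`, one row
#'   per record in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("auto", "DNA", "RNA")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  had_u <- grepl("U", seqs, fixed = TRUE)
  if (alphabet_policy == "DNA" && any(had_u))
    stop("'U' found under alphabet_policy = \"DNA\" in record(s): ",
         paste(ids[had_u], collapse = ", "))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad)) {
    off <- regmatches(seqs[bad], regexpr("[^ACGTNRYSWKMBDHV]", seqs[bad]))
    stop("non-IUPAC character(s) in record(s): ",
         paste(sprintf("%s ('%s')", ids[bad], off), collapse = ", "))
  }
  amb <- grepl("[RYSWKMBDHV]", seqs)
  if (any(amb)) {
    warning("IUPAC ambiguity codes converted to N in record(s): ",
            paste(ids[amb], collapse = ", "))
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  src <- switch(alphabet_policy,
                auto = ifelse(had_u, "RNA", "DNA"),
                DNA  = rep("DNA", length(ids)),
                RNA  = rep("RNA", length(ids)))
  as_log("read_fasta: ", length(ids), " record(s) from ", path)
  data.frame(id = ids, seq = unname(seqs), source_alphabet = src,
             stringsAsFactors = FALSE)
}

#' Write a sequence-record table as FASTA
#'
#' @param records data.frame with columns `id`, `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  writeLines(paste0(">", records$id, "\n", records$seq), path)
  invisible(path)
}

#' Read a sense-antisense pair table
#'
#' A TSV with (at least) columns `sense_id` and `antisense_id`, one row per
#' conserved sense-antisense pair (the role played by the FANTOM-3 conserved
#' NAT list in the original analysis).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `sense_id`, `antisense_id` (and `pair_id`
#'   if present in the file), rows in file order.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sense_id", "antisense_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pair table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) warning("pair table has a header but no rows: ", path)
  key <- paste(tab$sense_id, tab$antisense_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate pair(s) in table: ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])), collapse = ", "))
  as_log("read_pair_table: ", nrow(tab), " pair(s) from ", path)
  tab[, intersect(c("pair_id", need), names(tab)), drop = FALSE]
}

#' Resolve a pair table against loaded sequences
#'
#' Drops pairs whose sense or antisense id is absent from `records`, logging
#' the filter arithmetic (in the original study 993 retrieved pairs minus 99
#' unresolvable gave 894 usable pairs).
#'
#' @param pairs data.frame from [read_pair_table()].
#' @param records data.frame from [read_fasta()].
#' @return list with `usable` and `dropped` pair data.frames.
#' @export
resolve_pairs <- function(pairs, records) {
  ok <- pairs$sense_id %in% records$id & pairs$antisense_id %in% records$id
  as_log("resolve_pairs: ", nrow(pairs), " input pair(s); ",
         sum(!ok), " unresolvable dropped; ", sum(ok), " usable")
  list(usable = pairs[ok, , drop = FALSE],
       dropped = pairs[!ok, , drop = FALSE])
}

#' Write the predicted-site table
#'
#' Coordinates are written 1-based inclusive; rows are sorted on
#' (`transcript_id`, `start`, `mirna_id`) so output is byte-deterministic.
#'
#' @param sites data.frame of predicted sites with internal 0-based half-open
#'   `start`/`end` (as returned by [scan_regions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("transcript_id", "start", "end", "strand_scanned", "mirna_id",
            "region_class", "score", "energy_kcal_mol")
  if (is.null(sites) || nrow(sites) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(
    transcript_id = sites$transcript_id,
    start = sites$start + 1L,            # 1-based inclusive
    end = sites$end,
    strand_scanned = sites$strand_scanned %||% "+",
    mirna_id = sites$mirna_id,
    region_class = sites$region_class,
    score = sites$score,
    energy_kcal_mol = sites$energy,
    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$start, out$mirna_id), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' Restores internal 0-based half-open coordinates.
#'
#' @param path path to the TSV.
#' @return data.frame of sites.
#' @export
read_site_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab$start <- tab$start - 1L
    names(tab)[names(tab) == "energy_kcal_mol"] <- "energy"
  }
  tab
}

#' Write the per-pair, per-region density table
#'
#' Mirrors the study's supplementary listing of pairs and their potential
#' miRNA-binding sites in overlapping and non-overlapping regions.  Densities
#' are printed to 5 decimals.
#'
#' @param records data.frame of density records (see [density_records()]),
#'   with columns `pair_id`, `sense_id`, `antisense_id`, `region_class`,
#'   `site_count`, `length_nt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(records, path) {
  if (any(records$length_nt == 0))
    stop("density records with length_nt = 0 cannot be written")
  d <- records$site_count / records$length_nt
  out <- data.frame(
    pair_id = records$pair_id,
    sense_id = records$sense_id %||% NA_character_,
    antisense_id = records$antisense_id %||% NA_character_,
    region_class = records$region_class,
    site_count = records$site_count,
    length_nt = records$length_nt,
    density_per_nt = sprintf("%.5f", d),
    density_per_100nt = sprintf("%.5f", 100 * d),
    stringsAsFactors = FALSE)
  out <- out[order(out$pair_id, out$region_class), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a density table written by [write_density_table()]
#'
#' @param path path to the TSV.
#' @return data.frame of density records (densities re-parsed as numeric).
#' @export
read_density_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$density_per_nt <- as.numeric(tab$density_per_nt)
  tab$density_per_100nt <- as.numeric(tab$density_per_100nt)
  tab
}

#' Read a flat key-value configuration file
#'
#' A deliberately minimal flat `key: value` document (a YAML subset): one
#' setting per line, `#` comments and blank lines ignored.  Values are typed
#' as logical (`true`/`false`), numeric when they parse as numbers, character
#' otherwise.  Every CLI flag of the companion script has a config twin; CLI
#' flags override config values.
#'
#' @param path path to the config file.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!all(grepl(":", lines, fixed = TRUE)))
    stop("config lines must be 'key: value': ",
         lines[!grepl(":", lines, fixed = TRUE)][1])
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  typed <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(typed, keys)
}
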