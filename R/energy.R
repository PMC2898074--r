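## Nearest-neighbor RNA:RNA duplex free energy at 37 degrees C.
##
## Watson-Crick stack values are the Turner-group parameters (Xia et al.
## 1998); G:U wobble stacks follow the Mathews et al. (1999) extension and
## should be read as approximate — the package asserts internal consistency
## of the energy walk, not agreement with any particular web server.  Duplex
## initiation +4.09 kcal/mol; +0.45 per terminal A:U or G:U pair; dangling
## ends ignored; each interior helix interruption (mismatch or bulge run)
## costs a fixed loop-opening penalty.

NN_INIT <- 4.09
NN_TERM_AU <- 0.45   # per duplex-terminal A:U or G:U pair
NN_LOOP_OPEN <- 3.0  # per interior unpaired opening (fixed, a model choice)

## Canonical stack entries, key "XY/WZ": top strand 5'-XY-3' (target),
## bottom strand 3'-WZ-5' (miRNA), pairs X:W and Y:Z.  The full 36-entry
## table is completed by the symmetry dG(XY/WZ) == dG(ZW/YX).
nn_canonical <- c(
  ## Watson-Crick (Xia et al. 1998)
  "AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33, "CU/GA" = -2.08,
  "CA/GU" = -2.11, "GU/CA" = -2.24, "GA/CU" = -2.35, "CG/GC" = -2.36,
  "GG/CC" = -3.26, "GC/CG" = -3.42,
  ## G:U wobble (Mathews et al. 1999; approximate)
  "AG/UU" = -0.55, "AU/UG" = -1.36, "UG/AU" = -1.00, "UU/AG" = -1.27,
  "CG/GU" = -1.41, "CU/GG" = -2.11, "GG/CU" = -1.53, "GU/CG" = -2.51,
  "GG/UU" = -0.50, "GU/UG" =  1.29, "UG/GU" =  0.30)

## Build the complete stack lookup (environment used as a hash).
nn_table <- local({
  tab <- new.env(parent = emptyenv())
  for (k in names(nn_canonical)) {
    v <- nn_canonical[[k]]
    x <- substr(k, 1, 1); y <- substr(k, 2, 2)
    w <- substr(k, 4, 4); z <- substr(k, 5, 5)
    assign(k, v, envir = tab)
    assign(paste0(z, w, "/", y, x), v, envir = tab)  # symmetry partner
  }
  tab
})

is_pair <- function(t, m) {
  (t == "A" & m == "U") | (t == "U" & m == "A") |
  (t == "G" & m == "C") | (t == "C" & m == "G") |
  (t == "G" & m == "U") | (t == "U" & m == "G")
}

is_au_or_gu <- function(t, m) {
  (t == "A" & m == "U") | (t == "U" & m == "A") |
  (t == "G" & m == "U") | (t == "U" & m == "G")
}

#' Nearest-neighbor free energy of a miRNA:target duplex alignment
#'
#' Sums published RNA:RNA stacking free energies over consecutive paired
#' positions of an alignment trace, plus the duplex initiation penalty and a
#' fixed loop-opening penalty for each interior run of unpaired (mismatched
#' or gapped) positions.  More negative is more stable.  An alignment with no
#' paired position is defined as 0 kcal/mol (with a warning).
#'
#' @param alignment a list (or one-row data.frame) with gapped alignment
#'   strings `target` (written 5' to 3') and `mirna` (written 3' to 5',
#'   column-aligned with `target`), as produced by [align_mirna()].  DNA
#'   letters are accepted and read as RNA (`T` = `U`).
#' @return free energy in kcal/mol.
#' @export
#' @examples
#' duplex_energy(list(target = "GCGCG", mirna = "CGCGC"))
duplex_energy <- function(alignment) {
  at <- chartr("Tt", "Uu", toupper(alignment$target))
  am <- chartr("Tt", "Uu", toupper(alignment$mirna))
  stopifnot(nchar(at) == nchar(am))
  t_ch <- strsplit(at, "")[[1]]
  m_ch <- strsplit(am, "")[[1]]
  paired <- t_ch != "-" & m_ch != "-" & is_pair(t_ch, m_ch)
  idx <- which(paired)
  if (length(idx) == 0L) {
    warning("alignment has no paired positions; energy defined as 0")
    return(0)
  }
  dg <- NN_INIT
  ## terminal penalty at the two outermost pairs of the duplex
  dg <- dg + NN_TERM_AU * (is_au_or_gu(t_ch[idx[1]], m_ch[idx[1]]) +
                             is_au_or_gu(t_ch[idx[length(idx)]],
                                         m_ch[idx[length(idx)]]))
  if (length(idx) > 1L) {
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (j == i + 1L) {
        key <- paste0(t_ch[i], t_ch[j], "/", m_ch[i], m_ch[j])
        v <- get0(key, envir = nn_table, ifnotfound = NA_real_)
        if (is.na(v)) stop("missing nearest-neighbor entry: ", key)
        dg <- dg + v
      } else {
        dg <- dg + NN_LOOP_OPEN  # one opening per interior interruption
      }
    }
  }
  dg
}
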