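# Physical constants used throughout.  Lengths are in Angstrom, scattering
# lengths are stored in fm and converted with FM_PER_ANGSTROM, SLDs are in
# 1/Angstrom^2.
AVOGADRO <- 6.02214076e23
FM_TO_ANGSTROM <- 1e-5
R_ELECTRON_FM <- 2.8179403262 # classical electron (Thomson) radius, fm

.scattermd <- new.env(parent = emptyenv())

#' Isotope scattering-length table
#'
#' Loads the table of bound coherent neutron scattering lengths, atomic
#' numbers and atomic masses shipped with the package
#' (`inst/extdata/isotope_table.tsv`, values frozen from the Sears 1992
#' compilation).  Labels are element symbols for natural-abundance mixtures
#' ("H", "C", "Si") or mass-number-prefixed isotopes ("2H", "13C"); "D" and
#' "T" are aliases for "2H" and "3H".
#'
#' @param path Optional path to an alternative table with the same columns
#'   (`label`, `b_coh_fm`, `Z`, `mass_amu`).
#' @return A data frame with one row per isotope label.
#' @export
#' @examples
#' tab <- isotope_table()
#' tab[tab$label == "2H", ]
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.scattermd$isotopes)) return(.scattermd$isotopes)
    path <- system.file("extdata", "isotope_table.tsv", package = "scattermd",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("label", "b_coh_fm", "Z", "mass_amu") %in% names(tab)))
  if (anyDuplicated(tab$label))
    stop("duplicate isotope labels in table: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  .scattermd$isotopes <- tab
  tab
}

# Map user-facing aliases onto canonical table labels.
normalize_isotope <- function(label) {
  label <- trimws(as.character(label))
  alias <- c(D = "2H", T = "3H")
  hit <- match(label, names(alias))
  label[!is.na(hit)] <- alias[hit[!is.na(hit)]]
  label
}

isotope_row <- function(label, table = isotope_table()) {
  canon <- normalize_isotope(label)
  idx <- match(canon, table$label)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown isotope label(s): ", paste(bad, collapse = ", "))
  }
  table[idx, , drop = FALSE]
}

#' Look up a coherent neutron scattering length
#'
#' @param label Isotope label ("H", "D", "2H", "C", ...).  "D" resolves to
#'   the same entry as "2H".
#' @param table Isotope table, see [isotope_table()].
#' @return Bound coherent scattering length in fm (vectorised over `label`).
#' @export
#' @examples
#' lookup_scattering_length("H") # -3.739 fm
#' lookup_scattering_length("D") #  6.671 fm
lookup_scattering_length <- function(label, table = isotope_table()) {
  isotope_row(label, table)$b_coh_fm
}

#' Atomic number of an isotope label
#' @inheritParams lookup_scattering_length
#' @return Integer atomic number Z.
#' @export
lookup_atomic_number <- function(label, table = isotope_table()) {
  isotope_row(label, table)$Z
}
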