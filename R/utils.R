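# Shared internal helpers.

# Three-letter codes of the 20 standard amino acids.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Common non-standard residues and their standard parents (used only when
# the caller opts in to mapping at parse time).
NONSTANDARD_MAP <- c(MSE = "MET", HSD = "HIS", HSE = "HIS", HSP = "HIS",
                     HID = "HIS", HIE = "HIS", HIP = "HIS", CYX = "CYS",
                     SEC = "CYS")

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' printed summary tables), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y over grid x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Title-case a 3-letter residue code: "TRP" -> "Trp".
title_case3 <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Format residue labels
#'
#' Builds text residue labels of the form `"Trp37"` (title-cased 3-letter
#' amino-acid code followed by the author residue number).
#'
#' @param residue_name Character vector of 3-letter residue codes (any case).
#' @param residue_number Integer vector of author residue numbers.
#' @return Character vector of labels.
#' @seealso [parse_residue_label()]
#' @export
#' @examples
#' format_residue_label("TRP", 37)
format_residue_label <- function(residue_name, residue_number) {
  up <- toupper(residue_name)
  bad <- !(up %in% AA3)
  if (any(bad)) {
    stop("non-standard residue code(s): ",
         paste(unique(residue_name[bad]), collapse = ", "))
  }
  paste0(title_case3(up), as.integer(residue_number))
}

#' Parse residue labels
#'
#' Inverse of [format_residue_label()]: splits `"Trp37"` into its residue
#' code and number. Labels round-trip unchanged through parse/format.
#'
#' @param label Character vector of labels such as `"Gly26"`.
#' @return A data.frame with columns `residue_name` (upper-case 3-letter
#'   code) and `residue_number` (integer).
#' @export
#' @examples
#' parse_residue_label(c("Gly26", "Trp37"))
parse_residue_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]{3})([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  code <- toupper(vapply(m[!bad], `[`, "", 2L))
  if (any(bad) || !all(code %in% AA3)) {
    offenders <- unique(c(label[bad], label[!bad][!(code %in% AA3)]))
    stop("unparseable residue label(s): ", paste(offenders, collapse = ", "))
  }
  data.frame(
    residue_name = code,
    residue_number = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

# Residue numbers from labels ("Trp37" -> 37L).
label_numbers <- function(label) parse_residue_label(label)$residue_number
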