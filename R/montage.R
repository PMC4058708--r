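#' Standard 10-20 analysis montage
#'
#' The 19 scalp channels of the international 10-20 system used throughout the
#' package, in fixed montage order. All adjacency matrices and recordings use
#' this channel order.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Common alias spellings seen in EDF exports (modified combinatorial
# nomenclature and case variants) mapped onto the montage labels.
.label_aliases <- function() {
  c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6",
    FP1 = "Fp1", FP2 = "Fp2", FZ = "Fz", CZ = "Cz", PZ = "Pz")
}

#' Normalize channel labels to the 10-20 montage
#'
#' Strips common prefixes ("EEG "), reference suffixes ("-REF", "-AVG") and
#' whitespace, then applies the alias table (e.g. "T7" -> "T3").
#'
#' @param labels character vector of raw channel labels.
#' @param aliases named character vector mapping alias -> montage label.
#' @return Character vector of cleaned labels (not necessarily all montage
#'   members; extras such as "ECG" pass through and are dropped downstream).
#' @export
normalize_labels <- function(labels, aliases = .label_aliases()) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("-(REF|AVG|LE|A1A2)$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  montage <- montage_1020()
  canon <- montage[match(toupper(x), toupper(montage))]
  ali <- aliases[match(toupper(x), toupper(names(aliases)))]
  out <- ifelse(!is.na(canon), canon, ifelse(!is.na(ali), unname(ali), x))
  out
}
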