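# Character registry: 60 characters (25 body + 19 head + 4 gill + 12 meristic).
# Morphometric abbreviations follow the field's usage; the meristic lower-arch
# gill-raker count is "LGRN" (to keep it distinct from the morphometric LGR,
# longest gill raker length) and the combined count is "totalGR".

.characters <- local({
  body <- rbind(
    c("PelvFB", "Pelvic fin base"),
    c("PelvFS", "Pelvic fin 'spine' length"),
    c("PelvF",  "Pelvic fin length"),
    c("PecFB",  "Pectoral fin base"),
    c("PecF1",  "Pectoral fin 1 length"),
    c("PecF2",  "Pectoral fin 2 length"),
    c("DFB",    "Dorsal fin base"),
    c("DFAe",   "Length of anterior part of dorsal fin erected"),
    c("DFAd",   "Length of anterior part of dorsal fin depressed"),
    c("DFPe",   "Length of posterior part of dorsal fin erected"),
    c("AFB",    "Anal fin base"),
    c("AFAe",   "Length of anterior part of the anal fin"),
    c("AdFB",   "Adipose fin base"),
    c("CF",     "Caudal fin length"),
    c("CD",     "Caudal peduncle depth"),
    c("CL",     "Caudal peduncle length"),
    c("PAdC",   "Length from posterior part of adipose fin to caudal fin base"),
    c("DHL",    "Dorsal head length"),
    c("PreP",   "Prepelvic length"),
    c("PreA",   "Preanal length"),
    c("SL",     "Standard length"),
    c("TL",     "Total length"),
    c("PreD",   "Predorsal length"),
    c("BD",     "Body depth"),
    c("PostD",  "Postdorsal length"))
  head_ <- rbind(
    c("ED",    "Eye diameter"),
    c("EC",    "Eye cavity"),
    c("EH",    "Eye height"),
    c("ES",    "Eye socket"),
    c("PostO", "Postorbital length"),
    c("HL",    "Head length"),
    c("HD",    "Head depth"),
    c("HW",    "Head width"),
    c("MW",    "Mouth width"),
    c("UJ",    "Upper jaw length"),
    c("LJ",    "Lower jaw length"),
    c("LJW",   "Lower jaw width"),
    c("UJW",   "Upper jaw width"),
    c("M",     "Length of maxilla"),
    c("SN",    "Snout length"),
    c("SD",    "Snout depth"),
    c("SW",    "Snout width"),
    c("IOW",   "Interorbital width"),
    c("INW",   "Internarial width"))
  gill <- rbind(
    c("UA",  "Upper arch length"),
    c("LA",  "Lower arch length"),
    c("MGR", "Middle gill raker length"),
    c("LGR", "Longest gill raker length"))
  meristic <- rbind(
    c("PelvFR",  "Pelvic fin rays"),
    c("PecFR",   "Pectoral fin rays"),
    c("DFR",     "Dorsal fin rays"),
    c("AFR",     "Anal fin rays"),
    c("LS",      "Lateral line scales"),
    c("PDS",     "Predorsal scales"),
    c("TDS",     "Transverse dorsal scales"),
    c("TAS",     "Transverse anal scales"),
    c("TPS",     "Transverse pelvic scales"),
    c("UGR",     "Upper arch gill raker number"),
    c("LGRN",    "Lower arch gill raker number"),
    c("totalGR", "Total gill raker number"))
  reg <- data.frame(
    abbreviation = c(body[, 1], head_[, 1], gill[, 1], meristic[, 1]),
    full_name    = c(body[, 2], head_[, 2], gill[, 2], meristic[, 2]),
    category     = rep(c("body", "head", "gill", "meristic"),
                       c(nrow(body), nrow(head_), nrow(gill), nrow(meristic))),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(reg$abbreviation), nrow(reg) == 60L)
  reg
})

#' Character registry
#'
#' The registry of the 60 morphological and meristic characters used
#' throughout the package: 25 body characters, 19 head characters, 4 gill
#' characters (all measured in mm) and 12 meristic counts. Body characters
#' are standardized by standard length (SL), head and gill characters by
#' head length (HL); meristic counts are never standardized.
#'
#' @param category optional filter, one or more of `"body"`, `"head"`,
#'   `"gill"`, `"meristic"`.
#' @return a data.frame with columns `abbreviation`, `full_name`, `category`.
#' @examples
#' nrow(character_registry())            # 60
#' character_registry("meristic")$abbreviation
#' @export
character_registry <- function(category = NULL) {
  reg <- .characters
  if (!is.null(category)) {
    category <- match.arg(category, c("body", "head", "gill", "meristic"),
                          several.ok = TRUE)
    reg <- reg[reg$category %in% category, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Look up the category of character abbreviations
#'
#' @param abbreviation character vector of abbreviations (case-insensitive).
#' @return character vector of categories; unknown abbreviations give `NA`.
#' @export
character_category <- function(abbreviation) {
  idx <- match(tolower(abbreviation), tolower(.characters$abbreviation))
  .characters$category[idx]
}

#' Canonical abbreviation spelling (case-insensitive resolve)
#' @param abbreviation character vector.
#' @return canonical abbreviations, `NA` where unknown.
#' @export
resolve_character <- function(abbreviation) {
  idx <- match(tolower(abbreviation), tolower(.characters$abbreviation))
  .characters$abbreviation[idx]
}

is_meristic <- function(abbreviation) {
  character_category(abbreviation) == "meristic"
}

# Size denominator used for percent standardization of a character:
# "SL" for body, "HL" for head/gill, NA for meristics. HL itself is the
# head denominator but is reported as a percentage of SL.
standardization_denominator <- function(abbreviation) {
  cat <- character_category(abbreviation)
  out <- rep(NA_character_, length(cat))
  out[cat == "body"] <- "SL"
  out[cat %in% c("head", "gill")] <- "HL"
  out[resolve_character(abbreviation) == "HL"] <- "SL"
  out
}
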