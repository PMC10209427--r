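# Specimen tables: I/O, replicate QC, percent standardization, summaries.
#
# A specimen table is a plain data.frame, one row per fish, with metadata
# columns (id, species, lake, year, era, sex, age, type_status) followed by
# character columns named by registry abbreviations. Morphometric values are
# in mm, meristic values are integer counts. Missing characters are NA.

.metadata_cols <- c("id", "species", "lake", "year", "era", "sex", "age",
                    "type_status")

#' Read a specimen table
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) with one header row and one row per specimen. Column names are
#' resolved case-insensitively against [character_registry()]; metadata
#' columns `id, species, lake, year, era, sex, age, type_status` are kept as
#' is (only `id` and `species` are required). Unknown columns are dropped
#' with a warning and recorded in the `"unknown_columns"` attribute. Empty
#' cells become `NA` (an absent measurement), never zero.
#'
#' @param path path to the file.
#' @return a data.frame of class `specimen_table`.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA", "na"),
                           strip.white = TRUE, comment.char = "")
  nm <- names(raw)
  meta_idx <- match(tolower(nm), .metadata_cols)
  char_nm <- resolve_character(nm)
  unknown <- nm[is.na(meta_idx) & is.na(char_nm)]
  if (length(unknown)) {
    warn_("dropping unknown columns: %s", paste(unknown, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (j in seq_along(nm)) {
    if (!is.na(meta_idx[j])) {
      col <- .metadata_cols[meta_idx[j]]
      out[[col]] <- raw[[j]]
    } else if (!is.na(char_nm[j])) {
      vals <- raw[[j]]
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(num))
      if (length(bad)) {
        stop_("unparseable numeric value '%s' in column '%s', file row %d",
              vals[bad[1]], nm[j], bad[1] + 1L)  # +1 for the header line
      }
      if (is_meristic(char_nm[j])) {
        if (any(num[!is.na(num)] %% 1 != 0) || any(num < 0, na.rm = TRUE)) {
          stop_("meristic column '%s' must hold nonnegative integers", nm[j])
        }
        num <- as.integer(num)
      } else if (any(num <= 0, na.rm = TRUE)) {
        stop_("morphometric column '%s' must be positive (mm)", nm[j])
      }
      out[[char_nm[j]]] <- num
    }
  }
  for (col in c("id", "species")) {
    if (is.null(out[[col]])) stop_("required column '%s' missing", col)
  }
  if (anyDuplicated(out$id)) {
    stop_("duplicate specimen id(s): %s",
          paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  if (!is.null(out$year)) out$year <- as.integer(out$year)
  if (!is.null(out$age)) out$age <- as.integer(out$age)
  attr(out, "unknown_columns") <- unknown
  class(out) <- c("specimen_table", "data.frame")
  out
}

#' Write a specimen table
#'
#' Inverse of [read_specimens()]: writes a delimited text file that
#' round-trips through the reader.
#'
#' @param specimens a specimen table.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_specimens <- function(specimens, path, sep = ",") {
  utils::write.table(specimens, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Specimen table constructor
#'
#' Builds a specimen table from a data.frame already holding metadata and
#' character columns (used by the simulators and in tests).
#'
#' @param df a data.frame with at least `id` and `species` columns.
#' @return the data.frame with class `specimen_table`.
#' @export
as_specimen_table <- function(df) {
  stopifnot(is.data.frame(df), !is.null(df$id), !is.null(df$species))
  if (anyDuplicated(df$id)) stop_("duplicate specimen ids")
  class(df) <- unique(c("specimen_table", class(df)))
  df
}

character_columns <- function(specimens) {
  intersect(names(specimens), character_registry()$abbreviation)
}

#' Replicate-measurement quality control
#'
#' Each character is measured twice; the pair is accepted when the percent
#' deviance `100 * |a - b| / mean(a, b)` is below the threshold, in which
#' case the mean is taken. A pair exceeding the threshold is flagged for
#' re-measurement; once the re-measured pair is appended (4 replicates) the
#' mean of the closest pair with deviance under the threshold is accepted.
#'
#' @param replicates numeric vector of positive replicate measurements (mm);
#'   usually length 2, length 4 after re-measurement.
#' @param threshold_pct maximal tolerated percent deviance (default 5).
#' @return a list with `value` (accepted mean, or NA when flagged),
#'   `accepted` (logical), `deviance_pct` (deviance of the accepted or best
#'   pair) and `flag` (`"ok"`, `"re-measure"` or `"single-replicate"`).
#' @examples
#' qc_replicates(c(10.0, 10.4))   # accepted, mean 10.2
#' qc_replicates(c(10.0, 10.61))  # flagged for re-measurement
#' @export
qc_replicates <- function(replicates, threshold_pct = 5) {
  if (any(!is.finite(replicates)) || any(replicates <= 0)) {
    stop_("replicates must be positive finite numbers")
  }
  if (length(replicates) == 1L) {
    warn_("single replicate: value passed through without QC")
    return(list(value = replicates, accepted = TRUE, deviance_pct = NA_real_,
                flag = "single-replicate"))
  }
  pair_dev <- function(a, b) 100 * abs(a - b) / mean(c(a, b))
  if (length(replicates) == 2L) {
    dev <- pair_dev(replicates[1], replicates[2])
    if (dev < threshold_pct) {
      return(list(value = mean(replicates), accepted = TRUE,
                  deviance_pct = dev, flag = "ok"))
    }
    return(list(value = NA_real_, accepted = FALSE, deviance_pct = dev,
                flag = "re-measure"))
  }
  # 4 replicates after re-measurement: accept the closest acceptable pair
  pairs <- utils::combn(length(replicates), 2)
  devs <- apply(pairs, 2, function(ij) pair_dev(replicates[ij[1]],
                                                replicates[ij[2]]))
  best <- which.min(devs)
  if (devs[best] < threshold_pct) {
    ij <- pairs[, best]
    return(list(value = mean(replicates[ij]), accepted = TRUE,
                deviance_pct = devs[best], flag = "ok"))
  }
  list(value = NA_real_, accepted = FALSE, deviance_pct = devs[best],
       flag = "re-measure")
}

#' Standardize measurements to percent of SL / HL
#'
#' Body characters become percentages of standard length, head and gill
#' characters percentages of head length; meristic counts pass through
#' unchanged. `SL` and `HL` themselves are reported as `SL_mm` / `HL_mm`
#' alongside `HL` in percent of SL.
#'
#' @param specimens a specimen table (mm values).
#' @return a data.frame with the metadata columns, `SL_mm`, `HL_mm` (if
#'   present) and the character columns in percent (meristics unchanged).
#' @examples
#' sp <- as_specimen_table(data.frame(id = "h", species = "C.litoralis",
#'                                    SL = 326, HL = 67.5))
#' standardize(sp)$HL  # 20.7 %SL
#' @export
standardize <- function(specimens) {
  chars <- character_columns(specimens)
  if (!"SL" %in% chars) stop_("SL column required for standardization")
  SL <- specimens$SL
  if (any(!is.na(SL) & SL <= 0)) stop_("SL must be positive")
  HL <- if ("HL" %in% chars) specimens$HL else rep(NA_real_, nrow(specimens))
  out <- specimens[, intersect(names(specimens), .metadata_cols),
                   drop = FALSE]
  out$SL_mm <- SL
  out$HL_mm <- HL
  for (ch in setdiff(chars, "SL")) {
    denom_name <- standardization_denominator(ch)
    if (is.na(denom_name)) {       # meristic: unchanged
      out[[ch]] <- specimens[[ch]]
      next
    }
    denom <- if (denom_name == "SL") SL else HL
    present <- !is.na(specimens[[ch]])
    if (denom_name == "HL" && any(present & is.na(denom))) {
      stop_("character '%s' present but HL missing for specimen(s) %s", ch,
            paste(specimens$id[present & is.na(denom)], collapse = ", "))
    }
    out[[ch]] <- 100 * specimens[[ch]] / denom
  }
  class(out) <- c("standardized_table", "data.frame")
  out
}

#' Convert a standardized table back to mm
#'
#' Inverse of [standardize()]; reproduces mm values exactly up to floating
#' point rounding.
#'
#' @param standardized output of [standardize()].
#' @return a specimen table in mm.
#' @export
to_mm <- function(standardized) {
  SL <- standardized$SL_mm
  HL <- standardized$HL_mm
  out <- standardized[, intersect(names(standardized), .metadata_cols),
                      drop = FALSE]
  chars <- intersect(names(standardized), character_registry()$abbreviation)
  out$SL <- SL
  for (ch in setdiff(chars, "SL")) {
    denom_name <- standardization_denominator(ch)
    if (is.na(denom_name)) {
      out[[ch]] <- standardized[[ch]]
    } else {
      denom <- if (denom_name == "SL") SL else HL
      out[[ch]] <- standardized[[ch]] * denom / 100
    }
  }
  as_specimen_table(out)
}

#' All values attaining the maximal count
#' @param x integer-valued vector (NAs dropped).
#' @return sorted vector of modal values (possibly several).
#' @export
count_modes <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(integer(0))
  tab <- table(x)
  sort(as.numeric(names(tab)[tab == max(tab)]))
}

#' Per-species summary of one character
#'
#' For a morphometric character the summary is the mean and range of the
#' percent-standardized values; for a meristic character the mode(s) and
#' range of the raw counts. With no data the summary is flagged `na`; with a
#' single specimen a low-n flag is set. When every observed value is a
#' singleton the summary is flagged multimodal and all values are modes.
#'
#' @param specimens a specimen table sharing one species label.
#' @param character a registry abbreviation.
#' @return a list with `species`, `character`, `n`, `na`, `low_n` and either
#'   `mean`/`min`/`max` (morphometric, percent) or `modes`/`min`/`max`
#'   (meristic) plus `multimodal`.
#' @export
summarize_species <- function(specimens, character) {
  character <- resolve_character(character)
  if (is.na(character)) stop_("unknown character")
  sp <- unique(specimens$species)
  if (length(sp) != 1L) stop_("specimens must share a single species label")
  if (is_meristic(character)) {
    x <- specimens[[character]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      return(list(species = sp, character = character, n = 0L, na = TRUE,
                  low_n = FALSE, modes = integer(0), min = NA, max = NA,
                  multimodal = FALSE))
    }
    modes <- count_modes(x)
    list(species = sp, character = character, n = n, na = FALSE,
         low_n = n == 1L, modes = modes, min = min(x), max = max(x),
         multimodal = length(modes) > 1L)
  } else {
    std <- standardize(specimens)
    x <- if (character == "SL") std$SL_mm else std[[character]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      return(list(species = sp, character = character, n = 0L, na = TRUE,
                  low_n = FALSE, mean = NA_real_, min = NA_real_,
                  max = NA_real_))
    }
    list(species = sp, character = character, n = n, na = FALSE,
         low_n = n == 1L, mean = mean(x), min = min(x), max = max(x))
  }
}

#' Species summary table
#'
#' Summarises every character column for every species in a specimen table,
#' in the layout of a taxonomic description table (percent means and ranges
#' for morphometrics, modes and ranges for meristics; percents rounded to 1
#' decimal in the `text` column, unrounded values kept alongside).
#'
#' @param specimens a specimen table (possibly several species).
#' @return a data.frame with one row per species x character.
#' @export
species_summary <- function(specimens) {
  rows <- list()
  for (sp in unique(specimens$species)) {
    sub <- specimens[specimens$species == sp, , drop = FALSE]
    for (ch in character_columns(specimens)) {
      s <- summarize_species(sub, ch)
      if (is_meristic(ch)) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, character = ch, n = s$n,
          mean = NA_real_, min = as.numeric(s$min), max = as.numeric(s$max),
          modes = paste(s$modes, collapse = ";"),
          text = if (s$na) "na" else
            sprintf("%s (%s-%s)", paste(s$modes, collapse = ";"),
                    s$min, s$max),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, character = ch, n = s$n,
          mean = s$mean, min = s$min, max = s$max, modes = NA_character_,
          text = if (s$na) "na" else
            sprintf("%.1f (%.1f-%.1f)", s$mean, s$min, s$max),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
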