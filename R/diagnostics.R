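# Diagnostic screening: ratio overlap (asterisk rule), dichotomous
# identification keys, and meristic frequency-table diagnostics.

#' Overlap assessment between two species' diagnostic values
#'
#' Counts how many specimens of A fall inside B's closed observed range
#' `[min(B), max(B)]` and vice versa. The ratio earns an asterisk (eligible
#' for keys and diagnoses) when at most one specimen of one species overlaps
#' the other species in total.
#'
#' @param values_A,values_B numeric vectors of per-specimen values.
#' @return an `overlap_assessment`: list with `count_A_in_B`,
#'   `count_B_in_A`, `asterisk`.
#' @export
assess_overlap <- function(values_A, values_B) {
  if (!length(values_A) || !length(values_B)) stop_("empty value list")
  a_in_b <- sum(in_range(values_A, min(values_B), max(values_B)))
  b_in_a <- sum(in_range(values_B, min(values_A), max(values_A)))
  out <- list(count_A_in_B = a_in_b, count_B_in_A = b_in_a,
              asterisk = (a_in_b + b_in_a) <= 1L)
  class(out) <- "overlap_assessment"
  out
}

# ---- identification keys ----------------------------------------------------

#' Read a dichotomous identification key
#'
#' The key is a YAML file with an `entry` couplet id and a list of
#' `couplets`. Each couplet has an `id` and two `alternatives`; each
#' alternative carries one or two `conditions` (a `quantity` - either a
#' ratio "X/Y" of two characters, a standardized character in percent, or a
#' meristic count - with an inclusive `min`..`max` interval) and an
#' `outcome`, either `species: <name>` or `couplet: <id>`. The key graph
#' must be acyclic and every referenced couplet must exist.
#'
#' @param path YAML file path.
#' @return an `identification_key` object.
#' @export
read_key <- function(path) {
  raw <- yaml::read_yaml(path)
  key <- list(entry = raw$entry, couplets = raw$couplets)
  ids <- vapply(key$couplets, function(cp) cp$id, numeric(1))
  if (anyDuplicated(ids)) stop_("duplicate couplet ids")
  names(key$couplets) <- as.character(ids)
  for (cp in key$couplets) {
    if (length(cp$alternatives) != 2L) {
      stop_("couplet %s must have exactly 2 alternatives", cp$id)
    }
    for (alt in cp$alternatives) {
      if (is.null(alt$outcome$species) && is.null(alt$outcome$couplet)) {
        stop_("couplet %s: alternative lacks an outcome", cp$id)
      }
      if (!is.null(alt$outcome$couplet) &&
          !as.character(alt$outcome$couplet) %in% names(key$couplets)) {
        stop_("couplet %s references unknown couplet %s", cp$id,
              alt$outcome$couplet)
      }
    }
  }
  assert_acyclic(key)
  class(key) <- "identification_key"
  key
}

assert_acyclic <- function(key) {
  # DFS from every couplet; a back edge means a cycle
  visit <- function(id, seen) {
    if (id %in% seen) stop_("identification key contains a cycle at %s", id)
    cp <- key$couplets[[id]]
    for (alt in cp$alternatives) {
      nxt <- alt$outcome$couplet
      if (!is.null(nxt)) visit(as.character(nxt), c(seen, id))
    }
  }
  visit(as.character(key$entry), character(0))
  invisible(TRUE)
}

#' Species reachable from a key
#' @param key an `identification_key`.
#' @return character vector of species names at the leaves (unique).
#' @export
key_species <- function(key) {
  out <- character(0)
  for (cp in key$couplets) {
    for (alt in cp$alternatives) {
      if (!is.null(alt$outcome$species)) out <- c(out, alt$outcome$species)
    }
  }
  unique(out)
}

#' Classify a specimen with an identification key
#'
#' Deterministically traverses the key from its entry couplet. At each
#' couplet the supplied value of the tested quantity is checked against the
#' two alternatives' closed intervals (a conjunction requires both
#' conditions of an alternative). A value falling in neither alternative
#' returns `"undetermined"` with the couplet id attached as the
#' `"couplet"` attribute. Quantities are named as in the key file, e.g.
#' `"PreD/ED"` or `"totalGR"`.
#'
#' @param key an `identification_key`.
#' @param values named numeric vector or list supplying every quantity on
#'   the traversed path.
#' @return species name, or `"undetermined"` (with attribute `couplet`).
#' @export
classify_with_key <- function(key, values) {
  values <- unlist(values)
  id <- as.character(key$entry)
  repeat {
    cp <- key$couplets[[id]]
    matched <- NULL
    for (alt in cp$alternatives) {
      ok <- TRUE
      for (cond in alt$conditions) {
        q <- cond$quantity
        if (!q %in% names(values)) {
          stop_("couplet %s requires quantity '%s' which was not supplied",
                id, q)
        }
        v <- values[[q]]
        lo <- cond$min %||% -Inf
        hi <- cond$max %||% Inf
        if (!in_range(v, lo, hi)) { ok <- FALSE; break }
      }
      if (ok) { matched <- alt; break }
    }
    if (is.null(matched)) {
      return(structure("undetermined", couplet = cp$id))
    }
    if (!is.null(matched$outcome$species)) return(matched$outcome$species)
    id <- as.character(matched$outcome$couplet)
  }
}

#' Ratio and character quantities for key classification
#'
#' Computes, from one specimen row (mm values), the named quantities a key
#' needs: raw-mm ratios for `"X/Y"` quantities, percent values for
#' morphometric characters, and raw counts for meristics. Ratios are
#' computed from the mm values so that mm- and percent-based inputs give
#' identical ratios.
#'
#' @param specimen one-row specimen table (mm).
#' @param quantities character vector of quantity names.
#' @return named numeric vector.
#' @export
key_quantities <- function(specimen, quantities) {
  stopifnot(nrow(specimen) == 1L)
  std <- standardize(specimen)
  out <- numeric(0)
  for (q in quantities) {
    if (grepl("/", q, fixed = TRUE)) {
      parts <- resolve_character(strsplit(q, "/", fixed = TRUE)[[1]])
      if (anyNA(parts)) stop_("unknown characters in quantity '%s'", q)
      num <- specimen[[parts[1]]]; den <- specimen[[parts[2]]]
      if (is.null(num) || is.null(den) || is.na(num) || is.na(den)) {
        stop_("quantity '%s' not computable: missing measurement", q)
      }
      out[q] <- num / den
    } else {
      ch <- resolve_character(q)
      if (is.na(ch)) stop_("unknown quantity '%s'", q)
      v <- if (is_meristic(ch)) specimen[[ch]] else std[[ch]]
      if (is.null(v) || is.na(v)) stop_("quantity '%s' missing", q)
      out[q] <- v
    }
  }
  out
}

#' Quantities referenced by a key
#' @param key an `identification_key`.
#' @return character vector of quantity names used anywhere in the key.
#' @export
key_required_quantities <- function(key) {
  out <- character(0)
  for (cp in key$couplets) {
    for (alt in cp$alternatives) {
      for (cond in alt$conditions) out <- c(out, cond$quantity)
    }
  }
  unique(out)
}

# ---- meristic frequency tables ---------------------------------------------

#' Read a meristic frequency table
#'
#' Delimited text in the layout of a published frequency-of-occurrence
#' table: one row per species (columns `species`, `N`, then one column per
#' integer character value holding counts; empty cells are zero counts).
#'
#' @param path file path (tab- or comma-delimited, autodetected).
#' @return a `meristic_frequency_table`: list with `counts` (species x
#'   value matrix), `N` (named per-species totals), `inconsistent` (named
#'   logical: row sums disagreeing with N, kept but flagged).
#' @export
read_freq_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          na.strings = c("", "NA"), strip.white = TRUE,
                          fill = TRUE)
  if (!all(c("species", "N") %in% names(df))) {
    stop_("frequency table needs 'species' and 'N' columns")
  }
  value_cols <- setdiff(names(df), c("species", "N"))
  vals <- suppressWarnings(as.integer(value_cols))
  if (anyNA(vals)) stop_("value columns must be integers")
  counts <- as.matrix(df[, value_cols, drop = FALSE])
  counts[is.na(counts)] <- 0
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$species
  colnames(counts) <- value_cols
  N <- stats::setNames(as.integer(df$N), df$species)
  out <- list(counts = counts, N = N,
              inconsistent = rowSums(counts) != N)
  class(out) <- "meristic_frequency_table"
  out
}

#' Build a frequency table from raw counts
#' @param values named list: species -> integer vector of per-specimen
#'   counts.
#' @return a `meristic_frequency_table`.
#' @export
freq_table_from_counts <- function(values) {
  all_vals <- sort(unique(unlist(values)))
  counts <- t(vapply(values, function(v)
    as.integer(table(factor(v, levels = all_vals))),
    integer(length(all_vals))))
  colnames(counts) <- all_vals
  out <- list(counts = counts,
              N = vapply(values, length, integer(1)),
              inconsistent = stats::setNames(rep(FALSE, length(values)),
                                             names(values)))
  class(out) <- "meristic_frequency_table"
  out
}

#' Modes and range from a frequency table
#'
#' @param table a `meristic_frequency_table`.
#' @param species species row name.
#' @return list with `modes` (all values attaining the maximal count),
#'   `min`, `max`, `N`, `inconsistent` flag.
#' @export
meristic_modes <- function(table, species) {
  if (!species %in% rownames(table$counts)) {
    stop_("species '%s' not in table", species)
  }
  cnt <- table$counts[species, ]
  if (sum(cnt) < 1L) stop_("species '%s' has no counts", species)
  vals <- as.integer(colnames(table$counts))
  present <- vals[cnt > 0]
  list(modes = vals[cnt == max(cnt) & cnt > 0],
       min = min(present), max = max(present),
       N = unname(table$N[species]),
       inconsistent = unname(table$inconsistent[species]))
}

# ---- diagnosis report -------------------------------------------------------

#' Assemble a structured differential-diagnosis report
#'
#' Combines per-species summaries, ratio comparison reports and meristic
#' contrasts into one machine-readable report listing, for a species pair,
#' the asterisked diagnostic ratios with both ranges, the meristic
#' mode/range contrasts, and standardized characters whose observed ranges
#' do not overlap.
#'
#' @param specimens specimen table holding the two species.
#' @param report a `comparison_report` for the pair (optional; ratios
#'   section empty when NULL).
#' @param meristic_chars meristic characters to contrast (default: those
#'   present).
#' @return a `diagnosis_report` list; serialize with
#'   [write_diagnosis()] / render with [format_diagnosis()].
#' @export
build_diagnosis <- function(specimens, report = NULL,
                            meristic_chars = NULL) {
  sp <- unique(specimens$species)
  if (length(sp) != 2L) stop_("two species required")
  ratios <- list()
  if (!is.null(report)) {
    for (cd in report$candidates) {
      ratios[[length(ratios) + 1L]] <- list(
        ratio = paste0(cd$numerator, "/", cd$denominator),
        asterisk = isTRUE(cd$overlap$asterisk),
        range1 = cd$range1, range2 = cd$range2, D = cd$D)
    }
  }
  chars <- character_columns(specimens)
  mer <- meristic_chars %||% chars[is_meristic(chars)]
  meristics <- list()
  for (ch in mer) {
    s1 <- summarize_species(specimens[specimens$species == sp[1], ], ch)
    s2 <- summarize_species(specimens[specimens$species == sp[2], ], ch)
    if (s1$na || s2$na) next
    meristics[[ch]] <- list(character = ch,
                            modes1 = s1$modes, range1 = c(s1$min, s1$max),
                            modes2 = s2$modes, range2 = c(s2$min, s2$max))
  }
  nonoverlap <- list()
  for (ch in chars[!is_meristic(chars) & chars != "SL"]) {
    s1 <- summarize_species(specimens[specimens$species == sp[1], ], ch)
    s2 <- summarize_species(specimens[specimens$species == sp[2], ], ch)
    if (s1$na || s2$na) next
    if (s1$max < s2$min || s2$max < s1$min) {
      nonoverlap[[ch]] <- list(character = ch,
                               range1 = c(s1$min, s1$max),
                               range2 = c(s2$min, s2$max))
    }
  }
  out <- list(species = sp, ratios = ratios,
              meristics = unname(meristics),
              nonoverlapping_characters = unname(nonoverlap))
  class(out) <- "diagnosis_report"
  out
}

#' Serialize / restore / render a diagnosis report
#' @param diagnosis a `diagnosis_report`.
#' @param path JSON path.
#' @export
write_diagnosis <- function(diagnosis, path) {
  write_json_report(unclass(diagnosis), path)
}

#' @rdname write_diagnosis
#' @export
read_diagnosis <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(species = unlist(raw$species),
              ratios = lapply(raw$ratios, function(r) {
                list(ratio = r$ratio, asterisk = r$asterisk,
                     range1 = unlist(r$range1), range2 = unlist(r$range2),
                     D = r$D)
              }),
              meristics = lapply(raw$meristics, function(m) {
                list(character = m$character, modes1 = unlist(m$modes1),
                     range1 = unlist(m$range1), modes2 = unlist(m$modes2),
                     range2 = unlist(m$range2))
              }),
              nonoverlapping_characters =
                lapply(raw$nonoverlapping_characters, function(m) {
                  list(character = m$character, range1 = unlist(m$range1),
                       range2 = unlist(m$range2))
                }))
  class(out) <- "diagnosis_report"
  out
}

#' @rdname write_diagnosis
#' @export
format_diagnosis <- function(diagnosis) {
  sp <- diagnosis$species
  lines <- c(sprintf("## Differential diagnosis: %s vs. %s", sp[1], sp[2]), "")
  if (length(diagnosis$ratios)) {
    lines <- c(lines, "Diagnostic ratios:")
    for (r in diagnosis$ratios) {
      star <- if (isTRUE(r$asterisk)) "*" else ""
      lines <- c(lines, sprintf(
        "- larger '%s' ratio%s (%.3g-%.3g vs. %.3g-%.3g)", r$ratio, star,
        r$range1[1], r$range1[2], r$range2[1], r$range2[2]))
    }
    lines <- c(lines, "")
  }
  if (length(diagnosis$meristics)) {
    lines <- c(lines, "Meristic contrasts:")
    for (m in diagnosis$meristics) {
      lines <- c(lines, sprintf(
        "- %s: %d-%d (mode %s) vs. %d-%d (mode %s)", m$character,
        m$range1[1], m$range1[2], paste(m$modes1, collapse = " and "),
        m$range2[1], m$range2[2], paste(m$modes2, collapse = " and ")))
    }
    lines <- c(lines, "")
  }
  if (length(diagnosis$nonoverlapping_characters)) {
    lines <- c(lines, "Non-overlapping standardized characters:")
    for (m in diagnosis$nonoverlapping_characters) {
      lines <- c(lines, sprintf("- %s: %.1f-%.1f vs. %.1f-%.1f", m$character,
                                m$range1[1], m$range1[2], m$range2[1],
                                m$range2[2]))
    }
  }
  paste(lines, collapse = "\n")
}
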