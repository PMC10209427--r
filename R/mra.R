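# Multivariate ratio analysis: two-group LDA on log-transformed characters,
# exhaustive best-ratio extraction by standard distance, and the delta
# statistic separating shape from allometric size.
#
# All discriminant computations run in natural-log space, where a ratio of
# two characters is the contrast direction e_i - e_j. Any fixed log base
# gives identical standard distances and rankings.

#' Build a log-shape matrix for a two-group comparison
#'
#' Takes the morphometric (mm) columns of a specimen table, restricts them
#' to `characters` (default: all morphometric columns present), drops any
#' column with a missing value in either group (recorded in `dropped`), and
#' returns natural-log values with group labels.
#'
#' @param specimens a specimen table with exactly two species.
#' @param characters optional character subset (registry abbreviations).
#' @return an object of class `log_shape_matrix`: a list with `X` (n x p
#'   log-mm matrix), `groups` (factor of length n), `dropped` (columns
#'   removed because of missing values).
#' @export
log_shape_matrix <- function(specimens, characters = NULL) {
  sp <- unique(specimens$species)
  if (length(sp) != 2L) stop_("exactly two species required, got %d",
                              length(sp))
  chars <- character_columns(specimens)
  chars <- chars[!is_meristic(chars)]
  if (!is.null(characters)) {
    characters <- resolve_character(characters)
    if (anyNA(characters)) stop_("unknown characters in subset")
    missing_cols <- setdiff(characters, chars)
    if (length(missing_cols)) {
      stop_("characters not present in table: %s",
            paste(missing_cols, collapse = ", "))
    }
    chars <- characters
  }
  M <- as.matrix(specimens[, chars, drop = FALSE])
  if (any(M[!is.na(M)] <= 0)) stop_("all raw measurements must be positive")
  keep <- colSums(is.na(M)) == 0L
  dropped <- chars[!keep]
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 2L) stop_("fewer than 2 complete characters left")
  out <- list(X = log(M),
              groups = factor(specimens$species, levels = sp),
              dropped = dropped)
  rownames(out$X) <- specimens$id
  class(out) <- "log_shape_matrix"
  out
}

group_stats <- function(lsm) {
  g <- lsm$groups
  X <- lsm$X
  lev <- levels(g)
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  if (n1 < 2L || n2 < 2L) stop_("each group needs at least 2 specimens")
  X1 <- X[g == lev[1], , drop = FALSE]
  X2 <- X[g == lev[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  list(mu1 = mu1, mu2 = mu2, S = S, n1 = n1, n2 = n2)
}

#' Two-group discriminant direction in log-shape space
#'
#' Computes the Fisher discriminant direction `w` proportional to
#' `solve(S) \%*\% (mu1 - mu2)` (S the pooled within-group covariance),
#' normalized to unit length. A numerically singular S is regularized with
#' a ridge term `1e-8 * mean(diag(S))` on the diagonal, reported via the
#' `ridge_applied` flag. The number of specimens minus 2 must reach the
#' number of characters; otherwise the caller is directed to
#' [select_subset()].
#'
#' @param lsm a [log_shape_matrix()].
#' @return an object of class `discriminant_result`: list with `w` (unit
#'   p-vector), `mu1`, `mu2`, `S`, `u` (unit isometric size axis),
#'   `groups` (the two labels), `ridge_applied`.
#' @export
lda_direction <- function(lsm) {
  p <- ncol(lsm$X)
  if (p < 2L) stop_("need at least 2 characters")
  st <- group_stats(lsm)
  if (st$n1 + st$n2 - 2L < p) {
    stop_(paste0("more variables (%d) than specimens allow (n1+n2-2 = %d); ",
                 "use select_subset() first"), p, st$n1 + st$n2 - 2L)
  }
  S <- st$S
  d <- st$mu1 - st$mu2
  ridge_applied <- FALSE
  w <- tryCatch(solve(S, d), error = function(e) NULL)
  if (is.null(w) || rcond(S) < 1e-12) {
    S <- S + diag(1e-8 * mean(diag(S)), p)
    w <- solve(S, d)
    ridge_applied <- TRUE
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    # identical group means: direction undefined
    w <- rep(NA_real_, p)
  } else {
    w <- w / nw
  }
  out <- list(w = w, mu1 = st$mu1, mu2 = st$mu2, S = st$S,
              u = rep(1, p) / sqrt(p), groups = levels(lsm$groups),
              n1 = st$n1, n2 = st$n2, ridge_applied = ridge_applied)
  class(out) <- "discriminant_result"
  out
}

#' Standard distance along a direction
#'
#' The between-group mean difference projected on `direction`, standardized
#' by the pooled within-group standard deviation along the same direction:
#' `|t(d) (mu1 - mu2)| / sqrt(t(d) S d)`. For a ratio direction
#' `e_i - e_j` this is the univariate standard distance of `log(x_i/x_j)`.
#'
#' @param lsm a [log_shape_matrix()].
#' @param direction numeric p-vector (need not be normalized).
#' @return nonnegative scalar D.
#' @export
standard_distance <- function(lsm, direction) {
  if (length(direction) != ncol(lsm$X)) stop_("direction has wrong length")
  if (all(direction == 0)) stop_("direction must be nonzero")
  st <- group_stats(lsm)
  denom2 <- drop(crossprod(direction, st$S %*% direction))
  if (denom2 <= 0) stop_("degenerate variance along direction")
  abs(sum(direction * (st$mu1 - st$mu2))) / sqrt(denom2)
}

#' Allometry content of a discriminant (delta)
#'
#' `delta = |<w, u>|`, the absolute cosine between the unit discriminant
#' direction and the unit isometric size axis `u = (1, ..., 1)/sqrt(p)`.
#' delta is 1 when discrimination is carried purely by size, 0 when the
#' discriminant is a pure shape contrast (coefficients summing to zero):
#' the smaller delta, the less allometry contributes to the separation.
#'
#' @param result a `discriminant_result` from [lda_direction()].
#' @return delta in `[0, 1]`, or NA if the direction was undefined.
#' @export
delta_allometry <- function(result) {
  w <- result$w
  if (anyNA(w)) return(NA_real_)
  abs(sum(w * result$u))
}

#' Select an informative character subset
#'
#' When a comparison has more variables than individuals the discriminant is
#' not computable; a subset of at most `max_vars` characters is used
#' instead. An explicit list (e.g. a published preset) is used verbatim;
#' otherwise characters are ranked by their univariate standard distance
#' `|mu1_j - mu2_j| / sqrt(S_jj)` and the top `min(p, max_vars)` retained.
#'
#' @param lsm a [log_shape_matrix()].
#' @param max_vars maximal number of characters to keep (>= 2).
#' @param explicit optional explicit character vector, used verbatim.
#' @return character vector of retained abbreviations.
#' @export
select_subset <- function(lsm, max_vars, explicit = NULL) {
  chars <- colnames(lsm$X)
  if (!is.null(explicit)) {
    explicit <- resolve_character(explicit)
    if (anyNA(explicit)) stop_("explicit subset names unknown characters")
    missing_cols <- setdiff(explicit, chars)
    if (length(missing_cols)) {
      stop_("explicit subset characters absent from matrix: %s",
            paste(missing_cols, collapse = ", "))
    }
    return(explicit)
  }
  if (max_vars < 2L) stop_("max_vars must be >= 2")
  st <- group_stats(lsm)
  uni <- abs(st$mu1 - st$mu2) / sqrt(diag(st$S))
  keep <- order(uni, decreasing = TRUE)[seq_len(min(length(chars), max_vars))]
  chars[sort(keep)]
}

subset_lsm <- function(lsm, characters) {
  out <- lsm
  out$X <- lsm$X[, characters, drop = FALSE]
  out
}

#' Extract the best diagnostic ratios
#'
#' Evaluates every ordered character pair (i, j), i < j, as the log-space
#' contrast `e_i - e_j`, ranks pairs by [standard_distance()] and returns
#' the top `k`. Pairs may share a character. Each candidate is oriented so
#' that the first-listed group has the larger mean ratio; per-specimen raw
#' ratio values and per-group observed ranges are attached.
#'
#' @param lsm a [log_shape_matrix()].
#' @param k number of candidates to return (default 2).
#' @return a list of `ratio_candidate` objects, each a list with
#'   `numerator`, `denominator`, `D`, `values` (named per-specimen ratios),
#'   `range1`, `range2` (c(min, max) per group), `groups`.
#' @export
extract_best_ratios <- function(lsm, k = 2) {
  chars <- colnames(lsm$X)
  p <- length(chars)
  if (p < 2L) stop_("need at least 2 characters")
  st <- group_stats(lsm)
  dmu <- st$mu1 - st$mu2
  S <- st$S
  pairs <- utils::combn(p, 2)
  D <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    v2 <- S[i, i] + S[j, j] - 2 * S[i, j]
    dm <- dmu[i] - dmu[j]
    vscale <- S[i, i] + S[j, j]
    if (v2 <= 1e-12 * max(vscale, 1e-300)) {
      # ratio constant within groups: either identical between groups
      # (D = 0) or perfectly separating (infinite standard distance)
      mscale <- max(abs(dmu[i]), abs(dmu[j]), 1e-300)
      D[q] <- if (abs(dm) <= 1e-8 * mscale) 0 else Inf
    } else {
      D[q] <- abs(dm) / sqrt(v2)
    }
  }
  if (all(D == 0)) warn_("all pairwise standard distances are zero")
  ord <- order(D, decreasing = TRUE)
  k <- min(k, length(ord))
  lev <- levels(lsm$groups)
  lapply(ord[seq_len(k)], function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    # orient so group 1 has the larger mean log-ratio
    if (dmu[i] - dmu[j] < 0) { tmp <- i; i <- j; j <- tmp }
    vals <- exp(lsm$X[, i] - lsm$X[, j])
    g1 <- vals[lsm$groups == lev[1]]
    g2 <- vals[lsm$groups == lev[2]]
    out <- list(numerator = chars[i], denominator = chars[j], D = D[q],
                values = vals, range1 = range(g1), range2 = range(g2),
                groups = lev)
    class(out) <- "ratio_candidate"
    out
  })
}

#' @export
print.ratio_candidate <- function(x, ...) {
  cat(sprintf("%s/%s  D = %.2f  %s: %.3g-%.3g  %s: %.3g-%.3g\n",
              x$numerator, x$denominator, x$D,
              x$groups[1], x$range1[1], x$range1[2],
              x$groups[2], x$range2[1], x$range2[2]))
  invisible(x)
}

#' Pairwise species comparison report
#'
#' Composes the full ratio-analysis pipeline for one species pair: builds
#' the log-shape matrix (dropping characters with missing values), applies
#' the variables-vs-individuals subsetting rule (explicit preset or
#' univariate ranking capped at `n1 + n2 - 2`), extracts the best `k`
#' ratios, screens their per-group ranges for overlap (asterisk rule, see
#' [assess_overlap()]) and computes the delta allometry statistic of the
#' full discriminant.
#'
#' @param specimens a specimen table holding exactly the two species.
#' @param characters optional explicit character subset.
#' @param k number of ratio candidates (default 2).
#' @return an object of class `comparison_report`: list with `species`
#'   (the pair), `subset` (characters used), `subset_applied`, `dropped`,
#'   `candidates` (ratio candidates with `overlap` assessments), `delta`,
#'   `delta_undefined`.
#' @export
compare_species_pair <- function(specimens, characters = NULL, k = 2) {
  lsm <- log_shape_matrix(specimens, characters)
  st <- group_stats(lsm)
  p <- ncol(lsm$X)
  cap <- st$n1 + st$n2 - 2L
  subset_applied <- FALSE
  if (p > cap) {
    keep <- select_subset(lsm, max_vars = cap)
    lsm <- subset_lsm(lsm, keep)
    subset_applied <- TRUE
  }
  dres <- lda_direction(lsm)
  delta <- delta_allometry(dres)
  cands <- extract_best_ratios(lsm, k = k)
  cands <- lapply(cands, function(cd) {
    g1 <- cd$values[lsm$groups == dres$groups[1]]
    g2 <- cd$values[lsm$groups == dres$groups[2]]
    cd$overlap <- assess_overlap(g1, g2)
    cd
  })
  out <- list(species = dres$groups,
              subset = colnames(lsm$X),
              subset_applied = subset_applied || !is.null(characters),
              dropped = lsm$dropped,
              candidates = cands,
              delta = delta,
              delta_undefined = is.na(delta),
              n = c(st$n1, st$n2))
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison: %s vs. %s (n = %d, %d)\n", x$species[1],
              x$species[2], x$n[1], x$n[2]))
  if (x$subset_applied)
    cat(sprintf("  subset of %d characters used\n", length(x$subset)))
  for (cd in x$candidates) {
    star <- if (isTRUE(cd$overlap$asterisk)) " *" else ""
    cat(sprintf("  %s/%s%s  %.3g-%.3g vs. %.3g-%.3g  D = %.2f\n",
                cd$numerator, cd$denominator, star,
                cd$range1[1], cd$range1[2], cd$range2[1], cd$range2[2],
                cd$D))
  }
  cat(sprintf("  delta = %s\n",
              if (x$delta_undefined) "undefined" else sprintf("%.2f", x$delta)))
  invisible(x)
}

#' Serialize / restore a comparison report
#'
#' @param report a `comparison_report`.
#' @param path output (input) JSON path.
#' @return `read_comparison_report` returns the restored report.
#' @export
write_comparison_report <- function(report, path) {
  x <- unclass(report)
  x$candidates <- lapply(x$candidates, function(cd) {
    cd$values <- as.list(cd$values)
    cd$overlap <- unclass(cd$overlap)
    unclass(cd)
  })
  write_json_report(x, path)
}

#' @rdname write_comparison_report
#' @export
read_comparison_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  candidates <- lapply(raw$candidates, function(cd) {
    vals <- unlist(cd$values)
    out <- list(numerator = cd$numerator, denominator = cd$denominator,
                D = cd$D, values = vals,
                range1 = unlist(cd$range1), range2 = unlist(cd$range2),
                groups = unlist(cd$groups))
    out$overlap <- structure(list(count_A_in_B = cd$overlap$count_A_in_B,
                                  count_B_in_A = cd$overlap$count_B_in_A,
                                  asterisk = cd$overlap$asterisk),
                             class = "overlap_assessment")
    class(out) <- "ratio_candidate"
    out
  })
  out <- list(species = unlist(raw$species), subset = unlist(raw$subset),
              subset_applied = raw$subset_applied,
              dropped = as.character(unlist(raw$dropped)),
              candidates = candidates,
              delta = if (is.null(raw$delta)) NA_real_ else raw$delta,
              delta_undefined = raw$delta_undefined,
              n = unlist(raw$n))
  class(out) <- "comparison_report"
  out
}
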