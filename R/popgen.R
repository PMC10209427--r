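# Microsatellite population genetics: genotype containers, GenePop I/O,
# allele frequencies, HWE permutation test, Weir-Cockerham theta with
# permutations, and Cavalli-Sforza chord distances.

#' Diploid genotype matrix
#'
#' Container for individuals x loci diploid microsatellite calls. Alleles
#' are integer ids (repeat lengths); a missing genotype has NA in both
#' allele slots.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   alleles of each genotype (unordered); NA for missing.
#' @param pop character/factor of population labels, one per individual.
#' @param loci optional locus names (default `L1..Lp`).
#' @param ids optional individual ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, pop, loci = NULL, ids = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)), nrow(a1) == length(pop))
  if (ncol(a1) < 1L) stop_("at least one locus required")
  if (any(is.na(a1) != is.na(a2))) stop_("half-missing genotypes not allowed")
  pop <- as.character(pop)
  if (any(!nzchar(pop))) stop_("population labels must be nonempty")
  loci <- loci %||% paste0("L", seq_len(ncol(a1)))
  ids <- ids %||% paste0("ind", seq_len(nrow(a1)))
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- ids
  out <- list(a1 = a1, a2 = a2, pop = pop, loci = loci, ids = ids)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals, %d loci, %d populations\n",
              nrow(x$a1), length(x$loci), length(unique(x$pop))))
  invisible(x)
}

#' Populations of a genotype matrix
#' @param G a `genotype_matrix`.
#' @export
populations <- function(G) unique(G$pop)

#' Subset a genotype matrix by population
#' @param G a `genotype_matrix`.
#' @param pops population labels to keep.
#' @export
subset_pops <- function(G, pops) {
  keep <- G$pop %in% pops
  genotype_matrix(G$a1[keep, , drop = FALSE], G$a2[keep, , drop = FALSE],
                  G$pop[keep], loci = G$loci, ids = G$ids[keep])
}

# ---- GenePop I/O ------------------------------------------------------------

#' Read / write GenePop files
#'
#' Standard GenePop format: a title line, one locus name per line (or one
#' comma-separated line), populations separated by `Pop` lines, and one
#' individual per line as `id ,  aaabbb aaabbb ...` with 2- or 3-digit
#' allele codes; `00`/`000` codes a missing allele. Population labels are
#' taken from the id of the first individual in each `Pop` block (the
#' GenePop convention), with a `popN` fallback.
#'
#' @param path file path.
#' @return `read_genepop` returns a [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop_("not a GenePop file: %s", path)
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop_("no 'Pop' separator found")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  ids <- character(0); pops <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_n <- 0L
  cur_pop <- NA_character_
  for (i in seq(pop_idx[1], length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_n <- pop_n + 1L
      cur_pop <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop_("malformed GenePop line: %s", ln)
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != L) {
      stop_("individual '%s' has %d genotypes, expected %d", id,
            length(gts), L)
    }
    digits <- nchar(gts[1]) / 2
    if (!digits %in% c(2, 3)) stop_("allele coding must be 2 or 3 digits")
    al1 <- as.integer(substr(gts, 1, digits))
    al2 <- as.integer(substr(gts, digits + 1, 2 * digits))
    al1[al1 == 0L] <- NA_integer_
    al2[al2 == 0L] <- NA_integer_
    # a genotype with one missing allele is treated as fully missing
    miss <- is.na(al1) | is.na(al2)
    al1[miss] <- NA_integer_; al2[miss] <- NA_integer_
    if (is.na(cur_pop)) cur_pop <- if (nzchar(id)) id else paste0("pop", pop_n)
    ids <- c(ids, id); pops <- c(pops, cur_pop)
    rows1[[length(rows1) + 1L]] <- al1
    rows2[[length(rows2) + 1L]] <- al2
  }
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2), pops,
                  loci = loci, ids = make.unique(ids))
}

#' @rdname read_genepop
#' @param G a [genotype_matrix()].
#' @param title title line content.
#' @param digits allele code width, 2 or 3.
#' @export
write_genepop <- function(G, path, title = "coregonid genotypes",
                          digits = 3) {
  stopifnot(digits %in% c(2, 3))
  if (any(G$a1 >= 10^digits | G$a2 >= 10^digits, na.rm = TRUE)) {
    stop_("allele ids too large for %d-digit coding", digits)
  }
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(G$loci, con)
  for (p in populations(G)) {
    writeLines("Pop", con)
    idx <- which(G$pop == p)
    for (i in idx) {
      gt <- paste0(fmt(G$a1[i, ]), fmt(G$a2[i, ]))
      writeLines(paste0(p, "_", G$ids[i], " ,  ", paste(gt, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read / write a long-format genotype table
#'
#' Delimited alternative to GenePop: columns `id`, `pop`, `locus`,
#' `allele1`, `allele2` (empty alleles = missing).
#' @param path file path.
#' @export
read_genotypes_long <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), strip.white = TRUE)
  need <- c("id", "pop", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop_("long genotype table needs columns: %s", paste(need, collapse = ", "))
  }
  ids <- unique(df$id)
  loci <- unique(df$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(df$id, ids), match(df$locus, loci))] <- as.integer(df$allele1)
  a2[cbind(match(df$id, ids), match(df$locus, loci))] <- as.integer(df$allele2)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  pop <- df$pop[match(ids, df$id)]
  genotype_matrix(a1, a2, pop, loci = loci, ids = ids)
}

# ---- allele frequencies -----------------------------------------------------

#' Per-population allele frequencies
#'
#' Tallies non-missing alleles per population and locus and normalizes to
#' frequencies. A population with zero non-missing calls at a locus gets no
#' frequency vector there and is flagged in `absent`.
#'
#' @param G a [genotype_matrix()].
#' @return an `allele_freq_table`: list with `freq[[pop]][[locus]]` (named
#'   frequency vectors), `n[[pop]][[locus]]` (diploid sample sizes) and
#'   `absent` (data.frame of pop/locus combinations without data).
#' @export
allele_frequencies <- function(G) {
  pops <- populations(G)
  freq <- list(); nn <- list()
  absent <- list()
  for (p in pops) {
    idx <- G$pop == p
    freq[[p]] <- list(); nn[[p]] <- list()
    for (l in G$loci) {
      al <- c(G$a1[idx, l], G$a2[idx, l])
      al <- al[!is.na(al)]
      if (!length(al)) {
        absent[[length(absent) + 1L]] <- data.frame(pop = p, locus = l)
        next
      }
      tab <- table(al)
      freq[[p]][[l]] <- stats::setNames(as.numeric(tab) / sum(tab),
                                        names(tab))
      nn[[p]][[l]] <- length(al) / 2
    }
  }
  out <- list(freq = freq, n = nn,
              absent = if (length(absent)) do.call(rbind, absent) else
                data.frame(pop = character(0), locus = character(0)),
              loci = G$loci, pops = pops)
  class(out) <- "allele_freq_table"
  out
}

# ---- heterozygosity and HWE -------------------------------------------------

#' Observed and unbiased expected heterozygosity
#'
#' @param G a [genotype_matrix()].
#' @param population population label.
#' @param locus locus name.
#' @return list with `Ho`, `He` (Nei's unbiased expected heterozygosity,
#'   `2n/(2n-1) * (1 - sum p^2)`), `n` (genotyped individuals).
#' @export
heterozygosity <- function(G, population, locus) {
  idx <- G$pop == population
  a1 <- G$a1[idx, locus]; a2 <- G$a2[idx, locus]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 1L) return(list(Ho = NA_real_, He = NA_real_, n = 0L))
  Ho <- mean(a1 != a2)
  p <- table(c(a1, a2)) / (2 * n)
  He <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  list(Ho = Ho, He = He, n = n)
}

#' Hardy-Weinberg permutation test
#'
#' The statistic is the heterozygote-deficit index `1 - Ho/He` (positive
#' under a deficit of heterozygotes, negative under an excess). The null
#' distribution is generated by randomly re-pairing the population's
#' observed allele pool into genotypes; the two-sided p-value is the
#' proportion of permutations with `|stat|` at least as large as observed,
#' with the add-one correction `(b + 1)/(n_perm + 1)`.
#'
#' @param G a [genotype_matrix()].
#' @param population,locus which sample to test.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list with `statistic`, `p_value`, `Ho`, `He`, `n`; all NA for a
#'   monomorphic locus.
#' @export
hwe_test <- function(G, population, locus, n_perm = 1000, seed = NULL) {
  idx <- G$pop == population
  a1 <- G$a1[idx, locus]; a2 <- G$a2[idx, locus]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 2L) stop_("need >= 2 genotyped individuals")
  pool <- c(a1, a2)
  if (length(unique(pool)) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_, Ho = NA_real_,
                He = NA_real_, n = n, note = "monomorphic"))
  }
  het <- heterozygosity(G, population, locus)
  stat <- 1 - het$Ho / het$He
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pool)
      b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
      Ho_b <- mean(b1 != b2)
      stat_b <- 1 - Ho_b / het$He   # allele pool (hence He) is invariant
      if (abs(stat_b) >= abs(stat) - 1e-12) exceed <- exceed + 1L
    }
    list(statistic = stat, p_value = (exceed + 1) / (n_perm + 1),
         Ho = het$Ho, He = het$He, n = n)
  })
}

# ---- Weir-Cockerham theta ---------------------------------------------------

# Variance components (a, b, c) summed over alleles of one locus for two
# populations; x1/y1, x2/y2 are the allele vectors of the two populations
# (non-missing genotypes only).
wc_components_locus <- function(a1_1, a2_1, a1_2, a2_2) {
  n1 <- length(a1_1); n2 <- length(a1_2)
  if (n1 < 1L || n2 < 1L) return(NULL)
  alleles <- unique(c(a1_1, a2_1, a1_2, a2_2))
  if (length(alleles) < 2L) return(NULL)   # monomorphic locus
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    p1 <- (sum(a1_1 == al) + sum(a2_1 == al)) / (2 * n1)
    p2 <- (sum(a1_2 == al) + sum(a2_2 == al)) / (2 * n2)
    h1 <- mean((a1_1 == al) != (a2_1 == al))
    h2 <- mean((a1_2 == al) != (a2_2 == al))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a_comp <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b_comp <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    c_comp <- hbar / 2
    a_sum <- a_sum + a_comp
    b_sum <- b_sum + b_comp
    c_sum <- c_sum + c_comp
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

wc_theta <- function(a1A, a2A, a1B, a2B, loci) {
  tot <- c(a = 0, b = 0, c = 0)
  used <- 0L
  for (l in loci) {
    kA <- !is.na(a1A[, l]); kB <- !is.na(a1B[, l])
    if (sum(kA) < 1L || sum(kB) < 1L) next
    comp <- wc_components_locus(a1A[kA, l], a2A[kA, l], a1B[kB, l], a2B[kB, l])
    if (is.null(comp)) next
    tot <- tot + comp
    used <- used + 1L
  }
  if (used == 0L) return(NULL)
  denom <- sum(tot)
  theta <- if (denom == 0) 0 else tot[["a"]] / denom
  list(theta = max(-1, min(1, theta)), n_loci = used)
}

#' Pairwise Weir-Cockerham theta (Fst) with permutation test
#'
#' Estimates Weir and Cockerham's (1984) theta between two populations from
#' the variance components a (among populations), b (among individuals
#' within populations) and c (within individuals), combined across loci and
#' alleles as the ratio of sums `sum(a) / sum(a + b + c)`. Significance is
#' assessed by permuting individuals between the two populations; the
#' p-value is `(b + 1)/(n_perm + 1)` for permuted theta >= observed.
#'
#' @param G a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param n_perm permutations (default 1000; 0 skips the test).
#' @param seed optional RNG seed.
#' @return list with `theta` (clipped to `[-1, 1]`), `p_value` (NA when
#'   `n_perm = 0`), `n_loci` used; NA theta when no shared polymorphic
#'   locus exists.
#' @export
pairwise_fst <- function(G, popA, popB, n_perm = 1000, seed = NULL) {
  iA <- which(G$pop == popA); iB <- which(G$pop == popB)
  if (length(iA) < 2L || length(iB) < 2L) {
    stop_("both populations need >= 2 individuals")
  }
  est <- wc_theta(G$a1[iA, , drop = FALSE], G$a2[iA, , drop = FALSE],
                  G$a1[iB, , drop = FALSE], G$a2[iB, , drop = FALSE], G$loci)
  if (is.null(est)) {
    return(list(theta = NA_real_, p_value = NA_real_, n_loci = 0L,
                note = "no shared polymorphic locus"))
  }
  p_value <- NA_real_
  if (n_perm > 0) {
    idx <- c(iA, iB)
    nA <- length(iA)
    p_value <- with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(idx)
        jA <- perm[seq_len(nA)]; jB <- perm[-seq_len(nA)]
        eb <- wc_theta(G$a1[jA, , drop = FALSE], G$a2[jA, , drop = FALSE],
                       G$a1[jB, , drop = FALSE], G$a2[jB, , drop = FALSE],
                       G$loci)
        if (!is.null(eb) && eb$theta >= est$theta - 1e-12) {
          exceed <- exceed + 1L
        }
      }
      (exceed + 1) / (n_perm + 1)
    })
  }
  list(theta = est$theta, p_value = p_value, n_loci = est$n_loci)
}

# ---- chord distance ---------------------------------------------------------

#' Cavalli-Sforza and Edwards chord distance
#'
#' For each locus shared by the two populations,
#' `f_l = 1 - sum_a sqrt(p_Aa * p_Ba)`; the chord distance is
#' `(2 * sqrt(2) / pi) * sqrt(mean_l f_l)`. It is 0 for identical frequency
#' vectors and attains its maximum `2*sqrt(2)/pi` (about 0.9003) for
#' completely disjoint allele sets at every shared locus.
#'
#' @param F an [allele_frequencies()] table.
#' @param popA,popB population labels.
#' @return the chord distance, or NA if no shared locus has data.
#' @export
chord_distance <- function(F, popA, popB) {
  fs <- numeric(0)
  for (l in F$loci) {
    pA <- F$freq[[popA]][[l]]; pB <- F$freq[[popB]][[l]]
    if (is.null(pA) || is.null(pB)) next
    alleles <- union(names(pA), names(pB))
    qA <- stats::setNames(rep(0, length(alleles)), alleles)
    qB <- qA
    qA[names(pA)] <- pA; qB[names(pB)] <- pB
    fs <- c(fs, 1 - sum(sqrt(qA * qB)))
  }
  if (!length(fs)) return(NA_real_)
  (2 * sqrt(2) / pi) * sqrt(max(0, mean(fs)))
}

#' Chord distance matrix between all populations
#'
#' @param F an [allele_frequencies()] table.
#' @return symmetric matrix with zero diagonal, labelled by population.
#' @export
chord_distance_matrix <- function(F) {
  pops <- F$pops
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- chord_distance(F, pops[i], pops[j])
    }
  }
  D
}

#' Read / write a square distance matrix
#'
#' Delimited square matrix with row/column labels; a PHYLIP-style leading
#' line holding only the number of taxa is tolerated on read.
#' @param path file path.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  if (grepl("^\\s*\\d+\\s*$", lines[1])) lines <- lines[-1]
  con <- textConnection(lines)
  on.exit(close(con))
  first <- strsplit(lines[1], "[\t ,]+")[[1]]
  has_header <- suppressWarnings(all(is.na(as.numeric(
    first[nzchar(first)][-1]))))
  m <- as.matrix(utils::read.table(con, header = has_header,
                                   row.names = 1, check.names = FALSE))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop_("distance matrix is not symmetric")
  }
  colnames(m) <- rownames(m)
  m
}

#' @rdname read_distance_matrix
#' @param D symmetric matrix.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(data.frame(label = rownames(D), D, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
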