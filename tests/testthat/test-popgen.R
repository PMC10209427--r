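test_that("allele frequencies are direct normalized counts", {
  # 2 individuals: AA and AB -> p(A) = 0.75
  G <- genotype_matrix(rbind(1, 1), rbind(1, 2), c("p1", "p1"))
  F <- allele_frequencies(G)
  expect_equal(F$freq$p1$L1, c("1" = 0.75, "2" = 0.25))
  expect_equal(F$n$p1$L1, 2)

  # all-missing locus is flagged absent
  G2 <- genotype_matrix(cbind(c(1, 1), c(NA, NA)), cbind(c(1, 2), c(NA, NA)),
                        c("p1", "p1"))
  F2 <- allele_frequencies(G2)
  expect_null(F2$freq$p1$L2)
  expect_equal(nrow(F2$absent), 1L)

  # seeded random matrix equals a brute-force tally oracle
  set.seed(41)
  n <- 40
  a1 <- matrix(sample(1:5, n * 3, replace = TRUE), n, 3)
  a2 <- matrix(sample(1:5, n * 3, replace = TRUE), n, 3)
  a1[sample(length(a1), 10)] <- NA
  a2[is.na(a1)] <- NA
  pop <- sample(c("x", "y"), n, replace = TRUE)
  G3 <- genotype_matrix(a1, a2, pop)
  F3 <- allele_frequencies(G3)
  for (p in c("x", "y")) for (l in 1:3) {
    al <- c(a1[pop == p, l], a2[pop == p, l])
    al <- al[!is.na(al)]
    oracle <- table(al) / length(al)
    got <- F3$freq[[p]][[paste0("L", l)]]
    expect_equal(unname(got[names(oracle)]), unname(as.numeric(oracle)))
  }
})

test_that("frequency vectors sum to one over observed alleles", {
  G <- simulate_genotypes(n_demes = 3, n_per_deme = 20, n_loci = 5,
                          seed = 42)
  F <- allele_frequencies(G)
  for (p in F$pops) for (l in F$loci) {
    if (!is.null(F$freq[[p]][[l]])) {
      expect_equal(sum(F$freq[[p]][[l]]), 1, tolerance = 1e-9)
    }
  }
})

test_that("HWE statistic is near zero under equilibrium, one under fixation", {
  set.seed(43)
  # large sample in exact HWE proportions: p = q = 0.5
  n <- 400
  geno <- sample(rep(c("AA", "AB", "BB"), c(100, 200, 100)))
  a1 <- ifelse(substr(geno, 1, 1) == "A", 1L, 2L)
  a2 <- ifelse(substr(geno, 2, 2) == "A", 1L, 2L)
  G <- genotype_matrix(cbind(a1, a1), cbind(a2, a2), rep("p", n),
                       loci = c("L1", "L2"))
  res <- hwe_test(G, "p", "L1", n_perm = 199, seed = 1)
  expect_lt(abs(res$statistic), 0.01)
  expect_gt(res$p_value, 0.1)

  # complete heterozygote deficit: all homozygotes at 50/50 alleles
  G2 <- genotype_matrix(cbind(rep(c(1L, 2L), each = 25)),
                        cbind(rep(c(1L, 2L), each = 25)), rep("p", 50))
  res2 <- hwe_test(G2, "p", "L1", n_perm = 199, seed = 1)
  expect_equal(res2$statistic, 1)
  expect_lte(res2$p_value, 1 / (199 + 1) + 1e-12)

  # monomorphic locus
  G3 <- genotype_matrix(cbind(rep(1L, 10)), cbind(rep(1L, 10)), rep("p", 10))
  expect_true(is.na(hwe_test(G3, "p", "L1", n_perm = 9)$statistic))
})

test_that("permutation p-value matches exact enumeration on a toy sample", {
  # 6 genotypes, alleles enumerable: exact null over all allele pairings
  a1 <- c(1L, 1L, 1L, 2L, 2L, 1L)
  a2 <- c(1L, 1L, 2L, 2L, 2L, 1L)
  G <- genotype_matrix(cbind(a1), cbind(a2), rep("p", 6))
  obs <- hwe_test(G, "p", "L1", n_perm = 4000, seed = 7)

  pool <- c(a1, a2)
  n <- length(a1)
  He <- obs$He
  # enumerate all distinct orderings via all permutations of the pool is
  # too large; enumerate all perfect matchings recursively instead
  match_stats <- function(items) {
    if (!length(items)) return(0L)   # count heterozygote pairs below
    NULL
  }
  hets_dist <- new.env()
  recurse <- function(items, hets, weight) {
    if (!length(items)) {
      key <- as.character(hets)
      hets_dist[[key]] <- (hets_dist[[key]] %||% 0) + weight
      return(invisible())
    }
    first <- items[1]
    rest <- items[-1]
    for (k in seq_along(rest)) {
      recurse(rest[-k], hets + (first != rest[k]), weight)
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  recurse(pool, 0L, 1)
  keys <- as.integer(ls(hets_dist))
  weights <- vapply(as.character(keys), function(k) hets_dist[[k]],
                    numeric(1))
  probs <- weights / sum(weights)
  stats <- 1 - (keys / n) / He
  p_exact <- sum(probs[abs(stats) >= abs(obs$statistic) - 1e-12])
  expect_lt(abs(obs$p_value - p_exact), 0.05)
})

test_that("theta is one for fixed differences and near zero under panmixia", {
  # two populations fixed for different alleles at every locus
  n <- 20
  a <- matrix(1L, n, 4); b <- matrix(2L, n, 4)
  G <- genotype_matrix(rbind(a, b), rbind(a, b),
                       rep(c("p1", "p2"), each = n))
  expect_equal(pairwise_fst(G, "p1", "p2", n_perm = 0)$theta, 1)

  # one panmictic population split at random
  set.seed(44)
  G0 <- simulate_genotypes(n_demes = 1, n_per_deme = 200, n_loci = 10,
                           n_alleles = 8, F = 0, seed = 45)
  G0$pop <- sample(rep(c("h1", "h2"), each = 100))
  res0 <- pairwise_fst(G0, "h1", "h2", n_perm = 99, seed = 2)
  expect_lt(abs(res0$theta), 0.02)
  expect_gt(res0$p_value, 0.05)
})

test_that("theta equals an independently coded variance-component oracle", {
  # independent reimplementation following the published per-allele
  # component formulas, specialised to two populations
  wc_oracle <- function(g1, g2) {
    num <- den <- 0
    for (l in seq_along(g1)) {
      x <- g1[[l]]; y <- g2[[l]]
      n1 <- nrow(x); n2 <- nrow(y)
      alleles <- sort(unique(c(x, y)))
      if (length(alleles) < 2) next
      nbar <- mean(c(n1, n2))
      nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar))
      for (al in alleles) {
        p1 <- mean(x == al); p2 <- mean(y == al)
        h1 <- mean(xor(x[, 1] == al, x[, 2] == al))
        h2 <- mean(xor(y[, 1] == al, y[, 2] == al))
        pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
        s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
        hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
        a <- (nbar / nc) *
          (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        num <- num + a
        den <- den + a + b + cc
      }
    }
    num / den
  }
  set.seed(46)
  for (rep in 1:3) {
    n1 <- 15; n2 <- 12
    g1 <- list(cbind(sample(1:3, n1, TRUE), sample(1:3, n1, TRUE)),
               cbind(sample(1:4, n1, TRUE), sample(1:4, n1, TRUE)))
    g2 <- list(cbind(sample(2:4, n2, TRUE), sample(2:4, n2, TRUE)),
               cbind(sample(1:4, n2, TRUE), sample(1:4, n2, TRUE)))
    a1 <- rbind(cbind(g1[[1]][, 1], g1[[2]][, 1]),
                cbind(g2[[1]][, 1], g2[[2]][, 1]))
    a2 <- rbind(cbind(g1[[1]][, 2], g1[[2]][, 2]),
                cbind(g2[[1]][, 2], g2[[2]][, 2]))
    G <- genotype_matrix(a1, a2, rep(c("p1", "p2"), c(n1, n2)))
    got <- pairwise_fst(G, "p1", "p2", n_perm = 0)$theta
    expect_equal(got, wc_oracle(g1, g2), tolerance = 1e-12)
  }
})

test_that("chord distance matches its closed forms and direct evaluation", {
  mk_freq <- function(freqs) {
    # freqs: list pop -> list locus -> named vector
    out <- list(freq = freqs,
                n = lapply(freqs, function(x) lapply(x, function(...) 10)),
                absent = data.frame(),
                loci = names(freqs[[1]]), pops = names(freqs))
    class(out) <- "allele_freq_table"
    out
  }
  same <- list(L1 = c("1" = 0.3, "2" = 0.7), L2 = c("1" = 1))
  F1 <- mk_freq(list(a = same, b = same))
  expect_equal(chord_distance(F1, "a", "b"), 0)

  # completely disjoint allele sets at a single locus: the maximum
  F2 <- mk_freq(list(a = list(L1 = c("1" = 0.5, "2" = 0.5)),
                     b = list(L1 = c("3" = 0.2, "4" = 0.8))))
  expect_equal(chord_distance(F2, "a", "b"), 2 * sqrt(2) / pi,
               tolerance = 1e-12)

  # random frequency pair: direct formula oracle
  set.seed(47)
  for (i in 1:10) {
    pA <- prop.table(runif(4)); pB <- prop.table(runif(4))
    names(pA) <- names(pB) <- as.character(1:4)
    F3 <- mk_freq(list(a = list(L1 = pA), b = list(L1 = pB)))
    oracle <- (2 * sqrt(2) / pi) * sqrt(1 - sum(sqrt(pA * pB)))
    expect_equal(chord_distance(F3, "a", "b"), oracle, tolerance = 1e-12)
    expect_equal(chord_distance(F3, "a", "b"), chord_distance(F3, "b", "a"))
    expect_lte(chord_distance(F3, "a", "b"), 2 * sqrt(2) / pi + 1e-12)
  }
})

test_that("GenePop files round-trip genotypes, populations and missing data", {
  G <- simulate_genotypes(n_demes = 3, n_per_deme = 8, n_loci = 4,
                          n_alleles = 6, F = 0.2, seed = 48)
  G$a1[2, 3] <- NA; G$a2[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(G, path)
  back <- read_genepop(path)
  expect_equal(back$loci, G$loci)
  expect_equal(unname(back$a1), unname(G$a1))
  expect_equal(unname(back$a2), unname(G$a2))
  expect_equal(length(unique(back$pop)), 3L)
  # population sizes preserved
  expect_equal(unname(table(back$pop)[unique(back$pop)]),
               unname(table(G$pop)[unique(G$pop)]))

  # 2-digit coding round-trips too
  path2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(G, path2, digits = 2)
  back2 <- read_genepop(path2)
  expect_equal(unname(back2$a1), unname(G$a1))
})

test_that("long-format genotype tables are read correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pop,locus,allele1,allele2",
               "i1,p1,L1,100,102", "i1,p1,L2,7,7",
               "i2,p1,L1,102,102", "i2,p1,L2,,",
               "i3,p2,L1,100,100", "i3,p2,L2,7,9"), path)
  G <- read_genotypes_long(path)
  expect_equal(dim(G$a1), c(3L, 2L))
  expect_true(is.na(G$a1[2, "L2"]))
  expect_equal(unname(G$a1[1, "L1"]), 100L)
  expect_equal(G$pop, c("p1", "p1", "p2"))
})
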