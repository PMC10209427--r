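# helper: wrap a log-space matrix as a two-group specimen table (mm)
lsm_from_log <- function(X, groups, chars = NULL) {
  chars <- chars %||% paste0("c", seq_len(ncol(X)))
  chars <- c("CD", "UJW", "PreD", "BD", "ED", "SN", "M", "HW")[
    seq_len(ncol(X))]
  tab <- as.data.frame(exp(X))
  names(tab) <- chars
  tab$SL <- 300
  tab$id <- paste0("s", seq_len(nrow(X)))
  tab$species <- groups
  log_shape_matrix(as_specimen_table(tab), characters = chars)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("discriminant direction matches the normalized S^-1 (mu1 - mu2)", {
  # construct data whose sample moments are controlled
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(2 * n), ncol = 2)
  X[seq_len(n / 2), 1] <- X[seq_len(n / 2), 1] + 1.5
  groups <- rep(c("A", "B"), each = n / 2)
  lsm <- lsm_from_log(X, groups)
  res <- lda_direction(lsm)
  expect_equal(sqrt(sum(res$w^2)), 1, tolerance = 1e-12)
  st <- coregonid:::group_stats(lsm)
  oracle <- solve(st$S, st$mu1 - st$mu2)
  oracle <- oracle / sqrt(sum(oracle^2))
  expect_equal(abs(sum(res$w * oracle)), 1, tolerance = 1e-9)
})

test_that("discriminant agrees with MASS::lda and dominates random directions", {
  set.seed(9)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  X[1:15, 1:2] <- X[1:15, 1:2] + 1
  groups <- rep(c("A", "B"), each = 15)
  lsm <- lsm_from_log(X, groups)
  res <- lda_direction(lsm)
  # independent oracle: MASS::lda first discriminant is collinear with w
  fit <- MASS::lda(X, grouping = groups)
  v <- fit$scaling[, 1]
  cosang <- abs(sum(res$w * v)) / sqrt(sum(v^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
  # w maximises the standard distance over random unit directions
  D_w <- standard_distance(lsm, res$w)
  set.seed(10)
  for (i in 1:200) {
    d <- rnorm(p)
    expect_lte(standard_distance(lsm, d), D_w + 1e-9)
  }
})

test_that("too many variables for the sample size is refused", {
  set.seed(4)
  X <- matrix(rnorm(6 * 8), 6, 8)
  lsm <- lsm_from_log(X, rep(c("A", "B"), each = 3))
  expect_error(lda_direction(lsm), "select_subset")
  expect_error(lsm_from_log(matrix(rnorm(4), 4, 1),
                            rep(c("A", "B"), each = 2)))
})

test_that("standard distance reproduces closed forms and the 1-D projection", {
  # group means differing by 1 in column 1, pooled sd 0.5 -> D = 2
  d <- 0.5 / sqrt(2)
  X <- rbind(c(-d, 0), c(d, 0), c(1 - d, 0), c(1 + d, 0)) +
    cbind(0, c(-d, d, -d, d))
  lsm <- lsm_from_log(X, c("A", "A", "B", "B"))
  expect_equal(standard_distance(lsm, c(1, 0)), 2, tolerance = 1e-9)
  # identical group means -> D = 0
  X0 <- rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1))
  lsm0 <- lsm_from_log(X0, c("A", "A", "B", "B"))
  expect_equal(standard_distance(lsm0, c(1, 0)), 0)
  expect_error(standard_distance(lsm0, c(0, 0)), "nonzero")

  # ratio direction equals the univariate computation on log(x_i/x_j)
  set.seed(5)
  X <- matrix(rnorm(24 * 3), 24, 3)
  X[1:12, 1] <- X[1:12, 1] + 0.8
  g <- rep(c("A", "B"), each = 12)
  lsm <- lsm_from_log(X, g)
  r <- X[, 1] - X[, 2]
  m1 <- mean(r[g == "A"]); m2 <- mean(r[g == "B"])
  s2 <- (11 * var(r[g == "A"]) + 11 * var(r[g == "B"])) / 22
  oracle <- abs(m1 - m2) / sqrt(s2)
  expect_equal(standard_distance(lsm, c(1, -1, 0)), oracle,
               tolerance = 1e-12)
})

test_that("best-ratio extraction agrees with exhaustive enumeration", {
  # planted: groups differ only in the log x1 - log x2 contrast
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3, sd = 0.1), n, 3)
  X[1:(n / 2), 1] <- X[1:(n / 2), 1] + 0.5
  X[1:(n / 2), 2] <- X[1:(n / 2), 2] - 0.5
  lsm <- lsm_from_log(X, rep(c("A", "B"), each = n / 2))
  best <- extract_best_ratios(lsm, k = 2)
  expect_setequal(c(best[[1]]$numerator, best[[1]]$denominator),
                  c("CD", "UJW"))

  # exhaustive oracle on seeded data, p = 6: identical ranking
  set.seed(12)
  X <- matrix(rnorm(24 * 6), 24, 6)
  X[1:12, ] <- X[1:12, ] + matrix(rnorm(6, sd = 0.6), 12, 6, byrow = TRUE)
  lsm <- lsm_from_log(X, rep(c("A", "B"), each = 12))
  cands <- extract_best_ratios(lsm, k = 15)
  chars <- colnames(lsm$X)
  oracle <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    dir <- numeric(6); dir[i] <- 1; dir[j] <- -1
    oracle <- rbind(oracle,
                    data.frame(i = chars[i], j = chars[j],
                               D = standard_distance(lsm, dir)))
  }
  oracle <- oracle[order(-oracle$D), ]
  got_D <- vapply(cands, function(cd) cd$D, numeric(1))
  expect_equal(got_D, oracle$D, tolerance = 1e-9)
  for (q in seq_along(cands)) {
    expect_setequal(c(cands[[q]]$numerator, cands[[q]]$denominator),
                    c(oracle$i[q], oracle$j[q]))
  }
  # orientation: first group has the larger mean ratio
  for (cd in cands) {
    g1 <- cd$values[lsm$groups == "A"]; g2 <- cd$values[lsm$groups == "B"]
    expect_gte(mean(log(g1)), mean(log(g2)))
  }
})

test_that("delta measures the size content of the discriminant", {
  p <- 7
  u <- rep(1, p) / sqrt(p)
  mk <- function(w) structure(list(w = w / sqrt(sum(w^2)), u = u),
                              class = "discriminant_result")
  # pure shape: contrast orthogonal to u
  w_shape <- c(1, -1, rep(0, p - 2))
  expect_equal(delta_allometry(mk(w_shape)), 0, tolerance = 1e-12)
  # pure size
  expect_equal(delta_allometry(mk(rep(1, p))), 1, tolerance = 1e-12)
  # random unit w: |sum(w)| / sqrt(p) oracle
  set.seed(8)
  for (i in 1:20) {
    w <- rnorm(p); w <- w / sqrt(sum(w^2))
    expect_equal(delta_allometry(mk(w)), abs(sum(w)) / sqrt(p),
                 tolerance = 1e-12)
    expect_gte(delta_allometry(mk(w)), 0)
    expect_lte(delta_allometry(mk(w)), 1)
  }
})

test_that("subset selection keeps the top univariate discriminators", {
  set.seed(13)
  X <- matrix(rnorm(20 * 8), 20, 8)
  shifts <- seq(0, 1.4, length.out = 8)
  X[1:10, ] <- X[1:10, ] + matrix(shifts, 10, 8, byrow = TRUE)
  lsm <- lsm_from_log(X, rep(c("A", "B"), each = 10))
  keep <- select_subset(lsm, max_vars = 4)
  st <- coregonid:::group_stats(lsm)
  uni <- abs(st$mu1 - st$mu2) / sqrt(diag(st$S))
  oracle <- colnames(lsm$X)[order(uni, decreasing = TRUE)[1:4]]
  expect_setequal(keep, oracle)
  # explicit preset is used verbatim
  expect_equal(select_subset(lsm, 4, explicit = c("CD", "PreD")),
               c("CD", "PreD"))
  expect_error(select_subset(lsm, 4, explicit = "XYZ"), "unknown")
  # arithmetic of the variables-vs-individuals rule (p = 50 -> keep 18)
  set.seed(14)
  big <- matrix(rnorm(20 * 50), 20, 50)
  tab <- as.data.frame(exp(big))
  names(tab) <- character_registry()$abbreviation[1:50]
  tab$id <- paste0("s", 1:20); tab$species <- rep(c("A", "B"), each = 10)
  tab$SL <- tab$SL * 100
  lsm_big <- log_shape_matrix(as_specimen_table(tab))
  expect_length(select_subset(lsm_big, max_vars = 18), 18)
})

test_that("species-pair comparison recovers a planted diagnostic ratio", {
  tab <- demo_specimens(seed = 21)
  rep1 <- compare_species_pair(tab)
  planted <- attr(planted_ratio_spec(), "planted")
  expect_setequal(c(rep1$candidates[[1]]$numerator,
                    rep1$candidates[[1]]$denominator), planted)
  expect_true(rep1$candidates[[1]]$overlap$asterisk)
  # ranges are disjoint for the planted contrast at this effect size
  expect_true(rep1$candidates[[1]]$range1[1] > rep1$candidates[[1]]$range2[2] ||
                rep1$candidates[[1]]$range2[1] > rep1$candidates[[1]]$range1[2])
  expect_false(is.na(rep1$delta))
})

test_that("comparing a group against itself yields zero distances", {
  tab <- demo_specimens(seed = 22, n = 10)
  half <- tab[tab$species == "A", ]
  half$species <- rep(c("A", "B"), each = 5)
  half$id <- paste0("s", 1:10)
  # same distribution; now literally duplicate specimens across groups
  dup <- half
  dup[6:10, setdiff(names(dup), c("id", "species"))] <-
    dup[1:5, setdiff(names(dup), c("id", "species"))]
  class(dup) <- c("specimen_table", "data.frame")
  expect_warning(repid <- compare_species_pair(dup), "zero")
  expect_equal(repid$candidates[[1]]$D, 0)
  expect_true(repid$delta_undefined)
  expect_false(repid$candidates[[1]]$overlap$asterisk)
})

test_that("comparison reports round-trip through JSON", {
  tab <- demo_specimens(seed = 23, n = 8)
  rep1 <- compare_species_pair(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_report(rep1, path)
  back <- read_comparison_report(path)
  expect_equal(back$species, rep1$species)
  expect_equal(back$subset, rep1$subset)
  expect_equal(back$delta, rep1$delta, tolerance = 1e-12)
  expect_equal(length(back$candidates), length(rep1$candidates))
  expect_equal(back$candidates[[1]]$D, rep1$candidates[[1]]$D,
               tolerance = 1e-12)
  expect_equal(unname(back$candidates[[1]]$values),
               unname(rep1$candidates[[1]]$values), tolerance = 1e-12)
  expect_equal(back$candidates[[1]]$overlap$asterisk,
               rep1$candidates[[1]]$overlap$asterisk)
})

test_that("ratio analysis is invariant to size and unit changes", {
  tab <- demo_specimens(seed = 24, n = 10)
  chars <- coregonid:::character_columns(tab)
  lsm <- log_shape_matrix(tab)
  base <- extract_best_ratios(lsm, k = 5)
  # specimen-specific size change: multiply every character of a specimen
  set.seed(25)
  scaled <- tab
  fac <- exp(runif(nrow(tab), -0.3, 0.3))
  for (ch in chars) scaled[[ch]] <- scaled[[ch]] * fac
  class(scaled) <- class(tab)
  got <- extract_best_ratios(log_shape_matrix(scaled), k = 5)
  for (q in seq_along(base)) {
    expect_equal(got[[q]]$D, base[[q]]$D, tolerance = 1e-9)
    expect_equal(got[[q]]$numerator, base[[q]]$numerator)
    expect_equal(unname(got[[q]]$values), unname(base[[q]]$values),
                 tolerance = 1e-9)
  }
  # global unit change of one character: D values and ranking unchanged
  units <- tab
  units$CD <- units$CD * 10
  class(units) <- class(tab)
  got2 <- extract_best_ratios(log_shape_matrix(units), k = 5)
  for (q in seq_along(base)) {
    expect_equal(got2[[q]]$D, base[[q]]$D, tolerance = 1e-9)
    expect_equal(got2[[q]]$numerator, base[[q]]$numerator)
  }
})
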