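# Cluster-number inference: an EM finite-mixture surrogate generating
# LnP(D)-style log-likelihood traces, and the Evanno delta-K criterion.
#
# The mixture model assigns each diploid individual to one of K clusters,
# each cluster holding its own per-locus allele frequencies; the genotype
# likelihood assumes Hardy-Weinberg proportions within a cluster (the
# no-admixture model). EM with soft assignments maximises the observed-data
# likelihood; the delta-K calculator is independent of how a trace was
# produced and also accepts externally computed LnP(D) files.

# integer-recoded genotype data: per locus, alleles mapped to 1..A_l
recode_genotypes <- function(G) {
  L <- length(G$loci)
  idx1 <- idx2 <- matrix(NA_integer_, nrow(G$a1), L)
  levels_l <- vector("list", L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(G$a1[, l], G$a2[, l])))
    al <- al[!is.na(al)]
    levels_l[[l]] <- al
    idx1[, l] <- match(G$a1[, l], al)
    idx2[, l] <- match(G$a2[, l], al)
  }
  list(idx1 = idx1, idx2 = idx2, levels = levels_l, L = L, n = nrow(G$a1))
}

# log genotype likelihood of every individual under every cluster
# freqs: list over loci of (A_l x K) frequency matrices
loglik_matrix <- function(rec, freqs, K) {
  n <- rec$n
  ll <- matrix(0, n, K)
  log2_ <- log(2)
  for (l in seq_len(rec$L)) {
    i1 <- rec$idx1[, l]; i2 <- rec$idx2[, l]
    ok <- !is.na(i1)
    if (!any(ok)) next
    lp <- log(freqs[[l]])
    het <- (i1[ok] != i2[ok]) * log2_
    ll[ok, ] <- ll[ok, ] + lp[i1[ok], , drop = FALSE] +
      lp[i2[ok], , drop = FALSE] + het
  }
  ll
}

# One EM run. Initialisation follows the short-run ("em-EM") strategy:
# `n_bursts` random starts are advanced for `burst_iter` iterations and the
# best is continued to convergence, which makes single runs reliably reach
# a good optimum at and below the true cluster number while preserving
# across-run variability above it.
em_once <- function(rec, K, max_iter, tol, n_bursts = 5, burst_iter = 20) {
  if (K == 1L) {
    return(em_core(rec, K, matrix(1, rec$n, 1), max_iter, tol))
  }
  best <- NULL
  for (s in seq_len(n_bursts)) {
    resp0 <- matrix(stats::rexp(rec$n * K), rec$n, K)
    resp0 <- resp0 / rowSums(resp0)
    cand <- em_core(rec, K, resp0, burst_iter, tol = 0)
    if (is.null(best) || cand$logL > best$logL) best <- cand
  }
  out <- em_core(rec, K, best$memberships, max_iter, tol)
  out$trace <- c(best$trace, out$trace)
  out
}

em_core <- function(rec, K, resp, max_iter, tol) {
  n <- rec$n
  loglik <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # M-step
    w <- colMeans(resp)
    freqs <- vector("list", rec$L)
    for (l in seq_len(rec$L)) {
      A <- length(rec$levels[[l]])
      cnt <- matrix(0, A, K)
      i1 <- rec$idx1[, l]; i2 <- rec$idx2[, l]
      ok <- which(!is.na(i1))
      for (k in seq_len(K)) {
        rk <- resp[ok, k]
        cnt[, k] <- rowsum_count(i1[ok], rk, A) + rowsum_count(i2[ok], rk, A)
      }
      tot <- colSums(cnt)
      tot[tot == 0] <- 1
      freqs[[l]] <- sweep(cnt, 2, tot, "/")
    }
    # E-step
    ll <- loglik_matrix(rec, freqs, K)
    lw <- log(w)
    lw[w == 0] <- -Inf
    lj <- sweep(ll, 2, lw, "+")
    mx <- apply(lj, 1, max)
    lse <- mx + log(rowSums(exp(lj - mx)))
    new_loglik <- sum(lse)
    resp <- exp(lj - lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  list(logL = loglik, memberships = resp, weights = w, freqs = freqs,
       trace = trace, iterations = length(trace),
       loglik_by_individual = lse)
}

# weighted allele counts: sum of weights w over positions where idx == a
rowsum_count <- function(idx, w, A) {
  out <- numeric(A)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit a K-cluster allele-frequency mixture by EM
#'
#' @param G a [genotype_matrix()].
#' @param K number of clusters (>= 1, at most the number of individuals).
#' @param n_restarts independent random restarts; the best converged
#'   log-likelihood is returned (default 10).
#' @param max_iter EM iteration cap per restart (default 300).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param seed optional RNG seed.
#' @param n_bursts,burst_iter short-run initialisation: each restart
#'   advances `n_bursts` random soft assignments for `burst_iter`
#'   iterations and continues the best to convergence.
#' @return list with `logL` (best restart), `memberships` (n x K posterior
#'   matrix, rows summing to 1), `weights`, `freqs` (per-locus allele
#'   frequency matrices), `trace` (log-likelihood per iteration of the best
#'   restart), `K`.
#' @export
fit_mixture_em <- function(G, K, n_restarts = 10, max_iter = 300,
                           tol = 1e-6, seed = NULL, n_bursts = 3,
                           burst_iter = 20) {
  if (K < 1L) stop_("K must be >= 1")
  if (K > nrow(G$a1)) stop_("K exceeds the number of individuals")
  rec <- recode_genotypes(G)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- em_once(rec, K, max_iter = max_iter, tol = tol,
                     n_bursts = n_bursts, burst_iter = burst_iter)
      if (is.null(best) || fit$logL > best$logL) best <- fit
    }
    best$K <- K
    best
  })
}

#' Build a log-likelihood trace across K values
#'
#' Runs the EM mixture independently `n_runs` times for every K in
#' `K_range`, recording one converged log-likelihood per run. The
#' resulting trace plays the role of the LnP(D) values of repeated
#' Bayesian clustering runs and feeds [evanno_deltaK()].
#'
#' With `resample = TRUE` (the default) each run reports the converged
#' model's log-likelihood summed over an individual bootstrap resample
#' instead of the exact maximised value. This mimics the run-to-run
#' stochasticity of MCMC estimates of LnP(D): a deterministic optimiser
#' converging to the same optimum in every run would collapse the
#' across-run standard deviation that the Evanno criterion divides by,
#' leaving the criterion undefined exactly where the fit is most reliable.
#' The bootstrap noise floor is comparable across K, so the curvature of
#' the likelihood profile — not optimiser luck — drives the selection.
#'
#' @param G a [genotype_matrix()].
#' @param K_range integer vector of consecutive K values (>= 3 values).
#' @param n_runs runs per K (default 10).
#' @param max_iter,tol EM controls per run.
#' @param seed optional RNG seed (each run derives its own child seed).
#' @param n_restarts,n_bursts,burst_iter per-run optimisation protocol,
#'   passed to [fit_mixture_em()].
#' @param resample report bootstrap-resampled log-likelihoods (default
#'   TRUE); set FALSE to record the exact converged values.
#' @return a `likelihood_trace` data.frame with columns `K`, `run`, `logL`.
#' @export
lnp_trace <- function(G, K_range, n_runs = 10, max_iter = 300, tol = 1e-6,
                      seed = NULL, n_restarts = 1, n_bursts = 3,
                      burst_iter = 20, resample = TRUE) {
  K_range <- sort(unique(as.integer(K_range)))
  rows <- list()
  for (K in K_range) {
    for (r in seq_len(n_runs)) {
      s <- if (is.null(seed)) NULL else child_seed(seed, K * 1000 + r)
      fit <- fit_mixture_em(G, K, n_restarts = n_restarts,
                            max_iter = max_iter, tol = tol, seed = s,
                            n_bursts = n_bursts, burst_iter = burst_iter)
      logL <- fit$logL
      if (resample) {
        lli <- fit$loglik_by_individual
        logL <- with_seed(if (is.null(s)) NULL else child_seed(s, 77L),
                          sum(lli[sample.int(length(lli), replace = TRUE)]))
      }
      rows[[length(rows) + 1L]] <- data.frame(K = K, run = r, logL = logL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("likelihood_trace", "data.frame")
  out
}

#' Read / write a log-likelihood trace
#'
#' Delimited text with columns `K`, `run`, `logL` (tab or comma).
#' @param path file path.
#' @export
read_lnp_trace <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE)
  if (!all(c("K", "run", "logL") %in% names(df))) {
    stop_("trace file needs columns K, run, logL")
  }
  df <- df[, c("K", "run", "logL")]
  class(df) <- c("likelihood_trace", "data.frame")
  df
}

#' @rdname read_lnp_trace
#' @param trace a `likelihood_trace`.
#' @export
write_lnp_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Evanno delta-K criterion
#'
#' For every interior K of the trace, the per-run second difference
#' `L''_r(K) = L_r(K+1) - 2 L_r(K) + L_r(K-1)` (runs matched by run index)
#' is averaged in absolute value and divided by the across-run standard
#' deviation of `L(K)`:
#' `deltaK(K) = mean_r |L''_r(K)| / sd_r(L_r(K))`.
#' The selected K is the interior K maximising deltaK. An interior K with
#' zero across-run standard deviation is flagged and excluded from the
#' argmax with a warning; an exactly flat deltaK profile is flagged as a
#' tie.
#'
#' @param trace a `likelihood_trace` (>= 3 consecutive K values, >= 2 runs
#'   per K, equal run counts).
#' @return a `deltaK_result`: data.frame `table` with per-K mean, sd,
#'   mean |L''| and deltaK, plus `selected_K`, `tie`, `excluded_K`.
#' @export
evanno_deltaK <- function(trace) {
  Ks <- sort(unique(trace$K))
  if (length(Ks) < 3L || any(diff(Ks) != 1L)) {
    stop_("need at least 3 consecutive K values")
  }
  runs <- sort(unique(trace$run))
  if (length(runs) < 2L) stop_("need at least 2 runs per K")
  L <- matrix(NA_real_, length(runs), length(Ks),
              dimnames = list(runs, Ks))
  L[cbind(match(trace$run, runs), match(trace$K, Ks))] <- trace$logL
  if (anyNA(L)) stop_("every K needs the same set of runs")
  meanL <- colMeans(L)
  sdL <- apply(L, 2, stats::sd)
  interior <- seq(2, length(Ks) - 1L)
  mean_abs_L2 <- rep(NA_real_, length(Ks))
  deltaK <- rep(NA_real_, length(Ks))
  for (k in interior) {
    L2 <- L[, k + 1L] - 2 * L[, k] + L[, k - 1L]
    mean_abs_L2[k] <- mean(abs(L2))
    deltaK[k] <- if (sdL[k] > 0) mean_abs_L2[k] / sdL[k] else NA_real_
  }
  excluded <- Ks[interior][sdL[interior] == 0]
  if (length(excluded)) {
    warn_("zero across-run sd at K = %s; excluded from selection",
          paste(excluded, collapse = ", "))
  }
  cand <- interior[sdL[interior] > 0]
  if (!length(cand)) stop_("no interior K with positive across-run sd")
  dk <- deltaK[cand]
  tie <- diff(range(dk)) <= 1e-9 * max(1, max(abs(dk)))
  if (tie && length(cand) > 1L) {
    warn_("deltaK profile is flat: selection is a tie")
  }
  selected <- Ks[cand[which.max(dk)]]
  out <- list(table = data.frame(K = Ks, mean_logL = meanL, sd_logL = sdL,
                                 mean_abs_L2 = mean_abs_L2,
                                 deltaK = deltaK),
              selected_K = selected, tie = tie, excluded_K = excluded)
  class(out) <- "deltaK_result"
  out
}

#' @export
print.deltaK_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected K = %d%s\n", x$selected_K,
              if (x$tie) " (tie)" else ""))
  invisible(x)
}

#' End-to-end cluster-number selection
#'
#' Convenience wrapper: builds an LnP-style trace with the EM surrogate for
#' `K_range` and applies the Evanno criterion.
#'
#' @inheritParams lnp_trace
#' @return a `deltaK_result` (with the trace attached as `"trace"`).
#' @export
select_K <- function(G, K_range = 1:7, n_runs = 10, max_iter = 300,
                     tol = 1e-6, seed = NULL, n_restarts = 1,
                     n_bursts = 3, burst_iter = 20, resample = TRUE) {
  trace <- lnp_trace(G, K_range, n_runs = n_runs, max_iter = max_iter,
                     tol = tol, seed = seed, n_restarts = n_restarts,
                     n_bursts = n_bursts, burst_iter = burst_iter,
                     resample = resample)
  res <- evanno_deltaK(trace)
  attr(res, "trace") <- trace
  res
}
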