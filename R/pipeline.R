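# Pipeline surface: one entry point dispatching the analysis workflows,
# driven by a configuration list (or YAML file). Every run writes its
# artifacts plus a JSON log echoing versions, seeds and parameters. A thin
# command-line wrapper over this function ships in inst/cli/coregonid.R.

#' Run an analysis pipeline command
#'
#' Commands:
#' * `summarize`: specimen table -> species summary (TSV + JSON).
#' * `compare`: specimen table + two species -> comparison report (JSON).
#' * `diagnose`: specimen table + two species -> differential diagnosis
#'   (JSON + markdown).
#' * `key`: specimen table + key file -> per-specimen classifications (TSV).
#' * `popgen`: GenePop file -> heterozygosity/HWE/pairwise theta tables and
#'   an NJ tree with bootstrap supports (TSV + newick).
#' * `deltak`: GenePop file (or LnP trace) -> Evanno table and selected K.
#' * `sediment`: core scheme + find depths -> dated finds (JSON).
#' * `simulate`: write synthetic specimen/genotype tables.
#'
#' @param command one of the commands above.
#' @param config a named list of parameters (see the pipeline vignette) or
#'   the path to a YAML file holding one. Common fields: `input`,
#'   `out_dir`, `seed`, plus command-specific blocks (`species`, `n_perm`,
#'   `n_boot`, `K_range`, `n_runs`, ...).
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(command = c("summarize", "compare", "diagnose",
                                     "key", "popgen", "deltak", "sediment",
                                     "simulate"),
                         config) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop_("input file not found: %s", config$input)
  }
  seed <- config$seed
  artifacts <- switch(command,
    summarize = pipe_summarize(config, out_dir),
    compare   = pipe_compare(config, out_dir),
    diagnose  = pipe_diagnose(config, out_dir),
    key       = pipe_key(config, out_dir),
    popgen    = pipe_popgen(config, out_dir, seed),
    deltak    = pipe_deltak(config, out_dir, seed),
    sediment  = pipe_sediment(config, out_dir),
    simulate  = pipe_simulate(config, out_dir, seed))
  log <- list(command = command,
              package_version = as.character(utils::packageVersion("coregonid")),
              r_version = R.version.string,
              seed = seed, config = config,
              artifacts = artifacts,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  log_path <- file.path(out_dir, paste0(command, "_log.json"))
  write_json_report(log, log_path)
  invisible(c(artifacts, log = log_path))
}

pair_subset <- function(config) {
  specimens <- read_specimens(config$input)
  if (!is.null(config$species)) {
    specimens <- specimens[specimens$species %in% config$species, ,
                           drop = FALSE]
    class(specimens) <- c("specimen_table", "data.frame")
  }
  specimens
}

pipe_summarize <- function(config, out_dir) {
  specimens <- pair_subset(config)
  summ <- species_summary(specimens)
  tsv <- file.path(out_dir, "species_summary.tsv")
  utils::write.table(summ, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  json <- file.path(out_dir, "species_summary.json")
  write_json_report(summ, json)
  c(tsv = tsv, json = json)
}

pipe_compare <- function(config, out_dir) {
  specimens <- pair_subset(config)
  report <- compare_species_pair(specimens,
                                 characters = config$characters,
                                 k = config$k %||% 2)
  json <- file.path(out_dir, "comparison_report.json")
  write_comparison_report(report, json)
  # Table-10-style delimited row(s)
  rows <- do.call(rbind, lapply(report$candidates, function(cd) {
    data.frame(species1 = report$species[1], species2 = report$species[2],
               ratio = paste0(cd$numerator, "/", cd$denominator),
               asterisk = isTRUE(cd$overlap$asterisk),
               range1 = sprintf("%.4g-%.4g", cd$range1[1], cd$range1[2]),
               range2 = sprintf("%.4g-%.4g", cd$range2[1], cd$range2[2]),
               standard_distance = cd$D, delta = report$delta)
  }))
  tsv <- file.path(out_dir, "comparison_table.tsv")
  utils::write.table(rows, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  c(json = json, tsv = tsv)
}

pipe_diagnose <- function(config, out_dir) {
  specimens <- pair_subset(config)
  report <- compare_species_pair(specimens,
                                 characters = config$characters,
                                 k = config$k %||% 2)
  diag <- build_diagnosis(specimens, report)
  json <- file.path(out_dir, "diagnosis.json")
  write_diagnosis(diag, json)
  md <- file.path(out_dir, "diagnosis.md")
  writeLines(format_diagnosis(diag), md)
  c(json = json, md = md)
}

pipe_key <- function(config, out_dir) {
  specimens <- read_specimens(config$input)
  key <- read_key(config$key)
  quantities <- key_required_quantities(key)
  res <- lapply(seq_len(nrow(specimens)), function(i) {
    vals <- key_quantities(specimens[i, , drop = FALSE], quantities)
    cls <- classify_with_key(key, vals)
    data.frame(id = specimens$id[i], species = specimens$species[i],
               classified = as.character(cls),
               couplet = attr(cls, "couplet") %||% NA)
  })
  res <- do.call(rbind, res)
  tsv <- file.path(out_dir, "key_classification.tsv")
  utils::write.table(res, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  c(tsv = tsv)
}

pipe_popgen <- function(config, out_dir, seed) {
  G <- read_genepop(config$input)
  n_perm <- config$n_perm %||% 1000
  n_boot <- config$n_boot %||% 1000
  pops <- populations(G)
  hwe <- do.call(rbind, lapply(pops, function(p) {
    do.call(rbind, lapply(G$loci, function(l) {
      res <- tryCatch(hwe_test(G, p, l, n_perm = n_perm,
                               seed = child_seed(seed %||% 1, 1)),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(pop = p, locus = l, statistic = res$statistic,
                 p_value = res$p_value, Ho = res$Ho, He = res$He)
    }))
  }))
  hwe_tsv <- file.path(out_dir, "hwe.tsv")
  utils::write.table(hwe, hwe_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fst <- do.call(rbind, lapply(utils::combn(pops, 2, simplify = FALSE),
    function(pr) {
      res <- pairwise_fst(G, pr[1], pr[2], n_perm = n_perm,
                          seed = child_seed(seed %||% 1, 2))
      data.frame(popA = pr[1], popB = pr[2], theta = res$theta,
                 p_value = res$p_value)
    }))
  fst_tsv <- file.path(out_dir, "pairwise_fst.tsv")
  utils::write.table(fst, fst_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  arts <- c(hwe = hwe_tsv, fst = fst_tsv)
  if (length(pops) >= 3L && length(G$loci) >= 2L) {
    tree <- bootstrap_support(G, n_boot = n_boot,
                              seed = child_seed(seed %||% 1, 3))
    nwk <- file.path(out_dir, "nj_tree.nwk")
    write_tree(tree, nwk)
    arts <- c(arts, tree = nwk)
  }
  arts
}

pipe_deltak <- function(config, out_dir, seed) {
  if (!is.null(config$trace)) {
    trace <- read_lnp_trace(config$trace)
  } else {
    G <- read_genepop(config$input)
    trace <- lnp_trace(G, K_range = config$K_range %||% 1:7,
                       n_runs = config$n_runs %||% 10,
                       seed = seed %||% 1)
  }
  res <- evanno_deltaK(trace)
  trace_tsv <- file.path(out_dir, "lnp_trace.tsv")
  write_lnp_trace(trace, trace_tsv)
  json <- file.path(out_dir, "deltaK.json")
  write_json_report(list(table = res$table, selected_K = res$selected_K,
                         tie = res$tie, excluded_K = res$excluded_K), json)
  c(trace = trace_tsv, json = json)
}

pipe_sediment <- function(config, out_dir) {
  scheme <- core_scheme(config$slice_thickness_cm, config$net_rate_cm_per_yr,
                        config$reference_year)
  finds <- lapply(config$finds, function(f) {
    unclass(date_find(scheme, f$top_cm, f$bottom_cm, f$item %||% ""))
  })
  json <- file.path(out_dir, "chronology.json")
  write_json_report(list(slice_duration_yr = slice_duration(scheme),
                         finds = finds), json)
  c(json = json)
}

pipe_simulate <- function(config, out_dir, seed) {
  what <- config$what %||% "morpho"
  if (what == "morpho") {
    spec <- planted_ratio_spec(
      shift = config$shift %||% 0.2,
      sigma = config$sigma %||% 0.03,
      n = config$n %||% 20)
    tab <- simulate_morpho(spec, seed = seed %||% 1)
    path <- file.path(out_dir, "synthetic_specimens.csv")
    write_specimens(tab, path)
    c(specimens = path)
  } else if (what == "genotypes") {
    G <- simulate_genotypes(n_demes = config$n_demes %||% 4,
                            n_per_deme = config$n_per_deme %||% 60,
                            n_loci = config$n_loci %||% 10,
                            n_alleles = config$n_alleles %||% 8,
                            F = config$F %||% 0.15,
                            seed = seed %||% 1)
    path <- file.path(out_dir, "synthetic_genotypes.gen")
    write_genepop(G, path)
    c(genotypes = path)
  } else {
    stop_("unknown simulation target '%s'", what)
  }
}
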