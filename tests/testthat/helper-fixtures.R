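# Shared fixtures, built in code.

extdata <- function(...) {
  system.file("extdata", ..., package = "coregonid", mustWork = TRUE)
}

# small two-species specimen table with a known diagnostic structure
# (generator defaults: diagnostic-grade planted CD/UJW contrast)
demo_specimens <- function(seed = 101, n = 20) {
  simulate_morpho(planted_ratio_spec(n = n), seed = seed)
}

# tiny hand-written genotype matrix: 2 populations, 2 loci
toy_genotypes <- function() {
  #        L1        L2
  a1 <- rbind(c(1, 1), c(1, 2), c(2, 2),   # popA
              c(2, 1), c(2, 2), c(2, NA))  # popB
  a2 <- rbind(c(1, 1), c(2, 2), c(2, 2),
              c(2, 2), c(2, 2), c(2, NA))
  genotype_matrix(a1, a2, rep(c("popA", "popB"), each = 3),
                  loci = c("L1", "L2"))
}

# holotype fixture: printed percent values -> one-row mm specimen tables
holotype_mm <- function() {
  df <- utils::read.csv(extdata("holotype_percentages.csv"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mm <- data.frame(id = r$species, species = r$species,
                     SL = r$SL_mm, HL = r$HL_mm,
                     totalGR = r$totalGR)
    for (col in names(df)) {
      if (grepl("_pctSL$", col)) {
        mm[[sub("_pctSL$", "", col)]] <- r[[col]] * r$SL_mm / 100
      } else if (grepl("_pctHL$", col)) {
        mm[[sub("_pctHL$", "", col)]] <- r[[col]] * r$HL_mm / 100
      }
    }
    as_specimen_table(mm)
  })
  names(out) <- df$species
  out
}
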