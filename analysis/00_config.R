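# Shared settings for the analysis workflow. Every script sources this
# file, so one seed and one set of cohort dimensions govern the whole run.

library(tropigwas)

SEED <- 2025
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

N_SNPS <- 6000
N_DIVERGENT <- 150
DIVERGENCE <- 0.2
N_INDIVIDUALS <- 1000
N_SIRES <- 25

# ten traits named after the adaptation phenotypes the package targets,
# heritabilities spanning the low-to-moderate range typical of them
H2 <- c(FT = 0.44, TEMP = 0.22, EPG = 0.39, SHEATH = 0.51, COLOUR = 0.54,
        FLY = 0.19, TICK = 0.09, COAT = 0.41, COND = 0.45, YWT = 0.38)

# large-effect QTL on chromosome 1 for the sheath-score analogue, plus a
# shared pleiotropic locus for body condition and weight, and an ancestry
# slope with opposite signs around the 30% split for the parasite trait
QTL <- data.frame(snp = c(400L, 400L, 3600L),
                  trait = c("SHEATH", "COND", "YWT"),
                  pct_vg = c(40, 8, 8),
                  sign = c(1, 1, -1))
ANCESTRY_SLOPE <- list(EPG = list(below = -8, above = 5, threshold = 0.30),
                       SHEATH = -0.5, YWT = 1.0)

sim_config <- function() {
  simulation_config(
    n_individuals = N_INDIVIDUALS, n_sires = N_SIRES, h2_targets = H2,
    qtl_spec = QTL, ancestry_slope = ANCESTRY_SLOPE, seed = SEED)
}

make_panels <- function() {
  simulate_ancestral_panels(N_SNPS, DIVERGENCE, n_divergent = N_DIVERGENT,
                            seed = SEED)
}
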