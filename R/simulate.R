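#' Default 26-kinase panel
#'
#' Kinase labels used by the synthetic screen generator: a panel spanning
#' the TK, CMGC, CAMK, CK1 and AGC families with the three follow-up
#' targets (MPS1, Aurora A, Aurora B) first.
#'
#' @format character vector of 26 kinase labels.
#' @export
KINASE_PANEL_26 <- c(
  "MPS1", "AURKA", "AURKB", "ABL1", "AKT2", "CHK1", "CHK2", "CK1D",
  "CDK2", "EGFR", "ERK2", "GSK3B", "IGF1R", "JAK2", "LCK", "MET",
  "P38A", "PKA", "PKCZ", "PKD2", "PLK4", "ROCK2", "RSK1", "SRC",
  "SYK", "VEGFR2"
)

# run code with a private RNG stream; the caller's RNG state is restored
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic panel screen. The defaults emulate the
#' study conditions of a fragment-library campaign: 26 kinases, a
#' 100 uM single-point screen, assays run at ATP = Km (so IC50 = 2 Ki),
#' additive Gaussian readout noise (sd 5% single-point, 2% on curves),
#' 8-point half-log dilutions from 100 uM in triplicate, and a compound
#' library mixing promiscuous, selective and inactive archetypes
#' (fractions 0.25/0.50/0.25).
#'
#' @param seed integer seed; mandatory, drives all randomness.
#' @param n_compounds number of library compounds.
#' @param n_kinases panel size; up to 26 uses [KINASE_PANEL_26] labels.
#' @param screen_conc single-point screening concentration, uM.
#' @param atp_over_km per-kinase ATP/Km ratio, scalar or length
#'   `n_kinases` (0.1-10 is the realistic assay range).
#' @param km_atp Km for ATP in uM (sets the absolute ATP scale).
#' @param noise_sd_single_point Gaussian noise sd on single-point %.
#' @param noise_sd_curve Gaussian noise sd on curve responses, %.
#' @param top_conc top dose-response concentration, uM.
#' @param dilution_factor fold between consecutive doses (half-log).
#' @param n_dilutions points per curve.
#' @param n_replicates replicates per concentration.
#' @param archetype_mix named fractions for promiscuous/selective/inactive
#'   compounds; must sum to 1.
#' @param dropout per-cell probability that a panel measurement is missing.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_compounds = 24,
                       n_kinases = 26,
                       screen_conc = 100,
                       atp_over_km = 1,
                       km_atp = 20,
                       noise_sd_single_point = 5,
                       noise_sd_curve = 2,
                       top_conc = 100,
                       dilution_factor = sqrt(10),
                       n_dilutions = 8,
                       n_replicates = 3,
                       archetype_mix = c(promiscuous = 0.25,
                                         selective = 0.50,
                                         inactive = 0.25),
                       dropout = 0.02) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    fs_stop("a scalar integer seed is mandatory", "fragscreen_input_error")
  }
  if (n_compounds < 1) fs_stop("n_compounds must be >= 1", "fragscreen_input_error")
  nm <- c("promiscuous", "selective", "inactive")
  if (!all(nm %in% names(archetype_mix)) ||
      abs(sum(archetype_mix) - 1) > 1e-8 || any(archetype_mix < 0)) {
    fs_stop("archetype_mix must be non-negative fractions for promiscuous/selective/inactive summing to 1",
            "fragscreen_input_error")
  }
  if (any(c(noise_sd_single_point, noise_sd_curve) < 0)) {
    fs_stop("noise sds must be >= 0", "fragscreen_input_error")
  }
  structure(list(
    seed = as.integer(seed), n_compounds = as.integer(n_compounds),
    n_kinases = as.integer(n_kinases), screen_conc = screen_conc,
    atp_over_km = rep_len(atp_over_km, n_kinases), km_atp = km_atp,
    noise_sd_single_point = noise_sd_single_point,
    noise_sd_curve = noise_sd_curve, top_conc = top_conc,
    dilution_factor = dilution_factor, n_dilutions = as.integer(n_dilutions),
    n_replicates = as.integer(n_replicates),
    archetype_mix = archetype_mix[nm], dropout = dropout
  ), class = "sim_config")
}

# deterministic archetype allocation: largest-remainder apportionment
allocate_archetypes <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Sample a ground-truth affinity matrix
#'
#' Draws true pKi values per compound x kinase cell by archetype:
#' promiscuous compounds are uniformly modestly potent
#' (pKi ~ N(5.0, 0.5) across all kinases), selective compounds sit on a
#' weak baseline (pKi ~ N(3.0, 0.3)) with 1-3 randomly chosen target
#' kinases boosted by +1.5 pKi units, and inactive compounds draw
#' pKi ~ N(2.5, 0.3). Hill slopes are 1. Per-kinase assay conditions
#' ([ATP], Km) come from the config's ATP/Km ratios.
#'
#' @param config a [sim_config()].
#' @return list of class `ground_truth`: `true_pki` (compound x kinase
#'   matrix), `true_hill`, `archetype` (named by compound),
#'   `assay_conditions` (data.frame `kinase_id, atp_conc_uM, km_atp_uM`),
#'   `config`. Same seed, same output, bit for bit.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nC <- config$n_compounds; nK <- config$n_kinases
  kin <- if (nK <= length(KINASE_PANEL_26)) KINASE_PANEL_26[seq_len(nK)] else
    c(KINASE_PANEL_26, sprintf("KIN%02d", seq_len(nK - length(KINASE_PANEL_26)) +
                                 length(KINASE_PANEL_26)))
  cmp <- sprintf("C%02d", seq_len(nC))
  arch <- allocate_archetypes(nC, config$archetype_mix)
  names(arch) <- cmp
  pki <- with_rng(config$seed, {
    m <- matrix(NA_real_, nC, nK, dimnames = list(cmp, kin))
    for (i in seq_len(nC)) {
      m[i, ] <- switch(arch[i],
        promiscuous = stats::rnorm(nK, 5.0, 0.5),
        selective = {
          base <- stats::rnorm(nK, 3.0, 0.3)
          targets <- sample.int(nK, sample(1:3, 1))
          base[targets] <- base[targets] + 1.5
          base
        },
        inactive = stats::rnorm(nK, 2.5, 0.3)
      )
    }
    m
  })
  structure(list(
    true_pki = pki,
    true_hill = matrix(1, nC, nK, dimnames = list(cmp, kin)),
    archetype = arch,
    assay_conditions = data.frame(
      kinase_id = kin,
      atp_conc_uM = config$atp_over_km * config$km_atp,
      km_atp_uM = config$km_atp,
      stringsAsFactors = FALSE
    ),
    config = config
  ), class = "ground_truth")
}

# true IC50 (uM) implied by truth: Cheng-Prusoff run forward,
# IC50 = Ki * (1 + [ATP]/Km), Ki = 10^(6 - pKi) uM
true_ic50_matrix <- function(truth) {
  shift <- 1 + truth$assay_conditions$atp_conc_uM / truth$assay_conditions$km_atp_uM
  ki <- 10^(6 - truth$true_pki)
  sweep(ki, 2, shift, `*`)
}

#' Simulate the single-point panel screen
#'
#' Pushes the ground truth through the forward observation model: per
#' cell, IC50 = Ki (1 + [ATP]/Km), expected inhibition from the one-site
#' single-point model at the screening concentration, plus additive
#' Gaussian noise, clipped to [-20, 120] (screens report values slightly
#' outside [0, 100]). Cells then drop out at the config's missingness
#' rate, exercising the selectivity denominators.
#'
#' @param truth a [sample_truth()] result.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return a [panel_profile()].
#' @export
forward_screen <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  ic50 <- true_ic50_matrix(truth)
  expected <- 100 / (1 + sweep(ic50, 1, rep_len(config$screen_conc, nrow(ic50)), `/`))
  obs <- with_rng(config$seed + 1L, {
    x <- expected + stats::rnorm(length(expected), 0, config$noise_sd_single_point)
    x <- pmin(pmax(x, -20), 120)
    if (config$dropout > 0) {
      miss <- stats::runif(length(x)) < config$dropout
      x[miss] <- NA_real_
    }
    x
  })
  dim(obs) <- dim(expected); dimnames(obs) <- dimnames(expected)
  # a fully missing row would make the profile ill-defined; restore one cell
  gone <- rowSums(!is.na(obs)) == 0
  obs[gone, 1] <- pmin(pmax(expected[gone, 1], -20), 120)
  panel_profile(obs, rep_len(config$screen_conc, nrow(obs)))
}

#' Simulate dose-response curves for selected pairs
#'
#' Generates replicated multi-point curves for a subset of
#' compound x kinase pairs: `n_dilutions`-point serial dilution from
#' `top_conc` (half-log by default), `n_replicates` replicates, responses
#' from the 4PL at the pair's true IC50 and Hill slope (asymptotes 0/100)
#' plus Gaussian noise.
#'
#' @param truth a [sample_truth()] result.
#' @param subset data.frame with `compound_id`, `kinase_id`; defaults to
#'   every pair whose true IC50 lies within the tested dilution range
#'   (the pairs a screening campaign would follow up).
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return data.frame `compound_id, kinase_id, conc_uM, response_pct`.
#' @export
forward_curves <- function(truth, subset = NULL, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  ic50 <- true_ic50_matrix(truth)
  conc <- config$top_conc / config$dilution_factor^(seq_len(config$n_dilutions) - 1)
  if (is.null(subset)) {
    idx <- which(ic50 >= min(conc) & ic50 <= max(conc), arr.ind = TRUE)
    subset <- data.frame(compound_id = rownames(ic50)[idx[, 1]],
                         kinase_id = colnames(ic50)[idx[, 2]],
                         stringsAsFactors = FALSE)
  }
  if (!nrow(subset)) {
    return(data.frame(compound_id = character(), kinase_id = character(),
                      conc_uM = numeric(), response_pct = numeric()))
  }
  i <- match(as.character(subset$compound_id), rownames(ic50))
  j <- match(as.character(subset$kinase_id), colnames(ic50))
  if (anyNA(i) || anyNA(j)) {
    fs_stop("subset refers to unknown compound or kinase ids",
            "fragscreen_input_error")
  }
  cc <- rep(rep(conc, each = config$n_replicates), times = nrow(subset))
  per <- config$n_dilutions * config$n_replicates
  out <- data.frame(
    compound_id = rep(as.character(subset$compound_id), each = per),
    kinase_id = rep(as.character(subset$kinase_id), each = per),
    conc_uM = cc, stringsAsFactors = FALSE
  )
  mu <- four_pl(cc, rep(ic50[cbind(i, j)], each = per),
                rep(truth$true_hill[cbind(i, j)], each = per))
  out$response_pct <- with_rng(config$seed + 2L,
    mu + stats::rnorm(length(mu), 0, config$noise_sd_curve))
  out
}
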