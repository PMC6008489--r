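#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For an ATP-competitive inhibitor assayed at substrate (ATP) concentration
#' `atp_conc` with Michaelis constant `km_atp`,
#' `Ki = IC50 / (1 + atp_conc / km_atp)`. Ki equals IC50 when the assay is
#' run at vanishing ATP and is halved when run at ATP = Km. Converting to
#' Ki makes potencies comparable across kinases assayed at different ATP
#' concentrations.
#'
#' @param ic50 IC50 in uM (> 0). Vectorized.
#' @param atp_conc assay ATP concentration in uM (>= 0).
#' @param km_atp Km for ATP in uM (> 0).
#' @return Ki in uM, in (0, ic50].
#' @examples
#' cheng_prusoff_ki(12, atp_conc = 10, km_atp = 5) # 4
#' @export
cheng_prusoff_ki <- function(ic50, atp_conc, km_atp) {
  check_positive(ic50, "ic50")
  check_positive(km_atp, "km_atp")
  if (any(!is.finite(atp_conc)) || any(atp_conc < 0)) {
    fs_stop("`atp_conc` must be finite and >= 0", "fragscreen_domain_error")
  }
  ic50 / (1 + atp_conc / km_atp)
}

#' pKi from Ki in micromolar
#'
#' @param ki Ki in uM (> 0).
#' @return -log10(Ki in molar); e.g. 1 uM -> 6.
#' @export
pki <- function(ki) {
  check_positive(ki, "ki")
  -log10(ki * 1e-6)
}

#' Ligand efficiency
#'
#' Binding free energy per heavy atom, `LE = 1.37 * pKi / HAC` in
#' kcal/mol per heavy atom. The constant 1.37 is 2.303*R*T in kcal/mol at
#' T = 298 K, i.e. the free-energy value of one pKi unit.
#'
#' @param ki Ki in uM (> 0).
#' @param heavy_atoms heavy-atom count (>= 1).
#' @param le_const kcal/mol per pKi unit; default 1.37 (298 K).
#' @return LE in kcal/mol per heavy atom (full precision; reports round
#'   half-up to 2 dp).
#' @examples
#' ligand_efficiency(5.4, 22) # ~0.33
#' @export
ligand_efficiency <- function(ki, heavy_atoms, le_const = 1.37) {
  if (any(!is.finite(heavy_atoms)) || any(heavy_atoms < 1)) {
    fs_stop("`heavy_atoms` must be >= 1", "fragscreen_domain_error")
  }
  le_const * pki(ki) / heavy_atoms
}

#' Expected single-point inhibition from an IC50
#'
#' One-site response model: percent inhibition observed when a compound
#' with a given IC50 is screened at a single concentration,
#' `100 / (1 + (ic50/conc)^hill)`; 0 at zero concentration.
#'
#' @param ic50 IC50 in uM (> 0). Vectorized with `conc`.
#' @param conc screening concentration in uM (>= 0).
#' @param hill Hill slope (> 0), default 1.
#' @return percent inhibition in [0, 100).
#' @examples
#' single_point_inhibition(25, 100) # 80
#' @export
single_point_inhibition <- function(ic50, conc, hill = 1) {
  check_positive(ic50, "ic50")
  check_positive(hill, "hill")
  if (any(!is.finite(conc)) || any(conc < 0)) {
    fs_stop("`conc` must be finite and >= 0", "fragscreen_domain_error")
  }
  n <- max(length(ic50), length(conc))
  ic50 <- rep_len(as.vector(ic50), n)
  conc <- rep_len(as.vector(conc), n)
  out <- 100 / (1 + (ic50 / conc)^hill)
  out[conc == 0] <- 0
  out
}

#' IC50 implied by a single-point inhibition measurement
#'
#' Exact inverse of [single_point_inhibition()]:
#' `ic50 = conc * ((100 - pct)/pct)^(1/hill)`. Measurements at or outside
#' the open interval (0, 100)% carry no point estimate; they are returned
#' censored at the screening concentration (`<` for saturated, `>` for
#' inactive), mirroring how screen tables report bounds.
#'
#' @param pct observed percent inhibition. Vectorized.
#' @param conc screening concentration in uM (> 0).
#' @param hill Hill slope (> 0), default 1.
#' @return data.frame with columns `ic50_uM` (estimate, or the bound
#'   `conc` when censored), `censored` (logical), `operator` (`"="`,
#'   `"<"` saturated, `">"` inactive).
#' @examples
#' ic50_from_single_point(80, 100)$ic50_uM # 25
#' @export
ic50_from_single_point <- function(pct, conc, hill = 1) {
  check_positive(conc, "conc")
  check_positive(hill, "hill")
  n <- max(length(pct), length(conc))
  pct <- rep_len(pct, n); conc <- rep_len(conc, n)
  op <- ifelse(pct >= 100, "<", ifelse(pct <= 0, ">", "="))
  val <- ifelse(op == "=", conc * ((100 - pct) / pct)^(1 / hill), conc)
  data.frame(ic50_uM = val, censored = op != "=", operator = op,
             stringsAsFactors = FALSE)
}

# internal: parse an IC50 column that may carry ">" censoring prefixes
parse_censored_ic50 <- function(x) {
  x <- trimws(as.character(x))
  cens <- startsWith(x, ">")
  val <- suppressWarnings(as.numeric(sub("^>", "", x)))
  if (any(is.na(val) & nzchar(x))) {
    fs_stop(sprintf("unparseable ic50 entry '%s'", x[which(is.na(val) & nzchar(x))[1]]),
            "fragscreen_input_error")
  }
  data.frame(ic50_uM = val, censored = cens)
}

#' Build a potency record table
#'
#' Joins measured IC50s with per-kinase assay conditions and compound
#' heavy-atom counts to produce Ki (Cheng-Prusoff), pKi and ligand
#' efficiency per compound-kinase pair. Entries censored as `"> x"` keep
#' their bound, get Ki/pKi/LE of `NA`, and are flagged — the `"> x (-)"`
#' convention of potency tables.
#'
#' @param ic50_tbl data.frame with `compound_id`, `kinase_id`, `ic50_uM`
#'   (numeric, or character with optional `">"` prefix for censored rows).
#' @param conditions data.frame with `kinase_id`, `atp_conc_uM`, `km_atp_uM`.
#' @param compounds optional compound table from [read_compound_table()];
#'   rows without a heavy-atom count get `le = NA` with a warning.
#' @return data.frame `compound_id, kinase_id, ic50_uM, ki_uM, pki, le,
#'   censored`, ordered by compound then kinase id.
#' @export
potency_table <- function(ic50_tbl, conditions, compounds = NULL) {
  need <- c("compound_id", "kinase_id", "ic50_uM")
  if (!all(need %in% names(ic50_tbl))) {
    fs_stop("ic50 table needs compound_id, kinase_id, ic50_uM", "fragscreen_input_error")
  }
  cens <- parse_censored_ic50(ic50_tbl$ic50_uM)
  out <- data.frame(
    compound_id = as.character(ic50_tbl$compound_id),
    kinase_id = as.character(ic50_tbl$kinase_id),
    ic50_uM = cens$ic50_uM, censored = cens$censored,
    stringsAsFactors = FALSE
  )
  j <- match(out$kinase_id, conditions$kinase_id)
  if (anyNA(j)) {
    fs_stop(sprintf("no assay conditions for kinase '%s'",
                    out$kinase_id[which(is.na(j))[1]]), "fragscreen_input_error")
  }
  out$ki_uM <- out$pki <- NA_real_
  act <- !out$censored
  if (any(act)) {
    out$ki_uM[act] <- cheng_prusoff_ki(out$ic50_uM[act],
                                       conditions$atp_conc_uM[j][act],
                                       conditions$km_atp_uM[j][act])
    out$pki[act] <- pki(out$ki_uM[act])
  }
  out$le <- NA_real_
  if (!is.null(compounds)) {
    k <- match(out$compound_id, compounds$compound_id)
    hac <- compounds$heavy_atoms[k]
    ok <- !out$censored & !is.na(hac)
    out$le[ok] <- 1.37 * out$pki[ok] / hac[ok]
    miss <- !out$censored & is.na(hac)
    if (any(miss)) {
      warning(sprintf("no heavy-atom count for compound(s) %s; LE left blank",
                      paste(unique(out$compound_id[miss]), collapse = ", ")),
              call. = FALSE)
    }
  }
  out <- out[order(out$compound_id, out$kinase_id), ]
  rownames(out) <- NULL
  out[, c("compound_id", "kinase_id", "ic50_uM", "ki_uM", "pki", "le", "censored")]
}
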