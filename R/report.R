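# presentation formatting: fixed decimals, half-up, blank for NA,
# "> x (-)" convention handled by callers
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits), format = "f",
                               digits = digits))
}

#' Run the profiling analysis and write its report bundle
#'
#' End-to-end potency + selectivity report: converts an IC50 table to
#' Ki/pKi/LE under the stated assay conditions (Cheng-Prusoff) and scores
#' compound- and kinase-level selectivity over the panel profile. Output
#' rows are ordered by compound id then kinase id and all numeric
#' formatting is fixed-width, so identical inputs give byte-identical
#' files.
#'
#' Written files (into `out_dir`): `potency.csv`
#' (`compound_id,kinase_id,ic50_uM,ki_uM,pki,le,censored`; censored rows
#' render as `">x"` with LE blank), `selectivity.csv`
#' (`subject_type,subject_id,theta,hits,evaluated,score`), and
#' `summary.csv` (per compound: best Ki, best kinase, S(theta) at the
#' first theta).
#'
#' @param compounds compound table ([read_compound_table()] data.frame)
#'   or path.
#' @param ic50_tbl IC50 table (`compound_id,kinase_id,ic50_uM` with
#'   optional `">"` prefixes) or path; may be `NULL` when only a panel
#'   profile is supplied.
#' @param conditions assay-condition table
#'   (`kinase_id,atp_conc_uM,km_atp_uM`) or path; required with
#'   `ic50_tbl`.
#' @param profile a [panel_profile()] or path; may be `NULL`.
#' @param out_dir output directory, created if needed.
#' @param thetas selectivity thresholds in percent (default 50).
#' @return invisibly, a list with the computed `potency` and
#'   `selectivity` data.frames (full precision, before rounding).
#' @export
run_profile <- function(compounds, ic50_tbl = NULL, conditions = NULL,
                        profile = NULL, out_dir, thetas = 50) {
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  if (is.character(ic50_tbl)) {
    ic50_tbl <- utils::read.csv(ic50_tbl, colClasses = "character")
  }
  if (is.character(conditions)) conditions <- utils::read.csv(conditions)
  if (is.character(profile)) profile <- read_panel_profile(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pot <- NULL
  if (!is.null(ic50_tbl)) {
    if (is.null(conditions)) {
      fs_stop("assay conditions are required to convert IC50 to Ki",
              "fragscreen_input_error")
    }
    pot <- potency_table(ic50_tbl, conditions, compounds)
    out <- data.frame(
      compound_id = pot$compound_id, kinase_id = pot$kinase_id,
      ic50_uM = ifelse(pot$censored, paste0(">", fmt_num(pot$ic50_uM, 1)),
                       fmt_num(pot$ic50_uM, 3)),
      ki_uM = fmt_num(pot$ki_uM, 3), pki = fmt_num(pot$pki, 3),
      le = fmt_num(pot$le, 2), censored = tolower(pot$censored),
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, file.path(out_dir, "potency.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  sel <- NULL
  if (!is.null(profile)) {
    sel <- selectivity_table(profile, thetas)
  } else {
    sel <- data.frame(subject_type = character(), subject_id = character(),
                      theta = numeric(), hits = integer(),
                      evaluated = integer(), score = numeric())
  }
  out <- data.frame(
    subject_type = sel$subject_type, subject_id = sel$subject_id,
    theta = fmt_num(sel$theta, 0), hits = sel$hits,
    evaluated = sel$evaluated, score = fmt_num(sel$score, 2),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, file.path(out_dir, "selectivity.csv"),
                   row.names = FALSE, quote = FALSE)

  if (!is.null(pot)) {
    act <- pot[!pot$censored & !is.na(pot$ki_uM), ]
    best <- do.call(rbind, lapply(split(act, act$compound_id), function(d) {
      i <- which.min(d$ki_uM)
      data.frame(compound_id = d$compound_id[i], best_kinase = d$kinase_id[i],
                 best_ki_uM = d$ki_uM[i], best_le = d$le[i],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(best)) {
      if (nrow(sel)) {
        s1 <- sel[sel$subject_type == "compound" & sel$theta == thetas[1], ]
        best$s_score <- s1$score[match(best$compound_id, s1$subject_id)]
      } else {
        best$s_score <- NA_real_
      }
      best <- best[order(best$compound_id), ]
      out <- data.frame(compound_id = best$compound_id,
                        best_kinase = best$best_kinase,
                        best_ki_uM = fmt_num(best$best_ki_uM, 3),
                        best_le = fmt_num(best$best_le, 2),
                        s_score = fmt_num(best$s_score, 2),
                        stringsAsFactors = FALSE)
      utils::write.csv(out, file.path(out_dir, "summary.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(list(potency = pot, selectivity = sel))
}

#' Generate and write a complete synthetic screen bundle
#'
#' Samples ground truth, runs the forward single-point screen and the
#' follow-up dose-response curves, and writes the whole dataset with its
#' generating truth and an MD5 manifest. Re-running with the same config
#' reproduces every file byte for byte.
#'
#' Written files: `compounds.csv`, `assay_conditions.csv`,
#' `panel_profile.csv`, `dose_response.csv`, `ground_truth.csv`
#' (`compound_id,kinase_id,true_pki,true_hill,archetype`), `config.txt`
#' (key = value echo) and `manifest.txt` (MD5 per file).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, list with `truth`, `profile`, `curves`, `files`.
#' @export
run_simulate <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    fs_stop(sprintf("output directory '%s' is not empty (use force = TRUE)",
                    out_dir), "fragscreen_input_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sample_truth(config)
  prof <- forward_screen(truth)
  curves <- forward_curves(truth)

  cmp <- data.frame(compound_id = rownames(truth$true_pki),
                    name = paste0("synthetic-", truth$archetype),
                    ion_formula = "", neutral_formula = "",
                    heavy_atoms = "", stringsAsFactors = FALSE)
  gt <- data.frame(
    compound_id = rep(rownames(truth$true_pki), ncol(truth$true_pki)),
    kinase_id = rep(colnames(truth$true_pki), each = nrow(truth$true_pki)),
    true_pki = as.vector(truth$true_pki),
    true_hill = as.vector(truth$true_hill),
    archetype = rep(unname(truth$archetype), ncol(truth$true_pki)),
    stringsAsFactors = FALSE
  )
  gt <- gt[order(gt$compound_id, gt$kinase_id), ]
  gt$true_pki <- sprintf("%.10f", gt$true_pki)

  paths <- c(compounds = "compounds.csv", conditions = "assay_conditions.csv",
             profile = "panel_profile.csv", curves = "dose_response.csv",
             truth = "ground_truth.csv", config = "config.txt")
  paths <- vapply(paths, function(p) file.path(out_dir, p), "")
  utils::write.csv(cmp, paths["compounds"], row.names = FALSE, quote = FALSE)
  utils::write.csv(truth$assay_conditions, paths["conditions"],
                   row.names = FALSE, quote = FALSE)
  write_panel_profile(prof, paths["profile"])
  cv <- curves
  cv$conc_uM <- sprintf("%.6f", cv$conc_uM)
  cv$response_pct <- sprintf("%.6f", cv$response_pct)
  utils::write.csv(cv, paths["curves"], row.names = FALSE, quote = FALSE)
  utils::write.csv(gt, paths["truth"], row.names = FALSE, quote = FALSE)
  cfg <- config
  cfg_lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(format(cfg[[k]], digits = 15), collapse = ",")), "")
  writeLines(cfg_lines, paths["config"])
  sums <- tools::md5sum(unname(paths))
  writeLines(sprintf("%s  %s", sums, basename(names(sums))),
             file.path(out_dir, "manifest.txt"))
  invisible(list(truth = truth, profile = prof, curves = curves,
                 files = c(paths, manifest = file.path(out_dir, "manifest.txt"))))
}

#' Run the contact analysis on a structure and write its report
#'
#' Hydrogen-bond (N/O, distance-only) and hydrophobic (C-C) contacts of
#' a bound ligand, written as `contacts.csv` with a human-readable
#' `contacts_summary.txt` naming the contacted residues. The output
#' header records the geometric criteria used.
#'
#' @param structure path to a PDB file or a [read_structure()] model.
#' @param ligand_resname ligand residue code (HETATM selection).
#' @param out_dir output directory.
#' @param max_hbond H-bond distance cutoff in Å (default 3.5).
#' @param max_hydrophobic C-C cutoff in Å (default 4.5).
#' @return invisibly, list with `hbonds` and `hydrophobic` data.frames.
#' @export
run_contacts <- function(structure, ligand_resname, out_dir,
                         max_hbond = 3.5, max_hydrophobic = 4.5) {
  model <- if (is.character(structure)) read_structure(structure) else structure
  lig_sel <- list(resname = ligand_resname, hetero = TRUE)
  if (!nrow(do.call(select_atoms, c(list(model), lig_sel)))) {
    fs_stop(sprintf("no ligand atoms match residue name '%s'", ligand_resname),
            "fragscreen_input_error")
  }
  pro_sel <- list(hetero = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hb <- find_hbonds(model, lig_sel, pro_sel, max_dist = max_hbond)
  hp <- find_hydrophobic_contacts(model, lig_sel, pro_sel,
                                  max_dist = max_hydrophobic)
  tab <- rbind(
    if (nrow(hb)) data.frame(
      contact_type = "hbond", ligand_atom = hb$ligand_atom,
      protein_chain = hb$protein_chain,
      protein_residue = paste0(hb$protein_residue, hb$protein_resno),
      protein_atom = hb$protein_atom,
      distance_A = fmt_num(hb$distance, 2), stringsAsFactors = FALSE),
    if (nrow(hp)) data.frame(
      contact_type = "hydrophobic", ligand_atom = "",
      protein_chain = hp$protein_chain,
      protein_residue = paste0(hp$protein_residue, hp$protein_resno),
      protein_atom = "", distance_A = fmt_num(hp$min_distance, 2),
      stringsAsFactors = FALSE)
  )
  if (is.null(tab)) {
    tab <- data.frame(contact_type = character(), ligand_atom = character(),
                      protein_chain = character(), protein_residue = character(),
                      protein_atom = character(), distance_A = character())
  }
  con <- file.path(out_dir, "contacts.csv")
  writeLines(c(
    sprintf("# criteria: hbond = ligand/protein N,O pairs <= %.2f A (distance only, no angle term); hydrophobic = C-C pairs <= %.2f A",
            max_hbond, max_hydrophobic),
    paste(names(tab), collapse = ",")), con)
  if (nrow(tab)) {
    utils::write.table(tab, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE, append = TRUE)
  }
  summ <- c(
    sprintf("ligand %s: %d hydrogen-bond contact(s), %d hydrophobic residue(s)",
            ligand_resname, nrow(hb), nrow(hp)),
    if (nrow(hb)) sprintf("  H-bond: %s %s%d %s -- ligand %s, %.2f A (%s donor)",
                          hb$protein_chain, hb$protein_residue, hb$protein_resno,
                          hb$protein_atom, hb$ligand_atom, hb$distance, hb$donor),
    if (nrow(hp)) sprintf("  packing: %s %s%d, %d C-C pair(s), closest %.2f A",
                          hp$protein_chain, hp$protein_residue, hp$protein_resno,
                          hp$n_pairs, hp$min_distance)
  )
  writeLines(summ, file.path(out_dir, "contacts_summary.txt"))
  invisible(list(hbonds = hb, hydrophobic = hp))
}
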