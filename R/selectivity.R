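#' Panel single-point profile
#'
#' Container for a compound x kinase matrix of percent inhibition measured
#' at a single screening concentration per compound. Values outside
#' [0, 100] are legitimate (assay noise and normalization artifacts);
#' anything outside [-100, 200] is rejected. Missing cells (`NA`) are
#' allowed but every compound must have at least one measurement.
#'
#' @param inhibition numeric matrix, rows = compounds, cols = kinases,
#'   with dimnames; `NA` marks a missing measurement.
#' @param screen_conc screening concentration(s) in uM, scalar or one per
#'   compound (e.g. 100, with poorly soluble compounds at 30).
#' @return object of class `panel_profile`.
#' @export
panel_profile <- function(inhibition, screen_conc) {
  if (!is.matrix(inhibition) || is.null(rownames(inhibition)) ||
      is.null(colnames(inhibition))) {
    fs_stop("inhibition must be a matrix with compound rownames and kinase colnames",
            "fragscreen_input_error")
  }
  if (any(!is.na(inhibition) & (inhibition < -100 | inhibition > 200))) {
    fs_stop("inhibition values outside [-100, 200]", "fragscreen_input_error")
  }
  if (any(rowSums(!is.na(inhibition)) == 0)) {
    fs_stop("every compound row needs at least one non-missing cell",
            "fragscreen_input_error")
  }
  screen_conc <- rep_len(screen_conc, nrow(inhibition))
  check_positive(screen_conc, "screen_conc")
  structure(list(inhibition = inhibition, screen_conc = screen_conc),
            class = "panel_profile")
}

#' @export
print.panel_profile <- function(x, ...) {
  cat(sprintf("<panel_profile> %d compounds x %d kinases, %d missing cells\n",
              nrow(x$inhibition), ncol(x$inhibition), sum(is.na(x$inhibition))))
  invisible(x)
}

# shared core: selectivity score over one row or column
score_vector <- function(v, theta, subject_id, subject_type) {
  v <- v[!is.na(v)]
  if (!length(v)) {
    fs_stop(sprintf("%s '%s' has no measurements", subject_type, subject_id),
            "fragscreen_input_error")
  }
  hits <- sum(v > theta)           # strict: ties at theta do not count
  data.frame(subject_type = subject_type, subject_id = subject_id,
             theta = theta, hits = hits, evaluated = length(v),
             score = hits / length(v), stringsAsFactors = FALSE)
}

#' Compound selectivity score S_compound(theta)
#'
#' Fraction of panel kinases a compound inhibits by strictly more than
#' `theta` percent at its screening concentration. 0 is fully selective
#' (or inactive); 1 is completely non-selective. Missing cells are dropped
#' from the denominator, so `evaluated` can be less than the panel size.
#'
#' @param profile a [panel_profile()].
#' @param compound_id compound row label.
#' @param theta threshold in percent (default 50, the conventional S(50%)).
#' @return one-row data.frame `subject_type, subject_id, theta, hits,
#'   evaluated, score` (score = hits/evaluated, exact).
#' @export
s_compound <- function(profile, compound_id, theta = 50) {
  stopifnot(inherits(profile, "panel_profile"))
  i <- match(compound_id, rownames(profile$inhibition))
  if (is.na(i)) fs_stop(sprintf("unknown compound '%s'", compound_id),
                        "fragscreen_input_error")
  score_vector(profile$inhibition[i, ], theta, compound_id, "compound")
}

#' Kinase selectivity score S_kinase(theta)
#'
#' Fraction of library compounds that inhibit a given kinase by strictly
#' more than `theta` percent: the column-wise mirror of [s_compound()].
#'
#' @inheritParams s_compound
#' @param kinase_id kinase column label.
#' @return one-row data.frame as in [s_compound()].
#' @export
s_kinase <- function(profile, kinase_id, theta = 50) {
  stopifnot(inherits(profile, "panel_profile"))
  j <- match(kinase_id, colnames(profile$inhibition))
  if (is.na(j)) fs_stop(sprintf("unknown kinase '%s'", kinase_id),
                        "fragscreen_input_error")
  score_vector(profile$inhibition[, j], theta, kinase_id, "kinase")
}

#' Batch selectivity report
#'
#' Scores every compound and every kinase at each threshold. For a fixed
#' subject, scores are non-increasing in theta. Kinase columns that are
#' entirely missing are skipped (a compound row cannot be, by
#' construction of [panel_profile()]).
#'
#' @inheritParams s_compound
#' @param thetas vector of thresholds in percent.
#' @return data.frame `subject_type, subject_id, theta, hits, evaluated,
#'   score`, compounds first, in profile order; empty for empty `thetas`.
#' @export
selectivity_table <- function(profile, thetas = 50) {
  stopifnot(inherits(profile, "panel_profile"))
  rows <- list()
  for (th in thetas) {
    for (cid in rownames(profile$inhibition)) {
      rows[[length(rows) + 1L]] <- s_compound(profile, cid, th)
    }
    for (kid in colnames(profile$inhibition)) {
      if (all(is.na(profile$inhibition[, kid]))) next
      rows[[length(rows) + 1L]] <- s_kinase(profile, kid, th)
    }
  }
  if (!length(rows)) {
    return(data.frame(subject_type = character(), subject_id = character(),
                      theta = numeric(), hits = integer(),
                      evaluated = integer(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a panel profile from delimited text
#'
#' Expected layout: first column `compound_id`, second `screen_conc_uM`,
#' one further column per kinase; blank cells are missing measurements.
#'
#' @param path CSV path.
#' @return a [panel_profile()].
#' @export
read_panel_profile <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3 || names(raw)[1] != "compound_id" ||
      names(raw)[2] != "screen_conc_uM") {
    fs_stop("panel profile needs columns compound_id, screen_conc_uM, then kinases",
            "fragscreen_input_error")
  }
  m <- as.matrix(raw[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw$compound_id)
  panel_profile(m, raw$screen_conc_uM)
}

#' Write a panel profile to delimited text
#'
#' Inverse of [read_panel_profile()].
#'
#' @param profile a [panel_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_profile <- function(profile, path) {
  stopifnot(inherits(profile, "panel_profile"))
  df <- data.frame(compound_id = rownames(profile$inhibition),
                   screen_conc_uM = profile$screen_conc,
                   profile$inhibition, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
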