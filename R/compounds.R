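#' Read a compound table
#'
#' Reads the delimited compound registry with header
#' `compound_id,name,ion_formula,neutral_formula,heavy_atoms`. Exactly one
#' of the last three columns must be non-empty per row; the other two are
#' derived where possible (an ion formula yields the neutral formula by
#' removing one H; any formula yields the heavy-atom count and [M+H]+ m/z;
#' a bare heavy-atom count yields no formula or mass). Lines starting with
#' `#` are comments.
#'
#' @param path path to a comma-separated compound table (UTF-8).
#' @return data.frame with columns `compound_id`, `name`,
#'   `neutral_formula` (Hill string or `NA`), `heavy_atoms` (integer),
#'   `mz_mh` ([M+H]+ monoisotopic m/z in Da, `NA` without a formula).
#' @export
read_compound_table <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  need <- c("compound_id", "name", "ion_formula", "neutral_formula", "heavy_atoms")
  if (!all(need %in% names(raw))) {
    fs_stop(sprintf("compound table must have columns %s",
                    paste(need, collapse = ", ")), "fragscreen_input_error")
  }
  filled <- function(x) !is.na(x) & nzchar(x)
  n_given <- filled(raw$ion_formula) + filled(raw$neutral_formula) + filled(raw$heavy_atoms)
  if (any(n_given != 1L)) {
    bad <- raw$compound_id[n_given != 1L][1]
    fs_stop(sprintf(
      "compound '%s': exactly one of ion_formula/neutral_formula/heavy_atoms must be given",
      bad), "fragscreen_input_error")
  }
  out <- data.frame(
    compound_id = raw$compound_id, name = raw$name,
    neutral_formula = NA_character_, heavy_atoms = NA_integer_,
    mz_mh = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(raw))) {
    if (filled(raw$ion_formula[i])) {
      neutral <- neutral_from_protonated(parse_formula(raw$ion_formula[i]))
    } else if (filled(raw$neutral_formula[i])) {
      neutral <- parse_formula(raw$neutral_formula[i])
    } else {
      hac <- suppressWarnings(as.integer(raw$heavy_atoms[i]))
      if (is.na(hac) || hac < 1L) {
        fs_stop(sprintf("compound '%s': heavy_atoms must be a positive integer",
                        raw$compound_id[i]), "fragscreen_input_error")
      }
      out$heavy_atoms[i] <- hac
      next
    }
    out$neutral_formula[i] <- format(neutral)
    out$heavy_atoms[i] <- heavy_atom_count(neutral)
    out$mz_mh[i] <- monoisotopic_mz(neutral)
  }
  out
}
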