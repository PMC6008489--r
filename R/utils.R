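#' Round half away from zero
#'
#' Presentation-layer rounding used throughout report output. Unlike base
#' [round()], which rounds half to even (0.345 -> 0.34), this rounds
#' half up (0.345 -> 0.35), matching how the assay tables present 2-dp
#' ligand efficiencies and 1-dp percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` places.
#' @examples
#' round_half_up(0.345, 2) # 0.35
#' round_half_up(2.5, 0)   # 3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 (an FP
  # representation artifact, e.g. 0.335*100 = 33.499999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: stop with a classed condition so callers/tests can be specific
fs_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "fragscreen_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

# internal: scalar-positive check used by potency/dose-response entry points
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    fs_stop(sprintf("`%s` must be finite and > 0", name), "fragscreen_domain_error")
  }
  invisible(x)
}
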