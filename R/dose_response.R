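#' Four-parameter logistic response
#'
#' `response = bottom + (top - bottom) / (1 + (ic50/conc)^hill)`.
#' Monotone increasing in concentration for hill > 0, equal to the
#' midpoint (top+bottom)/2 at conc = ic50, and symmetric about ic50 on
#' the log-concentration axis.
#'
#' @param conc concentration in uM (> 0). Vectorized.
#' @param ic50 inflection concentration in uM (> 0).
#' @param hill Hill slope (> 0).
#' @param top upper asymptote in percent inhibition.
#' @param bottom lower asymptote in percent inhibition.
#' @return response in percent.
#' @examples
#' four_pl(4, ic50 = 2, hill = 1, top = 100, bottom = 0) # 66.67
#' @export
four_pl <- function(conc, ic50, hill = 1, top = 100, bottom = 0) {
  check_positive(conc, "conc")
  check_positive(ic50, "ic50")
  check_positive(hill, "hill")
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit a four-parameter logistic curve
#'
#' Levenberg-Marquardt least squares on concentration-response data.
#' IC50 is optimized on the log10 scale and the Hill slope on the log
#' scale (both therefore stay positive). By default the asymptotes are
#' fixed at bottom = 0, top = 100, the natural constraint for a
#' normalized percent-inhibition readout; `free_asymptotes = TRUE` fits
#' all four parameters. Initial values: bottom = min response, top = max
#' response, ic50 = concentration whose response is nearest the
#' midpoint, hill = 1.
#'
#' A fitted IC50 above the highest tested concentration is an
#' extrapolation the data cannot support, so it is reported censored at
#' that concentration (`ic50 > c_max`). Optimizer failure and flat
#' response data yield `converged = FALSE`, never an error.
#'
#' @param conc concentrations in uM; at least 4 distinct values.
#' @param response percent inhibition, same length (replicates = repeated
#'   concentrations).
#' @param free_asymptotes fit top and bottom instead of fixing 0/100.
#' @param bottom,top fixed asymptote values when not freed.
#' @return list of class `fit_4pl`: `ic50`, `hill`, `top`, `bottom`,
#'   `rss`, `converged`, `censored`, `c_max`, `ic50_stderr`, `n`.
#' @export
fit_4pl <- function(conc, response, free_asymptotes = FALSE,
                    bottom = 0, top = 100) {
  check_positive(conc, "conc")
  if (length(conc) != length(response) || any(!is.finite(response))) {
    fs_stop("conc and response must be equal-length finite vectors",
            "fragscreen_input_error")
  }
  if (length(unique(conc)) < 4L) {
    fs_stop("at least 4 distinct concentrations are required",
            "fragscreen_input_error")
  }
  c_max <- max(conc)
  res <- list(ic50 = NA_real_, hill = NA_real_, top = top, bottom = bottom,
              rss = NA_real_, converged = FALSE, censored = FALSE,
              c_max = c_max, ic50_stderr = NA_real_, n = length(conc))
  class(res) <- "fit_4pl"
  if (diff(range(response)) < 1e-9) return(res)  # flat data: nothing to fit

  b0 <- if (free_asymptotes) min(response) else bottom
  t0 <- if (free_asymptotes) max(response) else top
  mid <- (t0 + b0) / 2
  ic50_0 <- conc[which.min(abs(response - mid))]
  # p = (log10 ic50, log hill [, bottom, top])
  p0 <- c(log10(ic50_0), 0)
  if (free_asymptotes) p0 <- c(p0, b0, t0)
  model <- function(p, cc) {
    bb <- if (free_asymptotes) p[3] else bottom
    tt <- if (free_asymptotes) p[4] else top
    bb + (tt - bb) / (1 + (10^p[1] / cc)^exp(p[2]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = function(p) response - model(p, conc),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(res)
  p <- fit$par
  res$ic50 <- 10^p[1]
  res$hill <- exp(p[2])
  if (free_asymptotes) { res$bottom <- p[3]; res$top <- p[4] }
  res$rss <- sum(fit$fvec^2)
  res$converged <- TRUE
  res$censored <- res$ic50 > c_max
  # stderr of ic50 via delta method from the log10-scale covariance
  se <- tryCatch({
    cv <- tryCatch(solve(fit$hessian) * res$rss /
                     max(length(conc) - length(p), 1), error = function(e) NULL)
    if (is.null(cv)) NA_real_ else sqrt(cv[1, 1]) * log(10) * res$ic50
  }, error = function(e) NA_real_)
  res$ic50_stderr <- se
  res
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (!x$converged) {
    cat("<fit_4pl> not converged\n")
  } else if (x$censored) {
    cat(sprintf("<fit_4pl> ic50 > %g uM (censored), hill = %.3g, rss = %.3g\n",
                x$c_max, x$hill, x$rss))
  } else {
    cat(sprintf("<fit_4pl> ic50 = %.4g uM, hill = %.3g, [%.3g, %.3g], rss = %.3g\n",
                x$ic50, x$hill, x$bottom, x$top, x$rss))
  }
  invisible(x)
}

#' Fit 4PL curves for a batch of compound-kinase pairs
#'
#' @param dr data.frame with `compound_id, kinase_id, conc_uM,
#'   response_pct` (the dose-response exchange format; replicate rows
#'   allowed).
#' @param ... passed to [fit_4pl()].
#' @return data.frame `compound_id, kinase_id, ic50_uM, hill, top,
#'   bottom, rss, converged, censored`, one row per pair, ordered by
#'   compound then kinase; censored rows carry the top tested
#'   concentration in `ic50_uM`.
#' @export
fit_4pl_table <- function(dr, ...) {
  need <- c("compound_id", "kinase_id", "conc_uM", "response_pct")
  if (!all(need %in% names(dr))) {
    fs_stop("dose-response table needs compound_id, kinase_id, conc_uM, response_pct",
            "fragscreen_input_error")
  }
  key <- interaction(dr$compound_id, dr$kinase_id, drop = TRUE, sep = "\r")
  out <- lapply(split(dr, key), function(d) {
    f <- fit_4pl(d$conc_uM, d$response_pct, ...)
    data.frame(compound_id = as.character(d$compound_id[1]),
               kinase_id = as.character(d$kinase_id[1]),
               ic50_uM = if (f$censored) f$c_max else f$ic50,
               hill = f$hill, top = f$top, bottom = f$bottom, rss = f$rss,
               converged = f$converged, censored = f$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$compound_id, out$kinase_id), ]
  rownames(out) <- NULL
  out
}
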