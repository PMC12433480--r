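#' Fit an immunoassay standard curve
#'
#' Least-squares calibration of plate-reader standards. Two models:
#' \describe{
#'   \item{4PL}{`y = d + (a - d) / (1 + (x / c)^b)` — four-parameter
#'     logistic, the standard ELISA/electrochemiluminescence model; `a` is
#'     the response at zero concentration, `d` the response at infinite
#'     concentration, `c` the inflection concentration and `b` the slope.}
#'   \item{hyperbolic}{`y = Bmax * x / (Kd + x)` — one-site saturation
#'     binding, used for luminescence-based ATP quantification.}
#' }
#' Fitting is by [minpack.lm::nlsLM()] (Levenberg-Marquardt), unweighted by
#' default with optional `1/y^2` weighting. The 4PL fit starts from the
#' extreme responses (`a`, `d`), the geometric mid concentration (`c`) and
#' slope 1, and is refit from 3 perturbed starts, keeping the lowest
#' residual sum of squares.
#'
#' @param conc known standard concentrations (> 0 for the 4PL model; >= 5
#'   standards spanning at least two decades).
#' @param resp measured responses (OD or luminescence).
#' @param model `"4PL"` or `"hyperbolic"`.
#' @param weighting `"none"` (default) or `"1/y2"`.
#' @return an object of class `standard_curve`: list with `model`,
#'   `params`, `rss`, `valid_response_range` (the open interval of
#'   responses that can be inverted, bounded by the asymptotes and clipped
#'   to the standards' span), `conc_range`.
#' @export
fit_standard_curve <- function(conc, resp, model = c("4PL", "hyperbolic"),
                               weighting = c("none", "1/y2")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  vs_check(length(conc) == length(resp), "viroscore_length_mismatch",
           "conc and resp differ in length")
  vs_check(all(is.finite(conc)) && all(is.finite(resp)), "viroscore_nonfinite",
           "non-finite standards")
  w <- if (weighting == "1/y2") 1 / pmax(resp, .Machine$double.eps)^2 else rep(1, length(resp))
  d <- data.frame(x = conc, y = resp, w = w)
  d <- d[order(d$x), ]

  if (model == "4PL") {
    vs_check(length(conc) >= 5, "viroscore_too_few_standards",
             "4PL needs >= 5 standards, got %d", length(conc))
    vs_check(all(conc > 0), "viroscore_bad_standards",
             "4PL standards must have positive concentrations")
    vs_check(max(conc) / min(conc) >= 100, "viroscore_narrow_standards",
             "standards should span at least two decades of concentration")
    rtrend <- cor(rank(d$x), rank(d$y))
    vs_check(abs(rtrend) > 0.7, "viroscore_nonmonotone_standards",
             "standards show no monotone concentration-response trend")
    # with b > 0, a is the zero-concentration response and d the plateau,
    # so taking them from the extreme standards fits either direction
    start0 <- list(a = d$y[[1]], b = 1,
                   c = exp(mean(log(range(conc)))), d = d$y[[nrow(d)]])
    fits <- list()
    set_starts <- c(list(start0), lapply(1:3, function(i) {
      list(a = start0$a * (1 + 0.1 * i), b = start0$b * (1 + 0.25 * i),
           c = start0$c * 2^(i - 2), d = start0$d * (1 - 0.05 * i))
    }))
    for (st in set_starts) {
      f <- tryCatch(
        minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b), data = d,
                          start = st, weights = d$w,
                          lower = c(a = -Inf, b = -Inf, c = 1e-12, d = -Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    vs_check(length(fits) > 0, "viroscore_fit_failed",
             "4PL fit failed to converge from all starts")
    rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
    best <- fits[[which.min(rss)]]
    p <- as.list(coef(best))
    fitted_ends <- p$d + (p$a - p$d) / (1 + (range(d$x) / p$c)^p$b)
    out <- list(model = "4PL", params = p, rss = min(rss),
                valid_response_range = sort(fitted_ends),
                conc_range = range(d$x))
  } else {
    vs_check(length(conc) >= 3, "viroscore_too_few_standards",
             "hyperbolic fit needs >= 3 standards")
    vs_check(all(conc >= 0), "viroscore_bad_standards",
             "concentrations must be non-negative")
    st <- list(Bmax = max(d$y), Kd = max(median(d$x), .Machine$double.eps))
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x), data = d, start = st,
                        weights = d$w, lower = c(Bmax = 1e-12, Kd = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    vs_check(!is.null(f), "viroscore_fit_failed", "hyperbolic fit failed to converge")
    p <- as.list(coef(f))
    fitted_ends <- p$Bmax * range(d$x) / (p$Kd + range(d$x))
    out <- list(model = "hyperbolic", params = p, rss = sum(resid(f)^2),
                valid_response_range = sort(fitted_ends),
                conc_range = range(d$x))
  }
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve\n", x$model))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
                         collapse = ", "), "\n")
  cat(sprintf("  rss = %.4g, invertible response range [%.4g, %.4g]\n",
              x$rss, x$valid_response_range[[1]], x$valid_response_range[[2]]))
  invisible(x)
}

#' Evaluate a standard curve at given concentrations
#'
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param conc concentrations.
#' @return predicted responses.
#' @export
eval_curve <- function(curve, conc) {
  vs_check(inherits(curve, "standard_curve"), "viroscore_bad_curve",
           "curve must come from fit_standard_curve()")
  p <- curve$params
  if (curve$model == "4PL") {
    p$d + (p$a - p$d) / (1 + (conc / p$c)^p$b)
  } else {
    p$Bmax * conc / (p$Kd + conc)
  }
}

#' Back-calculate concentrations from responses
#'
#' Analytic inversion of the fitted curve: for the 4PL,
#' `x = c * ((a - d) / (y - d) - 1)^(1 / b)`; for the hyperbolic,
#' `x = Kd * y / (Bmax - y)`. In-range responses are inverted and
#' multiplied by the dilution factor; responses outside the invertible
#' range are flagged `below_fit` / `above_fit` and not inverted (use
#' [substitute_out_of_range()] to apply detection-limit substitution).
#'
#' @param curve a `standard_curve`.
#' @param response measured responses.
#' @param dilution fold dilution of the unknowns (scalar or per response).
#' @return data frame (one row per response): `response`, `dilution`,
#'   `concentration` (NA when out of range), `flag`.
#' @export
invert_curve <- function(curve, response, dilution = 1) {
  vs_check(inherits(curve, "standard_curve"), "viroscore_bad_curve",
           "curve must come from fit_standard_curve()")
  vs_check(all(dilution > 0), "viroscore_bad_dilution", "dilution must be positive")
  dilution <- rep_len(dilution, length(response))
  p <- curve$params
  rng <- curve$valid_response_range
  increasing <- eval_curve(curve, curve$conc_range[[2]]) >
                eval_curve(curve, curve$conc_range[[1]])
  lo_flag <- if (increasing) response < rng[[1]] else response > rng[[2]]
  hi_flag <- if (increasing) response > rng[[2]] else response < rng[[1]]
  flag <- ifelse(lo_flag, "below_fit", ifelse(hi_flag, "above_fit", "in_range"))
  x <- rep(NA_real_, length(response))
  ok <- flag == "in_range"
  if (any(ok)) {
    y <- response[ok]
    if (curve$model == "4PL") {
      vs_check(all(abs(y - p$d) > .Machine$double.eps) &&
               all(abs(y - p$a) > .Machine$double.eps), "viroscore_at_asymptote",
               "response exactly at an asymptote cannot be inverted")
      x[ok] <- p$c * ((p$a - p$d) / (y - p$d) - 1)^(1 / p$b)
    } else {
      vs_check(all(p$Bmax - y > .Machine$double.eps), "viroscore_at_asymptote",
               "response at or above Bmax cannot be inverted")
      x[ok] <- p$Kd * y / (p$Bmax - y)
    }
    x[ok] <- x[ok] * dilution[ok]
  }
  data.frame(response = response, dilution = dilution, concentration = x,
             flag = flag, stringsAsFactors = FALSE)
}

#' Substitute out-of-range measurements by detection limits
#'
#' Values below the fitted range are replaced by `lower_limit / sqrt(2)`,
#' values above it by `upper_limit`; in-range values pass through. The
#' substitution is idempotent.
#'
#' @param measurements data frame from [invert_curve()] (columns
#'   `concentration` and `flag`).
#' @param lower_limit,upper_limit positive detection limits,
#'   `lower_limit < upper_limit`.
#' @return the data frame with substituted concentrations.
#' @export
substitute_out_of_range <- function(measurements, lower_limit, upper_limit) {
  vs_check(lower_limit > 0 && upper_limit > lower_limit, "viroscore_bad_limits",
           "limits must satisfy 0 < lower_limit < upper_limit")
  vs_check(all(c("concentration", "flag") %in% names(measurements)),
           "viroscore_schema", "measurements need concentration and flag columns")
  m <- measurements
  m$concentration[m$flag == "below_fit"] <- lower_limit / sqrt(2)
  m$concentration[m$flag == "above_fit"] <- upper_limit
  m
}

#' Plaque-assay viral titer
#'
#' `PFU/mL = mean(countable plaques) * dilution_factor / infection_volume`,
#' where only wells with a countable number of isolated plaques (between 5
#' and 50, inclusive) enter the mean.
#'
#' @param plaque_counts integer plaque counts per well at one dilution.
#' @param dilution_factor fold dilution of the counted wells (e.g. `1e5`).
#' @param infection_volume_ml inoculum volume in mL.
#' @param countable inclusive countable window, default `c(5, 50)`.
#' @return titer in PFU/mL.
#' @examples
#' plaque_titer(c(20, 30), dilution_factor = 1e5, infection_volume_ml = 0.5) # 5e6
#' @export
plaque_titer <- function(plaque_counts, dilution_factor, infection_volume_ml,
                         countable = c(5, 50)) {
  vs_check(length(plaque_counts) >= 1 && all(plaque_counts >= 0) &&
           all(plaque_counts == round(plaque_counts)), "viroscore_bad_counts",
           "plaque counts must be non-negative integers")
  vs_check(dilution_factor > 0 && infection_volume_ml > 0, "viroscore_bad_inputs",
           "dilution factor and infection volume must be positive")
  keep <- plaque_counts >= countable[[1]] & plaque_counts <= countable[[2]]
  vs_check(any(keep), "viroscore_nothing_countable",
           "no well in the countable window [%g, %g]; counts were: %s",
           countable[[1]], countable[[2]], paste(plaque_counts, collapse = ", "))
  mean(plaque_counts[keep]) * dilution_factor / infection_volume_ml
}
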