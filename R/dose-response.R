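#' Blank-correct and normalise fluorescence by optical density
#'
#' Plate-reader fluorescence and OD600 are corrected by subtracting the
#' cell-free medium blanks, then fluorescence is normalised by the corrected
#' optical density:
#' `(fluorescence - fluorescence_blank) / (od - od_blank)`.
#' Points whose corrected OD is not positive carry no usable cell signal and
#' are flagged invalid (they are excluded from fits).
#'
#' @param data tibble with columns `fluorescence`, `od`,
#'   `fluorescence_blank`, `od_blank` (other columns pass through).
#' @return the input with two added columns: `response` (normalised
#'   fluorescence, `NA` for invalid points) and `valid` (logical).
#' @examples
#' normalize_fluorescence(tibble::tibble(
#'   fluorescence = 1000, od = 0.5, fluorescence_blank = 100, od_blank = 0.05
#' ))
#' @export
normalize_fluorescence <- function(data) {
  stopifnot(all(c("fluorescence", "od", "fluorescence_blank", "od_blank")
                %in% names(data)))
  data |>
    mutate(
      valid = (od - od_blank) > 0,
      response = ifelse(valid,
                        (fluorescence - fluorescence_blank) / (od - od_blank),
                        NA_real_)
    )
}

#' Hill dose-response function
#'
#' `b0 + (bmax - b0) * conc^h / (km^h + conc^h)`: the four-parameter
#' sigmoidal model relating inducer concentration to reporter output. At
#' `conc = km` the response is the midpoint `(b0 + bmax) / 2`; at `conc = 0`
#' it is the basal response `b0`.
#'
#' @param conc inducer concentration(s), uM, >= 0.
#' @param b0 basal response.
#' @param bmax maximal response.
#' @param km half-maximal inducer concentration (uM), > 0.
#' @param h Hill coefficient, > 0.
#' @return numeric vector of responses.
#' @export
hill_response <- function(conc, b0, bmax, km, h) {
  stopifnot(all(conc >= 0), km > 0, h > 0)
  # conc^h with conc = 0 is 0 for h > 0; R handles 0^positive correctly
  b0 + (bmax - b0) * conc^h / (km^h + conc^h)
}

#' Fit a Hill function to dose-response data
#'
#' Bounded Levenberg-Marquardt least squares on the four-parameter Hill
#' model. Initialisation: `b0` = minimum response, `bmax` = maximum response,
#' `km` = dose at half span (log-interpolated between the bracketing doses),
#' `h` = 1; bounds `h` in (0, 10], `km` in (0, 10 * max dose]. The fit is
#' deterministic for given data. Uninduced (zero-concentration) wells enter
#' the fit at `conc = 0`.
#'
#' @param data tibble with columns `inducer_conc_uM` and `response`
#'   (normalised fluorescence), or raw plate columns accepted by
#'   [normalize_fluorescence()], which is then applied first. Invalid points
#'   are excluded.
#' @param seed unused (the optimiser is deterministic); accepted so callers
#'   can treat all fitting entry points uniformly.
#' @return object of class `hill_fit`: parameters (`b0`, `bmax`, `km`, `h`),
#'   `residual_norm`, `converged` (logical), `message`, `n_points`, and the
#'   fitted data. Non-convergence or degenerate input (e.g. constant
#'   responses) yields `converged = FALSE` with a diagnostic message rather
#'   than an error.
#' @export
fit_hill <- function(data, seed = NULL) {
  data <- as_tibble(data)
  if (!"response" %in% names(data)) {
    data <- normalize_fluorescence(data)
  }
  if (!"valid" %in% names(data)) data$valid <- !is.na(data$response)
  stopifnot("inducer_conc_uM" %in% names(data))
  pts <- filter(data, valid, !is.na(response))

  fail <- function(msg) {
    structure(
      list(b0 = NA_real_, bmax = NA_real_, km = NA_real_, h = NA_real_,
           residual_norm = NA_real_, converged = FALSE, message = msg,
           n_points = nrow(pts), data = pts),
      class = "hill_fit"
    )
  }
  if (nrow(pts) < 5) {
    return(fail(sprintf("need >= 5 valid points, got %d", nrow(pts))))
  }
  if (diff(range(pts$response)) <= 0 ||
      stats::sd(pts$response) < 1e-12 * max(abs(pts$response), 1)) {
    return(fail("responses are constant; no transition to fit"))
  }

  mean_by_dose <- pts |>
    group_by(inducer_conc_uM) |>
    summarise(response = mean(response)) |>
    arrange(inducer_conc_uM)
  b0_init <- min(mean_by_dose$response)
  bmax_init <- max(mean_by_dose$response)
  half <- (b0_init + bmax_init) / 2
  pos <- filter(mean_by_dose, inducer_conc_uM > 0)
  km_init <- if (nrow(pos) >= 2) {
    # log-interpolate the dose at half span along the mean curve
    ap <- approx(x = pos$response, y = log(pos$inducer_conc_uM), xout = half,
                 ties = mean, rule = 2)
    exp(ap$y)
  } else {
    max(pts$inducer_conc_uM, 1)
  }
  max_dose <- max(pts$inducer_conc_uM)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ b0 + (bmax - b0) * inducer_conc_uM^h /
        (km^h + inducer_conc_uM^h),
      data = pts,
      start = list(b0 = b0_init, bmax = bmax_init, km = km_init, h = 1),
      lower = c(b0 = -Inf, bmax = -Inf, km = 1e-9, h = 1e-6),
      upper = c(b0 = Inf, bmax = Inf, km = 10 * max_dose, h = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  est <- coef(fit)
  out <- structure(
    list(b0 = unname(est["b0"]), bmax = unname(est["bmax"]),
         km = unname(est["km"]), h = unname(est["h"]),
         residual_norm = sqrt(sum(resid(fit)^2)),
         converged = fit$convInfo$isConv %||% TRUE,
         message = "converged", n_points = nrow(pts), data = pts),
    class = "hill_fit"
  )
  if (!is.na(out$bmax) && !is.na(out$b0) && out$bmax <= out$b0) {
    out$converged <- FALSE
    out$message <- "degenerate fit: bmax <= b0"
  }
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> FAILED:", x$message, sprintf("(n = %d)\n", x$n_points))
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> b0 = %.4g, bmax = %.4g, Km = %.4g uM, h = %.3g (n = %d, resid norm = %.4g)\n",
    x$b0, x$bmax, x$km, x$h, x$n_points, x$residual_norm
  ))
  rng <- operational_range(x)
  cat(sprintf("  operational range (5-95%%): %.4g - %.4g uM\n",
              rng$lower, rng$upper))
  invisible(x)
}

#' Predicted Hill response at new concentrations
#' @param object a converged `hill_fit`.
#' @param newdata optional tibble with `inducer_conc_uM` (default: the fitted
#'   data).
#' @param ... ignored.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  stopifnot(object$converged)
  conc <- if (is.null(newdata)) object$data$inducer_conc_uM else newdata$inducer_conc_uM
  hill_response(conc, object$b0, object$bmax, object$km, object$h)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hill fit into one row per parameter
#' @param x a `hill_fit`.
#' @param ... ignored.
#' @return tibble with columns `term` and `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("b0", "bmax", "km", "h"),
    estimate = c(x$b0, x$bmax, x$km, x$h)
  )
}

#' One-row summary of a Hill fit
#' @param x a `hill_fit`.
#' @param ... ignored.
#' @return tibble with the parameters, residual norm, convergence flag,
#'   number of points and the 5-95% operational range bounds.
#' @export
glance.hill_fit <- function(x, ...) {
  rng <- if (x$converged) operational_range(x) else tibble(lower = NA_real_, upper = NA_real_)
  tibble(
    b0 = x$b0, bmax = x$bmax, km = x$km, h = x$h,
    residual_norm = x$residual_norm, converged = x$converged,
    n_points = x$n_points,
    range_lower = rng$lower, range_upper = rng$upper
  )
}

#' Operational range of a sensor from its Hill parameters
#'
#' The inducer concentration interval over which the reporter output runs
#' from `lo` to `hi` of the span above basal. With the fractional response
#' `f = (y - b0) / (bmax - b0)`, the Hill model inverts in closed form to
#' `I(f) = km * (f / (1 - f))^(1/h)`, evaluated at `f = lo` and `f = hi`
#' (defaults 5% and 95%). When `hi == 1 - lo` the bounds satisfy
#' `I(lo) * I(hi) == km^2`.
#'
#' @param fit a converged `hill_fit`, or `NULL` when `km` and `h` are given
#'   directly.
#' @param km,h Hill parameters, used when `fit` is `NULL`.
#' @param lo,hi fractional response bounds, `0 < lo < hi < 1`.
#' @return tibble with columns `lower` and `upper` (uM).
#' @examples
#' operational_range(km = 167, h = 2.13) # ~42 to ~665 uM
#' @export
operational_range <- function(fit = NULL, km = NULL, h = NULL,
                              lo = 0.05, hi = 0.95) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "hill_fit"))
    if (!fit$converged) abort("cannot compute operational range of a failed fit")
    km <- fit$km
    h <- fit$h
  }
  stopifnot(is.numeric(km), is.numeric(h), km > 0, h > 0,
            lo > 0, hi < 1, lo < hi)
  inv <- function(f) km * (f / (1 - f))^(1 / h)
  tibble(lower = inv(lo), upper = inv(hi))
}

#' Plot a Hill dose-response fit
#'
#' Points are the normalised measurements; the line is the fitted curve on a
#' log10 concentration axis (zero-concentration wells are drawn at half the
#' smallest positive dose); dashed verticals mark the 5-95% operational
#' range.
#'
#' @param object a converged `hill_fit`.
#' @param n_curve points used to draw the curve (default 200).
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.hill_fit <- function(object, n_curve = 200, ...) {
  stopifnot(object$converged)
  pts <- object$data
  pos <- pts$inducer_conc_uM[pts$inducer_conc_uM > 0]
  floor_conc <- min(pos) / 2
  pts$conc_plot <- pmax(pts$inducer_conc_uM, floor_conc)
  curve <- tibble(
    inducer_conc_uM = exp(seq(log(floor_conc), log(max(pos)), length.out = n_curve))
  )
  curve$response <- predict(object, curve)
  rng <- operational_range(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc_plot, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$inducer_conc_uM, y = .data$response)) +
    ggplot2::geom_vline(xintercept = c(rng$lower, rng$upper), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inducer concentration (uM)",
                  y = "normalised fluorescence (a.u.)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
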