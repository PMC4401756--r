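#' Fit a cross-species phenotype-function interface model
#'
#' Regresses a plant-side response (by default the mean EFN abundance of the
#' plants each ant species visits) on a functional ant trait across species,
#' with jackknife inference and the quantities needed for mean-response
#' confidence bands. Only species that visited more than five plants
#' (\code{eligible} in the profile table) enter the fit. Hypothesized
#' directions follow the biology of ant-EFN protection mutualisms: EFN
#' abundance is expected to increase with ant body size and decrease with
#' recruitment; herbivory is expected to decrease with recruitment, while no
#' direction is assumed for herbivory vs size.
#'
#' @param profiles An \code{ant_species_profiles} data frame from
#'   [species_profiles()].
#' @param predictor \code{"size"} (body length, mm) or \code{"recruitment"}
#'   (ants per 100 leaves).
#' @param response \code{"efn"} (mean EFN per leaflet of visited plants) or
#'   \code{"herbivory"} (mean damage fraction of visited plants).
#' @param tail Hypothesis direction; \code{NULL} (default) selects the
#'   stated direction for the predictor/response pair: efn~size positive,
#'   efn~recruitment negative, herbivory~recruitment negative,
#'   herbivory~size two-sided.
#' @param transform Transform for the predictor: \code{"log10"} (default
#'   for recruitment, whose max-based distribution is strongly right-skewed)
#'   or \code{"identity"}. \code{NULL} picks the default per predictor.
#' @param alpha Band level for downstream classification (default 0.05).
#' @return Object of class \code{interface_model}: the
#'   \code{jackknife_regression} fit plus \code{predictor}, \code{response},
#'   \code{transform}, \code{alpha}, \code{n_species}.
#' @seealso [predict_band()], [classify_matching()]
#' @export
fit_interface <- function(profiles, predictor = c("size", "recruitment"),
                          response = c("efn", "herbivory"),
                          tail = NULL, transform = NULL, alpha = 0.05) {
  predictor <- match.arg(predictor)
  response <- match.arg(response)
  el <- profiles[profiles$eligible, , drop = FALSE]
  if (nrow(el) < 4L) stop("fewer than 4 eligible species profiles")
  x_raw <- switch(predictor, size = el$body_length_mm, recruitment = el$recruitment)
  y <- switch(response, efn = el$mean_efn_visited, herbivory = el$mean_herbivory_visited)
  transform <- transform %||% if (predictor == "recruitment") "log10" else "identity"
  if (!transform %in% c("identity", "log10")) stop("unknown transform: ", transform)
  if (transform == "log10" && any(x_raw <= 0)) stop("log10 transform needs positive predictor values")
  x <- if (transform == "log10") log10(x_raw) else x_raw
  tail <- tail %||% default_tail(predictor, response)
  fit <- jackknife_regression(x, y, tail = tail)
  structure(c(unclass(fit),
              list(predictor = predictor, response = response,
                   transform = transform, alpha = alpha,
                   n_species = nrow(el), species = el$species)),
            class = c("interface_model", "jackknife_regression"))
}

default_tail <- function(predictor, response) {
  if (response == "efn") {
    if (predictor == "size") "positive" else "negative"
  } else {
    if (predictor == "recruitment") "negative" else "two.sided"
  }
}

#' Mean-response confidence band of an interface regression
#'
#' Predicted response and the confidence band for the mean response at a
#' new predictor value: \code{yhat +/- t(1 - alpha/2, n - 2) * s *
#' sqrt(1/n + (x0 - x_bar)^2 / Sxx)}. The band is narrowest at the
#' predictor mean and widens symmetrically away from it.
#'
#' @param model An \code{interface_model} or \code{jackknife_regression}.
#' @param x0 Predictor value(s), on the model's (transformed) predictor
#'   scale.
#' @param alpha Band level (default: the model's \code{alpha}, else 0.05).
#' @return Data frame with columns \code{x0, fit, lower, upper}.
#' @export
predict_band <- function(model, x0, alpha = NULL) {
  alpha <- alpha %||% model$alpha %||% 0.05
  if (anyNA(x0) || any(!is.finite(x0))) stop("x0 must be finite")
  n <- model$n
  yhat <- model$intercept + model$slope * x0
  half <- stats::qt(1 - alpha / 2, df = n - 2L) * model$s *
    sqrt(1 / n + (x0 - model$x_bar)^2 / model$sxx)
  data.frame(x0 = x0, fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Table of interface fits for the standard predictor-response pairs
#'
#' Convenience wrapper fitting the bivariate relationships that make up the
#' ant-EFN phenotypic interface: EFN abundance vs ant size and recruitment,
#' herbivory vs size and recruitment, and the size-recruitment trade-off
#' across species (jackknife regression of log10 recruitment on size,
#' negative one-tailed).
#'
#' @inheritParams fit_interface
#' @return Data frame \code{interface_fits}: one row per relationship with
#'   slope, jackknife estimate, SE, t, p, tail, transform and n.
#' @export
interface_fit_table <- function(profiles, alpha = 0.05) {
  el <- profiles[profiles$eligible, , drop = FALSE]
  fits <- list(
    efn_vs_size = fit_interface(profiles, "size", "efn", alpha = alpha),
    efn_vs_recruitment = fit_interface(profiles, "recruitment", "efn", alpha = alpha),
    herbivory_vs_size = fit_interface(profiles, "size", "herbivory", alpha = alpha),
    herbivory_vs_recruitment = fit_interface(profiles, "recruitment", "herbivory", alpha = alpha)
  )
  tr <- jackknife_regression(el$body_length_mm, log10(el$recruitment), tail = "negative")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(relationship = nm, slope = f$slope, jackknife_slope = f$estimate,
               se = f$se, t = f$t, p = f$p, tail = f$tail,
               transform = f$transform, n = f$n)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    relationship = "recruitment_vs_size", slope = tr$slope,
    jackknife_slope = tr$estimate, se = tr$se, t = tr$t, p = tr$p,
    tail = tr$tail, transform = "log10(response)", n = tr$n)
  do.call(rbind, rows)
}

#' @export
print.interface_model <- function(x, ...) {
  cat(sprintf("Interface model: mean %s ~ %s(%s) across %d ant species\n",
              x$response, x$transform, x$predictor, x$n_species))
  cat(sprintf("  OLS slope %.4g; jackknife %.4g +/- %.4g; t = %.3g, p = %.4g [%s]\n",
              x$slope, x$estimate, x$se, x$t, x$p, x$tail))
  invisible(x)
}
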