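#' Code a natural factor level to the [-1, 1] scale
#'
#' Standard factorial coding: \code{coded = (x - center) / half_range}.
#' \code{decode_levels} is the exact inverse.
#'
#' @param x natural value (e.g. minutes, mg)
#' @param center factor center
#' @param half_range half the factor range (> 0)
#' @return coded value (dimensionless)
#' @export
code_levels <- function(x, center, half_range) {
  if (!is.numeric(half_range) || any(half_range <= 0)) {
    stop("half_range must be positive", call. = FALSE)
  }
  (x - center) / half_range
}

#' @rdname code_levels
#' @param coded coded value
#' @export
decode_levels <- function(coded, center, half_range) {
  if (!is.numeric(half_range) || any(half_range <= 0)) {
    stop("half_range must be positive", call. = FALSE)
  }
  center + coded * half_range
}

#' The shipped pesticide-retention factorial design
#'
#' The 2^2 + 3 center-point design used to characterize dimethoate
#' retention by the 20 wt-% malic-acid hydrogel: factor A is contact
#' time (10-90 min), factor B is hydrogel mass (34.2-101.3 mg), response
#' is the retention percentage. The coded levels are the exact values
#' used in the original design (the center points carry small non-zero
#' B codes because the weighed masses deviate from the nominal center).
#'
#' @return data frame with columns \code{run}, \code{time_min},
#'   \code{coded_A}, \code{mass_mg}, \code{coded_B},
#'   \code{retention_pct}
#' @export
doe_design_table <- function() {
  path <- system.file("extdata", "retention_design.csv",
                      package = "hydrosieve", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit the two-factor interaction model to a factorial design
#'
#' Ordinary least squares for
#' \deqn{y = b_0 + b_1 A + b_2 B + b_3 AB + \varepsilon}
#' using the design's coded values exactly as given. The fit is
#' delegated to \code{\link[stats]{lm}}; the model object is returned
#' for diagnostics. R-squared is reported on the percent scale.
#'
#' @param design data frame with columns \code{coded_A}, \code{coded_B}
#'   and a response column (\code{retention_pct} or \code{response})
#' @return a \code{doe_model}: list with \code{coefficients} (b0, b1,
#'   b2, b3), \code{r_squared} (percent), \code{standard_errors},
#'   \code{t_values}, \code{df}, \code{critical_t_95}, \code{fit} (the
#'   underlying \code{lm})
#' @export
fit_interaction_model <- function(design) {
  y <- design$retention_pct
  if (is.null(y)) y <- design$response
  if (is.null(y)) {
    stop("design needs a 'retention_pct' or 'response' column",
         call. = FALSE)
  }
  A <- design$coded_A
  B <- design$coded_B
  if (length(y) < 5) {
    stop("need at least 5 runs to fit 4 parameters with df >= 1",
         call. = FALSE)
  }
  X <- cbind(1, A, B, A * B)
  if (qr(X)$rank < 4) {
    stop("singular design: the model matrix [1, A, B, AB] is rank ",
         "deficient", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("undefined R-squared: response has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ A + B + I(A * B))
  # summary.lm warns on noiseless data ("essentially perfect fit");
  # exact recovery is a legitimate use here
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  df <- fit$df.residual
  structure(list(
    coefficients = stats::setNames(co[, "Estimate"],
                                   c("b0", "b1", "b2", "b3")),
    standard_errors = stats::setNames(co[, "Std. Error"],
                                      c("b0", "b1", "b2", "b3")),
    t_values = stats::setNames(co[, "t value"],
                               c("b0", "b1", "b2", "b3")),
    r_squared = 100 * sm$r.squared,
    df = df,
    critical_t_95 = stats::qt(0.975, df),
    fit = fit), class = "doe_model")
}

#' @export
print.doe_model <- function(x, ...) {
  b <- x$coefficients
  cat(sprintf(
    "retention%% = %.2f %+.2f A %+.2f B %+.2f AB   (R2 = %.2f%%)\n",
    b[1], b[2], b[3], b[4], x$r_squared))
  cat(sprintf("df = %d, critical |t| (95%%) = %.3f\n", x$df,
              x$critical_t_95))
  invisible(x)
}

#' Standardized effects and 95\% significance flags
#'
#' The standardized (Pareto) effect of each model term is
#' \code{t = b / SE(b)}; a term is significant at the 95\% level when
#' \code{|t|} exceeds the two-sided Student-t critical value with the
#' fit's residual degrees of freedom.
#'
#' @param model a \code{doe_model}
#' @return data frame with columns \code{term}, \code{estimate},
#'   \code{t_value}, \code{abs_t}, \code{critical_t}, \code{significant}
#'   for the A, B and AB terms
#' @export
standardized_effects <- function(model) {
  if (model$df < 1) stop("no residual degrees of freedom", call. = FALSE)
  terms <- c("A", "B", "AB")
  t <- model$t_values[2:4]
  data.frame(term = terms,
             estimate = unname(model$coefficients[2:4]),
             t_value = unname(t),
             abs_t = unname(abs(t)),
             critical_t = model$critical_t_95,
             significant = unname(abs(t) >= model$critical_t_95),
             stringsAsFactors = FALSE)
}

#' Evaluate the fitted response surface on a coded grid
#'
#' @param model a \code{doe_model}
#' @param grid_a,grid_b coded grid values (default 41 points over
#'   [-1, 1])
#' @return data frame with columns \code{A}, \code{B},
#'   \code{predicted}; the grid argmax is attached as attribute
#'   \code{argmax} (list with A, B, value)
#' @export
response_surface <- function(model, grid_a = seq(-1, 1, length.out = 41),
                             grid_b = seq(-1, 1, length.out = 41)) {
  if (length(grid_a) < 1 || length(grid_b) < 1) {
    stop("empty response-surface grid", call. = FALSE)
  }
  g <- expand.grid(A = grid_a, B = grid_b)
  b <- model$coefficients
  g$predicted <- b[1] + b[2] * g$A + b[3] * g$B + b[4] * g$A * g$B
  k <- which.max(g$predicted)
  attr(g, "argmax") <- list(A = g$A[k], B = g$B[k], value = g$predicted[k])
  g
}

#' Absorption percentage from absorbance readings
#'
#' \deqn{Absorption\% = (A_0 - A) / A_0 \times 100}
#' where \code{a0} is the initial and \code{a} the final absorbance at
#' the monitored wavelength (280 nm for dimethoate).
#'
#' @param a0 initial absorbance (> 0)
#' @param a final absorbance
#' @return percent absorbed
#' @export
absorption_percent <- function(a0, a) {
  if (!is.numeric(a0) || any(a0 <= 0)) {
    stop("initial absorbance a0 must be positive", call. = FALSE)
  }
  (a0 - a) / a0 * 100
}

#' Recover factor coding parameters from printed (value, code) pairs
#'
#' Given natural values and their published coded levels, recovers the
#' (center, half_range) pair by least squares on
#' \code{value = center + half_range * code}.
#'
#' @param values natural factor values
#' @param codes corresponding coded levels
#' @return list with \code{center} and \code{half_range}
#' @export
recover_coding <- function(values, codes) {
  fit <- stats::lm(values ~ codes)
  list(center = unname(stats::coef(fit)[1]),
       half_range = unname(stats::coef(fit)[2]))
}
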