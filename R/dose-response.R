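#' Saturating DNA dose-response model
#'
#' Suppression as a function of delivered DNA dose:
#' `S(D) = 1 + (sup_max - 1) * D / (dd50 + D)` — a rectangular hyperbola
#' anchored at the no-tRNA baseline `S(0) = 1` (forced by the ratio
#' definition), saturating at `sup_max`, with half-maximal response above
#' baseline at `D = dd50` (ng/ul). An optional Hill exponent `h` allows
#' sensitivity analysis: `S(D) = 1 + (sup_max-1) * D^h / (dd50^h + D^h)`.
#'
#' @param D dose(s), ng/ul, >= 0.
#' @param sup_max maximal suppression ratio (>= 1).
#' @param dd50 dose of half-maximal suppression (> 0).
#' @param hill Hill exponent (default 1).
#' @return Predicted suppression ratio(s).
#' @export
dose_model <- function(D, sup_max, dd50, hill = 1) {
  if (dd50 <= 0) stopf("dd50 must be > 0")
  if (sup_max < 1) stopf("sup_max must be >= 1")
  1 + (sup_max - 1) * D^hill / (dd50^hill + D^hill)
}

#' Fit the DNA dose-response model
#'
#' Least-squares fit of [dose_model] to suppression ratios over a dose
#' grid, estimating `sup_max` (maximal suppression) and `dd50` (DNA dose,
#' ng/ul, giving half-maximal suppression). Starting values are
#' `sup_max = max(ratio)` and `dd50 =` the dose whose mean ratio is
#' nearest `(1 + max(ratio)) / 2`; bounds keep `sup_max >= 1`,
#' `dd50 > 0`. Optional bootstrap (resampling replicates within dose)
#' yields percentile confidence intervals.
#'
#' Flat data (all ratios ~ 1) fit `sup_max ~ 1` but leave `dd50`
#' unidentifiable; this is flagged rather than an error.
#'
#' @param data data.frame with columns `dose` (ng/ul) and `ratio`
#'   (normalized suppression ratio, > 0); an optional `replicate` column
#'   is used for bootstrap resampling.
#' @param hill fixed Hill exponent (default 1, the declared model).
#' @param boot number of bootstrap resamples for CIs (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level for percentile CIs.
#' @return Object of class `"dose_fit"` with elements `sup_max`, `dd50`,
#'   `hill`, `rss`, `n`, `data`, `fitted`, `unidentifiable`,
#'   `ci_sup_max`, `ci_dd50`, `boot`.
#' @export
fit_dose_response <- function(data, hill = 1, boot = 0, seed = 1,
                              conf = 0.95) {
  if (!all(c("dose", "ratio") %in% names(data)))
    stopf("data needs columns dose and ratio")
  if (any(data$dose < 0)) stopf("doses must be >= 0")
  if (any(data$ratio <= 0)) stopf("ratios must be > 0")
  if (length(unique(data$dose)) < 3)
    stopf("need >= 3 distinct doses to fit")
  est <- fit_dose_core(data, hill)
  fit <- structure(
    list(sup_max = est$sup_max, dd50 = est$dd50, hill = hill,
         rss = est$rss, n = nrow(data), data = data,
         fitted = if (est$unidentifiable) rep(est$sup_max, nrow(data))
                  else dose_model(data$dose, est$sup_max, est$dd50, hill),
         unidentifiable = est$unidentifiable,
         ci_sup_max = NULL, ci_dd50 = NULL, boot = NULL),
    class = "dose_fit")
  if (boot > 0) {
    bs <- with_seed(seed, boot_dose(data, hill, boot))
    a <- (1 - conf) / 2
    fit$ci_sup_max <- stats::quantile(bs$sup_max, c(a, 1 - a), na.rm = TRUE)
    fit$ci_dd50 <- stats::quantile(bs$dd50, c(a, 1 - a), na.rm = TRUE)
    fit$boot <- bs
  }
  fit
}

#' @noRd
fit_dose_core <- function(data, hill) {
  mx <- max(data$ratio)
  # flat data: the dose term is unidentifiable
  if (mx - min(data$ratio) < 1e-8 || mx <= 1 + 1e-8) {
    return(list(sup_max = mean(data$ratio), dd50 = NA_real_,
                rss = sum((data$ratio - mean(data$ratio))^2),
                unidentifiable = TRUE))
  }
  half <- (1 + mx) / 2
  mean_by_dose <- tapply(data$ratio, data$dose, mean)
  doses <- as.numeric(names(mean_by_dose))
  dd50_0 <- doses[which.min(abs(mean_by_dose - half))]
  if (dd50_0 <= 0) dd50_0 <- min(doses[doses > 0], 1)
  fit <- minpack.lm::nlsLM(
    ratio ~ 1 + (sup_max - 1) * dose^hill / (dd50^hill + dose^hill),
    data = data,
    start = list(sup_max = mx, dd50 = dd50_0),
    lower = c(sup_max = 1, dd50 = .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  co <- stats::coef(fit)
  list(sup_max = unname(co["sup_max"]), dd50 = unname(co["dd50"]),
       rss = sum(stats::resid(fit)^2), unidentifiable = FALSE)
}

# Bootstrap by resampling replicate series (or rows, lacking replicates).
#' @noRd
boot_dose <- function(data, hill, boot) {
  out <- data.frame(sup_max = rep(NA_real_, boot), dd50 = NA_real_)
  by_rep <- !is.null(data$replicate)
  reps <- if (by_rep) unique(data$replicate)
  for (b in seq_len(boot)) {
    smp <- if (by_rep) {
      pick <- sample(reps, length(reps), replace = TRUE)
      do.call(rbind, lapply(pick, function(r)
        data[data$replicate == r, , drop = FALSE]))
    } else data[sample(nrow(data), replace = TRUE), , drop = FALSE]
    est <- tryCatch(fit_dose_core(smp, hill), error = function(e) NULL)
    if (!is.null(est)) {
      out$sup_max[b] <- est$sup_max
      out$dd50[b] <- est$dd50
    }
  }
  out
}

#' Invert the dose-response model
#'
#' Analytic dose that produces a given suppression level:
#' `D = dd50 * ((level - 1) / (sup_max - level))^(1/hill)`.
#'
#' @param fit a `"dose_fit"` (or list with `sup_max`, `dd50`, `hill`).
#' @param level target suppression ratio, `1 < level < sup_max`.
#' @return Dose in ng/ul.
#' @export
dose_at_level <- function(fit, level) {
  h <- if (is.null(fit$hill)) 1 else fit$hill
  if (level <= 1 || level >= fit$sup_max)
    stopf("level %.3g unreachable for fit with sup_max %.3g",
          level, fit$sup_max)
  fit$dd50 * ((level - 1) / (fit$sup_max - level))^(1 / h)
}

#' Dose-sparing factor between two cassettes
#'
#' How much less DNA cassette `a` needs than cassette `b` to reach the
#' same suppression level: `D_b(level) / D_a(level)` with the analytic
#' inversion [dose_at_level]. At the shared half-maximal level of two fits
#' with equal `sup_max` this is exactly their `dd50` ratio. The paper-style
#' headline "16-fold less DNA" is this quantity.
#'
#' @param fit_a,fit_b `"dose_fit"` objects (a = optimized, b = original).
#' @param level suppression level at which to compare; must be reachable
#'   by both fits.
#' @return Fold sparing (> 1 means `a` needs less DNA).
#' @export
dose_sparing <- function(fit_a, fit_b, level) {
  dose_at_level(fit_b, level) / dose_at_level(fit_a, level)
}

#' @export
print.dose_fit <- function(x, ...) {
  cat("Saturating dose-response fit\n")
  cat(sprintf("  sup_max = %.4g%s\n", x$sup_max,
              if (!is.null(x$ci_sup_max))
                sprintf("  [%.4g, %.4g]", x$ci_sup_max[1], x$ci_sup_max[2])
              else ""))
  if (x$unidentifiable) {
    cat("  dd50    = unidentifiable (flat response)\n")
  } else {
    cat(sprintf("  dd50    = %.4g ng/ul%s\n", x$dd50,
                if (!is.null(x$ci_dd50))
                  sprintf("  [%.4g, %.4g]", x$ci_dd50[1], x$ci_dd50[2])
                else ""))
  }
  cat(sprintf("  hill = %g, n = %d, RSS = %.4g\n", x$hill, x$n, x$rss))
  invisible(x)
}

#' @export
summary.dose_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  S(dd50) = %.4g (midpoint identity: (1 + sup_max)/2)\n",
              if (object$unidentifiable) NA
              else dose_model(object$dd50, object$sup_max, object$dd50,
                              object$hill)))
  invisible(object)
}

#' @export
coef.dose_fit <- function(object, ...) {
  c(sup_max = object$sup_max, dd50 = object$dd50)
}

#' @export
predict.dose_fit <- function(object, newdata = NULL, ...) {
  D <- if (is.null(newdata)) object$data$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  dose_model(D, object$sup_max, object$dd50, object$hill)
}

#' @export
residuals.dose_fit <- function(object, ...) {
  object$data$ratio - object$fitted
}

#' @export
plot.dose_fit <- function(x, ...) {
  graphics::plot(x$data$dose, x$data$ratio, log = "x",
                 xlab = "delivered DNA (ng/ul)",
                 ylab = "normalized suppression ratio", ...)
  grid <- exp(seq(log(max(min(x$data$dose[x$data$dose > 0]), 1e-3) / 4),
                  log(max(x$data$dose) * 2), length.out = 200))
  graphics::lines(grid, dose_model(grid, x$sup_max, x$dd50, x$hill))
  if (!x$unidentifiable)
    graphics::abline(v = x$dd50, lty = 2)
  invisible(x)
}

#' @export
simulate.dose_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1, ...) {
  sim1 <- function() {
    mu <- object$fitted
    sdlog <- sqrt(log(1 + cv^2))
    mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  }
  code <- function() as.data.frame(replicate(nsim, sim1()))
  out <- if (is.null(seed)) code() else with_seed(seed, code())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
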