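# Self-assembly metal-binding equilibria: n peptide chains + 1 metal form
# MP_n with K_D = [M]^(1/n) [P] / [MP_n]^(1/n)  (the dissociation constant
# on this scale collapses dimensionally to molar and is what the reported
# micromolar values refer to, with n = 2).  Direct titrations, two-metal
# competition, and the two-state pH transition are solved and fitted here.

#' Solve the single-metal self-assembly equilibrium
#'
#' Mass balances P_t = [P] + n [MP_n], M_t = [M] + [MP_n] with
#' [MP_n] = [M] [P]^n / K_D^n are reduced to a monotone one-dimensional
#' root problem in free peptide and solved by bracketed root finding.
#'
#' @param P_t total peptide (monomer units), M
#' @param M_t total metal, M
#' @param K_D dissociation constant, M (on the 1/n-power scale above)
#' @param n stoichiometry, peptides per metal (default 2)
#' @return list with \code{P_f}, \code{M_f}, \code{complex} (all M) and
#'   the saturation fraction \code{Y} = n [MP_n] / P_t
#' @export
solve_single <- function(P_t, M_t, K_D, n = 2) {
  stopifnot(P_t > 0, M_t >= 0, K_D > 0, n >= 1)
  if (M_t == 0)
    return(list(P_f = P_t, M_f = 0, complex = 0, Y = 0))
  cplx <- function(p) M_t * p^n / (K_D^n + p^n)
  f <- function(p) p + n * cplx(p) - P_t
  root <- uniroot(f, lower = P_t * 1e-15, upper = P_t,
                  tol = .Machine$double.eps * P_t, maxiter = 2000)
  p <- root$root
  mp <- cplx(p)
  list(P_f = p, M_f = M_t - mp, complex = mp, Y = n * mp / P_t)
}

#' Solve the two-metal competition equilibrium
#'
#' Metals 1 and 2 compete for the same n:1 peptide complex.  The exchange
#' constant K_ex = [M2P_n][M1]/[M1P_n][M2] relates the two dissociation
#' constants as K_D2 = K_D1 / K_ex^(1/n) (for n = 2, K_D2 = K_D1/sqrt(K_ex)).
#'
#' @param P_t total peptide, M
#' @param M1_t,M2_t total concentrations of metal 1 (e.g. Co) and metal 2
#'   (e.g. Zn), M
#' @param K_D1 dissociation constant of metal 1, M
#' @param K_ex exchange equilibrium constant (> 0)
#' @param n stoichiometry (default 2)
#' @return list with \code{P_f}, per-metal free and complex
#'   concentrations, saturation fractions \code{Y1}, \code{Y2}, and the
#'   implied \code{K_D2}
#' @export
solve_competition <- function(P_t, M1_t, M2_t, K_D1, K_ex, n = 2) {
  stopifnot(P_t > 0, M1_t >= 0, M2_t >= 0, K_D1 > 0, K_ex > 0)
  K_D2 <- K_D1 / K_ex^(1 / n)
  c1 <- function(p) M1_t * p^n / (K_D1^n + p^n)
  c2 <- function(p) M2_t * p^n / (K_D2^n + p^n)
  f <- function(p) p + n * (c1(p) + c2(p)) - P_t
  root <- uniroot(f, lower = P_t * 1e-15, upper = P_t,
                  tol = .Machine$double.eps * P_t, maxiter = 2000)
  p <- root$root
  mp1 <- c1(p); mp2 <- c2(p)
  list(P_f = p, M1_f = M1_t - mp1, M2_f = M2_t - mp2,
       complex1 = mp1, complex2 = mp2,
       Y1 = n * mp1 / P_t, Y2 = n * mp2 / P_t, K_D2 = K_D2)
}

# Least squares core shared by the fitters: minimizes sum (y - f(theta))^2
# over unconstrained parameters, SEs from the numerical Jacobian at the
# optimum.
.ls_fit <- function(theta0, predict_fun, y, lower = NULL, upper = NULL) {
  obj <- function(th) {
    yy <- predict_fun(th)
    if (any(!is.finite(yy))) return(1e10)
    sum((y - yy)^2)
  }
  op <- if (length(theta0) > 1)
    optim(theta0, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 5000))
  else list(par = theta0)
  op <- optim(op$par, obj, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  th <- op$par
  rss <- op$value
  m <- length(y); p <- length(th)
  J <- matrix(NA_real_, m, p)
  for (j in seq_len(p)) {
    h <- max(1e-6, abs(th[j]) * 1e-6)
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    J[, j] <- (predict_fun(tp) - predict_fun(tm)) / (2 * h)
  }
  sigma2 <- if (m > p) rss / (m - p) else NA_real_
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, p, p))
  list(theta = th, se = sqrt(pmax(0, diag(cov))), rss = rss,
       fitted = predict_fun(th), n_obs = m)
}

new_binding_fit <- function(kind, estimates, se, rss, data, fitted, extra) {
  structure(c(list(kind = kind, estimates = estimates, se = se, rss = rss,
                   data = data, fitted = fitted), extra),
            class = "binding_fit")
}

#' Fit a direct titration to the self-assembly isotherm
#'
#' Unweighted least squares of observed saturation fractions against the
#' equilibrium solution, with K_D log-parameterized for positivity and the
#' stoichiometry n optionally fitted as a continuous parameter (reported
#' alongside its rounded value).
#'
#' @param data data.frame with columns \code{titrant_total_M} and
#'   \code{observed} (saturation fraction Y)
#' @param P_t total peptide concentration, M
#' @param fit_n also fit the stoichiometry (default FALSE: n fixed)
#' @param n stoichiometry used (or the starting value when fitted)
#' @param K_D_start starting K_D, M
#' @return object of class \code{binding_fit} with estimates \code{K_D}
#'   (and \code{n} if fitted), standard errors, and residual sum of squares
#' @export
fit_direct <- function(data, P_t, fit_n = FALSE, n = 2, K_D_start = 1e-4) {
  stopifnot(all(c("titrant_total_M", "observed") %in% names(data)))
  if (nrow(data) < 6 || min(data$observed) > 0.2 || max(data$observed) < 0.8)
    warning("fit_direct: fewer than 6 points or narrow Y span; ",
            "the fit may be poorly constrained")
  M <- data$titrant_total_M
  y <- data$observed
  pred <- function(th) {
    kd <- exp(th[1])
    nn <- if (fit_n) th[2] else n
    if (nn < 0.5 || nn > 6) return(rep(NA_real_, length(M)))
    vapply(M, function(m)
      if (m <= 0) 0 else solve_single(P_t, m, kd, nn)$Y, numeric(1))
  }
  th0 <- if (fit_n) c(log(K_D_start), n) else log(K_D_start)
  fit <- .ls_fit(th0, pred, y)
  kd <- exp(fit$theta[1])
  est <- c(K_D = kd)
  se <- c(K_D = kd * fit$se[1])     # delta method through the log
  if (fit_n) {
    est <- c(est, n = fit$theta[2])
    se <- c(se, n = fit$se[2])
  }
  new_binding_fit("direct", est, se, fit$rss, data, fit$fitted,
                  list(P_t = P_t, n = if (fit_n) fit$theta[2] else n,
                       n_rounded = if (fit_n) round(fit$theta[2]) else n,
                       fit_n = fit_n))
}

#' Fit a competition titration for the exchange constant
#'
#' Least squares over K_ex (log-parameterized) on the displacement curve
#' of the metal-1 saturation fraction as metal 2 is titrated in; the
#' metal-1 dissociation constant is fixed at its directly fitted value.
#' Reports K_ex and the derived K_D2 = K_D1 / K_ex^(1/n) with the SE
#' propagated through the power law.
#'
#' @param data data.frame with columns \code{titrant_total_M} (metal-2
#'   total) and \code{observed} (metal-1 saturation fraction)
#' @param K_D1 fixed dissociation constant of metal 1, M
#' @param P_t total peptide, M
#' @param M1_t total metal 1, M
#' @param n stoichiometry (default 2)
#' @param K_ex_start starting exchange constant
#' @return object of class \code{binding_fit} with estimates \code{K_ex}
#'   and \code{K_D2}
#' @export
fit_competition <- function(data, K_D1, P_t, M1_t, n = 2, K_ex_start = 100) {
  stopifnot(all(c("titrant_total_M", "observed") %in% names(data)))
  M2 <- data$titrant_total_M
  y <- data$observed
  pred <- function(th) {
    kex <- exp(th[1])
    vapply(M2, function(m)
      solve_competition(P_t, M1_t, m, K_D1, kex, n)$Y1, numeric(1))
  }
  fit <- .ls_fit(log(K_ex_start), pred, y)
  kex <- exp(fit$theta[1])
  kd2 <- K_D1 / kex^(1 / n)
  se_kex <- kex * fit$se[1]
  se_kd2 <- kd2 * fit$se[1] / n     # |d log K_D2 / d log K_ex| = 1/n
  new_binding_fit("competition",
                  c(K_ex = kex, K_D2 = kd2),
                  c(K_ex = se_kex, K_D2 = se_kd2),
                  fit$rss, data, fit$fitted,
                  list(K_D1 = K_D1, P_t = P_t, M1_t = M1_t, n = n))
}

#' Fit a two-state pH transition
#'
#' Least-squares fit of signal = low + (high - low) /
#' (1 + 10^(h (pH_mid - pH))); the midpoint is sign-agnostic (increasing
#' or decreasing transitions give the same pH_mid).
#'
#' @param ph numeric vector of pH values
#' @param signal observed signal at each pH
#' @return object of class \code{binding_fit} with estimates
#'   \code{pH_mid}, \code{hill}, \code{low}, \code{high}
#' @export
fit_ph_midpoint <- function(ph, signal) {
  stopifnot(length(ph) == length(signal), length(ph) >= 5)
  lo0 <- min(signal); hi0 <- max(signal)
  mid0 <- ph[which.min(abs(signal - (lo0 + hi0) / 2))]
  if (mid0 <= min(ph) || mid0 >= max(ph))
    stop("fit_ph_midpoint: data do not bracket a transition")
  increasing <- stats::cor(ph, signal) >= 0
  th0 <- c(mid0, 1, if (increasing) c(lo0, hi0) else c(hi0, lo0))
  pred <- function(th)
    th[3] + (th[4] - th[3]) / (1 + 10^(th[2] * (th[1] - ph)))
  fit <- .ls_fit(th0, pred, signal)
  est <- c(pH_mid = fit$theta[1], hill = fit$theta[2],
           low = fit$theta[3], high = fit$theta[4])
  se <- setNames(fit$se, names(est))
  new_binding_fit("ph", est, se, fit$rss,
                  data.frame(ph = ph, observed = signal), fit$fitted,
                  list())
}

# ---- methods ---------------------------------------------------------------

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit>", x$kind, "fit,", nrow(x$data), "points\n")
  for (nm in names(x$estimates)) {
    v <- x$estimates[[nm]]; s <- x$se[[nm]]
    if (nm %in% c("K_D", "K_D2", "K_ex") && v < 1e-2 && nm != "K_ex") {
      cat(sprintf("  %-6s %.3g M (%.2f uM) +/- %.2f uM\n",
                  nm, v, v * 1e6, s * 1e6))
    } else {
      cat(sprintf("  %-6s %.4g +/- %.2g\n", nm, v, s))
    }
  }
  cat(sprintf("  RSS: %.3g\n", x$rss))
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 sigma = sqrt(object$rss / max(1, nrow(object$data) -
                                                 length(object$estimates))),
                 residual_range = range(res)), class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD: %.4g, range [%.3g, %.3g]\n",
              x$sigma, x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) object$estimates

#' @export
residuals.binding_fit <- function(object, ...)
  object$data$observed - object$fitted

#' Predicted saturation curve from a fitted binding model
#' @param object a \code{binding_fit}
#' @param newdata optional vector of titrant totals (or pH values)
#' @param ... unused
#' @return numeric vector of predicted observables
#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    if (object$kind == "ph") object$data$ph else object$data$titrant_total_M
  } else newdata
  switch(object$kind,
    direct = vapply(x, function(m)
      if (m <= 0) 0 else solve_single(object$P_t, m,
                                      object$estimates[["K_D"]],
                                      object$n)$Y, numeric(1)),
    competition = vapply(x, function(m)
      solve_competition(object$P_t, object$M1_t, m, object$K_D1,
                        object$estimates[["K_ex"]], object$n)$Y1,
      numeric(1)),
    ph = {
      e <- object$estimates
      e[["low"]] + (e[["high"]] - e[["low"]]) /
        (1 + 10^(e[["hill"]] * (e[["pH_mid"]] - x)))
    })
}

#' @export
plot.binding_fit <- function(x, ...) {
  xx <- if (x$kind == "ph") x$data$ph else x$data$titrant_total_M
  xlab <- if (x$kind == "ph") "pH" else "titrant total (M)"
  graphics::plot(xx, x$data$observed, xlab = xlab, ylab = "observed",
                 pch = 19, ...)
  xs <- seq(min(xx), max(xx), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "firebrick")
  invisible(x)
}

#' Simulate a titration dataset from a known system
#'
#' Thin wrapper over the equilibrium solvers producing noisy saturation
#' data for a given titrant grid; reproducible per seed.
#'
#' @param P_t total peptide, M
#' @param titrant numeric vector of titrant totals, M (strictly increasing)
#' @param K_D dissociation constant, M
#' @param n stoichiometry
#' @param noise_sd additive Gaussian noise SD on Y
#' @param seed integer seed (NULL = no seeding)
#' @return data.frame (\code{titrant_total_M}, \code{observed})
#' @export
simulate_titration <- function(P_t, titrant, K_D, n = 2, noise_sd = 0,
                               seed = NULL) {
  stopifnot(noise_sd >= 0, !is.unsorted(titrant, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  y <- vapply(titrant, function(m)
    if (m <= 0) 0 else solve_single(P_t, m, K_D, n)$Y, numeric(1))
  data.frame(titrant_total_M = titrant,
             observed = y + rnorm(length(y), 0, noise_sd))
}
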