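#' Clamp raw inhibition values to the unit interval
#'
#' Negative inhibition values correspond to growth promotion rather than
#' inhibition and are set to 0 before any Bliss calculation. Values above 1
#' (viability below zero, an artifact of background subtraction) are capped
#' at 1; a warning reports how many values were capped.
#'
#' @param I numeric vector of raw inhibition fractions.
#' @return numeric vector with every value in \[0, 1\].
#' @examples
#' clampInhibition(c(-0.1, 0.4, 1.2))
#' @export
clampInhibition <- function(I) {
  if (!is.numeric(I) || any(!is.finite(I)))
    stop("inhibition values must be finite numbers")
  nCap <- sum(I > 1)
  if (nCap > 0)
    warning(sprintf("%d inhibition value(s) > 1 capped at 1", nCap))
  pmin(pmax(I, 0), 1)
}

#' Excess Over Bliss for a single dose pair
#'
#' Under Bliss independence two non-interacting drugs leave a surviving
#' fraction equal to the product of the monotherapy surviving fractions,
#' \eqn{V_X V_Y = (1-I_X)(1-I_Y)}. The Excess Over Bliss score is
#' \deqn{EOB = 100 (I_{XY} - (I_X + I_Y - I_X I_Y)),}
#' the observed minus the expected inhibition on the percent scale. Positive
#' values indicate synergy, negative antagonism. When standard errors of the
#' mean are supplied the propagated error of the score is returned alongside
#' (see [eobError()]).
#'
#' @param Ix,Iy,Ixy inhibition fractions for the two monotherapies and the
#'   combination; expected to be clamped to \[0, 1\]
#'   (see [clampInhibition()]).
#' @param semX,semY,semXY standard errors of the mean of the inhibition
#'   fractions (default 0).
#' @return an object of class `SynergyScore`: a list with elements `eob`,
#'   `eobError` (both percent), `expectedViability` and `observedViability`
#'   (fractions).
#' @examples
#' excessOverBliss(0.2, 0.3, 0.6)  # eob = 16
#' @export
excessOverBliss <- function(Ix, Iy, Ixy, semX = 0, semY = 0, semXY = 0) {
  stopifnot(is.finite(Ix), is.finite(Iy), is.finite(Ixy))
  eob <- 100 * (Ixy - (Ix + Iy - Ix * Iy))
  out <- list(
    eob = eob,
    eobError = eobError(Ix, Iy, semX, semY, semXY),
    expectedViability = (1 - Ix) * (1 - Iy),
    observedViability = 1 - Ixy
  )
  class(out) <- "SynergyScore"
  out
}

#' @export
print.SynergyScore <- function(x, ...) {
  cat(sprintf("EOB = %.2f +/- %.2f (expected viability %.3f, observed %.3f)\n",
              x$eob, x$eobError, x$expectedViability, x$observedViability))
  invisible(x)
}

#' Propagated error of the Excess Over Bliss score
#'
#' First-order error propagation through the Bliss excess gives
#' \deqn{Error_{EOB} = 100\sqrt{SEM_X^2(1 + I_Y^2 - 2I_Y) +
#'   SEM_Y^2(1 + I_X^2 - 2I_X) + SEM_{XY}^2},}
#' which is algebraically identical to
#' \eqn{100\sqrt{SEM_X^2(1-I_Y)^2 + SEM_Y^2(1-I_X)^2 + SEM_{XY}^2}}.
#' Returned on the percent scale so it is commensurate with the score itself.
#'
#' @param Ix,Iy monotherapy inhibition fractions.
#' @param semX,semY,semXY standard errors of the mean of the inhibitions.
#' @return propagated error in percent (non-negative scalar).
#' @export
eobError <- function(Ix, Iy, semX = 0, semY = 0, semXY = 0) {
  if (any(c(semX, semY, semXY) < 0)) stop("SEMs must be non-negative")
  100 * sqrt(semX^2 * (1 + Iy^2 - 2 * Iy) +
             semY^2 * (1 + Ix^2 - 2 * Ix) +
             semXY^2)
}

#' Convert a long-format replicate viability table to a dose cube
#'
#' @param df data.frame with columns `dose_a`, `dose_b`, `replicate`,
#'   `viability` (fraction of vehicle). Both dose grids must include 0; the
#'   (0, 0) cell is the vehicle itself.
#' @return 3-d array doses_a x doses_b x replicates with numeric dose
#'   dimnames.
#' @export
viabilityCube <- function(df) {
  need <- c("dose_a", "dose_b", "replicate", "viability")
  if (!all(need %in% names(df)))
    stop("long table needs columns: ", paste(need, collapse = ", "))
  da <- sort(unique(df$dose_a)); db <- sort(unique(df$dose_b))
  reps <- sort(unique(df$replicate))
  cube <- array(NA_real_, dim = c(length(da), length(db), length(reps)),
                dimnames = list(dose_a = da, dose_b = db, replicate = reps))
  cube[cbind(match(df$dose_a, da), match(df$dose_b, db),
             match(df$replicate, reps))] <- df$viability
  cube
}

#' Excess Over Bliss over a full dose matrix
#'
#' Computes, for every interior dose pair of a replicate viability cube, the
#' mean inhibition of each monotherapy margin and of the combination, their
#' standard errors, the Excess Over Bliss score and its propagated error,
#' and reports the maximum score over the matrix with its location.
#'
#' @param cube 3-d array (doses_a x doses_b x replicates) of viability
#'   fractions relative to vehicle, with numeric dose dimnames; both dose
#'   grids must start at 0 (the margins at dose 0 are the monotherapies /
#'   vehicle).
#' @return list with `table` (one row per interior dose pair: doses, the
#'   three clamped mean inhibitions, `eob`, `eob_error`) and `max` (row of
#'   `table` with the largest `eob`).
#' @export
eobMatrix <- function(cube) {
  stopifnot(length(dim(cube)) == 3)
  da <- as.numeric(dimnames(cube)[[1]]); db <- as.numeric(dimnames(cube)[[2]])
  if (da[1] != 0 || db[1] != 0)
    stop("dose grids must include 0 so monotherapy margins exist")
  nrep <- dim(cube)[3]
  if (nrep == 1)
    warning("single-replicate cube: SEMs reported as 0")
  inhib <- function(i, j) {
    v <- cube[i, j, ]
    v <- v[!is.na(v)]
    if (!length(v)) stop(sprintf("no replicate at dose pair (%g, %g)",
                                 da[i], db[j]))
    I <- clampInhibition(mean(1 - v))
    sem <- if (length(v) > 1) stats::sd(1 - v) / sqrt(length(v)) else 0
    c(I = I, sem = sem)
  }
  rows <- list()
  for (i in seq_along(da)[-1]) {
    mx <- inhib(i, 1)
    for (j in seq_along(db)[-1]) {
      my <- inhib(1, j)
      mxy <- inhib(i, j)
      sc <- excessOverBliss(mx["I"], my["I"], mxy["I"],
                            mx["sem"], my["sem"], mxy["sem"])
      rows[[length(rows) + 1L]] <- data.frame(
        dose_a = da[i], dose_b = db[j],
        Ix = unname(mx["I"]), Iy = unname(my["I"]), Ixy = unname(mxy["I"]),
        eob = sc$eob, eob_error = sc$eobError)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, max = tab[which.max(tab$eob), , drop = FALSE])
}

#' Fit the median-effect (Chou) model to a monotherapy dose response
#'
#' The median-effect equation \eqn{f_a/(1-f_a) = (D/D_m)^m} is linear in
#' log dose versus log effect-odds; `fitMedianEffect` estimates the slope
#' \eqn{m} and the median-effect dose \eqn{D_m} by ordinary least squares of
#' \eqn{\log(f_a/(1-f_a))} on \eqn{\log D}. Fractions affected exactly at 0
#' or 1 are clipped to `eps`/`1 - eps` (the log-odds transform is undefined
#' at the endpoints) with a warning.
#'
#' @param dose positive dose vector.
#' @param fa fraction of cells affected at each dose.
#' @param eps endpoint clipping bound (default 1e-4).
#' @return object of class `MedianEffectFit`: list with `m`, `Dm`, `r2`,
#'   `n` and a `monotone` flag (FALSE when `fa` is not non-decreasing in
#'   dose, reported but not rejected).
#' @examples
#' d <- c(2, 5, 10, 20, 40)
#' fa <- 1 / (1 + (10 / d)^1.5)          # exact median-effect curve
#' fitMedianEffect(d, fa)
#' @export
fitMedianEffect <- function(dose, fa, eps = 1e-4) {
  stopifnot(length(dose) == length(fa))
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(fa <= 0 | fa >= 1)) {
    warning("fa values at or beyond {0,1} clipped to [eps, 1-eps]")
    fa <- pmin(pmax(fa, eps), 1 - eps)
  }
  if (length(dose) < 3) stop("need at least 3 usable dose levels")
  ord <- order(dose)
  monotone <- !is.unsorted(fa[ord])
  y <- log(fa / (1 - fa)); x <- log(dose)
  fit <- stats::lm.fit(cbind(1, x), y)
  b0 <- fit$coefficients[1]; m <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  out <- list(m = unname(m), Dm = unname(exp(-b0 / m)), r2 = unname(r2),
              n = length(dose), monotone = monotone)
  class(out) <- "MedianEffectFit"
  out
}

#' @export
print.MedianEffectFit <- function(x, ...) {
  cat(sprintf("median-effect fit: m = %.4g, Dm = %.4g (r2 = %.4f, n = %d)%s\n",
              x$m, x$Dm, x$r2, x$n,
              if (x$monotone) "" else " [non-monotone data]"))
  invisible(x)
}

#' Predicted fraction affected from a median-effect fit
#' @param fit a `MedianEffectFit`.
#' @param dose dose(s) at which to evaluate.
#' @return fraction affected in (0, 1).
#' @export
medianEffectFa <- function(fit, dose) {
  r <- (dose / fit$Dm)^fit$m
  r / (1 + r)
}

#' Loewe combination index from median-effect fits
#'
#' Computes \eqn{CI = d_1/D_1 + d_2/D_2}, where \eqn{d_k} are the doses used
#' in the combination and \eqn{D_k = D_{m,k}(f_a/(1-f_a))^{1/m_k}} are the
#' monotherapy doses that would each alone achieve the combination's
#' fraction affected. CI < 1 indicates synergy, CI = 1 additivity, CI > 1
#' antagonism.
#'
#' @param fit1,fit2 `MedianEffectFit` objects for the two monotherapies.
#' @param d1,d2 combination doses (non-negative; a zero dose contributes 0).
#' @param faCombo fraction affected achieved by the combination, in (0, 1).
#' @return object of class `CombinationIndexResult`: list with `ci`,
#'   `faCombo`, `d1`, `d2`, `D1`, `D2`.
#' @export
combinationIndex <- function(fit1, fit2, d1, d2, faCombo) {
  if (faCombo <= 0 || faCombo >= 1) stop("faCombo must be in (0,1)")
  if (d1 < 0 || d2 < 0) stop("doses must be non-negative")
  odds <- faCombo / (1 - faCombo)
  D1 <- fit1$Dm * odds^(1 / fit1$m)
  D2 <- fit2$Dm * odds^(1 / fit2$m)
  out <- list(ci = d1 / D1 + d2 / D2, faCombo = faCombo,
              d1 = d1, d2 = d2, D1 = D1, D2 = D2)
  class(out) <- "CombinationIndexResult"
  out
}

#' @export
print.CombinationIndexResult <- function(x, ...) {
  cat(sprintf("CI = %.4f at fa = %.3f (d1/D1 = %.3g/%.3g, d2/D2 = %.3g/%.3g)\n",
              x$ci, x$faCombo, x$d1, x$D1, x$d2, x$D2))
  invisible(x)
}

#' Excess Over Bliss of a sham self-combination
#'
#' Treats the response at dose `dA + dB` of a single drug as if it were the
#' "combination" of the two lower doses, and scores it by Bliss excess. A
#' drug whose viability is exactly Bliss-multiplicative in dose
#' (\eqn{V(d) = e^{-kd}}) scores 0 for every split; departures measure how
#' much apparent "synergy" a pure dose increase can produce.
#'
#' @param dose dose vector of the monotherapy curve (should include 0 or the
#'   vehicle is assumed to have viability 1).
#' @param viability mean viability fraction at each dose, relative to
#'   vehicle.
#' @param dA,dB the two doses of the sham split; `dA + dB` must also be in
#'   `dose` (either may be 0).
#' @return `SynergyScore` (see [excessOverBliss()]).
#' @export
shamCombinationEOB <- function(dose, viability, dA, dB) {
  lookup <- function(d) {
    if (d == 0 && !any(dose == 0)) return(1)
    i <- which(dose == d)
    if (!length(i)) stop(sprintf("no viability measured at dose %g", d))
    mean(viability[i])
  }
  Ix <- clampInhibition(1 - lookup(dA))
  Iy <- clampInhibition(1 - lookup(dB))
  Ixy <- clampInhibition(1 - lookup(dA + dB))
  excessOverBliss(Ix, Iy, Ixy)
}
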