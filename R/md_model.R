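# Melting-diagram model: a sharp onset step, a flat plateau between T_fno
# and T_fne (the homogeneous first hydration shell), and a power-series rise
#   n = A + B (T_fn - T_fn1) + C (T_fn - T_fn2)^2 + ...
# above the plateau (the heterogeneous binding-energy region). The
# differential melting diagram (DMD)
#   dn/dT_fn = B + 2C (T_fn - T_fn2) + ...
# is the distribution of potential-energy barriers to bound-water motion.
#
# Anchor identifiability: a linear term's intercept folds into A, so T_fn1
# and B are not jointly identifiable with A. The fit therefore uses the
# re-parameterization n = A + B'(t - T_fne) + C'(t - T_fne)^2 with
# continuity n(T_fne) = A built in, and reports the anchors as
# T_fn1 = T_fn2 = T_fne by convention.

# Piecewise forward model shared by the fit and the synthetic generator.
eval_piecewise_md <- function(t_fn, onset, t_fno, t_fne, A, B = 0, C = 0,
                              D = 0) {
  n <- numeric(length(t_fn))
  ramp <- t_fn >= onset & t_fn < t_fno
  if (t_fno > onset) {
    n[ramp] <- A * (t_fn[ramp] - onset) / (t_fno - onset)
  } else {
    n[ramp] <- A
  }
  plat <- t_fn >= t_fno & t_fn <= t_fne
  n[plat] <- A
  hi <- t_fn > t_fne
  x <- t_fn[hi] - t_fne
  n[hi] <- A + B * x + C * x^2 + D * x^3
  n
}

#' Detect the melting onset of a diagram
#'
#' The onset ("melting point" of the hydration shell) is the first
#' normalized fundamental temperature at which the mobile fraction exceeds a
#' threshold, located by linear interpolation between the bracketing points.
#'
#' @param md a `melting_diagram`.
#' @param threshold fraction above which water counts as mobile; default
#'   3 times the baseline noise level (estimated robustly from successive
#'   differences) or 1 percent of the maximum fraction, whichever is larger
#'   (the floor guards against a noise estimate deflated by the clamped
#'   frozen baseline).
#' @return A list with `onset_t_fn`, `onset_celsius`, and the `threshold`
#'   used.
#' @export
detect_onset <- function(md, threshold = NULL) {
  stopifnot(inherits(md, "melting_diagram"))
  d <- md_reliable(md)
  if (is.null(threshold)) {
    threshold <- max(3 * estimate_noise_sd(d$n), 0.01 * max(d$n), 1e-9)
  }
  above <- d$n > threshold
  if (all(above)) {
    hm_stop("all points above threshold: no onset in the measured window",
            "no_onset")
  }
  # require a sustained crossing (the next point above too, except at the
  # series end) so an isolated noise spike in the frozen baseline cannot
  # fake an onset
  sustained <- above & c(above[-1L], TRUE)
  if (!any(sustained)) {
    hm_stop("no sustained crossing above threshold: no melting in the measured window",
            "no_melting")
  }
  j <- which(sustained)[1]
  if (j == 1L) {
    hm_stop("first point already above threshold: no onset in window",
            "no_onset")
  }
  # Linear interpolation of the crossing between the bracketing points. When
  # the step is unresolved by the grid (the jump dwarfs the threshold) the
  # threshold crossing degenerates to the lower point; interpolating at the
  # midpoint of the bracketing amplitudes is then the unbiased estimate.
  t0 <- d$t_fn[j - 1L]; t1 <- d$t_fn[j]
  n0 <- d$n[j - 1L]; n1 <- d$n[j]
  level <- max(threshold, (n0 + n1) / 2)
  onset <- t0 + (level - n0) / (n1 - n0) * (t1 - t0)
  list(onset_t_fn = onset,
       onset_celsius = kelvin_to_celsius(tfn_to_kelvin(onset)),
       threshold = threshold)
}

# Segmented (plateau mean + continuous polynomial rise) residual sum of
# squares for a candidate plateau end e; `powers` are the exponents of the
# rise terms (2 for a tangential departure, 1:2 for a kinked one). Used by
# the breakpoint refinement.
segmented_rss <- function(t, n, e, powers = 1:2) {
  plat <- t <= e
  if (!any(plat)) return(Inf)
  A <- mean(n[plat])
  rss <- sum((n[plat] - A)^2)
  hi <- !plat
  m <- sum(hi)
  if (m > 0L) {
    x <- t[hi] - e
    dy <- n[hi] - A
    X <- outer(x, powers[seq_len(min(length(powers), m))], `^`)
    fit <- stats::lm.fit(X, dy)
    rss <- rss + sum(fit$residuals^2)
  }
  rss
}

#' Detect the melting-diagram plateau
#'
#' Finds the homogeneous first-shell plateau `[T_fno, T_fne]` after the
#' onset: the longest contiguous run of points whose local finite-difference
#' slope magnitude stays within `slope_tol` and whose span is at least
#' `min_span`. The plateau end is then refined on a continuous scale by
#' segmented least squares (plateau mean plus a polynomial rise continuous
#' at the breakpoint), which locates `T_fne` to better than the grid
#' spacing. If no run qualifies the diagram has no plateau (the
#' intrinsically-disordered limit) and `t_fno = t_fne = onset` is returned.
#'
#' @param md a `melting_diagram`.
#' @param slope_tol slope threshold (dimensionless, on the n vs T_fn scale);
#'   default 3 times the propagated noise slope `sd * sqrt(2) / h`.
#' @param min_span minimum plateau span in T_fn units (default 0.02).
#' @param onset result of [detect_onset()]; computed if `NULL`. If the
#'   whole window is above the onset threshold the search starts at the
#'   first point.
#' @param refine logical; refine `t_fne` by segmented least squares
#'   (default `TRUE`).
#' @return A list with `t_fno`, `t_fne`, `no_plateau`, `onset_t_fn`,
#'   `onset_celsius`, `slope_tol`, `noise_sd`, `boundary_err` (grid
#'   resolution limit on the boundaries) and `t_fne_err` (1-sigma profile
#'   uncertainty of the plateau end; at least the grid resolution).
#' @export
detect_plateau <- function(md, slope_tol = NULL, min_span = 0.02,
                           onset = NULL, refine = TRUE) {
  stopifnot(inherits(md, "melting_diagram"))
  d <- md_reliable(md)
  if (is.null(onset)) {
    onset <- tryCatch(detect_onset(md), hydromelt_no_onset = function(e) {
      list(onset_t_fn = d$t_fn[1], onset_celsius =
             kelvin_to_celsius(d$temperature[1]), threshold = NA_real_)
    })
  }
  noise_sd <- estimate_noise_sd(d$n)
  h <- stats::median(diff(d$t_fn))
  if (is.null(slope_tol)) {
    slope_tol <- max(3 * noise_sd * sqrt(2) / h, 1e-12)
  }

  idx <- which(d$t_fn >= onset$onset_t_fn - 1e-12)
  if (length(idx) < 3L) {
    hm_stop("need at least 3 points above the onset", "invalid_input")
  }
  t <- d$t_fn[idx]; n <- d$n[idx]
  s <- diff(n) / diff(t)
  ok <- abs(s) <= slope_tol

  # longest contiguous run of low-slope intervals
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL; best_span <- -Inf
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r] + 1L  # interval k joins points k, k+1
    span <- t[i1] - t[i0]
    if (span >= min_span && span > best_span) {
      best <- c(i0, i1); best_span <- span
    }
  }
  res <- list(onset_t_fn = onset$onset_t_fn,
              onset_celsius = onset$onset_celsius,
              slope_tol = slope_tol, noise_sd = noise_sd,
              boundary_err = h / 2)
  if (is.null(best)) {
    res$t_fno <- onset$onset_t_fn
    res$t_fne <- onset$onset_t_fn
    res$t_fne_err <- res$boundary_err
    res$no_plateau <- TRUE
    return(res)
  }
  t_fno <- t[best[1]]
  t_fne <- t[best[2]]

  if (refine) {
    # Continuous breakpoint by segmented least squares over [t_fno, max].
    # Two rise families are tried: a tangential departure (curvature only,
    # the slope stays continuous at the plateau end) and a kinked one (slope
    # + curvature). When the rise leaves the plateau tangentially the
    # breakpoint and the kink slope are nearly unidentifiable jointly, which
    # inflates the breakpoint variance; the kinked family is therefore
    # accepted only if it beats the tangential one by `kink_bic_margin` BIC
    # units.
    sel <- t >= t_fno - 1e-12
    ts <- t[sel]; ns <- n[sel]; m <- length(ts)
    refine_one <- function(powers, n_par) {
      cand <- ts[ts >= t_fno + min_span]
      if (length(cand) == 0L) return(NULL)
      rss <- vapply(cand, function(e) segmented_rss(ts, ns, e, powers), 0)
      # ties (e.g. an exactly flat diagram) resolve to the longest plateau
      tie <- rss <= min(rss) + 1e-12 * (1 + min(rss))
      e0 <- max(cand[tie])
      best <- list(e = e0, rss = min(rss), n_par = n_par,
                   cand = cand, rss_profile = rss)
      lo <- max(t_fno + min_span, e0 - 1.5 * h)
      hi <- min(max(ts), e0 + 1.5 * h)
      if (hi > lo) {
        op <- stats::optimize(function(e) segmented_rss(ts, ns, e, powers),
                              lower = lo, upper = hi,
                              tol = .Machine$double.eps^0.6)
        if (op$objective < best$rss * (1 - 1e-12)) {
          best$e <- op$minimum
          best$rss <- op$objective
        }
      }
      best
    }
    tang <- refine_one(2L, 3L)      # A, C, breakpoint
    kink <- refine_one(1:2, 4L)     # A, B, C, breakpoint
    if (!is.null(tang)) {
      bic <- function(r) m * log(max(r$rss, m * 1e-300) / m) + r$n_par * log(m)
      kink_bic_margin <- 2
      fam <- if (!is.null(kink) && bic(kink) < bic(tang) - kink_bic_margin) {
        kink
      } else {
        tang
      }
      t_fne <- fam$e
      # 1-sigma profile interval: candidates whose RSS stays within one
      # per-point noise variance of the minimum
      if (noise_sd > 0) {
        prof <- fam$cand[fam$rss_profile <= fam$rss + noise_sd^2]
        if (length(prof) > 0L) {
          res$t_fne_err <- max(h / 2, (max(prof) - min(prof)) / 2)
        }
      }
    }
  }
  res$t_fno <- t_fno
  res$t_fne <- t_fne
  if (is.null(res$t_fne_err)) res$t_fne_err <- res$boundary_err
  res$no_plateau <- FALSE
  res
}

#' Fit the plateau + power-series melting-diagram model
#'
#' The plateau level `A` is the (optionally error-weighted) mean of all
#' points on the plateau; the rise above `T_fne` is fitted by least squares
#' with the continuity constraint `n(T_fne) = A` built in. The polynomial
#' order starts quadratic and a cubic term is admitted only if it improves
#' the BIC by `ic_margin`.
#'
#' @param md a `melting_diagram`.
#' @param plateau result of [detect_plateau()]; computed if `NULL`.
#' @param max_order highest polynomial order of the rise (2 or 3).
#' @param weighted use `1/n_err^2` weights for the plateau mean when errors
#'   are available (default `FALSE`, unweighted).
#' @param ic_margin BIC improvement required to accept the cubic term.
#' @return An object of class `md_fit` with fields `onset_t_fn`, `A`,
#'   `t_fno`, `t_fne`, `B`, `C`, `D`, `t_fn1`, `t_fn2`, `param_errors`,
#'   `fit_window`, `rss`, `order`, `noise_sd`, `grid_bin`, `no_plateau`.
#' @examples
#' md <- generate_md(md_presets("ubiquitin_like"), seed = 1)
#' fit <- fit_melting_model(md)
#' fit$A
#' @export
fit_melting_model <- function(md, plateau = NULL, max_order = 2L,
                              weighted = FALSE, ic_margin = 6) {
  stopifnot(inherits(md, "melting_diagram"))
  if (is.null(plateau)) plateau <- detect_plateau(md)
  d <- md_reliable(md)
  e <- plateau$t_fne
  grid_bin <- stats::median(diff(d$t_fn))

  if (isTRUE(plateau$no_plateau)) {
    plat_idx <- integer(0)
  } else {
    plat_idx <- which(d$t_fn >= plateau$t_fno - 1e-12 & d$t_fn <= e + 1e-12)
  }
  if (length(plat_idx) > 0L) {
    w <- if (weighted && all(is.finite(d$n_err[plat_idx])) &&
             all(d$n_err[plat_idx] > 0)) 1 / d$n_err[plat_idx]^2 else
               rep(1, length(plat_idx))
    A <- sum(w * d$n[plat_idx]) / sum(w)
    plat_res <- d$n[plat_idx] - A
    A_se <- if (length(plat_idx) > 1L) {
      stats::sd(plat_res) / sqrt(length(plat_idx))
    } else NA_real_
    noise_sd <- if (length(plat_idx) > 2L) stats::sd(plat_res) else
      plateau$noise_sd
  } else {
    # no-plateau (IDP) limit: the step top stands in for A
    top <- which(d$t_fn > plateau$onset_t_fn)[1]
    A <- if (is.na(top)) 0 else d$n[top]
    plat_res <- numeric(0)
    A_se <- NA_real_
    noise_sd <- plateau$noise_sd
  }

  hi <- which(d$t_fn > e + 1e-12)
  coefs <- c(B = 0, C = 0, D = 0)
  errs <- c(B = NA_real_, C = NA_real_, D = NA_real_)
  order_used <- 0L
  rise_rss <- 0
  if (length(hi) > 0L) {
    x <- d$t_fn[hi] - e
    dy <- d$n[hi] - A
    m <- length(hi)
    if (m < 2L) {
      hm_warn("rise segment under-determined; linear term only", "fit")
      coefs["B"] <- dy[1] / x[1]
      order_used <- 1L
    } else {
      fit_powers <- function(powers) {
        X <- outer(x, powers, `^`)
        list(lmf = stats::lm(dy ~ 0 + X), powers = powers)
      }
      k2 <- min(2L, m)
      f2 <- fit_powers(seq_len(k2))
      # a negative initial slope is unphysical (the melting diagram is
      # nondecreasing): drop the linear term and keep curvature only
      if (k2 == 2L && stats::coef(f2$lmf)[[1]] < 0) {
        f2 <- fit_powers(2L)
      }
      chosen <- f2; order_used <- k2
      if (max_order >= 3L && m >= 4L) {
        f3 <- fit_powers(1:3)
        if (stats::BIC(f3$lmf) < stats::BIC(f2$lmf) - ic_margin) {
          chosen <- f3; order_used <- 3L
        }
      }
      cf <- stats::coef(chosen$lmf)
      se <- tryCatch(sqrt(diag(stats::vcov(chosen$lmf))),
                     error = function(e) rep(NA_real_, length(cf)))
      nm <- c("B", "C", "D")[chosen$powers]
      coefs[nm] <- unname(cf)
      errs[nm] <- unname(se)
      rise_rss <- sum(stats::residuals(chosen$lmf)^2)
    }
  }

  structure(list(
    onset_t_fn = plateau$onset_t_fn,
    onset_celsius = plateau$onset_celsius,
    A = A,
    t_fno = plateau$t_fno,
    t_fne = e,
    B = unname(coefs["B"]), C = unname(coefs["C"]), D = unname(coefs["D"]),
    t_fn1 = e, t_fn2 = e,
    param_errors = c(A = A_se, B = unname(errs["B"]), C = unname(errs["C"]),
                     D = unname(errs["D"]),
                     t_fno = plateau$boundary_err,
                     t_fne = plateau$t_fne_err %||% plateau$boundary_err),
    fit_window = c(min(d$t_fn), max(d$t_fn)),
    rss = sum(plat_res^2) + rise_rss,
    order = order_used,
    noise_sd = noise_sd,
    grid_bin = grid_bin,
    no_plateau = isTRUE(plateau$no_plateau)
  ), class = "md_fit")
}

#' Evaluate a fitted melting-diagram model
#'
#' @param object an `md_fit`.
#' @param t_fn normalized fundamental temperatures at which to evaluate.
#' @param ... unused.
#' @return Predicted mobile fractions.
#' @export
predict.md_fit <- function(object, t_fn, ...) {
  eval_piecewise_md(t_fn, object$onset_t_fn, object$t_fno, object$t_fne,
                    object$A, object$B, object$C, object$D)
}

#' @export
print.md_fit <- function(x, ...) {
  cat(sprintf("Melting-diagram fit\n  onset  T_fn = %.4f (%.1f degC)\n",
              x$onset_t_fn, x$onset_celsius))
  if (x$no_plateau) {
    cat("  no plateau detected (IDP limit)\n")
  } else {
    cat(sprintf("  plateau T_fno = %.4f, T_fne = %.4f, A = %.4g\n",
                x$t_fno, x$t_fne, x$A))
  }
  cat(sprintf("  rise (order %d): B = %.4g, C = %.4g, D = %.4g (anchors at T_fne)\n",
              x$order, x$B, x$C, x$D))
  cat(sprintf("  rss = %.4g, plateau noise sd = %.3g\n", x$rss, x$noise_sd))
  invisible(x)
}

dmd_curve <- function(t_fn, dn_dtfn, segment, segments, fit = NULL) {
  structure(data.frame(t_fn = t_fn, dn_dtfn = dn_dtfn, segment = segment,
                       stringsAsFactors = FALSE),
            class = c("dmd_curve", "data.frame"),
            segments = segments, fit = fit)
}

#' Analytic differential melting diagram
#'
#' Derivative of the fitted piecewise model: zero below the onset and on the
#' plateau; the onset step is rendered as a finite bar (width one onset bin,
#' area `A`); `B + 2C (t - T_fn2) + 3D (t - T_fn2)^2` above `T_fne`.
#'
#' @param fit an `md_fit`.
#' @param grid T_fn values at which to evaluate; defaults to 401 points over
#'   the fit window. Points outside the fit window are clipped with a
#'   warning.
#' @return A `dmd_curve`: data.frame `(t_fn, dn_dtfn, segment)` with a
#'   `segments` attribute listing per-segment areas and the originating fit
#'   in the `fit` attribute (used for closed-form integration).
#' @export
dmd_analytic <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "md_fit"))
  if (is.null(grid)) {
    grid <- seq(fit$fit_window[1], fit$fit_window[2], length.out = 401L)
  }
  out <- grid >= fit$fit_window[1] - 1e-9 & grid <= fit$fit_window[2] + 1e-9
  if (!all(out)) {
    hm_warn("grid points outside the fit window were clipped", "clipped_grid")
    grid <- grid[out]
  }
  width <- fit$t_fno - fit$onset_t_fn
  if (width <= 0) width <- fit$grid_bin
  bar_height <- fit$A / width
  y <- numeric(length(grid))
  seg <- rep("pre_onset", length(grid))
  in_bar <- grid >= fit$onset_t_fn & grid < fit$onset_t_fn + width
  y[in_bar] <- bar_height
  seg[in_bar] <- "onset"
  plat <- grid >= fit$onset_t_fn + width & grid <= fit$t_fne
  seg[plat] <- "plateau"
  hi <- grid > fit$t_fne
  xx <- grid[hi] - fit$t_fn2
  y[hi] <- fit$B + 2 * fit$C * xx + 3 * fit$D * xx^2
  seg[hi] <- "heterogeneous"
  if (any(hi)) {
    # warn only when the dip is significant against the coefficient errors
    eb <- fit$param_errors[["B"]]; ec <- fit$param_errors[["C"]]
    dip_tol <- if (is.finite(eb) && is.finite(ec)) {
      3 * sqrt(eb^2 + (2 * max(xx) * ec)^2)
    } else {
      1e-8 * max(1, max(abs(y)))
    }
    if (min(y[seg == "heterogeneous"]) < -dip_tol) {
      hm_warn("fitted DMD dips below zero: the fitted model is not monotone",
              "model_validity")
    }
  }
  xe <- fit$fit_window[2] - fit$t_fne
  segments <- data.frame(
    segment = c("onset", "plateau", "heterogeneous"),
    area = c(fit$A, 0,
             fit$B * xe + fit$C * xe^2 + fit$D * xe^3)
  )
  dmd_curve(grid, y, seg, segments, fit = fit)
}

#' Numerical differential melting diagram
#'
#' Model-free centered finite differences of n against T_fn at the interior
#' points of the diagram; the independent check of [dmd_analytic()].
#'
#' @param md a `melting_diagram`.
#' @return A `dmd_curve` over the interior points.
#' @export
dmd_numeric <- function(md) {
  stopifnot(inherits(md, "melting_diagram"))
  d <- md_reliable(md)
  if (nrow(d) < 3L) hm_stop("need at least 3 points", "invalid_input")
  m <- nrow(d)
  i <- 2:(m - 1L)
  dd <- (d$n[i + 1L] - d$n[i - 1L]) / (d$t_fn[i + 1L] - d$t_fn[i - 1L])
  dmd_curve(d$t_fn[i], dd, rep("numeric", length(i)),
            segments = data.frame(segment = "numeric",
                                  area = trapz(d$t_fn[i], dd)))
}

#' Integrate a differential melting diagram
#'
#' Area under the DMD between two normalized fundamental temperatures: the
#' number of water molecules (as a fraction of total water) that start to
#' move in that excitation-energy range. Analytic curves are integrated in
#' closed form (bar area plus the polynomial antiderivative); numeric curves
#' by the trapezoidal rule with endpoint interpolation.
#'
#' @param dmd a `dmd_curve`.
#' @param a,b integration bounds in T_fn, `a < b`.
#' @return The dimensionless area.
#' @export
integrate_dmd <- function(dmd, a, b) {
  stopifnot(inherits(dmd, "dmd_curve"))
  if (!is.finite(a) || !is.finite(b) || a >= b) {
    hm_stop("need finite bounds with a < b", "invalid_input")
  }
  fit <- attr(dmd, "fit")
  if (!is.null(fit)) {
    width <- fit$t_fno - fit$onset_t_fn
    if (width <= 0) width <- fit$grid_bin
    bar <- c(fit$onset_t_fn, fit$onset_t_fn + width)
    ov <- max(0, min(b, bar[2]) - max(a, bar[1]))
    area <- fit$A * ov / width
    x1 <- max(a, fit$t_fne) - fit$t_fne
    x2 <- b - fit$t_fne
    if (x2 > x1) {
      anti <- function(x) fit$B * x + fit$C * x^2 + fit$D * x^3
      area <- area + anti(x2) - anti(x1)
    }
    return(area)
  }
  x <- dmd$t_fn; y <- dmd$dn_dtfn
  lo <- max(a, min(x)); hi <- min(b, max(x))
  if (hi <= lo) return(0)
  xs <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
  ys <- stats::approx(x, y, xout = xs)$y
  trapz(xs, ys)
}

#' Serialize a melting-diagram fit to JSON
#'
#' All parameters, standard errors, tolerances and the fit window are
#' written; [read_fit_json()] restores the `md_fit` exactly.
#'
#' @param fit an `md_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$param_errors <- as.list(x$param_errors)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) {
    hm_stop(sprintf("fit JSON not found: %s", path), "invalid_input")
  }
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  pe <- vapply(j$param_errors, function(v) {
    if (is.null(v) || !is.numeric(v)) NA_real_ else as.numeric(v)
  }, 0)
  scalars <- setdiff(names(j), c("param_errors", "fit_window"))
  out <- lapply(j[scalars], function(v) if (is.null(v)) NA else v[[1]])
  out$param_errors <- pe
  out$fit_window <- as.numeric(unlist(j$fit_window))
  structure(out, class = "md_fit")
}

#' Write a DMD curve to CSV
#'
#' Columns `t_fn, dn_dtfn, segment`.
#'
#' @param dmd a `dmd_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmd_csv <- function(dmd, path) {
  utils::write.table(as.data.frame(dmd), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
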