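#' Construct an ITC thermogram
#'
#' @param heats per-injection integrated heats (ucal), one per injection of
#'   the protocol (the first small priming injection included)
#' @param protocol an [itc_protocol()]
#' @param label free-text label identifying the titrated pair
#' @return an `itc_thermogram` tibble with columns `injection`, `heat_ucal`
#' @export
itc_thermogram <- function(heats, protocol = itc_protocol(), label = "") {
  if (length(heats) != protocol$n_inj) {
    abort(sprintf("%d heats supplied for a %d-injection protocol",
                  length(heats), protocol$n_inj),
          class = "nrpsdock_value_error")
  }
  out <- tibble(injection = seq_along(heats), heat_ucal = as.numeric(heats))
  class(out) <- c("itc_thermogram", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "label") <- label
  out
}

thermo_protocol <- function(x) attr(x, "protocol")

#' Baseline-correct an ITC thermogram
#'
#' Two modes mirror common instrument practice:
#'
#' * `"plateau"`: when the macromolecule is saturated in the final injections
#'   a clear heat plateau is reached; its mean (last `m` injections) is
#'   subtracted. If the last-`m` heats still trend (no plateau), a warning
#'   recommends buffer mode instead.
#' * `"buffer"`: a matched titrant-into-buffer run is subtracted
#'   injection-wise — required when full saturation is not reached, as for
#'   the weaker docking-domain pairs.
#'
#' @param raw an [itc_thermogram()]
#' @param mode `"plateau"` or `"buffer"`
#' @param buffer_run matched buffer titration (same protocol), for
#'   `mode = "buffer"`
#' @param m number of final injections defining the plateau
#' @param slope_tol plateau test: warn when the |slope| of the last `m` heats
#'   exceeds this fraction of the thermogram amplitude per injection
#' @return a corrected `itc_thermogram`
#' @export
baseline_correct <- function(raw, mode = c("plateau", "buffer"),
                             buffer_run = NULL, m = 3L, slope_tol = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "itc_thermogram"))
  if (mode == "plateau") {
    tail_idx <- seq(nrow(raw) - m + 1L, nrow(raw))
    tail_heats <- raw$heat_ucal[tail_idx]
    amplitude <- diff(range(raw$heat_ucal[-1]))
    slope <- coef(stats::lm(tail_heats ~ tail_idx))[2]
    if (amplitude > 0 && abs(slope) > slope_tol * amplitude) {
      warn(paste0("no clear plateau in the final injections ",
                  "(titration not saturated); consider buffer-mode ",
                  "baseline correction"))
    }
    corrected <- raw$heat_ucal - mean(tail_heats)
  } else {
    if (is.null(buffer_run)) {
      abort("buffer mode requires a buffer_run thermogram",
            class = "nrpsdock_value_error")
    }
    if (!protocols_identical(thermo_protocol(raw), thermo_protocol(buffer_run))) {
      abort("buffer run protocol does not match the titration protocol",
            class = "nrpsdock_protocol_error")
    }
    corrected <- raw$heat_ucal - buffer_run$heat_ucal
  }
  out <- itc_thermogram(corrected, thermo_protocol(raw), attr(raw, "label"))
  attr(out, "baseline_mode") <- mode
  out
}

#' Fit a one-site binding model to an ITC thermogram
#'
#' Nonlinear least squares of the forward model [itc_heats()] against the
#' observed injection heats over (n, Kd, dH, baseline), or with n fixed at 1.
#' The Kd is parameterised as log10(Kd) and the Levenberg-Marquardt
#' optimisation is restarted from three Kd decades to avoid local minima;
#' standard errors come from the Jacobian at the optimum. The priming
#' injection is excluded from the objective by default.
#'
#' The Wiseman c-value `n * [M]_T / Kd` gates the verdict: `"reliable"` for
#' c > 1, otherwise `"weak_qualitative"` — below c = 1 the isotherm shape no
#' longer determines Kd and the number is reported as indicative only,
#' regardless of how small the residuals are.
#'
#' @param corrected a baseline-corrected [itc_thermogram()]
#' @param float_n float the stoichiometry within (0.5, 2) (default) or fix
#'   n = 1
#' @param exclude_first drop the priming injection from the objective
#' @param starts log10 Kd starting decades for the multi-start
#' @return an `itc_fit` object; see [tidy()] and [glance()] methods
#' @export
fit_one_site <- function(corrected, float_n = TRUE, exclude_first = TRUE,
                         starts = c(-4, -5, -6)) {
  stopifnot(inherits(corrected, "itc_thermogram"))
  protocol <- thermo_protocol(corrected)
  obs <- corrected$heat_ucal
  use <- if (exclude_first) seq_along(obs)[-1] else seq_along(obs)
  if (length(use) < 6) {
    abort("need at least 6 informative injections",
          class = "nrpsdock_insufficient_data")
  }
  amplitude <- diff(range(obs[use]))
  if (amplitude < 1e-9) {
    warn("thermogram carries no heat signal; Kd is unidentifiable")
    return(structure(
      list(params = tibble(term = c("n", "kd", "dh", "baseline"),
                           estimate = NA_real_, std.error = NA_real_),
           kd = NA_real_, n = NA_real_, dh = NA_real_, baseline = NA_real_,
           c_value = NA_real_, verdict = "unidentifiable",
           mode = attr(corrected, "baseline_mode") %||% "none",
           identifiable = FALSE, data = corrected, fitted = NULL,
           convergence = NA, label = attr(corrected, "label")),
      class = "itc_fit"
    ))
  }

  # crude dH start from total evolved heat assuming full conversion
  dh0 <- sum(obs[use]) * 1e-6 / (protocol$cell_volume * protocol$cell_conc)

  model_heats <- function(par) {
    p <- binding_params(
      n = if (float_n) par[["n"]] else 1,
      kd = 10^par[["log_kd"]], dh = par[["dh"]], baseline = par[["baseline"]]
    )
    itc_heats(p, protocol)$heat_ucal
  }
  resid_fn <- function(par) model_heats(par)[use] - obs[use]

  lower <- c(log_kd = -12, dh = -Inf, baseline = -Inf)
  upper <- c(log_kd = -1, dh = Inf, baseline = Inf)
  if (float_n) {
    lower <- c(n = 0.5, lower); upper <- c(n = 2.0, upper)
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(log_kd = s, dh = dh0, baseline = 0)
    if (float_n) par0 <- c(n = 1, par0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    abort("one-site fit failed to converge from any start",
          class = "nrpsdock_convergence_error")
  }
  par <- coef(best)
  n_hat <- if (float_n) par[["n"]] else 1
  kd_hat <- 10^par[["log_kd"]]
  dof <- max(length(use) - length(par), 1)
  sigma2 <- best$deviance / dof
  # nls.lm's hessian is the Gauss-Newton J'J at the optimum
  vc <- tryCatch(sigma2 * solve(best$hessian),
                 error = function(e) matrix(NA_real_, length(par), length(par),
                                            dimnames = list(names(par), names(par))))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(par)
  # delta method: SE(Kd) from SE(log10 Kd)
  kd_se <- kd_hat * log(10) * se[["log_kd"]]

  cval <- c_value(n_hat, kd_hat, protocol$cell_conc)
  verdict <- if (cval > 1) "reliable" else "weak_qualitative"
  params <- tibble(
    term = c("n", "kd", "dh", "baseline"),
    estimate = c(n_hat, kd_hat, par[["dh"]], par[["baseline"]]),
    std.error = c(if (float_n) se[["n"]] else 0, kd_se,
                  se[["dh"]], se[["baseline"]])
  )
  structure(
    list(params = params, kd = kd_hat, n = n_hat, dh = par[["dh"]],
         baseline = par[["baseline"]], c_value = cval, verdict = verdict,
         mode = attr(corrected, "baseline_mode") %||% "none",
         identifiable = TRUE, data = corrected,
         fitted = model_heats(par), residuals = resid_fn(par),
         rss = best$deviance, convergence = best$info,
         label = attr(corrected, "label")),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!isTRUE(x$identifiable)) {
    cat("<itc_fit> unidentifiable (no heat signal)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<itc_fit> %s\n  Kd = %.3g M, n = %.2f, dH = %.3g kcal/mol\n  c = %.3g -> %s\n",
    if (nzchar(x$label %||% "")) x$label else "one-site fit",
    x$kd, x$n, x$dh / 1000, x$c_value, x$verdict))
  invisible(x)
}

#' Summarise replicate ITC fits of the same pair
#'
#' Independent titrations of the same docking-domain pair are summarised as
#' mean Kd +/- standard deviation, the conventional replicate report.
#'
#' @param fits list of [fit_one_site()] results sharing one label
#' @return one-row tibble: `label`, `n_replicates`, `kd_mean`, `kd_sd`,
#'   `c_min`, `verdict` (worst-case across replicates)
#' @export
replicate_summary <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "itc_fit")))
  labels <- unique(vapply(fits, function(f) f$label %||% "", ""))
  if (length(labels) != 1) {
    abort(paste0("fits are of different pairs: ",
                 paste(labels, collapse = " vs ")),
          class = "nrpsdock_pairing_error")
  }
  kds <- vapply(fits, `[[`, 0, "kd")
  cs <- vapply(fits, `[[`, 0, "c_value")
  verdicts <- vapply(fits, `[[`, "", "verdict")
  tibble(
    label = labels, n_replicates = length(fits),
    kd_mean = mean(kds), kd_sd = sd(kds), c_min = min(cs),
    verdict = if (any(verdicts == "weak_qualitative")) "weak_qualitative"
              else "reliable"
  )
}
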