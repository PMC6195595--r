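# broom-style tidiers for the fitted objects.

#' @export
tidy.itc_fit <- function(x, ...) x$params

#' @export
glance.itc_fit <- function(x, ...) {
  tibble(
    kd = x$kd, n = x$n, dh = x$dh, baseline = x$baseline,
    c_value = x$c_value, verdict = x$verdict, baseline_mode = x$mode,
    rss = x$rss %||% NA_real_, identifiable = isTRUE(x$identifiable)
  )
}

#' @export
tidy.csp_fit <- function(x, ...) {
  dplyr::rename(x$amplitudes, estimate = "saturation_delta")
}

#' @export
glance.csp_fit <- function(x, ...) {
  tibble(
    kd = x$kd, kd_ci_low = x$kd_ci[1], kd_ci_high = x$kd_ci[2],
    n_residues = nrow(x$amplitudes), n_points = x$diagnostics$n_points,
    saturation_at_max_ratio = x$diagnostics$saturation_at_max_ratio,
    ssr = x$diagnostics$ssr
  )
}

#' @export
tidy.register_pairing <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "register_pairing")
  out
}

#' @export
glance.register_pairing <- function(x, ...) {
  tibble(
    ndd_id = attr(x, "ndd_id") %||% NA_character_,
    cdd_id = attr(x, "cdd_id") %||% NA_character_,
    total_score = total_score(x),
    n_salt_bridges = sum(x$label == "salt_bridge"),
    n_clashes = sum(x$label == "clash")
  )
}
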