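# File-level workflows tying the analysis modules together: each reads the
# documented CSV/FASTA dialects, runs one analysis stage, writes tabular
# reports plus a provenance log, and returns the results invisibly.

#' Read/write a titration CSV
#'
#' Columns: `residue`, `ratio`, `h_ppm`, `n_ppm`, `observable`.
#' @param path file path
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nrpsdock_io_error")
  }
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(out) == 0) {
    abort(paste0("no data rows in ", path), class = "nrpsdock_parse_error")
  }
  check_titration(out)
}

#' @rdname read_titration_csv
#' @param data titration tibble
#' @export
write_titration_csv <- function(data, path) {
  readr::write_csv(check_titration(data), path)
  invisible(path)
}

#' Read/write a thermogram CSV (`injection`, `heat_ucal`)
#'
#' The protocol travels in comment header lines (`# key=value`).
#' @param path file path
#' @export
read_thermogram_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nrpsdock_io_error")
  }
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", header), "=")
  fields <- setNames(
    lapply(kv, function(x) utils::type.convert(x[2], as.is = TRUE)),
    vapply(kv, `[[`, "", 1)
  )
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("injection", "heat_ucal") %in% names(data))) {
    abort(paste0("thermogram CSV needs columns injection, heat_ucal: ", path),
          class = "nrpsdock_parse_error")
  }
  protocol <- itc_protocol(
    cell_conc = fields$cell_conc %||% 50e-6,
    syringe_conc = fields$syringe_conc %||% 1e-3,
    cell_volume = fields$cell_volume %||% 200e-6,
    first_volume = fields$first_volume %||% 0.2e-6,
    inj_volume = fields$inj_volume %||% 2e-6,
    n_inj = fields$n_inj %||% nrow(data)
  )
  itc_thermogram(data$heat_ucal, protocol, fields$label %||% "")
}

#' @rdname read_thermogram_csv
#' @param thermo an [itc_thermogram()]
#' @export
write_thermogram_csv <- function(thermo, path) {
  p <- thermo_protocol(thermo)
  header <- sprintf("# %s=%s",
                    c("cell_conc", "syringe_conc", "cell_volume",
                      "first_volume", "inj_volume", "n_inj", "label"),
                    c(format(c(p$cell_conc, p$syringe_conc, p$cell_volume,
                               p$first_volume, p$inj_volume), digits = 12),
                      p$n_inj, attr(thermo, "label") %||% ""))
  writeLines(header, path)
  readr::write_csv(tibble(injection = thermo$injection,
                          heat_ucal = thermo$heat_ucal),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_run_log <- function(out_dir, inputs, config) {
  lines <- c(
    paste0("package=nrpsdock ", as.character(utils::packageVersion("nrpsdock"))),
    paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("input=", inputs),
    paste0("config_hash=", rlang::hash(config))
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

#' Run the CSP mapping workflow on a titration CSV
#'
#' Computes the endpoint CSP profile, maps the binding site, and writes
#' `csp_profile.csv`, `binding_site.tsv`, a provenance log, and (optionally)
#' a histogram plot.
#'
#' @param titration_csv input path
#' @param out_dir output directory (created if absent)
#' @param endpoint_ratio endpoint molar ratio (default: largest present)
#' @param n_mad threshold rule, see [map_binding_site()]
#' @param plot write `csp_profile.png`
#' @return invisibly, list with `profile` and `sites`
#' @export
run_csp <- function(titration_csv, out_dir, endpoint_ratio = NULL, n_mad = 4,
                    plot = FALSE) {
  data <- read_titration_csv(titration_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profile <- csp_profile(data, endpoint_ratio = endpoint_ratio)
  sites <- map_binding_site(profile, n_mad = n_mad)
  readr::write_csv(profile, file.path(out_dir, "csp_profile.csv"))
  readr::write_tsv(sites, file.path(out_dir, "binding_site.tsv"))
  if (plot) {
    ggplot2::ggsave(file.path(out_dir, "csp_profile.png"),
                    autoplot(profile), width = 7, height = 3.5, dpi = 150)
  }
  write_run_log(out_dir, titration_csv,
                list(endpoint_ratio = endpoint_ratio, n_mad = n_mad))
  invisible(list(profile = profile, sites = sites))
}

#' Run the ITC fitting workflow on a thermogram CSV
#'
#' Baseline-corrects, fits the one-site model, and writes the corrected
#' thermogram, a JSON fit report (parameters, standard errors, c-value,
#' verdict), a provenance log, and (optionally) an isotherm plot.
#'
#' @param thermogram_csv input path
#' @param out_dir output directory
#' @param baseline `"plateau"` or `"buffer"`
#' @param buffer_csv matched buffer-run CSV, for buffer mode
#' @param float_n float the stoichiometry
#' @param plot write `isotherm.png`
#' @return invisibly, the [fit_one_site()] result
#' @export
run_itc <- function(thermogram_csv, out_dir, baseline = "plateau",
                    buffer_csv = NULL, float_n = TRUE, plot = FALSE) {
  raw <- read_thermogram_csv(thermogram_csv)
  buffer_run <- if (!is.null(buffer_csv)) read_thermogram_csv(buffer_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corrected <- baseline_correct(raw, mode = baseline, buffer_run = buffer_run)
  fit <- fit_one_site(corrected, float_n = float_n)
  write_thermogram_csv(corrected, file.path(out_dir, "corrected.csv"))
  report <- list(
    label = fit$label, params = fit$params, c_value = fit$c_value,
    verdict = fit$verdict, baseline_mode = fit$mode,
    identifiable = fit$identifiable, rss_ucal2 = fit$rss
  )
  jsonlite::write_json(report, file.path(out_dir, "itc_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plot && isTRUE(fit$identifiable)) {
    ggplot2::ggsave(file.path(out_dir, "isotherm.png"), autoplot(fit),
                    width = 5, height = 4, dpi = 150)
  }
  write_run_log(out_dir, thermogram_csv,
                list(baseline = baseline, float_n = float_n))
  invisible(fit)
}

#' Run the recognition-rules workflow
#'
#' * `action = "score"`: score one NDD/CDD pair, write `pairing.tsv`
#' * `action = "rank"`: rank-consistency report on a ladder, write
#'   `rank_report.tsv` (scored ladder) and `inversions.tsv`
#' * `action = "suggest"`: reprogramming proposals, write `suggestions.tsv`
#' * `action = "scan"`: scan a FASTA of proteins for candidate CDD termini,
#'   write `scan_report.tsv`
#'
#' @param action one of `"score"`, `"rank"`, `"suggest"`, `"scan"`
#' @param out_dir output directory
#' @param ndd an [ndd_features()] or the name of a bundled Kj12 NDD
#'   (`"Kj12A"`, `"Kj12B"`, `"Kj12C"`)
#' @param cdd a CDD [dd_seq()], the name of a bundled CDD, or (for `scan`) a
#'   FASTA path
#' @param ladder ladder tibble for `rank` (default: the bundled Kj12 ladder)
#' @param objective,mutable_side for `suggest`, see [suggest_reprogramming()]
#' @param top_k rows returned by `suggest`/`scan`
#' @param rules rule table
#' @return invisibly, the underlying result object
#' @export
run_dock <- function(action = c("score", "rank", "suggest", "scan"),
                     out_dir, ndd = NULL, cdd = NULL, ladder = NULL,
                     objective = "strengthen", mutable_side = "CDD",
                     top_k = 10L, rules = default_rules()) {
  action <- match.arg(action)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(ndd)) ndd <- kj12_ndd_features()[[ndd]]
  if (is.character(cdd) && action != "scan") cdd <- kj12_cdds()[[cdd]]
  result <- switch(action,
    score = {
      pairing <- score_pair(ndd, beta3_register(cdd), rules)
      out <- dplyr::mutate(as_tibble(pairing),
                           total = total_score(pairing))
      readr::write_tsv(out, file.path(out_dir, "pairing.tsv"))
      pairing
    },
    rank = {
      ladder <- ladder %||% kj12_ladder()
      rep <- rank_consistency(ladder, rules)
      readr::write_tsv(rep$scored, file.path(out_dir, "rank_report.tsv"))
      readr::write_tsv(rep$inversions, file.path(out_dir, "inversions.tsv"))
      rep
    },
    suggest = {
      sets <- suggest_reprogramming(ndd, beta3_register(cdd),
                                    objective = objective,
                                    mutable_side = mutable_side,
                                    top_k = top_k, rules = rules)
      readr::write_tsv(sets, file.path(out_dir, "suggestions.tsv"))
      sets
    },
    scan = {
      seqs <- if (is.character(cdd)) {
        set <- Biostrings::readAAStringSet(cdd)
        setNames(as.character(set), sub("\\s.*", "", names(set)))
      } else cdd
      hits <- scan_for_cdd_termini(seqs, ndd, top_k = top_k, rules = rules)
      readr::write_tsv(hits, file.path(out_dir, "scan_report.tsv"))
      hits
    }
  )
  write_run_log(out_dir, action,
                list(action = action, objective = objective,
                     mutable_side = mutable_side, top_k = top_k,
                     weights = rules$weights))
  invisible(result)
}
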