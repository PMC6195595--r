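#' Key-residue feature set of an N-terminal docking domain
#'
#' The CDD-facing surface of these NDDs is strand beta2 plus helix alpha2.
#' Four beta2 positions carry the recognition code: 24 and 28 make the two
#' inter-strand salt bridges, 27 packs against the small register -3 side
#' chain, and 26 is mutated in reprogramming experiments but is not assigned
#' a contact by the default rules. Two hydrophobic pockets (at alpha2 and at
#' beta2/loop2) bury the register -1 and -5 side chains.
#'
#' Unknown positions are stored as `NA` and never silently defaulted: scoring
#' a contact that needs an unknown residue is an error.
#'
#' @param id identifier
#' @param res24,res26,res27,res28 one-letter codes (or `NA` if unknown)
#' @param pocket_alpha2,pocket_beta2 logical pocket flags
#' @param notes provenance note
#' @return an `ndd_features` object
#' @export
ndd_features <- function(id, res24, res28, res26 = NA_character_,
                         res27 = NA_character_, pocket_alpha2 = TRUE,
                         pocket_beta2 = TRUE, notes = NULL) {
  if (is.na(res24) || is.na(res28)) {
    abort("positions 24 and 28 must be defined",
          class = "nrpsdock_unknown_feature")
  }
  for (r in c(res24, res26, res27, res28)) {
    if (!is.na(r) && !(r %in% AA_CODES)) {
      abort(paste0("invalid residue code: ", r),
            class = "nrpsdock_alphabet_error")
    }
  }
  structure(
    list(id = id, res24 = res24, res26 = res26, res27 = res27, res28 = res28,
         pocket_alpha2 = pocket_alpha2, pocket_beta2 = pocket_beta2,
         notes = notes),
    class = "ndd_features"
  )
}

#' @export
print.ndd_features <- function(x, ...) {
  cat(sprintf("<ndd_features> %s: 24=%s 26=%s 27=%s 28=%s\n", x$id,
              x$res24, x$res26, x$res27, x$res28))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Default recognition-rule table
#'
#' Editable weights for the five register contacts. The defaults are
#' uncalibrated priors that reproduce the qualitative affinity ordering of
#' the Kj12 system: salt bridges dominate (+2), charge clashes penalise
#' symmetric (-2), a hydrogen bond can substitute for a bridge (+1), glycine
#' at register -3 is required for the tight aromatic stacking (+1; alanine
#' -1, anything larger -2), and each buried large hydrophobic side chain at
#' -1/-5 adds +1 (smaller or polar replacements -1).
#'
#' `his_charged` switches histidine from neutral-but-H-bond-capable (the
#' default at the experimental pH 6.5) to formally positive.
#'
#' @param weights named numeric vector of contact-label weights
#' @param his_charged logical
#' @return a `dock_rules` list
#' @export
default_rules <- function(weights = NULL, his_charged = FALSE) {
  w <- c(salt_bridge = 2, clash = -2, h_bond = 1, neutral = 0,
         steric_ok = 1, steric_penalty = -1, steric_block = -2,
         hydrophobic_fit = 1, hydrophobic_loss = -1)
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(list(weights = w, his_charged = his_charged),
            class = "dock_rules")
}

# Label one electrostatic beta2<->beta3 contact.
electro_label <- function(aa_ndd, aa_reg, rules) {
  qa <- aa_charge(aa_ndd, rules$his_charged)
  qb <- aa_charge(aa_reg, rules$his_charged)
  if (qa * qb < 0) return("salt_bridge")  # polarity-reversed bridges included
  if (qa * qb > 0) return("clash")
  if ((abs(qa) > 0 && aa_hbond_polar(aa_reg, rules$his_charged)) ||
      (abs(qb) > 0 && aa_hbond_polar(aa_ndd, rules$his_charged))) {
    return("h_bond")
  }
  "neutral"
}

steric_label <- function(aa_reg) {
  if (aa_reg == "G") "steric_ok"
  else if (aa_reg == "A") "steric_penalty"
  else "steric_block"
}

hydrophobic_label <- function(aa_reg) {
  if (aa_reg %in% AA_LARGE_HYDROPHOBIC) "hydrophobic_fit"
  else "hydrophobic_loss"
}

register_aa <- function(register, pos) {
  aa <- register$aa[register$position == pos]
  if (length(aa) != 1 || is.na(aa)) {
    abort(sprintf("register position %d is unknown", pos),
          class = "nrpsdock_unknown_feature")
  }
  aa
}

#' Score an NDD/CDD pair from its beta-strand registers
#'
#' Evaluates the five recognition contacts between the beta2 key residues of
#' the NDD and the beta3 register (last five residues) of the CDD:
#'
#' * electrostatic: NDD 24 vs register -2, NDD 28 vs register -4
#' * steric: NDD 27 vs register -3 (graded on the register side chain)
#' * hydrophobic burial: alpha2 pocket vs register -1, beta2/loop2 pocket vs
#'   register -5
#'
#' @param ndd an [ndd_features()]
#' @param register a [beta3_register()] (or a CDD [dd_seq()], whose register
#'   is extracted)
#' @param rules a [default_rules()] table
#' @return a `register_pairing` tibble with one row per contact and columns
#'   `contact`, `ndd_residue`, `position`, `register_aa`, `label`, `score`;
#'   the total is available via [total_score()]
#' @export
score_pair <- function(ndd, register, rules = default_rules()) {
  stopifnot(inherits(ndd, "ndd_features"))
  if (inherits(register, "dd_seq")) register <- beta3_register(register)
  if (nrow(register) != 5) {
    abort("register must have exactly five positions",
          class = "nrpsdock_value_error")
  }
  w <- rules$weights
  rows <- list(
    list(contact = "electro_24_m2", ndd_residue = ndd$res24, position = -2L,
         label = electro_label(ndd$res24, register_aa(register, -2), rules)),
    list(contact = "electro_28_m4", ndd_residue = ndd$res28, position = -4L,
         label = electro_label(ndd$res28, register_aa(register, -4), rules)),
    list(contact = "steric_27_m3", ndd_residue = ndd$res27, position = -3L,
         label = steric_label(register_aa(register, -3))),
    list(contact = "pocket_alpha2_m1", ndd_residue = NA_character_,
         position = -1L, label = hydrophobic_label(register_aa(register, -1))),
    list(contact = "pocket_beta2_m5", ndd_residue = NA_character_,
         position = -5L, label = hydrophobic_label(register_aa(register, -5)))
  )
  out <- purrr::map_dfr(rows, function(r) {
    tibble(contact = r$contact, ndd_residue = r$ndd_residue,
           position = r$position,
           register_aa = register_aa(register, r$position),
           label = r$label, score = unname(w[[r$label]]))
  })
  class(out) <- c("register_pairing", class(out))
  attr(out, "total") <- sum(out$score)
  attr(out, "ndd_id") <- ndd$id
  attr(out, "cdd_id") <- attr(register, "source_id")
  out
}

#' Total recognition score of a pairing
#' @param pairing a [score_pair()] result
#' @export
total_score <- function(pairing) {
  stopifnot(inherits(pairing, "register_pairing"))
  attr(pairing, "total")
}

#' @export
print.register_pairing <- function(x, ...) {
  cat(sprintf("<register_pairing> %s / %s, total %+d\n",
              attr(x, "ndd_id") %||% "?", attr(x, "cdd_id") %||% "?",
              as.integer(attr(x, "total"))))
  NextMethod()
}

#' Calibrate affinity-class cutpoints on a reference ladder
#'
#' Fits three monotone cutpoints on the total score such that the observed
#' affinity classes of a reference ladder (strong/moderate/weak from the
#' measured Kd, none for censored pairs) are reproduced as well as possible:
#' all (c_weak, c_moderate, c_strong) triples on the midpoint grid between
#' observed scores are searched and the triple with the fewest
#' misclassifications (widest margins among ties) is kept.
#'
#' @param ladder an affinity ladder, see [kj12_ladder()]
#' @param rules a [default_rules()] table
#' @param class_breaks_um Kd breakpoints (uM) mapping numeric rows to classes:
#'   Kd <= first -> strong, <= second -> moderate, else weak
#' @return a `dock_calibration` object with the cutpoints and the scored
#'   ladder used for the fit
#' @export
calibrate_classes <- function(ladder = kj12_ladder(), rules = default_rules(),
                              class_breaks_um = c(20, 80)) {
  scored <- score_ladder(ladder, rules)
  target <- dplyr::case_when(
    scored$censored ~ "none",
    scored$kd_um <= class_breaks_um[1] ~ "strong",
    scored$kd_um <= class_breaks_um[2] ~ "moderate",
    TRUE ~ "weak"
  )
  s <- scored$score
  grid <- sort(unique(c(s - 0.5, s + 0.5)))
  best <- NULL
  for (cw in grid) for (cm in grid[grid > cw]) for (cs in grid[grid > cm]) {
    pred <- class_from_score(s, c(weak = cw, moderate = cm, strong = cs))
    acc <- sum(pred == target)
    margin <- min(cm - cw, cs - cm)
    if (is.null(best) || acc > best$acc ||
        (acc == best$acc && margin > best$margin)) {
      best <- list(cuts = c(weak = cw, moderate = cm, strong = cs),
                   acc = acc, margin = margin)
    }
  }
  structure(
    list(cutpoints = best$cuts, accuracy = best$acc / length(s),
         ladder = dplyr::mutate(scored, target_class = target)),
    class = "dock_calibration"
  )
}

class_from_score <- function(score, cuts) {
  dplyr::case_when(
    score >= cuts[["strong"]] ~ "strong",
    score >= cuts[["moderate"]] ~ "moderate",
    score >= cuts[["weak"]] ~ "weak",
    TRUE ~ "none"
  )
}

#' Predict the affinity class of a pairing
#'
#' Monotone non-decreasing mapping from total score to
#' strong/moderate/weak/none through calibrated cutpoints.
#'
#' @param pairing a [score_pair()] result (or a bare total score)
#' @param calibration a [calibrate_classes()] result; there is no implicit
#'   default — calibrate on a ladder first
#' @return character class
#' @export
predict_class <- function(pairing, calibration) {
  if (missing(calibration) || !inherits(calibration, "dock_calibration")) {
    abort("no calibration supplied; run calibrate_classes() on a ladder first",
          class = "nrpsdock_uncalibrated")
  }
  score <- if (inherits(pairing, "register_pairing")) total_score(pairing)
           else as.numeric(pairing)
  class_from_score(score, calibration$cutpoints)
}

# Score every row of an affinity ladder: resolve the NDD features and CDD
# register from the bundled fixtures, apply any row mutations (lenient mode,
# because published residue numbering for the Kj12A peptide is inconsistent),
# and attach the total score.
score_ladder <- function(ladder, rules = default_rules(),
                         ndds = kj12_ndd_features(), cdds = kj12_cdds()) {
  rows <- purrr::pmap(ladder, function(ndd, cdd, cdd_mutations, ...) {
    feats <- ndds[[ndd]]
    if (is.null(feats)) {
      abort(paste0("unknown NDD id: ", ndd), class = "nrpsdock_value_error")
    }
    seq <- cdds[[cdd]]
    if (is.null(seq)) {
      abort(paste0("unknown CDD id: ", cdd), class = "nrpsdock_value_error")
    }
    if (!is.na(cdd_mutations) && nzchar(cdd_mutations)) {
      muts <- strsplit(cdd_mutations, ",")[[1]]
      seq <- suppressWarnings(apply_mutations(seq, muts, strict = FALSE))
    }
    total_score(score_pair(feats, beta3_register(seq), rules))
  })
  dplyr::mutate(ladder, score = unlist(rows))
}

#' Rank consistency of recognition scores against a Kd ladder
#'
#' Scores every ladder row (mutations applied first) and reports the
#' rank correlation between total score and -log10(Kd), with censored
#' ("too weak to quantify") rows tied at the bottom of the affinity ranking,
#' plus every pairwise inversion (a tighter-binding row scoring strictly
#' lower than a weaker one).
#'
#' @param ladder affinity ladder tibble, see [kj12_ladder()]
#' @param rules a [default_rules()] table
#' @param method rank-correlation method (`"spearman"` or `"kendall"`)
#' @return list with `correlation`, `method`, `scored` (the scored ladder),
#'   `inversions` (tibble of misordered pairs)
#' @export
rank_consistency <- function(ladder = kj12_ladder(), rules = default_rules(),
                             method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (nrow(ladder) == 0) {
    abort("ladder is empty", class = "nrpsdock_value_error")
  }
  scored <- score_ladder(ladder, rules)
  if (nrow(scored) < 2) {
    inform("rank correlation undefined for a single-row ladder")
    return(list(correlation = NA_real_, method = method, scored = scored,
                inversions = tibble()))
  }
  neglog <- -log10(scored$kd_um)
  floor_val <- min(neglog, na.rm = TRUE) - 1
  neglog[scored$censored] <- floor_val
  corr <- cor(scored$score, neglog, method = method)
  pairs <- utils::combn(nrow(scored), 2)
  inv <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (neglog[i] == neglog[j]) return(tibble())
    if (neglog[i] < neglog[j]) { tmp <- i; i <- j; j <- tmp }
    if (scored$score[i] < scored$score[j]) {
      tibble(tighter = paste0(scored$ndd[i], "/", scored$cdd[i],
                              ifelse(is.na(scored$cdd_mutations[i]), "",
                                     paste0("(", scored$cdd_mutations[i], ")"))),
             weaker = paste0(scored$ndd[j], "/", scored$cdd[j],
                             ifelse(is.na(scored$cdd_mutations[j]), "",
                                    paste0("(", scored$cdd_mutations[j], ")"))),
             score_tighter = scored$score[i], score_weaker = scored$score[j])
    } else tibble()
  })
  list(correlation = corr, method = method, scored = scored, inversions = inv)
}
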