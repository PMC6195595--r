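# Reprogramming design and sequence scanning on top of the recognition rules.
# Because the default rule table is additive over the five contacts, candidate
# substitutions can be scored through per-position contribution lookups
# instead of re-scoring whole pairings.

contact_contribution <- function(ndd, pos, aa, rules) {
  w <- rules$weights
  label <- switch(as.character(pos),
    "-2" = electro_label(ndd$res24, aa, rules),
    "-4" = electro_label(ndd$res28, aa, rules),
    "-3" = steric_label(aa),
    "-1" = hydrophobic_label(aa),
    "-5" = hydrophobic_label(aa)
  )
  unname(w[[label]])
}

ndd_position_contribution <- function(pos, aa, register, rules) {
  w <- rules$weights
  switch(as.character(pos),
    "24" = unname(w[[electro_label(aa, register_aa(register, -2), rules)]]),
    "28" = unname(w[[electro_label(aa, register_aa(register, -4), rules)]]),
    # 26 and 27 carry no weight under the default rules (27's packing is
    # graded on the register side; 26 is user-extensible)
    "26" = 0,
    "27" = 0
  )
}

#' Propose reprogramming mutations for a docking-domain pair
#'
#' Enumerates substitution sets (1 up to `max_mutations` positions) on either
#' the CDD beta3 register or the NDD beta2 key positions, scores every
#' variant with the recognition rules, and returns the sets that move the
#' total score furthest in the requested direction. Every individual
#' substitution in a returned set changes the score in the direction of the
#' objective on its own. Among sets reaching the same total, smaller
#' mutation counts rank first.
#'
#' @param ndd an [ndd_features()]
#' @param register a [beta3_register()] (or CDD [dd_seq()])
#' @param objective `"strengthen"` or `"weaken"`
#' @param mutable_side `"CDD"` (register positions -5..-1) or `"NDD"`
#'   (positions 24, 26, 27, 28)
#' @param max_mutations largest set size to consider (default 3)
#' @param top_k number of sets to return (ties with the last kept row are
#'   included)
#' @param rules a [default_rules()] table
#' @return tibble with columns `mutations` (comma-separated specs in parent
#'   numbering), `size`, `new_score`, `delta`, sorted best-first; zero rows
#'   (with a `message` attribute) when no substitution can improve the pair
#' @export
suggest_reprogramming <- function(ndd, register,
                                  objective = c("strengthen", "weaken"),
                                  mutable_side = c("CDD", "NDD"),
                                  max_mutations = 3L, top_k = 10L,
                                  rules = default_rules()) {
  objective <- match.arg(objective)
  mutable_side <- match.arg(mutable_side)
  stopifnot(inherits(ndd, "ndd_features"))
  if (inherits(register, "dd_seq")) register <- beta3_register(register)
  sign <- if (objective == "strengthen") 1 else -1
  current_total <- total_score(score_pair(ndd, register, rules))

  if (mutable_side == "CDD") {
    positions <- register$position
    current_aa <- setNames(register$aa, positions)
    numbers <- setNames(register$residue_number, positions)
    contrib <- function(pos, aa) contact_contribution(ndd, pos, aa, rules)
    spec_of <- function(pos, aa) {
      paste0(current_aa[[as.character(pos)]], numbers[[as.character(pos)]], aa)
    }
  } else {
    positions <- c(24L, 26L, 27L, 28L)
    current_aa <- setNames(
      c(ndd$res24, ndd$res26, ndd$res27, ndd$res28), positions)
    if (anyNA(current_aa)) {
      positions <- positions[!is.na(current_aa)]
      current_aa <- current_aa[!is.na(current_aa)]
    }
    contrib <- function(pos, aa) {
      ndd_position_contribution(pos, aa, register, rules)
    }
    spec_of <- function(pos, aa) {
      paste0(current_aa[[as.character(pos)]], pos, aa)
    }
  }

  # strictly improving single substitutions per position
  candidates <- purrr::map(positions, function(pos) {
    cur <- current_aa[[as.character(pos)]]
    base <- contrib(pos, cur)
    alts <- setdiff(AA_CODES, cur)
    deltas <- vapply(alts, function(aa) contrib(pos, aa) - base, 0,
                     USE.NAMES = FALSE)
    keep <- sign * deltas > 0
    tibble(position = pos, aa = alts[keep], delta = deltas[keep],
           spec = vapply(alts[keep], function(aa) spec_of(pos, aa), "",
                         USE.NAMES = FALSE))
  })
  names(candidates) <- as.character(positions)
  candidates <- purrr::keep(candidates, ~ nrow(.x) > 0)
  if (length(candidates) == 0) {
    out <- tibble(mutations = character(), size = integer(),
                  new_score = numeric(), delta = numeric())
    attr(out, "message") <- "no single substitution moves the score in the requested direction"
    return(out)
  }

  sets <- purrr::map_dfr(seq_len(min(max_mutations, length(candidates))),
                         function(k) {
    pos_sets <- utils::combn(names(candidates), k, simplify = FALSE)
    purrr::map_dfr(pos_sets, function(ps) {
      grids <- purrr::map(ps, function(p) seq_len(nrow(candidates[[p]])))
      idx <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
      delta_mat <- do.call(cbind, lapply(seq_along(ps), function(j) {
        candidates[[ps[j]]]$delta[idx[[j]]]
      }))
      spec_mat <- do.call(cbind, lapply(seq_along(ps), function(j) {
        candidates[[ps[j]]]$spec[idx[[j]]]
      }))
      tibble(
        mutations = apply(spec_mat, 1, paste, collapse = ","),
        size = k,
        delta = rowSums(delta_mat)
      )
    })
  })
  sets$new_score <- current_total + sets$delta
  ord <- order(-sign * sets$new_score, sets$size)
  sets <- sets[ord, c("mutations", "size", "new_score", "delta")]
  if (nrow(sets) > top_k) {
    cut_score <- sets$new_score[top_k]
    cut_size <- sets$size[top_k]
    keep <- seq_len(nrow(sets)) <= top_k |
      (sets$new_score == cut_score & sets$size == cut_size)
    sets <- sets[keep, ]
  }
  attr(sets, "current_score") <- current_total
  sets
}

#' Scan protein sequences for candidate CDD termini
#'
#' Rule-based surrogate for a homology survey: every sequence's C-terminal
#' 5-mer is treated as a putative beta3 register and scored against the
#' supplied NDD. Sequences shorter than 5 residues are skipped with a
#' warning.
#'
#' @param sequences named character vector of protein sequences, an
#'   `AAStringSet`, or a list of [dd_seq()]
#' @param ndd an [ndd_features()]
#' @param top_k rows to return
#' @param rules a [default_rules()] table
#' @param calibration optional [calibrate_classes()] result; adds a `class`
#'   column
#' @return tibble sorted by score: `id`, `terminus`, `total_score`, `labels`
#'   (per-contact labels -5..-1), and `class` when calibrated
#' @export
scan_for_cdd_termini <- function(sequences, ndd, top_k = 10L,
                                 rules = default_rules(), calibration = NULL) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  } else if (is.list(sequences)) {
    sequences <- setNames(
      vapply(sequences, function(s) if (inherits(s, "dd_seq")) s$sequence else s, ""),
      vapply(sequences, function(s) if (inherits(s, "dd_seq")) s$id else "", "")
    )
  }
  if (length(sequences) == 0) {
    abort("no sequences supplied", class = "nrpsdock_value_error")
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  short <- nchar(sequences) < 5
  if (any(short)) {
    warn(sprintf("skipping %d sequence(s) shorter than 5 residues: %s",
                 sum(short), paste(names(sequences)[short], collapse = ", ")))
    sequences <- sequences[!short]
  }
  rows <- purrr::imap_dfr(sequences, function(s, id) {
    cdd <- dd_seq(s, id = id, role = "CDD")
    pairing <- score_pair(ndd, beta3_register(cdd), rules)
    ordered <- pairing[order(pairing$position), ]
    tibble(id = id,
           terminus = substr(s, nchar(s) - 4, nchar(s)),
           total_score = total_score(pairing),
           labels = paste(ordered$label, collapse = "|"))
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$total_score))
  if (!is.null(calibration)) {
    rows$class <- predict_class(rows$total_score, calibration)
  }
  head(rows, top_k)
}
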