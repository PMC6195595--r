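ndds <- kj12_ndd_features()
cdds <- kj12_cdds()

test_that("pair scoring reproduces the documented contact patterns", {
  # Kj12C-NDD vs Kj12B-CDD: two salt bridges, glycine fit, two buried
  # hydrophobics
  p <- score_pair(ndds$Kj12C, beta3_register(cdds$Kj12B))
  expect_equal(total_score(p), 7)
  expect_equal(sum(p$label == "salt_bridge"), 2)
  expect_equal(p$label[p$contact == "steric_27_m3"], "steric_ok")
  expect_equal(sum(p$label == "hydrophobic_fit"), 2)

  # Kj12B-NDD: K28 clashes with R1565 instead of bridging
  p2 <- score_pair(ndds$Kj12B, beta3_register(cdds$Kj12B))
  expect_equal(total_score(p2), 3)
  expect_equal(p2$label[p2$contact == "electro_28_m4"], "clash")
  expect_equal(p2$label[p2$contact == "electro_24_m2"], "salt_bridge")

  # charge-free partners leave both electrostatic contacts at zero, so the
  # total reduces to the steric and hydrophobic terms alone
  neutral_ndd <- ndd_features("neutral", res24 = "S", res28 = "T",
                              res27 = "Y")
  neutral_reg <- beta3_register(dd_seq("LTGSI", "neutral-cdd", "CDD"))
  pn <- score_pair(neutral_ndd, neutral_reg)
  electro <- grepl("^electro", pn$contact)
  expect_true(all(pn$label[electro] == "neutral"))
  expect_true(all(pn$score[electro] == 0))
  expect_equal(total_score(pn), sum(pn$score[!electro]))
})

test_that("scoring is symmetric under full charge reversal of a bridge", {
  reg <- beta3_register(cdds$Kj12B)  # -2 = E, -4 = R
  fwd <- score_pair(ndds$Kj12C, reg)  # R24-E, E28-R
  flipped_ndd <- ndd_features("flipped", res24 = "E", res28 = "R",
                              res27 = "Y")
  flipped_reg <- beta3_register(dd_seq("LEGRI", "flipped-cdd", "CDD"))
  rev <- score_pair(flipped_ndd, flipped_reg)
  expect_equal(total_score(rev), total_score(fwd))
  expect_equal(rev$label[rev$contact == "electro_24_m2"], "salt_bridge")
})

test_that("hydrogen bonds substitute for salt bridges at +1", {
  # histidine at -2 against R24: charged + H-bond-capable polar
  reg <- beta3_register(cdds$Kj12A)
  p <- score_pair(ndds$Kj12C, reg)
  expect_equal(p$label[p$contact == "electro_24_m2"], "h_bond")
  expect_equal(p$score[p$contact == "electro_24_m2"], 1)
  # with protonated histidine the same contact becomes a clash
  p2 <- score_pair(ndds$Kj12C, reg, default_rules(his_charged = TRUE))
  expect_equal(p2$label[p2$contact == "electro_24_m2"], "clash")
})

test_that("steric grading at register -3 follows G < A < larger", {
  mk <- function(aa) beta3_register(dd_seq(paste0("LR", aa, "EI"), "x", "CDD"))
  lab <- function(aa) {
    p <- score_pair(ndds$Kj12C, mk(aa))
    p$label[p$contact == "steric_27_m3"]
  }
  expect_equal(lab("G"), "steric_ok")
  expect_equal(lab("A"), "steric_penalty")
  expect_equal(lab("W"), "steric_block")
  s <- vapply(c("G", "A", "W"), function(aa) {
    p <- score_pair(ndds$Kj12C, mk(aa))
    p$score[p$contact == "steric_27_m3"]
  }, 0)
  expect_true(all(diff(s) < 0))
})

test_that("unknown key positions raise explicit errors", {
  expect_error(ndd_features("x", res24 = NA, res28 = "E"),
               class = "nrpsdock_unknown_feature")
})

test_that("the measured affinity ladder is ordered as documented", {
  ladder <- kj12_ladder()
  expect_equal(nrow(ladder), 9)
  expect_equal(sum(ladder$censored), 2)
  # censored rows sort after numeric rows
  expect_gt(min(which(ladder$censored)), max(which(!ladder$censored)))

  rc <- rank_consistency(ladder)
  sc <- rc$scored
  key <- function(n, c, m = NA) {
    sc$score[sc$ndd == n & sc$cdd == c &
               (is.na(m) & is.na(sc$cdd_mutations) |
                  !is.na(m) & !is.na(sc$cdd_mutations) & sc$cdd_mutations == m)]
  }
  # tight pairs beat the moderate pair, which beats the weak pair
  expect_gt(key("Kj12C", "Kj12B"), key("Kj12B", "Kj12B"))
  expect_gt(key("Kj12A", "Kj12B"), key("Kj12B", "Kj12B"))
  expect_gt(key("Kj12B", "Kj12B"), key("Kj12C", "Kj12A"))
  # rescue mutations beat their parents
  expect_gt(key("Kj12B", "Kj12B", "R1565E"), key("Kj12B", "Kj12B"))
  expect_gt(key("Kj12C", "Kj12A", "E1169R,H1171E"), key("Kj12C", "Kj12A"))
  # the short peptide scores like the full-length CDD (same register)
  expect_equal(key("Kj12C", "Kj12B_short"), key("Kj12C", "Kj12B"))
  expect_true(is.numeric(rc$correlation))
})

test_that("single-row ladders have undefined correlation", {
  one <- kj12_ladder()[1, ]
  expect_message(rc <- rank_consistency(one), "undefined")
  expect_true(is.na(rc$correlation))
  expect_error(rank_consistency(kj12_ladder()[0, ]),
               class = "nrpsdock_value_error")
})

test_that("class prediction is calibrated and monotone", {
  cal <- calibrate_classes()
  expect_error(predict_class(5), class = "nrpsdock_uncalibrated")
  p_cb <- score_pair(ndds$Kj12C, beta3_register(cdds$Kj12B))
  p_bb <- score_pair(ndds$Kj12B, beta3_register(cdds$Kj12B))
  p_ca <- score_pair(ndds$Kj12C, beta3_register(cdds$Kj12A))
  expect_equal(predict_class(p_cb, cal), "strong")
  expect_equal(predict_class(p_bb, cal), "moderate")
  expect_equal(predict_class(p_ca, cal), "weak")
  # monotone non-decreasing over the whole score range
  lv <- c(none = 0, weak = 1, moderate = 2, strong = 3)
  cls <- lv[predict_class(seq(-8, 8, 0.5), cal)]
  expect_true(all(diff(cls) >= 0))
})

test_that("reprogramming proposals recover the documented designs", {
  # strengthening Kj12A-CDD for Kj12C-NDD: the documented double swap
  # (E1169R + H1171E) restores both salt bridges and tops the list
  sug <- suggest_reprogramming(ndds$Kj12C, beta3_register(cdds$Kj12A),
                               "strengthen", "CDD", max_mutations = 2)
  best <- sug[sug$new_score == max(sug$new_score), ]
  expect_true("E1169R,H1171E" %in% best$mutations)
  expect_equal(unique(best$size), 2)

  # strengthening Kj12B-NDD for Kj12B-CDD: K28E restores the broken bridge
  sugn <- suggest_reprogramming(ndds$Kj12B, beta3_register(cdds$Kj12B),
                                "strengthen", "NDD")
  bestn <- sugn[sugn$new_score == max(sugn$new_score), ]
  expect_true("K28E" %in% bestn$mutations)
  expect_equal(unique(bestn$size), 1)

  # the documented weakening pair on Kj12C-NDD lowers the score
  weakened <- ndd_features("Kj12C-mut", res24 = "R", res26 = "K",
                           res27 = "Y", res28 = "A")
  expect_lt(total_score(score_pair(weakened, beta3_register(cdds$Kj12B))),
            total_score(score_pair(ndds$Kj12C, beta3_register(cdds$Kj12B))))
})

test_that("every proposed substitution moves the score as requested", {
  reg <- beta3_register(cdds$Kj12A)
  for (obj in c("strengthen", "weaken")) {
    sug <- suggest_reprogramming(ndds$Kj12C, reg, obj, "CDD",
                                 max_mutations = 2, top_k = 5)
    sgn <- if (obj == "strengthen") 1 else -1
    base <- total_score(score_pair(ndds$Kj12C, reg))
    for (row in seq_len(nrow(sug))) {
      specs <- strsplit(sug$mutations[row], ",")[[1]]
      # re-score the full set from scratch via sequence mutation
      mutated <- suppressWarnings(
        apply_mutations(cdds$Kj12A, specs, strict = FALSE))
      rescored <- total_score(score_pair(ndds$Kj12C,
                                         beta3_register(mutated)))
      expect_equal(rescored, sug$new_score[row])
      # each single substitution individually moves in the right direction
      for (spec in specs) {
        single <- suppressWarnings(
          apply_mutations(cdds$Kj12A, spec, strict = FALSE))
        delta1 <- total_score(score_pair(ndds$Kj12C,
                                         beta3_register(single))) - base
        expect_gt(sgn * delta1, 0)
      }
    }
  }
})

test_that("an already optimal pair yields no strengthening proposals", {
  best_reg <- beta3_register(dd_seq("LRGEI", "opt", "CDD"))
  sug <- suggest_reprogramming(ndds$Kj12C, best_reg, "strengthen", "CDD")
  expect_equal(nrow(sug), 0)
  expect_match(attr(sug, "message"), "no single substitution")
})

test_that("terminus scanning finds planted partners and rejects decoys", {
  dec <- gen_decoy_sequences(21, 15, planted = beta3_register(cdds$Kj12B))
  hits <- scan_for_cdd_termini(dec$sequences, ndds$Kj12C)
  expect_equal(hits$id[1], "planted")
  expect_equal(hits$total_score[1], 7)

  # charge-incompatible decoys never reach a favourable score
  cal <- calibrate_classes()
  dec2 <- gen_decoy_sequences(22, 15, incompatible_with = ndds$Kj12C)
  hits2 <- scan_for_cdd_termini(dec2$sequences, ndds$Kj12C,
                                calibration = cal)
  expect_true(all(hits2$total_score < 0))
  expect_false(any(hits2$class %in% c("strong", "moderate")))

  # scanning the Kj12B CDD itself recovers its terminus as a top candidate
  self <- scan_for_cdd_termini(
    setNames(cdds$Kj12B$sequence, "Kj12B"), ndds$Kj12C)
  expect_equal(self$total_score, 7)

  expect_warning(
    scan_for_cdd_termini(c(a = "LRG", b = cdds$Kj12B$sequence), ndds$Kj12C),
    "skipping")
})
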