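# Coordinate-level verification: superposition/RMSD, NMR-ensemble precision,
# and detection of the intermolecular salt bridges and beta-sheet register
# that define the docking interface.

#' Read a PDB file into a tidy atom table
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns one row per atom per
#' model with columns `model`, `chain`, `resno`, `resid`, `elety`, `x`, `y`,
#' `z`. Multi-model (NMR ensemble) files are expanded over `model`.
#'
#' @param path PDB file path
#' @return a tibble of atoms
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nrpsdock_io_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  purrr::map_dfr(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    tibble(model = m, chain = at$chain, resno = at$resno, resid = at$resid,
           elety = at$elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

#' Build an atom table in code (for fixtures and examples)
#'
#' @param chain,resno,resid,elety,x,y,z atom fields, recycled as needed
#' @param model model index
#' @return a tibble of atoms in the [read_structure()] layout
#' @export
structure_tbl <- function(chain, resno, resid, elety, x, y, z, model = 1L) {
  tibble(model = model, chain = chain, resno = resno, resid = resid,
         elety = elety, x = x, y = y, z = z)
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation minimising the
#' RMSD between paired coordinate sets, via the SVD of the covariance matrix
#' of the centred coordinates.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fit is
#'   `mobile %*% rotation + translation`), `rmsd` (Angstrom), and `fitted`
#'   coordinates
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be matched n x 3 matrices",
          class = "nrpsdock_pairing_error")
  }
  if (nrow(mobile) < 3) {
    abort("need at least 3 paired atoms", class = "nrpsdock_value_error")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  h <- crossprod(a, b)
  sv <- svd(h)
  if (sv$d[2] < 1e-10) {
    abort("degenerate (collinear) geometry; superposition is rank-deficient",
          class = "nrpsdock_rank_error")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(a %*% t(rot), 2, cr, `+`)
  list(rotation = t(rot), translation = cr - cm %*% t(rot),
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
       fitted = fitted)
}

#' Superpose two structure models and report the RMSD
#'
#' Atoms are paired by (chain, residue number, atom name); the selection can
#' be restricted to given residues, chains, and atom names (default: the
#' backbone N, CA, C, O).
#'
#' @param mobile,reference atom tables ([read_structure()] layout), one model
#'   each
#' @param atoms atom names to use
#' @param residues optional residue numbers to restrict to
#' @param chains optional chains to restrict to
#' @return the [kabsch()] result, with the paired atom count as `n_atoms`
#' @export
superpose_rmsd <- function(mobile, reference,
                           atoms = c("N", "CA", "C", "O"),
                           residues = NULL, chains = NULL) {
  pick <- function(tb) {
    tb <- dplyr::filter(tb, .data$elety %in% atoms)
    if (!is.null(residues)) tb <- dplyr::filter(tb, .data$resno %in% residues)
    if (!is.null(chains)) tb <- dplyr::filter(tb, .data$chain %in% chains)
    dplyr::arrange(tb, .data$chain, .data$resno, .data$elety)
  }
  a <- pick(mobile); b <- pick(reference)
  key <- function(tb) paste(tb$chain, tb$resno, tb$elety)
  shared <- intersect(key(a), key(b))
  a <- a[match(shared, key(a)), ]; b <- b[match(shared, key(b)), ]
  if (nrow(a) < 3) {
    abort("fewer than 3 paired atoms in the selection",
          class = "nrpsdock_pairing_error")
  }
  out <- kabsch(coords_matrix(a), coords_matrix(b))
  out$n_atoms <- nrow(a)
  out
}

#' Coordinate precision of a structural ensemble
#'
#' Mean pairwise backbone RMSD over all model pairs, restricted to a stated
#' set of ordered residues — the standard precision statistic for NMR
#' ensembles. The ordered set is typically defined by heteronuclear NOE
#' ratios above 0.6 or by the secondary-structure elements.
#'
#' @param ensemble multi-model atom table
#' @param residues residue numbers of the ordered set
#' @param atoms atom names (default backbone)
#' @param chains optional chain restriction
#' @return mean pairwise RMSD (Angstrom), with the per-pair values as
#'   attribute `"pairwise"`
#' @export
ensemble_precision <- function(ensemble, residues,
                               atoms = c("N", "CA", "C", "O"),
                               chains = NULL) {
  if (length(residues) == 0) {
    abort("ordered residue set is empty", class = "nrpsdock_value_error")
  }
  models <- sort(unique(ensemble$model))
  if (length(models) < 2) {
    abort("need at least 2 models", class = "nrpsdock_value_error")
  }
  pairs <- utils::combn(models, 2)
  vals <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- dplyr::filter(ensemble, .data$model == pairs[1, k])
    b <- dplyr::filter(ensemble, .data$model == pairs[2, k])
    superpose_rmsd(a, b, atoms = atoms, residues = residues,
                   chains = chains)$rmsd
  }, 0)
  out <- mean(vals)
  attr(out, "pairwise") <- vals
  out
}

SIDECHAIN_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
SIDECHAIN_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect inter-chain salt bridges
#'
#' Reports residue pairs where a side-chain nitrogen of Lys/Arg (His
#' optionally, via `his_charged`) on one chain lies within `cutoff` of a
#' side-chain carboxylate oxygen of Asp/Glu on the other, with the minimum
#' N-O distance per pair. Multi-model files are evaluated per model and a
#' consensus (pair present in at least half the models) is returned.
#'
#' @param complex_atoms atom table of the complex
#' @param chain_a,chain_b the two chains to examine (order does not matter)
#' @param cutoff maximum N-O distance (Angstrom, default 4.0)
#' @param his_charged count histidine as a salt-bridge donor
#' @return tibble: `basic_chain`, `basic_resno`, `basic_resid`,
#'   `acidic_chain`, `acidic_resno`, `acidic_resid`, `min_dist`,
#'   `n_models`, `frac_models`
#' @export
find_salt_bridges <- function(complex_atoms, chain_a, chain_b, cutoff = 4.0,
                              his_charged = FALSE) {
  for (ch in c(chain_a, chain_b)) {
    if (!any(complex_atoms$chain == ch)) {
      abort(paste0("chain not present: ", ch), class = "nrpsdock_value_error")
    }
  }
  donors <- if (his_charged) SIDECHAIN_N else SIDECHAIN_N[c("LYS", "ARG")]
  models <- sort(unique(complex_atoms$model))
  per_model <- purrr::map_dfr(models, function(m) {
    at <- dplyr::filter(complex_atoms, .data$model == m,
                        .data$chain %in% c(chain_a, chain_b))
    pick_sidechain <- function(tb, atom_map) {
      tb <- dplyr::filter(tb, .data$resid %in% names(atom_map))
      if (nrow(tb) == 0) return(tb)
      keep <- vapply(seq_len(nrow(tb)), function(i) {
        tb$elety[i] %in% atom_map[[tb$resid[i]]]
      }, TRUE)
      tb[keep, ]
    }
    nat <- pick_sidechain(at, donors)
    oat <- pick_sidechain(at, SIDECHAIN_O)
    if (nrow(nat) == 0 || nrow(oat) == 0) return(tibble())
    cross <- tidyr::crossing(
      ni = seq_len(nrow(nat)), oi = seq_len(nrow(oat))
    ) |>
      dplyr::filter(nat$chain[.data$ni] != oat$chain[.data$oi])
    if (nrow(cross) == 0) return(tibble())
    d <- sqrt((nat$x[cross$ni] - oat$x[cross$oi])^2 +
                (nat$y[cross$ni] - oat$y[cross$oi])^2 +
                (nat$z[cross$ni] - oat$z[cross$oi])^2)
    tibble(
      model = m,
      basic_chain = nat$chain[cross$ni], basic_resno = nat$resno[cross$ni],
      basic_resid = nat$resid[cross$ni],
      acidic_chain = oat$chain[cross$oi], acidic_resno = oat$resno[cross$oi],
      acidic_resid = oat$resid[cross$oi],
      dist = d
    ) |>
      dplyr::group_by(.data$basic_chain, .data$basic_resno,
                      .data$basic_resid, .data$acidic_chain,
                      .data$acidic_resno, .data$acidic_resid,
                      .data$model) |>
      dplyr::summarise(dist = min(.data$dist), .groups = "drop") |>
      dplyr::filter(.data$dist <= cutoff)
  })
  if (nrow(per_model) == 0) return(per_model)
  per_model |>
    dplyr::group_by(.data$basic_chain, .data$basic_resno, .data$basic_resid,
                    .data$acidic_chain, .data$acidic_resno,
                    .data$acidic_resid) |>
    dplyr::summarise(min_dist = min(.data$dist), n_models = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(frac_models = .data$n_models / length(models)) |>
    dplyr::filter(.data$frac_models >= 0.5) |>
    dplyr::arrange(.data$min_dist)
}

#' Infer the inter-chain beta-sheet register
#'
#' Finds inter-chain backbone hydrogen bonds (amide N to carbonyl O within
#' `cutoff`; when the carbonyl carbon is present the N-O-C angle must exceed
#' `min_angle` degrees) and assembles them into a residue pairing ladder.
#' In an antiparallel sheet the paired residue numbers run in opposite
#' directions and each rung is supported by the reciprocal pair of H-bonds;
#' the ladder is flagged `antiparallel = FALSE` when the pairing trend is
#' parallel instead.
#'
#' @param complex_atoms atom table (single model is used; pass a filtered
#'   table or the first model of an ensemble)
#' @param chain_a,chain_b chains forming the sheet
#' @param cutoff N-O distance cutoff (Angstrom, default 3.5)
#' @param min_angle minimum N-O=C angle in degrees (default 90; skipped when
#'   no carbonyl carbon is present)
#' @return list with `pairs` (tibble `resno_a`, `resno_b`, `n_hbonds`,
#'   `min_dist`) and `antiparallel` (logical, `NA` when undecidable)
#' @export
infer_beta_register <- function(complex_atoms, chain_a, chain_b,
                                cutoff = 3.5, min_angle = 90) {
  at <- dplyr::filter(complex_atoms, .data$model == min(complex_atoms$model))
  get_atoms <- function(ch, name) {
    dplyr::filter(at, .data$chain == ch, .data$elety == name)
  }
  hbonds_between <- function(ch_n, ch_o) {
    ns <- get_atoms(ch_n, "N"); os <- get_atoms(ch_o, "O")
    cs <- get_atoms(ch_o, "C")
    if (nrow(ns) == 0 || nrow(os) == 0) return(tibble())
    cross <- tidyr::crossing(i = seq_len(nrow(ns)), j = seq_len(nrow(os)))
    d <- sqrt((ns$x[cross$i] - os$x[cross$j])^2 +
                (ns$y[cross$i] - os$y[cross$j])^2 +
                (ns$z[cross$i] - os$z[cross$j])^2)
    keep <- d <= cutoff
    cross <- cross[keep, ]; d <- d[keep]
    if (nrow(cross) == 0) return(tibble())
    # angle filter when the carbonyl C of the acceptor residue is available
    ok <- vapply(seq_len(nrow(cross)), function(k) {
      cj <- dplyr::filter(cs, .data$resno == os$resno[cross$j[k]])
      if (nrow(cj) == 0) return(TRUE)
      v1 <- c(ns$x[cross$i[k]] - os$x[cross$j[k]],
              ns$y[cross$i[k]] - os$y[cross$j[k]],
              ns$z[cross$i[k]] - os$z[cross$j[k]])
      v2 <- c(cj$x[1] - os$x[cross$j[k]],
              cj$y[1] - os$y[cross$j[k]],
              cj$z[1] - os$z[cross$j[k]])
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      ang >= min_angle
    }, TRUE)
    tibble(resno_n = ns$resno[cross$i[ok]], resno_o = os$resno[cross$j[ok]],
           dist = d[ok])
  }
  ab <- hbonds_between(chain_a, chain_b)
  ba <- hbonds_between(chain_b, chain_a)
  if (nrow(ab) + nrow(ba) == 0) {
    inform("no inter-chain backbone H-bonds found")
    return(list(pairs = tibble(), antiparallel = NA))
  }
  all_pairs <- dplyr::bind_rows(
    dplyr::transmute(ab, resno_a = .data$resno_n, resno_b = .data$resno_o,
                     dist = .data$dist),
    dplyr::transmute(ba, resno_a = .data$resno_o, resno_b = .data$resno_n,
                     dist = .data$dist)
  ) |>
    dplyr::group_by(.data$resno_a, .data$resno_b) |>
    dplyr::summarise(n_hbonds = dplyr::n(), min_dist = min(.data$dist),
                     .groups = "drop") |>
    dplyr::arrange(.data$resno_a)
  trend <- if (nrow(all_pairs) >= 2) {
    cor(all_pairs$resno_a, all_pairs$resno_b, method = "spearman")
  } else NA_real_
  list(pairs = all_pairs,
       antiparallel = if (is.na(trend)) NA else trend < 0)
}
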