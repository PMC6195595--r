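test_that("superposition is exact for identical and rigidly moved copies", {
  set.seed(3)
  m <- matrix(rnorm(36), 12, 3)
  expect_lt(kabsch(m, m)$rmsd, 1e-10)

  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  moved <- m %*% rot + matrix(rep(c(3, -2, 5), each = 12), 12)
  expect_lt(kabsch(moved, m)$rmsd, 1e-8)
  # returned transform actually maps mobile onto reference
  k <- kabsch(moved, m)
  mapped <- moved %*% k$rotation + matrix(rep(k$translation, each = 12), 12)
  expect_lt(max(abs(mapped - m)), 1e-8)
})

test_that("RMSD agrees with the rotation-grid oracle and with bio3d", {
  toy <- toy_coords()
  ours <- kabsch(toy$mobile, toy$reference)$rmsd
  oracle <- oracle_min_rmsd(toy$mobile, toy$reference)
  expect_equal(ours, oracle, tolerance = 1e-3)
  # independent library cross-check
  b3d <- bio3d::rmsd(as.vector(t(toy$reference)), as.vector(t(toy$mobile)),
                     fit = TRUE)
  expect_equal(ours, b3d, tolerance = 1e-3)
})

test_that("RMSD is symmetric and invariant to pre-rotation", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(kabsch(a, b)$rmsd, kabsch(b, a)$rmsd, tolerance = 1e-9)
  th <- 0.6
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
                byrow = TRUE)
  expect_equal(kabsch(a %*% rot, b)$rmsd, kabsch(a, b)$rmsd,
               tolerance = 1e-9)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), class = "nrpsdock_rank_error")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "nrpsdock_value_error")
})

test_that("ensemble precision matches expectation under known jitter", {
  base <- toy_sheet(n_res = 8)
  sigma <- 0.1
  set.seed(9)
  ensemble <- dplyr::bind_rows(lapply(1:6, function(m) {
    jit <- dplyr::mutate(base,
                         model = m,
                         x = .data$x + rnorm(dplyr::n(), 0, sigma),
                         y = .data$y + rnorm(dplyr::n(), 0, sigma),
                         z = .data$z + rnorm(dplyr::n(), 0, sigma))
    jit
  }))
  dup <- dplyr::bind_rows(dplyr::mutate(base, model = 1),
                          dplyr::mutate(base, model = 2))
  expect_lt(ensemble_precision(dup, residues = 1:8, chains = "A"), 1e-10)

  prec <- ensemble_precision(ensemble, residues = 1:8, chains = "A")
  # two independently jittered models differ by sqrt(2) * sigma * sqrt(3)
  # per atom before the fit removes ~6 degrees of freedom
  expected <- sigma * sqrt(2) * sqrt(3)
  expect_lt(abs(prec - expected) / expected, 0.2)
  expect_error(ensemble_precision(ensemble, residues = integer(0)),
               class = "nrpsdock_value_error")
})

test_that("salt bridges are detected inside the cutoff only", {
  hit <- find_salt_bridges(toy_bridge(3.0), "A", "B")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_dist, 3.0, tolerance = 1e-9)
  expect_equal(hit$basic_resno, 24)
  expect_equal(hit$acidic_resno, 1567)

  expect_equal(nrow(find_salt_bridges(toy_bridge(4.5), "A", "B")), 0)
  # symmetric in chain order
  hit2 <- find_salt_bridges(toy_bridge(3.0), "B", "A")
  expect_equal(hit2$min_dist, hit$min_dist)
  expect_error(find_salt_bridges(toy_bridge(), "A", "Z"),
               class = "nrpsdock_value_error")
})

test_that("histidine participates in bridges only when protonated", {
  his <- dplyr::bind_rows(
    structure_tbl("A", 10, "HIS", c("N", "CA", "NE2"),
                  x = c(0, 1, 2), y = 0, z = 0),
    structure_tbl("B", 20, "GLU", c("N", "CA", "OE1"),
                  x = c(6, 5, 4.8), y = 0, z = 0)
  )
  expect_equal(nrow(find_salt_bridges(his, "A", "B")), 0)
  expect_equal(nrow(find_salt_bridges(his, "A", "B", his_charged = TRUE)), 1)
})

test_that("beta register inference recovers the antiparallel ladder", {
  sheet <- toy_sheet(n_res = 5, antiparallel = TRUE)
  reg <- infer_beta_register(sheet, "A", "B")
  expect_true(reg$antiparallel)
  expect_equal(nrow(reg$pairs), 5)
  # rung k of chain A pairs with the reversed rung of chain B
  expect_equal(reg$pairs$resno_b, 100 + (5:1))
  expect_true(all(reg$pairs$n_hbonds == 2))

  par <- infer_beta_register(toy_sheet(n_res = 5, antiparallel = FALSE),
                             "A", "B")
  expect_false(par$antiparallel)

  # strands pulled apart: no H-bonds, empty register with a diagnostic
  apart <- dplyr::mutate(sheet, y = ifelse(.data$chain == "B",
                                           .data$y + 10, .data$y))
  expect_message(none <- infer_beta_register(apart, "A", "B"), "no inter")
  expect_equal(nrow(none$pairs), 0)
})

test_that("PDB files round-trip through the atom table", {
  # write a small PDB with bio3d and read it back
  path <- withr::local_tempfile(fileext = ".pdb")
  sheet <- toy_sheet(n_res = 3)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(sheet[, c("x", "y", "z")]))),
    chain = sheet$chain, resno = sheet$resno, resid = sheet$resid,
    elety = sheet$elety
  )
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(sheet))
  expect_equal(back$x, sheet$x, tolerance = 1e-3)
  expect_equal(back$chain, sheet$chain)
  expect_error(read_structure("no/such.pdb"), class = "nrpsdock_io_error")
})
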