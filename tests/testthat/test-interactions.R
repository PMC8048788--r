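# helper: quick atom spec rows
atom_row <- function(resno, elety, elesy, x, y = 0, z = 0, resid = "ALA",
                     chain = "A", record = "ATOM") {
  data.frame(record = record, elety = elety, elesy = elesy, resid = resid,
             chain = chain, resno = resno, x = x, y = y, z = z)
}

test_that("polar contacts respect the distance cutoff and exclude intra-residue pairs", {
  s <- toy_model(rbind(
    atom_row(1, "N", "N", 0), atom_row(1, "O", "O", 1.5),  # same residue
    atom_row(2, "O", "O", 2.9),                            # 2.9 A from res-1 N
    atom_row(3, "OG", "O", 5.1)))                          # 3.6 A from res-1 O
  rec <- find_polar_contacts(s, s$atom[s$atom$resno == 1, ],
                             s$atom[s$atom$resno > 1, ])
  expect_identical(nrow(rec), 2L)  # N..O(2.9) and O(1.5)..O(2.9) at 1.4
  expect_true(all(rec$distance <= 3.4))
  expect_false(any(rec$resno_a == rec$resno_b))
  none <- find_polar_contacts(s, s$atom[s$atom$resno == 1, ],
                              s$atom[s$atom$resno == 3, ])
  expect_identical(nrow(none), 0L)
})

test_that("hydrophobic detection uses apolar side-chain carbons only", {
  s <- toy_model(rbind(
    atom_row(1, "CB", "C", 0, resid = "LEU"),
    atom_row(1, "CA", "C", 0.5, resid = "LEU"),   # backbone: excluded
    atom_row(2, "CD1", "C", 3.5, resid = "ILE"),
    atom_row(3, "CB", "C", 4.2, resid = "VAL"),   # beyond 3.9
    atom_row(4, "CB", "C", 3.0, resid = "SER")))  # polar-adjacent: excluded
  rec <- find_hydrophobic_contacts(s, s$atom[s$atom$resno == 1, ],
                                   s$atom[s$atom$resno > 1, ])
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$atom_b, "CD1")
  expect_equal(rec$distance, 3.5, tolerance = 1e-9)
})

test_that("metal coordination finds inner-sphere partners, bidentate as two records", {
  s <- toy_model(rbind(
    atom_row(1, "NE2", "N", 2.0, resid = "HIS"),
    atom_row(2, "OE1", "O", -2.1, resid = "GLU"),
    atom_row(2, "OE2", "O", 0, y = 2.2, resid = "GLU"),
    atom_row(3, "ND1", "N", 0, y = -3.2, resid = "HIS"),        # outside 2.8
    atom_row(50, "O", "O", 0, z = 2.5, resid = "HOH", record = "HETATM"),
    atom_row(99, "ZN", "ZN", 0, resid = "ZN", record = "HETATM")))
  rec <- find_metal_coordination(s, "ZN")
  expect_identical(nrow(rec), 4L)  # His NE2, Glu OE1+OE2 (bidentate), water
  expect_identical(sum(rec$resid_b == "GLU"), 2L)
  expect_true("HOH" %in% rec$resid_b)
  expect_false(any(rec$resno_b == 3))
  expect_error(find_metal_coordination(s, "FE"), "no hetero atom")
})

test_that("water bridges are found by BFS and bounded by max_waters", {
  # A - w1 - B (single bridge) and A - w2 - w3 - w4 - C (three waters)
  s <- toy_model(rbind(
    atom_row(1, "OG", "O", 0, resid = "SER"),
    atom_row(2, "NE2", "N", 5.6, resid = "GLN"),
    atom_row(3, "OD1", "O", 0, y = 12, resid = "ASP"),
    atom_row(11, "O", "O", 2.8, resid = "HOH", record = "HETATM"),
    atom_row(12, "O", "O", 0, y = 3.0, resid = "HOH", record = "HETATM"),
    atom_row(13, "O", "O", 0, y = 6.0, resid = "HOH", record = "HETATM"),
    atom_row(14, "O", "O", 0, y = 9.0, resid = "HOH", record = "HETATM")))
  selA <- s$atom[s$atom$resno == 1, ]
  one <- find_water_bridges(s, selA, s$atom[s$atom$resno == 2, ])
  expect_identical(nrow(one), 1L)
  expect_identical(one$waters, "11")
  expect_equal(one$distance, 2.8 * 2, tolerance = 1e-9)
  three <- find_water_bridges(s, selA, s$atom[s$atom$resno == 3, ])
  expect_identical(three$waters, "12,13,14")
  # the same pair is NOT bridged when only one water is allowed
  expect_identical(nrow(find_water_bridges(s, selA,
                                           s$atom[s$atom$resno == 3, ],
                                           max_waters = 1)), 0L)
  # breaking one link kills the bridge
  s2 <- s
  s2$atom$x[s2$atom$resno == 11] <- 3.6
  expect_identical(nrow(find_water_bridges(s2, selA,
                                           s2$atom[s2$atom$resno == 2, ])), 0L)
})

test_that("detectors are symmetric under selection swap", {
  set.seed(21)
  n <- 12
  s <- toy_model(data.frame(
    resno = rep(1:6, each = 2),
    elety = rep(c("N", "O"), 6), elesy = rep(c("N", "O"), 6),
    resid = "GLY",
    x = runif(n, 0, 6), y = runif(n, 0, 6), z = runif(n, 0, 6)))
  A <- s$atom[s$atom$resno <= 3, ]; B <- s$atom[s$atom$resno > 3, ]
  ab <- find_polar_contacts(s, A, B); ba <- find_polar_contacts(s, B, A)
  key <- function(r) sort(paste(pmin(paste0(r$resno_a, r$atom_a),
                                     paste0(r$resno_b, r$atom_b)),
                                pmax(paste0(r$resno_a, r$atom_a),
                                     paste0(r$resno_b, r$atom_b)),
                                round(r$distance, 9)))
  expect_identical(key(ab), key(ba))
})

test_that("contact sets are monotone in the cutoff and distances recompute", {
  set.seed(31)
  n <- 20
  s <- toy_model(data.frame(
    resno = rep(1:10, each = 2), elety = rep(c("N", "O"), 10),
    elesy = rep(c("N", "O"), 10), resid = "GLY",
    x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8)))
  A <- s$atom[s$atom$resno <= 5, ]; B <- s$atom[s$atom$resno > 5, ]
  tight <- find_polar_contacts(s, A, B, d_max = 3.2)
  loose <- find_polar_contacts(s, A, B, d_max = 3.4)
  keys <- function(r) paste(r$resno_a, r$atom_a, r$resno_b, r$atom_b)
  expect_true(all(keys(tight) %in% keys(loose)))
  # every reported distance recomputes from the coordinates
  for (r in seq_len(nrow(loose))) {
    pa <- s$atom[s$atom$resno == loose$resno_a[r] &
                   s$atom$elety == loose$atom_a[r], c("x", "y", "z")]
    pb <- s$atom[s$atom$resno == loose$resno_b[r] &
                   s$atom$elety == loose$atom_b[r], c("x", "y", "z")]
    expect_lt(abs(loose$distance[r] -
                    sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))), 1e-6)
  }
})

test_that("interface fingerprint merges contact kinds and lists silent residues", {
  # 3-residue peptide chain B: res 1 H-bonds, res 2 silent, res 3 hydrophobic
  s <- toy_model(rbind(
    atom_row(10, "O", "O", 0, resid = "GLY"),
    atom_row(11, "CB", "C", 10, resid = "LEU"),
    atom_row(1, "N", "N", 2.9, chain = "B", resid = "GLY"),
    atom_row(2, "N", "N", 6, y = 6, chain = "B", resid = "GLY"),
    atom_row(3, "CB", "C", 10, y = 3.5, chain = "B", resid = "ALA")))
  fp <- interface_fingerprint(s, "B", "A")
  expect_identical(sort(unique(fp$records$resno_a)), c(1L, 3L))
  expect_setequal(fp$records$kind, c("hbond", "hydrophobic"))
  expect_identical(fp$silent, 2L)
  expect_error(interface_fingerprint(s, "Z", "A"), "no polymer chain")
})

test_that("a designed per-residue H-bond ladder yields one record per peptide residue", {
  rows <- list()
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- atom_row(i, "N", "N", i * 10, chain = "B",
                                          resid = "GLY")
    rows[[length(rows) + 1L]] <- atom_row(100 + i, "O", "O", i * 10 + 2.9,
                                          resid = "GLY")
  }
  s <- toy_model(do.call(rbind, rows))
  fp <- interface_fingerprint(s, "B", "A")
  expect_identical(nrow(fp$records), 3L)
  expect_true(all(table(fp$records$resno_a) == 1L))
  expect_length(fp$silent, 0)
})
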