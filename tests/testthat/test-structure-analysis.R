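# PDB IO, Kabsch superposition, CDR RMSD, key-residue calling,
# trajectory RMSD series and balance detection.

test_that("PDB structures round-trip through read/write", {
  fx <- make_sequence_fixture(seed = 81)
  rmap <- region_map_table(fx$chains, "imgt")
  st <- make_structure_fixture(seed = 82, region_map = rmap,
                               heavy_atoms = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st$reference, path)
  back <- read_structure(path)
  expect_equal(n_frames(back), 1)
  expect_equal(nrow(back), nrow(st$reference))
  # PDB stores 3 decimals
  expect_equal(back$x, st$reference$x, tolerance = 1e-3)
  expect_setequal(unique(back$chain), c("L", "H"))
})

test_that("multi-model PDBs become frames with shared topology", {
  tr <- make_trajectory_fixture(seed = 83, n_residues = 10,
                                duration_ns = 0.05, frame_interval_ps = 25,
                                plateau_frame = 1, noise_sd = 0)
  expect_equal(n_frames(tr$trajectory), 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tr$trajectory, path)
  back <- read_structure(path)
  expect_equal(n_frames(back), 2)
  f1 <- structure_frame(back, 1)
  f2 <- structure_frame(back, 2)
  expect_equal(f1$resno, f2$resno)
})

test_that("malformed PDB input is rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", path)
  expect_error(read_structure(path))
  # frames with differing atom counts
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "END"
  )
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path2)
  expect_error(read_structure(path2))
})

test_that("minimum residue distance matches brute force", {
  two <- structure_model(tibble::tibble(
    frame = 1L, chain = "L", resno = c(1L, 2L), resname = "GLY",
    elety = "CA", element = "C",
    x = c(0, 3), y = c(0, 4), z = c(0, 0)
  ))
  expect_equal(min_residue_distance(two, "L:1", "L:2"), 5)
  expect_equal(min_residue_distance(two, "L:1", "L:1"), 0)

  withr::with_seed(85, {
    atoms <- tibble::tibble(
      frame = 1L, chain = "L", resno = rep(c(1L, 2L), each = 5),
      resname = "ARG",
      elety = rep(c("N", "CA", "CB", "CG", "CD"), 2), element = "C",
      x = rnorm(10, sd = 4), y = rnorm(10, sd = 4), z = rnorm(10, sd = 4)
    )
    st <- structure_model(atoms)
    a <- as.matrix(atoms[1:5, c("x", "y", "z")])
    b <- as.matrix(atoms[6:10, c("x", "y", "z")])
    expect_equal(min_residue_distance(st, "L:1", "L:2"),
                 oracle_min_dist(a, b))
  })
})

test_that("Kabsch superposition is exact under rigid motions", {
  withr::with_seed(91, {
    for (i in 1:20) {
      p <- matrix(rnorm(3 * sample(3:12, 1), sd = 3), ncol = 3)
      fit <- kabsch_superpose(p, p)
      expect_lt(fit$rmsd, 1e-9)
      moved <- apply_rigid(p, random_rotation(), rnorm(3, sd = 10))
      fit2 <- kabsch_superpose(moved, p)
      expect_lt(fit2$rmsd, 1e-6)
      expect_equal(det(fit2$rotation), 1, tolerance = 1e-8)
    }
  })
  # the documented 90-degree-about-z case
  p <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 2, 2, 2), ncol = 3, byrow = TRUE)
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(kabsch_superpose(apply_rigid(p, rz, c(5, -2, 7)), p)$rmsd, 1e-9)
})

test_that("Kabsch residual is optimal and symmetric", {
  withr::with_seed(93, {
    for (i in 1:10) {
      p <- matrix(rnorm(18, sd = 2), ncol = 3)
      q <- p + matrix(rnorm(18, sd = 0.5), ncol = 3)
      fit <- kabsch_superpose(p, q)
      # never worse than no fit at all
      expect_lte(fit$rmsd, abscan:::rmsd_formula(p, q) + 1e-12)
      # never worse than the best of many random rigid motions
      expect_lte(fit$rmsd,
                 oracle_best_rigid_rmsd(p, q, n_motions = 2000) + 1e-9)
      # symmetric within tolerance
      expect_equal(fit$rmsd, kabsch_superpose(q, p)$rmsd, tolerance = 1e-6)
      # agrees with the bio3d reference implementation
      b3d <- bio3d::rmsd(as.vector(t(q)), as.vector(t(p)), fit = TRUE)
      expect_equal(fit$rmsd, b3d, tolerance = 1e-3)
    }
  })
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("CDR RMSD pools the six CDRs and matches an independent fit", {
  fx <- make_sequence_fixture(seed = 95)
  rmap <- region_map_table(fx$chains, "imgt")
  st <- make_structure_fixture(seed = 96, region_map = rmap,
                               magnitudes = c(M1 = 2.0))
  expect_equal(cdr_rmsd(st$reference, st$reference, rmap), 0)

  got <- cdr_rmsd(st$mutants$M1, st$reference, rmap)
  # independent oracle: bio3d's fitted RMSD on the same pooled CDR CAs
  cdr <- rmap[startsWith(rmap$region, "CDR"), ]
  cdr <- cdr[order(cdr$chain, cdr$position), ]
  mob <- abscan:::select_ca(st$mutants$M1, cdr)
  ref <- abscan:::select_ca(st$reference, cdr)
  b3d <- bio3d::rmsd(as.vector(t(mob)), as.vector(t(ref)), fit = TRUE)
  expect_equal(got, b3d, tolerance = 1e-3)
  expect_equal(got, 2.0, tolerance = 0.05)
})

test_that("CDR length mismatches are reported by region", {
  fx <- make_sequence_fixture(seed = 97)
  rmap <- region_map_table(fx$chains, "imgt")
  st <- make_structure_fixture(seed = 98, region_map = rmap)
  truncated <- structure_model(
    dplyr::filter(
      tibble::as_tibble(st$reference),
      !(.data$chain == "L" &
          .data$resno %in% rmap$position[rmap$chain == "L" &
                                           rmap$region == "CDR3"])
    )
  )
  expect_error(cdr_rmsd(truncated, st$reference, rmap), "CDR3")
})

test_that("key residues are called at the threshold", {
  rep1 <- call_key_residues(tibble::tibble(mutant = c("A", "B"),
                                           rmsd = c(0.4, 1.6)))
  expect_equal(rep1$key_residues, "B")
  expect_true(rep1$table$is_identical[rep1$table$mutant == "A"])

  rep2 <- call_key_residues(tibble::tibble(mutant = letters[1:4], rmsd = 0))
  expect_equal(length(rep2$key_residues), 0)
  expect_true(all(rep2$table$is_identical))

  expect_error(call_key_residues(tibble::tibble(mutant = "a", rmsd = -1)),
               "negative")

  # planted-truth recovery and monotonicity in the threshold
  withr::with_seed(101, {
    rmsds <- tibble::tibble(
      mutant = sprintf("M%02d", 1:30),
      rmsd = c(runif(25, 0, 1.0), runif(5, 1.5, 2.0))[sample(30)]
    )
  })
  planted <- rmsds$mutant[rmsds$rmsd >= 1.5]
  rep3 <- call_key_residues(rmsds, threshold = 1.5)
  expect_setequal(rep3$key_residues, planted)
  for (th in c(0.5, 1.0, 1.7, 2.5)) {
    expect_true(all(
      call_key_residues(rmsds, threshold = th + 0.3)$key_residues %in%
        call_key_residues(rmsds, threshold = th)$key_residues
    ))
  }
  # tidy/glance expose the full sorted table
  expect_equal(nrow(tidy(rep3)), 30)
  expect_false(is.unsorted(rev(tidy(rep3)$rmsd)))
  expect_equal(glance(rep3)$n_key, 5)
})

test_that("RMSD series are zero for identical or rigidly moved frames", {
  base <- tibble::tibble(
    frame = 1L, chain = "A", resno = 1:8, resname = "ALA", elety = "CA",
    element = "C", x = as.numeric(1:8) * 2, y = c(1, 3, 2, 5, 4, 7, 6, 9),
    z = as.numeric(8:1)
  )
  frames <- dplyr::bind_rows(base, dplyr::mutate(base, frame = 2L),
                             dplyr::mutate(base, frame = 3L))
  tr <- structure_model(frames)
  expect_equal(rmsd_series(tr)$rmsd, c(0, 0, 0))

  withr::with_seed(103, {
    moved <- dplyr::bind_rows(lapply(1:4, function(f) {
      xyz <- apply_rigid(as.matrix(base[, c("x", "y", "z")]),
                         random_rotation(), rnorm(3, sd = 5))
      dplyr::mutate(base, frame = f, x = xyz[, 1], y = xyz[, 2],
                    z = xyz[, 3])
    }))
  })
  expect_true(all(rmsd_series(structure_model(moved), 1)$rmsd < 1e-6))
  expect_error(rmsd_series(structure_model(base)), "2 frames")
})

test_that("balance detection finds plateaus and rejects drifting series", {
  expect_equal(detect_balance(rep(1.5, 200), window = 20), 1L)
  rising <- seq(0, 10, length.out = 200)   # ~10 A/ns at 5 ps spacing
  expect_true(is.na(detect_balance(rising, window = 20)))
  expect_error(detect_balance(rep(1, 10), window = 50), "window larger")

  # synthetic saturating curve with known changepoint; noise well below
  # both tolerances
  withr::with_seed(105, {
    k <- 120
    n <- 300
    series <- c(seq(0, 1.5, length.out = k),
                rep(1.5, n - k)) + rnorm(n, sd = 0.002)
  })
  got <- detect_balance(series, window = 40)
  expect_false(is.na(got))
  expect_lte(abs(got - k), 40)
})

test_that("average structures reduce to the expected frames", {
  tr <- make_trajectory_fixture(seed = 107, n_residues = 12,
                                duration_ns = 0.1, frame_interval_ps = 20,
                                plateau_frame = 3, noise_sd = 0.1)
  traj <- tr$trajectory
  # single-frame range: identity
  avg1 <- average_structure(traj, 2)
  f2 <- structure_frame(traj, 2)
  expect_equal(avg1$x, f2$x)
  # identical frames: that frame
  rep_frames <- dplyr::bind_rows(
    dplyr::mutate(f2, frame = 1L), dplyr::mutate(f2, frame = 2L)
  )
  avg2 <- average_structure(structure_model(rep_frames), 1:2)
  expect_equal(avg2$x, f2$x, tolerance = 1e-9)
  # frames related by a rigid motion average to the first frame
  withr::with_seed(108, {
    xyz <- as.matrix(f2[, c("x", "y", "z")])
    moved <- apply_rigid(xyz, random_rotation(), rnorm(3, sd = 3))
  })
  two <- dplyr::bind_rows(
    dplyr::mutate(f2, frame = 1L),
    dplyr::mutate(f2, frame = 2L, x = moved[, 1], y = moved[, 2],
                  z = moved[, 3])
  )
  avg3 <- average_structure(structure_model(two), 1:2)
  expect_equal(avg3$x, f2$x, tolerance = 1e-6)
  expect_error(average_structure(traj, integer()), "empty")
})
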