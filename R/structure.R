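#' Construct a structure model from an atom table
#'
#' A structure model is a tidy coordinate hierarchy: one or more frames
#' (MD snapshots or PDB MODELs) sharing an identical atom topology.
#'
#' @param atoms Tibble with columns `frame`, `chain`, `resno`, `resname`,
#'   `elety` (atom name), `element`, `x`, `y`, `z` and optionally
#'   `is_hydrogen`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("frame", "chain", "resno", "resname", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(sprintf("atom table needs columns %s", paste(need, collapse = ", ")))
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  }
  if (!"is_hydrogen" %in% names(atoms)) {
    atoms$is_hydrogen <- atoms$element == "H"
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in atom table")
  }
  atoms <- atoms |>
    mutate(frame = as.integer(.data$frame), resno = as.integer(.data$resno)) |>
    arrange(.data$frame)
  keys <- split(
    paste(atoms$chain, atoms$resno, atoms$elety, sep = "|"), atoms$frame
  )
  if (length(unique(vapply(keys, paste, character(1), collapse = ";"))) != 1) {
    abort("inconsistent atom topology across frames")
  }
  structure(atoms, class = c("structure_model", class(atoms)),
            n_frames = length(keys))
}

#' @export
print.structure_model <- function(x, ...) {
  nf <- attr(x, "n_frames")
  f1 <- x[x$frame == x$frame[1], ]
  cat(sprintf(
    "<structure_model> %d frame(s); %d atoms, %d residues, chains: %s\n",
    nf, nrow(f1), nrow(distinct(f1, .data$chain, .data$resno)),
    paste(unique(f1$chain), collapse = ", ")
  ))
  invisible(x)
}

#' Number of frames of a structure model
#' @param model A `structure_model`.
#' @export
n_frames <- function(model) attr(model, "n_frames")

#' Extract one frame of a structure model as a plain atom tibble
#' @param model A `structure_model`.
#' @param frame Frame number.
#' @export
structure_frame <- function(model, frame = 1) {
  frames <- unique(model$frame)
  if (!frame %in% frames) {
    abort(sprintf("frame %d not in structure (frames 1..%d)", frame,
                  attr(model, "n_frames")))
  }
  as_tibble(model[model$frame == frame, , drop = FALSE])
}

#' Read a PDB structure (single- or multi-model)
#'
#' Parses ATOM/HETATM records with bio3d; MODEL/ENDMDL records delimit
#' frames. Hydrogens are retained but tagged; for alternate locations the
#' highest-occupancy atom is kept.
#'
#' @param path PDB file path.
#' @return A `structure_model`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(sprintf("cannot read PDB '%s': %s", path,
                                      conditionMessage(e)))
  )
  at <- pdb$atom
  if (!nrow(at)) abort(sprintf("no ATOM records in '%s'", path))
  if (ncol(pdb$xyz) != 3 * nrow(at)) {
    abort(sprintf("inconsistent atom topology across MODEL frames in '%s'",
                  path))
  }
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  # resolve altLoc: keep highest occupancy per (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  keep <- !duplicated(key[order(-occ)])[order(order(-occ))]
  nfr <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nfr), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    tibble(
      frame = f,
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno,
      resname = at$resid,
      elety = at$elety,
      element = if (!is.null(at$elesy) && any(nzchar(at$elesy)))
        toupper(trimws(at$elesy))
      else substr(gsub("[0-9]", "", at$elety), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )[keep, ]
  })
  structure_model(bind_rows(frames))
}

#' Write a structure model to a PDB file
#'
#' Multi-frame models are written as MODEL/ENDMDL blocks (via bio3d).
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  f1 <- structure_frame(model, unique(model$frame)[1])
  frames <- unique(model$frame)
  xyz <- do.call(rbind, lapply(frames, function(f) {
    m <- as.matrix(model[model$frame == f, c("x", "y", "z")])
    as.vector(t(m))
  }))
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = f1$resno, chain = f1$chain,
    resid = f1$resname, elety = f1$elety
  )
  invisible(path)
}

#' Minimum interatomic distance between two residues
#'
#' @param model A `structure_model`.
#' @param res_a,res_b Residue specifiers `"chain:resno"`, e.g. `"L:38"`.
#' @param atom_mode `"heavy"` (non-hydrogen atoms) or `"ca"`.
#' @param frame Frame to measure in.
#' @return Distance in Angstroms.
#' @export
min_residue_distance <- function(model, res_a, res_b,
                                 atom_mode = c("heavy", "ca"), frame = 1) {
  atom_mode <- match.arg(atom_mode)
  fr <- structure_frame(model, frame)
  get_coords <- function(spec) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort("residue specifier must be 'chain:resno'")
    sel <- fr[fr$chain == parts[1] & fr$resno == as.integer(parts[2]), ]
    if (atom_mode == "ca") sel <- sel[sel$elety == "CA", ]
    else sel <- sel[!sel$is_hydrogen, ]
    if (!nrow(sel)) {
      abort(sprintf("residue %s has no %s atoms in the structure", spec,
                    if (atom_mode == "ca") "CA" else "heavy"))
    }
    as.matrix(sel[, c("x", "y", "z")])
  }
  min_pair_distance(get_coords(res_a), get_coords(res_b))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets, and returns the RMSD
#' \eqn{\sqrt{\frac{1}{N}\sum_i \|r_i - r_i^0\|^2}} evaluated after the
#' transformation. The rotation is constrained to determinant +1 (no
#' reflection).
#'
#' @param mobile,reference Numeric matrices of paired coordinates, `N x 3`
#'   with `N >= 3`, neither set collinear.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`,
#'   and `transformed` (the mobile set after superposition). The transform
#'   maps a mobile point `p` to `p %*% t(rotation) + translation`.
#' @examples
#' p <- matrix(rnorm(18), ncol = 3)
#' kabsch_superpose(p, p)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3) abort("coordinates must be N x 3")
  n <- nrow(mobile)
  if (nrow(reference) != n) abort("point sets must be paired (equal N)")
  if (n < 3) abort("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  if (collinear(pm) || collinear(pr)) {
    abort("degenerate geometry: points are collinear")
  }
  h <- crossprod(pm, pr)           # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(pm %*% t(rot), 2, cr, "+")
  list(
    rotation = rot,
    translation = as.vector(cr - rot %*% cm),
    rmsd = rmsd_formula(transformed, reference),
    transformed = transformed
  )
}

collinear <- function(centered, tol = 1e-8) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv, 1)) < 2
}

# sqrt((1/N) * sum ||r_i - r_i0||^2), no fitting
rmsd_formula <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# chain-qualified CA coordinates at given (chain, position) rows, in row order
select_ca <- function(model, sel, frame = 1) {
  fr <- structure_frame(model, frame)
  ca <- fr[fr$elety == "CA", ]
  idx <- match(paste(sel$chain, sel$position), paste(ca$chain, ca$resno))
  if (anyNA(idx)) {
    missing <- sel[is.na(idx), ]
    abort(sprintf(
      "CA atoms missing for %s",
      paste(paste0(missing$chain, ":", missing$position), collapse = ", ")
    ))
  }
  as.matrix(ca[idx, c("x", "y", "z")])
}

#' CDR RMSD between a mutant and a reference structure
#'
#' Pools the C-alpha atoms of all six CDRs (three per chain, or all CDRs
#' present in the region map), superposes them with [kabsch_superpose()]
#' and returns the RMSD. This is the similarity measure used to decide
#' whether a framework mutation disturbs the antigen-binding loops.
#' The alternative `fit_region = "fr"` mode superposes on framework
#' C-alphas and evaluates the RMSD over the CDRs without refitting.
#'
#' @param mutant,reference `structure_model`s containing all CDR residues
#'   with CA atoms; CDR lengths must agree.
#' @param region_map Tibble with columns `chain`, `position`, `region`
#'   (single scheme), e.g. from [region_map_table()].
#' @param fit_region `"cdr"` (default, fit and measure on the CDRs) or
#'   `"fr"` (fit on FRs, measure on CDRs).
#' @param frame_mutant,frame_reference Frames to compare.
#' @return RMSD in Angstroms.
#' @export
cdr_rmsd <- function(mutant, reference, region_map, fit_region = c("cdr", "fr"),
                     frame_mutant = 1, frame_reference = 1) {
  fit_region <- match.arg(fit_region)
  map <- as_tibble(region_map)
  if (!all(c("chain", "position", "region") %in% names(map))) {
    abort("region_map needs columns chain, position, region")
  }
  cdr <- map |>
    filter(startsWith(.data$region, "CDR")) |>
    arrange(.data$chain, .data$position)
  if (!nrow(cdr)) abort("region map contains no CDR positions")
  check_lengths <- function(model, frame, label) {
    fr <- structure_frame(model, frame)
    ca <- fr[fr$elety == "CA", ]
    per <- cdr |>
      group_by(.data$chain, .data$region) |>
      summarise(
        expected = n(),
        found = sum(paste(.data$chain[1], .data$position) %in%
                      paste(ca$chain, ca$resno)),
        .groups = "drop"
      )
    bad <- per[per$expected != per$found, ]
    if (nrow(bad)) {
      abort(sprintf(
        "CDR length mismatch in %s structure: %s", label,
        paste(sprintf("%s %s (%d/%d CA)", bad$chain, bad$region, bad$found,
                      bad$expected), collapse = "; ")
      ))
    }
  }
  check_lengths(mutant, frame_mutant, "mutant")
  check_lengths(reference, frame_reference, "reference")
  if (fit_region == "cdr") {
    mob <- select_ca(mutant, cdr, frame_mutant)
    ref <- select_ca(reference, cdr, frame_reference)
    kabsch_superpose(mob, ref)$rmsd
  } else {
    frs <- map |>
      filter(startsWith(.data$region, "FR")) |>
      arrange(.data$chain, .data$position)
    fit <- kabsch_superpose(select_ca(mutant, frs, frame_mutant),
                            select_ca(reference, frs, frame_reference))
    mob <- select_ca(mutant, cdr, frame_mutant)
    moved <- sweep(mob %*% t(fit$rotation), 2, fit$translation, "+")
    rmsd_formula(moved, select_ca(reference, cdr, frame_reference))
  }
}

#' Build a single-scheme region-map table for a set of chains
#'
#' @param chains List of delimited `annotated_chain`s.
#' @param scheme Numbering scheme.
#' @return Tibble with columns `chain`, `position`, `region`, `aa`.
#' @export
region_map_table <- function(chains, scheme = "imgt") {
  if (inherits(chains, "annotated_chain")) chains <- list(chains)
  purrr::map_dfr(chains, function(ch) {
    region_map(ch, scheme) |> mutate(chain = ch$chain_id, .before = 1)
  })
}

#' Call conformation-critical key residues from per-mutant CDR RMSDs
#'
#' A mutant whose CDR RMSD against the parental structure reaches the
#' threshold (default 1.5 Angstroms) marks its mutated framework position
#' as a key residue: the human substitution there disturbs the CDR
#' conformation, so the refined antibody back-mutates it. Mutants with
#' RMSD below `identical_cutoff` (default 1.0 Angstroms) are annotated as
#' structurally identical to the parent.
#'
#' @param rmsds Tibble with columns `mutant`, `rmsd`, or a named numeric
#'   vector.
#' @param threshold Key-residue threshold in Angstroms.
#' @param identical_cutoff RMSD below which structures count as identical.
#' @return An object of class `rmsd_report`: list with `table` (tibble
#'   `mutant`, `rmsd`, `is_key`, `is_identical`, sorted by decreasing
#'   RMSD), `key_residues`, `threshold`, `identical_cutoff`.
#' @examples
#' call_key_residues(c(L38 = 1.6, L9 = 0.4))$key_residues
#' @export
call_key_residues <- function(rmsds, threshold = 1.5, identical_cutoff = 1.0) {
  if (is.numeric(rmsds)) {
    rmsds <- tibble(mutant = names(rmsds) %||% as.character(seq_along(rmsds)),
                    rmsd = as.numeric(rmsds))
  }
  rmsds <- as_tibble(rmsds)
  if (!all(c("mutant", "rmsd") %in% names(rmsds))) {
    abort("rmsds needs columns 'mutant' and 'rmsd'")
  }
  if (any(rmsds$rmsd < 0)) abort("negative RMSD values are not allowed")
  tab <- rmsds |>
    mutate(
      is_key = .data$rmsd >= threshold,
      is_identical = .data$rmsd < identical_cutoff
    ) |>
    arrange(dplyr::desc(.data$rmsd))
  structure(
    list(
      table = tab,
      key_residues = tab$mutant[tab$is_key],
      threshold = threshold,
      identical_cutoff = identical_cutoff
    ),
    class = "rmsd_report"
  )
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf(
    "<rmsd_report> %d mutants; threshold %.2f A, identical below %.2f A\n",
    nrow(x$table), x$threshold, x$identical_cutoff
  ))
  cat(sprintf("key residues: %s\n",
              if (length(x$key_residues)) paste(x$key_residues, collapse = ", ")
              else "none"))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' RMSD time series of a trajectory against a reference frame
#'
#' Each frame is superposed (Kabsch) onto the reference frame over the
#' selected atoms and the post-fit RMSD recorded, giving the familiar
#' RMSD-versus-time convergence curve of an MD production run.
#'
#' @param traj A multi-frame `structure_model`.
#' @param reference_frame Frame index used as reference (default 1).
#' @param selection Optional tibble `chain`, `position` restricting the
#'   atoms; `NULL` uses all residues.
#' @param atom_mode `"ca"` (default) or `"heavy"`.
#' @param frame_interval_ps Frame spacing in picoseconds; when given, a
#'   `time_ps` column is added.
#' @return Tibble with columns `frame`, `rmsd` (and `time_ps`).
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = NULL,
                        atom_mode = c("ca", "heavy"),
                        frame_interval_ps = NULL) {
  atom_mode <- match.arg(atom_mode)
  nf <- attr(traj, "n_frames")
  if (is.null(nf) || nf < 2) abort("trajectory needs at least 2 frames")
  pick <- function(fr) {
    if (atom_mode == "ca") fr <- fr[fr$elety == "CA", ]
    else fr <- fr[!fr$is_hydrogen, ]
    if (!is.null(selection)) {
      keep <- paste(fr$chain, fr$resno) %in%
        paste(selection$chain, selection$position)
      fr <- fr[keep, ]
    }
    if (!nrow(fr)) abort("empty atom selection")
    as.matrix(fr[order(fr$chain, fr$resno, fr$elety), c("x", "y", "z")])
  }
  ref <- pick(structure_frame(traj, reference_frame))
  frames <- sort(unique(traj$frame))
  vals <- vapply(frames, function(f) {
    if (f == reference_frame) return(0)
    kabsch_superpose(pick(structure_frame(traj, f)), ref)$rmsd
  }, numeric(1))
  out <- tibble(frame = frames, rmsd = vals)
  if (!is.null(frame_interval_ps)) {
    out$time_ps <- (out$frame - 1) * frame_interval_ps
  }
  out
}

#' Detect the balanced (converged) phase of an RMSD series
#'
#' Scans sliding windows over the series and reports the earliest index
#' from which every subsequent window is flat: absolute least-squares
#' slope at most `slope_tol` (in Angstroms per nanosecond) and standard
#' deviation at most `std_tol`. This is the plateau from which average
#' structures are extracted.
#'
#' @param series Numeric RMSD values, or the tibble from [rmsd_series()].
#' @param window Window length in frames; default 10% of the series.
#' @param slope_tol Slope tolerance, Angstrom/ns.
#' @param std_tol Standard-deviation tolerance, Angstrom.
#' @param frame_interval_ps Frame spacing used to express slopes in
#'   Angstrom/ns (default 5 ps, the common snapshot interval).
#' @return 1-based index of the first balanced frame, or `NA` if the
#'   series never balances.
#' @export
detect_balance <- function(series, window = NULL, slope_tol = 0.02,
                           std_tol = 0.15, frame_interval_ps = 5) {
  if (is.data.frame(series)) {
    if (!is.null(series$time_ps) && nrow(series) > 1) {
      frame_interval_ps <- diff(series$time_ps[1:2])
    }
    series <- series$rmsd
  }
  n <- length(series)
  window <- window %||% max(2L, as.integer(ceiling(0.1 * n)))
  if (window > n) abort("window larger than the series")
  starts <- seq_len(n - window + 1L)
  x <- (seq_len(window) - 1) * frame_interval_ps / 1000  # ns
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ok <- vapply(starts, function(s) {
    y <- series[s:(s + window - 1L)]
    slope <- sum(xc * (y - mean(y))) / sxx
    abs(slope) <= slope_tol && sd(y) <= std_tol
  }, logical(1))
  # earliest start from which every later window is also flat
  rev_ok <- rev(cumprod(rev(ok)))
  idx <- which(rev_ok == 1)
  if (!length(idx)) return(NA_integer_)
  starts[idx[1]]
}

#' Average structure over a frame range
#'
#' Superposes every frame of the range onto the first frame of the range
#' (all atoms) and averages the coordinates per atom, yielding the
#' time-averaged structure of a trajectory's stable phase.
#'
#' @param traj A `structure_model`.
#' @param frame_range Integer vector of frames (e.g. `600:1000`).
#' @return Single-frame `structure_model`.
#' @export
average_structure <- function(traj, frame_range) {
  frame_range <- as.integer(frame_range)
  if (!length(frame_range)) abort("empty frame range")
  frames <- unique(traj$frame)
  if (!all(frame_range %in% frames)) {
    abort("frame range outside the trajectory")
  }
  ref_fr <- structure_frame(traj, frame_range[1])
  ref <- as.matrix(ref_fr[, c("x", "y", "z")])
  acc <- matrix(0, nrow(ref), 3)
  for (f in frame_range) {
    m <- as.matrix(structure_frame(traj, f)[, c("x", "y", "z")])
    acc <- acc + if (f == frame_range[1]) ref else
      kabsch_superpose(m, ref)$transformed
  }
  avg <- acc / length(frame_range)
  out <- ref_fr
  out$x <- avg[, 1]; out$y <- avg[, 2]; out$z <- avg[, 3]
  out$frame <- 1L
  structure_model(out)
}

#' Read / write per-mutant RMSD tables
#'
#' TSV with columns `mutant`, `rmsd`.
#'
#' @param path TSV path.
#' @export
read_rmsd_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param rmsds Tibble `mutant`, `rmsd`.
#' @rdname read_rmsd_table
#' @export
write_rmsd_table <- function(rmsds, path) {
  readr::write_tsv(rmsds, path, progress = FALSE)
  invisible(path)
}
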