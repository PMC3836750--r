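# Deterministic synthetic fixtures emulating the study inputs: a rodent
# query chain with planted rat-unique residues, a 20-sequence human
# template set, idealized CA traces, CDR-perturbed mutant structures and
# saturating MD-like trajectories. All generators are reproducible: the
# same seed yields identical objects.

# residues used for random filler; C, F and W are reserved for the anchor
# positions so that delimitation anchors are unambiguous
FIXTURE_ALPHABET <- setdiff(AA_STANDARD, c("C", "F", "W", "G"))

# canonical block layout (IMGT-style offsets) used by the sequence fixture
fixture_layout <- function(chain) {
  if (chain == "L") {
    list(cys1 = 23L, cys2 = 88L, j_anchor = 98L, length = 107L,
         fr4 = "FGQGTKLEIK")
  } else {
    list(cys1 = 22L, cys2 = 98L, j_anchor = 109L, length = 118L,
         fr4 = "WGQGTTVTVS")
  }
}

#' Generate a sequence-level test fixture
#'
#' Builds a two-chain rodent-like query, a human template set that agrees
#' with the query everywhere except at planted rat-unique positions (where
#' every template carries a different residue), an identity query-to-column
#' mapping, and the planted truth. Defaults emulate the study conditions:
#' 20 human templates per chain and IMGT region delimitation.
#'
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @param n_templates Human templates per chain (default 20).
#' @param planted_unique Tibble with columns `chain`, `position` of
#'   positions to make rat-unique; must lie in framework regions.
#' @param diversity_columns Number of additional framework positions per
#'   chain at which templates other than the first vary (the query residue
#'   stays present in the set, so these never become epitopes).
#' @param scheme Numbering scheme used to delimit the fixture chains.
#' @return List with `chains` (named list of delimited `annotated_chain`),
#'   `templates` (named list of `template_set`), `mappings` (named list of
#'   `query_mapping`), and `truth` (list with `planted_unique`).
#' @export
make_sequence_fixture <- function(seed = 1, n_templates = 20,
                                  planted_unique = NULL,
                                  diversity_columns = 3, scheme = "imgt") {
  scheme <- match_scheme(scheme)
  planted_unique <- if (is.null(planted_unique)) {
    tibble(chain = character(), position = integer())
  } else {
    as_tibble(planted_unique)
  }
  withr::with_seed(seed, {
    chains <- list()
    templates <- list()
    mappings <- list()
    for (id in c("L", "H")) {
      lay <- fixture_layout(id)
      aa <- sample(FIXTURE_ALPHABET, lay$length, replace = TRUE)
      aa[c(lay$cys1, lay$cys2)] <- "C"
      aa[lay$j_anchor:lay$length] <- strsplit(lay$fr4, "")[[1]]
      query <- parse_chain(paste(aa, collapse = ""), id)
      query <- delimit_regions(query, scheme)
      frp <- fr_positions(query, scheme)

      planted <- planted_unique$position[planted_unique$chain == id]
      if (length(setdiff(planted, frp))) {
        abort(sprintf(
          "planted position(s) %s of chain %s are not in a framework region",
          paste(setdiff(planted, frp), collapse = ", "), id
        ))
      }
      mat <- matrix(rep(aa, n_templates), nrow = n_templates, byrow = TRUE)
      for (p in planted) {
        mat[, p] <- sample(setdiff(FIXTURE_ALPHABET, aa[p]), n_templates,
                           replace = TRUE)
      }
      if (diversity_columns > 0 && n_templates > 1) {
        free <- setdiff(frp, planted)
        div <- sample(free, min(diversity_columns, length(free)))
        for (p in div) {
          mat[-1, p] <- sample(setdiff(FIXTURE_ALPHABET, aa[p]),
                               n_templates - 1, replace = TRUE)
        }
      }
      set <- template_set(
        sprintf("%sT%02d", id, seq_len(n_templates)),
        apply(mat, 1, paste, collapse = "")
      )
      chains[[id]] <- query
      templates[[id]] <- set
      mappings[[id]] <- new_query_mapping(
        tibble(query_position = seq_along(aa), column = seq_along(aa)),
        anchor = set$templates$accession[1], chain_id = id
      )
    }
    list(
      chains = chains, templates = templates, mappings = mappings,
      truth = list(planted_unique = planted_unique),
      scheme = scheme, seed = seed
    )
  })
}

# idealized CA helix: consecutive CA spacing `spacing` Angstroms
helix_trace <- function(n, spacing = 3.8, radius = 2.3, rise = 1.5,
                        origin = c(0, 0, 0)) {
  chord <- sqrt(spacing^2 - rise^2)
  omega <- 2 * asin(chord / (2 * radius))
  t <- seq_len(n)
  cbind(
    radius * cos(omega * t) + origin[1],
    radius * sin(omega * t) + origin[2],
    rise * t + origin[3]
  )
}

atoms_from_ca <- function(ca, chain, resno, heavy_atoms = FALSE) {
  base <- tibble(
    frame = 1L, chain = chain, resno = as.integer(resno), resname = "ALA",
    elety = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3]
  )
  if (!heavy_atoms) return(base)
  # three dummy side-chain heavy atoms fanning out from each CA
  offs <- list(CB = c(1.2, 0.8, 0.4), CG = c(-0.9, 1.3, -0.5),
               CD = c(0.5, -1.1, 1.0))
  extra <- purrr::imap_dfr(offs, function(o, nm) {
    rot <- (resno %% 7) / 7 * 2 * pi  # vary orientation along the chain
    ox <- o[1] * cos(rot) - o[2] * sin(rot)
    oy <- o[1] * sin(rot) + o[2] * cos(rot)
    tibble(
      frame = 1L, chain = chain, resno = as.integer(resno), resname = "ALA",
      elety = nm, element = "C",
      x = ca[, 1] + ox, y = ca[, 2] + oy, z = ca[, 3] + o[3]
    )
  })
  bind_rows(base, extra) |> arrange(.data$resno, .data$elety)
}

#' Generate reference and CDR-perturbed mutant structures
#'
#' The reference is an idealized CA trace (3.8 Angstrom consecutive
#' spacing on a helical curve, one helix per chain). Each mutant displaces
#' the pooled CDR C-alphas by a random field scaled iteratively so that
#' the CDR-fit Kabsch RMSD against the reference equals the requested
#' magnitude to within 0.02 Angstroms. This reproduces, at desk scale, the
#' situation the key-residue analysis faces: most mutants barely move the
#' CDRs while a few planted ones cross the threshold.
#'
#' @param seed Integer seed.
#' @param region_map Region-map tibble (`chain`, `position`, `region`),
#'   e.g. from [region_map_table()] on a sequence fixture.
#' @param magnitudes Named numeric vector: per-mutant target CDR RMSD in
#'   Angstroms (names are mutant labels such as `"L38"`).
#' @param heavy_atoms Add three dummy side-chain heavy atoms per residue
#'   (needed for heavy-atom conformational scans).
#' @return List with `reference` (`structure_model`), `mutants` (named
#'   list of `structure_model`) and `region_map`.
#' @export
make_structure_fixture <- function(seed = 1, region_map, magnitudes = NULL,
                                   heavy_atoms = FALSE) {
  map <- as_tibble(region_map)
  stopifnot(all(c("chain", "position", "region") %in% names(map)))
  if (any(magnitudes < 0)) abort("unreachable magnitude: RMSD must be >= 0")
  withr::with_seed(seed, {
    chains <- unique(map$chain)
    ref_atoms <- purrr::imap_dfr(setNames(chains, chains), function(id, nm) {
      pos <- sort(map$position[map$chain == id])
      off <- c(30 * (match(id, chains) - 1), 0, 0)  # separate the chains
      atoms_from_ca(helix_trace(length(pos), origin = off), id, pos,
                    heavy_atoms)
    })
    reference <- structure_model(ref_atoms)
    cdr_rows <- map |>
      filter(startsWith(.data$region, "CDR")) |>
      arrange(.data$chain, .data$position)

    mutants <- purrr::imap(magnitudes %||% numeric(), function(mag, label) {
      at <- as_tibble(reference)
      is_cdr_ca <- at$elety == "CA" &
        paste(at$chain, at$resno) %in% paste(cdr_rows$chain, cdr_rows$position)
      if (mag == 0) return(structure_model(at))
      d <- matrix(rnorm(3 * sum(is_cdr_ca)), ncol = 3)
      ref_ca <- as.matrix(at[is_cdr_ca, c("x", "y", "z")])
      s <- mag / rmsd_formula(ref_ca + d, ref_ca)
      for (iter in 1:60) {
        cur <- kabsch_superpose(ref_ca + s * d, ref_ca)$rmsd
        if (abs(cur - mag) < 0.01) break
        s <- s * mag / cur
      }
      moved <- ref_ca + s * d
      at$x[is_cdr_ca] <- moved[, 1]
      at$y[is_cdr_ca] <- moved[, 2]
      at$z[is_cdr_ca] <- moved[, 3]
      # displace side-chain atoms of perturbed residues along with the CA
      if (heavy_atoms) {
        shift <- s * d
        keys <- paste(at$chain[is_cdr_ca], at$resno[is_cdr_ca])
        side <- which(at$elety != "CA" &
                        paste(at$chain, at$resno) %in% keys)
        m <- match(paste(at$chain[side], at$resno[side]), keys)
        at$x[side] <- at$x[side] + shift[m, 1]
        at$y[side] <- at$y[side] + shift[m, 2]
        at$z[side] <- at$z[side] + shift[m, 3]
      }
      structure_model(at)
    })
    list(reference = reference, mutants = mutants, region_map = map)
  })
}

#' Generate a synthetic MD-like trajectory with a known balance point
#'
#' Frames drift away from the first frame along a fixed random
#' displacement field with a saturating amplitude — linear rise until the
#' plateau frame, constant afterwards — plus Gaussian coordinate noise.
#' Defaults emulate a 5 ns production run stored every 5 ps (1000 frames)
#' that plateaus at a CA RMSD of 1.5 Angstroms.
#'
#' @param seed Integer seed.
#' @param n_residues Residues in the single-chain CA trace.
#' @param duration_ns,frame_interval_ps Run length and snapshot interval;
#'   their ratio must be a whole number of frames.
#' @param plateau_frame Frame at which the drift saturates.
#' @param plateau_rmsd Asymptotic CA RMSD versus frame 1, Angstroms.
#' @param noise_sd Gaussian noise per coordinate, Angstroms.
#' @return List with `trajectory` (multi-frame `structure_model`),
#'   `balance_frame`, `frame_interval_ps`, `n_frames`.
#' @export
make_trajectory_fixture <- function(seed = 1, n_residues = 40,
                                    duration_ns = 5, frame_interval_ps = 5,
                                    plateau_frame = 600,
                                    plateau_rmsd = 1.5, noise_sd = 0.05) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  n_frames <- duration_ns * 1000 / frame_interval_ps
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("duration must be a whole number of frames")
  }
  n_frames <- as.integer(round(n_frames))
  if (plateau_frame < 1 || plateau_frame > n_frames) {
    abort("plateau_frame outside the trajectory")
  }
  withr::with_seed(seed, {
    ref <- helix_trace(n_residues)
    u <- matrix(rnorm(3 * n_residues), ncol = 3)
    s <- plateau_rmsd / rmsd_formula(ref + u, ref)
    for (iter in 1:60) {
      cur <- kabsch_superpose(ref + s * u, ref)$rmsd
      if (abs(cur - plateau_rmsd) < 0.005) break
      s <- s * plateau_rmsd / cur
    }
    frames <- purrr::map_dfr(seq_len(n_frames), function(f) {
      amp <- s * min(f - 1, plateau_frame - 1) / max(1, plateau_frame - 1)
      xyz <- ref + amp * u +
        matrix(rnorm(3 * n_residues, sd = noise_sd), ncol = 3)
      tibble(
        frame = f, chain = "A", resno = seq_len(n_residues), resname = "ALA",
        elety = "CA", element = "C",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
      )
    })
    list(
      trajectory = structure_model(frames),
      balance_frame = as.integer(plateau_frame),
      frame_interval_ps = frame_interval_ps,
      n_frames = n_frames
    )
  })
}
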