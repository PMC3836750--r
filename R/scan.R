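#' Epitope-scan configuration
#'
#' Parameters of the framework-region epitope scan. Defaults follow the
#' method's published settings: 6-residue sliding probes for linear
#' epitopes, a 5 Angstrom heavy-atom distance cutoff for conformational
#' residue pairs, and exact (zero-mismatch) matching of a probe against a
#' single human template.
#'
#' @param window_length Probe length in residues for the linear scan.
#' @param max_mismatches Mismatches tolerated when matching a probe window
#'   against one template (0 = exact).
#' @param pair_distance_cutoff Distance cutoff in Angstroms below which a
#'   residue pair counts as spatially adjacent.
#' @param neighborhood_radius Sequence radius (residues) used to describe a
#'   position's local context; informational, equals `window_length` by
#'   default.
#' @param match_mode `"per_template"` requires a probe to match within one
#'   template sequence (default); `"column_union"` accepts any residue seen
#'   at each column across templates.
#' @param atom_mode `"heavy"` (all non-hydrogen atoms) or `"ca"` for the
#'   conformational distance.
#' @param exclude_adjacent Drop sequence-adjacent pairs (|i-j| <= 1) from
#'   the conformational scan; those are covered by the linear scan.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_length = 6L, max_mismatches = 0L,
                        pair_distance_cutoff = 5.0,
                        neighborhood_radius = 6L,
                        match_mode = c("per_template", "column_union"),
                        atom_mode = c("heavy", "ca"),
                        exclude_adjacent = TRUE) {
  if (window_length < 1) abort("window_length must be >= 1")
  if (pair_distance_cutoff <= 0) abort("pair_distance_cutoff must be > 0")
  structure(
    list(
      window_length = as.integer(window_length),
      max_mismatches = as.integer(max_mismatches),
      pair_distance_cutoff = pair_distance_cutoff,
      neighborhood_radius = as.integer(neighborhood_radius),
      match_mode = match.arg(match_mode),
      atom_mode = match.arg(atom_mode),
      exclude_adjacent = isTRUE(exclude_adjacent)
    ),
    class = "scan_config"
  )
}

# template residues at the given columns: matrix [templates x columns]
template_char_matrix <- function(set, columns) {
  set$.chars[, columns, drop = FALSE]
}

#' Rat-unique framework positions
#'
#' A framework position is rat-unique when the query residue at that
#' position does not appear in any human template at the aligned column.
#' `X` (unknown) residues are never called rat-unique.
#'
#' @param query An `annotated_chain` with regions delimited.
#' @param mapping A `query_mapping` covering all FR positions.
#' @param set A `template_set`.
#' @param scheme Numbering scheme whose FR/CDR partition is used.
#' @return Tibble with columns `chain`, `position`, `aa`, `column`.
#' @export
rat_unique_positions <- function(query, mapping, set, scheme = "imgt") {
  frpos <- fr_positions(query, scheme)
  cols <- mapped_columns(mapping, frpos)
  aa <- query$residues$aa[frpos]
  unique_here <- vapply(seq_along(frpos), function(k) {
    if (aa[k] == "X") return(FALSE)
    prof <- set$profiles[[cols[k]]]
    !(aa[k] %in% names(prof))
  }, logical(1))
  tibble(
    chain = query$chain_id,
    position = frpos[unique_here],
    aa = aa[unique_here],
    column = cols[unique_here]
  )
}

#' Linear epitope scan over framework regions
#'
#' Slides a probe of `window_length` residues (default 6) along each
#' framework region, one residue per step; windows straddling a CDR are
#' never formed. A window is a possible linear epitope when no single human
#' template matches it at all aligned columns with at most
#' `max_mismatches` mismatches (a template gap counts as a mismatch).
#' Windows containing `X` are skipped. Framework regions shorter than the
#' probe contribute no windows and trigger a single warning.
#'
#' @inheritParams rat_unique_positions
#' @param config A [scan_config()].
#' @return Tibble with columns `chain`, `window_start`, `window_end`,
#'   `window_residues` and `rat_unique` (list-column of the window's
#'   rat-unique positions).
#' @export
linear_scan <- function(query, mapping, set, config = scan_config(),
                        scheme = "imgt") {
  stopifnot(inherits(config, "scan_config"))
  w <- config$window_length
  map <- region_map(query, scheme)
  frs <- map |>
    filter(startsWith(.data$region, "FR")) |>
    group_by(.data$region) |>
    summarise(start = min(.data$position), end = max(.data$position))
  short <- frs$region[frs$end - frs$start + 1 < w]
  if (length(short)) {
    warn(sprintf(
      "framework region(s) shorter than the %d-residue probe: %s",
      w, paste(short, collapse = ", ")
    ))
  }
  ru <- rat_unique_positions(query, mapping, set, scheme)
  aa <- query$residues$aa
  out <- list()
  for (i in seq_len(nrow(frs))) {
    if (frs$end[i] - frs$start[i] + 1 < w) next
    for (s in frs$start[i]:(frs$end[i] - w + 1)) {
      win <- s:(s + w - 1)
      if (any(aa[win] == "X")) next
      cols <- mapped_columns(mapping, win)
      if (!window_matches(aa[win], set, cols, config)) {
        out[[length(out) + 1]] <- tibble(
          chain = query$chain_id,
          window_start = s,
          window_end = s + w - 1L,
          window_residues = paste(aa[win], collapse = ""),
          rat_unique = list(intersect(win, ru$position))
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(
      chain = character(), window_start = integer(), window_end = integer(),
      window_residues = character(), rat_unique = list()
    ))
  }
  bind_rows(out)
}

# does the window match the human set under the configured mode?
window_matches <- function(win_aa, set, cols, config) {
  tm <- template_char_matrix(set, cols)
  if (config$match_mode == "per_template") {
    mism <- rowSums(tm != matrix(win_aa, nrow(tm), length(win_aa), byrow = TRUE))
    any(mism <= config$max_mismatches)
  } else {
    absent <- vapply(seq_along(cols), function(k) {
      !(win_aa[k] %in% names(set$profiles[[cols[k]]]))
    }, logical(1))
    sum(absent) <= config$max_mismatches
  }
}

#' Conformational epitope scan over framework residue pairs
#'
#' Examines every unordered pair of framework residues of the chain (by
#' default excluding sequence-adjacent pairs, which the linear scan already
#' covers). A pair is a conformational epitope when the minimum distance
#' between its constituent atoms (heavy atoms by default) is below the
#' cutoff (5 Angstroms) and no single human template carries both residues
#' at the respective aligned columns.
#'
#' @inheritParams linear_scan
#' @param structure A `structure_model` whose residue numbers match query
#'   positions on the query's chain.
#' @param frame Frame of the structure to use (default 1).
#' @return Tibble with columns `chain`, `position_a`, `position_b`, `aa_a`,
#'   `aa_b`, `min_atom_distance`.
#' @export
conformational_scan <- function(structure, query, mapping, set,
                                config = scan_config(), scheme = "imgt",
                                frame = 1) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(config, "scan_config"))
  frpos <- fr_positions(query, scheme)
  cols <- mapped_columns(mapping, frpos)
  aa <- query$residues$aa[frpos]

  atoms <- structure_frame(structure, frame) |>
    filter(.data$chain == query$chain_id)
  if (config$atom_mode == "ca") {
    atoms <- filter(atoms, .data$elety == "CA")
  } else {
    atoms <- filter(atoms, !.data$is_hydrogen)
  }
  missing <- setdiff(frpos, unique(atoms$resno))
  if (length(missing)) {
    abort(sprintf(
      "residue(s) %s of chain %s missing from the structure",
      paste(missing, collapse = ", "), query$chain_id
    ))
  }
  coords <- split(as.matrix(atoms[, c("x", "y", "z")]), atoms$resno)
  coords <- lapply(coords, matrix, ncol = 3)

  tm <- template_char_matrix(set, cols)
  keep <- aa != "X"
  out <- list()
  n <- length(frpos)
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):n) {
      if (!keep[j]) next
      if (config$exclude_adjacent && abs(frpos[j] - frpos[i]) <= 1) next
      d <- min_pair_distance(coords[[as.character(frpos[i])]],
                             coords[[as.character(frpos[j])]])
      if (d >= config$pair_distance_cutoff) next
      cooccur <- any(tm[, i] == aa[i] & tm[, j] == aa[j])
      if (cooccur) next
      out[[length(out) + 1]] <- tibble(
        chain = query$chain_id,
        position_a = frpos[i], position_b = frpos[j],
        aa_a = aa[i], aa_b = aa[j],
        min_atom_distance = d
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      chain = character(), position_a = integer(), position_b = integer(),
      aa_a = character(), aa_b = character(), min_atom_distance = numeric()
    ))
  }
  bind_rows(out)
}

min_pair_distance <- function(a, b) {
  # minimum Euclidean distance between two small coordinate matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Propose humanizing substitutions from scan results
#'
#' Takes the union of rat-unique positions flagged by the linear and
#' conformational scans and proposes, for each, the human consensus
#' residue: the most frequent residue in the aligned column's profile
#' (ties broken alphabetically; gaps never chosen). Conformational-pair
#' members that are not themselves rat-unique are dropped, so every
#' proposed position fails the human-membership test. Positions whose
#' column is all-gap are skipped with a warning.
#'
#' @param linear Output of [linear_scan()].
#' @param conformational Output of [conformational_scan()] (may be an empty
#'   tibble when no structure is available).
#' @param set,mapping,query,scheme As used for the scans.
#' @return A substitution table: tibble with columns `chain`, `position`,
#'   `rat_aa`, `human_aa`, `provenance` (`"linear"`, `"conformational"` or
#'   `"both"`), ordered by chain (L before H) then position.
#' @export
propose_substitutions <- function(linear, conformational, set, mapping,
                                  query, scheme = "imgt") {
  ru <- rat_unique_positions(query, mapping, set, scheme)
  lin_pos <- sort(unique(unlist(linear$rat_unique)))
  conf_pos <- sort(unique(c(conformational$position_a,
                            conformational$position_b)))
  conf_pos <- intersect(conf_pos, ru$position)
  lin_pos <- intersect(lin_pos, ru$position)
  positions <- sort(union(lin_pos, conf_pos))
  if (!length(positions)) {
    return(empty_substitution_table())
  }
  rows <- purrr::map_dfr(positions, function(p) {
    col <- mapped_columns(mapping, p, what = "substitution")
    prof <- set$profiles[[col]]
    if (!length(prof)) {
      warn(sprintf("column %d is all-gap; position %d skipped", col, p))
      return(NULL)
    }
    best <- sort(names(prof)[prof == max(prof)])[1]
    tibble(
      chain = query$chain_id,
      position = p,
      rat_aa = query$residues$aa[p],
      human_aa = best,
      provenance = if (p %in% lin_pos && p %in% conf_pos) "both"
        else if (p %in% lin_pos) "linear" else "conformational"
    )
  })
  if (!nrow(rows)) return(empty_substitution_table())
  sort_substitutions(rows)
}

empty_substitution_table <- function() {
  tibble(
    chain = character(), position = integer(), rat_aa = character(),
    human_aa = character(), provenance = character()
  )
}

# canonical ordering: light before heavy, then ascending position
sort_substitutions <- function(tab) {
  tab |>
    mutate(.ord = match(.data$chain, c("L", "H"))) |>
    arrange(.data$.ord, .data$chain, .data$position) |>
    select(-".ord")
}

#' Read / write a substitution table TSV
#'
#' Tab-separated with columns `chain`, `position`, `rat_aa`, `human_aa`
#' and optionally `provenance`; rows ordered light chain first, then by
#' position.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_substitution_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(position = as.integer(.data$position))
  validate_substitution_table(tab)
  sort_substitutions(tab)
}

#' @param table Substitution table tibble.
#' @rdname read_substitution_table
#' @export
write_substitution_table <- function(table, path) {
  validate_substitution_table(table)
  readr::write_tsv(sort_substitutions(table), path, progress = FALSE)
  invisible(path)
}

validate_substitution_table <- function(tab) {
  need <- c("chain", "position", "rat_aa", "human_aa")
  if (!all(need %in% names(tab))) {
    abort(sprintf("substitution table needs columns %s",
                  paste(need, collapse = ", ")))
  }
  if (any(tab$rat_aa == tab$human_aa)) {
    abort("substitution table has records with rat_aa == human_aa")
  }
  dup <- duplicated(tab[, c("chain", "position")])
  if (any(dup)) {
    abort("substitution table has duplicate (chain, position) records")
  }
  invisible(tab)
}

#' Published substitutions for the 1-17-2 anti-DEC-205 antibody
#'
#' The 30 framework substitutions (20 light-chain, 10 heavy-chain)
#' identified by epitope scanning for humanization of the rat anti-human
#' DEC-205 antibody 1-17-2, as packaged TSV transcriptions, plus the five
#' conformation-critical key residues (L38, L43, L45, L71, H77) that are
#' back-mutated in the refined variant.
#'
#' @return `mab_1_17_2_substitutions()`: tibble with columns `chain`,
#'   `position`, `rat_aa`, `human_aa` (30 rows).
#' @export
mab_1_17_2_substitutions <- function() {
  light <- system.file("extdata", "mab_1_17_2_light_substitutions.tsv",
                       package = "abscan", mustWork = TRUE)
  heavy <- system.file("extdata", "mab_1_17_2_heavy_substitutions.tsv",
                       package = "abscan", mustWork = TRUE)
  read_one <- function(path, id) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
      mutate(chain = id, position = as.integer(.data$position)) |>
      select("chain", "position", "rat_aa", "human_aa")
  }
  sort_substitutions(bind_rows(read_one(light, "L"), read_one(heavy, "H")))
}

#' @return `mab_1_17_2_key_residues()`: tibble with columns `chain`,
#'   `position` (5 rows).
#' @rdname mab_1_17_2_substitutions
#' @export
mab_1_17_2_key_residues <- function() {
  path <- system.file("extdata", "mab_1_17_2_key_residues.tsv",
                      package = "abscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(position = as.integer(.data$position))
}
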