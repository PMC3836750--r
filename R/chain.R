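#' Parse an antibody variable-region chain
#'
#' Builds an annotated chain object from a one-letter amino-acid sequence.
#' Positions are 1-based and sequential (no insertion codes), matching the
#' convention used throughout the package for substitution tables and
#' region maps. Cysteine positions are recorded on construction; region
#' assignments are added later by [delimit_regions()].
#'
#' @param sequence_text One-letter amino-acid string. The 20 standard codes
#'   are accepted; `X` is permitted as an unknown residue and flagged (an
#'   `X` position never participates in epitope scanning).
#' @param chain_id Chain label, conventionally `"L"` or `"H"`.
#' @return An object of class `annotated_chain`: a list with elements
#'   `chain_id`, `sequence`, `residues` (tibble of `position`, `aa`),
#'   `regions` (tibble of `scheme`, `position`, `region`; empty until
#'   delimited), `cys_positions` and `x_positions`.
#' @examples
#' ch <- parse_chain("DIQMTQC", "L")
#' ch$cys_positions
#' @export
parse_chain <- function(sequence_text, chain_id = "L") {
  stopifnot(is.character(sequence_text), length(sequence_text) == 1)
  sequence_text <- toupper(trimws(sequence_text))
  if (nchar(sequence_text) == 0) {
    abort("empty sequence", class = "abscan_parse_error")
  }
  aa <- strsplit(sequence_text, "")[[1]]
  legal <- aa %in% c(AA_STANDARD, "X")
  if (!all(legal)) {
    bad <- which(!legal)[1]
    abort(
      sprintf("illegal residue character '%s' at position %d", aa[bad], bad),
      class = "abscan_parse_error"
    )
  }
  structure(
    list(
      chain_id = as.character(chain_id),
      sequence = sequence_text,
      residues = tibble(position = seq_along(aa), aa = aa),
      regions = tibble(
        scheme = character(), position = integer(), region = character()
      ),
      cys_positions = which(aa == "C"),
      x_positions = which(aa == "X")
    ),
    class = "annotated_chain"
  )
}

#' @export
print.annotated_chain <- function(x, ...) {
  cat(sprintf(
    "<annotated_chain %s> %d aa; Cys at %s\n", x$chain_id,
    nrow(x$residues),
    if (length(x$cys_positions)) paste(x$cys_positions, collapse = ", ")
    else "none"
  ))
  schemes <- unique(x$regions$scheme)
  if (length(schemes)) {
    cat("  regions delimited for:", paste(schemes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.annotated_chain <- function(x) nrow(x$residues)

REGION_ORDER <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
SCHEMES <- c("kabat", "chothia", "imgt")

#' CDR boundary rules used by anchor-based delimitation
#'
#' The delimitation in [delimit_regions()] is anchored on the two conserved
#' intradomain cysteines and on the J-segment motif (`WG.G` for heavy
#' chains, `[FW]G.G` for light chains). This table gives, per numbering
#' scheme and chain type, the offsets used to place CDR1/CDR2 relative to
#' the first cysteine and CDR3 relative to the second:
#' CDR1 starts `cdr1_start_offset` residues after the first cysteine and has
#' fixed length `cdr1_length`; FR2 and CDR2 follow with fixed lengths; CDR3
#' starts `cdr3_start_offset` after the second cysteine and runs up to the
#' residue before the J-anchor. The offsets are sequential-position
#' renderings of the published scheme definitions (e.g. Kabat L-CDR1 24-34
#' next to Cys23; IMGT CDRs begin 4 after the first and 1 after the second
#' cysteine; Kabat/Chothia heavy CDR3 begins 3 after the second cysteine).
#'
#' @return A tibble with columns `scheme`, `chain`, `cdr1_start_offset`,
#'   `cdr1_length`, `fr2_length`, `cdr2_length`, `cdr3_start_offset`.
#' @export
cdr_boundary_rules <- function() {
  tibble(
    scheme = rep(SCHEMES, each = 2),
    chain = rep(c("L", "H"), times = 3),
    cdr1_start_offset = c(1L, 9L, 1L, 4L, 4L, 4L),
    cdr1_length       = c(11L, 5L, 11L, 7L, 6L, 8L),
    fr2_length        = c(15L, 14L, 15L, 19L, 17L, 14L),
    cdr2_length       = c(7L, 16L, 7L, 5L, 3L, 8L),
    cdr3_start_offset = c(1L, 3L, 1L, 3L, 1L, 1L)
  )
}

match_scheme <- function(scheme) {
  scheme <- tolower(scheme)
  if (!scheme %in% SCHEMES) {
    abort(sprintf(
      "unknown numbering scheme '%s' (use one of %s)", scheme,
      paste(SCHEMES, collapse = ", ")
    ))
  }
  scheme
}

chain_type <- function(chain) {
  id <- toupper(chain$chain_id)
  if (startsWith(id, "H")) "H" else "L"
}

#' Delimit framework and CDR regions of a chain
#'
#' Assigns every position of the chain to one of FR1, CDR1, FR2, CDR2, FR3,
#' CDR3, FR4 under the requested numbering scheme. Delimitation is
#' anchor-based (see [cdr_boundary_rules()]): the two conserved cysteines
#' and the J-anchor motif are located first, then fixed per-scheme offsets
#' place the CDR boundaries. When the anchors cannot be found, an explicit
#' `region_map` must be supplied instead; a supplied map always overrides
#' the computed one.
#'
#' @param chain An [parse_chain()] object.
#' @param scheme `"kabat"`, `"chothia"` or `"imgt"` (default).
#' @param region_map Optional manual override: a tibble with columns
#'   `position` and `region` covering every position exactly once, regions
#'   contiguous and in canonical order.
#' @param force Allow chains outside the typical 90-130 aa variable-domain
#'   length range.
#' @return The chain with its `regions` table updated for `scheme`.
#' @examples
#' fx <- make_sequence_fixture(seed = 1)
#' region_map(fx$chains$L, "imgt")
#' @export
delimit_regions <- function(chain, scheme = "imgt", region_map = NULL,
                            force = FALSE) {
  stopifnot(inherits(chain, "annotated_chain"))
  scheme <- match_scheme(scheme)
  n <- nrow(chain$residues)

  if (!is.null(region_map)) {
    map <- validate_region_map(region_map, n)
  } else {
    if ((n < 90 || n > 130) && !force) {
      abort(sprintf(
        "chain length %d outside the 90-130 variable-domain range; use force = TRUE or supply region_map",
        n
      ))
    }
    map <- anchor_delimit(chain, scheme)
  }
  chain$regions <- bind_rows(
    filter(chain$regions, .data$scheme != !!scheme),
    tibble(scheme = scheme, position = map$position, region = map$region)
  )
  chain
}

validate_region_map <- function(region_map, n) {
  map <- as_tibble(region_map)
  if (!all(c("position", "region") %in% names(map))) {
    abort("region_map needs columns 'position' and 'region'")
  }
  map <- arrange(map, .data$position)
  if (!identical(as.integer(map$position), seq_len(n))) {
    abort(sprintf("region_map must cover positions 1..%d exactly once", n))
  }
  if (!all(map$region %in% REGION_ORDER)) {
    abort("region_map regions must be FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4")
  }
  seen <- rle(map$region)$values
  if (anyDuplicated(seen) || !identical(seen, REGION_ORDER[REGION_ORDER %in% seen])) {
    abort("regions must be contiguous and in the order FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4")
  }
  map
}

anchor_delimit <- function(chain, scheme) {
  n <- nrow(chain$residues)
  type <- chain_type(chain)
  cys <- chain$cys_positions
  cannot <- function(why) {
    abort(
      sprintf("cannot delimit (%s); supply region_map explicitly", why),
      class = "abscan_anchor_error"
    )
  }

  cys1 <- cys[cys >= 15 & cys <= 30]
  if (!length(cys1)) cannot("no conserved cysteine in positions 15-30")
  cys1 <- cys1[1]

  j_pattern <- if (type == "H") "WG.G" else "[FW]G.G"
  j_hits <- stringr::str_locate_all(chain$sequence, j_pattern)[[1]]
  j_hits <- j_hits[j_hits[, 1] >= 85, , drop = FALSE]
  if (!nrow(j_hits)) cannot("no J-anchor motif found")
  j_anchor <- unname(j_hits[1, 1])

  cys2 <- cys[cys >= 75 & cys <= j_anchor - 2]
  if (!length(cys2)) cannot("no second conserved cysteine before the J anchor")
  cys2 <- tail(cys2, 1)

  r <- filter(cdr_boundary_rules(), .data$scheme == !!scheme, .data$chain == type)
  cdr1_s <- cys1 + r$cdr1_start_offset
  cdr1_e <- cdr1_s + r$cdr1_length - 1L
  fr2_e <- cdr1_e + r$fr2_length
  cdr2_e <- fr2_e + r$cdr2_length
  cdr3_s <- cys2 + r$cdr3_start_offset
  cdr3_e <- j_anchor - 1L

  if (cdr2_e >= cdr3_s - 1L) cannot("CDR2 runs into CDR3")
  if (cdr3_e < cdr3_s) cannot("empty CDR3")
  if (j_anchor > n) cannot("no FR4")

  bounds <- c(
    FR1 = cdr1_s - 1L, CDR1 = cdr1_e, FR2 = fr2_e, CDR2 = cdr2_e,
    FR3 = cdr3_s - 1L, CDR3 = cdr3_e, FR4 = n
  )
  if (any(diff(c(0L, bounds)) < 1L)) cannot("region boundaries collapse")
  tibble(
    position = seq_len(n),
    region = rep(names(bounds), diff(c(0L, bounds)))
  )
}

#' Extract the region map of a chain for one scheme
#'
#' @param chain An annotated chain whose regions have been delimited.
#' @param scheme Numbering scheme name.
#' @return Tibble with columns `position`, `region` (and the chain's
#'   residues as column `aa`).
#' @export
region_map <- function(chain, scheme = "imgt") {
  scheme <- match_scheme(scheme)
  map <- filter(chain$regions, .data$scheme == !!scheme)
  if (!nrow(map)) {
    abort(sprintf(
      "chain %s has no region map for scheme '%s'; run delimit_regions() first",
      chain$chain_id, scheme
    ))
  }
  map |>
    select("position", "region") |>
    left_join(chain$residues, by = "position") |>
    arrange(.data$position)
}

#' Framework positions of a chain under one scheme
#' @inheritParams region_map
#' @return Integer vector of FR positions.
#' @export
fr_positions <- function(chain, scheme = "imgt") {
  map <- region_map(chain, scheme)
  map$position[startsWith(map$region, "FR")]
}

#' Pair cysteines into intradomain disulfide bonds
#'
#' Within each domain of each chain (variable domain = positions up to the
#' domain boundary, constant domain beyond it) cysteines are paired
#' sequentially: first with second, third with fourth, and so on. An odd
#' leftover cysteine is reported as unpaired, never an error. For a typical
#' IgG Fab (light chain cysteines 23/88/134/194, heavy 22/96/148/203) this
#' yields the four canonical intradomain bonds.
#'
#' @param chain_cys Named list of ascending cysteine position vectors, one
#'   element per chain (names are chain ids).
#' @param domain_boundary Named numeric: per chain, the last position of the
#'   variable domain.
#' @return List with `bonds` (tibble `position_a`, `position_b`, `chain`)
#'   and `unpaired` (tibble `chain`, `position`).
#' @examples
#' pair_cysteines(
#'   list(L = c(23, 88, 134, 194), H = c(22, 96, 148, 203)),
#'   c(L = 110, H = 120)
#' )
#' @export
pair_cysteines <- function(chain_cys, domain_boundary) {
  stopifnot(is.list(chain_cys), !is.null(names(chain_cys)))
  bonds <- list()
  unpaired <- list()
  for (id in names(chain_cys)) {
    cys <- sort(as.integer(chain_cys[[id]]))
    bound <- domain_boundary[[id]]
    if (is.null(bound) || is.na(bound)) {
      abort(sprintf("no domain boundary given for chain %s", id))
    }
    for (dom in list(cys[cys <= bound], cys[cys > bound])) {
      k <- length(dom) %/% 2
      if (k > 0) {
        idx <- seq_len(2 * k)
        bonds[[length(bonds) + 1]] <- tibble(
          position_a = dom[idx[c(TRUE, FALSE)]],
          position_b = dom[idx[c(FALSE, TRUE)]],
          chain = id
        )
      }
      if (length(dom) %% 2 == 1) {
        unpaired[[length(unpaired) + 1]] <- tibble(
          chain = id, position = tail(dom, 1)
        )
      }
    }
  }
  list(
    bonds = if (length(bonds)) bind_rows(bonds) else
      tibble(position_a = integer(), position_b = integer(), chain = character()),
    unpaired = if (length(unpaired)) bind_rows(unpaired) else
      tibble(chain = character(), position = integer())
  )
}

# ---- sequence / region-map file IO -----------------------------------------

#' Read antibody chains from a FASTA file
#'
#' The record name (first whitespace-delimited token of the description
#' line) is used as the chain id.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named list of `annotated_chain` objects.
#' @export
read_chain_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) abort(sprintf("no sequences in '%s'", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  chains <- purrr::map2(as.character(seqs), ids, parse_chain)
  names(chains) <- ids
  chains
}

#' Write antibody chains to a FASTA file
#'
#' @param chains Named list of `annotated_chain` objects or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(chains, path) {
  seqs <- chains_as_character(chains)
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# accept either annotated chains or plain named sequences
chains_as_character <- function(chains) {
  if (is.character(chains)) {
    if (is.null(names(chains))) abort("chain sequences must be named")
    return(chains)
  }
  if (inherits(chains, "annotated_chain")) chains <- list(chains)
  out <- vapply(chains, function(ch) {
    stopifnot(inherits(ch, "annotated_chain"))
    ch$sequence
  }, character(1))
  names(out) <- vapply(chains, function(ch) ch$chain_id, character(1))
  out
}

#' Read / write a region-map TSV
#'
#' Columns: `chain`, `position`, `scheme`, `region`. This is the manual
#' override format accepted by [delimit_regions()] (filter to one chain and
#' scheme) and the output of `abscan number`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_region_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(position = as.integer(.data$position))
}

#' @param map Tibble with columns `chain`, `position`, `scheme`, `region`.
#' @rdname read_region_map
#' @export
write_region_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}
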