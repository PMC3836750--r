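#' Apply humanizing substitutions to parental chains
#'
#' Replaces the rat residue with the human residue at every position of the
#' substitution table. Each record is guarded: the parental residue must
#' equal the table's `rat_aa`, otherwise the table and sequences have
#' drifted apart and an error is raised.
#'
#' @param chains Named character vector (or list of `annotated_chain`s) of
#'   parental variable-region sequences, names are chain ids.
#' @param table Substitution table (`chain`, `position`, `rat_aa`,
#'   `human_aa`).
#' @return Named character vector of humanized sequences.
#' @examples
#' apply_substitutions(c(L = "DIQA"), tibble::tibble(
#'   chain = "L", position = 4L, rat_aa = "A", human_aa = "S"
#' ))
#' @export
apply_substitutions <- function(chains, table) {
  seqs <- chains_as_character(chains)
  validate_substitution_table(table)
  for (i in seq_len(nrow(table))) {
    id <- table$chain[i]; pos <- table$position[i]
    if (!id %in% names(seqs)) {
      abort(sprintf("no chain '%s' among the parental sequences", id))
    }
    if (pos > nchar(seqs[[id]])) {
      abort(sprintf("position %s:%d beyond chain length", id, pos))
    }
    found <- substr(seqs[[id]], pos, pos)
    if (found != table$rat_aa[i]) {
      abort(sprintf("expected %s at %s:%d, found %s",
                    table$rat_aa[i], id, pos, found))
    }
    substr(seqs[[id]], pos, pos) <- table$human_aa[i]
  }
  seqs
}

#' Back-mutate key residues of a humanized antibody
#'
#' Reverts the listed key positions of the humanized chains to the
#' original rat residue recorded in the substitution table, producing the
#' refined variant; all other positions are untouched.
#'
#' @param chains Named character vector of humanized sequences.
#' @param table The substitution table that produced them.
#' @param keys Tibble with columns `chain`, `position` of key residues.
#' @return Named character vector of refined sequences.
#' @export
apply_back_mutations <- function(chains, table, keys) {
  seqs <- chains_as_character(chains)
  keys <- as_tibble(keys)
  if (!all(c("chain", "position") %in% names(keys))) {
    abort("keys needs columns 'chain' and 'position'")
  }
  idx <- match(paste(keys$chain, keys$position),
               paste(table$chain, table$position))
  if (anyNA(idx)) {
    missing <- keys[is.na(idx), ]
    abort(sprintf(
      "key position(s) not in the substitution table: %s",
      paste(paste0(missing$chain, ":", missing$position), collapse = ", ")
    ))
  }
  for (k in seq_along(idx)) {
    rec <- table[idx[k], ]
    found <- substr(seqs[[rec$chain]], rec$position, rec$position)
    if (found != rec$human_aa) {
      abort(sprintf("expected humanized residue %s at %s:%d, found %s",
                    rec$human_aa, rec$chain, rec$position, found))
    }
    substr(seqs[[rec$chain]], rec$position, rec$position) <- rec$rat_aa
  }
  seqs
}

#' Humanization rate of a variable domain
#'
#' The percentage of residues of human origin after humanization:
#' `100 * (fr_residue_count - back_mutation_count) / total_residue_count`,
#' reported half-up to one decimal. With the framework residue count 600,
#' total 663 and no back-mutations this gives 90.5; back-mutating the five
#' key residues lowers it to 89.7.
#'
#' @param fr_residue_count Number of framework residues substituted to
#'   human (the humanized framework size).
#' @param back_mutation_count Number of key residues reverted to rat.
#' @param total_residue_count Total residues of the region considered.
#' @return Percentage, rounded half-up to one decimal.
#' @examples
#' humanization_rate(600, 0, 663)
#' humanization_rate(600, 5, 663)
#' @export
humanization_rate <- function(fr_residue_count, back_mutation_count,
                              total_residue_count) {
  if (total_residue_count <= 0) abort("total residue count must be positive")
  if (back_mutation_count < 0 || fr_residue_count < back_mutation_count ||
      total_residue_count < fr_residue_count) {
    abort("counts must satisfy 0 <= back <= fr <= total")
  }
  pct <- 100 * (fr_residue_count - back_mutation_count) / total_residue_count
  floor(pct * 10 + 0.5) / 10  # half-up to one decimal
}

#' Positionwise differences between two chain sets
#'
#' @param a,b Named character vectors of sequences with matching names and
#'   per-chain lengths.
#' @return Tibble with columns `chain`, `position`, `aa_a`, `aa_b`, one row
#'   per differing position, ordered by chain then position.
#' @export
diff_chains <- function(a, b) {
  a <- chains_as_character(a); b <- chains_as_character(b)
  if (!setequal(names(a), names(b))) {
    abort("chain sets have different chain ids")
  }
  out <- purrr::map_dfr(names(a), function(id) {
    if (nchar(a[[id]]) != nchar(b[[id]])) {
      abort(sprintf("chain %s length mismatch (%d vs %d)", id,
                    nchar(a[[id]]), nchar(b[[id]])))
    }
    va <- strsplit(a[[id]], "")[[1]]
    vb <- strsplit(b[[id]], "")[[1]]
    pos <- which(va != vb)
    tibble(chain = id, position = pos, aa_a = va[pos], aa_b = vb[pos])
  })
  sort_substitutions(out)
}

#' Build the variant set of a humanization run
#'
#' Convenience wrapper producing the parental, humanized and refined
#' sequences together with the bookkeeping needed for reporting.
#'
#' @param parental Named character vector of parental sequences.
#' @param table Substitution table.
#' @param keys Key residues to back-mutate (tibble `chain`, `position`);
#'   may be empty for a humanized-only set.
#' @return List of class `variant_set` with elements `parental`,
#'   `humanized`, `refined`, `applied` (the table), `back_mutations`.
#' @export
build_variants <- function(parental, table, keys = NULL) {
  parental <- chains_as_character(parental)
  humanized <- apply_substitutions(parental, table)
  if (is.null(keys) || !nrow(keys)) {
    refined <- humanized
    keys <- tibble(chain = character(), position = integer())
  } else {
    refined <- apply_back_mutations(humanized, table, keys)
  }
  structure(
    list(parental = parental, humanized = humanized, refined = refined,
         applied = table, back_mutations = as_tibble(keys)),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "<variant_set> chains %s; %d substitutions, %d back-mutations\n",
    paste(names(x$parental), collapse = ", "),
    nrow(x$applied), nrow(x$back_mutations)
  ))
  invisible(x)
}
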