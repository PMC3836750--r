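#' Construct a human template set from aligned sequences
#'
#' @param accessions Character vector of template labels (e.g. GenBank
#'   accessions).
#' @param aligned Character vector of aligned sequences, all the same
#'   length; gap characters `-` and `.` are both accepted and normalized
#'   to `-`.
#' @return An object of class `template_set`: list with `templates`
#'   (tibble `accession`, `aligned`), `n_columns`, and `profiles`, a list
#'   of per-column counts of the non-gap residues observed at that column.
#' @export
template_set <- function(accessions, aligned) {
  stopifnot(length(accessions) == length(aligned), length(aligned) >= 1)
  aligned <- toupper(gsub(".", "-", aligned, fixed = TRUE))
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1) {
    abort("ragged alignment: sequences have unequal lengths")
  }
  n_col <- widths[1]
  if (n_col == 0) abort("empty alignment")
  chars <- do.call(rbind, strsplit(aligned, ""))
  profiles <- lapply(seq_len(n_col), function(j) {
    col <- chars[, j]
    table(col[col != "-"])
  })
  structure(
    list(
      templates = tibble(accession = as.character(accessions), aligned = aligned),
      n_columns = n_col,
      profiles = profiles,
      .chars = chars
    ),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf(
    "<template_set> %d sequences x %d columns\n",
    nrow(x$templates), x$n_columns
  ))
  invisible(x)
}

#' Read a human template alignment
#'
#' Reads an aligned FASTA or Clustal `.aln` file into a [template_set()].
#'
#' @param path Path to the alignment.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"clustal"`.
#' @return A `template_set`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (length(first) && grepl("^CLUSTAL", first)) "clustal" else "fasta"
  }
  if (format == "clustal") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(aln))
  } else {
    set <- Biostrings::readAAStringSet(path)
    if (!length(set)) abort(sprintf("no sequences in '%s'", path))
    seqs <- as.character(set)
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1) {
      abort("ragged alignment: sequences have unequal lengths")
    }
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  template_set(ids, unname(seqs))
}

#' Write a template set as aligned FASTA
#'
#' @param set A `template_set`.
#' @param path Output path.
#' @export
write_alignment <- function(set, path) {
  stopifnot(inherits(set, "template_set"))
  seqs <- Biostrings::AAStringSet(setNames(set$templates$aligned,
                                           set$templates$accession))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Per-column residue profiles of a template set
#'
#' @param set A `template_set`.
#' @return Tibble with columns `column`, `aa`, `count` (gaps excluded).
#' @export
column_profiles <- function(set) {
  stopifnot(inherits(set, "template_set"))
  purrr::imap_dfr(set$profiles, function(p, j) {
    if (!length(p)) return(tibble(column = integer(), aa = character(), count = integer()))
    tibble(column = as.integer(j), aa = names(p), count = as.integer(p))
  })
}

#' Optimal global pairwise alignment of two residue strings
#'
#' Needleman-Wunsch global alignment with affine gaps, computed with
#' Biostrings. Defaults mirror a blastp-like scoring: BLOSUM62, gap open
#' 10, gap extend 0.5. Supplying `match`/`mismatch` switches to a simple
#' match/mismatch matrix (useful for small, hand-checkable cases).
#'
#' @param query,template Non-empty residue strings.
#' @param sub_matrix Name of a substitution matrix (`"BLOSUM62"`,
#'   `"BLOSUM80"`, `"PAM30"`, ...) available in Biostrings.
#' @param gap_open,gap_extend Gap penalties (positive numbers; a gap of
#'   length k costs `gap_open + k * gap_extend`).
#' @param match,mismatch Optional scores overriding `sub_matrix`.
#' @return List with `score`, `query_aligned`, `template_aligned` (gapped
#'   strings) and `pairs`, a tibble of aligned `query_pos`/`template_pos`
#'   (both non-gap).
#' @examples
#' global_align("ACD", "AD", match = 1, mismatch = -1,
#'              gap_open = 0, gap_extend = 4)$score
#' @export
global_align <- function(query, template, sub_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         match = NULL, mismatch = NULL) {
  if (!nzchar(query) || !nzchar(template)) abort("sequences must be non-empty")
  if (!is.null(match) || !is.null(mismatch)) {
    match <- match %||% 1
    mismatch <- mismatch %||% -1
    alpha <- c(AA_STANDARD, "X")
    m <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(m) <- match
  } else {
    m <- get(data(list = sub_matrix, package = "Biostrings",
                  envir = environment()))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(template),
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  qa <- as.character(Biostrings::alignedPattern(pa))
  ta <- as.character(Biostrings::alignedSubject(pa))
  qv <- strsplit(qa, "")[[1]]
  tv <- strsplit(ta, "")[[1]]
  qpos <- cumsum(qv != "-")
  tpos <- cumsum(tv != "-")
  both <- qv != "-" & tv != "-"
  list(
    score = Biostrings::score(pa),
    query_aligned = qa,
    template_aligned = ta,
    pairs = tibble(query_pos = qpos[both], template_pos = tpos[both])
  )
}

#' Map a query chain onto template-set alignment columns
#'
#' The query is aligned pairwise against one anchor template (its gaps
#' removed), and the pairing is composed through the anchor's gap structure
#' to obtain a monotone partial map from query positions to alignment
#' columns. By default the anchor is the template with the highest global
#' alignment score against the query. A manual mapping (tibble
#' `query_position`, `column`) always overrides the computed one.
#'
#' @param query An `annotated_chain`.
#' @param set A `template_set`.
#' @param anchor_template Accession label of the anchor; `NULL` picks the
#'   highest-scoring template.
#' @param mapping Optional manual mapping tibble (columns `query_position`,
#'   `column`), e.g. from [read_mapping()].
#' @param ... Scoring arguments passed to [global_align()].
#' @return An object of class `query_mapping`: tibble with columns
#'   `query_position`, `column`; attribute `anchor` records the anchor used.
#' @export
map_query_to_msa <- function(query, set, anchor_template = NULL,
                             mapping = NULL, ...) {
  stopifnot(inherits(query, "annotated_chain"), inherits(set, "template_set"))
  if (!is.null(mapping)) {
    return(new_query_mapping(mapping, anchor = "manual",
                             chain_id = query$chain_id))
  }
  if (is.null(anchor_template)) {
    scores <- vapply(set$templates$aligned, function(a) {
      ung <- gsub("-", "", a, fixed = TRUE)
      if (!nzchar(ung)) return(-Inf)
      global_align(query$sequence, ung, ...)$score
    }, numeric(1))
    anchor_template <- set$templates$accession[which.max(scores)]
  }
  idx <- match(anchor_template, set$templates$accession)
  if (is.na(idx)) {
    abort(sprintf("anchor template '%s' not found in the set", anchor_template))
  }
  aligned <- set$templates$aligned[idx]
  achars <- strsplit(aligned, "")[[1]]
  non_gap_cols <- which(achars != "-")
  if (!length(non_gap_cols)) {
    abort(sprintf("anchor template '%s' is all gaps", anchor_template))
  }
  ungapped <- paste(achars[achars != "-"], collapse = "")
  aln <- global_align(query$sequence, ungapped, ...)
  map <- tibble(
    query_position = aln$pairs$query_pos,
    column = non_gap_cols[aln$pairs$template_pos]
  )
  new_query_mapping(map, anchor = anchor_template, chain_id = query$chain_id)
}

new_query_mapping <- function(map, anchor, chain_id) {
  map <- as_tibble(map)
  if (!all(c("query_position", "column") %in% names(map))) {
    abort("mapping needs columns 'query_position' and 'column'")
  }
  map <- map |>
    mutate(
      query_position = as.integer(.data$query_position),
      column = as.integer(.data$column)
    ) |>
    arrange(.data$query_position)
  if (anyDuplicated(map$query_position) || any(diff(map$column) <= 0)) {
    abort("mapping must be strictly monotone: one column per query position")
  }
  structure(map, class = c("query_mapping", class(map)),
            anchor = anchor, chain_id = chain_id)
}

#' @export
print.query_mapping <- function(x, ...) {
  cat(sprintf(
    "<query_mapping> %d positions mapped (anchor: %s)\n",
    nrow(x), attr(x, "anchor")
  ))
  NextMethod()
}

#' Read / write a query-to-column mapping TSV
#'
#' Columns `query_position`, `column`; the manual override format of
#' [map_query_to_msa()].
#'
#' @param path TSV path.
#' @return A `query_mapping`.
#' @export
read_mapping <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_query_mapping(m, anchor = "manual", chain_id = NA_character_)
}

#' @param mapping A `query_mapping`.
#' @rdname read_mapping
#' @export
write_mapping <- function(mapping, path) {
  readr::write_tsv(as_tibble(mapping), path, progress = FALSE)
  invisible(path)
}

# columns mapped for a set of query positions; error listing unmapped ones
mapped_columns <- function(mapping, positions, what = "FR") {
  idx <- match(positions, mapping$query_position)
  if (anyNA(idx)) {
    abort(sprintf(
      "unmapped %s positions: %s", what,
      paste(positions[is.na(idx)], collapse = ", ")
    ))
  }
  mapping$column[idx]
}
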