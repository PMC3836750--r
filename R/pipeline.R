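#' Run the full humanization pipeline
#'
#' Drives the workflow end to end: region delimitation, query-to-MSA
#' mapping, linear (and, when a structure is available, conformational)
#' epitope scanning, substitution proposal, humanization, and — when
#' mutant structures or a per-mutant RMSD table are supplied — CDR-RMSD
#' key-residue identification and back-mutation into the refined variant.
#' Without structures the pipeline degrades explicitly: the conformational
#' scan and RMSD stages are reported as skipped and only the humanized
#' variant is produced.
#'
#' @param config Named list (or path to a flat JSON file) with entries:
#'   \describe{
#'     \item{query_fasta / chains}{path to a FASTA of the variable-region
#'       chains, or a named character vector of sequences.}
#'     \item{msa}{named list per chain id of alignment paths (FASTA or
#'       Clustal) or `template_set` objects.}
#'     \item{anchor}{optional named list of anchor accessions.}
#'     \item{mapping}{optional named list of mapping-TSV paths.}
#'     \item{structure}{optional PDB path or `structure_model` of the Fab.}
#'     \item{mutants}{optional named list of mutant PDB paths or
#'       `structure_model`s, or `rmsd_table` (path or tibble) of
#'       precomputed per-mutant CDR RMSDs.}
#'     \item{scheme}{numbering scheme, default `"imgt"`.}
#'     \item{scan}{list of [scan_config()] overrides.}
#'     \item{threshold, identical_cutoff}{key-residue RMSD thresholds.}
#'     \item{out_dir}{output directory; created if missing.}
#'     \item{seed}{optional integer recorded in the report.}
#'   }
#' @return The run report (list), invisibly; also written as JSON to
#'   `out_dir/run_report.json` together with all intermediate tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  scheme <- match_scheme(cfg$scheme %||% "imgt")
  out_dir <- cfg$out_dir %||% abort("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(scan_config, cfg$scan %||% list())
  report <- list(
    parameters = list(
      scheme = scheme, seed = cfg$seed,
      threshold = cfg$threshold %||% 1.5,
      identical_cutoff = cfg$identical_cutoff %||% 1.0,
      scan = unclass(sc)
    ),
    stages = list(), artifacts = list()
  )
  manifest <- file.path(out_dir, "MANIFEST")
  done <- character()
  mark <- function(stage) {
    done <<- c(done, stage)
    writeLines(done, manifest)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(done, paste("FAILED:", name)), manifest)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # ---- load + delimit ------------------------------------------------------
  chains <- stage("load_query", {
    if (!is.null(cfg$chains)) {
      purrr::imap(cfg$chains, function(s, id) parse_chain(s, id))
    } else if (!is.null(cfg$query_fasta)) {
      if (!file.exists(cfg$query_fasta)) {
        abort(sprintf("query fasta '%s' does not exist", cfg$query_fasta))
      }
      read_chain_fasta(cfg$query_fasta)
    } else {
      abort("config needs 'query_fasta' or 'chains'")
    }
  })
  chains <- stage("delimit", {
    purrr::map(chains, delimit_regions, scheme = scheme)
  })
  rmap <- region_map_table(chains, scheme)
  write_region_map(mutate(rmap, scheme = scheme),
                   file.path(out_dir, "regions.tsv"))
  report$artifacts$regions <- "regions.tsv"
  mark("delimit")

  # ---- templates + mapping -------------------------------------------------
  if (is.null(cfg$msa)) abort("config needs 'msa' (one alignment per chain)")
  sets <- stage("load_msa", purrr::imap(cfg$msa, function(m, id) {
    if (inherits(m, "template_set")) return(m)
    if (!file.exists(m)) abort(sprintf("MSA '%s' does not exist", m))
    read_alignment(m)
  }))
  mappings <- stage("map", purrr::imap(sets, function(set, id) {
    if (!is.null(cfg$mapping[[id]])) {
      mp <- cfg$mapping[[id]]
      if (is.character(mp)) read_mapping(mp) else
        new_query_mapping(mp, "manual", id)
    } else {
      map_query_to_msa(chains[[id]], set,
                       anchor_template = cfg$anchor[[id]])
    }
  }))
  for (id in names(mappings)) {
    write_mapping(mappings[[id]],
                  file.path(out_dir, sprintf("mapping_%s.tsv", id)))
  }
  mark("map")

  # ---- scans ---------------------------------------------------------------
  fab <- NULL
  if (!is.null(cfg$structure)) {
    fab <- stage("load_structure", {
      if (inherits(cfg$structure, "structure_model")) cfg$structure
      else read_structure(cfg$structure)
    })
  }
  scans <- stage("scan", purrr::imap(sets, function(set, id) {
    lin <- linear_scan(chains[[id]], mappings[[id]], set, sc, scheme)
    conf <- if (!is.null(fab)) {
      conformational_scan(fab, chains[[id]], mappings[[id]], set, sc, scheme)
    } else {
      NULL
    }
    list(linear = lin, conformational = conf)
  }))
  lin_all <- purrr::map_dfr(scans, function(s) {
    mutate(s$linear, rat_unique = vapply(.data$rat_unique, paste,
                                         character(1), collapse = ","))
  })
  readr::write_tsv(lin_all, file.path(out_dir, "linear_epitopes.tsv"),
                   progress = FALSE)
  if (!is.null(fab)) {
    conf_all <- purrr::map_dfr(scans, "conformational")
    readr::write_tsv(conf_all, file.path(out_dir, "conformational_epitopes.tsv"),
                     progress = FALSE)
    report$stages$conformational_scan <- "run"
  } else {
    report$stages$conformational_scan <- "skipped (no structure supplied)"
  }
  mark("scan")

  subs <- stage("propose", {
    tabs <- purrr::imap(sets, function(set, id) {
      conf <- scans[[id]]$conformational %||%
        tibble(chain = character(), position_a = integer(),
               position_b = integer())
      propose_substitutions(scans[[id]]$linear, conf, set, mappings[[id]],
                            chains[[id]], scheme)
    })
    sort_substitutions(bind_rows(tabs))
  })
  if (nrow(subs)) {
    write_substitution_table(subs, file.path(out_dir, "substitutions.tsv"))
  } else {
    readr::write_tsv(subs, file.path(out_dir, "substitutions.tsv"),
                     progress = FALSE)
  }
  report$artifacts$substitutions <- "substitutions.tsv"
  mark("propose")

  # ---- humanize ------------------------------------------------------------
  parental <- chains_as_character(chains)
  humanized <- stage("humanize", apply_substitutions(parental, subs))

  # ---- key residues --------------------------------------------------------
  keys <- NULL
  key_report <- NULL
  if (!is.null(cfg$mutants)) {
    rmsds <- stage("rmsd", {
      if (!is.null(cfg$mutants$rmsd_table)) {
        rt <- cfg$mutants$rmsd_table
        if (is.character(rt)) read_rmsd_table(rt) else as_tibble(rt)
      } else {
        ref <- fab %||% abort("mutant structures require 'structure'")
        vals <- purrr::imap_dbl(cfg$mutants, function(m, label) {
          mod <- if (inherits(m, "structure_model")) m else read_structure(m)
          cdr_rmsd(mod, ref, rmap)
        })
        tibble(mutant = names(vals), rmsd = unname(vals))
      }
    })
    write_rmsd_table(rmsds, file.path(out_dir, "rmsds.tsv"))
    key_report <- stage("keyres", call_key_residues(
      rmsds, threshold = report$parameters$threshold,
      identical_cutoff = report$parameters$identical_cutoff
    ))
    keys <- parse_mutant_labels(key_report$key_residues)
    report$stages$key_residues <- "run"
    mark("keyres")
  } else {
    report$stages$key_residues <- "skipped (no mutants supplied)"
  }

  variants <- stage("variants", build_variants(parental, subs, keys))
  write_chain_fasta(
    setNames(variants$humanized,
             paste0(names(variants$humanized), "_humanized")),
    file.path(out_dir, "humanized.fasta")
  )
  if (!is.null(keys) && nrow(keys)) {
    write_chain_fasta(
      setNames(variants$refined, paste0(names(variants$refined), "_refined")),
      file.path(out_dir, "refined.fasta")
    )
  }
  mark("variants")

  # ---- rates + report ------------------------------------------------------
  fr_count <- sum(startsWith(rmap$region, "FR"))
  total <- nrow(rmap)
  back <- if (is.null(keys)) 0L else nrow(keys)
  report$summary <- list(
    n_substitutions = nrow(subs),
    n_key_residues = back,
    key_residues = if (!is.null(key_report)) key_report$key_residues else
      character(),
    fr_residue_count = fr_count,
    total_residue_count = total,
    humanization_rate = humanization_rate(fr_count, 0, total),
    refined_humanization_rate = humanization_rate(fr_count, back, total)
  )
  report$stages$completed <- done
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  mark("report")
  invisible(report)
}

# "L38" -> tibble(chain = "L", position = 38)
parse_mutant_labels <- function(labels) {
  if (!length(labels)) return(tibble(chain = character(), position = integer()))
  m <- stringr::str_match(labels, "^([A-Za-z]+)(\\d+)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("cannot parse mutant label(s): %s",
                  paste(labels[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(chain = m[, 2], position = as.integer(m[, 3]))
}
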