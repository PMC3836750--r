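#' Tidy a key-residue RMSD report
#'
#' @param x An `rmsd_report` from [call_key_residues()].
#' @param ... Unused.
#' @return Tibble with one row per mutant: `mutant`, `rmsd`, `is_key`,
#'   `is_identical`.
#' @export
tidy.rmsd_report <- function(x, ...) {
  x$table
}

#' @rdname tidy.rmsd_report
#' @return `glance()`: one-row tibble with `n_mutants`, `n_key`,
#'   `max_rmsd`, `threshold`, `identical_cutoff`.
#' @export
glance.rmsd_report <- function(x, ...) {
  tibble(
    n_mutants = nrow(x$table),
    n_key = length(x$key_residues),
    max_rmsd = if (nrow(x$table)) max(x$table$rmsd) else NA_real_,
    threshold = x$threshold,
    identical_cutoff = x$identical_cutoff
  )
}

#' Tidy a variant set
#'
#' @param x A `variant_set` from [build_variants()].
#' @param ... Unused.
#' @return Tibble with columns `chain`, `variant`, `sequence`.
#' @export
tidy.variant_set <- function(x, ...) {
  purrr::imap_dfr(
    list(parental = x$parental, humanized = x$humanized, refined = x$refined),
    function(seqs, nm) tibble(chain = names(seqs), variant = nm,
                              sequence = unname(seqs))
  )
}

#' @rdname tidy.variant_set
#' @export
glance.variant_set <- function(x, ...) {
  tibble(
    n_chains = length(x$parental),
    n_substitutions = nrow(x$applied),
    n_back_mutations = nrow(x$back_mutations),
    total_residues = sum(nchar(x$parental))
  )
}

#' Plot a per-mutant CDR RMSD report
#'
#' Bar chart of per-mutant CDR RMSD values with the key-residue threshold
#' and the structural-identity cutoff drawn as horizontal lines; key
#' mutants are highlighted.
#'
#' @param object An `rmsd_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_report <- function(object, ...) {
  tab <- object$table |>
    mutate(mutant = factor(.data$mutant, levels = .data$mutant))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mutant, y = .data$rmsd,
                                    fill = .data$is_key)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$identical_cutoff,
                        linetype = "dotted") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      name = "key residue"
    ) +
    ggplot2::labs(x = "mutant", y = "CDR RMSD (Å)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an RMSD-versus-time series with its detected balance point
#'
#' @param series Tibble from [rmsd_series()].
#' @param balance_start Optional frame index (e.g. from
#'   [detect_balance()]) drawn as a vertical line.
#' @return A ggplot.
#' @export
plot_rmsd_series <- function(series, balance_start = NULL) {
  xvar <- if ("time_ps" %in% names(series)) "time_ps" else "frame"
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data[[xvar]],
                                            y = .data$rmsd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = if (xvar == "time_ps") "time (ps)" else "frame",
      y = "RMSD (Å)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(balance_start) && !is.na(balance_start)) {
    xb <- if (xvar == "time_ps") series$time_ps[balance_start]
      else balance_start
    p <- p + ggplot2::geom_vline(xintercept = xb, colour = "#2980b9",
                                 linetype = "dashed")
  }
  p
}
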