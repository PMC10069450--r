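## broom-style tidiers for the package's result objects.

#' Tidy a registry spectrum
#'
#' @param x A [registry_spectrum()] object.
#' @param ... Unused.
#' @return Tibble with `registry`, `n_pairs`, `fraction`.
#' @method tidy registry_spectrum
#' @export
tidy.registry_spectrum <- function(x, ...) {
  out <- as_tibble(x)
  total <- sum(out$n_pairs)
  mutate(out, fraction = if (total > 0) .data$n_pairs / total else NA_real_)
}

#' @rdname tidy.registry_spectrum
#' @return For `glance()`: one row with `sizes`, `modal_registry`,
#'   `mode_fraction`, `n_pairs`.
#' @method glance registry_spectrum
#' @export
glance.registry_spectrum <- function(x, ...) {
  sizes <- attr(x, "sizes")
  if (nrow(x) == 0) {
    return(tibble(top_size = sizes[1], bottom_size = sizes[2],
                  modal_registry = NA_integer_, mode_fraction = NA_real_,
                  n_pairs = 0))
  }
  i <- which.max(x$n_pairs)
  tibble(top_size = sizes[1], bottom_size = sizes[2],
         modal_registry = as.integer(x$registry[i]),
         mode_fraction = x$n_pairs[i] / sum(x$n_pairs),
         n_pairs = sum(x$n_pairs))
}

#' Tidy a position-10 U signature report
#'
#' @param x A [u10_signature()] report.
#' @param ... Unused.
#' @return Long tibble with `position`, `base`, `freq`.
#' @method tidy u10_report
#' @export
tidy.u10_report <- function(x, ...) {
  as_tibble(x$matrix) %>%
    tidyr::pivot_longer(-"position", names_to = "base", values_to = "freq")
}

#' @rdname tidy.u10_report
#' @return For `glance()`: one row with `peak_position`, `peak_excess`,
#'   `n_reads`.
#' @method glance u10_report
#' @export
glance.u10_report <- function(x, ...) {
  tibble(peak_position = x$peak_position, peak_excess = x$peak_excess,
         n_reads = x$n_reads)
}

#' Tidy a positional frequency matrix
#'
#' @param x A [positional_matrix()].
#' @param ... Unused.
#' @return Long tibble with `position`, `base`, `freq` and an `anchor`
#'   column.
#' @method tidy positional_matrix
#' @export
tidy.positional_matrix <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(-"position", names_to = "base", values_to = "freq") %>%
    mutate(anchor = attr(x, "anchor"))
}

#' Tidy a DMR table
#'
#' @param x A [merge_dmrs()] result.
#' @param ... Unused.
#' @return The DMR tibble without its class decoration.
#' @method tidy dmr
#' @export
tidy.dmr <- function(x, ...) as_tibble(x)

#' @rdname tidy.dmr
#' @return For `glance()`: one row with `n_dmrs`, `total_bp`,
#'   `mean_delta`.
#' @method glance dmr
#' @export
glance.dmr <- function(x, ...) {
  tibble(n_dmrs = nrow(x),
         total_bp = if (nrow(x) > 0) sum(x$end - x$start) else 0L,
         mean_delta = if (nrow(x) > 0) mean(x$mean_delta) else NA_real_)
}

#' Tidy a DMR-siRNA association
#'
#' @param x A [dmr_sirna_association()] result.
#' @param ... Unused.
#' @return The per-DMR table (`tidy`) or a one-row summary (`glance`).
#' @method tidy dmr_association
#' @export
tidy.dmr_association <- function(x, ...) as_tibble(x$table)

#' @rdname tidy.dmr_association
#' @method glance dmr_association
#' @export
glance.dmr_association <- function(x, ...) {
  tibble(estimate = x$estimate, p_value = x$p_value, n = x$n)
}
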