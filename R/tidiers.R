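#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mined signature result
#'
#' Returns the evaluation audit as a tibble, one row per window examined
#' during the sweep, with a `winner` column marking the selected signature.
#'
#' @param x A `signature_result` from [mine_signature()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy signature_result
#' @export
tidy.signature_result <- function(x, ...) {
  ev <- x$evaluations
  if (nrow(ev) == 0L) {
    ev$winner <- logical(0)
    return(ev)
  }
  win <- x$signature
  ev$winner <- if (is.null(win) || nrow(win) == 0L) FALSE else {
    ev$residues == win$residues & ev$length == win$length
  }
  ev
}

#' One-row summary of a mined signature result
#'
#' @param x A `signature_result` from [mine_signature()].
#' @param ... Unused.
#' @return A one-row tibble: whether a signature was found, its residues and
#'   length, conservation fraction, minimum outgroup distance, and the
#'   numbers of conserved regions and windows evaluated.
#' @method glance signature_result
#' @export
glance.signature_result <- function(x, ...) {
  found <- !is.null(x$signature) && nrow(x$signature) == 1L
  tibble::tibble(
    found = found,
    residues = if (found) x$signature$residues else NA_character_,
    length = if (found) x$signature$length else NA_integer_,
    conservation_fraction = if (found) x$signature$conservation_fraction else NA_real_,
    min_distance = if (found) x$signature$min_distance else NA_real_,
    n_regions = nrow(x$regions),
    n_evaluated = nrow(x$evaluations)
  )
}

#' Plot the mining audit trail
#'
#' Window length against minimum outgroup distance for every window examined
#' during the sweep, coloured by the joint conserved/specific verdict, with
#' the selected signature highlighted. The horizontal line marks the required
#' distance `d_min`: the conserved-versus-specific trade-off is visible as
#' short windows falling below it.
#'
#' @param object A `signature_result` from [mine_signature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_result
#' @export
autoplot.signature_result <- function(object, ...) {
  ev <- tidy(object)
  if (nrow(ev) == 0L) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "No windows evaluated"))
  }
  ev$verdict <- dplyr::case_when(
    ev$conserved & ev$specific ~ "conserved + specific",
    ev$conserved ~ "conserved only",
    ev$specific ~ "specific only",
    TRUE ~ "neither"
  )
  ev$plot_distance <- pmin(ev$min_distance, max(ev$length))  # cap Inf for display
  p <- ggplot2::ggplot(ev, ggplot2::aes(x = .data$length, y = .data$plot_distance,
                                        colour = .data$verdict)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.1, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$parameters$policy$d_min,
                        linetype = "dashed") +
    ggplot2::labs(x = "window length (bp)", y = "min outgroup distance",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (any(ev$winner)) {
    p <- p + ggplot2::geom_point(data = ev[ev$winner, ], shape = 21, size = 4,
                                 stroke = 1.2, colour = "black", fill = NA)
  }
  p
}

#' Plot a length sweep
#'
#' Summarises an evaluation table (e.g. from [sweep_lengths()]) per length:
#' the fraction of windows at that length that are conserved, specific, and
#' both — the two opposing failure modes of too-long and too-short windows.
#'
#' @param evaluations An evaluation tibble with `length`, `conserved` and
#'   `specific` columns.
#' @return A ggplot object.
#' @export
plot_sweep <- function(evaluations) {
  stopifnot(all(c("length", "conserved", "specific") %in% names(evaluations)))
  summ <- evaluations |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(
      conserved = mean(.data$conserved),
      specific = mean(.data$specific),
      both = mean(.data$conserved & .data$specific),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"length", names_to = "criterion", values_to = "fraction")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$length, y = .data$fraction,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window length (bp)", y = "fraction of windows",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot signature detection results
#'
#' One tile per query showing whether the signature was found and, where
#' found, with how many mismatches and on which strand.
#'
#' @param detections A detection tibble from [detect_signature()].
#' @return A ggplot object.
#' @export
plot_detection <- function(detections) {
  stopifnot(all(c("query_id", "found") %in% names(detections)))
  d <- tibble::as_tibble(detections)
  d$label <- ifelse(d$found,
                    paste0("found (", d$mismatches, " mm, ", d$strand, ")"),
                    "not found")
  ggplot2::ggplot(d, ggplot2::aes(x = 1, y = .data$query_id, fill = .data$found)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#7fbf7b", `FALSE` = "#af8dc3"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
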