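#' Heatmap of a presence/absence matrix
#'
#' @param object A `"pt_presence"` tibble from [build_presence_matrix()].
#' @param ... Unused.
#' @return A ggplot object (species on the y axis, enzymes on the x axis,
#'   filled by presence).
#' @method autoplot pt_presence
#' @export
autoplot.pt_presence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$enzyme, y = .data$species,
                                       fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "white"),
                               name = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Pathway-call overview
#'
#' @param object A `"pt_pathway_calls"` tibble from [call_pathways()].
#' @param ... Unused.
#' @return A ggplot tile plot of the boolean call columns per species.
#' @method autoplot pt_pathway_calls
#' @export
autoplot.pt_pathway_calls <- function(object, ...) {
  long <- object |>
    select("species", "fdh_present", "codh_acs_complete", "gcs_complete",
           "wl_called", "rgly_called") |>
    tidyr::pivot_longer(-"species", names_to = "call", values_to = "value")
  long$call <- factor(long$call, levels = c("fdh_present", "codh_acs_complete",
                                            "gcs_complete", "wl_called",
                                            "rgly_called"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$call, y = .data$species,
                                     fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue4", `FALSE` = "white"),
                               name = "called") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Event counts of an ancestral scenario
#'
#' @param object A `"pt_scenario"` from [build_scenario()].
#' @param ... Unused.
#' @return A ggplot bar chart of gain/loss/transfer counts per trait.
#' @method autoplot pt_scenario
#' @export
autoplot.pt_scenario <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$trait_id, fill = .data$event)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_manual(values = c(gain = "forestgreen", loss = "firebrick",
                                          hgt_gain = "orchid4"), name = "event") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "events")
}
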