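#' Plot methods
#'
#' ggplot2 views of the pipeline's result objects: matches per cascade
#' step, per-region environment sizes, cuisine frequencies, and the
#' postcode density map.
#'
#' @name plots
NULL

#' @rdname plots
#' @param object a `cascade_linkage` object.
#' @param ... unused.
#' @method autoplot cascade_linkage
#' @export
autoplot.cascade_linkage <- function(object, ...) {
  lev <- c(as.character(1:15), "similarity_pass")
  df <- object$matches |>
    mutate(step = factor(.data$step, levels = lev)) |>
    count(.data$step, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "cascade step", y = "matched pairs",
      title = "Matches by cascade step"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot region_summary
#' @export
autoplot.region_summary <- function(object, ...) {
  df <- object |>
    as_tibble() |>
    tidyr::pivot_longer(
      c("n_local", "n_online", "n_hybrid"),
      names_to = "scope", values_to = "n", names_prefix = "n_"
    ) |>
    mutate(
      scope = factor(.data$scope, levels = c("local", "online", "hybrid")),
      region = factor(.data$region, levels = object$region)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n, fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "outlets",
      title = "Local, online, and hybrid food environments by region"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param freqs a [cuisine_frequencies()] tibble.
#' @param top_n how many descriptors to show.
#' @export
plot_cuisine_frequencies <- function(freqs, top_n = 20) {
  df <- head(freqs, top_n) |>
    mutate(descriptor = factor(.data$descriptor, levels = rev(.data$descriptor)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$descriptor, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "outlets", title = "Cuisine descriptor frequency") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param views an `environment_views` tibble.
#' @param geography the geography lookup.
#' @export
plot_density_map <- function(views, geography) {
  pts <- geography |>
    group_by(.data$postcode) |>
    summarise(lat = mean(.data$latitude), lon = mean(.data$longitude), .groups = "drop")
  df <- density_by_postcode(views) |> inner_join(pts, by = "postcode")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, colour = .data$density)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_colour_gradient(low = "mistyrose", high = "darkred") +
    ggplot2::labs(
      x = "longitude", y = "latitude",
      title = "Relative outlet density by postcode"
    ) +
    ggplot2::theme_minimal()
}
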