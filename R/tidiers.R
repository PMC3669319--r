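# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col labs theme_minimal scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' Tidy a balanced-growth solution into its flux table
#'
#' @param x A `balanced_growth_solution`.
#' @param ... Unused.
#' @return Tibble with one row per flux (`flux`, `type`, `species`,
#'   `reaction`, `value`, `lb`, `ub`).
#' @method tidy balanced_growth_solution
#' @export
tidy.balanced_growth_solution <- function(x, ...) {
  x$fluxes
}

#' One-row summary of a balanced-growth solution
#'
#' @param x A `balanced_growth_solution`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `mu`, `objective_value`,
#'   `n_binding`, and the biomass fractions as `f_<species>` columns.
#' @method glance balanced_growth_solution
#' @export
glance.balanced_growth_solution <- function(x, ...) {
  out <- tibble(status = x$status, mu = x$mu,
                objective_value = x$objective_value,
                n_binding = if (is.null(x$binding)) NA_integer_ else nrow(x$binding))
  for (sp in names(x$f)) out[[paste0("f_", sp)]] <- unname(x$f[sp])
  out
}

#' Tidy a fraction scan
#'
#' @param x A `fraction_scan`.
#' @param ... Unused.
#' @return The scan grid tibble.
#' @method tidy fraction_scan
#' @export
tidy.fraction_scan <- function(x, ...) x$grid

#' One-row summary of a fraction scan
#'
#' @param x A `fraction_scan`.
#' @param ... Unused.
#' @return One-row tibble with `mu_max`, the optimal fractions, grid size
#'   and feasibility counts.
#' @method glance fraction_scan
#' @export
glance.fraction_scan <- function(x, ...) {
  out <- tibble(mu_max = x$mu_max,
                n_grid = nrow(x$grid),
                n_feasible = sum(!is.na(x$grid$mu)),
                resolution = x$resolution)
  for (sp in names(x$argmax %||% numeric(0))) {
    out[[paste0("argmax_f_", sp)]] <- unname(x$argmax[sp])
  }
  out
}

#' Tidy a phase plane
#'
#' @param x A `phase_plane`.
#' @param ... Unused.
#' @return Long-format tibble, one row per grid cell.
#' @method tidy phase_plane
#' @export
tidy.phase_plane <- function(x, ...) x$grid

#' Tidy a cross-feeding screen
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return Tibble with one row per candidate metabolite.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$table

#' Plot the growth-rate curve of a fraction scan
#'
#' For two species, the optimal community growth rate against the fraction
#' of the first species. Infeasible compositions are drawn either as gaps
#' (default) or as zeros.
#'
#' @param object A `fraction_scan`.
#' @param infeasible_as `"gap"` or `"zero"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fraction_scan
#' @export
autoplot.fraction_scan <- function(object, infeasible_as = c("gap", "zero"), ...) {
  infeasible_as <- match.arg(infeasible_as)
  if (length(object$species_ids) != 2) {
    abort("autoplot supports two-species scans; use tidy() for higher dimensions")
  }
  fcol <- paste0("f_", object$species_ids[1])
  g <- object$grid
  if (infeasible_as == "zero") g$mu[is.na(g$mu)] <- 0
  ggplot(g, aes(x = .data[[fcol]], y = .data$mu)) +
    geom_line(na.rm = (infeasible_as == "gap")) +
    labs(x = sprintf("biomass fraction of %s", object$species_ids[1]),
         y = expression(paste("maximal community growth rate ", mu, " (", h^-1, ")"))) +
    theme_minimal()
}

#' Plot a phase plane as a growth-rate heat map
#'
#' @param object A `phase_plane`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_plane
#' @export
autoplot.phase_plane <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$bound1, y = .data$bound2,
                          fill = .data$mu_max)) +
    geom_tile() +
    scale_fill_viridis_c(name = expression(mu[max])) +
    labs(x = sprintf("upper bound of %s", object$bound1_id),
         y = sprintf("upper bound of %s", object$bound2_id)) +
    theme_minimal()
}

#' Plot a cross-feeding screen as percent changes
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  tb <- object$table[!is.na(object$table$percent_change), ]
  ggplot(tb, aes(x = stats::reorder(.data$metabolite, .data$percent_change),
                 y = .data$percent_change)) +
    geom_col() +
    labs(x = "cross-fed metabolite",
         y = sprintf("%% change in minimal %s uptake vs %s",
                     object$substrate, object$reference)) +
    theme_minimal()
}
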