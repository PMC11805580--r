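# Tidy interfaces: broom-style tidy()/glance() and ggplot2 autoplot().

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cord trajectory into a long tibble
#'
#' @param x A `cord_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per (snapshot, grid point): `t_h`, `r`,
#'   `z`, `C1`, `C2`, `C3` plus the matching vessel concentration `Cv` for
#'   the point's axial node.
#' @export
tidy.cord_trajectory <- function(x, ...) {
  rows <- lapply(x$snapshots, function(s) {
    grid <- expand.grid(ri = seq_along(s$r), zi = seq_along(s$z))
    tibble::tibble(
      t_h = s$t / SEC_PER_HOUR,
      r = s$r[grid$ri], z = s$z[grid$zi],
      C1 = s$C1[cbind(grid$ri, grid$zi)],
      C2 = s$C2[cbind(grid$ri, grid$zi)],
      C3 = s$C3[cbind(grid$ri, grid$zi)],
      Cv = s$Cv[grid$zi])
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a cord trajectory
#'
#' @param x A `cord_trajectory`.
#' @param ... Unused.
#' @return A tibble with run descriptors and solver statistics.
#' @export
glance.cord_trajectory <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  tibble::tibble(
    E = x$params$protocol$E,
    lambda_inl = x$params$blood$lambda_inl,
    pk = x$params$pk$kind,
    n_r = length(last$r), n_z = length(last$z),
    dt = x$params$numerics$dt,
    t_end_h = max(x$times) / SEC_PER_HOUR,
    n_snapshots = length(x$snapshots),
    mean_outer_iterations = x$stats$mean_outer_iterations,
    max_C1 = max(last$C1), max_C2 = max(last$C2), max_C3 = max(last$C3))
}

#' Plot concentration fields of a trajectory
#'
#' Raster panels of a field (or ratio) over the (z, r) domain, faceted by
#' report time.
#'
#' @param object A `cord_trajectory`.
#' @param field Field name (`"C1"`, `"C2"`, `"C3"`, `"C2/C1"`, `"C3/C1"`,
#'   `"C3/C2"`).
#' @param times_h Times to facet (default: up to six snapshot times).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cord_trajectory <- function(object, field = "C2/C1",
                                     times_h = NULL, ...) {
  all_t <- object$times / SEC_PER_HOUR
  times_h <- times_h %||% all_t[unique(round(seq(2, length(all_t),
                                                 length.out = min(6, length(all_t) - 1))))]
  rows <- lapply(times_h, function(th) {
    s <- snapshot_at(object, th)
    F <- snapshot_field(s, field)
    grid <- expand.grid(ri = seq_along(s$r), zi = seq_along(s$z))
    tibble::tibble(t_h = s$t / SEC_PER_HOUR,
                   r_um = s$r[grid$ri] * 1e6, z_um = s$z[grid$zi] * 1e6,
                   value = F[cbind(grid$ri, grid$zi)])
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$r_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~t_h, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::labs(x = "z (um)", y = "r (um)",
                  title = sprintf("%s over the tumor cord", field))
}

#' Plot an RTM classification map
#'
#' Tile map of the mechanism statements over the (z, r) domain, faceted by
#' reporting interval; points where the extracellular concentration
#' decreased over the interval are overlaid with markers.
#'
#' @param map A tibble from [rtm_map()].
#' @return A ggplot object.
#' @export
plot_rtm_map <- function(map) {
  df <- dplyr::mutate(map,
                      interval = sprintf("%.1f-%.1f h", .data$t_start_h,
                                         .data$t_end_h),
                      label = ifelse(.data$kind == "RELATION",
                                     .data$relation, .data$kind))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z * 1e6, y = .data$r * 1e6,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$c1_dir == "D"),
                        shape = 20, size = 0.3, colour = "black") +
    ggplot2::facet_wrap(~interval) +
    ggplot2::labs(x = "z (um)", y = "r (um)", fill = "statement")
}

#' Plot the transvascular ratio series
#'
#' Semilog-y time series of `Cv / C1(wall)` at the inlet with the
#' extravasation / reverse-diffusion threshold at 1.
#'
#' @param series A tibble from [transvascular_ratio_series()].
#' @return A ggplot object.
#' @export
plot_transvascular_ratio <- function(series) {
  ggplot2::ggplot(dplyr::filter(series, is.finite(.data$ratio)),
                  ggplot2::aes(x = .data$t_h, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, colour = "darkgreen") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t (h)", y = "Cv / C1 at wall, z = 0")
}

#' @importFrom rlang .data
NULL
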