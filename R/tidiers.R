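#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for analysis results
#'
#' `tidy()` returns the underlying observations as a plain tibble;
#' `glance()` returns a one-row summary of each result object.
#'
#' @param x An analysis result (`glyco_area`, `glyco_ldp`, `glyco_rdf`,
#'   `glyco_gauche`, `glyco_tilt`, `glyco_acf`, `glyco_tau`,
#'   `glyco_protrusion`).
#' @param ... Unused.
#' @return A tibble.
#' @name glycolam-tidiers
NULL

strip_tbl <- function(x) {
  out <- tibble::as_tibble(x)
  attributes(out)[setdiff(names(attributes(out)),
                          c("names", "row.names", "class"))] <- NULL
  out
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_area <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_area <- function(x, ...) {
  tibble::tibble(mean_area_A2 = attr(x, "mean"), se_A2 = attr(x, "se"),
                 blocks = attr(x, "blocks"), n_frames = nrow(x))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_ldp <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_ldp <- function(x, ...) {
  tibble::tibble(bin_width_A = attr(x, "bin_width"), lz_A = attr(x, "lz"),
                 blocks = attr(x, "blocks"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_rdf <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_rdf <- function(x, ...) {
  tibble::tibble(first_peak_A = rdf_first_peak(x, r_min = 2),
                 bin_width_A = attr(x, "bin_width"),
                 norm = attr(x, "norm"),
                 mean_pairs = attr(x, "mean_pairs"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_gauche <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_gauche <- function(x, ...) {
  ov <- x[x$label == "chain" & x$leaflet == 0L, ]
  tibble::tibble(p_gauche = ov$p_gauche, se = ov$se, n = ov$n,
                 chain = attr(x, "chain"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_tilt <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_tilt <- function(x, ...) {
  pk <- tilt_peaks(x)
  top <- pk[!duplicated(pk$leaflet), ]
  tibble::tibble(n_peaks = nrow(pk),
                 main_peak_deg = if (nrow(top)) top$theta_deg[1] else
                   NA_real_,
                 bin_width_deg = attr(x, "bin_width"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_acf <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_acf <- function(x, ...) {
  tibble::tibble(label = attr(x, "label"), c2_final = x$c2[nrow(x)],
                 max_lag_ps = max(x$lag_ps), dt_ps = attr(x, "dt_ps"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_tau <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_tau <- function(x, ...) {
  tibble::tibble(n_modes = nrow(x), tau_min_ns = min(x$tau_ns),
                 tau_max_ns = max(x$tau_ns),
                 n_flagged = sum(x$flag != "ok"))
}

#' @rdname glycolam-tidiers
#' @export
tidy.glyco_protrusion <- function(x, ...) strip_tbl(x)

#' @rdname glycolam-tidiers
#' @export
glance.glyco_protrusion <- function(x, ...) {
  tibble::tibble(mean_fraction = mean(x$fraction), leaflets = nrow(x))
}

#' Plot methods for analysis results
#'
#' Every result type has an `autoplot()` method returning a ggplot:
#' area-per-lipid time series, component density profiles, g(r) with block
#' error ribbons, per-dihedral gauche fractions by leaflet, tilt
#' histograms, C2(t) decays, and correlation-time profiles.
#'
#' @param object An analysis result object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name glycolam-autoplot
NULL

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_area <- function(object, ...) {
  ggplot2::ggplot(strip_tbl(object),
                  ggplot2::aes(x = .data$time_ps, y = .data$area_A2)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (ps)", y = expression(A ~ (ring(A)^2)),
                  title = "Area per lipid")
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_ldp <- function(object, ...) {
  d <- strip_tbl(object)
  ggplot2::ggplot(d[d$block == 0L, ],
                  ggplot2::aes(x = .data$z, y = .data$density,
                               color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)", y = "mass density (amu/Å³)",
                  title = "Local density profile (block average)")
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_rdf <- function(object, ...) {
  d <- strip_tbl(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = "Radial distribution function")
  if (!all(is.na(d$g_block_sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$g - .data$g_block_sd,
                   ymax = .data$g + .data$g_block_sd),
      alpha = 0.25)
  }
  p
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_gauche <- function(object, ...) {
  d <- strip_tbl(object)
  d <- d[d$label != "chain", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$p_gauche,
                                  group = factor(.data$leaflet),
                                  shape = factor(.data$leaflet))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "dihedral", y = "P(gauche)", shape = "leaflet",
                  title = "Gauche population along the chain") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_tilt <- function(object, ...) {
  ggplot2::ggplot(strip_tbl(object),
                  ggplot2::aes(x = .data$bin_center_deg, y = .data$count,
                               color = factor(.data$leaflet))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta ~ (degree)), y = "count",
                  color = "leaflet", title = "Chain tilt distribution")
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_acf <- function(object, ...) {
  ggplot2::ggplot(strip_tbl(object),
                  ggplot2::aes(x = .data$lag_ps, y = .data$c2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ps)", y = expression(C[2](t)),
                  title = attr(object, "label"))
}

#' @rdname glycolam-autoplot
#' @export
autoplot.glyco_tau <- function(object, ...) {
  d <- strip_tbl(object)
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$tau_ns)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tau_ns - .data$sigma_ns,
                                        ymax = .data$tau_ns + .data$sigma_ns),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(tau ~ (ns)),
                  title = "Correlation times") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
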