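#' Plot titration curves with fitted isotherms
#'
#' @param series Titration series from [csp_series()].
#' @param fit Optional `binding_fit`; fitted curves are overlaid for residues
#'   with converged fits.
#' @param residues Optional subset of residues to show.
#' @return A ggplot object (CSP vs ligand concentration, faceted by residue).
#' @export
plot_titration <- function(series, fit = NULL, residues = NULL) {
  df <- series
  if (!is.null(residues)) df <- df[df$residue %in% residues, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$l0, y = .data$dd)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$residue)) +
    ggplot2::labs(x = expression("[L]"[0] ~ "(µM)"),
                  y = expression(Delta * delta ~ "(ppm)"))
  if (!is.null(fit)) {
    ok <- fit$residues[fit$residues$status == "ok", ]
    if (!is.null(residues)) ok <- ok[ok$residue %in% residues, ]
    curves <- purrr::pmap_dfr(
      list(ok$residue, ok$kd, ok$dd_bound),
      function(res, kd, ddb) {
        l <- seq(0, max(df$l0), length.out = 80)
        tibble(residue = res, l0 = l,
               dd = binding_curve(l, max(df$p0), kd, ddb, fit$model))
      })
    p <- p + ggplot2::geom_line(data = curves, colour = "firebrick")
  }
  p
}

#' Per-residue relaxation panels
#'
#' @param records Relaxation records (see [extract_relaxation()]).
#' @return A ggplot with R1, R2 and NOE vs residue number.
#' @export
plot_relaxation <- function(records) {
  long <- records |>
    dplyr::select("residue", "domain", "r1", "r2", "noe") |>
    tidyr::pivot_longer(c("r1", "r2", "noe"), names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$value,
                                     colour = .data$domain)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "residue", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.saxs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$i)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$i - .data$sigma,
                                          ymax = .data$i + .data$sigma),
                             size = 0.1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  title = attr(object, "label"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.kratky_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q_rg,
                                            y = .data$kratky)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = expression(q * R[g]),
                  y = expression((q * R[g])^2 ~ I(q) / I(0)))
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.pofr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(r ~ (ring(A))), y = "P(r)")
}

#' Weighted Rg histogram of selected ensembles
#'
#' @param dist Output of [rg_distribution()].
#' @return A ggplot bar chart.
#' @export
plot_rg_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$rg_mid, y = .data$weight)) +
    ggplot2::geom_col(width = diff(dist$rg_mid[1:2]) * 0.9) +
    ggplot2::labs(x = expression(R[g] ~ (ring(A))), y = "weight")
}
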