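# ggplot2 views of run results. Plots are diagnostics, not analysis: every
# number shown is recomputable from the evaluation log.

#' Plot an EGO run in objective space
#'
#' Evaluated designs by phase (initial design vs iterations), with the final
#' approximation set highlighted and the reference point marked. With three
#' objectives, the pairwise projections are facetted.
#'
#' @param object An `ego_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ego_run <- function(object, ...) {
  X <- object$archive$X
  Y <- object$problem$objectives(X)
  objnames <- colnames(Y)
  n_init <- sum(object$log$iteration == 0) / length(object$problem$constraints)
  phase <- ifelse(seq_len(nrow(X)) <= n_init, "initial design", "iteration")
  pts <- tibble::as_tibble(as.data.frame(Y))
  pts$phase <- phase
  appr <- object$approx
  if (length(objnames) == 2) {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[objnames[1]]],
                                           y = .data[[objnames[2]]])) +
      ggplot2::geom_point(ggplot2::aes(shape = .data$phase), colour = "grey40") +
      ggplot2::annotate("point", x = object$problem$ref_point[1],
                        y = object$problem$ref_point[2], shape = 4, size = 3)
    if (nrow(appr) > 0)
      p <- p + ggplot2::geom_point(data = appr, colour = "#D55E00", size = 2.5) +
        ggplot2::geom_step(data = appr[order(appr[[objnames[1]]]), ],
                           colour = "#D55E00", direction = "hv")
    return(p + ggplot2::labs(shape = NULL,
                             title = "Evaluated designs and approximation set"))
  }
  pairs <- utils::combn(objnames, 2, simplify = FALSE)
  long <- dplyr::bind_rows(lapply(pairs, function(pr) {
    tibble::tibble(panel = paste(pr[2], "vs", pr[1]),
                   x = pts[[pr[1]]], y = pts[[pr[2]]], phase = pts$phase,
                   in_set = FALSE)
  }))
  if (nrow(appr) > 0) {
    long <- dplyr::bind_rows(long, dplyr::bind_rows(lapply(pairs, function(pr) {
      tibble::tibble(panel = paste(pr[2], "vs", pr[1]),
                     x = appr[[pr[1]]], y = appr[[pr[2]]],
                     phase = "approximation set", in_set = TRUE)
    })))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$in_set)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_colour_manual(values = c("grey40", "#D55E00"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise objective projections")
}

#' Plot a one-dimensional Gaussian process surrogate
#'
#' Mean and central 95% band over a grid, with the training observations and
#' their Monte Carlo error bars.
#'
#' @param object A `gp_model` with one input dimension.
#' @param n_grid Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_model <- function(object, n_grid = 200, ...) {
  if (ncol(object$X) != 1)
    stop("autoplot.gp_model draws one-dimensional models; use plot_gp_slice()")
  sp <- object$space
  grid <- matrix(seq(sp$lower, sp$upper, length.out = n_grid),
                 dimnames = list(NULL, sp$names))
  pr <- predict(object, grid)
  band <- tibble::tibble(x = grid[, 1], mean = pr$mean,
                         lo = pr$mean - 1.96 * pr$sd,
                         hi = pr$mean + 1.96 * pr$sd)
  obs <- tibble::tibble(x = object$X[, 1], y = object$y,
                        se = sqrt(object$noise_var))
  ggplot2::ggplot(band, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_pointrange(data = obs,
                             ggplot2::aes(x = .data$x, y = .data$y,
                                          ymin = .data$y - 1.96 * .data$se,
                                          ymax = .data$y + 1.96 * .data$se)) +
    ggplot2::labs(x = sp$names, y = "operating characteristic")
}

#' Plot a one-dimensional slice of a fitted surrogate
#'
#' Predictive mean and 95% band along one design dimension, the others held
#' fixed — a quick sanity check that the surrogate behaves as a power
#' surface should (e.g. monotone in sample size).
#'
#' @param model A `gp_model`.
#' @param dim Name of the dimension to vary.
#' @param at Named vector fixing the remaining dimensions (default: box
#'   midpoint).
#' @param n_grid Grid resolution.
#' @return A ggplot object.
#' @export
plot_gp_slice <- function(model, dim, at = NULL, n_grid = 100) {
  sp <- model$space
  stopifnot(dim %in% sp$names)
  mid <- stats::setNames((sp$lower + sp$upper) / 2, sp$names)
  if (!is.null(at)) mid[names(at)] <- at
  d <- match(dim, sp$names)
  grid <- matrix(rep(mid, each = n_grid), n_grid,
                 dimnames = list(NULL, sp$names))
  grid[, d] <- seq(sp$lower[d], sp$upper[d], length.out = n_grid)
  pr <- predict(model, grid)
  df <- tibble::tibble(x = grid[, d], mean = pr$mean,
                       lo = pr$mean - 1.96 * pr$sd,
                       hi = pr$mean + 1.96 * pr$sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = dim, y = "predicted operating characteristic")
}

#' Plot surrogate calibration diagnostics
#'
#' Standardised prediction errors by iteration with the +/- 3 reference
#' lines that flag a mis-specified surrogate.
#'
#' @param run An `ego_run`.
#' @return A ggplot object.
#' @export
plot_diagnostics <- function(run) {
  d <- ego_diagnostics(run)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$z,
                                  colour = .data$constraint)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 2) +
    ggplot2::labs(y = "standardised prediction error")
}
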