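#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ancestry space
#'
#' Scatter of two reference principal components, coloured by population.
#'
#' @param object An [ancestry_space][pca_reference()].
#' @param dims Which two PCs to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ancestry_space <- function(object, dims = c(1, 2), ...) {
  co <- tidy(object)
  xs <- paste0("PC", dims[1]); ys <- paste0("PC", dims[2])
  ggplot2::ggplot(co, ggplot2::aes(.data[[xs]], .data[[ys]],
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Reference ancestry space") +
    ggplot2::theme_minimal()
}

#' Plot placements over the reference space
#'
#' Reference individuals in grey-toned population colours, placed study
#' samples overlaid and shaded by their Procrustes similarity t.
#'
#' @param placements A placement tibble from [place_all()].
#' @param space The [ancestry_space][pca_reference()] used.
#' @param dims Which two PCs to show.
#' @return A ggplot.
#' @export
plot_placements <- function(placements, space, dims = c(1, 2)) {
  ref <- tidy(space)
  xs <- paste0("PC", dims[1]); ys <- paste0("PC", dims[2])
  ggplot2::ggplot() +
    ggplot2::geom_point(data = ref,
                        ggplot2::aes(.data[[xs]], .data[[ys]],
                                     colour = .data$population),
                        alpha = 0.35, size = 1) +
    ggplot2::geom_point(data = placements,
                        ggplot2::aes(.data[[xs]], .data[[ys]],
                                     alpha = .data$t),
                        shape = 17, size = 2) +
    ggplot2::labs(title = "Study placements in the reference ancestry space",
                  alpha = "t") +
    ggplot2::theme_minimal()
}
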