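#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a projection table
#'
#' @param x A `projection_table` from [project_fixations()].
#' @param ... Unused.
#' @return One-row tibble: fixation count, counts per status, mapped
#'   fraction, and mean beam length among mapped fixations.
#' @method glance projection_table
#' @export
glance.projection_table <- function(x, ...) {
  tibble::tibble(
    n_fixations = nrow(x),
    n_mapped = sum(x$status == "mapped"),
    n_no_intersection = sum(x$status == "no_intersection"),
    n_frame_not_registered = sum(x$status == "frame_not_registered"),
    mapped_fraction = mean(x$status == "mapped"),
    mean_ray_t = mean(x$ray_t, na.rm = TRUE)
  )
}

#' @rdname evaluate_dot_hits
#' @param x A `dot_evaluation`.
#' @param ... Unused.
#' @method tidy dot_evaluation
#' @export
tidy.dot_evaluation <- function(x, ...) x$fixations

#' @rdname evaluate_dot_hits
#' @method glance dot_evaluation
#' @export
glance.dot_evaluation <- function(x, ...) x$summary

#' Plot mapped fixations and beam origins in plan view
#'
#' Intersection points and camera (beam-origin) positions projected onto
#' two model axes; a quick structural check of a mapping run.
#'
#' @param object A `projection_table`.
#' @param axes Two of `"x"`, `"y"`, `"z"` to span the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot projection_table
#' @export
autoplot.projection_table <- function(object, axes = c("x", "z"), ...) {
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  pts <- tibble::tibble(
    a = object[[paste0("intersection_", axes[1])]],
    b = object[[paste0("intersection_", axes[2])]],
    status = object$status, kind = "intersection")
  org <- tibble::tibble(
    a = object[[paste0("fixation_start_", axes[1])]],
    b = object[[paste0("fixation_start_", axes[2])]],
    status = object$status, kind = "beam origin")
  dat <- dplyr::filter(dplyr::bind_rows(pts, org),
                       !is.na(.data$a), !is.na(.data$b))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$a, y = .data$b,
                                    colour = .data$status,
                                    shape = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste("model", axes[1]), y = paste("model", axes[2]),
                  colour = "status", shape = NULL)
}

#' Plot camera centres of a scene in plan view
#'
#' @param object An `sfm_scene`.
#' @param ... Unused.
#' @return A ggplot object showing camera x/y positions coloured by height.
#' @method autoplot sfm_scene
#' @export
autoplot.sfm_scene <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cx, y = .data$cy,
                                       colour = .data$cz)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "model x", y = "model y", colour = "height (z)")
}

#' @keywords internal
#' @importFrom rlang %||% .data
"_PACKAGE"
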