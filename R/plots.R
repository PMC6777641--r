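# Faceted plots: one facet per variable, samples on the x axis, with
# optional statistical annotation (compact letters or asterisks vs control)
# anchored above each sample's drawn elements.

PLOT_KINDS <- c("dotplot", "dotplot2", "barplot", "boxplot")
SAVE_FORMATS <- c("pdf", "svg", "eps", "png", "jpeg")

# Okabe-Ito colorblind-safe qualitative palette
DEFAULT_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                     "#0072B2", "#D55E00", "#CC79A7", "#999999")

#' Plot specification
#'
#' Bundles the knobs shared by the plotting functions. The facet label
#' position is derived from the kind: \code{dotplot} labels facets at the
#' bottom, all other kinds at the top.
#'
#' @param kind one of \code{"dotplot"}, \code{"dotplot2"}, \code{"barplot"},
#'   \code{"boxplot"}.
#' @param title optional plot title (centered when given).
#' @param palette character vector of colors; cycled when shorter than the
#'   number of samples. Defaults to a colorblind-safe qualitative set.
#' @param annot \code{"none"}, \code{"asterisks"} or \code{"letters"}.
#' @param method p-value adjustment for the annotation statistics.
#' @param alpha significance threshold for the annotation, in (0, 1).
#' @param jitter_seed seed for the horizontal point jitter, so exported
#'   figures are reproducible.
#' @return List of class \code{am_plot_spec}.
#' @export
plot_spec <- function(kind = "dotplot", title = NULL, palette = NULL,
                      annot = c("none", "asterisks", "letters"),
                      method = "none", alpha = 0.05, jitter_seed = 1L) {
  kind <- match.arg(kind, PLOT_KINDS)
  annot <- match.arg(annot)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(kind = kind, title = title,
                 palette = palette %||% DEFAULT_PALETTE,
                 annot = annot, method = method, alpha = alpha,
                 jitter_seed = jitter_seed,
                 facet_label_position = if (kind == "dotplot") "bottom" else "top"),
            class = "am_plot_spec")
}

# Long-format biological-replicate values with ordered factors.
figure_data <- function(ds) {
  per_rep <- replicate_values(ds)
  vars <- setdiff(names(per_rep), c(ID_COLUMNS, "trt"))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(Samples = per_rep$Samples, Replicates = per_rep$Replicates,
               variable = v, value = per_rep[[v]], stringsAsFactors = FALSE)
  }))
  long$Samples <- factor(long$Samples, levels = sample_order(ds))
  long$variable <- factor(long$variable, levels = vars)
  long
}

boxplot_stats <- function(values) {
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo <- min(values[values >= q[1L] - 1.5 * iqr])
  hi <- max(values[values <= q[3L] + 1.5 * iqr])
  list(lower = q[1L], middle = q[2L], upper = q[3L],
       whisker_low = lo, whisker_high = hi,
       outliers = values[values < lo | values > hi])
}

#' Build a figure description
#'
#' Assembles everything needed to draw (and test) one of the four plot
#' kinds: the long per-replicate data, per-facet geometry (bar heights and
#' SE whiskers, or box statistics with 1.5 IQR whiskers and outliers), the
#' statistical annotation marks with their anchor coordinates (5\% of the
#' facet y-range above each sample's highest drawn element), and the
#' ggplot object itself.
#'
#' @param ds an \code{am_dataset}.
#' @param spec an \code{am_plot_spec} from \code{\link{plot_spec}}.
#' @return List of class \code{am_figure} with elements \code{data},
#'   \code{spec}, \code{summary} (per-sample means/SE, bar kinds),
#'   \code{box} (per sample x variable box statistics, boxplot kind),
#'   \code{annotations} (data frame Samples/variable/mark/anchor or NULL)
#'   and \code{plot} (the ggplot). Printing an \code{am_figure} draws it.
#' @export
build_figure <- function(ds, spec = plot_spec()) {
  stopifnot(inherits(ds, "am_dataset"), inherits(spec, "am_plot_spec"))
  long <- figure_data(ds)
  samples <- sample_order(ds)
  summ <- am_summary(ds)

  if (spec$annot != "none" && length(samples) < 2L) {
    stop("statistical annotation needs at least 2 samples", call. = FALSE)
  }

  vars <- levels(long$variable)
  box <- NULL
  if (spec$kind == "boxplot") {
    box <- do.call(rbind, lapply(vars, function(v) {
      do.call(rbind, lapply(samples, function(s) {
        vals <- long$value[long$variable == v & long$Samples == s]
        st <- boxplot_stats(vals)
        data.frame(Samples = s, variable = v, lower = st$lower,
                   middle = st$middle, upper = st$upper,
                   whisker_low = st$whisker_low, whisker_high = st$whisker_high,
                   n_outliers = length(st$outliers), stringsAsFactors = FALSE)
      }))
    }))
  }

  # top of the drawn elements, per sample x facet
  drawn_top <- function(s, v) {
    vals <- long$value[long$variable == v & long$Samples == s]
    if (spec$kind == "barplot") {
      m <- summ$per_sample[[v]][summ$per_sample$Samples == s]
      se <- summ$per_sample[[paste0(v, "_se")]][summ$per_sample$Samples == s]
      m + if (is.na(se)) 0 else se
    } else {
      max(vals)
    }
  }

  annotations <- NULL
  if (spec$annot != "none") {
    cmp <- am_stat(ds, method = spec$method)
    annotations <- build_annotations(cmp, spec$annot, spec$alpha)
    tops <- mapply(drawn_top, annotations$Samples, annotations$variable)
    facet_range <- vapply(annotations$variable, function(v) {
      tops_v <- vapply(samples, drawn_top, numeric(1), v = v)
      lo <- if (spec$kind == "barplot") 0 else
        min(long$value[long$variable == v])
      r <- max(tops_v) - lo
      if (r > 0) r else 1
    }, numeric(1))
    annotations$anchor <- tops + 0.05 * facet_range
    annotations$Samples <- factor(annotations$Samples, levels = samples)
    annotations$variable <- factor(annotations$variable, levels = vars)
  }

  pal <- rep(spec$palette, length.out = length(samples))
  strip_pos <- spec$facet_label_position
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$Samples, y = .data$value))
  gg <- switch(spec$kind,
    dotplot = ,
    dotplot2 = gg + ggplot2::geom_point(
      ggplot2::aes(colour = .data$Samples), size = 2,
      position = ggplot2::position_jitter(width = 0.1, height = 0,
                                          seed = spec$jitter_seed)),
    barplot = {
      bar <- summ$per_sample
      bar_long <- do.call(rbind, lapply(vars, function(v) {
        data.frame(Samples = bar$Samples, variable = v, mean = bar[[v]],
                   se = bar[[paste0(v, "_se")]], stringsAsFactors = FALSE)
      }))
      bar_long$Samples <- factor(bar_long$Samples, levels = samples)
      bar_long$variable <- factor(bar_long$variable, levels = vars)
      ggplot2::ggplot(bar_long, ggplot2::aes(x = .data$Samples)) +
        ggplot2::geom_col(ggplot2::aes(y = .data$mean, fill = .data$Samples)) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - ifelse(is.na(.data$se), 0, .data$se),
                                            ymax = .data$mean + ifelse(is.na(.data$se), 0, .data$se)),
                               width = 0.25)
    },
    boxplot = gg + ggplot2::geom_boxplot(
      ggplot2::aes(colour = .data$Samples), outlier.shape = 16)
  )
  gg <- gg +
    ggplot2::facet_wrap(~variable, nrow = 1, strip.position = strip_pos) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = NULL, y = "Colonization (%)", title = spec$title) +
    ggplot2::theme_bw() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none",
                   strip.placement = "outside")
  if (!is.null(annotations)) {
    gg <- gg + ggplot2::geom_text(
      data = annotations,
      ggplot2::aes(x = .data$Samples, y = .data$anchor, label = .data$mark),
      colour = "black", inherit.aes = FALSE)
  }

  structure(list(data = long, spec = spec, summary = summ$per_sample,
                 box = box, annotations = annotations, plot = gg),
            class = "am_figure")
}

#' @export
print.am_figure <- function(x, ...) {
  print(x$plot, ...)
  invisible(x)
}

#' Dotplot of colonization data
#'
#' Strip chart with one facet per variable (labels at the bottom), one
#' jittered point per biological replicate. \code{am_dotplot2} puts the
#' facet labels on top instead.
#'
#' @param ds an \code{am_dataset}.
#' @param main optional centered title.
#' @param cbPalette optional color palette (cycled over samples).
#' @param annot \code{"none"}, \code{"asterisks"} or \code{"letters"}.
#' @param method p-value adjustment method for the annotation.
#' @param alpha significance threshold for the annotation.
#' @return An \code{am_figure}; print it to draw, or pass to
#'   \code{\link{am_save}}.
#' @export
am_dotplot <- function(ds, main = NULL, cbPalette = NULL, annot = "none",
                       method = "none", alpha = 0.05) {
  build_figure(ds, plot_spec("dotplot", title = main, palette = cbPalette,
                             annot = annot, method = method, alpha = alpha))
}

#' @rdname am_dotplot
#' @export
am_dotplot2 <- function(ds, main = NULL, cbPalette = NULL, annot = "none",
                        method = "none", alpha = 0.05) {
  build_figure(ds, plot_spec("dotplot2", title = main, palette = cbPalette,
                             annot = annot, method = method, alpha = alpha))
}

#' Barplot of per-sample means with SE whiskers
#'
#' Bar heights are the per-sample means and whisker half-lengths the
#' standard errors from \code{\link{am_summary}}.
#'
#' @inheritParams am_dotplot
#' @return An \code{am_figure}.
#' @export
am_barplot <- function(ds, main = NULL, cbPalette = NULL, annot = "none",
                       method = "none", alpha = 0.05) {
  build_figure(ds, plot_spec("barplot", title = main, palette = cbPalette,
                             annot = annot, method = method, alpha = alpha))
}

#' Boxplot of colonization data
#'
#' Box = interquartile range, bold line = median, whiskers = furthest data
#' point within 1.5 IQR, points beyond drawn as outliers.
#'
#' @inheritParams am_dotplot
#' @return An \code{am_figure}.
#' @export
am_boxplot <- function(ds, main = NULL, cbPalette = NULL, annot = "none",
                       method = "none", alpha = 0.05) {
  build_figure(ds, plot_spec("boxplot", title = main, palette = cbPalette,
                             annot = annot, method = method, alpha = alpha))
}

#' Save a figure to disk
#'
#' Writes the figure in the format implied by the file extension
#' (pdf, svg, eps, png or jpeg) at the requested physical size and
#' resolution.
#'
#' @param fig an \code{am_figure} or a ggplot.
#' @param path output path; extension selects the format.
#' @param width,height physical size in \code{units}.
#' @param units \code{"in"}, \code{"cm"} or \code{"mm"}.
#' @param dpi raster resolution in dots per inch.
#' @return Invisibly, the path.
#' @export
save_figure <- function(fig, path, width = 7, height = 7,
                        units = c("in", "cm", "mm"), dpi = 300) {
  units <- match.arg(units)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% SAVE_FORMATS) {
    stop(sprintf("unsupported figure format '%s'; supported: %s", ext,
                 paste(SAVE_FORMATS, collapse = ", ")), call. = FALSE)
  }
  plot <- if (inherits(fig, "am_figure")) fig$plot else fig
  device <- switch(ext, svg = grDevices::svg, eps = "eps", ext)
  ggplot2::ggsave(path, plot = plot, device = device, width = width,
                  height = height, units = units, dpi = dpi)
  invisible(path)
}

#' Save any analysis output
#'
#' One export entry point for the whole pipeline, choosing the writer from
#' the object class: summary tables become
#' \code{<basename>_per_Replicate.csv} and \code{<basename>_per_Sample.csv},
#' a comparison table becomes \code{<basename>_stat.csv}, and a figure is
#' written to the path itself (extension selects the format; sizing options
#' apply).
#'
#' @param x an \code{am_summary_tables}, \code{am_comparison},
#'   \code{am_figure} or ggplot.
#' @param path basename (tables) or full file name with extension (figures).
#' @param ... passed to \code{\link{save_figure}} for figures
#'   (\code{width}, \code{height}, \code{units}, \code{dpi}).
#' @return Invisibly, the written path(s).
#' @export
am_save <- function(x, path, ...) {
  if (inherits(x, "am_summary_tables")) {
    write_summary_tables(x, path)
  } else if (inherits(x, "am_comparison")) {
    write_stat_table(x, path)
  } else if (inherits(x, "am_figure") || inherits(x, "ggplot")) {
    save_figure(x, path, ...)
  } else {
    stop("am_save() does not know how to save objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}
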