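#' Assemble consensus diversity records for a set of libraries
#'
#' Joins the three per-library diversity summaries into one record per
#' library: the fingerprint metric on x (median intra-library Tanimoto
#' similarity — lower means more diverse), a scaffold metric on y (AUC,
#' F50, or SSE at a given top-n), the intra-set property distance (mapped
#' to colour), and the library size M (mapped to point area). Every
#' library must appear in all three inputs.
#'
#' @param scaffoldSummaries data.frame of [summarizeScaffolds()] rows, or a
#'   data.frame with columns `set_name`, `M` and the chosen y metric.
#' @param similaritySummaries data.frame of [intraSimilaritySummary()]
#'   rows (only `set_name` and `median` are used).
#' @param propertyDistances Named numeric vector of intra-set property
#'   distances (names = set names), e.g. `diag(setDistanceMatrix(...))`.
#' @param yMetric Which scaffold metric to place on y: `"auc"`, `"f50"`,
#'   or the name of an SSE column such as `"sse5"` present in
#'   `scaffoldSummaries`.
#' @return data.frame with columns `set_name`, `x_fp`, `y_metric`,
#'   `y_value`, `prop_diversity`, `size_M`, `quadrant` (NA until
#'   [classifyQuadrants()]).
#' @export
assembleCDP <- function(scaffoldSummaries, similaritySummaries,
                        propertyDistances, yMetric = "auc") {
  stopifnot(is.data.frame(scaffoldSummaries),
            is.data.frame(similaritySummaries))
  if (!yMetric %in% names(scaffoldSummaries))
    stop("y metric '", yMetric, "' not found in scaffold summaries")
  sets <- scaffoldSummaries$set_name
  miss_fp <- setdiff(sets, similaritySummaries$set_name)
  if (length(miss_fp))
    stop("missing fingerprint summary for set(s): ",
         paste(miss_fp, collapse = ", "))
  miss_pr <- setdiff(sets, names(propertyDistances))
  if (length(miss_pr))
    stop("missing property distance for set(s): ",
         paste(miss_pr, collapse = ", "))
  fp <- similaritySummaries$median[match(sets,
                                         similaritySummaries$set_name)]
  data.frame(set_name = sets, x_fp = fp, y_metric = yMetric,
             y_value = scaffoldSummaries[[yMetric]],
             prop_diversity = as.numeric(propertyDistances[sets]),
             size_M = scaffoldSummaries$M,
             quadrant = NA_character_, stringsAsFactors = FALSE)
}

#' Resolve quadrant thresholds for a consensus plot
#'
#' A threshold given as `"median"` resolves to the median (linear
#' interpolation) of that metric over the compared libraries; numeric
#' values pass through. The diversity direction of the y metric is forced
#' by its identity: for AUC a LOW value means high scaffold diversity, for
#' F50 and SSE a HIGH value does.
#'
#' @param records data.frame from [assembleCDP()].
#' @param xThreshold `"median"` or a similarity value.
#' @param yThreshold `"median"` or a metric value (the worked default for
#'   AUC in the field is 0.75).
#' @return List with `x_threshold`, `y_threshold` (numerics), `y_metric`,
#'   `y_high_is_diverse` (logical).
#' @export
resolveThresholds <- function(records, xThreshold = "median",
                              yThreshold = "median") {
  stopifnot(nrow(records) >= 1)
  if (nrow(records) == 1L)
    warning("resolving thresholds over a single library is degenerate")
  resolve <- function(th, v) {
    if (identical(th, "median")) stats::median(v) else as.numeric(th)
  }
  ym <- records$y_metric[1]
  list(x_threshold = resolve(xThreshold, records$x_fp),
       y_threshold = resolve(yThreshold, records$y_value),
       y_metric = ym,
       y_high_is_diverse = !identical(ym, "auc"))
}

#' Classify libraries into the four diversity quadrants
#'
#' Fingerprint diversity is HIGH iff the median similarity lies strictly
#' below the x threshold (lower similarity = higher diversity); scaffold
#' diversity is HIGH iff the y value beats its threshold in the direction
#' of the metric (strictly below for AUC, strictly above for F50/SSE).
#' Values exactly on a threshold classify as LOW diversity. Labels map to
#' the conventional quadrant colours: `both_high` = red, `both_low` =
#' white, `fp_only` = blue, `scaffold_only` = yellow.
#'
#' @param records data.frame from [assembleCDP()].
#' @param thresholds List from [resolveThresholds()].
#' @return `records` with the `quadrant` column filled in.
#' @export
classifyQuadrants <- function(records, thresholds) {
  fp_high <- records$x_fp < thresholds$x_threshold
  sc_high <- if (thresholds$y_high_is_diverse)
    records$y_value > thresholds$y_threshold
  else
    records$y_value < thresholds$y_threshold
  records$quadrant <- ifelse(fp_high & sc_high, "both_high",
                       ifelse(fp_high, "fp_only",
                         ifelse(sc_high, "scaffold_only", "both_low")))
  records
}

#' Colour conventionally associated with each quadrant label
#' @param quadrant Character vector of quadrant labels.
#' @return Character vector of colour names.
#' @export
quadrantColor <- function(quadrant) {
  map <- c(both_high = "red", both_low = "white", fp_only = "blue",
           scaffold_only = "yellow")
  unname(map[quadrant])
}

#' Render a Consensus Diversity Plot
#'
#' Scatter plot of the compared libraries: median fingerprint similarity
#' on x, the chosen scaffold metric on y, dashed threshold lines with
#' quadrant background tints (red/white/blue/yellow per
#' [classifyQuadrants()]), point area proportional to library size M, and
#' point fill mapped from the intra-set property distance through a
#' green-to-red continuous scale normalized between the minimum and
#' maximum distance among the compared sets (red = largest distance = most
#' property-diverse).
#'
#' @param records Classified records from [classifyQuadrants()].
#' @param thresholds List from [resolveThresholds()].
#' @param label Draw library names next to points.
#' @return A ggplot object.
#' @export
plotCDP <- function(records, thresholds, label = TRUE) {
  xt <- thresholds$x_threshold
  yt <- thresholds$y_threshold
  xr <- range(c(records$x_fp, xt))
  yr <- range(c(records$y_value, yt))
  xpad <- 0.08 * max(diff(xr), 0.05)
  ypad <- 0.08 * max(diff(yr), 0.05)
  xlim <- c(xr[1] - xpad, xr[2] + xpad)
  ylim <- c(yr[1] - ypad, yr[2] + ypad)
  up_is_diverse <- thresholds$y_high_is_diverse
  tint <- function(fp_high, sc_high) {
    lab <- if (fp_high && sc_high) "both_high" else if (fp_high) "fp_only"
      else if (sc_high) "scaffold_only" else "both_low"
    quadrantColor(lab)
  }
  quads <- expand.grid(left = c(TRUE, FALSE), bottom = c(TRUE, FALSE))
  rects <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    left <- quads$left[i]; bottom <- quads$bottom[i]
    sc_high <- if (up_is_diverse) !bottom else bottom
    data.frame(xmin = if (left) xlim[1] else xt,
               xmax = if (left) xt else xlim[2],
               ymin = if (bottom) ylim[1] else yt,
               ymax = if (bottom) yt else ylim[2],
               fill = tint(fp_high = left, sc_high = sc_high))
  }))
  ylab <- switch(thresholds$y_metric,
                 auc = "CSR curve AUC (lower = more diverse)",
                 f50 = "F50 (higher = more diverse)",
                 paste0(toupper(thresholds$y_metric),
                        " (higher = more diverse)"))
  g <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$x_fp, y = .data$y_value)) +
    ggplot2::geom_rect(data = rects, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = rects$fill, alpha = 0.15) +
    ggplot2::geom_vline(xintercept = xt, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = yt, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(size = .data$size_M,
                                     fill = .data$prop_diversity),
                        shape = 21, colour = "grey20") +
    ggplot2::scale_size_area(max_size = 12, name = "library size M") +
    ggplot2::scale_fill_gradientn(
      colours = c("forestgreen", "darkorange3", "red"),
      name = "property distance\n(red = more diverse)") +
    ggplot2::coord_cartesian(xlim = xlim, ylim = ylim, expand = FALSE) +
    ggplot2::labs(
      x = "median Tanimoto similarity (lower = more diverse)",
      y = ylab,
      caption = sprintf("thresholds: x = %.3f, y(%s) = %.3f", xt,
                        thresholds$y_metric, yt)) +
    ggplot2::theme_classic()
  if (label)
    g <- g + ggplot2::geom_text(ggplot2::aes(label = .data$set_name),
                                vjust = -1.2, size = 3)
  g
}

#' Write the consensus plot and its companion table
#'
#' Renders the plot to SVG and/or PNG (by file extension) and writes the
#' companion TSV carrying every plotted value plus the resolved
#' thresholds, so plot and table encode identical numbers.
#'
#' @param records Classified records from [classifyQuadrants()].
#' @param thresholds List from [resolveThresholds()].
#' @param plotFiles Character vector of output image paths (`.svg` or
#'   `.png`).
#' @param tableFile Path for the companion TSV (NULL to skip).
#' @param width,height,dpi Device geometry.
#' @return The companion data.frame, invisibly.
#' @export
writeCDP <- function(records, thresholds, plotFiles = character(0),
                     tableFile = NULL, width = 7, height = 5.5,
                     dpi = 150) {
  g <- plotCDP(records, thresholds)
  for (f in plotFiles) {
    ext <- tolower(tools::file_ext(f))
    if (ext == "svg") {
      grDevices::svg(f, width = width, height = height)
    } else if (ext == "png") {
      grDevices::png(f, width = width * dpi, height = height * dpi,
                     res = dpi)
    } else stop("unsupported plot format: ", ext)
    print(g)
    grDevices::dev.off()
  }
  out <- records
  out$x_threshold <- thresholds$x_threshold
  out$y_threshold <- thresholds$y_threshold
  if (!is.null(tableFile))
    utils::write.table(out, tableFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(out)
}
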