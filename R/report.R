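#' Per-class mean beat with standard-deviation band
#'
#' Pointwise mean and standard deviation of the beats of each class over
#' the 300-sample axis; the SD delimits the error band drawn around the
#' class mean.
#'
#' @param beats_by_class named list (class label -> beats matrix with one
#'   beat per row); every class needs at least two beats for the SD.
#' @return data.frame with columns class, sample (0-based), mean, sd.
#' @export
mean_beat_profile <- function(beats_by_class) {
  stopifnot(is.list(beats_by_class), length(names(beats_by_class)) > 0)
  rows <- lapply(names(beats_by_class), function(cls) {
    m <- beats_by_class[[cls]]
    abort_if(nrow(m) < 2,
             sprintf("class '%s' has fewer than 2 beats; SD undefined", cls))
    data.frame(class = cls, sample = seq_len(ncol(m)) - 1L,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin a CAM profile for histogram display
#'
#' Display-only binning of the 300-sample axis; all statistics elsewhere
#' use the unbinned vectors.
#'
#' @param cam numeric relevance vector.
#' @param bins number of equal-width bins.
#' @return data.frame with bin start (0-based sample), midpoint and mean
#'   relevance per bin.
#' @export
bin_cam <- function(cam, bins = 30) {
  n <- length(cam)
  width <- n / bins
  idx <- ceiling(seq_len(n) / width)
  data.frame(bin_start = (seq_len(bins) - 1) * width,
             mid = (seq_len(bins) - 0.5) * width,
             relevance = as.numeric(tapply(cam, idx, mean)))
}

#' Render the analysis report
#'
#' Writes a deterministic file set: tables as CSV/JSON (accuracy per
#' split, confusion matrix, mean-beat profiles, CAM profiles) and figures
#' (class-mean beats with SD bands, per-class CAM histograms, the overlap
#' profile, and a composite overlaying the mean beats on the overlap
#' histogram). Inputs are not modified; rerunning on the same inputs
#' reproduces the same tables byte for byte.
#'
#' @param metrics list with \code{accuracy} (named fractions, e.g.
#'   train/val/test) and \code{confusion} (2x2 matrix).
#' @param profiles [mean_beat_profile()] data.frame.
#' @param cams data.frame with columns sample, normal, obese, overlap.
#' @param out_dir output directory (created if needed).
#' @param fig_format "png" or "pdf".
#' @param bins histogram bins for CAM display.
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(metrics, profiles, cams, out_dir,
                          fig_format = c("png", "pdf"), bins = 30) {
  fig_format <- match.arg(fig_format)
  abort_if(is.null(metrics$accuracy), "missing input: metrics$accuracy")
  abort_if(is.null(metrics$confusion), "missing input: metrics$confusion")
  abort_if(is.null(profiles), "missing input: profiles")
  abort_if(is.null(cams), "missing input: cams")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name)
    files <<- c(files, p)
    p
  }

  acc <- data.frame(split = names(metrics$accuracy),
                    accuracy = as.numeric(metrics$accuracy),
                    percent = sprintf("%d%%",
                                      round(100 * as.numeric(metrics$accuracy))),
                    stringsAsFactors = FALSE)
  utils::write.csv(acc, put("accuracy_table.csv"), row.names = FALSE)

  cm <- as.data.frame(as.table(metrics$confusion))
  names(cm) <- c("true", "predicted", "count")
  utils::write.csv(cm, put("confusion_matrix.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = as.list(stats::setNames(as.numeric(metrics$accuracy),
                                            names(metrics$accuracy))),
         confusion = metrics$confusion),
    put("metrics.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  utils::write.csv(profiles, put("mean_beats.csv"), row.names = FALSE)
  utils::write.csv(cams, put("cam_profiles.csv"), row.names = FALSE)

  ms_per_sample <- 2
  t_ms <- function(s) (s - 100) * ms_per_sample # time relative to the R peak
  p_beats <- ggplot2::ggplot(profiles,
      ggplot2::aes(x = t_ms(sample), y = mean,
                   ymin = mean - sd, ymax = mean + sd,
                   colour = class, fill = class)) +
    ggplot2::geom_ribbon(alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from R peak (ms)", y = "amplitude",
                  title = "Class-mean beats with SD bands")
  save_fig(p_beats, put(paste0("mean_beats.", fig_format)))

  cam_long <- rbind(
    transform(bin_cam(cams$normal, bins), class = "normal"),
    transform(bin_cam(cams$obese, bins), class = "obese")
  )
  p_hist <- ggplot2::ggplot(cam_long,
      ggplot2::aes(x = t_ms(mid), y = relevance, fill = class)) +
    ggplot2::geom_col(position = "dodge",
                      width = 0.8 * ms_per_sample * nrow(cams) / bins) +
    ggplot2::labs(x = "time from R peak (ms)", y = "mean relevance",
                  title = "Grad-CAM++ relevance by class")
  save_fig(p_hist, put(paste0("cam_histogram.", fig_format)))

  ov <- bin_cam(cams$overlap, bins)
  p_ov <- ggplot2::ggplot(ov, ggplot2::aes(x = t_ms(mid), y = relevance)) +
    ggplot2::geom_col(fill = "grey40",
                      width = 0.8 * ms_per_sample * nrow(cams) / bins) +
    ggplot2::labs(x = "time from R peak (ms)", y = "overlap relevance",
                  title = "Class-overlap relevance")
  save_fig(p_ov, put(paste0("cam_overlap.", fig_format)))

  amp_scale <- max(abs(c(profiles$mean - profiles$sd,
                         profiles$mean + profiles$sd)))
  ov$scaled <- ov$relevance / max(ov$relevance) * amp_scale
  p_comp <- ggplot2::ggplot() +
    ggplot2::geom_col(data = ov,
                      ggplot2::aes(x = t_ms(mid), y = scaled),
                      fill = "grey70", alpha = 0.6,
                      width = 0.8 * ms_per_sample * nrow(cams) / bins) +
    ggplot2::geom_line(data = profiles,
                       ggplot2::aes(x = t_ms(sample), y = mean,
                                    colour = class)) +
    ggplot2::labs(x = "time from R peak (ms)", y = "amplitude",
                  title = "Mean beats over class-overlap relevance")
  save_fig(p_comp, put(paste0("composite.", fig_format)))

  invisible(files)
}

save_fig <- function(plot, path, width = 7, height = 4) {
  if (grepl("\\.pdf$", path)) {
    grDevices::pdf(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  }
  print(plot)
  grDevices::dev.off()
  invisible(path)
}
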