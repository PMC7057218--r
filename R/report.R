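#' Diagnostic plots and tables for an annotation
#'
#' Writes, per stretch, the discrete distribution of CV moduli along the
#' chain, the angles between consecutive CVs and the consecutive CA--CA
#' distances, as PNG plots plus CSV tables holding the same values. These
#' curves flag local main-chain anomalies (dips in moduli, angle spikes,
#' irregular CA spacing) and support visual assessment of the annotation.
#'
#' @param annotation a `cv_annotation`
#' @param out_dir output directory
#' @param prefix file-name prefix
#' @return named list of tables (`moduli`, `angles`, `ca_distances`), with
#'   the written file paths in attribute `"files"`
#' @export
annotation_report <- function(annotation, out_dir = ".", prefix = "annotation") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cvs <- annotation$cvs
  strc <- annotation$structure
  moduli <- data.frame(stretch = cvs$stretch, cv = cvs$start,
                       modulus = cvs$modulus,
                       label = annotation$cv_scores$label)
  ang <- NULL
  for (s in seq_along(strc$stretches)) {
    a <- consecutive_cv_angles(annotation$graph, s)
    if (length(a)) ang <- rbind(ang, data.frame(stretch = s,
                                                cv = seq_along(a), angle = a))
  }
  cad <- NULL
  for (s in seq_along(strc$stretches)) {
    ca <- strc$stretches[[s]]$xyz$CA
    if (nrow(ca) > 1) {
      d <- rowdist(ca[-nrow(ca), , drop = FALSE], ca[-1, , drop = FALSE])
      cad <- rbind(cad, data.frame(stretch = s, residue = seq_along(d),
                                   distance = d))
    }
  }
  tabs <- list(moduli = moduli,
               angles = ang %||% data.frame(stretch = integer(0),
                                            cv = integer(0), angle = numeric(0)),
               ca_distances = cad %||% data.frame(stretch = integer(0),
                                                  residue = integer(0),
                                                  distance = numeric(0)))
  files <- character(0)
  for (nm in names(tabs)) {
    csv <- file.path(out_dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.csv(tabs[[nm]], csv, row.names = FALSE)
    files <- c(files, csv)
  }
  plot_one <- function(tab, ycol, ylab, fname, hline = NULL) {
    png <- file.path(out_dir, fname)
    grDevices::png(png, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    if (nrow(tab) == 0) {
      plot.new(); title(main = ylab)
    } else {
      plot(seq_len(nrow(tab)), tab[[ycol]], type = "b", pch = 16,
           xlab = "position along chain", ylab = ylab,
           col = as.integer(factor(tab$stretch)))
      if (!is.null(hline)) graphics::abline(h = hline, lty = 2, col = "grey40")
    }
    png
  }
  files <- c(files,
             plot_one(tabs$moduli, "modulus", "CV modulus (A)",
                      sprintf("%s_moduli.png", prefix), hline = c(1.4, 2.2)),
             plot_one(tabs$angles, "angle", "consecutive CV angle (deg)",
                      sprintf("%s_angles.png", prefix), hline = c(7.5, 52.5)),
             plot_one(tabs$ca_distances, "distance", "CA-CA distance (A)",
                      sprintf("%s_ca_distances.png", prefix), hline = 3.8))
  attr(tabs, "files") <- files
  tabs
}
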