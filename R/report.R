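## Correlation strength labels, heatmaps, results grid -----------------------

#' Interpret a correlation's strength
#'
#' Applies the conventional four-bin reading of |R|: 0-0.3 very weak,
#' 0.31-0.5 weak, 0.51-0.7 moderate, 0.71-1.0 strong. The printed bins are
#' non-contiguous; values falling in a gap (e.g. 0.305) take the lower bin.
#'
#' @param R Correlation, |R| <= 1.
#' @return One of \code{"very weak"}, \code{"weak"}, \code{"moderate"},
#'   \code{"strong"}.
#' @export
#' @examples
#' interpret_r(0.82)   # "strong"
interpret_r <- function(R) {
  a <- abs(R)
  if (any(a > 1)) stop("|R| must not exceed 1")
  vapply(a, function(x) {
    if (x <= 0.305) "very weak"
    else if (x <= 0.505) "weak"
    else if (x <= 0.705) "moderate"
    else "strong"
  }, character(1))
}

#' Feature-by-scale correlation heatmap matrix
#'
#' Computes the Pearson correlation of every feature with every clinical
#' scale, plus the scale-by-scale intercorrelation block (used to spot
#' redundant clinical measures). Optionally writes the matrix as CSV and a
#' raster heatmap.
#'
#' @param rows Feature table.
#' @param features Feature columns (default: all metric columns present).
#' @param scales Scale columns (default: the four clinical scales present).
#' @param csv_path Optional path for the matrix CSV.
#' @param png_path Optional path for a PNG heatmap.
#' @return List with \code{feature_scale} (features x scales matrix) and
#'   \code{scale_scale} (symmetric scales x scales matrix).
#' @export
correlation_heatmap <- function(rows, features = NULL, scales = NULL,
                                csv_path = NULL, png_path = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("empty feature table")
  if (is.null(features)) features <- feature_columns(rows)
  if (is.null(scales)) scales <- intersect(CLINICAL_SCALES, names(rows))
  stopifnot(length(features) > 0, length(scales) > 0)
  fs <- matrix(NA_real_, length(features), length(scales),
               dimnames = list(features, scales))
  for (f in features) for (s in scales)
    fs[f, s] <- tryCatch(pearson_r(rows[[f]], rows[[s]]),
                         error = function(e) NA_real_)
  ss <- matrix(NA_real_, length(scales), length(scales),
               dimnames = list(scales, scales))
  for (s1 in scales) for (s2 in scales)
    ss[s1, s2] <- if (s1 == s2) 1 else
      tryCatch(pearson_r(rows[[s1]], rows[[s2]]), error = function(e) NA_real_)
  if (!is.null(csv_path)) {
    full <- rbind(fs, ss)
    utils::write.csv(data.frame(name = rownames(full), full,
                                check.names = FALSE),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 720, height = 200 + 18 * nrow(fs))
    on.exit(grDevices::dev.off())
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(fs, cluster_rows = FALSE, cluster_cols = FALSE,
                         display_numbers = TRUE,
                         main = "Feature-scale correlations")
    } else {
      graphics::image(t(fs[nrow(fs):1, , drop = FALSE]), axes = FALSE,
                      main = "Feature-scale correlations")
    }
  }
  list(feature_scale = fs, scale_scale = ss)
}

#' Assemble the results grid from cross-validation outcomes
#'
#' Builds the scale-by-device-by-model results structure: every cell carries
#' the cross-validated R, its p-value, the sample size, the features used
#' and the strength label. The motor-power analyses enter as distinct
#' measure rows (\code{MP_total}, \code{MP_kinematic_force},
#' \code{MP_force_transducer} with its deltaz and per-direction
#' sub-variants), and severity strata as separate measure labels.
#'
#' @param cv_results Named or unnamed list of \code{cv_result} objects; each
#'   may carry attributes \code{measure} (row label; defaults to the
#'   target) and \code{device} (\code{"shoulder_elbow"}, \code{"wrist"} or
#'   \code{"both"}).
#' @param vif_reports Optional list of \code{\link{vif}} data.frames.
#' @param scale_intercorrelations Optional scales x scales matrix (the
#'   \code{scale_scale} block of \code{\link{correlation_heatmap}}).
#' @param config Optional list recorded as provenance.
#' @return Object of class \code{correlation_report}: \code{grid}
#'   (data.frame: measure, device, model, R, p, n, label, features),
#'   \code{scale_intercorrelations}, \code{vif_blocks}, \code{provenance}.
#' @export
build_report <- function(cv_results, vif_reports = NULL,
                         scale_intercorrelations = NULL, config = NULL) {
  stopifnot(length(cv_results) >= 1)
  rows <- lapply(cv_results, function(cv) {
    stopifnot(inherits(cv, "cv_result"))
    measure <- attr(cv, "measure")
    if (is.null(measure)) measure <- cv$target
    device <- attr(cv, "device")
    if (is.null(device)) device <- "shoulder_elbow"
    data.frame(measure = measure, device = device,
               model = if (cv$model_kind == "mlp") "nonlinear" else "linear",
               R = cv$mean_R, p = cv$p_value, n = cv$n_rows,
               label = interpret_r(min(abs(cv$mean_R), 1)),
               features = paste(cv$features, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  if (anyDuplicated(grid[c("measure", "device", "model")]))
    stop("conflicting duplicate cells in report grid")
  structure(list(grid = grid,
                 scale_intercorrelations = scale_intercorrelations,
                 vif_blocks = vif_reports,
                 provenance = config),
            class = "correlation_report")
}

#' Render a correlation report as markdown
#'
#' @param report A \code{\link{build_report}} result.
#' @param path Optional file to write; otherwise the lines are returned.
#' @return Character vector of markdown lines (invisibly when written).
#' @export
render_report_markdown <- function(report, path = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  g <- report$grid
  lines <- c("# Correlation of kinematic and kinetic metrics with clinical measures",
             "",
             "| Measure | Device | Model | R | P | n | Strength |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("| %s | %s | %s | %.2f | %.3g | %d | %s |",
                              g$measure[i], g$device[i], g$model[i], g$R[i],
                              g$p[i], g$n[i], g$label[i]))
  }
  if (!is.null(report$scale_intercorrelations)) {
    ss <- report$scale_intercorrelations
    lines <- c(lines, "", "## Clinical scale intercorrelations", "",
               paste0("| |", paste(colnames(ss), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(ss) + 1), collapse = "|"),
                      "|"))
    for (i in seq_len(nrow(ss)))
      lines <- c(lines, sprintf("| %s | %s |", rownames(ss)[i],
                                paste(sprintf("%.2f", ss[i, ]),
                                      collapse = " | ")))
  }
  if (!is.null(report$vif_blocks)) {
    lines <- c(lines, "", "## Variance inflation factors", "")
    for (nm in names(report$vif_blocks)) {
      vb <- report$vif_blocks[[nm]]
      lines <- c(lines, sprintf("### %s", nm),
                 "| Feature | R_j2 | VIF | High |", "|---|---|---|---|",
                 sprintf("| %s | %.3f | %s | %s |", vb$feature, vb$r_squared,
                         ifelse(vb$infinite, "inf", sprintf("%.2f", vb$vif)),
                         ifelse(vb$flag_high, "yes", "no")),
                 "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Save / reload a correlation report as JSON
#'
#' @param report A \code{correlation_report}.
#' @param path JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "correlation_report"))
  ss <- report$scale_intercorrelations
  if (!is.null(ss))
    ss <- data.frame(name = rownames(ss), ss, check.names = FALSE)
  obj <- list(grid = report$grid,
              scale_intercorrelations = ss,
              vif_blocks = report$vif_blocks,
              provenance = report$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ss <- obj$scale_intercorrelations
  if (!is.null(ss)) {
    ss <- as.data.frame(ss)
    rn <- ss$name
    ss$name <- NULL
    ss <- as.matrix(ss)
    rownames(ss) <- rn
  }
  grid <- as.data.frame(obj$grid)
  grid$n <- as.integer(grid$n)
  structure(list(grid = grid,
                 scale_intercorrelations = ss,
                 vif_blocks = lapply(obj$vif_blocks, as.data.frame),
                 provenance = obj$provenance),
            class = "correlation_report")
}
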