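## Correlation-based feature selection, collinearity pruning, rescaling ------

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the Pearson correlation with
#' pairwise-complete handling of missing values; errors on degenerate
#' (zero-variance or too-short) input rather than returning NA.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Correlation-based feature selection
#'
#' Retains the features whose correlation with the target scale exceeds the
#' threshold in absolute value (worse-is-larger metrics such as deviation or
#' offset legitimately anti-correlate with clinical scores), sorted by |R|
#' descending. When no feature passes, the strongest \code{top_k} features
#' are returned instead, flagged as sub-threshold — mirroring the fallback
#' used for scales that correlate only weakly with kinematics.
#'
#' @param rows Feature table data.frame (see
#'   \code{\link{write_feature_table}} for the layout).
#' @param target Name of the target scale column (e.g. \code{"fma_ue"}).
#' @param r_threshold Selection threshold on the correlation (default 0.5).
#' @param signed If TRUE, threshold the signed R instead of |R|
#'   (default FALSE).
#' @param top_k Fallback count when nothing passes (default 4).
#' @param features Candidate feature columns; defaults to all metric columns.
#' @return Object of class \code{selection_result}: \code{target},
#'   \code{candidate_correlations} (named, all candidates — heatmap input),
#'   \code{selected} (ordered), \code{sub_threshold} flag, \code{pruned}
#'   (empty here; filled by \code{\link{prune_collinear}}),
#'   \code{r_threshold}.
#' @export
select_features <- function(rows, target, r_threshold = 0.5, signed = FALSE,
                            top_k = 4, features = NULL) {
  rows <- as.data.frame(rows)
  if (is.null(features)) features <- feature_columns(rows)
  stopifnot(target %in% names(rows), length(features) > 0)
  y <- rows[[target]]
  if (sum(!is.na(y)) < 3) stop("need at least 3 rows with non-missing target")
  cand <- vapply(features, function(f) {
    tryCatch(pearson_r(rows[[f]], y), error = function(e) NA_real_)
  }, numeric(1))
  score <- if (signed) cand else abs(cand)
  pass <- names(cand)[!is.na(score) & score > r_threshold]
  sub_threshold <- FALSE
  if (length(pass) == 0) {
    warning(sprintf(
      "no feature exceeds |R| > %.2f with %s; falling back to top %d by |R|",
      r_threshold, target, top_k))
    ranked <- names(sort(abs(cand[!is.na(cand)]), decreasing = TRUE))
    pass <- utils::head(ranked, top_k)
    sub_threshold <- TRUE
  }
  pass <- pass[order(abs(cand[pass]), decreasing = TRUE)]
  structure(list(target = target, candidate_correlations = cand,
                 selected = pass, sub_threshold = sub_threshold,
                 pruned = list(), r_threshold = r_threshold),
            class = "selection_result")
}

#' Prune mutually dependent features
#'
#' Within every connected component of the feature dependency graph (edges
#' between selected features whose mutual |R| exceeds
#' \code{dep_threshold}), a single representative is kept: the
#' \code{keep_list} member when one is present (the analyst's "better
#' interpretability" choice), otherwise the feature most correlated with the
#' target. All dropped features are recorded with the representative that
#' absorbed them and the dependency R.
#'
#' @param rows Feature table.
#' @param selection A \code{\link{select_features}} result.
#' @param dep_threshold Mutual-dependency threshold (default 0.85).
#' @param keep_list Optional character vector of preferred features.
#' @return The selection with \code{selected} reduced and \code{pruned}
#'   filled (named list: dropped feature -> list(kept, dependency_r)).
#' @export
prune_collinear <- function(rows, selection, dep_threshold = 0.85,
                            keep_list = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  sel <- selection$selected
  if (length(sel) <= 1) return(selection)
  X <- as.matrix(as.data.frame(rows)[sel])
  C <- abs(stats::cor(X, use = "pairwise.complete.obs"))
  adj <- C > dep_threshold
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  keep <- character(0)
  pruned <- selection$pruned
  for (members in comp) {
    nm <- sel[members]
    if (length(nm) == 1) { keep <- c(keep, nm); next }
    preferred <- intersect(keep_list, nm)
    rep_f <- if (length(preferred) > 0) preferred[1] else
      nm[which.max(abs(selection$candidate_correlations[nm]))]
    keep <- c(keep, rep_f)
    for (d in setdiff(nm, rep_f))
      pruned[[d]] <- list(kept = rep_f, dependency_r = C[d, rep_f])
  }
  selection$selected <- sel[sel %in% keep]
  selection$pruned <- pruned
  selection$dep_threshold <- dep_threshold
  selection
}

# Connected components of an undirected adjacency matrix (index lists).
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    stack <- i; comp <- integer(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE; comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Fit a max-rescaling specification on training rows
#'
#' Features are normalized to their training maxima (in absolute value, so
#' negatively signed metrics rescale symmetrically); the target scale is
#' rescaled the same way for the nonlinear model only, as the linear model
#' needs no bounded response.
#'
#' @param rows Training rows (feature table).
#' @param features Feature columns to scale.
#' @param target Target scale column.
#' @param mode \code{"linear"} (target untouched) or \code{"nonlinear"}
#'   (target divided by its max too).
#' @return Object of class \code{scaling_spec}: \code{feature_max} (named),
#'   \code{target}, \code{target_max} (1 for linear mode), \code{mode}.
#' @export
fit_scaling <- function(rows, features, target,
                        mode = c("linear", "nonlinear")) {
  mode <- match.arg(mode)
  rows <- as.data.frame(rows)
  fmax <- vapply(features, function(f) {
    m <- max(abs(rows[[f]]), na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stop("zero or undefined training maximum for feature '", f, "'")
    m
  }, numeric(1))
  tmax <- 1
  if (mode == "nonlinear") {
    tmax <- max(abs(rows[[target]]), na.rm = TRUE)
    if (!is.finite(tmax) || tmax == 0)
      stop("zero or undefined training maximum for target '", target, "'")
  }
  structure(list(feature_max = fmax, target = target, target_max = tmax,
                 mode = mode),
            class = "scaling_spec")
}

#' Apply (or invert) a scaling specification
#'
#' @param rows Feature table rows.
#' @param spec A \code{\link{fit_scaling}} result.
#' @param invert If TRUE, undo the scaling.
#' @return Rows with scaled (or restored) columns.
#' @export
apply_scaling <- function(rows, spec, invert = FALSE) {
  stopifnot(inherits(spec, "scaling_spec"))
  rows <- as.data.frame(rows)
  op <- if (invert) `*` else `/`
  for (f in names(spec$feature_max))
    rows[[f]] <- op(rows[[f]], spec$feature_max[[f]])
  if (spec$target %in% names(rows))
    rows[[spec$target]] <- op(rows[[spec$target]], spec$target_max)
  rows
}
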