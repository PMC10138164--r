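#' Confusion counts over the Cartesian product of candidate pairs
#'
#' Every candidate pair `(v, u)` of the `|V| x |U|` Cartesian product is
#' classified: TP if the pair is aligned and `u` is `v`'s true counterpart;
#' FP if aligned but not the true counterpart; FN if not aligned although
#' `u` is the true counterpart; TN otherwise. Derived rates: node
#' correctness `NC = TP / |V|`, `TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`.
#'
#' @param alignment an `alignment`.
#' @param truth named character vector mapping every source node id to its
#'   true counterpart in the target network (injective, total on `V`).
#' @param n_source,n_target sizes `|V|` and `|U|` of the two node sets;
#'   default to the number of aligned sources and of distinct targets in
#'   `truth`/alignment respectively (supply them explicitly when unaligned
#'   target nodes exist).
#' @return A `confusion_counts` list: `TP`, `FP`, `TN`, `FN`, `NC`, `TPR`,
#'   `FPR`, `n_source`, `n_target`.
#' @export
confusion_counts <- function(alignment, truth, n_source = NULL,
                             n_target = NULL) {
  stopifnot(inherits(alignment, "alignment"))
  mapping <- alignment$mapping
  if (length(mapping) == 0) {
    warning("empty alignment")
    mapping <- character(0)
  }
  unknown <- setdiff(names(mapping), names(truth))
  if (length(unknown) > 0)
    stop("aligned node(s) missing from the ground truth: ",
         paste(head(unknown, 5), collapse = ", "))
  if (anyDuplicated(truth) || anyDuplicated(names(truth)))
    stop("ground truth must be injective")
  n_source <- as.integer(n_source %||% length(truth))
  n_target <- as.integer(n_target %||% max(length(unique(c(truth, mapping))),
                                           length(mapping)))
  TP <- sum(truth[names(mapping)] == mapping)
  FP <- length(mapping) - TP
  # a source node's true pair is missed iff the node is misaligned/unaligned
  FN <- n_source - TP
  TN <- n_source * n_target - TP - FP - FN
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 NC = TP / n_source,
                 TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
                 n_source = n_source, n_target = n_target),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d | NC=%.4f TPR=%.4f FPR=%.4f\n",
              x$TP, x$FP, x$TN, x$FN, x$NC, x$TPR, x$FPR))
  invisible(x)
}

#' Node correctness of an alignment
#'
#' Fraction of source nodes mapped to their true counterparts,
#' `NC = TP / |V|`.
#'
#' @inheritParams confusion_counts
#' @return A fraction in `[0, 1]`; 0 with a warning for an empty alignment.
#' @export
node_correctness <- function(alignment, truth, n_source = NULL) {
  if (length(alignment$mapping) == 0) {
    warning("empty alignment: node correctness is 0")
    return(0)
  }
  confusion_counts(alignment, truth, n_source = n_source)$NC
}

#' ROC curve and AUC from (FPR, TPR) points
#'
#' Deduplicates and sorts the points by `(FPR, TPR)`, anchors the curve at
#' `(0, 0)` and `(1, 1)` if absent, and integrates by the trapezoidal rule.
#'
#' @param points two-column matrix or data frame (`fpr`, `tpr`), or a list
#'   of length-2 vectors; all coordinates in `[0, 1]`.
#' @return An `roc_result`: list with `points` (data frame `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns (FPR, TPR)")
  if (any(is.na(points)) || any(points < 0) || any(points > 1))
    stop("ROC coordinates must lie in [0, 1]")
  df <- unique(data.frame(fpr = points[, 1], tpr = points[, 2]))
  df <- df[order(df$fpr, df$tpr), , drop = FALSE]
  if (!any(df$fpr == 0 & df$tpr == 0)) df <- rbind(c(0, 0), df)
  if (!any(df$fpr == 1 & df$tpr == 1)) df <- rbind(df, c(1, 1))
  rownames(df) <- NULL
  auc <- sum(diff(df$fpr) * (head(df$tpr, -1) + df$tpr[-1]) / 2)
  structure(list(points = df, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Noise-robustness sweep: align a network against noisy copies of itself
#'
#' For each noise level and repeat, a copy of `base` is degraded with
#' [inject_noise()] and aligned back to `base`; the alignment is scored
#' against the identity (namesake) ground truth. Means over repeats are
#' reported per level and mode.
#'
#' @param base a `temporal_network`.
#' @param levels noise fractions in `[0, 1]` (e.g.
#'   `c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3)`).
#' @param modes one or both of `"edges"`, `"events"`.
#' @param wparams,sparams embedding parameters, see [align_networks()].
#' @param repeats repeats per level (>= 1); each uses a distinct derived
#'   seed.
#' @param seed integer base seed.
#' @return A data frame with columns `level`, `mode`, `mean_nc`, `mean_tpr`,
#'   `mean_fpr`, `n_repeats`.
#' @export
noise_sweep <- function(base, levels = c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                        modes = c("edges", "events"),
                        wparams = walk_params(), sparams = sg_params(),
                        repeats = 10, seed = 1) {
  stopifnot(inherits(base, "temporal_network"), repeats >= 1)
  if (any(levels < 0) || any(levels > 1))
    stop("noise levels must be in [0, 1]")
  modes <- match.arg(modes, several.ok = TRUE)
  truth <- stats::setNames(base$nodes, base$nodes)
  n <- length(base$nodes)
  rows <- list()
  run <- 0L
  for (mode in modes) {
    for (lv in levels) {
      nc <- tpr <- fpr <- numeric(repeats)
      for (r in seq_len(repeats)) {
        run <- run + 1L
        s <- mix_seed(seed, run)
        noisy <- inject_noise(base, lv, mode = mode, seed = s)
        sp <- sparams
        sp$seed <- s
        al <- align_networks(noisy, base, wparams, sp)
        cc <- confusion_counts(al, truth, n_source = n, n_target = n)
        nc[r] <- cc$NC
        tpr[r] <- cc$TPR
        fpr[r] <- cc$FPR
      }
      rows[[length(rows) + 1L]] <-
        data.frame(level = lv, mode = mode, mean_nc = mean(nc),
                   mean_tpr = mean(tpr), mean_fpr = mean(fpr),
                   n_repeats = repeats)
    }
  }
  do.call(rbind, rows)
}

#' ROC curves from a noise-sweep table
#'
#' Builds one ROC curve per mode from the per-level mean `(FPR, TPR)` points
#' of a [noise_sweep()] table.
#'
#' @param sweep data frame returned by [noise_sweep()].
#' @return Named list of `roc_result`, one per mode.
#' @export
sweep_roc <- function(sweep) {
  stopifnot(all(c("mode", "mean_tpr", "mean_fpr") %in% names(sweep)))
  lapply(split(sweep, sweep$mode), function(df)
    roc_auc(data.frame(fpr = df$mean_fpr, tpr = df$mean_tpr)))
}

#' Simple moving average
#'
#' Unweighted moving average used to extract trends from per-level accuracy
#' series.
#'
#' @param series numeric vector.
#' @param window positive integer window, `window <= length(series)`.
#' @return Numeric vector of length `length(series) - window + 1`.
#' @export
moving_average <- function(series, window) {
  if (window < 1 || window != floor(window))
    stop("window must be a positive integer")
  if (window > length(series))
    stop("window (", window, ") exceeds series length (", length(series), ")")
  as.numeric(stats::filter(series, rep(1 / window, window),
                           sides = 1))[window:length(series)]
}
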