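#' Polynomial-fit SMOTE
#'
#' Oversamples the minority class along deterministic geometric structures
#' instead of random neighbor interpolation:
#'
#' * `star` -- synthetic points on the segments joining each minority point to
#'   the minority centroid;
#' * `bus` -- synthetic points on the segments joining consecutive minority
#'   points in dataset order;
#' * `poly` -- a per-feature polynomial of degree `min(5, m - 1)` is fitted
#'   over the minority sample index `0..m-1` and synthetic points are read off
#'   at uniformly spaced fractional indices.
#'
#' Interpolation positions are evenly spaced, so the output is fully
#' determined by the row order. The `star` and `bus` topologies always emit at
#' least one synthetic point per minority sample, even when the classes are
#' already balanced -- a defining quirk of the method, and the reason it can
#' leak information (and hence show bias) even on balanced data. The `poly`
#' topology only generates when there is a deficit.
#'
#' @param table a [labeled_table()].
#' @param topology `"star"`, `"bus"` or `"poly"`.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   accepted for contract uniformity with the other resamplers).
#' @return a `labeled_table`.
#' @export
polyfit_smote <- function(table, topology = c("star", "bus", "poly"),
                          seed = 1L) {
  topology <- match.arg(topology)
  .check_two_classes(table)
  min_lab <- .minority_label(table$labels)
  min_pos <- which(table$labels == min_lab)
  m <- length(min_pos)
  if (m < 2L) stop("polyfit_smote requires at least 2 minority samples")
  if (topology == "poly" && m < 3L)
    stop("poly topology requires at least 3 minority samples")
  deficit <- length(table$labels) - 2L * m
  n_syn <- if (topology %in% c("star", "bus")) max(deficit, m) else deficit
  if (n_syn <= 0L) return(table)
  Xm <- table$features[min_pos, , drop = FALSE]
  ids <- table$row_ids[min_pos]

  if (topology == "star") {
    centroid <- colMeans(Xm)
    counts <- .spread_evenly(n_syn, m)
    pieces <- lapply(seq_len(m), function(j) {
      if (counts[j] == 0L) return(NULL)
      t_frac <- seq_len(counts[j]) / (counts[j] + 1)
      list(X = Xm[rep(j, counts[j]), , drop = FALSE] +
             t_frac * (matrix(centroid, counts[j], ncol(Xm), byrow = TRUE) -
                         Xm[rep(j, counts[j]), , drop = FALSE]),
           parents = rep(list(ids[j]), counts[j]))
    })
  } else if (topology == "bus") {
    n_seg <- m - 1L
    counts <- .spread_evenly(n_syn, n_seg)
    pieces <- lapply(seq_len(n_seg), function(j) {
      if (counts[j] == 0L) return(NULL)
      t_frac <- seq_len(counts[j]) / (counts[j] + 1)
      list(X = Xm[rep(j, counts[j]), , drop = FALSE] +
             t_frac * (Xm[rep(j + 1L, counts[j]), , drop = FALSE] -
                         Xm[rep(j, counts[j]), , drop = FALSE]),
           parents = rep(list(ids[c(j, j + 1L)]), counts[j]))
    })
  } else {
    degree <- min(5L, m - 1L)
    idx <- seq_len(m) - 1
    # fractional indices strictly inside [0, m-1], evenly spaced
    at <- seq_len(n_syn) / (n_syn + 1) * (m - 1)
    basis <- stats::poly(idx, degree = degree, raw = TRUE)
    X_new <- vapply(seq_len(ncol(Xm)), function(f) {
      fit <- stats::lm.fit(cbind(1, basis), Xm[, f])
      drop(cbind(1, stats::poly(at, degree = degree, raw = TRUE)) %*%
             fit$coefficients)
    }, numeric(n_syn))
    X_new <- matrix(X_new, nrow = n_syn)
    parents <- lapply(at, function(a) unique(ids[c(floor(a), ceiling(a)) + 1L]))
    pieces <- list(list(X = X_new, parents = parents))
  }

  pieces <- Filter(Negate(is.null), pieces)
  X_all <- do.call(rbind, lapply(pieces, `[[`, "X"))
  parents_all <- do.call(c, lapply(pieces, `[[`, "parents"))
  lt_append_synthetic(table, X_all, rep(min_lab, nrow(X_all)), parents_all)
}

# distribute n items over b bins as evenly as possible, extras to the first bins
.spread_evenly <- function(n, b) {
  base <- n %/% b
  extra <- n %% b
  counts <- rep(base, b)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}
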