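#' Resampling method specification
#'
#' Uniform description of the seven class-rebalancing methods studied by the
#' pipeline. SMOTE-family methods take a neighborhood size `k`;
#' polynomial-fit SMOTE takes a `topology` instead.
#'
#' @param method one of `"random_undersampling"`, `"tomek_links"`,
#'   `"random_oversampling"`, `"smote"`, `"polyfit_smote"`, `"mwmote"`,
#'   `"smote_tomek"` (or `"none"` for the identity resampler).
#' @param k neighborhood size for `smote` / `smote_tomek`, one of 3, 5, 7
#'   (default 5).
#' @param topology for `polyfit_smote` only: `"star"`, `"bus"` or `"poly"`.
#' @return a `resampler_spec` with a `type_tag` of `"undersampling"`,
#'   `"oversampling"`, `"combined"` or `"identity"`.
#' @export
resampler_spec <- function(method, k = 5L, topology = NULL) {
  methods <- c(random_undersampling = "undersampling",
               tomek_links = "undersampling",
               random_oversampling = "oversampling",
               smote = "oversampling",
               polyfit_smote = "oversampling",
               mwmote = "oversampling",
               smote_tomek = "combined",
               none = "identity")
  if (!method %in% names(methods))
    stop(sprintf("unknown resampling method '%s'; available: %s", method,
                 paste(setdiff(names(methods), "none"), collapse = ", ")))
  if (method == "polyfit_smote") {
    if (is.null(topology) || !topology %in% c("star", "bus", "poly"))
      stop("polyfit_smote requires topology 'star', 'bus' or 'poly'")
  } else if (!is.null(topology)) {
    stop("topology is only meaningful for polyfit_smote")
  }
  if (method %in% c("smote", "smote_tomek") && !k %in% c(3L, 5L, 7L))
    warning("k outside the usual {3, 5, 7} grid")
  structure(list(method = method, k = as.integer(k), topology = topology,
                 type_tag = unname(methods[method])),
            class = "resampler_spec")
}

#' All hyperparameter variants of a resampling method
#'
#' Expands a method name into the specs spanned by its hyperparameter grid
#' (k = 3, 5, 7 for the SMOTE family; star/bus/poly topologies for
#' polynomial-fit SMOTE). Best-model selection in the bias protocol maximizes
#' over these variants, so a method is reported as a single entity.
#'
#' @param method method name as in [resampler_spec()].
#' @return list of `resampler_spec`s.
#' @export
resampler_variants <- function(method) {
  switch(method,
    smote = ,
    smote_tomek = lapply(c(3L, 5L, 7L), function(k) resampler_spec(method, k = k)),
    polyfit_smote = lapply(c("star", "bus", "poly"),
                           function(tp) resampler_spec(method, topology = tp)),
    list(resampler_spec(method))
  )
}

# minority label under current counts; ties resolve to the positive class,
# matching the convention that positives are the minority in generated data
.minority_label <- function(labels) {
  n1 <- sum(labels == 1L); n0 <- length(labels) - n1
  if (n1 <= n0) 1L else 0L
}

.check_two_classes <- function(table) {
  if (length(unique(table$labels)) < 2L)
    stop("resampling requires both classes to be present")
}

# pairwise Euclidean distances; self-distance set to Inf for NN queries
.dist_matrix <- function(X, self_inf = TRUE) {
  D <- as.matrix(stats::dist(X))
  if (self_inf) diag(D) <- Inf
  D
}

#' Apply a resampling method
#'
#' Uniform entry point for all methods. Original rows that are kept are
#' bit-identical to their inputs; every synthesized row is flagged
#' `provenance = "synthetic"` and records the `row_id`s of the rows it was
#' generated from, so leakage audits can trace synthetic test samples back to
#' training-fold parents.
#'
#' @param table a [labeled_table()]; features should already be preprocessed.
#' @param spec a [resampler_spec()] or a method name.
#' @param seed integer seed; identical `(table, spec, seed)` gives identical
#'   output.
#' @return a resampled `labeled_table`.
#' @export
resample <- function(table, spec, seed = 1L) {
  if (is.character(spec)) spec <- resampler_spec(spec)
  stopifnot(inherits(spec, "resampler_spec"), inherits(table, "labeled_table"))
  switch(spec$method,
    none = table,
    random_undersampling = random_undersample(table, seed),
    tomek_links = tomek_links(table),
    random_oversampling = random_oversample(table, seed),
    smote = smote(table, k = spec$k, seed = seed),
    smote_tomek = smote_tomek(table, k = spec$k, seed = seed),
    polyfit_smote = polyfit_smote(table, topology = spec$topology, seed = seed),
    mwmote = mwmote(table, seed = seed)
  )
}

#' Random oversampling
#'
#' Duplicates minority rows, sampling with replacement, until class counts
#' are equal. Duplicates are flagged synthetic with the duplicated row as
#' their single parent.
#'
#' @param table a [labeled_table()].
#' @param seed integer seed.
#' @return a balanced `labeled_table`.
#' @export
random_oversample <- function(table, seed = 1L) {
  .check_two_classes(table)
  min_lab <- .minority_label(table$labels)
  min_pos <- which(table$labels == min_lab)
  deficit <- length(table$labels) - 2L * length(min_pos)
  if (deficit <= 0L) return(table)
  withr::with_seed(as.integer(seed), {
    dup <- sample(min_pos, deficit, replace = TRUE)
  })
  lt_append_synthetic(table, table$features[dup, , drop = FALSE],
                      rep(min_lab, deficit),
                      lapply(table$row_ids[dup], function(id) id))
}

#' Random undersampling
#'
#' Subsamples majority rows without replacement down to the minority count.
#' Never creates rows; kept rows stay in their original order.
#'
#' @param table a [labeled_table()].
#' @param seed integer seed.
#' @return a balanced `labeled_table` whose rows are a subset of the input.
#' @export
random_undersample <- function(table, seed = 1L) {
  .check_two_classes(table)
  min_lab <- .minority_label(table$labels)
  min_pos <- which(table$labels == min_lab)
  maj_pos <- which(table$labels != min_lab)
  if (length(maj_pos) <= length(min_pos)) return(table)
  withr::with_seed(as.integer(seed), {
    keep_maj <- sample(maj_pos, length(min_pos))
  })
  lt_subset(table, sort(c(min_pos, keep_maj)))
}

#' SMOTE oversampling
#'
#' Generates synthetic minority samples by linear interpolation:
#' `x_new = x_i + t * (x_nn - x_i)` with `t ~ Uniform(0, 1)` and `x_nn` one
#' of the `k` nearest minority neighbors (Euclidean) of a randomly chosen
#' minority row `x_i`. Generation continues until the classes are equal.
#' Each synthetic row records both parents.
#'
#' @param table a [labeled_table()].
#' @param k neighborhood size; clamped to `minority - 1` with a warning when
#'   the minority class is too small, so highly imbalanced small folds still
#'   run.
#' @param seed integer seed.
#' @return a balanced `labeled_table`.
#' @export
smote <- function(table, k = 5L, seed = 1L) {
  .check_two_classes(table)
  min_lab <- .minority_label(table$labels)
  min_pos <- which(table$labels == min_lab)
  m <- length(min_pos)
  if (m < 2L) stop("SMOTE requires at least 2 minority samples")
  deficit <- length(table$labels) - 2L * m
  if (deficit <= 0L) return(table)
  if (k >= m) {
    warning(sprintf("SMOTE k = %d >= minority count %d; clamped to %d",
                    k, m, m - 1L))
    k <- m - 1L
  }
  Xm <- table$features[min_pos, , drop = FALSE]
  D <- .dist_matrix(Xm)
  # k nearest minority neighbors per minority row, ties broken by lowest index
  nn_idx <- t(apply(D, 1L, function(d) order(d, seq_along(d))[seq_len(k)]))
  withr::with_seed(as.integer(seed), {
    i <- sample.int(m, deficit, replace = TRUE)
    j <- nn_idx[cbind(i, sample.int(k, deficit, replace = TRUE))]
    t_frac <- stats::runif(deficit)
  })
  X_new <- Xm[i, , drop = FALSE] + t_frac * (Xm[j, , drop = FALSE] - Xm[i, , drop = FALSE])
  parents <- lapply(seq_len(deficit), function(s)
    table$row_ids[min_pos[c(i[s], j[s])]])
  lt_append_synthetic(table, X_new, rep(min_lab, deficit), parents)
}

#' Tomek-link undersampling
#'
#' A Tomek link is a cross-class pair of samples that are mutual nearest
#' neighbors over the whole dataset. For every such pair the member of the
#' (current) majority class is removed; when the classes are tied the
#' label-0 member is removed, a documented deterministic tie-break. All links
#' are computed on the input data in one pass, then removed together. No
#' synthetic rows are ever created.
#'
#' @param table a [labeled_table()].
#' @return a `labeled_table` whose rows are a subset of the input.
#' @export
tomek_links <- function(table) {
  .check_two_classes(table)
  D <- .dist_matrix(table$features)
  nn <- apply(D, 1L, which.min)   # first minimum = lowest-index tie-break
  n <- length(nn)
  n1 <- sum(table$labels == 1L); n0 <- n - n1
  maj_lab <- if (n0 >= n1) 0L else 1L   # ties remove the label-0 member
  drop <- logical(n)
  for (a in seq_len(n)) {
    b <- nn[a]
    if (a < b && nn[b] == a && table$labels[a] != table$labels[b]) {
      drop[if (table$labels[a] == maj_lab) a else b] <- TRUE
    }
  }
  if (!any(drop)) return(table)
  lt_subset(table, which(!drop))
}

#' SMOTE followed by Tomek-link cleaning
#'
#' The combined method: [smote()] balances the classes, then [tomek_links()]
#' removes boundary pairs from the balanced result (so the per-pair
#' "majority" is resolved by the post-SMOTE counts, with the label-0
#' tie-break).
#'
#' @inheritParams smote
#' @return a `labeled_table`.
#' @export
smote_tomek <- function(table, k = 5L, seed = 1L) {
  tomek_links(smote(table, k = k, seed = seed))
}
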