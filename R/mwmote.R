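#' Majority-weighted minority oversampling (MWMOTE)
#'
#' Oversampler that concentrates generation on hard-to-learn borderline
#' minority samples and interpolates only within clusters of the minority
#' class, following the published procedure with its default hyperparameters:
#'
#' 1. filter noisy minority samples: keep only those whose `k1 = 5` nearest
#'    neighbors (over all samples) contain at least one minority sample;
#' 2. the borderline majority set is the union of the `k2 = 3` nearest
#'    majority neighbors of the filtered minority samples; the informative
#'    minority set is the union of the `k3 = ceiling(m / 2)` nearest filtered
#'    minority neighbors of that borderline majority set;
#' 3. each informative minority sample gets a selection weight accumulated
#'    from closeness and density factors with respect to the borderline
#'    majority set (closeness cut-off `Cf_th = 5`, scale `CMAX = 2`);
#' 4. the filtered minority set is clustered by average-linkage agglomerative
#'    clustering cut at `Cp = 3` times the mean nearest-neighbor distance
#'    within the set;
#' 5. each synthetic sample is `x + t * (y - x)`, `t ~ Uniform(0, 1)`, with
#'    `x` drawn by selection weight and `y` a random member of `x`'s cluster;
#'    generation continues until the classes are equal.
#'
#' If the informative set comes out empty (e.g. classes are far apart), the
#' weights fall back to uniform over the minority class with a warning.
#'
#' @param table a [labeled_table()].
#' @param seed integer seed.
#' @param k1,k2,cf_th,cmax,cp procedure hyperparameters; defaults are the
#'   original publication's.
#' @return a balanced `labeled_table`; synthetic rows record both
#'   interpolation endpoints as parents.
#' @export
mwmote <- function(table, seed = 1L, k1 = 5L, k2 = 3L,
                   cf_th = 5, cmax = 2, cp = 3) {
  .check_two_classes(table)
  min_lab <- .minority_label(table$labels)
  min_pos <- which(table$labels == min_lab)
  maj_pos <- which(table$labels != min_lab)
  m <- length(min_pos)
  if (m < 2L) stop("MWMOTE requires at least 2 minority samples")
  deficit <- length(table$labels) - 2L * m
  if (deficit <= 0L) return(table)

  X <- table$features
  D_all <- .dist_matrix(X)

  # step 1: drop minority samples with no minority point among their k1-NN
  k1_eff <- min(k1, nrow(X) - 1L)
  filtered <- min_pos[vapply(min_pos, function(i) {
    nb <- order(D_all[i, ], seq_len(ncol(D_all)))[seq_len(k1_eff)]
    any(nb %in% min_pos)
  }, logical(1))]

  weights_uniform <- FALSE
  if (length(filtered) == 0L) {
    filtered <- min_pos
    weights_uniform <- TRUE
  }

  # step 2: borderline majority and informative minority sets
  informative <- integer(0)
  border_maj <- integer(0)
  if (!weights_uniform) {
    k2_eff <- min(k2, length(maj_pos))
    border_maj <- unique(unlist(lapply(filtered, function(i) {
      maj_pos[order(D_all[i, maj_pos], seq_along(maj_pos))[seq_len(k2_eff)]]
    })))
    k3 <- min(ceiling(m / 2), length(filtered))
    informative <- unique(unlist(lapply(border_maj, function(j) {
      filtered[order(D_all[j, filtered], seq_along(filtered))[seq_len(k3)]]
    })))
  }

  if (length(informative) == 0L) {
    if (!weights_uniform)
      warning("MWMOTE informative minority set is empty; using uniform weights")
    cand <- min_pos
    sel_prob <- rep(1 / length(cand), length(cand))
  } else {
    # step 3: selection weights from closeness and density factors
    l <- ncol(X)
    cand <- informative
    Cf <- matrix(0, length(border_maj), length(cand))
    for (a in seq_along(border_maj)) {
      dn <- D_all[border_maj[a], cand] / l
      Cf[a, ] <- pmin(1 / pmax(dn, .Machine$double.eps), cf_th) / cf_th * cmax
    }
    rs <- rowSums(Cf)
    rs[rs == 0] <- 1
    Iw <- Cf * (Cf / rs)          # information weight = closeness * density
    Sw <- colSums(Iw)
    if (sum(Sw) == 0) Sw <- rep(1, length(cand))
    sel_prob <- Sw / sum(Sw)
  }

  # step 4: average-linkage clusters of the filtered minority set
  cl_of <- .mwmote_clusters(X[filtered, , drop = FALSE], cp)
  # candidates outside the filtered set (uniform fallback) join by nearest member
  cand_cluster <- vapply(cand, function(i) {
    if (i %in% filtered) cl_of[match(i, filtered)]
    else cl_of[which.min(D_all[i, filtered])]
  }, integer(1))

  withr::with_seed(as.integer(seed), {
    pick <- sample.int(length(cand), deficit, replace = TRUE, prob = sel_prob)
    X_new <- matrix(0, deficit, ncol(X))
    parents <- vector("list", deficit)
    for (s in seq_len(deficit)) {
      x_i <- cand[pick[s]]
      members <- filtered[cl_of == cand_cluster[pick[s]]]
      y_i <- members[sample.int(length(members), 1L)]
      t_frac <- stats::runif(1)
      X_new[s, ] <- X[x_i, ] + t_frac * (X[y_i, ] - X[x_i, ])
      parents[[s]] <- unique(table$row_ids[c(x_i, y_i)])
    }
  })
  lt_append_synthetic(table, X_new, rep(min_lab, deficit), parents)
}

# average-linkage agglomerative clustering cut at cp * (mean NN distance)
.mwmote_clusters <- function(Xf, cp) {
  nf <- nrow(Xf)
  if (nf == 1L) return(1L)
  Df <- .dist_matrix(Xf)
  davg <- mean(apply(Df, 1L, min))
  th <- cp * davg
  hc <- stats::hclust(stats::as.dist(.dist_matrix(Xf, self_inf = FALSE)),
                      method = "average")
  stats::cutree(hc, h = th)
}
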