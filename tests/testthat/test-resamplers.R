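test_that("resampler specs validate method names and hyperparameters", {
  expect_equal(resampler_spec("smote", k = 3)$type_tag, "oversampling")
  expect_equal(resampler_spec("smote_tomek")$type_tag, "combined")
  expect_equal(resampler_spec("tomek_links")$type_tag, "undersampling")
  expect_error(resampler_spec("adasyn"), "random_undersampling")
  expect_error(resampler_spec("polyfit_smote"), "topology")
  expect_error(resampler_spec("smote", topology = "star"), "topology")
  expect_length(resampler_variants("smote"), 3)
  expect_length(resampler_variants("polyfit_smote"), 3)
  expect_length(resampler_variants("mwmote"), 1)
})

test_that("random oversampling duplicates minority rows until balance", {
  tab <- imbalanced_table(80, 20)
  out <- random_oversample(tab, seed = 1)
  expect_equal(as.integer(table(out$labels)), c(80L, 80L))
  expect_equal(sum(out$provenance == "synthetic"), 60)
  # every duplicate is bit-identical to its recorded parent
  syn <- which(out$provenance == "synthetic")
  for (s in syn) {
    p <- match(out$parent_ids[[s]], out$row_ids)
    expect_identical(out$features[s, ], out$features[p, ])
  }
  # balanced input is untouched
  bal <- imbalanced_table(20, 20)
  expect_identical(random_oversample(bal, seed = 1), bal)
})

test_that("random undersampling subsamples the majority, never creates rows", {
  tab <- imbalanced_table(80, 20)
  out <- random_undersample(tab, seed = 1)
  expect_equal(as.integer(table(out$labels)), c(20L, 20L))
  expect_true(all(out$provenance == "original"))
  expect_true(all(out$row_ids %in% tab$row_ids))
  bal <- imbalanced_table(20, 20)
  expect_identical(random_undersample(bal, seed = 1), bal)
})

test_that("SMOTE interpolates on segments between recorded minority parents", {
  tab <- imbalanced_table(80, 20)
  out <- smote(tab, k = 5, seed = 2)
  expect_equal(as.integer(table(out$labels)), c(80L, 80L))
  expect_equal(sum(out$provenance == "synthetic"), 60)
  expect_true(all_synthetic_on_segments(out, tol = 1e-8))
  # parents are minority rows
  min_ids <- tab$row_ids[tab$labels == 1L]
  expect_true(all(unlist(out$parent_ids) %in% min_ids))

  # degenerate case: identical minority points reproduce that point
  X <- rbind(matrix(rnorm(16), ncol = 2), matrix(1.5, 4, 2))
  deg <- labeled_table(X, rep(c(0L, 1L), c(8, 4)))
  dout <- smote(deg, k = 3, seed = 3)
  syn <- dout$provenance == "synthetic"
  expect_true(all(dout$features[syn, ] == 1.5))

  expect_error(smote(lt_subset(tab, c(1:10, 81)), k = 5, seed = 1),
               "at least 2")
  expect_warning(smote(lt_subset(tab, c(1:20, 81:83)), k = 5, seed = 1),
                 "clamped")
})

test_that("Tomek links match a brute-force mutual-NN oracle", {
  # 1-D toy: majority {0.0, 0.9}, minority {1.0}; (0.9, 1.0) is a link
  toy <- labeled_table(matrix(c(0, 0.9, 1)), c(0L, 0L, 1L))
  out <- tomek_links(toy)
  expect_equal(out$features[, 1], c(0, 1))
  expect_equal(out$labels, c(0L, 1L))

  # random instances vs the oracle
  for (s in 1:5) {
    tab <- withr::with_seed(s, {
      X <- matrix(rnorm(40 * 2, sd = 0.6), ncol = 2)
      labeled_table(X, rbinom(40, 1, 0.35))
    })
    if (length(unique(tab$labels)) < 2) next
    out <- tomek_links(tab)
    expect_equal(out$row_ids, tab$row_ids[tomek_oracle(tab)])
  }

  # well-separated clusters produce no removals
  X <- rbind(matrix(rnorm(20, sd = 0.1), ncol = 2),
             matrix(rnorm(10, 10, sd = 0.1), ncol = 2))
  sep <- labeled_table(X, rep(c(0L, 1L), c(10, 5)))
  expect_identical(tomek_links(sep), sep)
})

test_that("SMOTE + Tomek links equals SMOTE when no links form after it", {
  X <- rbind(matrix(rnorm(40, sd = 0.2), ncol = 2),
             matrix(rnorm(10, 20, sd = 0.2), ncol = 2))
  tab <- labeled_table(X, rep(c(0L, 1L), c(20, 5)))
  expect_identical(smote_tomek(tab, k = 3, seed = 4),
                   smote(tab, k = 3, seed = 4))

  out <- smote_tomek(imbalanced_table(80, 20), k = 5, seed = 5)
  expect_s3_class(out, "labeled_table")
  expect_lte(abs(sum(out$labels == 0L) - sum(out$labels == 1L)), 160)
})

test_that("resampling is deterministic and provenance is complete", {
  tab <- imbalanced_table(40, 15, d = 3)
  for (m in c("random_undersampling", "tomek_links", "random_oversampling",
              "smote", "mwmote", "smote_tomek")) {
    a <- resample(tab, m, seed = 9)
    b <- resample(tab, m, seed = 9)
    expect_identical(a, b)
    # kept original rows are bit-identical to inputs
    kept <- a$provenance == "original"
    expect_identical(a$features[kept, , drop = FALSE],
                     tab$features[match(a$row_ids[kept], tab$row_ids), ,
                                  drop = FALSE])
    expect_equal(sum(a$provenance == "synthetic"),
                 nrow(a$features) - sum(kept))
    # undersamplers never create, oversamplers never delete
    tag <- resampler_spec(m)$type_tag
    if (tag == "undersampling")
      expect_equal(sum(a$provenance == "synthetic"), 0)
    if (tag == "oversampling")
      expect_true(all(tab$row_ids %in% a$row_ids))
  }
  one_class <- labeled_table(matrix(rnorm(10), ncol = 2), rep(0L, 5))
  for (m in c("random_undersampling", "tomek_links", "random_oversampling",
              "smote", "mwmote"))
    expect_error(resample(one_class, m, seed = 1), "both classes|minority")
})
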