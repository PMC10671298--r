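fake_averages <- function(ids, seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(compound_id = ids)
  for (nm in descriptor_names()) out[[nm]] <- rnorm(length(ids))
  out
}

test_that("assemble_features joins descriptors with energies and records exclusions", {
  ids <- sprintf("3%s", letters[1:10])
  avg <- fake_averages(ids)
  en <- tibble::tibble(compound_id = ids, dG_bind = rnorm(10, -30, 3))

  fm <- assemble_features(avg, en, exclude = "3c")
  expect_equal(nrow(fm), 9L)
  expect_false("3c" %in% fm$compound_id)
  expect_equal(attr(fm, "excluded_ids"), "3c")
  expect_equal(names(fm), c("compound_id", descriptor_names(), "dG_bind"))

  # exclude nothing: all rows retained
  expect_equal(nrow(assemble_features(avg, en)), 10L)

  # retained compound without an energy is an error naming both
  expect_error(assemble_features(avg, en[-4, ]), "'3d'.*dG_bind")
})

test_that("two perfectly correlated features load entirely on PC1", {
  feats <- tibble::tibble(
    compound_id = sprintf("c%d", 1:6),
    f1 = c(1, 2, 3, 4, 5, 6)
  )
  feats$f2 <- 2 * feats$f1 - 3
  fit <- pca_features(feats)
  expect_equal(fit$explained_variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("PCA reconstruction identity holds with all components kept", {
  sim <- make_feature_table(n_per_group = c(6, 6), group_shift = 2, seed = 4)
  fit <- pca_features(sim$features)
  recon <- as.matrix(fit$scores[, -1]) %*% t(fit$loadings)
  expect_lt(max(abs(recon - fit$standardized_matrix)), 1e-8)

  # loadings orthonormal; explained fractions non-increasing and sum to 1
  gram <- t(fit$loadings) %*% fit$loadings
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-9)
  ev <- fit$explained_variance_fraction
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(sum(ev), 1, tolerance = 1e-9)
})

test_that("PCA agrees with an independent eigen-decomposition oracle", {
  sim <- make_feature_table(n_per_group = c(5, 5), group_shift = 1.5, seed = 11)
  fit <- pca_features(sim$features)
  x <- scale(as.matrix(sim$features[, -1]))
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  n <- nrow(x)
  expect_equal(fit$sdev^2, eig$values[seq_along(fit$sdev)], tolerance = 1e-9)
  # loadings match up to sign
  for (k in 1:3) {
    expect_equal(abs(fit$loadings[, k]), abs(eig$vectors[, k]), tolerance = 1e-8,
      ignore_attr = TRUE)
  }
  # sign convention: each component's largest-|loading| entry is positive
  picks <- apply(fit$loadings, 2, function(col) col[which.max(abs(col))])
  expect_true(all(picks > 0))
})

test_that("scores are invariant (given the sign convention) to row permutation", {
  sim <- make_feature_table(group_shift = 2, seed = 6)
  fit1 <- pca_features(sim$features)
  perm <- sample(nrow(sim$features))
  fit2 <- pca_features(sim$features[perm, ])
  merged <- dplyr::inner_join(fit1$scores, fit2$scores, by = "compound_id",
    suffix = c("", ".p"))
  expect_equal(merged$PC1, merged$PC1.p, tolerance = 1e-9)
  expect_equal(merged$PC2, merged$PC2.p, tolerance = 1e-9)
})

test_that("an isotropic 2-feature cloud splits variance about evenly", {
  set.seed(12)
  feats <- tibble::tibble(
    compound_id = sprintf("c%03d", 1:2000),
    f1 = rnorm(2000), f2 = rnorm(2000)
  )
  ev <- pca_features(feats)$explained_variance_fraction
  expect_equal(ev[1], 0.5, tolerance = 0.05)
})

test_that("zero-variance features are rejected under standardization", {
  feats <- tibble::tibble(compound_id = c("a", "b", "c"), f1 = 1:3, f2 = 5)
  expect_error(pca_features(feats), "'f2'")
  expect_silent(pca_features(feats, standardize = FALSE))
})

test_that("planted two-group structure is recovered on PC1", {
  # deep separation (5 within-group SDs): PC1 must align with the grouping
  sim <- make_feature_table(n_per_group = c(10, 10), group_shift = 5, seed = 2)
  fit <- pca_features(sim$features)
  r <- cor(fit$scores$PC1, as.numeric(sim$labels$group == 2))
  expect_gt(abs(r), 0.8)

  # and the planted shift raises the alignment far above the null level
  r_at <- function(shift) {
    mean(vapply(1:20, function(seed) {
      sim <- make_feature_table(n_per_group = c(10, 10), group_shift = shift,
        seed = seed)
      abs(cor(pca_features(sim$features)$scores$PC1,
        as.numeric(sim$labels$group == 2)))
    }, numeric(1)))
  }
  expect_gt(r_at(3), r_at(0) + 0.3)
})

test_that("cluster_readout flags planted potent/weak separation", {
  sim <- make_feature_table(n_per_group = c(5, 5), group_shift = 3, seed = 3)
  fit <- pca_features(sim$features)
  # orient profiles so group 2 (shifted) is "potent": give it |effect| >= 40
  profiles <- tibble::tibble(
    compound_id = sim$labels$compound_id,
    activity_class = ifelse(sim$labels$group == 2, "PAM", "NA"),
    max_effect_pct = ifelse(sim$labels$group == 2, 70, 5)
  )
  ro <- cluster_readout(fit, profiles)
  # separation direction depends on the deterministic sign convention; the
  # potent group must sit together at one PC1 extreme, so the flag is decided
  pc1 <- ro$scores
  expect_false(is.na(ro$potent_separated))
  potent_mean <- mean(pc1$PC1[pc1$max_effect_pct >= 40])
  rest_mean <- mean(pc1$PC1[pc1$max_effect_pct < 40])
  expect_equal(ro$potent_separated, potent_mean > rest_mean)
  expect_gt(abs(potent_mean - rest_mean), 2) # strongly separated along PC1

  expect_setequal(ro$class_summary$activity_class, c("PAM", "NA"))
  expect_error(cluster_readout(fit, profiles[-1, ]), "no activity profile")
})

test_that("single-class input yields a not-applicable flag", {
  sim <- make_feature_table(group_shift = 0, seed = 5)
  fit <- pca_features(sim$features)
  profiles <- tibble::tibble(
    compound_id = sim$labels$compound_id,
    activity_class = "PAM", max_effect_pct = 70
  )
  ro <- cluster_readout(fit, profiles)
  expect_true(is.na(ro$potent_separated))
})

test_that("permuted labels separate at roughly chance rate", {
  sim <- make_feature_table(n_per_group = c(5, 5), group_shift = 3, seed = 7)
  fit <- pca_features(sim$features)
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    eff <- sample(ifelse(sim$labels$group == 2, 70, 5))
    profiles <- tibble::tibble(
      compound_id = sim$labels$compound_id,
      activity_class = ifelse(eff >= 40, "PAM", "NA"),
      max_effect_pct = eff
    )
    isTRUE(cluster_readout(fit, profiles)$potent_separated)
  }, logical(1))
  expect_gt(mean(hits), 0.25)
  expect_lt(mean(hits), 0.75)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- make_feature_table(seed = 8)
  fit <- pca_features(sim$features)

  td <- tidy(fit, matrix = "eigenvalues")
  expect_equal(nrow(td), length(fit$sdev))
  expect_equal(td$cumulative[length(fit$sdev)], 1, tolerance = 1e-9)

  sc <- tidy(fit, matrix = "scores")
  expect_equal(nrow(sc), nrow(sim$features) * length(fit$sdev))

  ld <- tidy(fit, matrix = "loadings")
  expect_setequal(unique(ld$feature), c(descriptor_names(), "dG_bind"))

  gl <- glance(fit)
  expect_equal(gl$n_compounds, 20L)
  expect_equal(gl$n_features, 9L)

  profiles <- tibble::tibble(
    compound_id = sim$labels$compound_id,
    activity_class = ifelse(sim$labels$group == 2, "PAM", "NA"),
    max_effect_pct = ifelse(sim$labels$group == 2, 60, 0)
  )
  p <- autoplot(fit, profiles)
  expect_s3_class(p, "ggplot")
})
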