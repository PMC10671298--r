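#' Assemble the compound feature matrix
#'
#' Joins per-compound window-averaged descriptors with supplied MM/GBSA
#' binding energies into the compounds x 9 feature table used for the PCA
#' correlation (the eight arrangement descriptors plus `dG_bind`, kcal/mol).
#' Compounds listed in `exclude` are dropped and recorded; any retained
#' compound missing a feature is an error naming compound and feature.
#'
#' @param averages Tibble with `compound_id` and the eight descriptor columns
#'   (one row per compound; window-averaged values).
#' @param energies Tibble with `compound_id` and `dG_bind` (kcal/mol).
#' @param exclude Character vector of compound ids to drop (e.g. an outlier
#'   distorting the PCA model, or inactive references).
#' @return Tibble `compound_id` + 9 feature columns, with attribute
#'   `excluded_ids`.
#' @export
assemble_features <- function(averages, energies, exclude = character()) {
  needed <- descriptor_names()
  miss_col <- setdiff(needed, names(averages))
  if (length(miss_col) > 0L) {
    abort(paste0("averages table lacks descriptor column '", miss_col[1], "'"))
  }
  if (!all(c("compound_id", "dG_bind") %in% names(energies))) {
    abort("energies table must have columns compound_id and dG_bind")
  }
  out <- averages |>
    dplyr::select("compound_id", dplyr::all_of(needed)) |>
    dplyr::left_join(dplyr::select(energies, "compound_id", "dG_bind"),
      by = "compound_id") |>
    dplyr::filter(!.data$compound_id %in% exclude)
  for (feat in c(needed, "dG_bind")) {
    bad <- which(!is.finite(out[[feat]]))
    if (length(bad) > 0L) {
      abort(paste0("compound '", out$compound_id[bad[1]],
        "' is missing feature '", feat, "'"))
    }
  }
  attr(out, "excluded_ids") <- intersect(exclude, averages$compound_id)
  out
}

#' Principal component analysis of the feature matrix
#'
#' Centers (and, by default, scales to unit variance) the features and
#' decomposes the resulting covariance — correlation-matrix PCA by default,
#' appropriate because the features mix degrees, Å and kcal/mol. Components
#' are ordered by decreasing variance and each component's sign is fixed so
#' that its largest-magnitude loading is positive, making scores and plots
#' reproducible.
#'
#' @param features Feature tibble from [assemble_features()] (a `compound_id`
#'   column plus numeric feature columns).
#' @param standardize Scale features to unit variance (default `TRUE`).
#'   Requires every feature to have positive variance.
#' @return An object of class `lbd_pca`: list with `scores` (tibble,
#'   `compound_id` + `PC1..PCk`), `loadings` (features x components matrix),
#'   `sdev`, `explained_variance_fraction`, `center`, `scale`,
#'   `feature_names`, `standardized_matrix`.
#' @examples
#' sim <- make_feature_table(group_shift = 3, seed = 1)
#' fit <- pca_features(sim$features)
#' glance(fit)
#' @export
pca_features <- function(features, standardize = TRUE) {
  stopifnot("compound_id" %in% names(features))
  x <- as.matrix(features[, setdiff(names(features), "compound_id"), drop = FALSE])
  rownames(x) <- features$compound_id
  if (nrow(x) < 2L) abort("PCA needs at least 2 compounds")
  if (standardize) {
    v <- apply(x, 2, sd)
    if (any(v <= 0)) {
      abort(paste0("zero-variance feature under standardization: '",
        colnames(x)[which(v <= 0)[1]], "'"))
    }
  }
  fit <- prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(fit$rotation, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  ev <- fit$sdev^2
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(compound_id = features$compound_id),
        tibble::as_tibble(scores)
      ),
      loadings = rotation,
      sdev = fit$sdev,
      explained_variance_fraction = ev / sum(ev),
      center = fit$center,
      scale = if (standardize) fit$scale else rep(1, ncol(x)),
      feature_names = colnames(x),
      standardized_matrix = scale(x, center = fit$center,
        scale = if (standardize) fit$scale else FALSE)
    ),
    class = "lbd_pca"
  )
}

#' @export
print.lbd_pca <- function(x, ...) {
  cat("<lbd_pca> ", nrow(x$scores), " compounds, ", length(x$feature_names),
    " features\n", sep = "")
  ev <- x$explained_variance_fraction
  cat("  variance explained: ",
    paste0(sprintf("PC%d %.1f%%", seq_along(ev), 100 * ev), collapse = ", "),
    "\n", sep = "")
  invisible(x)
}

#' Tidy a PCA fit
#'
#' broom-style tidier. `matrix = "scores"` returns one row per compound and
#' component; `"loadings"` one row per feature and component; `"eigenvalues"`
#' one row per component with the variance accounting.
#'
#' @param x An `lbd_pca` object.
#' @param matrix Which quantity to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lbd_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  k <- length(x$sdev)
  if (matrix == "scores") {
    tidyr::pivot_longer(x$scores, -"compound_id",
      names_to = "component", values_to = "score") |>
      dplyr::mutate(component = as.integer(sub("^PC", "", .data$component)))
  } else if (matrix == "loadings") {
    tibble::tibble(
      feature = rep(rownames(x$loadings), times = k),
      component = rep(seq_len(k), each = nrow(x$loadings)),
      loading = as.vector(x$loadings)
    )
  } else {
    tibble::tibble(
      component = seq_len(k),
      std_dev = x$sdev,
      variance_fraction = x$explained_variance_fraction,
      cumulative = cumsum(x$explained_variance_fraction)
    )
  }
}

#' Glance at a PCA fit
#' @param x An `lbd_pca` object.
#' @param ... Unused.
#' @return One-row tibble: compounds, features, PC1/PC2 variance fractions.
#' @export
glance.lbd_pca <- function(x, ...) {
  ev <- x$explained_variance_fraction
  tibble::tibble(
    n_compounds = nrow(x$scores),
    n_features = length(x$feature_names),
    pc1_variance_fraction = ev[1],
    pc2_variance_fraction = if (length(ev) >= 2) ev[2] else NA_real_
  )
}

#' Activity clustering readout in principal-component space
#'
#' Summarises where each activity class sits along PC1 and tests the
#' qualitative clustering claim: do the strong modulators (|max effect| at or
#' above `potent_threshold_pct`) sit at higher PC1 than the rest? The flag is
#' `NA` when either side of the split is empty (e.g. a single-class input).
#'
#' @param fit An `lbd_pca` object.
#' @param profiles Tibble from [classify_modulators()] covering every scored
#'   compound (`compound_id`, `activity_class`, `max_effect_pct`).
#' @param potent_threshold_pct Potency cut in percent (default 40, separating
#'   the strong modulators from moderate/inactive ones).
#' @return Object of class `lbd_readout`: list with `class_summary` (tibble:
#'   class, n, mean/min/max PC1), `potent_separated` (logical or `NA`),
#'   `potent_threshold_pct`, and the joined `scores` table.
#' @export
cluster_readout <- function(fit, profiles, potent_threshold_pct = 40) {
  sc <- fit$scores
  missing_prof <- setdiff(sc$compound_id, profiles$compound_id)
  if (length(missing_prof) > 0L) {
    abort(paste0("no activity profile for scored compound '", missing_prof[1], "'"))
  }
  joined <- dplyr::inner_join(
    sc,
    dplyr::select(profiles, "compound_id", "activity_class", "max_effect_pct"),
    by = "compound_id"
  )
  class_summary <- joined |>
    dplyr::group_by(.data$activity_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pc1 = mean(.data$PC1),
      min_pc1 = min(.data$PC1),
      max_pc1 = max(.data$PC1),
      .groups = "drop"
    )
  potent <- abs(joined$max_effect_pct) >= potent_threshold_pct
  sep <- if (any(potent) && any(!potent)) {
    mean(joined$PC1[potent]) > mean(joined$PC1[!potent])
  } else {
    NA
  }
  structure(
    list(
      class_summary = class_summary,
      potent_separated = sep,
      potent_threshold_pct = potent_threshold_pct,
      scores = joined
    ),
    class = "lbd_readout"
  )
}

#' @export
print.lbd_readout <- function(x, ...) {
  cat("<lbd_readout> potent (|effect| >= ", x$potent_threshold_pct,
    "%) separated along PC1: ", format(x$potent_separated), "\n", sep = "")
  print(x$class_summary)
  invisible(x)
}

#' Scatter plot of compounds in principal-component space
#'
#' PC1 vs PC2 scores, coloured by activity class when `profiles` is given,
#' with potentiation percentages as point labels — the standard
#' activity-clustering readout figure.
#'
#' @param object An `lbd_pca` object.
#' @param profiles Optional [classify_modulators()] output.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lbd_pca <- function(object, profiles = NULL, ...) {
  ev <- 100 * object$explained_variance_fraction
  df <- object$scores
  if (!is.null(profiles)) {
    df <- dplyr::inner_join(df,
      dplyr::select(profiles, "compound_id", "activity_class", "max_effect_pct"),
      by = "compound_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
      colour = .data$activity_class)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::geom_text(
        ggplot2::aes(label = ifelse(.data$activity_class == "PAM",
          sprintf("+%d%%", round(.data$max_effect_pct)), .data$compound_id)),
        vjust = -0.9, show.legend = FALSE
      )
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::geom_text(ggplot2::aes(label = .data$compound_id), vjust = -0.9)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ev[1]),
      y = if (length(ev) >= 2) sprintf("PC2 (%.1f%%)", ev[2]) else "PC2",
      colour = "activity"
    ) +
    ggplot2::theme_minimal()
}
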