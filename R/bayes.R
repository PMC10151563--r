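#' Naive-Bayes MSI classifier
#'
#' For every marker the classifier models the deletion frequency `d` and
#' the allelic bias `b` with Beta class-conditional densities, one pair per
#' class (MSI-H, MSS), fitted by the method of moments to
#' pseudocount-shrunk values. A sample's MSI score is the summed
#' log-likelihood ratio over its evaluable markers (natural logs, equal
#' class priors):
#' `S = sum over markers of [log f_MSI-H(d) - log f_MSS(d) +
#' log g_MSI-H(b) - log g_MSS(b)]`.
#'
#' A score above 0 classifies the sample MSI-H, otherwise MSS (ties go
#' conservatively to MSS); samples with too few evaluable markers are
#' non-evaluable. The score scale depends on these density choices and is
#' not comparable across classifier implementations.
#'
#' @name msi_bayes
NULL

#' Classifier fitting configuration
#'
#' @param epsilon pseudocount (reads) used to shrink per-sample
#'   frequencies away from 0 and 1: `d' = (d * D + epsilon) / (D + 2 *
#'   epsilon)`. Default 1 read.
#' @param min_marker_fraction minimum fraction of the panel that must be
#'   evaluable for a sample to receive a call (default 0.5).
#' @param var_floor lower bound on the moment-matched variance; keeps Beta
#'   fits from degenerating when a class's training values are nearly
#'   constant (default 1e-3).
#' @param enforce_monotone reject per-marker fits whose log-likelihood
#'   ratio is not monotone non-decreasing in `d` (default `TRUE`); a
#'   rejected marker falls back to a pooled fit shared by both classes, so
#'   it contributes nothing to the score. Rejected markers are listed in
#'   the classifier's `rejected_markers`.
#' @return a `bayes_config` list.
#' @export
bayes_config <- function(epsilon = 1, min_marker_fraction = 0.5,
                         var_floor = 1e-3, enforce_monotone = TRUE) {
  stopifnot(epsilon > 0, var_floor > 0)
  assert_prob(min_marker_fraction, "min_marker_fraction")
  structure(list(epsilon = epsilon, min_marker_fraction = min_marker_fraction,
                 var_floor = var_floor,
                 enforce_monotone = isTRUE(enforce_monotone)),
            class = "bayes_config")
}

# Pseudocount shrinkage of a proportion observed as x/n reads.
shrink_prop <- function(p, n, epsilon) {
  (p * n + epsilon) / (n + 2 * epsilon)
}

# Method-of-moments Beta fit with a variance floor; returns c(alpha, beta).
fit_beta_mom <- function(x, var_floor) {
  m <- mean(x)
  v <- max(stats::var(x), var_floor)
  # keep the fit proper: moment equations need v < m (1 - m)
  v <- min(v, 0.95 * m * (1 - m))
  k <- m * (1 - m) / v - 1
  c(alpha = m * k, beta = (1 - m) * k)
}

#' Fit the naive-Bayes MSI classifier
#'
#' @param profiles data frame of training profiles (columns `sample_id`,
#'   `marker_id`, `depth`, `d`, `b`, `evaluable`) covering the panel.
#' @param labels named character vector, `sample_id` -> `"MSI-H"` or
#'   `"MSS"`; at least two samples per class.
#' @param panel marker registry rows defining the panel.
#' @param panel_name label stored with the classifier.
#' @param config a [bayes_config()].
#' @return an `msi_classifier`: per-marker Beta parameters for `d` and `b`
#'   under both classes, the pseudocount, and training metadata.
#' @export
fit_msi_classifier <- function(profiles, labels, panel,
                               panel_name = "panel", config = bayes_config()) {
  classes <- c("MSI-H", "MSS")
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop_msi("unknown training label(s): ", paste(bad, collapse = ", "))
  if (!all(classes %in% labels)) {
    stop_msi("training set must contain both MSI-H and MSS samples")
  }
  if (any(table(labels) < 2)) stop_msi("need at least 2 samples per class")
  profiles <- profiles[profiles$sample_id %in% names(labels), , drop = FALSE]
  profiles$label <- labels[profiles$sample_id]

  fit_one <- function(mk_id) {
    mk <- profiles[profiles$marker_id == mk_id & profiles$evaluable, ,
                   drop = FALSE]
    if (nrow(mk) == 0L) {
      stop_msi("marker absent from all training samples: ", mk_id)
    }
    out <- list(marker_id = mk_id)
    for (cl in classes) {
      sub <- mk[mk$label == cl, , drop = FALSE]
      if (nrow(sub) < 2L) {
        stop_msi(sprintf("marker %s has fewer than 2 evaluable %s training samples",
                         mk_id, cl))
      }
      d_shr <- shrink_prop(sub$d, sub$depth, config$epsilon)
      db <- fit_beta_mom(d_shr, config$var_floor)
      # allelic bias: fitted over samples that actually carry deletions
      with_del <- sub[sub$d > 0, , drop = FALSE]
      if (nrow(with_del) >= 2L) {
        n_del <- round(with_del$d * with_del$depth)
        b_shr <- shrink_prop(with_del$b, n_del, config$epsilon)
        bb <- fit_beta_mom(b_shr, config$var_floor)
      } else {
        bb <- c(alpha = 1, beta = 1)  # uniform fallback
      }
      key <- if (cl == "MSI-H") "msih" else "mss"
      out[[paste0("d_alpha_", key)]] <- unname(db["alpha"])
      out[[paste0("d_beta_", key)]] <- unname(db["beta"])
      out[[paste0("b_alpha_", key)]] <- unname(bb["alpha"])
      out[[paste0("b_beta_", key)]] <- unname(bb["beta"])
    }
    # pooled fit of d over both classes, used when a fit is rejected
    d_all <- shrink_prop(mk$d, mk$depth, config$epsilon)
    pooled <- fit_beta_mom(d_all, config$var_floor)
    out$d_alpha_pooled <- unname(pooled["alpha"])
    out$d_beta_pooled <- unname(pooled["beta"])
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, lapply(panel$marker_id, fit_one))

  if (any(params$d_alpha_msih <= 0 | params$d_beta_msih <= 0 |
            params$d_alpha_mss <= 0 | params$d_beta_mss <= 0)) {
    stop_msi("degenerate Beta fit (non-positive shape)")
  }
  rejected <- character(0)
  if (config$enforce_monotone) {
    # log LR of two Betas is monotone non-decreasing in d iff
    # alpha_H >= alpha_S and beta_H <= beta_S; a violated discriminative
    # fit is rejected: both classes revert to the pooled fit and the
    # marker becomes uninformative for d (and b)
    mono <- params$d_alpha_msih >= params$d_alpha_mss &
      params$d_beta_msih <= params$d_beta_mss
    if (!all(mono)) {
      rejected <- params$marker_id[!mono]
      for (col in c("d_alpha_msih", "d_alpha_mss")) {
        params[[col]][!mono] <- params$d_alpha_pooled[!mono]
      }
      for (col in c("d_beta_msih", "d_beta_mss")) {
        params[[col]][!mono] <- params$d_beta_pooled[!mono]
      }
      for (col in c("b_alpha_msih", "b_alpha_mss",
                    "b_beta_msih", "b_beta_mss")) {
        params[[col]][!mono] <- 1
      }
    }
  }
  params$d_alpha_pooled <- NULL
  params$d_beta_pooled <- NULL
  n_tab <- table(labels)
  structure(list(panel = panel_name, markers = params,
                 epsilon = config$epsilon,
                 min_marker_fraction = config$min_marker_fraction,
                 rejected_markers = rejected,
                 training = list(n_msih = unname(n_tab[["MSI-H"]]),
                                 n_mss = unname(n_tab[["MSS"]]))),
            class = "msi_classifier")
}

#' @export
print.msi_classifier <- function(x, ...) {
  cat(sprintf("Naive-Bayes MSI classifier: panel %s (%d markers), trained on %d MSI-H / %d MSS\n",
              x$panel, nrow(x$markers), x$training$n_msih, x$training$n_mss))
  invisible(x)
}

#' Score a sample
#'
#' @param profiles the sample's per-marker profile data frame (one row per
#'   panel marker, as from [profile_sample()]).
#' @param classifier an `msi_classifier` for the same panel.
#' @param sample_id optional id carried into the result.
#' @return an `msi_score` list: `score`, `n_markers_used`, `call`
#'   (`"MSI-H"` when the score is strictly positive, `"MSS"` otherwise,
#'   `"NE"` when fewer than `min_marker_fraction` of the panel is
#'   evaluable).
#' @export
score_msi_sample <- function(profiles, classifier, sample_id = NA_character_) {
  extra <- setdiff(profiles$marker_id, classifier$markers$marker_id)
  if (length(extra)) {
    stop_msi("profiles contain markers unknown to the classifier: ",
             paste(extra, collapse = ", "))
  }
  pm <- merge(profiles, classifier$markers, by = "marker_id", sort = FALSE)
  use <- pm[pm$evaluable, , drop = FALSE]
  n_panel <- nrow(classifier$markers)
  if (nrow(use) < classifier$min_marker_fraction * n_panel) {
    return(structure(list(sample_id = sample_id, panel = classifier$panel,
                          score = NA_real_, n_markers_used = nrow(use),
                          call = "NE"), class = "msi_score"))
  }
  eps <- classifier$epsilon
  d_shr <- shrink_prop(use$d, use$depth, eps)
  s <- stats::dbeta(d_shr, use$d_alpha_msih, use$d_beta_msih, log = TRUE) -
    stats::dbeta(d_shr, use$d_alpha_mss, use$d_beta_mss, log = TRUE)
  n_del <- round(use$d * use$depth)
  has_del <- n_del > 0
  if (any(has_del)) {
    b_shr <- shrink_prop(use$b[has_del], n_del[has_del], eps)
    s[has_del] <- s[has_del] +
      stats::dbeta(b_shr, use$b_alpha_msih[has_del], use$b_beta_msih[has_del],
                   log = TRUE) -
      stats::dbeta(b_shr, use$b_alpha_mss[has_del], use$b_beta_mss[has_del],
                   log = TRUE)
  }
  score <- sum(s)
  structure(list(sample_id = sample_id, panel = classifier$panel,
                 score = score, n_markers_used = nrow(use),
                 call = if (score > 0) "MSI-H" else "MSS"),
            class = "msi_score")
}

#' Stratified k-fold cross-validation of the classifier
#'
#' @param profiles training profiles (long format, all samples).
#' @param labels named label vector as in [fit_msi_classifier()].
#' @param panel marker registry rows.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param config a [bayes_config()].
#' @return list with `accuracy`, per-sample `calls`, and `fold` assignment.
#' @export
cross_validate <- function(profiles, labels, panel, k = 5, seed = 1,
                           config = bayes_config()) {
  if (k < 2) stop_msi("k must be at least 2")
  if (any(table(labels) < k)) stop_msi("k exceeds the size of a class")
  ids <- names(labels)
  fold <- integer(length(ids))
  names(fold) <- ids
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- sample(ids[labels == cl])
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  calls <- setNames(character(length(ids)), ids)
  for (f in seq_len(k)) {
    test_ids <- ids[fold == f]
    train_ids <- setdiff(ids, test_ids)
    clf <- fit_msi_classifier(
      profiles[profiles$sample_id %in% train_ids, , drop = FALSE],
      labels[train_ids], panel, config = config)
    for (sid in test_ids) {
      prof <- profiles[profiles$sample_id == sid, , drop = FALSE]
      calls[sid] <- score_msi_sample(prof, clf, sid)$call
    }
  }
  scored <- calls != "NE"
  list(accuracy = mean(calls[scored] == labels[names(calls)[scored]]),
       calls = calls, fold = fold)
}

#' Serialize / deserialize a trained classifier
#'
#' @param classifier an `msi_classifier`.
#' @param path JSON file path.
#' @return `write_msi_classifier()` returns `path` invisibly;
#'   `read_msi_classifier()` the restored classifier.
#' @export
write_msi_classifier <- function(classifier, path) {
  jsonlite::write_json(unclass(classifier), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_msi_classifier
#' @export
read_msi_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$markers <- as.data.frame(x$markers, stringsAsFactors = FALSE)
  structure(x, class = "msi_classifier")
}
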