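#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when both samples have at most 10 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Two-sided.
#'
#' @param x,y Numeric samples (nonempty).
#' @return A list with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone, capped at 1, returned in the input
#' order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param n1,mean1,sd1 First sample size, mean, SD.
#' @param n2,mean2,sd2 Second sample size, mean, SD.
#' @return A list with `t`, `df`, `p_value` (two-sided).
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("SD must be nonnegative", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Exhaustive enumeration of all tables with the observed margins; the
#' two-sided p-value is the total hypergeometric probability of tables no
#' more probable than the observed one (with a small relative tolerance for
#' floating-point comparisons). Feasible for the small tables this package
#' targets (up to a few columns at n of a few dozen).
#'
#' @param tab Integer matrix of counts.
#' @return A list with `p_value` and `n_tables` enumerated.
#' @export
freeman_halton <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  log_prob <- function(m) log_const - sum(lgamma(m + 1))
  obs_lp <- log_prob(tab)
  r <- nrow(tab)
  cc <- ncol(tab)
  total <- 0
  count <- 0L
  # fill rows 1..r-1 cell by cell; the last cell of each row and the whole
  # last row are fixed by the margins
  fill_row <- function(rows_done, i, j, row_vec, row_left, col_left) {
    if (j == cc) {
      if (row_left > col_left[cc]) return(invisible())
      row_vec[cc] <- row_left
      cl <- col_left - row_vec
      if (i == r - 1L) {
        m <- rbind(do.call(rbind, c(rows_done, list(row_vec))), cl)
        count <<- count + 1L
        lp <- log_prob(m)
        if (lp <= obs_lp + 1e-7) total <<- total + exp(lp)
      } else {
        fill_row(c(rows_done, list(row_vec)), i + 1L, 1L,
                 numeric(cc), rs[i + 1L], cl)
      }
      return(invisible())
    }
    for (v in 0:min(row_left, col_left[j])) {
      row_vec[j] <- v
      fill_row(rows_done, i, j + 1L, row_vec, row_left - v, col_left)
    }
  }
  if (r == 1L || cc == 1L) return(list(p_value = 1, n_tables = 1L))
  fill_row(list(), 1L, 1L, numeric(cc), rs[1L], cs)
  list(p_value = min(1, total), n_tables = count)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided: the sum of hypergeometric probabilities of tables at most as
#' probable as the one observed.
#'
#' @param tab 2 x 2 integer matrix.
#' @return A list with `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("table must be 2 x 2", call. = FALSE)
  list(p_value = stats::fisher.test(tab)$p.value)
}

#' Bundled demographic summary of the emulated patient cohort
#'
#' The printed group-level demographics of the two patient groups the
#' synthetic cohorts emulate (25 left- and 16 right-lateralized patients):
#' age and onset age as summary statistics, gender and focal region as
#' 2 x 2 tables, MRI status and language laterality as 2 x 4 tables. These
#' serve as inputs to [cohort_matching_tests()].
#'
#' @return A list of named test-input entries.
#' @export
patient_demographics <- function() {
  list(
    age = list(type = "t_summary",
               data = list(n1 = 25, mean1 = 16.6, sd1 = 6.2,
                           n2 = 16, mean2 = 16.9, sd2 = 8.0)),
    onset_age = list(type = "t_summary",
                     data = list(n1 = 25, mean1 = 8.7, sd1 = 7.9,
                                 n2 = 16, mean2 = 8.5, sd2 = 5.7)),
    gender = list(type = "fisher",
                  data = matrix(c(13, 12, 10, 6), 2, byrow = TRUE,
                                dimnames = list(c("LP", "RP"),
                                                c("M", "F")))),
    focal_region = list(type = "fisher",
                        data = matrix(c(7, 18, 6, 10), 2, byrow = TRUE,
                                      dimnames = list(c("LP", "RP"),
                                                      c("TLE", "TELE")))),
    mri_status = list(type = "freeman_halton",
                      data = matrix(c(3, 6, 3, 13, 3, 4, 1, 8), 2,
                                    byrow = TRUE,
                                    dimnames = list(c("LP", "RP"),
                                                    c("Normal", "FCD",
                                                      "MTS", "Other")))),
    language_laterality = list(type = "freeman_halton",
                               data = matrix(c(11, 7, 3, 4, 11, 3, 0, 2), 2,
                                             byrow = TRUE,
                                             dimnames = list(
                                               c("LP", "RP"),
                                               c("left", "right",
                                                 "bilateral", "unknown"))))
  )
}

#' Cohort-matching test battery
#'
#' Runs the appropriate matching test per variable: pooled-variance t from
#' summary statistics (`t_summary`), Fisher's exact test for 2 x 2 tables
#' (`fisher`), the Freeman-Halton extension for larger tables
#' (`freeman_halton`), and the Wilcoxon rank-sum test for raw ordinal
#' values (`wilcoxon`, data = list(x, y)).
#'
#' @param variables A list of entries as produced by
#'   [patient_demographics()].
#' @return A data.frame with columns `variable`, `test`, `p_value`.
#' @export
cohort_matching_tests <- function(variables = patient_demographics()) {
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    p <- switch(v$type,
      t_summary = do.call(t_test_from_summary, v$data)$p_value,
      fisher = fisher_exact_2x2(v$data)$p_value,
      freeman_halton = freeman_halton(v$data)$p_value,
      wilcoxon = wilcoxon_ranksum(v$data$x, v$data$y)$p_value,
      stop("unknown test type: ", v$type, call. = FALSE)
    )
    data.frame(variable = nm, test = v$type, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Gaussian Naive-Bayes with repeated stratified cross-validation
# ---------------------------------------------------------------------------

#' @keywords internal
gnb_train <- function(x, y, var_floor_frac = 1e-9) {
  classes <- sort(unique(y))
  floor_val <- var_floor_frac * max(apply(x, 2, stats::var), 1e-300)
  models <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xc),
         var = pmax(apply(xc, 2, stats::var), floor_val),
         prior = nrow(xc) / nrow(x))
  })
  names(models) <- classes
  list(classes = classes, models = models)
}

#' @keywords internal
gnb_posterior <- function(fit, x) {
  logp <- vapply(fit$classes, function(cl) {
    m <- fit$models[[cl]]
    rowSums(t(stats::dnorm(t(x), mean = m$mean, sd = sqrt(m$var),
                           log = TRUE))) + log(m$prior)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) logp <- matrix(logp, nrow = 1,
                                   dimnames = list(NULL, fit$classes))
  mx <- apply(logp, 1, max)
  p <- exp(logp - mx)
  p / rowSums(p)
}

# area under the ROC curve by the rank (Mann-Whitney) formula, ties averaged
#' @keywords internal
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  fold
}

#' Naive-Bayes repeated cross-validated classification
#'
#' Gaussian Naive-Bayes (per-class feature means and variances with a
#' variance floor) evaluated by `n_repeats` random `n_folds`-fold
#' partitions. Folds are stratified by default so every training fold
#' contains every class; with `stratified = FALSE`, partitions that leave a
#' training fold without some class are re-drawn. Per repeat, each subject
#' is tested exactly once and accuracy, one-vs-rest sensitivity,
#' specificity, precision, and AUC (from class posterior probabilities) are
#' computed over all subjects; the report gives mean and SD across repeats.
#'
#' @param x Numeric feature matrix (subjects x features) or data.frame.
#' @param y Class labels (character or factor).
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of random partitions (default 100).
#' @param seed Integer seed.
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @return A list of class `hemilat_cv_report`: `accuracy` (mean, sd),
#'   `per_class` (data.frame of metric means and SDs), and
#'   `weighted_average` (class-prevalence-weighted metrics).
#' @export
nb_crossvalidate <- function(x, y, n_folds = 10, n_repeats = 100, seed = 1,
                             stratified = TRUE) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nrow(x) < n_folds) {
    stop("need at least n_folds subjects", call. = FALSE)
  }
  n <- nrow(x)
  metric_names <- c("sensitivity", "specificity", "precision", "auc")
  acc <- numeric(n_repeats)
  per_class <- array(NA_real_,
                     dim = c(n_repeats, length(classes),
                             length(metric_names)),
                     dimnames = list(NULL, classes, metric_names))
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      repeat {
        fold <- if (stratified) {
          stratified_folds(y, n_folds)
        } else {
          sample(rep_len(sample(n_folds), n))
        }
        ok <- all(vapply(seq_len(n_folds), function(f) {
          length(unique(y[fold != f])) == length(classes)
        }, logical(1)))
        if (ok) break
      }
      post <- matrix(NA_real_, n, length(classes),
                     dimnames = list(NULL, classes))
      for (f in seq_len(n_folds)) {
        test <- which(fold == f)
        if (length(test) == 0) next
        fit <- gnb_train(x[-test, , drop = FALSE], y[-test])
        post[test, fit$classes] <- gnb_posterior(fit,
                                                 x[test, , drop = FALSE])
      }
      pred <- classes[max.col(post, ties.method = "first")]
      acc[rep_i] <- mean(pred == y)
      for (cl in classes) {
        tp <- sum(pred == cl & y == cl)
        fn <- sum(pred != cl & y == cl)
        fp <- sum(pred == cl & y != cl)
        tn <- sum(pred != cl & y != cl)
        per_class[rep_i, cl, "sensitivity"] <- tp / (tp + fn)
        per_class[rep_i, cl, "specificity"] <- tn / (tn + fp)
        per_class[rep_i, cl, "precision"] <-
          if (tp + fp == 0) 0 else tp / (tp + fp)
        per_class[rep_i, cl, "auc"] <- auc_rank(post[, cl], y == cl)
      }
    }
  })
  prevalence <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  pc <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl,
               t(c(vapply(metric_names, function(m) {
                 mean(per_class[, cl, m])
               }, numeric(1)),
               stats::setNames(vapply(metric_names, function(m) {
                 stats::sd(per_class[, cl, m])
               }, numeric(1)), paste0(metric_names, "_sd")))),
               stringsAsFactors = FALSE)
  }))
  weighted <- vapply(metric_names, function(m) {
    sum(prevalence * pc[[m]])
  }, numeric(1))
  structure(list(
    accuracy = c(mean = mean(acc), sd = stats::sd(acc)),
    per_class = pc,
    weighted_average = weighted,
    n_folds = n_folds, n_repeats = n_repeats, classes = classes
  ), class = "hemilat_cv_report")
}

#' Per-area node counts
#'
#' Counts, for a flagged node set (e.g., nodes of an NBS component or nodes
#' with a significant local measure), how many nodes fall in each of the 48
#' atlas areas.
#'
#' @param nodes Integer vector of node ids (subset of 1..246).
#' @param atlas Atlas table.
#' @return A data.frame with `area_group`, `hemisphere`, `count` covering
#'   all 48 areas (zero counts included).
#' @export
area_summary <- function(nodes, atlas) {
  validate_atlas(atlas)
  if (length(nodes) > 0 && !all(nodes %in% atlas$node_id)) {
    stop("unknown node id", call. = FALSE)
  }
  areas <- unique(atlas[, c("area_group", "hemisphere")])
  areas <- areas[order(areas$hemisphere, areas$area_group), ]
  areas$count <- vapply(areas$area_group, function(a) {
    sum(atlas$node_id[atlas$area_group == a] %in% nodes)
  }, integer(1))
  rownames(areas) <- NULL
  areas
}

#' Area-level overlap between several node sets
#'
#' For each pair of node sets (e.g., NBS membership and each significant
#' local measure), counts the atlas areas in which both sets have at least
#' one flagged node.
#'
#' @param node_sets Named list of integer node-id vectors.
#' @param atlas Atlas table.
#' @return A list with `per_area` (counts per area per set) and `overlap`
#'   (data.frame of set pairs and matched-area counts).
#' @export
area_overlap_summary <- function(node_sets, atlas) {
  summaries <- lapply(node_sets, area_summary, atlas = atlas)
  per_area <- summaries[[1]][, c("area_group", "hemisphere")]
  for (nm in names(summaries)) per_area[[nm]] <- summaries[[nm]]$count
  pairs <- utils::combn(names(node_sets), 2)
  overlap <- data.frame(
    set_a = pairs[1, ], set_b = pairs[2, ],
    matched_areas = vapply(seq_len(ncol(pairs)), function(k) {
      sum(per_area[[pairs[1, k]]] > 0 & per_area[[pairs[2, k]]] > 0)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  list(per_area = per_area, overlap = overlap)
}

#' Subject-level feature table of quadrant global measures
#'
#' Builds the classifier input: one row per subject, one column per
#' (band, quadrant, measure) combination of GE, CPL and T.
#'
#' @param cohort An adjacency-mode `hemilat_cohort`.
#' @param atlas Atlas table.
#' @param density Proportional threshold density (default 0.10).
#' @param bands Bands to include (default: all bands in the cohort).
#' @return A data.frame with `subject_id`, `label`, then numeric features
#'   named `<band>_<side>_<measure>`.
#' @export
cohort_feature_table <- function(cohort, atlas = default_atlas(),
                                 density = 0.10, bands = cohort$bands) {
  rows <- lapply(cohort$subjects, function(s) {
    gm <- quadrant_global_measures(s$matrices[bands], atlas, density)
    vals <- stats::setNames(gm$value,
                            paste(gm$band,
                                  sub("_intra", "", gm$network),
                                  gm$measure, sep = "_"))
    cbind(data.frame(subject_id = s$id, label = s$group,
                     stringsAsFactors = FALSE),
          as.data.frame(t(vals)))
  })
  do.call(rbind, rows)
}

#' Groupwise Wilcoxon tests with FDR correction over features
#'
#' Applies the Wilcoxon rank-sum test to every feature column between two
#' label groups and Benjamini-Hochberg-adjusts the p-values across all
#' features supplied (the feature-selection step: bands x measures x
#' quadrants).
#'
#' @param features Feature table from [cohort_feature_table()].
#' @param group_a,group_b Label values to compare.
#' @return A data.frame with `feature`, `p_value`, `p_fdr`, and the sign of
#'   the group-A minus group-B median difference.
#' @export
feature_group_tests <- function(features, group_a = "RP", group_b = "LP") {
  num_cols <- setdiff(names(features), c("subject_id", "label"))
  a <- features$label == group_a
  b <- features$label == group_b
  res <- do.call(rbind, lapply(num_cols, function(f) {
    x <- features[[f]][a]
    y <- features[[f]][b]
    data.frame(feature = f,
               p_value = wilcoxon_ranksum(x, y)$p_value,
               direction = sign(stats::median(x) - stats::median(y)),
               stringsAsFactors = FALSE)
  }))
  res$p_fdr <- fdr_bh(res$p_value)
  res[, c("feature", "p_value", "p_fdr", "direction")]
}
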