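#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control: with `m` ordered p-values, rejects
#' all hypotheses up to the largest `k` with `p_(k) <= k/m * alpha`.
#' Implemented through [stats::p.adjust()]; flags are monotone in the
#' sorted p-values by construction.
#'
#' @param p numeric vector of p-values (`NA`s excluded from the family and
#'   returned as `NA` flags).
#' @param alpha family false-discovery level.
#' @return logical vector of rejections, same length as `p`.
#' @export
bh_significant <- function(p, alpha = 0.05) {
  out <- rep(NA, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= alpha
  out
}

.spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(n = length(x), rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(n = length(x), rho = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlations of markers with outcomes, BH-corrected
#'
#' Correlates every marker with each outcome, separately per transcript
#' version, and applies the Benjamini-Hochberg procedure within each
#' (outcome x version) family at the 0.05 and 0.01 levels. Constant or
#' near-empty marker columns are excluded from the family and reported
#' with missing correlations.
#'
#' @param features participant-level `marker_table`
#'   (see [aggregate_participants()]).
#' @param outcomes outcome data.frame with `participant_id` and the outcome
#'   columns.
#' @param outcome_cols outcome column names (default `c("spq", "pdi")`).
#' @return object of class `marker_correlations`: data.frame with columns
#'   `marker`, `outcome`, `version`, `n`, `rho`, `p`, `p_bh`, `sig_05`,
#'   `sig_01`.
#' @export
correlate_bh <- function(features, outcomes, outcome_cols = c("spq", "pdi")) {
  stopifnot(is.data.frame(features), is.data.frame(outcomes),
            all(outcome_cols %in% names(outcomes)))
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  merged <- merge(features,
                  outcomes[, c("participant_id", outcome_cols)],
                  by = "participant_id")
  res <- list()
  for (v in unique(merged$version)) {
    dv <- merged[merged$version == v, , drop = FALSE]
    for (oc in outcome_cols) {
      fam <- lapply(markers, function(mk) {
        s <- .spearman(dv[[mk]], dv[[oc]])
        data.frame(marker = mk, outcome = oc, version = v, n = s$n,
                   rho = s$rho, p = s$p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, fam)
      if (any(is.na(fam$p))) {
        message(sprintf("correlate_bh: %d marker(s) excluded from the %s/%s family",
                        sum(is.na(fam$p)), oc, v))
      }
      fam$p_bh <- NA_real_
      fam$p_bh[!is.na(fam$p)] <- stats::p.adjust(fam$p[!is.na(fam$p)],
                                                 method = "BH")
      fam$sig_05 <- bh_significant(fam$p, 0.05)
      fam$sig_01 <- bh_significant(fam$p, 0.01)
      res[[paste(v, oc)]] <- fam
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("marker_correlations", "data.frame")
  out
}

#' @export
print.marker_correlations <- function(x, ...) {
  d <- as.data.frame(x)
  if (!is.null(d$rho)) d$rho <- round(d$rho, 3)
  if (!is.null(d$sig_01)) {
    d$flag <- ifelse(is.na(d$sig_01), "", ifelse(d$sig_01, "**",
                                                 ifelse(d$sig_05, "*", "")))
  }
  cat("Marker-outcome Spearman correlations (BH-corrected families)\n")
  keep <- intersect(c("marker", "outcome", "version", "n", "rho", "p_bh",
                      "flag"), names(d))
  print(d[, keep], row.names = FALSE)
  cat("  *: significant at 0.05, **: at 0.01 (after BH within outcome x version)\n")
  invisible(x)
}

#' Mann-Whitney group comparison of markers
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per marker between two
#' groups, separately per transcript version, BH-corrected across markers
#' within each version. The reported `W` is the rank-sum statistic of the
#' first group level.
#'
#' @param features participant-level `marker_table`.
#' @param groups data.frame with `participant_id` and `group` (two levels),
#'   or a named character vector keyed by participant id.
#' @return data.frame with `marker`, `version`, `n1`, `n2`, `W`, `p`,
#'   `p_bh`, `sig_05`.
#' @export
group_test <- function(features, groups) {
  if (!is.data.frame(groups)) {
    groups <- data.frame(participant_id = names(groups),
                         group = unname(groups), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("participant_id", "group") %in% names(groups)))
  lev <- sort(unique(groups$group))
  if (length(lev) != 2) stop("groups must have exactly 2 levels")
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  merged <- merge(features, groups, by = "participant_id")
  res <- list()
  for (v in unique(merged$version)) {
    dv <- merged[merged$version == v, , drop = FALSE]
    fam <- lapply(markers, function(mk) {
      x1 <- dv[[mk]][dv$group == lev[1]]
      x2 <- dv[[mk]][dv$group == lev[2]]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      if (length(x1) < 2 || length(x2) < 2) {
        stop("group_test: fewer than 2 observations in a group for marker ",
             mk)
      }
      wt <- suppressWarnings(stats::wilcox.test(x1, x2,
                                                alternative = "two.sided"))
      data.frame(marker = mk, version = v, n1 = length(x1), n2 = length(x2),
                 W = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    fam$p_bh <- stats::p.adjust(fam$p, method = "BH")
    fam$sig_05 <- bh_significant(fam$p, 0.05)
    res[[v]] <- fam
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- regression ladders --------------------------------------------------

# participant-wide layout: one row per participant, markers suffixed by
# version
.wide_features <- function(features) {
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  out <- NULL
  for (v in c("automated", "manual")) {
    dv <- features[features$version == v,
                   c("participant_id", markers), drop = FALSE]
    names(dv)[-1] <- paste0(markers, "_", v)
    out <- if (is.null(out)) dv else merge(out, dv, by = "participant_id")
  }
  out
}

.demographic_frame <- function(outcomes) {
  d <- data.frame(participant_id = outcomes$participant_id,
                  age = as.numeric(outcomes$age),
                  education = as.numeric(outcomes$education),
                  stringsAsFactors = FALSE)
  # one-hot with first-level reference; levels with no variation dropped
  for (v in c("gender", "device")) {
    f <- factor(outcomes[[v]])
    if (nlevels(f) >= 2) d[[v]] <- f
  }
  d
}

.regressor_sets <- function(demo_vars, markers) {
  list(
    demographics = demo_vars,
    markers_auto = paste0(markers, "_automated"),
    markers_manual = paste0(markers, "_manual"),
    `demographics+markers_auto` = c(demo_vars,
                                    paste0(markers, "_automated")),
    `demographics+markers_manual` = c(demo_vars,
                                      paste0(markers, "_manual")))
}

.ladder_data <- function(features, outcomes, extra_cols) {
  w <- .wide_features(features)
  demo <- .demographic_frame(outcomes)
  dat <- merge(merge(demo, outcomes[, c("participant_id", extra_cols),
                                    drop = FALSE],
                     by = "participant_id"),
               w, by = "participant_id")
  # markers that never vary or are entirely missing cannot enter a design
  keep <- vapply(names(dat), function(nm) {
    x <- dat[[nm]]
    !(is.numeric(x) && (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0))
  }, logical(1))
  dropped <- names(dat)[!keep]
  if (length(dropped)) {
    message("ladder: dropping constant/empty column(s): ",
            paste(dropped, collapse = ", "))
  }
  dat <- dat[, keep, drop = FALSE]
  cc <- stats::complete.cases(dat)
  if (sum(!cc) > 0) {
    message(sprintf("ladder: %d incomplete case(s) excluded", sum(!cc)))
  }
  dat[cc, , drop = FALSE]
}

# Fit a model, dropping marker columns that are linearly dependent given
# the rest of the design (several connectivity and count markers coincide
# exactly on fully windowed excerpts, e.g. the largest-connected-component
# size equals the node count when every window is one connected chain).
# Dependent demographic columns are a genuine design defect and error.
.fit_dropping_dependent <- function(response, set, dat, demo_vars,
                                    family = NULL) {
  repeat {
    form <- if (length(set)) {
      stats::reformulate(set, response = response)
    } else {
      stats::as.formula(paste(response, "~ 1"))
    }
    fit <- if (is.null(family)) {
      stats::lm(form, data = dat)
    } else {
      stats::glm(form, data = dat, family = family)
    }
    nac <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    if (length(nac) == 0) {
      return(list(fit = fit, set = set))
    }
    offending <- unique(unlist(lapply(set, function(v) {
      if (any(startsWith(nac, v))) v
    })))
    if (length(offending) == 0 || any(offending %in% demo_vars)) {
      stop("rank-deficient design; collinear column(s): ",
           paste(if (length(offending)) offending else nac, collapse = ", "))
    }
    message("ladder: dropping linearly dependent marker column(s): ",
            paste(offending, collapse = ", "))
    set <- setdiff(set, offending)
  }
}

#' Hierarchical linear regression ladder for a continuous outcome
#'
#' Fits ordinary least squares for the five regressor sets of the two-step
#' design: demographics only; speech markers only (automated, then manual
#' transcripts); and demographics plus markers (automated, then manual).
#' All models are fitted on the same complete-case rows, so in-sample R²
#' can only grow along each nested pair. Reports R², adjusted R², RMSE
#' (root mean squared residual), and the overall F test.
#'
#' @param features participant-level `marker_table` with both versions.
#' @param outcomes outcome data.frame (`participant_id`, the outcome,
#'   `age`, `gender`, `education`, `device`).
#' @param outcome `"spq"` or `"pdi"` (any numeric outcome column).
#' @return object of class `marker_ladder`: data.frame with one row per
#'   regressor set and columns `model`, `n`, `k`, `r2`, `adj_r2`, `rmse`,
#'   `f`, `p`.
#' @export
fit_linear_ladder <- function(features, outcomes, outcome = "spq") {
  stopifnot(outcome %in% names(outcomes))
  dat <- .ladder_data(features, outcomes, outcome)
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  demo_vars <- intersect(c("age", "education", "gender", "device"),
                         names(dat))
  sets <- .regressor_sets(demo_vars, markers)
  sets <- lapply(sets, intersect, y = names(dat))
  rows <- lapply(names(sets), function(lbl) {
    fr <- .fit_dropping_dependent(outcome, sets[[lbl]], dat, demo_vars)
    fit <- fr$fit
    s <- summary(fit)
    fstat <- s$fstatistic
    data.frame(model = lbl, n = nrow(dat), k = length(fr$set),
               r2 = s$r.squared, adj_r2 = s$adj.r.squared,
               rmse = sqrt(mean(stats::residuals(fit)^2)),
               f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
               p = if (is.null(fstat)) NA_real_ else {
                 stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
               },
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("marker_ladder", "data.frame")
  attr(out, "family") <- "linear"
  attr(out, "outcome") <- outcome
  out
}

.rank_auc <- function(p, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification and pseudo-R² metrics from fitted probabilities
#'
#' Evaluates a logistic model in-sample from its fitted probabilities:
#' threshold-0.5 accuracy, sensitivity, specificity, precision, F-measure;
#' rank-statistic AUC; and the Cox & Snell `1 - (L0/L1)^(2/n)`, Nagelkerke
#' (Cox & Snell rescaled by its attainable maximum) and Tjur
#' (`mean(p | y = 1) - mean(p | y = 0)`) pseudo R² values, where `L0` is
#' the likelihood of the intercept-only model on the same observations.
#' For the intercept-only model itself all three pseudo R² are 0 and the
#' AUC is 0.5.
#'
#' @param p fitted probabilities in `[0, 1]`.
#' @param y observed 0/1 outcomes (or logical).
#' @return named numeric vector of the metrics plus the model `loglik`.
#' @export
logistic_metrics <- function(p, y) {
  y <- as.integer(y)
  stopifnot(length(p) == length(y), all(p >= 0 & p <= 1),
            all(y %in% c(0L, 1L)))
  n <- length(y)
  eps <- 1e-12
  pc <- pmin(1 - eps, pmax(eps, p))
  ll1 <- sum(y * log(pc) + (1 - y) * log(1 - pc))
  p0 <- pmin(1 - eps, pmax(eps, mean(y)))
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  pred <- as.integer(p >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  fmeas <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  nagelkerke <- cox_snell / (1 - exp((2 / n) * ll0))
  tjur <- mean(p[y == 1]) - mean(p[y == 0])
  c(accuracy = (tp + tn) / n, auc = .rank_auc(p, y),
    sensitivity = sens, specificity = spec, precision = prec,
    f_measure = fmeas, nagelkerke_r2 = nagelkerke, tjur_r2 = tjur,
    cox_snell_r2 = cox_snell, loglik = ll1)
}

.logistic_metrics <- function(fit, y) {
  logistic_metrics(stats::fitted(fit), y)
}

#' Hierarchical logistic regression ladder for a binary group outcome
#'
#' Maximum-likelihood logistic regression over the same five regressor
#' sets as [fit_linear_ladder()], evaluated in-sample: threshold-0.5
#' accuracy, sensitivity, specificity, precision and F-measure; AUC from
#' the rank statistic (threshold-free); and the Cox & Snell
#' (`1 - (L0/L1)^(2/n)`), Nagelkerke (Cox & Snell divided by its maximum)
#' and Tjur (difference of mean fitted probabilities between the observed
#' classes) pseudo R² values. A fit that separates perfectly is flagged
#' with a warning and reported from the converged-bounded estimates.
#'
#' @param features participant-level `marker_table` with both versions.
#' @param outcomes outcome data.frame including the group column.
#' @param group_col name of the binary group column (default `"group"`).
#' @param positive level treated as the positive class (default `"high"`
#'   when present, otherwise the second sorted level).
#' @return object of class `marker_ladder` with one row per regressor set
#'   and the classification and pseudo-R² metric columns.
#' @export
fit_logistic_ladder <- function(features, outcomes, group_col = "group",
                                positive = NULL) {
  stopifnot(group_col %in% names(outcomes))
  dat <- .ladder_data(features, outcomes, group_col)
  lev <- sort(unique(as.character(dat[[group_col]])))
  if (length(lev) != 2) stop("group column must have exactly 2 levels")
  positive <- positive %||% if ("high" %in% lev) "high" else lev[2]
  y <- as.integer(dat[[group_col]] == positive)
  dat$.y <- y
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  demo_vars <- intersect(c("age", "education", "gender", "device"),
                         names(dat))
  sets <- .regressor_sets(demo_vars, markers)
  sets <- lapply(sets, intersect, y = names(dat))
  rows <- lapply(names(sets), function(lbl) {
    separated <- FALSE
    fr <- withCallingHandlers(
      .fit_dropping_dependent(".y", sets[[lbl]], dat, demo_vars,
                              family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    fit <- fr$fit
    if (separated || any(abs(stats::fitted(fit) - 0.5) > 0.5 - 1e-10)) {
      separated <- TRUE
      warning("possible perfect separation in model '", lbl,
              "'; metrics reported from bounded estimates", call. = FALSE)
    }
    m <- .logistic_metrics(fit, y)
    cbind(data.frame(model = lbl, n = nrow(dat), k = length(fr$set),
                     separated = separated, stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("marker_ladder", "data.frame")
  attr(out, "family") <- "logistic"
  attr(out, "outcome") <- group_col
  out
}

#' @export
print.marker_ladder <- function(x, ...) {
  cat(sprintf("Hierarchical %s regression ladder (outcome: %s, in-sample)\n",
              attr(x, "family"), attr(x, "outcome")))
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits = 3)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write analysis tables to disk
#'
#' Writes each table of a results list as `<name>.csv` under `dir` —
#' correlation matrix, group tests and the regression ladders in the order
#' supplied. Output is deterministic: re-running on the same inputs writes
#' byte-identical tables.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
report <- function(results, dir) {
  stopifnot(is.list(results), length(results) > 0,
            !is.null(names(results)), all(nzchar(names(results))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    stopifnot(is.data.frame(results[[nm]]))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(results[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full marker-to-outcome analysis on a cohort
#'
#' Convenience chain: extract excerpt-level markers, average to participant
#' level, correlate markers with the questionnaire outcomes (BH-corrected),
#' compute manual-vs-automated marker agreement, and fit the regression
#' ladders — linear for continuous cohorts, logistic when the cohort has a
#' two-level `group` column (in which case the Mann-Whitney group tests are
#' also run).
#'
#' @param cohort a `speech_cohort`.
#' @param graph_cfg a [graph_config()].
#' @param sif_pc_remove passed to [extract_corpus()].
#' @return named list: `features_excerpt`, `features`, `agreement`,
#'   `correlations`, and either `linear_spq`/`linear_pdi` or
#'   `group_tests`/`logistic`.
#' @export
analyze_cohort <- function(cohort, graph_cfg = graph_config(),
                           sif_pc_remove = FALSE) {
  stopifnot(inherits(cohort, "speech_cohort"))
  fx <- extract_corpus(cohort, graph_cfg = graph_cfg,
                       sif_pc_remove = sif_pc_remove)
  fp <- aggregate_participants(fx)
  out <- list(features_excerpt = fx, features = fp,
              agreement = marker_agreement(fp),
              correlations = correlate_bh(fp, cohort$outcomes))
  if ("group" %in% names(cohort$outcomes)) {
    out$group_tests <- group_test(fp, cohort$outcomes[, c("participant_id",
                                                          "group")])
    out$logistic <- fit_logistic_ladder(fp, cohort$outcomes)
  } else {
    out$linear_spq <- fit_linear_ladder(fp, cohort$outcomes, "spq")
    out$linear_pdi <- fit_linear_ladder(fp, cohort$outcomes, "pdi")
  }
  out
}
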