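#' Mixed factorial ANOVA with subject error strata
#'
#' Classical (unadjusted) sums-of-squares decomposition for designs with
#' between-subject factors and repeated (within-subject) factors, the standard
#' analysis for group-by-condition behavioral tables. Between-subject effects
#' are tested against the subjects-within-groups mean square; each within
#' effect and its interactions with between factors are tested against the
#' corresponding effect-by-subject-within-group mean square. No sphericity
#' correction is applied. Fitting is delegated to [stats::aov()] with an
#' `Error(subject/(within factors))` stratum structure after the design is
#' checked for balance.
#'
#' @param data long-format data.frame, one row per subject x within-cell.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param between character vector of between-subject factor columns (may be
#'   empty).
#' @param within character vector of within-subject factor columns (may be
#'   empty; then an ordinary between-subjects ANOVA is fitted).
#' @return an object of classes `anova_result` and `data.frame` with one row
#'   per effect: `effect`, `df_num`, `df_den`, `sum_sq`, `mean_sq`,
#'   `statistic` (F) and `p_value`. The design descriptor is attached as
#'   attributes `between`, `within` and `n_subjects`.
#' @export
mixed_anova <- function(data, dv, subject, between = character(0),
                        within = character(0)) {
  data <- as.data.frame(data)
  for (col in c(dv, subject, between, within)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in data", call. = FALSE)
    }
  }
  if (anyNA(data[[dv]])) {
    stop("response column '", dv, "' contains missing values; drop ",
         "incomplete subjects first", call. = FALSE)
  }
  data[[subject]] <- factor(data[[subject]])
  for (col in c(between, within)) data[[col]] <- factor(data[[col]])

  check_mixed_design(data, subject, between, within)

  fixed <- paste(c(between, within), collapse = " * ")
  if (length(fixed) == 0L || fixed == "") {
    stop("at least one between or within factor is required", call. = FALSE)
  }
  if (length(within) > 0L) {
    form <- stats::as.formula(paste0(
      dv, " ~ ", fixed, " + Error(", subject, "/(",
      paste(within, collapse = " * "), "))"
    ))
  } else {
    form <- stats::as.formula(paste0(dv, " ~ ", fixed))
  }
  fit <- stats::aov(form, data = data)
  out <- tidy_aov_summary(fit)
  if (any(out$df_den <= 0)) {
    stop("singular design: an error stratum has no residual degrees of ",
         "freedom", call. = FALSE)
  }
  attr(out, "between") <- between
  attr(out, "within") <- within
  attr(out, "n_subjects") <- nlevels(data[[subject]])
  class(out) <- c("anova_result", "data.frame")
  out
}

check_mixed_design <- function(data, subject, between, within) {
  split_by <- interaction(data[c(subject, within)], drop = FALSE)
  counts <- table(split_by)
  subj_levels <- levels(data[[subject]])
  if (length(within) > 0L) {
    bad <- names(counts)[counts != 1L]
    if (length(bad) > 0L) {
      stop("unbalanced design: subject/cell '", bad[1], "' has ",
           counts[bad[1]], " observations (expected exactly 1)",
           call. = FALSE)
    }
  }
  for (b in between) {
    per_subj <- tapply(data[[b]], data[[subject]],
                       function(x) length(unique(x)))
    if (any(per_subj != 1L)) {
      stop("subject '", subj_levels[which(per_subj != 1L)[1]],
           "' appears under more than one level of between factor '", b, "'",
           call. = FALSE)
    }
    if (any(table(unique(data[c(subject, b)])[[b]]) < 2L)) {
      stop("each level of between factor '", b,
           "' needs at least 2 subjects", call. = FALSE)
    }
  }
}

tidy_aov_summary <- function(fit) {
  smry <- summary(fit)
  # aov with Error() returns a summary per stratum; plain aov a single table
  if (!inherits(fit, "aovlist")) smry <- list(`Within` = smry)
  rows <- list()
  for (stratum in names(smry)) {
    tab <- smry[[stratum]][[1]]
    effects <- trimws(rownames(tab))
    resid <- effects == "Residuals"
    df_den <- if (any(resid)) tab[resid, "Df"] else NA_real_
    for (k in which(!resid)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(" ", "", effects[k]),
        df_num = tab[k, "Df"],
        df_den = df_den,
        sum_sq = tab[k, "Sum Sq"],
        mean_sq = tab[k, "Mean Sq"],
        statistic = if ("F value" %in% colnames(tab)) tab[k, "F value"]
                    else NA_real_,
        p_value = if ("Pr(>F)" %in% colnames(tab)) tab[k, "Pr(>F)"]
                  else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed ANOVA (", attr(x, "n_subjects"), "subjects; between:",
      paste(attr(x, "between"), collapse = ", "), "; within:",
      paste(attr(x, "within"), collapse = ", "), ")\n")
  y <- as.data.frame(x)
  y$statistic <- signif(y$statistic, 5)
  y$p_value <- signif(y$p_value, 4)
  print(y[, c("effect", "df_num", "df_den", "statistic", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Two-sided pooled-variance t test with `n_a + n_b - 2` degrees of freedom.
#' Degenerate samples (zero pooled variance) do not error: equal means give
#' `t = 0, p = 1`; unequal means give an infinite statistic with `p = 0`, and
#' the result is flagged.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return an object of class `rs_test`: list with `method`, `statistic`
#'   (t), `df`, `p_value`, `estimate` (the two means) and `degenerate`.
#' @export
student_t <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  na <- length(sample_a)
  nb <- length(sample_b)
  if (na < 2L || nb < 2L) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
    df
  ma <- mean(sample_a)
  mb <- mean(sample_b)
  if (sp2 == 0) {
    if (ma == mb) {
      res <- list(statistic = 0, p_value = 1, degenerate = TRUE)
    } else {
      res <- list(statistic = sign(ma - mb) * Inf, p_value = 0,
                  degenerate = TRUE)
    }
  } else {
    ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                degenerate = FALSE)
  }
  structure(list(method = "student_t", statistic = res$statistic, df = df,
                 p_value = res$p_value,
                 estimate = c(mean_a = ma, mean_b = mb),
                 n = c(n_a = na, n_b = nb), degenerate = res$degenerate),
            class = "rs_test")
}

#' Pearson product-moment correlation with significance
#'
#' Two-sided p value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Pairs with a missing value in either variable are
#' dropped. Zero variance in either variable leaves the correlation undefined;
#' the result carries `r = NA` and is flagged degenerate rather than erroring.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return an object of class `rs_test`: list with `method`, `estimate` (r),
#'   `n`, `statistic` (t), `df`, `p_value` and `degenerate`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(method = "pearson", estimate = NA_real_, n = n,
                          statistic = NA_real_, df = n - 2L,
                          p_value = NA_real_, degenerate = TRUE),
                     class = "rs_test"))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(method = "pearson", estimate = unname(ht$estimate), n = n,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE),
            class = "rs_test")
}

#' @export
print.rs_test <- function(x, ...) {
  if (x$method == "pearson") {
    cat("Pearson correlation: r =", signif(x$estimate, 4), ", t(", x$df,
        ") =", signif(x$statistic, 4), ", p =", signif(x$p_value, 4),
        ", n =", x$n, "\n")
  } else {
    cat("Student's t test: t(", x$df, ") =", signif(x$statistic, 4),
        ", p =", signif(x$p_value, 4), "| means:",
        signif(x$estimate[1], 4), "vs", signif(x$estimate[2], 4), "\n")
  }
  if (isTRUE(x$degenerate)) cat("  (degenerate: zero variance)\n")
  invisible(x)
}
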