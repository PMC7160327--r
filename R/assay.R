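# Activation-induced-marker (CD154) assay statistics: activation metrics,
# 3x-over-background positivity calls, and random-intercept mixed models.

#' Activation metrics for one patient x stimulus
#'
#' Percentages are means over technical replicates of per-replicate
#' percentages. A response is positive when the activated-memory percentage
#' is at least `fold_threshold` (default 3, inclusive) times the same
#' patient's unstimulated background. A zero background with a non-zero
#' stimulated percentage yields an infinite fold, flagged
#' `"background-zero"`; the call is still made.
#'
#' @param counts data.frame of replicate rows with columns `memory`,
#'   `naive`, `cd154_memory`, `cd154_naive`.
#' @param background result of `activation_metrics()` on the same patient's
#'   unstimulated wells, or `NULL` when computing the background itself.
#' @param fold_threshold positivity boundary (default 3).
#' @return One-row data.frame: `pct_activated_memory`,
#'   `pct_activated_naive`, `fold_over_background`, `positive`,
#'   `memory_naive_ratio`, `flag`.
#' @export
activation_metrics <- function(counts, background = NULL,
                               fold_threshold = 3) {
  if (nrow(counts) < 1) stop_idioscope("need at least one replicate")
  if (any(counts$memory <= 0)) stop_idioscope("zero memory count")
  pct_mem <- mean(counts$cd154_memory / counts$memory) * 100
  pct_nai <- mean(ifelse(counts$naive > 0,
                         counts$cd154_naive / counts$naive, NA)) * 100
  flag <- ""
  if (is.null(background)) {
    fold <- NA_real_
    positive <- NA
  } else {
    bg <- background$pct_activated_memory
    if (bg == 0) {
      fold <- if (pct_mem > 0) Inf else NA_real_
      positive <- pct_mem > 0
      flag <- "background-zero"
    } else {
      fold <- pct_mem / bg
      # inclusive boundary, robust to floating-point ties at exactly 3x
      positive <- fold >= fold_threshold - 1e-9
    }
  }
  data.frame(pct_activated_memory = pct_mem,
             pct_activated_naive = pct_nai,
             fold_over_background = fold,
             positive = positive,
             memory_naive_ratio = if (!is.na(pct_nai) && pct_nai > 0) {
               pct_mem / pct_nai
             } else NA_real_,
             flag = flag,
             stringsAsFactors = FALSE)
}

#' Activation results for a full flow-count table
#'
#' Computes [activation_metrics()] for every patient x stimulus against
#' that patient's own unstimulated background.
#'
#' @param flow tidy data.frame of gated counts: one row per patient x
#'   stimulus x replicate, columns `patient_id`, `stimulus`, `category`,
#'   `replicate`, `memory`, `naive`, `cd154_memory`, `cd154_naive`.
#' @param background_label stimulus label of the unstimulated wells.
#' @param fold_threshold positivity boundary (default 3).
#' @return data.frame, one row per patient x stimulus (background rows
#'   carry `NA` fold/positivity).
#' @export
activation_results <- function(flow, background_label = "unstimulated",
                               fold_threshold = 3) {
  out <- list()
  for (p in unique(flow$patient_id)) {
    fp <- flow[flow$patient_id == p, , drop = FALSE]
    bgc <- fp[fp$stimulus == background_label, , drop = FALSE]
    if (nrow(bgc) == 0) {
      stop_idioscope("no unstimulated background for patient %s", p)
    }
    bg <- activation_metrics(bgc, NULL)
    for (s in unique(fp$stimulus)) {
      rows <- fp[fp$stimulus == s, , drop = FALSE]
      m <- activation_metrics(rows, if (s == background_label) NULL else bg,
                              fold_threshold)
      m <- cbind(data.frame(patient_id = p, stimulus = s,
                            category = rows$category[1],
                            stringsAsFactors = FALSE), m)
      out[[length(out) + 1]] <- m
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare activation between peptide categories with a mixed model
#'
#' Fits a linear mixed model of the activated-memory percentage with
#' peptide category as fixed effect and patient as random intercept (REML),
#' and reports pairwise category differences. With
#' `ddf = "satterthwaite"` (default) the model is fitted through lmerTest
#' and pairwise comparisons come from emmeans with Tukey adjustment; with
#' `ddf = "wald"` a fast normal-approximation path is used (suited to
#' simulation loops). A singular or zero-variance fit falls back to an
#' ordinary fixed-effects-only linear model, flagged.
#'
#' @param results data.frame with `pct_activated_memory`, `category`,
#'   `patient_id` (e.g. [activation_results()] restricted to peptide
#'   stimuli).
#' @param ddf `"satterthwaite"` or `"wald"`.
#' @return List of class `group_comparison`: `pairwise` (contrast,
#'   estimate, lower, upper, p), `var_patient`, `var_residual`,
#'   `singular`, `fallback_lm`, `model`.
#' @export
compare_groups <- function(results, ddf = c("satterthwaite", "wald")) {
  ddf <- match.arg(ddf)
  results <- results[!is.na(results$category) &
                       !is.na(results$pct_activated_memory), , drop = FALSE]
  if (length(unique(results$category)) < 2) {
    stop_idioscope("need at least two categories")
  }
  if (length(unique(results$patient_id)) < 2) {
    stop_idioscope("need at least two patients for a random intercept")
  }
  results$category <- factor(results$category)
  fallback <- FALSE
  singular <- FALSE
  if (ddf == "satterthwaite") {
    fit <- tryCatch(
      lmerTest::lmer(pct_activated_memory ~ category + (1 | patient_id),
                     data = results, REML = TRUE),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      lme4::lmer(pct_activated_memory ~ category + (1 | patient_id),
                 data = results, REML = TRUE),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    singular <- tryCatch(lme4::isSingular(fit, tol = 1e-6),
                         error = function(e) TRUE)
  }
  # zero random variance (singular) or failed fit: fixed-effects-only
  # fallback, flagged
  fallback <- is.null(fit) || singular
  mixed_summary <- function(fit) {
    v <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(patient = v$vcov[v$grp == "patient_id"],
            residual = v$vcov[v$grp == "Residual"])
    if (ddf == "satterthwaite") {
      em <- emmeans::emmeans(fit, "category")
      ct <- summary(emmeans::contrast(em, "pairwise"), infer = TRUE)
      pw <- data.frame(contrast = as.character(ct$contrast),
                       estimate = ct$estimate,
                       lower = ct$lower.CL, upper = ct$upper.CL,
                       p = ct$p.value, stringsAsFactors = FALSE)
    } else {
      pw <- pairwise_from_fit(fit, results$category)
    }
    list(vc = vc, pw = pw)
  }
  res <- NULL
  if (!fallback) {
    res <- tryCatch(mixed_summary(fit), error = function(e) NULL)
    if (is.null(res)) fallback <- TRUE   # degenerate fit (e.g. constant data)
  }
  if (fallback) {
    fit <- lm(pct_activated_memory ~ category, data = results)
    vc <- c(patient = 0, residual = summary(fit)$sigma^2)
    pw <- pairwise_from_fit(fit, results$category)
  } else {
    vc <- res$vc
    pw <- res$pw
  }
  structure(list(pairwise = pw, var_patient = unname(vc["patient"]),
                 var_residual = unname(vc["residual"]),
                 singular = singular, fallback_lm = fallback, model = fit),
            class = "group_comparison")
}

# Unadjusted pairwise contrasts by the delta method on the fixed effects
# (normal approximation); works for lm and lmerMod fits with treatment
# contrasts on `category`.
pairwise_from_fit <- function(fit, category) {
  levs <- levels(category)
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  k <- length(levs)
  rows <- list()
  cmat <- diag(k)[, -1, drop = FALSE]  # level -> coefficient design
  cmat[1, ] <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      L <- numeric(length(b))
      names(L) <- names(b)
      li <- paste0("category", levs[i]); lj <- paste0("category", levs[j])
      if (li %in% names(L)) L[li] <- 1
      if (lj %in% names(L)) L[lj] <- -1
      est <- sum(L * b)
      se <- sqrt(drop(t(L) %*% V %*% L))
      rows[[length(rows) + 1]] <- data.frame(
        contrast = paste(levs[i], "-", levs[j]), estimate = est,
        lower = est - qnorm(0.975) * se, upper = est + qnorm(0.975) * se,
        p = 2 * pnorm(-abs(est / se)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Mixed-model comparison of activation between peptide categories\n")
  cat(sprintf("  patient variance %.4g, residual variance %.4g%s%s\n",
              x$var_patient, x$var_residual,
              if (x$singular) " (singular fit)" else "",
              if (x$fallback_lm) " (fixed-effects fallback)" else ""))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Chemokine-receptor enrichment on activated memory cells
#'
#' Among samples with positive responses, compares the percentage of
#' CCR6+ (and CXCR3+) cells between activated (CD154+) and non-activated
#' (CD154-) memory cells, with activation status as fixed effect and
#' patient as random intercept. Unadjusted mean differences are reported
#' alongside the model estimates.
#'
#' @param flow flow-count table (as in [activation_results()]) with
#'   additional columns `cd154_memory`, `ccr6_cd154pos`, `cxcr3_cd154pos`,
#'   `cd154neg_memory`, `ccr6_cd154neg`, `cxcr3_cd154neg`.
#' @param positives data.frame `patient_id`, `stimulus` of positive
#'   responses (e.g. from [activation_results()]).
#' @return data.frame per marker: model `estimate` (CD154+ minus CD154-),
#'   `lower`, `upper`, `p`, `unadjusted_difference`; or `NULL` (with a
#'   message) when there are no positive responses.
#' @export
chemokine_enrichment <- function(flow, positives) {
  sel <- merge(flow, positives[, c("patient_id", "stimulus")],
               by = c("patient_id", "stimulus"))
  if (nrow(sel) == 0) {
    message("no positive responses: chemokine enrichment not estimable")
    return(NULL)
  }
  out <- list()
  for (marker in c("CCR6", "CXCR3")) {
    pos_col <- paste0(tolower(marker), "_cd154pos")
    neg_col <- paste0(tolower(marker), "_cd154neg")
    long <- rbind(
      data.frame(patient_id = sel$patient_id, status = "CD154+",
                 pct = 100 * sel[[pos_col]] / pmax(sel$cd154_memory, 1)),
      data.frame(patient_id = sel$patient_id, status = "CD154-",
                 pct = 100 * sel[[neg_col]] / pmax(sel$cd154neg_memory, 1)))
    long$status <- factor(long$status, levels = c("CD154-", "CD154+"))
    single_patient <- length(unique(long$patient_id)) < 2
    if (single_patient) {
      fit <- lm(pct ~ status, data = long)
      est <- coef(fit)["statusCD154+"]
      se <- sqrt(vcov(fit)["statusCD154+", "statusCD154+"])
      var_pat <- NA_real_
    } else {
      fit <- lmerTest::lmer(pct ~ status + (1 | patient_id), data = long)
      est <- lme4::fixef(fit)["statusCD154+"]
      se <- sqrt(as.matrix(vcov(fit))["statusCD154+", "statusCD154+"])
      v <- as.data.frame(lme4::VarCorr(fit))
      var_pat <- v$vcov[v$grp == "patient_id"]
    }
    p <- if (inherits(fit, "lmerModLmerTest")) {
      coef(summary(fit))["statusCD154+", "Pr(>|t|)"]
    } else {
      2 * pnorm(-abs(est / se))
    }
    out[[marker]] <- data.frame(
      marker = marker, estimate = unname(est),
      lower = unname(est - qnorm(0.975) * se),
      upper = unname(est + qnorm(0.975) * se), p = unname(p),
      unadjusted_difference = mean(long$pct[long$status == "CD154+"]) -
        mean(long$pct[long$status == "CD154-"]),
      var_patient = var_pat,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-well activation percentages with a known group effect
#'
#' Gaussian generator for calibrating the mixed-model machinery: patient
#' random intercepts plus residual noise around category means, on the
#' percent scale. Used by coverage / type-I-error simulations.
#'
#' @param n_patients number of patients (default 9).
#' @param n_per_group named vector of peptides per category (default
#'   10 stimulatory, 5 tolerogenic, 7 inert).
#' @param group_means named vector of category mean percentages.
#' @param sigma_patient,sigma_resid random-intercept and residual SDs (%).
#' @param seed RNG seed.
#' @return data.frame `patient_id`, `stimulus`, `category`,
#'   `pct_activated_memory`.
#' @export
simulate_group_response <- function(n_patients = 9,
                                    n_per_group = c(stimulatory = 10,
                                                    tolerogenic = 5,
                                                    inert = 7),
                                    group_means = c(stimulatory = 0.4,
                                                    tolerogenic = 0.4,
                                                    inert = 0.1),
                                    sigma_patient = 0.2,
                                    sigma_resid = 0.15,
                                    seed = 1L) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n_patients))
  u <- rnorm(n_patients, 0, sigma_patient)
  rows <- list()
  for (i in seq_len(n_patients)) {
    for (cat in names(n_per_group)) {
      n <- n_per_group[[cat]]
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pats[i],
        stimulus = paste0(cat, "_", seq_len(n)),
        category = cat,
        pct_activated_memory = group_means[[cat]] + u[i] +
          rnorm(n, 0, sigma_resid),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
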