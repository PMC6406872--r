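#' Presence filter across cell systems
#'
#' A protein enters the cross-system comparison only if it was detected
#' (non-missing in at least one replicate) in a minimum number of systems.
#' Within the retained set, systems with no detection at all are recorded as
#' absences — these proteins get a categorical absent-present call rather
#' than a numeric fold change.
#'
#' @param detected Logical matrix, proteins x systems: detected in >= 1
#'   replicate of that system.
#' @param min_systems Minimum number of systems with detection, default 2.
#' @return List with `retained` (logical per protein) and `absent` (logical
#'   matrix, proteins x systems; TRUE = absent from that system among
#'   retained proteins, FALSE elsewhere).
#' @export
presence_filter <- function(detected, min_systems = 2L) {
  stopifnot(is.matrix(detected), is.logical(detected))
  n_sys <- rowSums(detected)
  retained <- n_sys >= min_systems
  absent <- !detected & retained
  list(retained = retained, absent = absent)
}

#' One-way ANOVA with Tukey HSD post-hoc tests for one protein
#'
#' Compares log10 copy numbers of one protein across cell systems with a
#' fixed-effects one-way ANOVA, followed by Tukey honestly-significant-
#' difference tests for the pairwise contrasts. Copy numbers are compared on
#' the log10 scale, where multiplicative measurement noise is approximately
#' homoscedastic.
#'
#' @param values Numeric vector of replicate-level log10 copy numbers.
#' @param groups Factor or character vector of system labels, same length.
#' @return List with `anova_p`, and `tukey_p` (named vector per pair), or
#'   NULL when any group has fewer than 2 replicate values (the protein is
#'   then not comparable).
#' @export
anova_tukey <- function(values, groups) {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) return(NULL)
  if (stats::var(values) == 0) {
    # all observations identical: F = 0, no evidence of any difference
    pairs <- utils::combn(levels(groups), 2L, paste, collapse = "-")
    return(list(anova_p = 1, tukey_p = stats::setNames(rep(1, length(pairs)), pairs)))
  }
  fit <- stats::aov(values ~ groups)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$groups
  list(anova_p = anova_p, tukey_p = stats::setNames(tk[, "p adj"], rownames(tk)))
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error-rate control by the Holm-Bonferroni step-down procedure:
#' sort ascending, multiply the i-th smallest by (m - i + 1), enforce
#' monotonicity, cap at 1, return in input order. Delegates to
#' [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in [0, 1]; NA passed through.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Categorize a protein's difference versus the reference system
#'
#' Applies the comparison taxonomy with fixed precedence: an absent-present
#' pattern beats everything; otherwise a fold change above the "obvious"
#' threshold (20-fold by default) is called regardless of the p-value; then
#' Holm-adjusted significance; else unchanged. Proteins detected in fewer
#' than two systems are not comparable.
#'
#' @param fold_change Ratio of mean copies, cell line vs reference (linear
#'   scale; may be NA when one side is absent).
#' @param holm_p Holm-adjusted p-value (NA allowed).
#' @param present_test,present_ref Detection flags for the two systems.
#' @param comparable Is the protein in the >= 2-system retained set?
#' @param fc_obvious Fold-change threshold for the "obvious" call, default 20.
#' @param alpha Significance level on the adjusted p-value, default 0.05.
#' @return Character: one of "absent_present", "obvious", "significant",
#'   "unchanged", "not_comparable".
#' @export
categorize <- function(fold_change, holm_p, present_test, present_ref,
                       comparable = TRUE, fc_obvious = 20, alpha = 0.05) {
  if (!comparable) return("not_comparable")
  if (xor(present_test, present_ref)) return("absent_present")
  if (!present_test && !present_ref) return("not_comparable")
  if (!is.na(fold_change) &&
      max(fold_change, 1 / fold_change) > fc_obvious) return("obvious")
  if (!is.na(holm_p) && holm_p < alpha) return("significant")
  "unchanged"
}

#' Three-system proteome comparison
#'
#' Runs the full cross-system comparison on replicate-level copy numbers:
#' presence filtering (>= 2 of the systems), per-protein one-way ANOVA on
#' log10 copies with Tukey HSD post-hoc tests, Holm correction of the ANOVA
#' p-values across all comparable proteins, fold changes of each non-reference
#' system versus the reference, and the categorical calls.
#'
#' @param copies Numeric matrix, proteins x replicate samples (copies per
#'   cell; NA = not detected).
#' @param systems Character vector assigning each column to a cell system.
#' @param reference Reference system label (default "PHH").
#' @param fc_obvious,alpha Category thresholds; see [categorize()].
#' @return Data frame, one row per protein: detection flags, `anova_p`,
#'   `holm_p`, Tukey pairwise p-values, `fc_<system>` and
#'   `category_<system>` for each non-reference system, and an overall
#'   `category` (strongest call across comparisons).
#' @export
compare_systems <- function(copies, systems, reference = "PHH",
                            fc_obvious = 20, alpha = 0.05) {
  stopifnot(is.matrix(copies), length(systems) == ncol(copies))
  sys_levels <- unique(systems)
  if (!reference %in% sys_levels) {
    stop("reference system '", reference, "' not present in data")
  }
  detected <- vapply(
    sys_levels,
    function(s) rowSums(!is.na(copies[, systems == s, drop = FALSE])) > 0,
    logical(nrow(copies))
  )
  pf <- presence_filter(detected, min_systems = 2L)

  mean_log <- vapply(
    sys_levels,
    function(s) rowMeans(log10(copies[, systems == s, drop = FALSE]), na.rm = TRUE),
    numeric(nrow(copies))
  )
  mean_log[is.nan(mean_log)] <- NA_real_

  stat <- lapply(seq_len(nrow(copies)), function(i) {
    if (!pf$retained[i]) return(NULL)
    anova_tukey(log10(copies[i, ]), systems)
  })
  anova_p <- vapply(stat, function(s) if (is.null(s)) NA_real_ else s$anova_p,
                    numeric(1L))
  holm_p <- rep(NA_real_, length(anova_p))
  family <- which(!is.na(anova_p))
  holm_p[family] <- holm_adjust(anova_p[family])

  pair_names <- utils::combn(sort(sys_levels), 2L, paste, collapse = "-")
  tukey <- matrix(NA_real_, nrow(copies), length(pair_names),
                  dimnames = list(NULL, paste0("tukey_", pair_names)))
  for (i in seq_along(stat)) {
    if (is.null(stat[[i]])) next
    tp <- stat[[i]]$tukey_p
    idx <- match(paste0("tukey_", names(tp)), colnames(tukey))
    ok <- !is.na(idx)
    tukey[i, idx[ok]] <- tp[ok]
  }

  out <- data.frame(
    accession = rownames(copies) %||% paste0("P", seq_len(nrow(copies))),
    retained = pf$retained,
    anova_p = anova_p,
    holm_p = holm_p
  )
  for (s in sys_levels) out[[paste0("detected_", s)]] <- detected[, s]
  out <- cbind(out, tukey)

  others <- setdiff(sys_levels, reference)
  cat_mat <- matrix(NA_character_, nrow(copies), length(others))
  for (k in seq_along(others)) {
    s <- others[k]
    fc <- 10^(mean_log[, s] - mean_log[, reference])
    out[[paste0("fc_", s)]] <- fc
    out[[paste0("log10_fc_", s)]] <- mean_log[, s] - mean_log[, reference]
    cat_mat[, k] <- vapply(seq_len(nrow(copies)), function(i) {
      categorize(
        fold_change = fc[i], holm_p = holm_p[i],
        present_test = detected[i, s], present_ref = detected[i, reference],
        comparable = pf$retained[i],
        fc_obvious = fc_obvious, alpha = alpha
      )
    }, character(1L))
    out[[paste0("category_", s)]] <- cat_mat[, k]
  }
  rank_cat <- c(not_comparable = 0, unchanged = 1, significant = 2,
                obvious = 3, absent_present = 4)
  out$category <- apply(cat_mat, 1L, function(cc) {
    cc[which.max(rank_cat[cc])]
  })
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
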