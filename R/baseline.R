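#' Per-molecule t-test baseline
#'
#' The conventional single-molecule analysis the differential-correlation
#' pipeline is compared against: a Welch two-sample t-test per molecule on
#' the same expression set, selection by an (uncorrected) p-value threshold,
#' and a single-molecule AUC as the Mann-Whitney concordance of the
#' expression values (equal to the in-sample AUC of a univariate logistic
#' fit up to orientation).
#'
#' @param object an [expression_set()] or numeric matrix (then `class`
#'   required).
#' @param class two-level factor (ignored for an [expression_set()]).
#' @param alpha selection threshold on the per-molecule p-value (default
#'   0.05).
#' @return data.frame of class `"ttest_markers"`: per molecule the class
#'   means, Welch `t`, `p_value`, `auc`, and `selected`; zero-variance
#'   molecules are excluded and listed in attribute `"excluded"`. Attribute
#'   `"auc_summary"` holds mean/sd of the selected molecules' AUCs.
#' @export
ttest_markers <- function(object, class = NULL, alpha = 0.05) {
  if (inherits(object, "expression_set")) {
    vals <- object$values
    class <- object$class
  } else {
    vals <- as.matrix(object)
    if (is.null(class)) stop("'class' is required when 'object' is a matrix")
    class <- droplevels(as.factor(class))
  }
  stopifnot(nlevels(class) == 2)
  is_case <- class == levels(class)[2]
  mols <- colnames(vals)
  excluded <- character()
  rows <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    x <- vals[!is_case, i]; y <- vals[is_case, i]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2 ||
        stats::var(x) == 0 || stats::var(y) == 0) {
      excluded <- c(excluded, mols[i])
      next
    }
    tt <- stats::t.test(y, x)   # Welch; case minus control
    v <- vals[, i]; ok <- !is.na(v)
    # Mann-Whitney concordance of the expression values themselves; equals
    # the in-sample AUC of a univariate logistic fit up to orientation
    rows[[i]] <- data.frame(
      molecule = mols[i], mean_control = mean(x), mean_case = mean(y),
      t = unname(tt$statistic), p_value = tt$p.value,
      auc = roc_auc(v[ok], class[ok]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no molecule with computable variance in both classes")
  out$selected <- out$p_value < alpha
  out <- out[order(out$p_value, out$molecule), , drop = FALSE]
  rownames(out) <- NULL
  sel <- out$auc[out$selected]
  attr(out, "auc_summary") <- c(mean = mean(sel), sd = stats::sd(sel),
                                n_selected = length(sel))
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  class(out) <- c("ttest_markers", "data.frame")
  out
}

#' @export
print.ttest_markers <- function(x, digits = 3, n = 10, ...) {
  s <- attr(x, "auc_summary")
  cat(sprintf("Welch t-test baseline: %d molecules, %d selected at alpha = %g\n",
              nrow(x), sum(x$selected), attr(x, "alpha")))
  if (s[["n_selected"]] > 0) {
    cat(sprintf("  selected-molecule AUC: %.3f +/- %.3f\n",
                s[["mean"]], if (is.na(s[["sd"]])) 0 else s[["sd"]]))
  }
  print(format(utils::head(as.data.frame(x), n), digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' Best main-effects logistic AUC over molecule subsets
#'
#' Exhaustive search over all subsets of the given size: for each subset a
#' main-effects-only logistic model (no interactions) is fitted and the
#' maximum in-sample AUC returned. This is the multivariate extension of the
#' t-test baseline that the paired interaction models are compared against.
#'
#' @param object an [expression_set()] or numeric matrix (then `class`
#'   required).
#' @param molecules character vector of candidate molecules.
#' @param class two-level factor (ignored for an [expression_set()]).
#' @param subset_size molecules per model (default 4).
#' @param max_models refuse to enumerate more than this many subsets
#'   (default 1e6).
#' @return list: `auc` (best in-sample AUC), `molecules` (best subset),
#'   `n_models` evaluated.
#' @export
best_subset_auc <- function(object, molecules, class = NULL, subset_size = 4,
                            max_models = 1e6) {
  if (inherits(object, "expression_set")) {
    vals <- object$values
    class <- object$class
  } else {
    vals <- as.matrix(object)
    if (is.null(class)) stop("'class' is required when 'object' is a matrix")
    class <- droplevels(as.factor(class))
  }
  molecules <- as.character(molecules)
  stopifnot(all(molecules %in% colnames(vals)))
  k <- length(molecules)
  if (k < subset_size) {
    stop(sprintf("need at least %d candidate molecules, have %d", subset_size, k))
  }
  nm <- choose(k, subset_size)
  if (nm > max_models) {
    stop(sprintf(paste0("%d subsets of size %d exceed the cap of %g; ",
                        "shrink the candidate set or raise 'max_models'"),
                 nm, subset_size, max_models))
  }
  y <- as.integer(class == levels(class)[2])
  best <- -Inf; best_set <- NULL
  combos <- utils::combn(molecules, subset_size)
  for (ci in seq_len(ncol(combos))) {
    X <- cbind(1, vals[, combos[, ci], drop = FALSE])
    cc <- stats::complete.cases(X)
    fit <- suppressWarnings(stats::glm.fit(X[cc, , drop = FALSE], y[cc],
                                           family = stats::binomial(),
                                           control = list(maxit = 100)))
    a <- roc_auc(fit$fitted.values, class[cc])
    if (a > best) { best <- a; best_set <- combos[, ci] }
  }
  list(auc = best, molecules = best_set, n_models = ncol(combos))
}
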