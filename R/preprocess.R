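# Probe filtering, per-feature winsorization and covariate-adjusted
# residualization of the beta matrix.

#' Filter QC-flagged probes
#'
#' Removes every probe carrying a non-empty QC flag set (cross-reactive,
#' SNP-overlapping, sex-chromosome, non-CpG) from the beta matrix and its
#' annotation.
#'
#' @param beta Probes x samples numeric matrix with probe ids as rownames.
#' @param annot Probe annotation data frame (`probe_id`, `chromosome`,
#'   `position`, `gene`, `flags`; `flags` is a comma-separated string,
#'   empty when unflagged).
#' @return List with the filtered `beta`, matching `annot`, and a `report`
#'   (counts removed per flag category, total removed, retained).
#' @export
filter_probes <- function(beta, annot) {
  missing <- setdiff(rownames(beta), annot$probe_id)
  if (length(missing))
    stop("probes without annotation: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  ann <- annot[match(rownames(beta), annot$probe_id), , drop = FALSE]
  flag_list <- strsplit(ifelse(is.na(ann$flags), "", ann$flags), ",",
                        fixed = TRUE)
  flagged <- lengths(flag_list) > 0L
  categories <- c("cross_reactive", "snp", "sex_chromosome", "non_cpg")
  per_flag <- vapply(categories, function(f)
    sum(vapply(flag_list, function(v) f %in% v, logical(1))), integer(1))
  keep <- !flagged
  list(beta = beta[keep, , drop = FALSE],
       annot = ann[keep, , drop = FALSE],
       report = list(n_input = nrow(beta),
                     n_removed = sum(flagged),
                     n_retained = sum(keep),
                     removed_per_flag = as.list(per_flag)))
}

#' Winsorize each feature of the beta matrix
#'
#' Per probe (row), values above the `upper_q` quantile are replaced by
#' that quantile and values below the `lower_q` quantile by that quantile.
#' Quantiles use linear interpolation of order statistics (the k-th order
#' statistic of n values sits at quantile (k-1)/(n-1)).
#'
#' @param beta Probes x samples numeric matrix.
#' @param lower_q,upper_q Winsorization quantiles, default 0.05 and 0.95.
#' @return Matrix of the same shape and dimnames.
#' @export
winsorize <- function(beta, lower_q = 0.05, upper_q = 0.95) {
  stopifnot(lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  q <- t(apply(beta, 1, quantile, probs = c(lower_q, upper_q),
               type = 7, names = FALSE))
  lo <- matrix(q[, 1], nrow(beta), ncol(beta))
  hi <- matrix(q[, 2], nrow(beta), ncol(beta))
  out <- pmin(pmax(beta, lo), hi)
  dimnames(out) <- dimnames(beta)
  out
}

#' Build the covariate design matrix
#'
#' Intercept + age + sex + ancestry + smoking (two dummies) + study wave +
#' five of the six cell fractions (one dropped for the simplex constraint) +
#' OP count. Errors on a rank-deficient design, naming the collinear
#' columns.
#'
#' @param covariates Covariate table (see [generate_cohort()]; must contain
#'   `op_count`).
#' @param drop_cell Which cell-fraction column to drop (default `"gran"`).
#' @return Numeric design matrix, samples in rows.
#' @export
design_matrix <- function(covariates, drop_cell = "gran") {
  cells <- c("cd8t", "cd4t", "nk", "bcell", "mono", "gran")
  stopifnot(drop_cell %in% cells,
            all(c("age", "sex", "ancestry", "smoking", "wave", "op_count",
                  cells) %in% names(covariates)))
  if (!all(covariates$smoking %in% c("never", "former", "current")))
    stop("smoking must be never/former/current", call. = FALSE)
  if (!all(covariates$sex %in% c("F", "M")))
    stop("sex must be F/M", call. = FALSE)
  if (!all(covariates$wave %in% c("PEG1", "PEG2")))
    stop("wave must be PEG1/PEG2", call. = FALSE)
  d <- covariates
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$smoking <- factor(d$smoking, levels = c("never", "former", "current"))
  d$wave <- factor(d$wave, levels = c("PEG1", "PEG2"))
  keep_cells <- setdiff(cells, drop_cell)
  form <- stats::as.formula(paste(
    "~ age + sex + ancestry + smoking + wave +",
    paste(keep_cells, collapse = " + "), "+ op_count"))
  X <- model.matrix(form, data = d)
  # drop unused factor levels' all-zero columns before the rank check
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(X) <- covariates$participant_id
  X
}

#' Covariate-adjusted residual matrix
#'
#' Regresses each probe on the covariate design and returns the residuals
#' that downstream association tests consume. `mode = "ols"` gives plain
#' per-feature least-squares residuals (orthogonal to the design).
#' `mode = "eb"` shrinks each probe's coefficient vector toward the
#' across-probe mean coefficient, with per-covariate shrinkage weights
#' inverse to the sampling variances (ridge-toward-prior; the intercept is
#' never shrunk), before forming residuals.
#'
#' Disease status is deliberately not part of the design: methylation can
#' be a mediator between exposure and disease, so conditioning on case
#' status would open a collider path. Stratified analyses instead subset
#' samples before residualizing.
#'
#' @param beta Probes x samples matrix (filtered, winsorized).
#' @param covariates Covariate table aligned to `colnames(beta)`.
#' @param mode `"ols"` (default) or `"eb"`.
#' @param drop_cell Cell fraction dropped from the design.
#' @return Residual matrix with the same dimnames as `beta`; the design is
#'   attached as attribute `"design"`.
#' @export
residualize <- function(beta, covariates, mode = c("ols", "eb"),
                        drop_cell = "gran") {
  mode <- match.arg(mode)
  if (!setequal(colnames(beta), covariates$participant_id))
    stop("samples in beta and covariates differ", call. = FALSE)
  covariates <- covariates[match(colnames(beta),
                                 covariates$participant_id), , drop = FALSE]
  X <- design_matrix(covariates, drop_cell = drop_cell)
  Y <- t(beta)                       # samples x probes
  qx <- qr(X)
  if (mode == "ols") {
    R <- t(qr.resid(qx, Y))
  } else {
    n <- nrow(X); k <- ncol(X)
    if (n <= k) stop("eb mode needs more samples than covariates",
                     call. = FALSE)
    XtX <- crossprod(X)
    XtXinv <- chol2inv(chol(XtX))
    B <- t(qr.coef(qx, Y))          # probes x k OLS coefficients
    res_ols <- qr.resid(qx, Y)
    s2 <- colSums(res_ols^2) / (n - k)            # per-probe residual var
    ckk <- diag(XtXinv)
    b_bar <- colMeans(B)
    # prior variance per covariate: across-probe coefficient variance
    # minus the mean sampling variance, floored; intercept never shrunk
    tau2 <- apply(B, 2, var) - mean(s2) * ckk
    tau2 <- pmax(tau2, 1e-8)
    tau2[1] <- Inf
    XtY <- crossprod(X, Y)           # k x probes
    Bt <- matrix(0, nrow(beta), k)
    prior_prec <- 1 / tau2
    for (g in seq_len(nrow(beta))) {
      A <- XtX / s2[g] + diag(prior_prec, k)
      rhs <- XtY[, g] / s2[g] + prior_prec * b_bar
      Bt[g, ] <- solve(A, rhs)
    }
    R <- beta - tcrossprod(Bt, X)
    R <- R - rowMeans(R)             # re-center (intercept not shrunk)
  }
  dimnames(R) <- dimnames(beta)
  attr(R, "design") <- X
  attr(R, "mode") <- mode
  R
}
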