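#' Fit the cell-means linear model to an expression set
#'
#' Fits, gene by gene (in one vectorised least-squares pass), the model
#' `S = GYT + R + eps`: one mean per genotype:tissue:condition cell plus a
#' fixed, sum-to-zero biological-replicate effect. Returns per-gene cell-mean
#' estimates, residual variances and the shared unscaled covariance needed
#' for contrast standard errors.
#'
#' @param expr An `expression_set` (see [simulate_expression()] or
#'   [expression_set()]).
#' @return A `moderated_fit` list: `coefficients` (genes x cells),
#'   `sigma2`, `df_residual`, `cov_unscaled`, `cells` (tibble mapping cell
#'   labels to genotype/tissue/condition), `sample_meta`. Empirical-Bayes
#'   hyperparameters are filled in by [ebayes_moderate()].
#' @export
fit_linear_model <- function(expr) {
  stopifnot(inherits(expr, "expression_set"))
  meta <- expr$sample_meta
  cell <- interaction(meta$genotype, meta$tissue, meta$condition,
                      drop = TRUE, sep = ":")
  reps <- factor(meta$replicate)
  n <- nrow(meta)
  if (nlevels(reps) > 1) {
    X <- model.matrix(~ 0 + cell + reps,
                      contrasts.arg = list(reps = "contr.sum"))
  } else {
    X <- model.matrix(~ 0 + cell)
  }
  colnames(X) <- sub("^cell", "", colnames(X))
  rank <- qr(X)$rank
  df_resid <- n - rank
  if (df_resid <= 0) {
    stop("model is saturated: no residual degrees of freedom ",
         "(need >=2 replicates per cell)", call. = FALSE)
  }
  fit <- lm.fit(X, t(expr$values))
  coefs <- if (is.matrix(fit$coefficients)) {
    t(fit$coefficients)
  } else {
    matrix(fit$coefficients, nrow = 1,
           dimnames = list(rownames(expr$values), names(fit$coefficients)))
  }
  resid2 <- if (is.matrix(fit$residuals)) {
    colSums(fit$residuals^2)
  } else {
    setNames(sum(fit$residuals^2), rownames(expr$values))
  }
  cell_cols <- levels(cell)
  cov_unscaled <- chol2inv(chol(crossprod(X)))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))

  cells <- tibble::tibble(cell = levels(cell)) |>
    tidyr::separate_wider_delim("cell", delim = ":",
                                names = c("genotype", "tissue", "condition"),
                                cols_remove = FALSE)

  structure(list(
    coefficients = coefs[, cell_cols, drop = FALSE],
    all_coefficients = coefs,
    sigma2 = resid2 / df_resid,
    df_residual = rep(df_resid, nrow(coefs)),
    cov_unscaled = cov_unscaled,
    cells = cells,
    sample_meta = meta,
    df_prior = NULL, s2_prior = NULL, s2_post = NULL
  ), class = "moderated_fit")
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' a scaled inverse-chi-square prior on the gene-wise residual variances by
#' moment matching of `log(s_g^2)` against a scaled-F distribution
#' (digamma/trigamma inversion), then forms the posterior variance
#' `s2_post = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` used by all moderated
#' t-statistics. If the observed variances are underdispersed relative to
#' the chi-square sampling noise, `d0 = Inf` and `s2_post = s0^2`.
#'
#' @param fit A `moderated_fit` from [fit_linear_model()].
#' @return The fit with `df_prior`, `s2_prior` and `s2_post` filled in.
#' @export
ebayes_moderate <- function(fit) {
  stopifnot(inherits(fit, "moderated_fit"))
  ok <- fit$df_residual > 0 & is.finite(fit$sigma2)
  if (sum(ok) < 10) {
    stop("need at least 10 genes with positive residual df", call. = FALSE)
  }
  pos <- ok & fit$sigma2 > 0
  hyper <- if (sum(pos) < 2 || var(log(fit$sigma2[pos])) < 1e-14) {
    # degenerate: all (positive) variances equal -> no between-gene spread
    list(df_prior = Inf, s2_prior = mean(fit$sigma2[ok]))
  } else {
    fit_f_dist(fit$sigma2[pos], fit$df_residual[pos][1])
  }
  fit$df_prior <- hyper$df_prior
  fit$s2_prior <- hyper$s2_prior
  fit$s2_post <- if (is.finite(hyper$df_prior)) {
    (hyper$df_prior * hyper$s2_prior + fit$df_residual * fit$sigma2) /
      (hyper$df_prior + fit$df_residual)
  } else {
    rep(hyper$s2_prior, length(fit$sigma2))
  }
  fit
}

# moment matching of log s^2 to log scaled-F (Smyth 2004)
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1)
  rhs <- evar - trigamma(df / 2)
  if (rhs > 0) {
    df_prior <- 2 * trigamma_inverse(rhs)
    s2_prior <- exp(ebar + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(ebar)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Newton inversion of trigamma on (0, Inf)
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Storey q-values with fixed-lambda pi0 estimation
#'
#' Estimates the null proportion `pi0 = #\{p > lambda\} / ((1 - lambda) m)`
#' at `lambda = 0.5`, clamped to `(0, 1]`, and converts p-values to
#' q-values: on the sorted p-values, `q(i) = min_{j >= i} pi0 * m * p(j)/j`.
#' Setting `pi0 = 1` recovers Benjamini-Hochberg adjusted p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter for pi0 estimation.
#' @param pi0 Optional fixed pi0 overriding the estimate.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- sum(p > lambda) / ((1 - lambda) * m)
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Attributes of pi0 estimation
#' @noRd
estimate_pi0 <- function(p, lambda = 0.5) {
  m <- length(p)
  min(max(sum(p > lambda) / ((1 - lambda) * m), 1 / m), 1)
}

# contrast estimate + moderated inference; contrast is a named numeric
# vector over cell labels
contrast_stats <- function(fit, contrast) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (is.null(fit$s2_post)) fit <- ebayes_moderate(fit)
  p_all <- colnames(fit$all_coefficients)
  L <- setNames(numeric(length(p_all)), p_all)
  missing <- setdiff(names(contrast), p_all)
  if (length(missing)) {
    stop("unknown cell(s) in contrast: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  L[names(contrast)] <- contrast
  est <- unname(drop(fit$all_coefficients %*% L))
  se_unscaled <- sqrt(drop(t(L) %*% fit$cov_unscaled %*% L))
  se <- unname(sqrt(fit$s2_post)) * se_unscaled
  tstat <- ifelse(se > 0, est / se,
                  ifelse(est == 0, 0, Inf * sign(est)))
  df_total <- fit$df_prior + fit$df_residual
  pval <- ifelse(is.finite(tstat),
                 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE),
                 0)
  tibble::tibble(gene_id = rownames(fit$all_coefficients),
                 estimate = est, se = se, t = tstat, df = df_total,
                 p = pval)
}

cell_label <- function(fit, genotype, tissue, condition) {
  hit <- fit$cells |>
    dplyr::filter(.data$genotype == .env$genotype,
                  .data$tissue == .env$tissue,
                  .data$condition == .env$condition)
  if (nrow(hit) != 1) {
    stop("no unique design cell for genotype=", genotype, ", tissue=",
         tissue, ", condition=", condition, call. = FALSE)
  }
  hit$cell
}

#' Call differentially expressed genes for a mutant-vs-WT contrast
#'
#' Computes the moderated log2 fold-change (mutant cell mean minus WT cell
#' mean), moderated t and p-value, Storey q-values across genes, and applies
#' the DEG rule: fold-change above 2 (`|log2FC| > 1`) and `q < 0.01`.
#'
#' @param fit A `moderated_fit`, moderated via [ebayes_moderate()] (done
#'   automatically if not).
#' @param mutant,reference Genotype labels of the contrast (reference
#'   defaults to `"WT"`).
#' @param tissue,condition Design cell selectors.
#' @param fc_threshold Log2 fold-change threshold (strict inequality).
#' @param q_threshold Q-value threshold (strict inequality).
#' @return A tibble (`deg_table`): gene_id, contrast, log2FC, t, p, q,
#'   is_DEG, direction (`up`/`down` in the mutant).
#' @export
call_degs <- function(fit, mutant, reference = "WT", tissue = "leaf",
                      condition = "SD", fc_threshold = 1, q_threshold = 0.01) {
  geno <- unique(fit$cells$genotype)
  for (g in c(mutant, reference)) {
    if (!g %in% geno) stop("unknown genotype: ", g, call. = FALSE)
  }
  cm <- cell_label(fit, mutant, tissue, condition)
  cr <- cell_label(fit, reference, tissue, condition)
  contrast <- setNames(c(1, -1), c(cm, cr))
  st <- contrast_stats(fit, contrast)
  st |>
    dplyr::mutate(
      contrast = paste0(mutant, ":", reference),
      tissue = tissue, condition = condition,
      log2FC = .data$estimate,
      q = storey_qvalues(.data$p),
      is_DEG = abs(.data$log2FC) > fc_threshold & .data$q < q_threshold,
      direction = dplyr::if_else(.data$log2FC > 0, "up", "down")
    ) |>
    dplyr::select("gene_id", "contrast", "tissue", "condition", "log2FC",
                  "t", "p", "q", "is_DEG", "direction")
}

#' @rdname tidy.duetseq
#' @export
tidy.moderated_fit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell",
                        values_to = "estimate") |>
    dplyr::left_join(x$cells, by = "cell")
}

#' @rdname tidy.duetseq
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$coefficients),
                 n_samples = nrow(x$sample_meta),
                 df_residual = x$df_residual[1],
                 df_prior = x$df_prior %||% NA_real_,
                 s2_prior = x$s2_prior %||% NA_real_)
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit>", nrow(x$coefficients), "genes,",
      ncol(x$coefficients), "design cells, residual df",
      x$df_residual[1])
  if (!is.null(x$df_prior)) cat(", prior df", signif(x$df_prior, 4))
  cat("\n")
  invisible(x)
}
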