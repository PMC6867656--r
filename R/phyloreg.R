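#' Brownian-motion phylogenetic covariance matrix
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`
#' (diagonal = root-to-tip depth), the covariance of a unit-rate Brownian
#' trait on the tree.
#'
#' @param tree A rooted `phylo` tree with nonnegative branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

#' Stationary Ornstein-Uhlenbeck covariance matrix
#'
#' `V[i, j] = exp(-alpha * d_ij) / (2 * alpha)` with `d_ij` the tip-to-tip
#' patristic distance: the stationary covariance of an OU process with
#' selection strength `alpha` and unit diffusion. As `alpha -> 0` the kernel
#' approaches Brownian-motion scaling.
#'
#' @inheritParams bm_covariance
#' @param alpha Positive selection strength.
#' @export
ou_covariance <- function(tree, alpha) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  D <- ape::cophenetic.phylo(tree)
  exp(-alpha * D) / (2 * alpha)
}

#' Maximum-likelihood phylogenetic regression with measurement error
#'
#' Fits `y = X beta + eps`, `eps ~ N(0, sigma_p^2 V + sigma_e^2 I)`, where
#' `V` is the Brownian-motion covariance of the tree (or a stationary OU
#' kernel whose selection strength `alpha` is estimated), by maximum
#' likelihood. The default design is the Ku/genome-length model: intercept,
#' binary Ku, log10 genome length, and their interaction. The response is
#' logit GC content (or GC at fourfold degenerate sites, optionally
#' logit-transformed).
#'
#' The mixture weight `w = sigma_p^2 / (sigma_p^2 + sigma_e^2)`-like ratio is
#' profiled on `[0, 1]` with the overall scale concentrated out, so both
#' variance components are bounded below at zero. Coefficient p-values use t
#' statistics with `n - p` degrees of freedom.
#'
#' @param traits Tibble with columns `taxon`, the response column, `ku`
#'   (0/1) and `log10_length`. A `gc` column is logit-transformed on the fly
#'   when `response = "gc_logit"` and no `gc_logit` column exists.
#' @param tree Rooted `phylo` tree; tips absent from either side are dropped
#'   with a message.
#' @param response `"gc_logit"`, `"gc4"` or `"gc4_logit"`.
#' @param model `"BM"` or `"OU"`.
#' @param formula Model formula over trait columns (default
#'   `~ ku * log10_length`).
#' @return Object of class `breakgc_pgls`; see [tidy.breakgc_pgls()] /
#'   [glance.breakgc_pgls()] for tabular views.
#' @export
fit_pgls <- function(traits, tree, response = c("gc_logit", "gc4",
                                                "gc4_logit"),
                     model = c("BM", "OU"),
                     formula = ~ ku * log10_length) {
  response <- match.arg(response)
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"), "taxon" %in% names(traits))
  traits <- as.data.frame(traits)
  if (response == "gc_logit" && !"gc_logit" %in% names(traits)) {
    traits$gc_logit <- logit_gc(traits$gc)
  }
  if (response == "gc4_logit") {
    traits$gc4_logit <- logit_gc(traits$gc4)
  }
  common <- intersect(tree$tip.label, traits$taxon)
  dropped <- length(tree$tip.label) - length(common) +
    sum(!traits$taxon %in% common)
  if (length(common) == 0L) stop("no taxa shared between tree and traits")
  if (dropped > 0L) {
    message(dropped, " taxa absent from tree or trait table dropped")
    tree <- ape::keep.tip(tree, common)
  }
  traits <- traits[match(tree$tip.label, traits$taxon), , drop = FALSE]
  y <- traits[[response]]
  if (anyNA(y)) stop("missing values in response ", response)
  X <- stats::model.matrix(formula, data = traits)
  if (nrow(X) < nrow(traits)) stop("missing values in predictors")
  p <- ncol(X)
  n <- nrow(X)
  if (n < p + 2L) stop("need at least p + 2 taxa")
  if (qr(X)$rank < p) {
    const <- colnames(X)[apply(X, 2L, function(z) length(unique(z)) == 1L)]
    const <- setdiff(const, "(Intercept)")
    stop("singular design matrix",
         if (length(const)) paste0(": constant column(s) ",
                                   paste(const, collapse = ", ")) else "")
  }

  if (model == "BM") {
    V <- bm_covariance(tree)
    best <- pgls_profile_w(V, X, y)
    alpha_hat <- NA_real_
    k <- p + 2L
  } else {
    D <- ape::cophenetic.phylo(tree)
    obj <- function(log_alpha) {
      a <- exp(log_alpha)
      -pgls_profile_w(exp(-a * D) / (2 * a), X, y)$loglik
    }
    grid <- log(10^seq(-2, 2, by = 0.5))
    g0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
    opt <- optimize(obj, interval = c(g0 - log(10), g0 + log(10)),
                    tol = 1e-6)
    alpha_hat <- exp(opt$minimum)
    V <- exp(-alpha_hat * D) / (2 * alpha_hat)
    best <- pgls_profile_w(V, X, y)
    k <- p + 3L
  }

  se <- sqrt(diag(best$beta_cov))
  tstat <- best$beta / se
  pvals <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  structure(
    list(
      model = model, response = response, n = n, k = k,
      beta = best$beta, se = se, t = tstat, p_values = pvals,
      sigma_p2 = best$sigma_p2, sigma_e2 = best$sigma_e2,
      ou_alpha = alpha_hat, loglik = best$loglik,
      aic = 2 * k - 2 * best$loglik,
      w = best$w, formula = formula, terms = colnames(X)
    ),
    class = "breakgc_pgls"
  )
}

# profile likelihood over the V-vs-I mixture weight, scale concentrated out
pgls_profile_w <- function(V, X, y, tol = 1e-9) {
  n <- length(y)
  eval_w <- function(w) {
    A <- w * V
    diag(A) <- diag(A) + (1 - w)
    L <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(L)) {
      return(list(ll = -Inf, fit = NULL, s = NA_real_, Xi = NULL,
                  rss = NA_real_))
    }
    Xi <- backsolve(L, X, transpose = TRUE)
    yi <- backsolve(L, y, transpose = TRUE)
    fit <- stats::lm.fit(Xi, yi)
    rss <- sum(fit$residuals^2)
    s <- rss / n
    ll <- -n / 2 * (log(2 * pi) + 1 + log(s)) - sum(log(diag(L)))
    list(ll = ll, fit = fit, s = s, Xi = Xi, rss = rss)
  }
  opt <- optimize(function(w) -eval_w(w)$ll, interval = c(0, 1), tol = tol)
  # compare against the boundaries, which optimize() can miss
  cand <- c(opt$minimum, 0, 1)
  lls <- vapply(cand, function(w) eval_w(w)$ll, numeric(1))
  w <- cand[which.max(lls)]
  ev <- eval_w(w)
  p <- ncol(X)
  s_unb <- ev$rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(ev$Xi)))
  list(
    w = w,
    beta = setNames(ev$fit$coefficients, colnames(X)),
    beta_cov = s_unb * XtX_inv,
    sigma_p2 = ev$s * w,
    sigma_e2 = ev$s * (1 - w),
    loglik = ev$ll
  )
}

#' @export
print.breakgc_pgls <- function(x, ...) {
  cat("<breakgc_pgls> ", x$model, " model, response ", x$response,
      ", n = ", x$n, "\n", sep = "")
  print(tidy(x))
  cat(sprintf("sigma_p2 = %.4g, sigma_e2 = %.4g%s, logLik = %.2f, AIC = %.2f\n",
              x$sigma_p2, x$sigma_e2,
              if (is.na(x$ou_alpha)) "" else sprintf(", alpha = %.4g",
                                                     x$ou_alpha),
              x$loglik, x$aic))
  invisible(x)
}

#' Tidy a phylogenetic regression fit
#'
#' @param x A `breakgc_pgls` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.breakgc_pgls <- function(x, ...) {
  tibble::tibble(term = x$terms, estimate = unname(x$beta),
                 std.error = unname(x$se), statistic = unname(x$t),
                 p.value = unname(x$p_values))
}

#' One-row model summary of a phylogenetic regression fit
#'
#' @inheritParams tidy.breakgc_pgls
#' @return Tibble: `model`, `response`, `n`, `sigma_p2`, `sigma_e2`,
#'   `ou_alpha`, `logLik`, `AIC`.
#' @export
glance.breakgc_pgls <- function(x, ...) {
  tibble::tibble(model = x$model, response = x$response, n = x$n,
                 sigma_p2 = x$sigma_p2, sigma_e2 = x$sigma_e2,
                 ou_alpha = x$ou_alpha, logLik = x$loglik, AIC = x$aic)
}

#' Restrict a trait table to genera with uniform Ku incidence
#'
#' Drops genera represented by fewer than two genomes, then genera whose
#' members disagree on Ku presence — a guard against recent horizontal
#' transfer of the NHEJ machinery confounding the regression.
#'
#' @param traits Tibble with columns `genus` and `ku`.
#' @return Filtered tibble.
#' @export
uniform_ku_filter <- function(traits) {
  stopifnot(all(c("genus", "ku") %in% names(traits)))
  traits |>
    dplyr::group_by(.data$genus) |>
    dplyr::filter(dplyr::n() >= 2L, length(unique(.data$ku)) == 1L) |>
    dplyr::ungroup()
}

#' Point-biserial correlation between Ku presence and GC content
#'
#' Pearson correlation of the binary Ku indicator with GC content across
#' genomes, with its two-sided p-value.
#'
#' @param traits Tibble with columns `ku` (0/1) and `gc`.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
ku_gc_correlation <- function(traits) {
  stopifnot(all(c("ku", "gc") %in% names(traits)))
  if (length(unique(traits$ku)) < 2L) stop("`ku` is constant")
  if (length(unique(traits$gc)) < 2L) stop("`gc` is constant")
  ct <- cor.test(traits$gc, as.numeric(traits$ku))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(traits))
}

#' Benjamini-Hochberg significance flags across a set of fits
#'
#' Collects every coefficient p-value from a list of `breakgc_pgls` fits and
#' applies the step-up FDR rule jointly.
#'
#' @param fits Named list of `breakgc_pgls` objects.
#' @param alpha Target FDR (default 0.05).
#' @return Tibble: `fit`, `term`, `estimate`, `p.value`, `significant`.
#' @export
bh_table <- function(fits, alpha = 0.05) {
  tbl <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(tidy(f), fit = nm, .before = 1)
  })
  dplyr::mutate(tbl, significant = bh_correct(.data$p.value, fdr = alpha))
}
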