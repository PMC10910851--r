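#' Fit the per-gene mutational-variance mixed model
#'
#' Poisson GLMM (log link, Laplace approximation) for the read counts of
#' one gene across the MA lines of a strain and their ancestor:
#' \deqn{\log \lambda = \beta_0 + \beta_1 x_i + u_{1i} x_i + b_k + o}
#' where \eqn{x_i} is the per-line covariate (generations since the
#' ancestor, or the accumulated mutation count), \eqn{u_{1i} \sim N(0,
#' \sigma^2_u)} is a per-line random slope whose variance measures
#' between-line divergence, \eqn{b_k \sim N(0, \sigma^2_b)} is an
#' observation-level random effect absorbing extra-Poisson dispersion,
#' and \eqn{o} is the size-factor offset. The mutational variance is
#' \eqn{V_m = 2\,\mathrm{Var}(u_{1i})} (per generation, or per mutation
#' when `covariate_kind = "mutations"`), the environmental variance is
#' \eqn{V_e = \sigma^2_b}, and the mutational heritability is
#' \eqn{h^2_m = V_m / V_e}.
#'
#' A fixed intercept is included even though the divergence model can be
#' written without one: a Poisson model for expression level needs a
#' baseline. The covariate is rescaled to unit range internally (and the
#' estimates mapped back exactly), which makes the fit invariant by
#' construction under rescaling of the covariate. The offset defaults to
#' \eqn{\ln(1/sf)} (`offset_sign = "printed"`); `"standard"` uses
#' \eqn{+\ln(sf)}, the usual normalization convention.
#'
#' @param y integer counts, one per sample.
#' @param line per-sample line identifier (ancestor samples share one).
#' @param x per-sample covariate value (0 for ancestor samples).
#' @param sf per-sample size factors.
#' @param covariate_kind `"generations"` or `"mutations"`; recorded in
#'   the result.
#' @param offset_sign `"printed"` for \eqn{\ln(1/sf)}, `"standard"` for
#'   \eqn{+\ln(sf)}.
#' @param gene_id optional label.
#' @return an object of class `mutvar_fit`: gene_id, beta1, var_u, v_m,
#'   v_e, h2_m (NA with `h2_defined = FALSE` when \eqn{V_e \approx 0}),
#'   covariate_kind, converged, loglik.
#' @export
fit_gene_glmm <- function(y, line, x, sf = NULL,
                          covariate_kind = c("generations", "mutations"),
                          offset_sign = c("printed", "standard"),
                          gene_id = NA_character_) {
  covariate_kind <- match.arg(covariate_kind)
  offset_sign <- match.arg(offset_sign)
  if (all(y == 0)) stopf("gene has zero counts in every sample")
  line <- factor(line)
  if (length(unique(x[!duplicated(line)])) < 3)
    stopf("need >= 3 lines with a varying covariate")
  if (is.null(sf)) sf <- rep(1, length(y))
  off <- if (offset_sign == "printed") -log(sf) else log(sf)
  xscale <- max(abs(x))
  if (xscale == 0) stopf("covariate is identically zero")
  dat <- data.frame(y = y, line = line, xs = x / xscale,
                    obs = factor(seq_along(y)))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(y ~ xs + (0 + xs | line) + (1 | obs),
                data = dat, family = stats::poisson(), offset = off,
                control = lme4::glmerControl(
                  calc.derivs = FALSE,
                  check.conv.singular = "ignore",
                  optCtrl = list(maxfun = 500)))
  ))
  vc <- lme4::VarCorr(fit)
  var_u <- as.numeric(vc$line[1, 1]) / xscale^2
  var_b <- as.numeric(vc$obs[1, 1])
  beta1 <- unname(lme4::fixef(fit)["xs"]) / xscale
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))
  v_m <- 2 * var_u
  h2_defined <- var_b > 1e-12
  out <- list(gene_id = gene_id, beta1 = beta1, var_u = var_u,
              v_m = v_m, v_e = var_b,
              h2_m = if (h2_defined) v_m / var_b else NA_real_,
              h2_defined = h2_defined,
              covariate_kind = covariate_kind,
              converged = converged,
              loglik = as.numeric(stats::logLik(fit)))
  class(out) <- "mutvar_fit"
  out
}

#' @export
print.mutvar_fit <- function(x, ...) {
  cat(sprintf("Mutational variance fit%s (covariate: %s)\n",
              if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id),
              x$covariate_kind))
  cat(sprintf("  beta1 = %.4g  Vm = %.4g  Ve = %.4g  h2m = %.4g%s\n",
              x$beta1, x$v_m, x$v_e, x$h2_m,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
coef.mutvar_fit <- function(object, ...) {
  c(beta1 = object$beta1, var_u = object$var_u, v_m = object$v_m,
    v_e = object$v_e, h2_m = object$h2_m)
}

#' @export
logLik.mutvar_fit <- function(object, ...) {
  structure(object$loglik, df = 4, class = "logLik")
}

#' Per-gene variance components across a strain
#'
#' Runs [fit_gene_glmm()] for every gene of one strain (its MA lines
#' plus ancestor replicates; ancestors enter with covariate 0) and
#' summarizes strain-level medians.
#'
#' @param counts an `ma_counts` object, typically filtered.
#' @param covariate_kind `"generations"` or `"mutations"`.
#' @param strain strain to fit; default is the first.
#' @param exclude_lines optional line ids to drop before fitting (e.g.
#'   mutator lines).
#' @param sf optional precomputed size factors (named by sample); by
#'   default the median-of-ratios factors of `counts`.
#' @param offset_sign see [fit_gene_glmm()].
#' @return a data.frame (one row per gene) with attribute `medians`
#'   holding median v_m, v_e and h2_m over converged fits.
#' @export
variance_table <- function(counts, covariate_kind = c("generations", "mutations"),
                           strain = NULL, exclude_lines = NULL, sf = NULL,
                           offset_sign = c("printed", "standard")) {
  covariate_kind <- match.arg(covariate_kind)
  offset_sign <- match.arg(offset_sign)
  smp <- counts$samples
  if (is.null(strain)) strain <- smp$strain[1]
  if (is.null(sf)) sf <- size_factors(counts)
  keep <- smp$strain == strain & !(smp$line_id %in% exclude_lines)
  smp <- smp[keep, ]
  y <- counts$counts[, smp$sample_id, drop = FALSE]
  sf <- sf[smp$sample_id]
  x <- if (covariate_kind == "generations") smp$generations else smp$n_mutations
  x[smp$is_ancestor] <- 0
  rows <- lapply(rownames(y), function(g) {
    f <- tryCatch(
      fit_gene_glmm(y[g, ], smp$line_id, x, sf,
                    covariate_kind = covariate_kind,
                    offset_sign = offset_sign, gene_id = g),
      error = function(e) NULL)
    if (is.null(f))
      return(data.frame(gene_id = g, covariate_kind = covariate_kind,
                        beta1 = NA, var_u = NA, v_m = NA, v_e = NA,
                        h2_m = NA, converged = FALSE, loglik = NA,
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, covariate_kind = covariate_kind,
               beta1 = f$beta1, var_u = f$var_u, v_m = f$v_m, v_e = f$v_e,
               h2_m = f$h2_m, converged = f$converged, loglik = f$loglik,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & !is.na(tab$v_m)
  attr(tab, "medians") <- c(
    v_m = stats::median(tab$v_m[ok]),
    v_e = stats::median(tab$v_e[ok]),
    h2_m = stats::median(tab$h2_m[ok], na.rm = TRUE))
  attr(tab, "strain") <- strain
  tab
}
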