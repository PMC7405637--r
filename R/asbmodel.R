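#' Build the design rows for one candidate site
#'
#' Encodes the 2 x 2 factorial per replicate: `x_r` = 0 for
#' the binding-site (footprint) region and 1 for the flanking region; `x_a` =
#' 0 for the reference allele and 1 for the alternative allele.
#'
#' @param table CountTable `data.frame` from [count_cuts_by_region()]
#'   (columns `replicate`, `allele`, `region`, `count`).
#' @return `data.frame` with columns `y`, `x_r`, `x_a`, `replicate`,
#'   4 rows per replicate.
#' @export
build_design <- function(table) {
  need <- expand.grid(replicate = unique(table$replicate),
                      allele = c("REF", "ALT"),
                      region = c("footprint", "flank"),
                      stringsAsFactors = FALSE)
  key_t <- paste(table$replicate, table$allele, table$region)
  key_n <- paste(need$replicate, need$allele, need$region)
  if (!all(key_n %in% key_t) || anyDuplicated(key_t))
    stop("incomplete design: need one count per allele x region x replicate")
  m <- match(key_n, key_t)
  data.frame(y = as.integer(table$count[m]),
             x_r = as.integer(need$region == "flank"),
             x_a = as.integer(need$allele == "ALT"),
             replicate = need$replicate)
}

.design_matrix <- function(design) {
  cbind(`(Intercept)` = 1, x_r = design$x_r, x_a = design$x_a,
        x_int = design$x_r * design$x_a)
}

# IRLS for a log-link count GLM with fixed NB size theta (Inf = Poisson)
.irls <- function(y, X, beta, theta, max_iter = 100, tol = 1e-10) {
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), 1e-12)
    w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
    z <- eta + (y - mu) / mu
    beta_new <- tryCatch(qr.solve(sqrt(w) * X, sqrt(w) * z),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new)))
      return(list(beta = beta, converged = FALSE))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged)
}

# Cox-Reid adjusted profile log-likelihood of log(theta) given coefficients
.apl <- function(y, X, beta, log_theta, adjust = TRUE) {
  theta <- exp(log_theta)
  mu <- exp(drop(X %*% beta))
  ll <- sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  if (adjust) {
    w <- mu / (1 + mu / theta)
    ll <- ll - 0.5 * as.numeric(
      determinant(crossprod(X, w * X), logarithm = TRUE)$modulus)
  }
  ll
}

.init_beta <- function(y, X) qr.solve(X, log(pmax(y, 0.5)))

#' Fit the negative-binomial interaction GLM for one site
#'
#' Fits `log E(y) = b0 + b_r x_r + b_a x_a + b_int x_r x_a` by iteratively
#' reweighted least squares, with the negative-binomial size (1/dispersion)
#' either supplied (e.g. a common value estimated across sites, the default
#' pipeline behaviour) or estimated for this site by maximising the Cox-Reid
#' adjusted profile likelihood. When the model is saturated (one replicate)
#' or the estimated dispersion is below 1e-8, the Poisson limit is used.
#'
#' Sites where one allele has no phased coverage at all, or where a whole
#' allele-region margin is zero (complete separation, infinite interaction),
#' are reported unconverged with a reason rather than given a fabricated
#' finite coefficient.
#'
#' @param design `data.frame` from [build_design()].
#' @param dispersion `NULL` to estimate per site, or a fixed non-negative
#'   dispersion (NB variance = mu + dispersion * mu^2).
#' @param df_dispersion Residual degrees of freedom behind the dispersion
#'   estimate; used as the Wald reference-t df. Defaults to `4R - 4` for
#'   per-site estimation; pass the pooled df when `dispersion` comes from a
#'   common estimate (then the reference is effectively normal).
#' @return A `glm_fit` list: `beta0`, `beta_r`, `beta_a`, `beta_int`,
#'   `se_int`, `dispersion`, `df`, `loglik`, `converged`, `reason`,
#'   `fitted`.
#' @export
fit_nb_glm <- function(design, dispersion = NULL, df_dispersion = NULL) {
  y <- design$y
  X <- .design_matrix(design)
  n <- length(y); p <- ncol(X)
  fail <- function(reason) list(
    beta0 = NA_real_, beta_r = NA_real_, beta_a = NA_real_,
    beta_int = NA_real_, se_int = NA_real_, dispersion = NA_real_,
    df = NA_real_, loglik = NA_real_, converged = FALSE, reason = reason,
    fitted = rep(NA_real_, n))
  if (n < 4L) return(fail("fewer than 4 design rows"))
  if (all(y[design$x_a == 0] == 0) || all(y[design$x_a == 1] == 0))
    return(fail("no phased coverage"))
  # complete separation: a whole cell margin at zero makes beta_int infinite
  cells <- tapply(y, list(design$x_r, design$x_a), sum)
  if (any(cells == 0))
    return(fail("complete separation"))

  saturated <- n == p
  if (saturated) {
    # fitted means equal observed counts; dispersion unidentifiable -> Poisson
    theta <- Inf
    fit <- .irls(y, X, .init_beta(y, X), theta)
    if (!fit$converged) return(fail("IRLS not converged"))
    beta <- fit$beta
  } else if (!is.null(dispersion)) {
    theta <- if (dispersion <= 1e-8) Inf else 1 / dispersion
    fit <- .irls(y, X, .init_beta(y, X), theta)
    if (!fit$converged) return(fail("IRLS not converged"))
    beta <- fit$beta
  } else {
    beta <- .irls(y, X, .init_beta(y, X), Inf)$beta
    theta <- Inf
    for (k in seq_len(30)) {
      opt <- optimize(function(lt) -.apl(y, X, beta, lt),
                      interval = c(log(1e-4), log(1e8)))
      theta_new <- exp(opt$minimum)
      fit <- .irls(y, X, beta, theta_new)
      if (!fit$converged) return(fail("IRLS not converged"))
      moved <- max(abs(fit$beta - beta))
      beta <- fit$beta
      theta <- theta_new
      if (moved < 1e-9 && k > 2) break
    }
    if (theta >= 1e8 - 1) theta <- Inf  # Poisson limit
  }
  mu <- exp(drop(X %*% beta))
  w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
  cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
  if (is.null(cov)) return(fail("singular information"))
  df <- if (!is.null(df_dispersion)) df_dispersion
        else if (saturated || !is.null(dispersion)) Inf
        else n - p
  ll <- if (is.finite(theta))
    sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  else sum(dpois(y, lambda = mu, log = TRUE))
  beta <- unname(beta)
  list(beta0 = beta[1], beta_r = beta[2], beta_a = beta[3],
       beta_int = beta[4], se_int = sqrt(cov[4, 4]),
       dispersion = if (is.finite(theta)) 1 / theta else 0,
       df = df, loglik = ll, converged = TRUE, reason = "",
       fitted = mu)
}

#' Estimate a common dispersion across candidate sites
#'
#' Maximises the sum of per-site Cox-Reid adjusted profile likelihoods over a
#' single shared dispersion, alternating with per-site coefficient updates.
#' With few replicates per site this pools hundreds of residual degrees of
#' freedom and is far more stable than per-site estimation.
#'
#' @param designs List of design `data.frame`s ([build_design()]); sites with
#'   structural failures are ignored.
#' @return List with `dispersion` and `df` (summed residual degrees of
#'   freedom).
#' @export
estimate_common_dispersion <- function(designs) {
  prep <- lapply(designs, function(d) {
    y <- d$y; X <- .design_matrix(d)
    if (length(y) <= ncol(X)) return(NULL)
    if (all(y[d$x_a == 0] == 0) || all(y[d$x_a == 1] == 0)) return(NULL)
    if (any(tapply(y, list(d$x_r, d$x_a), sum) == 0)) return(NULL)
    list(y = y, X = X)
  })
  prep <- prep[!vapply(prep, is.null, logical(1))]
  if (length(prep) == 0L)
    return(list(dispersion = 0, df = 0))
  betas <- lapply(prep, function(s) .irls(s$y, s$X, .init_beta(s$y, s$X), Inf)$beta)
  theta <- Inf
  for (k in seq_len(15)) {
    obj <- function(lt) -sum(vapply(seq_along(prep), function(i)
      .apl(prep[[i]]$y, prep[[i]]$X, betas[[i]], lt), numeric(1)))
    theta_new <- exp(optimize(obj, interval = c(log(1e-4), log(1e8)))$minimum)
    betas_new <- lapply(seq_along(prep), function(i)
      .irls(prep[[i]]$y, prep[[i]]$X, betas[[i]], theta_new)$beta)
    moved <- max(mapply(function(a, b) max(abs(a - b)), betas, betas_new))
    betas <- betas_new
    theta <- theta_new
    if (moved < 1e-9 && k > 1) break
  }
  df <- sum(vapply(prep, function(s) length(s$y) - ncol(s$X), numeric(1)))
  list(dispersion = if (theta >= 1e8 - 1) 0 else 1 / theta, df = df)
}

#' Wald test of the allele-by-region interaction
#'
#' The null hypothesis is `beta_int = 0`: the flank-to-footprint contrast is
#' the same on both alleles. The two-sided p-value refers
#' `beta_int / se_int` to a t distribution whose degrees of freedom reflect
#' the residual information behind the dispersion estimate (`fit$df`);
#' with a common dispersion pooled over many sites the reference is
#' effectively the standard normal. The sign of `beta_int` is interpreted
#' directly: positive means gain of binding on the variant allele, negative a
#' loss.
#'
#' @param fit A [fit_nb_glm()] result.
#' @return Two-sided p-value, or `NA` if the fit is unusable.
#' @export
test_interaction <- function(fit) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  if (!is.finite(fit$se_int) || fit$se_int <= 0) return(NA_real_)
  z <- fit$beta_int / fit$se_int
  df <- if (is.null(fit$df) || !is.finite(fit$df)) Inf else fit$df
  if (is.finite(df)) 2 * pt(-abs(z), df = df) else 2 * pnorm(-abs(z))
}

#' Likelihood-ratio test of the allele-by-region interaction
#'
#' Refits the site without the interaction term at the same dispersion and
#' refers twice the log-likelihood difference to chi-square with 1 df. An
#' alternative to the default Wald test; both target `beta_int = 0`.
#'
#' @param design `data.frame` from [build_design()].
#' @param fit The full-model [fit_nb_glm()] result on `design`.
#' @return Two-sided p-value, or `NA` if the full fit is unusable.
#' @export
test_interaction_lrt <- function(design, fit) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  y <- design$y
  X0 <- .design_matrix(design)[, 1:3, drop = FALSE]
  theta <- if (fit$dispersion <= 1e-8) Inf else 1 / fit$dispersion
  f0 <- .irls(y, X0, qr.solve(X0, log(pmax(y, 0.5))), theta)
  if (!f0$converged) return(NA_real_)
  mu0 <- exp(drop(X0 %*% f0$beta))
  ll0 <- if (is.finite(theta))
    sum(dnbinom(y, size = theta, mu = mu0, log = TRUE))
  else sum(dpois(y, lambda = mu0, log = TRUE))
  pchisq(2 * (fit$loglik - ll0), df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; input order (and names)
#' are preserved.
#'
#' @param pvalues Numeric vector in `[0, 1]`; `NA`s propagate.
#' @return Vector of q-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  p.adjust(pvalues, method = "BH")
}

#' Fit and test all candidate sites
#'
#' Orchestrates the model stage: builds designs, estimates dispersion
#' (common across sites by default, per site optionally), fits each site,
#' tests the interaction, and adjusts p-values over all converged fits.
#'
#' @param count_tables Named list of CountTables (one per candidate site).
#' @param dispersion `"common"` (default) or `"site"`.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return `data.frame` with one row per site: coefficients, `se_int`,
#'   `dispersion`, `pvalue`, `qvalue`, `converged`, `reason`, and the allele
#'   summary counts `A_ref`, `A_alt`, `C_ref`, `C_alt` (footprint/flank sums
#'   across replicates).
#' @export
fit_asb_sites <- function(count_tables, dispersion = c("common", "site"),
                          test = c("wald", "lrt")) {
  dispersion <- match.arg(dispersion)
  test <- match.arg(test)
  designs <- lapply(count_tables, build_design)
  if (dispersion == "common") {
    cd <- estimate_common_dispersion(designs)
    fits <- lapply(designs, fit_nb_glm, dispersion = cd$dispersion,
                   df_dispersion = cd$df)
  } else {
    fits <- lapply(designs, fit_nb_glm)
  }
  pv <- if (test == "wald") vapply(fits, test_interaction, numeric(1))
    else mapply(test_interaction_lrt, designs, fits)
  qv <- rep(NA_real_, length(pv))
  qv[!is.na(pv)] <- adjust_fdr(pv[!is.na(pv)])
  sums <- t(vapply(designs, function(d) c(
    A_ref = sum(d$y[d$x_r == 0 & d$x_a == 0]),
    A_alt = sum(d$y[d$x_r == 0 & d$x_a == 1]),
    C_ref = sum(d$y[d$x_r == 1 & d$x_a == 0]),
    C_alt = sum(d$y[d$x_r == 1 & d$x_a == 1])), numeric(4)))
  data.frame(
    site_id = if (is.null(names(count_tables)))
      as.character(seq_along(count_tables)) else names(count_tables),
    beta0 = vapply(fits, `[[`, numeric(1), "beta0"),
    beta_r = vapply(fits, `[[`, numeric(1), "beta_r"),
    beta_a = vapply(fits, `[[`, numeric(1), "beta_a"),
    beta_int = vapply(fits, `[[`, numeric(1), "beta_int"),
    se_int = vapply(fits, `[[`, numeric(1), "se_int"),
    dispersion = vapply(fits, `[[`, numeric(1), "dispersion"),
    pvalue = pv, qvalue = qv,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    reason = vapply(fits, `[[`, character(1), "reason"),
    sums,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Second-round empirical filter on candidate ASB calls
#'
#' Retains calls that are simultaneously (i) significant after FDR control,
#' (ii) strongly motif-disrupting, (iii) sign-consistent — a gain of binding
#' on the variant allele (`beta_int > 0`) must pair with the variant scoring
#' higher (`delta < 0`), so `beta_int * delta < 0` — and (iv) of high allelic
#' magnitude, `|log2((A_ref/A_alt) / (C_ref/C_alt))| >=
#' min_abs_log2_magnitude` with a pseudocount of 1 on each sum.
#'
#' @param calls `data.frame` with columns `qvalue`, `delta`, `beta_int`,
#'   `A_ref`, `A_alt`, `C_ref`, `C_alt` (e.g. [fit_asb_sites()] output merged
#'   with the disruption table).
#' @param fdr_max Maximum q-value (default 0.05, strict `<`).
#' @param min_abs_delta Minimum |deltaPSSM| (default 5, strict `>`).
#' @param min_abs_log2_magnitude Minimum allelic footprint magnitude
#'   (default 1, inclusive `>=`; set 0 to disable).
#' @return `calls` with added columns `magnitude`, `verdict`
#'   (`"significant"` / `"filtered_out"`), and `reasons` (comma-separated
#'   failed gates among `fdr`, `delta`, `inconsistent`, `magnitude`,
#'   `unconverged`).
#' @export
empirical_filter <- function(calls, fdr_max = 0.05, min_abs_delta = 5,
                             min_abs_log2_magnitude = 1) {
  mag <- log2(((calls$A_ref + 1) / (calls$A_alt + 1)) /
                ((calls$C_ref + 1) / (calls$C_alt + 1)))
  reasons <- vapply(seq_len(nrow(calls)), function(i) {
    r <- character()
    if (is.na(calls$qvalue[i]) || is.na(calls$beta_int[i]))
      return("unconverged")
    if (!(calls$qvalue[i] < fdr_max)) r <- c(r, "fdr")
    if (!(abs(calls$delta[i]) > min_abs_delta)) r <- c(r, "delta")
    if (!(calls$beta_int[i] * calls$delta[i] < 0)) r <- c(r, "inconsistent")
    if (!(abs(mag[i]) >= min_abs_log2_magnitude)) r <- c(r, "magnitude")
    paste(r, collapse = ",")
  }, character(1))
  calls$magnitude <- mag
  calls$verdict <- ifelse(reasons == "", "significant", "filtered_out")
  calls$reasons <- reasons
  calls
}

#' Per-SNP summary of retained ASB calls
#'
#' @param calls Output of [empirical_filter()] with a `snp_id` and `motif_id`
#'   column.
#' @return `data.frame` with one row per SNP carrying at least one retained
#'   call: `snp_id`, `n_motifs` (distinct TFs disrupted), `n_calls`,
#'   `motif_ids` (comma-separated).
#' @export
summarize_snps <- function(calls) {
  kept <- calls[calls$verdict == "significant", , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(snp_id = character(), n_motifs = integer(),
                      n_calls = integer(), motif_ids = character(),
                      stringsAsFactors = FALSE))
  sp <- split(kept, kept$snp_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    snp_id = d$snp_id[1],
    n_motifs = length(unique(d$motif_id)),
    n_calls = nrow(d),
    motif_ids = paste(sort(unique(d$motif_id)), collapse = ","),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$snp_id), , drop = FALSE]
}
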