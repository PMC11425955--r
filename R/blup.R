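#' Best linear unbiased prediction of line values for one trait/condition
#'
#' Fits the mixed model `value = mu + year + replicate-within-year + line + e`
#' with the line effect random and year/replicate fixed, by restricted
#' maximum likelihood. The single-random-effect structure admits a stable
#' closed-form EM update on the mixed-model equations (absorbing the
#' random effects through the diagonal of Z'Z), iterated to a relative
#' tolerance of 1e-8. The reported per-line value is the estimated
#' population mean (average fixed-effect prediction over the observed
#' design) plus the line's BLUP, so shrinkage pulls lines with poor
#' replication toward the grand mean.
#'
#' @param observations long data.frame with columns `line_id`, `trait`,
#'   `condition`, `year`, `replicate`, `value`.
#' @param trait,condition the cell to fit.
#' @param tol relative convergence tolerance on the variance components.
#' @param max_iter maximum EM iterations.
#' @return list with `blup` (named per-line vector: mu + line BLUP; NA for
#'   lines without observations), `u` (line effects), `mu` (population
#'   mean), `varcomp` (genetic, residual), `n_iter`, `converged`.
#' @export
fit_blup <- function(observations, trait, condition,
                     tol = 1e-8, max_iter = 500) {
  d <- observations[observations$trait == trait &
                      observations$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for ", trait, "/", condition)
  if (any(!is.finite(d$value))) stop("non-finite trait values")
  all_lines <- unique(observations$line_id)
  line <- factor(d$line_id, levels = sort(unique(d$line_id)))
  if (nlevels(line) < 2) stop("need >= 2 lines with observations")

  yr <- factor(d$year)
  rp <- factor(d$replicate)
  X <- if (nlevels(yr) > 1 && nlevels(rp) > 1)
    stats::model.matrix(~ yr / rp) else if (nlevels(yr) > 1)
      stats::model.matrix(~ yr) else matrix(1, nrow(d), 1)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  y <- d$value
  n <- length(y); p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + line)
  q <- ncol(Z)

  XtX <- crossprod(X); XtZ <- crossprod(X, Z)
  nz <- colSums(Z)                     # Z'Z is diagonal (indicator design)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y * y)

  vy <- stats::var(y)
  if (vy == 0) {
    mu <- mean(y)
    bl <- stats::setNames(rep(mu, q), levels(line))
    out <- stats::setNames(rep(NA_real_, length(all_lines)), all_lines)
    out[names(bl)] <- bl
    return(list(blup = out, u = bl * 0, mu = mu,
                varcomp = c(genetic = 0, residual = 0),
                n_iter = 0L, converged = TRUE))
  }
  se2 <- vy / 2; sg2 <- vy / 2
  floor_v <- vy * 1e-12
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    alpha <- se2 / sg2
    dinv <- 1 / (nz + alpha)
    ## absorb u: beta from the reduced normal equations
    A <- XtX - XtZ %*% (dinv * t(XtZ))
    b <- Xty - XtZ %*% (dinv * Zty)
    beta <- solve(A, b)
    u <- dinv * (Zty - t(XtZ) %*% beta)
    ## tr of the uu block of the inverse MME coefficient matrix
    Tm <- dinv * t(XtZ)                       # q x p
    S <- solve(A)
    tr_cuu <- sum(dinv) + sum((Tm %*% S) * Tm)
    se2_new <- as.numeric(yty - crossprod(beta, Xty) - crossprod(u, Zty)) / (n - p)
    se2_new <- max(se2_new, floor_v)
    sg2_new <- max(as.numeric(crossprod(u) + se2_new * tr_cuu) / q, floor_v)
    delta <- max(abs(se2_new - se2), abs(sg2_new - sg2)) /
      max(se2, sg2, floor_v)
    se2 <- se2_new; sg2 <- sg2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  alpha <- se2 / sg2
  dinv <- 1 / (nz + alpha)
  A <- XtX - XtZ %*% (dinv * t(XtZ))
  beta <- solve(A, Xty - XtZ %*% (dinv * Zty))
  u <- as.numeric(dinv * (Zty - t(XtZ) %*% beta))
  names(u) <- levels(line)
  mu <- mean(X %*% beta)
  out <- stats::setNames(rep(NA_real_, length(all_lines)), all_lines)
  out[names(u)] <- mu + u
  list(blup = out, u = u, mu = mu,
       varcomp = c(genetic = sg2, residual = se2),
       n_iter = it, converged = converged)
}

#' BLUP table over all traits and conditions
#'
#' Applies [fit_blup()] to every trait-by-condition cell present in the
#' observations.
#'
#' @param observations long trait-observation data.frame.
#' @return long data.frame `line_id`, `trait`, `condition`, `blup`, with a
#'   `varcomp` attribute (one row per trait/condition).
#' @export
blup_table <- function(observations) {
  cells <- unique(observations[, c("trait", "condition")])
  res <- list(); vcs <- list()
  for (i in seq_len(nrow(cells))) {
    f <- fit_blup(observations, cells$trait[i], cells$condition[i])
    res[[i]] <- data.frame(line_id = names(f$blup), trait = cells$trait[i],
                           condition = cells$condition[i],
                           blup = as.numeric(f$blup),
                           stringsAsFactors = FALSE)
    vcs[[i]] <- data.frame(trait = cells$trait[i], condition = cells$condition[i],
                           genetic = f$varcomp["genetic"],
                           residual = f$varcomp["residual"],
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  attr(out, "varcomp") <- do.call(rbind, vcs)
  out
}
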