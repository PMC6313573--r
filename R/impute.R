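#' Censored concentration panel
#'
#' Long-format panel of water concentration records: one row per
#' (unit, date, substance). For censored records the stored `value` is the
#' detection limit itself, never a concentration. An `obs_id` column, when
#' present, identifies the sampling event shared by the co-measured
#' substances; otherwise (unit_id, date) is used as the event key.
#'
#' @param records data.frame with columns unit_id, date, substance, value,
#'   censored, dl (extra columns kept)
#' @return data.frame of class `censored_panel`
#' @export
censored_panel <- function(records) {
  req <- c("unit_id", "date", "substance", "value", "censored", "dl")
  if (!all(req %in% names(records))) {
    stop("panel needs columns: ", paste(req, collapse = ", "))
  }
  if (any(records$dl <= 0, na.rm = TRUE)) stop("detection limits must be > 0")
  bad <- records$censored & abs(records$value - records$dl) > 1e-9 * records$dl
  if (any(bad)) stop("censored records must store the DL as value")
  if (!"obs_id" %in% names(records)) {
    records$obs_id <- as.integer(factor(paste(records$unit_id, records$date)))
  }
  class(records) <- c("censored_panel", "data.frame")
  records
}

#' @export
print.censored_panel <- function(x, ...) {
  cat(sprintf("<censored_panel %d records, %d substances, %.1f%% censored>\n",
              nrow(x), length(unique(x$substance)), 100 * mean(x$censored)))
  invisible(x)
}

panel_wide <- function(panel) {
  # one row per sampling event, one column per substance, log scale;
  # censored cells NA with an upper bound at log(DL)
  subs <- sort(unique(panel$substance))
  ev <- !duplicated(panel$obs_id)
  ids <- panel$obs_id[ev]
  n <- length(ids)
  pos <- match(panel$obs_id, ids)
  Y <- UB <- matrix(NA_real_, n, length(subs),
                    dimnames = list(NULL, subs))
  sidx <- match(panel$substance, subs)
  Y[cbind(pos, sidx)] <- ifelse(panel$censored, NA_real_, log(panel$value))
  UB[cbind(pos, sidx)] <- ifelse(panel$censored, log(panel$dl), NA_real_)
  list(Y = Y, UB = UB, ids = ids, date = panel$date[ev], subs = subs,
       unit = panel$unit_id[ev])
}

time_poly <- function(date, window = range(as.numeric(date))) {
  t <- (as.numeric(date) - window[1]) / max(diff(window), 1)
  cbind(t1 = t, t2 = t^2, t3 = t^3)
}

# Moments of N(mu, sd^2) truncated to (-Inf, b]; vectorized.
trunc_moments <- function(mu, sd, b) {
  a <- (b - mu) / sd
  a <- pmax(a, -37)                       # guard pnorm underflow
  h <- stats::dnorm(a) / stats::pnorm(a)
  m <- mu - sd * h
  v <- sd^2 * pmax(1 - a * h - h^2, 1e-12)
  list(mean = m, var = v)
}

# EM for a multivariate normal whose unobserved entries are left-censored at
# known upper bounds (UB; NA where observed). The E-step uses the moments of
# the conditional normal truncated at the bound — exact for one censored
# coordinate per row, approximated by two conditional sweeps when several
# coordinates are censored together. UB = +Inf reduces to plain missing-data
# EM.
em_mvnorm <- function(Y, UB = NULL, maxit = 100, tol = 1e-6, ridge = 1e-6) {
  n <- nrow(Y); p <- ncol(Y)
  if (is.null(UB)) UB <- matrix(Inf, n, p)
  UB2 <- ifelse(is.na(Y) & is.na(UB), Inf, UB)
  mu <- colMeans(Y, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  diag(S)[diag(S) <= 0 | !is.finite(diag(S))] <- 1
  S <- regularize_cov(S, ridge)
  pat <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  warned <- FALSE
  for (it in seq_len(maxit)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (ix in groups) {
      miss <- is.na(Y[ix[1], ])
      Yg <- Y[ix, , drop = FALSE]
      if (!any(miss)) {
        T1 <- T1 + colSums(Yg)
        T2 <- T2 + crossprod(Yg)
        next
      }
      O <- which(!miss); M <- which(miss)
      ng <- length(ix)
      if (length(O) == 0) {
        Eh <- matrix(mu[M], ng, length(M), byrow = TRUE)
        Cm <- S[M, M, drop = FALSE]
      } else {
        Soo <- S[O, O, drop = FALSE]
        Soo <- Soo + diag(1e-8 * mean(diag(Soo)), length(O))
        B <- S[M, O, drop = FALSE] %*% solve(Soo)
        Eh <- matrix(mu[M], ng, length(M), byrow = TRUE) +
          (Yg[, O, drop = FALSE] -
             matrix(mu[O], ng, length(O), byrow = TRUE)) %*% t(B)
        Cm <- S[M, M, drop = FALSE] - B %*% S[O, M, drop = FALSE]
      }
      # truncate at the censoring bounds: conditional sweeps over the
      # censored coordinates (exact when |M| == 1)
      Bnds <- UB2[ix, M, drop = FALSE]
      Vg <- matrix(rep(pmax(diag(Cm), 1e-12), each = ng), ng, length(M))
      if (length(M) == 1) {
        tm <- trunc_moments(Eh[, 1], sqrt(Vg[, 1]), Bnds[, 1])
        Eh[, 1] <- tm$mean; Vg[, 1] <- tm$var
      } else if (any(is.finite(Bnds))) {
        # sweeps of univariate truncation given the current expectations of
        # the other censored coordinates (deterministic Gibbs approximation)
        Eh0 <- Eh
        for (sweep in 1:2) {
          for (j in seq_along(M)) {
            oth <- setdiff(seq_along(M), j)
            Cjo <- Cm[j, oth, drop = FALSE]
            Coo <- Cm[oth, oth, drop = FALSE]
            Coo <- Coo + diag(1e-8 * mean(pmax(diag(Coo), 1e-12)), length(oth))
            Bj <- Cjo %*% solve(Coo)
            cvar <- max(Cm[j, j] - drop(Bj %*% t(Cjo)), 1e-12)
            cmu <- Eh0[, j] + drop((Eh[, oth, drop = FALSE] -
                     Eh0[, oth, drop = FALSE]) %*% t(Bj))
            tm <- trunc_moments(cmu, sqrt(cvar), Bnds[, j])
            Eh[, j] <- ifelse(is.finite(Bnds[, j]), tm$mean, cmu)
            Vg[, j] <- ifelse(is.finite(Bnds[, j]), tm$var, cvar)
          }
        }
      }
      Yfull <- Yg
      Yfull[, M] <- Eh
      T1 <- T1 + colSums(Yfull)
      T2 <- T2 + crossprod(Yfull)
      # second-moment correction: truncated variances on the diagonal,
      # untruncated conditional cross-covariances off it
      Cadd <- Cm * 0
      Cadd[cbind(seq_along(M), seq_along(M))] <- colSums(Vg)
      off <- Cm
      diag(off) <- 0
      T2[M, M] <- T2[M, M] + Cadd + ng * off
    }
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    if (any(!is.finite(mu_new)) || any(!is.finite(S_new))) {
      warning("EM update produced non-finite moments; stopping early")
      break
    }
    S_new <- regularize_cov(S_new, ridge, warn = !warned)
    if (attr(S_new, "regularized") && !warned) warned <- TRUE
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S, iterations = it)
}

regularize_cov <- function(S, ridge = 1e-6, warn = FALSE) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  reg <- FALSE
  if (min(ev) < ridge * max(ev)) {
    if (warn) warning("singular covariance; ridge-regularized")
    bump <- ridge * max(max(ev), 1) + max(0, -min(ev))
    S <- S + diag(bump, nrow(S))
    reg <- TRUE
  }
  attr(S, "regularized") <- reg
  S
}

# one draw from N(mean, sd) truncated to (-Inf, upper]
rtrunc_upper <- function(n, mean, sd, upper) {
  b <- (upper - mean) / sd
  out <- numeric(n)
  easy <- b > -6
  if (any(easy)) {
    pb <- stats::pnorm(b[easy])
    out[easy] <- stats::qnorm(stats::runif(sum(easy)) * pb)
  }
  if (any(!easy)) {
    # far tail: Robert's translated-exponential rejection on the lower tail
    for (i in which(!easy)) {
      a <- -b[i]
      repeat {
        z <- a + stats::rexp(1, a)
        if (stats::runif(1) <= exp(-(z - a)^2 / 2)) { out[i] <- -z; break }
      }
    }
  }
  mean + sd * out
}

#' Bootstrap-EM multiple imputation of a left-censored panel
#'
#' Completes a censored concentration panel by multiple imputation in the
#' style of cross-sectional time-series missing-data engines: the panel is
#' reshaped to one row per sampling event with one (log-)column per
#' substance, a cubic time polynomial is appended as fully observed
#' covariates, and for each of `m` bootstrap resamples an EM algorithm
#' estimates the multivariate normal mean and covariance. The E-step is
#' censoring-aware: censored cells contribute the moments of their
#' conditional normal truncated above at log(DL), so the heavy left-censoring
#' does not bias the estimated means and correlations. Censored cells are
#' then drawn from their conditional distribution given the observed cells
#' under the resample's parameters, truncated to (0, DL]. Uncensored records
#' are untouched and identical across imputations.
#'
#' @param panel a `censored_panel` with >= 2 substances
#' @param m number of imputed datasets (default 8; 5 is usually the minimum
#'   for stable pooling)
#' @param seed RNG seed; each bootstrap replicate uses an independent
#'   substream
#' @param maxit,tol EM controls
#' @return object of class `imputed_panel_set`: list with `m`, `panels`
#'   (list of complete panels carrying an `imputed` flag column) and
#'   `diagnostics` (per-imputed-cell across-imputation mean and sd)
#' @export
em_bootstrap_impute <- function(panel, m = 8, seed = 1L, maxit = 100,
                                tol = 1e-6) {
  stopifnot(inherits(panel, "censored_panel"), m >= 2)
  subs <- unique(panel$substance)
  if (length(subs) < 2) {
    stop("need >= 2 substances to exploit cross-substance correlation")
  }
  if (!any(!panel$censored)) stop("all records censored; nothing to anchor EM")
  if (!any(panel$censored)) {
    pl <- lapply(seq_len(m), function(b) { p <- panel; p$imputed <- FALSE; p })
    return(structure(list(m = m, panels = pl, diagnostics = NULL),
                     class = "imputed_panel_set"))
  }
  w <- panel_wide(panel)
  TP <- time_poly(w$date)
  X <- cbind(w$Y, TP)                       # time columns fully observed
  n <- nrow(X); psub <- ncol(w$Y)
  miss_rows <- which(rowSums(is.na(w$Y)) > 0)
  draws <- array(NA_real_, c(length(miss_rows), psub, m))
  UBX <- cbind(w$UB, matrix(NA_real_, n, ncol(TP)))
  for (b in seq_len(m)) {
    set.seed(seed + 1000L * b)
    bix <- sample.int(n, n, replace = TRUE)
    fit <- em_mvnorm(X[bix, , drop = FALSE], UBX[bix, , drop = FALSE],
                     maxit = maxit, tol = tol)
    for (k in seq_along(miss_rows)) {
      i <- miss_rows[k]
      miss <- is.na(X[i, ])
      O <- which(!miss); M <- which(miss)
      Soo <- fit$sigma[O, O, drop = FALSE]
      B <- fit$sigma[M, O, drop = FALSE] %*% solve(Soo)
      cmu <- fit$mu[M] + drop(B %*% (X[i, O] - fit$mu[O]))
      Cm <- fit$sigma[M, M, drop = FALSE] - B %*% fit$sigma[O, M, drop = FALSE]
      ub <- w$UB[i, M]                      # log(DL) per censored cell
      if (length(M) == 1) {
        z <- rtrunc_upper(1, cmu, sqrt(max(Cm[1, 1], 1e-12)), ub)
      } else {
        z <- NULL
        L <- chol(regularize_cov(Cm, 1e-8))
        for (try in 1:100) {
          cand <- cmu + drop(crossprod(L, stats::rnorm(length(M))))
          if (all(cand <= ub)) { z <- cand; break }
        }
        if (is.null(z)) {                   # componentwise fallback
          z <- rtrunc_upper(length(M), cmu, sqrt(pmax(diag(Cm), 1e-12)), ub)
        }
      }
      draws[k, M, b] <- z
    }
  }
  pl <- lapply(seq_len(m), function(b) {
    Yb <- w$Y
    Yb[miss_rows, ] <- ifelse(is.na(w$Y[miss_rows, , drop = FALSE]),
                              draws[, , b], w$Y[miss_rows, , drop = FALSE])
    p <- panel
    pos <- match(p$obs_id, w$ids)
    sidx <- match(p$substance, colnames(w$Y))
    v <- exp(Yb[cbind(pos, sidx)])
    p$value <- ifelse(p$censored, pmin(v, p$dl), p$value)
    p$imputed <- p$censored
    p$censored <- FALSE
    class(p) <- "data.frame"
    p
  })
  lmean <- apply(draws, c(1, 2), mean)
  lsd <- apply(draws, c(1, 2), stats::sd)
  keep <- which(!is.na(lmean), arr.ind = TRUE)
  diagnostics <- data.frame(obs_id = w$ids[miss_rows[keep[, 1]]],
                            substance = colnames(w$Y)[keep[, 2]],
                            log_mean = lmean[keep], log_sd = lsd[keep])
  structure(list(m = m, panels = pl, diagnostics = diagnostics),
            class = "imputed_panel_set")
}

#' @export
print.imputed_panel_set <- function(x, ...) {
  cat(sprintf("<imputed_panel_set m=%d, %d records each>\n",
              x$m, nrow(x$panels[[1]])))
  invisible(x)
}

#' Pool an imputed panel set to a single complete panel
#'
#' Across-imputation mean per cell (the pooled point estimate used
#' downstream); the across-imputation standard deviation is attached as
#' column `impute_sd`.
#'
#' @param set an `imputed_panel_set`
#' @return complete panel (data.frame) with `imputed` flags
#' @export
pool_imputations <- function(set) {
  stopifnot(inherits(set, "imputed_panel_set"))
  vals <- sapply(set$panels, `[[`, "value")
  out <- set$panels[[1]]
  out$value <- rowMeans(vals)
  out$impute_sd <- apply(vals, 1, stats::sd)
  out
}

#' Naive substitution of censored records
#'
#' Replaces each censored value by a constant rule applied to its own
#' detection limit: DL/2, DL/sqrt(2), or 0.
#'
#' @param panel a `censored_panel`
#' @param rule one of `"half_dl"`, `"dl_over_sqrt2"`, `"zero"`
#' @return complete panel with `imputed` flags
#' @export
substitute_censored <- function(panel,
                                rule = c("half_dl", "dl_over_sqrt2", "zero")) {
  rule <- match.arg(rule)
  rep_val <- switch(rule, half_dl = panel$dl / 2,
                    dl_over_sqrt2 = panel$dl / sqrt(2),
                    zero = 0)
  out <- panel
  out$value <- ifelse(panel$censored, rep_val, panel$value)
  out$imputed <- panel$censored
  out$censored <- FALSE
  class(out) <- "data.frame"
  out
}

#' Artificially censor a complete panel at a DL threshold
#'
#' Simulation harness for evaluating imputation bias on data whose truth is
#' known: every value of the selected substances below `threshold` is flagged
#' censored and stored at the threshold, which becomes its DL. The realized
#' censoring fraction is attached as attribute `censoring_rate`.
#'
#' @param panel complete panel (no censored records)
#' @param threshold DL threshold on the natural scale
#' @param substances substances to censor (default: all)
#' @return a `censored_panel`
#' @export
artificial_censor <- function(panel, threshold, substances = NULL) {
  if (any(panel$censored)) stop("panel must be complete")
  sel <- if (is.null(substances)) rep(TRUE, nrow(panel)) else
    panel$substance %in% substances
  cen <- sel & panel$value < threshold
  if (all(cen[sel])) stop("threshold censors 100% of the selected records")
  out <- panel
  out$value <- ifelse(cen, threshold, panel$value)
  out$censored <- cen
  out$dl <- ifelse(cen, threshold, panel$dl)
  out$dl[sel] <- threshold
  out <- censored_panel(as.data.frame(out))
  attr(out, "censoring_rate") <- mean(cen[sel])
  out
}

#' Imputation bias statistics (AME, RMSE)
#'
#' Compares an estimate against the known truth on the originally-censored
#' cells only: AME = mean |est - true|, RMSE = sqrt(mean (est - true)^2).
#' For an `imputed_panel_set` the across-imputation mean per cell is scored.
#'
#' @param truth complete panel with the true values
#' @param estimate complete panel carrying an `imputed` flag column, or an
#'   `imputed_panel_set`
#' @return list with `ame`, `rmse`, `n_cells`
#' @export
evaluate_imputation <- function(truth, estimate) {
  if (inherits(estimate, "imputed_panel_set")) estimate <- pool_imputations(estimate)
  if (!"imputed" %in% names(estimate)) stop("estimate lacks `imputed` flags")
  key_t <- paste(truth$obs_id, truth$substance)
  key_e <- paste(estimate$obs_id, estimate$substance)
  ix <- match(key_e, key_t)
  if (any(is.na(ix))) stop("record sets differ")
  sel <- estimate$imputed
  if (!any(sel)) stop("no censored cells to evaluate")
  err <- estimate$value[sel] - truth$value[ix][sel]
  list(ame = mean(abs(err)), rmse = sqrt(mean(err^2)), n_cells = sum(sel))
}
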